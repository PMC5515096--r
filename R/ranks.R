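#' Rank ladder
#'
#' The taxonomy model uses ranks only minimally: a fixed, totally ordered
#' ladder from the largest (domain) down to below-variety, plus a
#' distinguished "no rank" value that carries no ordinal and compares to
#' nothing. The default vocabulary is the union of the NCBI and GBIF rank
#' ladders (about 40 levels); `tax_ranks()` returns it in order.
#'
#' @return A character vector of rank labels, largest first. `"no rank"`
#'   is not part of the ordered ladder.
#' @export
tax_ranks <- function() .tax_rank_ladder

.tax_rank_ladder <- c(
  "domain", "superkingdom", "kingdom", "subkingdom", "infrakingdom",
  "superphylum", "phylum", "subphylum", "infraphylum",
  "superclass", "class", "subclass", "infraclass", "parvclass",
  "superorder", "order", "suborder", "infraorder", "parvorder",
  "superfamily", "family", "subfamily", "tribe", "subtribe",
  "genus", "subgenus", "section", "subsection", "series", "subseries",
  "species group", "species subgroup",
  "species", "subspecies", "infraspecificname", "varietas", "variety",
  "subvariety", "forma", "form", "subform"
)

#' Ordinal level of a rank label
#'
#' @param rank Character vector of rank labels (or `NA`/"no rank").
#' @return Integer vector: position in the ladder (1 = domain), `NA` for
#'   unranked or unknown labels.
#' @export
rank_level <- function(rank) {
  out <- match(tolower(trimws(as.character(rank))), .tax_rank_ladder)
  out[is.na(rank) | rank == "no rank"] <- NA_integer_
  out
}

.level_of <- function(label) match(label, .tax_rank_ladder)

#' Rank band predicates
#'
#' Decidable predicates on the rank ladder used by normalization and by the
#' disparate-ranks alignment heuristic. Unranked values yield `FALSE`.
#'
#' @param rank Character vector of rank labels.
#' @return Logical vector.
#' @export
rank_is_species_or_below <- function(rank) {
  lv <- rank_level(rank)
  !is.na(lv) & lv >= .level_of("species")
}

#' @rdname rank_is_species_or_below
#' @export
rank_is_genus_or_below <- function(rank) {
  lv <- rank_level(rank)
  !is.na(lv) & lv >= .level_of("genus")
}

#' @rdname rank_is_species_or_below
#' @export
rank_is_family_or_above <- function(rank) {
  lv <- rank_level(rank)
  !is.na(lv) & lv <= .level_of("family")
}
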