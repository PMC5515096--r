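#' Summary statistics of a taxonomy
#'
#' One-row summary in the spirit of the headline metrics reported for
#' released reference taxonomies: node, tip and internal counts, synonym
#' records, Linnaean-binomial counts, homonym name-string counts (overall
#' and restricted to species- and genus-rank nodes), rank-band counts,
#' maximum nesting depth, maximum child count, branching factor, and
#' incertae sedis / extinct counts.
#'
#' @param t A taxonomy.
#' @return A one-row tibble.
#' @export
tax_stats <- function(t) {
  nd <- t$nodes
  tips <- tax_tip_ids(t)
  internal <- setdiff(nd$id, tips)
  binomial <- grepl("^[A-Z][a-zA-Z-]+ [a-z][a-zA-Z-]+$", nd$name)
  prim <- norm_name(nd$name)
  tab <- table(prim)
  homonym_names <- names(tab)[tab > 1]
  hom_rank <- function(r) {
    sum(vapply(homonym_names, function(nm) {
      ranks <- nd$rank[prim == nm]
      any(!is.na(ranks) & ranks == r)
    }, logical(1)))
  }
  depths <- tax_depths(t)
  kid_counts <- table(nd$parent[!is.na(nd$parent)])
  species_rows <- !is.na(nd$rank) & nd$rank == "species"
  below_species <- !is.na(nd$rank) &
    rank_level(nd$rank) > .level_of("species")
  # internal nodes above species rank subtending no species-rank node
  above_no_species <- vapply(internal, function(id) {
    r <- nd$rank[match(id, nd$id)]
    lv <- rank_level(r)
    if (!is.na(lv) && lv >= .level_of("species")) return(FALSE)
    sub <- subtree_ids(t, id)
    !any(species_rows[match(sub, nd$id)])
  }, logical(1))
  inc <- vapply(flag_split(nd$flags), function(f) "incertae_sedis" %in% f,
                logical(1))
  ext <- vapply(flag_split(nd$flags), function(f) "extinct" %in% f, logical(1))
  n_internal <- length(internal)
  branching <- if (n_internal) sum(!is.na(nd$parent)) / n_internal else NA_real_
  tibble(
    total = nrow(nd),
    synonyms = nrow(t$synonyms),
    internal = n_internal,
    tips = length(tips),
    species_rank = sum(species_rows),
    below_species = sum(below_species),
    above_species_no_species = sum(above_no_species),
    binomials = sum(binomial),
    homonym_names = length(homonym_names),
    homonym_names_species = hom_rank("species"),
    homonym_names_genus = hom_rank("genus"),
    max_depth = if (nrow(nd)) max(depths) else 0L,
    max_children = if (length(kid_counts)) max(kid_counts) else 0L,
    branching_factor = branching,
    incertae_sedis = sum(inc),
    extinct = sum(ext)
  )
}
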