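#' Strip diacritic marks from a name-string
#'
#' Accents, umlauts and other diacritics are removed (Unicode canonical
#' decomposition followed by removal of combining marks) to improve name
#' matching and to follow the nomenclatural codes, which prohibit them.
#' When a name changes, the caller is expected to retain the original
#' spelling as a synonym; [normalize_taxonomy()] does this.
#'
#' @param name Character vector.
#' @return A list with elements `name` (stripped) and `changed` (logical).
#' @export
strip_diacritics <- function(name) {
  out <- stringi::stri_trans_general(name, "NFD; [:Nonspacing Mark:] Remove; NFC")
  list(name = out, changed = !is.na(name) & out != name)
}

.default_containers <- c("incertae sedis", "environmental samples")

#' Collapse container nodes
#'
#' "Containers" are groupings that do not represent taxa (e.g. nodes named
#' "incertae sedis" or "environmental samples"): their members are not more
#' closely related to one another than to the container's siblings. Every
#' node whose primary name matches a container name (exact,
#' case-insensitive) is removed; its children become children of the
#' container's parent and are flagged `was_container`.
#'
#' @param t A taxonomy.
#' @param container_names Names identifying containers.
#' @return The modified taxonomy; errors if a container is a root.
#' @export
collapse_containers <- function(t, container_names = .default_containers) {
  repeat {
    hit <- t$nodes$id[tolower(norm_name(t$nodes$name)) %in%
                        tolower(container_names)]
    if (!length(hit)) return(t)
    id <- hit[1]
    if (is.na(tax_parent_id(t, id))) abort("container node at root")
    kids <- tax_children_ids(t, id)
    for (k in kids) t <- tax_add_flag(t, k, "was_container")
    t <- tax_remove_nodes(t, id, children = "reattach")
  }
}

#' Rename subgenera homonymous with their genus
#'
#' When a subgenus X has the same primary name-string as its containing
#' genus, its name is changed to `"X subgenus X"` (a convention used by
#' sequence-database taxonomies) and the original name is kept as a
#' synonym. This keeps the two records distinguishable during alignment.
#'
#' @param t A taxonomy.
#' @return The modified taxonomy.
#' @export
rename_homonymous_subgenera <- function(t) {
  sub_ids <- t$nodes$id[!is.na(t$nodes$rank) & t$nodes$rank == "subgenus"]
  for (id in sub_ids) {
    nm <- tax_name(t, id)
    anc <- tax_ancestor_ids(t, id)
    anc_rows <- match(anc, t$nodes$id)
    genus <- anc[!is.na(t$nodes$rank[anc_rows]) &
                   t$nodes$rank[anc_rows] == "genus" &
                   t$nodes$name[anc_rows] == nm]
    if (length(genus)) {
      new <- sprintf("%s subgenus %s", nm, nm)
      t$nodes$name[.rowof(t, id)] <- new
      t <- tax_add_synonym(t, id, nm, type = "original")
    }
  }
  t
}

#' Combine sibling taxa with the same name-string
#'
#' Siblings sharing a primary name are merged into one node: the node with
#' the lowest local id survives; children, synonyms and provenance pairs of
#' the others are transferred to it. Applied to a fixed point, so merged
#' children that become homonymous siblings are merged in turn.
#'
#' @param t A taxonomy.
#' @return The modified taxonomy; afterwards no two siblings share a
#'   primary name.
#' @export
merge_sibling_duplicates <- function(t) {
  repeat {
    key <- paste0(ifelse(is.na(t$nodes$parent), "<root>", t$nodes$parent),
                  "\r", t$nodes$name)
    dup_keys <- unique(key[duplicated(key)])
    if (!length(dup_keys)) return(t)
    k <- dup_keys[1]
    ids <- sort(t$nodes$id[key == k])
    survivor <- ids[1]
    losers <- ids[-1]
    for (id in losers) {
      for (kid in tax_children_ids(t, id)) t <- tax_reattach(t, kid, survivor)
      syn <- t$synonyms[t$synonyms$id == id, ]
      for (i in seq_len(nrow(syn))) {
        t <- tax_add_synonym(t, survivor, syn$name[i], syn$type[i])
      }
      t <- tax_add_sources(t, survivor, node_sources(t, id))
    }
    t <- tax_remove_nodes(t, losers, children = "reattach")
  }
}

#' Suppression rules
#'
#' A suppression rule pairs a predicate with an action. Predicate kinds:
#' `name-contains` (primary name contains the argument, case-insensitive),
#' `status-equals` (node status equals one of the argument values),
#' `rank-in` (rank among the argument values), `provenance-equals` (the
#' node's *sole* provenance tag equals the argument). Actions:
#' `drop-record` (remove the record) or `flag-suppressed`.
#'
#' @param kind Predicate kind.
#' @param arg Character vector argument.
#' @param action `"drop-record"` or `"flag-suppressed"`.
#' @return A `suppression_rule` object.
#' @export
suppression_rule <- function(kind = c("name-contains", "status-equals",
                                      "rank-in", "provenance-equals"),
                             arg, action = c("drop-record", "flag-suppressed")) {
  kind <- match.arg(kind)
  action <- match.arg(action)
  if (!length(arg) || any(!nzchar(arg))) abort("suppression rule needs a nonempty argument")
  structure(list(kind = kind, arg = arg, action = action),
            class = "suppression_rule")
}

.rule_matches <- function(t, rule) {
  nd <- t$nodes
  switch(rule$kind,
    "name-contains" = nd$id[stringr::str_detect(
      tolower(nd$name), stringr::fixed(tolower(rule$arg[1])))],
    "status-equals" = nd$id[!is.na(nd$status) & nd$status %in% rule$arg],
    "rank-in" = nd$id[!is.na(nd$rank) & nd$rank %in% rule$arg],
    "provenance-equals" = {
      cnt <- table(t$sources$id)
      sole <- t$sources$id[t$sources$tag %in% rule$arg]
      ids <- intersect(nd$id, sole)
      ids[cnt[as.character(ids)] == 1]
    }
  )
}

#' Apply suppression rules
#'
#' Matching records are removed or flagged `suppressed` according to each
#' rule's action. When a dropped node has children, they are reattached to
#' the nearest unsuppressed ancestor — except for `rank-in` rules
#' (infraspecific suppression), which delete the whole subtree.
#'
#' @param t A taxonomy.
#' @param rules List of [suppression_rule()]s.
#' @return List with elements `taxonomy` and `dropped` (count of removed
#'   or flagged records).
#' @export
apply_suppressions <- function(t, rules) {
  dropped <- 0L
  for (rule in rules) {
    ids <- .rule_matches(t, rule)
    if (!length(ids)) next
    if (rule$action == "flag-suppressed") {
      t <- tax_add_flag(t, ids, "suppressed")
      dropped <- dropped + length(ids)
    } else if (rule$kind == "rank-in") {
      all_ids <- unique(unlist(lapply(ids, subtree_ids, t = t)))
      t <- tax_remove_nodes(t, all_ids, children = "delete")
      dropped <- dropped + length(all_ids)
    } else {
      t <- tax_remove_nodes(t, ids, children = "reattach")
      dropped <- dropped + length(ids)
    }
  }
  list(taxonomy = t, dropped = dropped)
}

#' Annotate extinct taxa from provenance
#'
#' Applies provenance-based extinct heuristics: a node whose *sole*
#' provenance tag matches a configured tag (i.e. it does not come from any
#' other taxonomic source) is flagged `extinct`. The classic use is
#' flagging records that originate only from a paleontological database.
#'
#' @param t A taxonomy.
#' @param sole_tags Character vector of provenance tags.
#' @return The modified taxonomy.
#' @export
annotate_extinct <- function(t, sole_tags) {
  if (!length(sole_tags)) return(t)
  cnt <- table(t$sources$id)
  hit <- t$sources$id[t$sources$tag %in% sole_tags]
  ids <- intersect(t$nodes$id, hit)
  ids <- ids[cnt[as.character(ids)] == 1]
  if (length(ids)) t <- tax_add_flag(t, ids, "extinct")
  t
}

#' Normalize a source taxonomy
#'
#' Runs the four import normalizations in order — diacritics removal
#' (originals kept as synonyms), container collapsing, renaming of
#' subgenera homonymous with their genus, and merging of same-named
#' siblings — optionally preceded by suppression rules and followed by
#' extinct annotation, then guarantees every node carries provenance.
#'
#' @param t A taxonomy.
#' @param container_names Container name list.
#' @param suppressions List of [suppression_rule()]s.
#' @param extinct_sole_tags Tags for [annotate_extinct()].
#' @return The normalized taxonomy.
#' @export
normalize_taxonomy <- function(t, container_names = .default_containers,
                               suppressions = list(),
                               extinct_sole_tags = character()) {
  t <- ensure_provenance(t)
  if (length(suppressions)) t <- apply_suppressions(t, suppressions)$taxonomy
  sd <- strip_diacritics(t$nodes$name)
  orig <- t$nodes$name[sd$changed]
  ids <- t$nodes$id[sd$changed]
  t$nodes$name <- sd$name
  for (i in seq_along(ids)) {
    t <- tax_add_synonym(t, ids[i], orig[i], type = "original")
  }
  # synonyms keep their original spelling (the name index normalizes at
  # lookup time), but never duplicate their node's stripped primary name
  t$synonyms <- dplyr::distinct(t$synonyms, .data$id, .data$name,
                                .keep_all = TRUE)
  prim <- stats::setNames(t$nodes$name, t$nodes$id)
  t$synonyms <- t$synonyms[t$synonyms$name !=
                             prim[as.character(t$synonyms$id)], ]
  t <- collapse_containers(t, container_names)
  t <- rename_homonymous_subgenera(t)
  t <- merge_sibling_duplicates(t)
  t <- annotate_extinct(t, extinct_sole_tags)
  validate_taxonomy(t)
}
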