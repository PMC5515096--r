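#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a taxonomy into one row per node
#'
#' @param x A taxonomy.
#' @param ... Unused.
#' @return A tibble with the node table plus `depth`, `n_children` and
#'   `n_synonyms`.
#' @method tidy taxonomy
#' @export
tidy.taxonomy <- function(x, ...) {
  nd <- x$nodes
  depth <- tax_depths(x)
  kids <- table(nd$parent[!is.na(nd$parent)])
  syn <- table(x$synonyms$id)
  dplyr::mutate(
    nd,
    depth = unname(depth[as.character(.data$id)]),
    n_children = as.integer(kids[as.character(.data$id)]) %|0|% 0L,
    n_synonyms = as.integer(syn[as.character(.data$id)]) %|0|% 0L
  )
}

`%|0|%` <- function(x, y) {
  x[is.na(x)] <- y
  x
}

#' @rdname tidy.taxonomy
#' @method glance taxonomy
#' @export
glance.taxonomy <- function(x, ...) tax_stats(x)

#' Tidy an alignment
#'
#' @param x A `tax_alignment`.
#' @param ... Unused.
#' @return `tidy()`: the pairs tibble with one row per aligned source
#'   node. `glance()`: one row of counts.
#' @method tidy tax_alignment
#' @export
tidy.tax_alignment <- function(x, ...) x$pairs

#' @rdname tidy.tax_alignment
#' @method glance tax_alignment
#' @export
glance.tax_alignment <- function(x, ...) {
  tibble(
    aligned = nrow(x$pairs),
    ambiguous = length(x$ambiguous),
    unmatched = length(x$unmatched),
    multi_candidate_wins = sum(x$telemetry$wins)
  )
}
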