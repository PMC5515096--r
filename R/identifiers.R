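#' Assign stable identifiers across taxonomy versions
#'
#' Carries persistent identifiers (uids) from a previous taxonomy version
#' to a newly assembled one. The previous version is aligned to the new
#' one with the standard heuristic pipeline extended, ahead of all other
#' heuristics, by a *same-source-id* rule: a candidate sharing any
#' provenance pair `(tag, src_id)` with the previous-version node is
#' accepted. Aligned nodes inherit the previous identifier; every
#' remaining node is given a newly minted identifier, strictly greater
#' than all previous ones, in deterministic depth-first order (children in
#' canonical name order). The previous version is used only for identifier
#' assignment — it is never merged. An identifier persists only while its
#' taxon continues to occur in some source taxonomy.
#'
#' @param new Newly assembled taxonomy.
#' @param prev Previous-version taxonomy whose nodes carry uids, or `NULL`
#'   (all identifiers minted).
#' @param sep Optional separation taxonomy for the Separation heuristic.
#' @return List with `taxonomy` (uids filled in), `assignment` (tibble
#'   `id, uid, minted`), and `minted` (the new uids).
#' @export
assign_ids <- function(new, prev = NULL, sep = NULL) {
  order_ids <- .canonical_preorder(new)
  uid <- stats::setNames(rep(NA_integer_, node_count(new)),
                         as.character(new$nodes$id))
  start <- 1L
  if (!is.null(prev)) {
    prev_uid <- prev$nodes$uid
    if (any(is.na(prev_uid))) abort("previous version has nodes without uids")
    if (anyDuplicated(prev_uid)) abort("duplicate identifiers in previous version")
    prev_sources <- split(paste0(prev$sources$tag, ":", prev$sources$src_id),
                          prev$sources$id)
    new_sources <- split(paste0(new$sources$tag, ":", new$sources$src_id),
                         new$sources$id)
    source_id_verdict <- function(n, c) {
      a <- prev_sources[[as.character(n)]]
      b <- new_sources[[as.character(c)]]
      if (length(a) && length(b) && length(intersect(a, b))) "accept"
      else "no-info"
    }
    al <- align_taxonomy(prev, new, sep = sep,
                         extra_verdict = source_id_verdict)
    ord <- order(prev$nodes$uid[match(al$pairs$src_id, prev$nodes$id)])
    for (i in ord) {
      n <- al$pairs$src_id[i]
      w <- as.character(al$pairs$ws_id[i])
      if (is.na(uid[[w]])) uid[[w]] <- prev$nodes$uid[.rowof(prev, n)]
    }
    start <- max(prev_uid) + 1L
  }
  minted <- integer(0)
  nxt <- start
  for (id in order_ids) {
    key <- as.character(id)
    if (is.na(uid[[key]])) {
      uid[[key]] <- nxt
      minted <- c(minted, nxt)
      nxt <- nxt + 1L
    }
  }
  new$nodes$uid <- unname(uid[as.character(new$nodes$id)])
  list(
    taxonomy = new,
    assignment = tibble(id = new$nodes$id, uid = new$nodes$uid,
                        minted = new$nodes$uid %in% minted),
    minted = minted
  )
}

# Depth-first traversal with children in canonical (byte-order) name order;
# the minting order, so reassembly of identical inputs mints identically.
.canonical_preorder <- function(t) {
  name_of <- stats::setNames(t$nodes$name, t$nodes$id)
  out <- integer(0)
  stack <- sort(tax_root_ids(t))
  while (length(stack)) {
    id <- stack[1]
    stack <- stack[-1]
    out <- c(out, id)
    kids <- tax_children_ids(t, id)
    kids <- kids[order(name_of[as.character(kids)], method = "radix")]
    stack <- c(kids, stack)
  }
  out
}
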