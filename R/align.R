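#' Candidate workspace nodes for a source node
#'
#' All workspace nodes sharing any name-string (primary or synonym,
#' diacritic-normalized) with the source node's name-strings.
#'
#' @param src Source taxonomy.
#' @param n Source node id.
#' @param ws Workspace taxonomy.
#' @param ws_index Optional precomputed [name_index()] of `ws`.
#' @return Integer vector of workspace node ids (sorted).
#' @export
candidates <- function(src, n, ws, ws_index = name_index(ws)) {
  names_n <- norm_name(node_names(src, n))
  sort(unique(ws_index$id[ws_index$name %in% names_n]))
}

# -- separation taxonomy ----------------------------------------------------

#' Map separation taxa into a taxonomy
#'
#' The separation taxonomy is a small curated tree of major groups (e.g.
#' Fungi, Metazoa, Lepidoptera) used to forbid alignments across disjoint
#' major clades. It is aligned to a taxonomy by a restricted pipeline:
#' candidates by name-string, kept only if consistent with the image of the
#' nearest already-mapped separation ancestor (containment in that image,
#' or being an ancestor of it), then narrowed by primary-name match; a
#' unique survivor is mapped.
#'
#' @param t Taxonomy to map into.
#' @param sep Separation taxonomy.
#' @return Tibble with columns `sep_id`, `node_id`.
#' @export
separation_map <- function(t, sep) {
  idx <- name_index(t)
  map <- tibble(sep_id = integer(), node_id = integer())
  for (s in tax_preorder(sep)) {
    cands <- candidates(sep, s, t, idx)
    if (!length(cands)) next
    anc <- tax_ancestor_ids(sep, s)
    mapped_anc <- anc[anc %in% map$sep_id]
    if (length(mapped_anc)) {
      z <- map$node_id[match(mapped_anc[1], map$sep_id)]
      ok <- vapply(cands, function(c) {
        is_ancestor(t, z, c) || is_ancestor(t, c, z)
      }, logical(1))
      cands <- cands[ok]
    }
    if (length(cands) > 1L) {
      prim <- t$nodes$name[match(cands, t$nodes$id)]
      same <- cands[norm_name(prim) == norm_name(tax_name(sep, s))]
      if (length(same)) cands <- same
    }
    if (length(cands) == 1L) {
      map <- dplyr::bind_rows(map, tibble(sep_id = s, node_id = cands))
    }
  }
  map
}

#' Separation assignment of every node
#'
#' For each node, the separation taxon of its nearest ancestor-or-self
#' that is mapped to a separation node; `NA` if none. A node's assignment
#' equals its parent's unless the node itself is separation-mapped.
#'
#' @param t Taxonomy.
#' @param sepmap Result of [separation_map()].
#' @return Named integer vector (names = node ids, values = sep node ids).
#' @export
sep_assignment <- function(t, sepmap) {
  assign <- stats::setNames(rep(NA_integer_, node_count(t)), t$nodes$id)
  direct <- stats::setNames(sepmap$sep_id, sepmap$node_id)
  for (id in tax_preorder(t)) {
    key <- as.character(id)
    p <- tax_parent_id(t, id)
    inherited <- if (!is.na(p)) assign[[as.character(p)]] else NA_integer_
    assign[[key]] <- if (!is.na(direct[key])) direct[[key]] else inherited
  }
  assign
}

# -- verdicts ---------------------------------------------------------------
# Each heuristic maps a (source node, candidate) pair to one of
# "accept", "reject", "no-info".

#' Alignment heuristic verdicts
#'
#' The six ordered heuristics each return `"accept"`, `"reject"` or
#' `"no-info"` for a (source node, workspace candidate) pair:
#'
#' * **Separation** — reject when the two nodes sit in disjoint separation
#'   taxa; accept when equal; no-info when either is unassigned or one
#'   separation taxon contains the other.
#' * **Disparate ranks** — reject when one node is ranked genus-or-below
#'   and the other family-or-above.
#' * **Lineage** — accept when the source node's quasi-parent name (nearest
#'   ancestor whose name is not a generated placeholder) occurs among the
#'   candidate's ancestors' name-strings, or symmetrically.
#' * **Overlap** — accept when the source subtree contains an aligned node
#'   whose image falls inside the candidate's subtree; reject when both
#'   subtrees contain aligned material but none of the source images fall
#'   inside the candidate.
#' * **Proximity** — accept a candidate that descends from the image of
#'   the source node's nearest aligned ancestor; never rejects.
#' * **Same name-string** — accept on exact primary/primary name equality
#'   (post-normalization).
#'
#' @param n Source node id.
#' @param c Workspace candidate node id.
#' @param src,ws Source and workspace taxonomies.
#' @param sep Separation taxonomy.
#' @param src_assign,ws_assign [sep_assignment()] vectors.
#' @param pairs Named integer vector of alignments so far
#'   (names = source ids, values = workspace ids).
#' @return One of `"accept"`, `"reject"`, `"no-info"`.
#' @name verdicts
NULL

#' @rdname verdicts
#' @export
separation_verdict <- function(n, c, sep, src_assign, ws_assign) {
  a_n <- src_assign[[as.character(n)]]
  a_c <- ws_assign[[as.character(c)]]
  if (is.na(a_n) || is.na(a_c)) return("no-info")
  if (a_n == a_c) return("accept")
  if (is_ancestor(sep, a_n, a_c) || is_ancestor(sep, a_c, a_n)) return("no-info")
  "reject"
}

#' @rdname verdicts
#' @export
ranks_verdict <- function(n, c, src, ws) {
  rn <- src$nodes$rank[.rowof(src, n)]
  rc <- ws$nodes$rank[.rowof(ws, c)]
  if ((rank_is_genus_or_below(rn) && rank_is_family_or_above(rc)) ||
      (rank_is_genus_or_below(rc) && rank_is_family_or_above(rn))) {
    return("reject")
  }
  "no-info"
}

.quasi_parent_name <- function(t, id) {
  for (a in tax_ancestor_ids(t, id)) {
    if (!has_flag(t, a, "hidden")) return(norm_name(tax_name(t, a)))
  }
  NA_character_
}

.ancestor_names <- function(t, id) {
  anc <- tax_ancestor_ids(t, id)
  norm_name(unlist(lapply(anc, node_names, t = t), use.names = FALSE))
}

#' @rdname verdicts
#' @export
lineage_verdict <- function(n, c, src, ws) {
  qn <- .quasi_parent_name(src, n)
  if (!is.na(qn) && qn %in% .ancestor_names(ws, c)) return("accept")
  qc <- .quasi_parent_name(ws, c)
  if (!is.na(qc) && qc %in% .ancestor_names(src, n)) return("accept")
  "no-info"
}

#' @rdname verdicts
#' @export
overlap_verdict <- function(n, c, src, ws, pairs) {
  desc <- setdiff(subtree_ids(src, n), n)
  aligned_desc <- desc[as.character(desc) %in% names(pairs)]
  if (!length(aligned_desc)) return("no-info")
  images <- pairs[as.character(aligned_desc)]
  in_c <- vapply(images, function(im) is_ancestor(ws, c, im), logical(1))
  if (any(in_c)) return("accept")
  # reject only if the candidate's subtree holds aligned material of its own
  c_sub <- subtree_ids(ws, c)
  if (any(pairs %in% c_sub)) return("reject")
  "no-info"
}

#' @rdname verdicts
#' @export
proximity_verdict <- function(n, c, src, ws, pairs) {
  for (a in tax_ancestor_ids(src, n)) {
    key <- as.character(a)
    if (key %in% names(pairs)) {
      z <- pairs[[key]]
      return(if (is_ancestor(ws, z, c)) "accept" else "no-info")
    }
  }
  "no-info"
}

#' @rdname verdicts
#' @export
same_name_verdict <- function(n, c, src, ws) {
  if (norm_name(tax_name(src, n)) == norm_name(tax_name(ws, c))) "accept"
  else "no-info"
}

.heuristic_labels <- c(
  source_id = "Same source id",
  separation = "Separation",
  ranks = "Disparate ranks",
  lineage = "Lineage",
  overlap = "Overlap",
  proximity = "Proximity",
  same_name = "Same name-string"
)

# -- pipeline ---------------------------------------------------------------

# Run the ordered heuristics over a candidate set for one source node.
# Returns list(status, winner, decider, n_candidates).
.align_node_pipeline <- function(n, cands, ctx, heuristics) {
  live <- cands
  if (!length(live)) {
    return(list(status = "unmatched", winner = NA_integer_,
                decider = NA_character_, n_candidates = 0L))
  }
  verdict_of <- function(h, c) {
    switch(h,
      source_id = ctx$source_id_verdict(n, c),
      separation = separation_verdict(n, c, ctx$sep, ctx$src_assign, ctx$ws_assign),
      ranks = ranks_verdict(n, c, ctx$src, ctx$ws),
      lineage = lineage_verdict(n, c, ctx$src, ctx$ws),
      overlap = overlap_verdict(n, c, ctx$src, ctx$ws, ctx$pairs),
      proximity = proximity_verdict(n, c, ctx$src, ctx$ws, ctx$pairs),
      same_name = same_name_verdict(n, c, ctx$src, ctx$ws)
    )
  }
  for (h in heuristics) {
    before <- length(live)
    v <- vapply(live, function(c) verdict_of(h, c), character(1))
    live <- live[v != "reject"]
    acc <- live[v[v != "reject"] == "accept"]
    if (length(acc)) live <- acc
    if (!length(live)) {
      return(list(status = "unmatched", winner = NA_integer_,
                  decider = NA_character_, n_candidates = 0L))
    }
    if (length(live) == 1L && before >= 2L) {
      return(list(status = "aligned", winner = live,
                  decider = .heuristic_labels[[h]], n_candidates = before))
    }
  }
  if (length(live) == 1L) {
    list(status = "aligned", winner = live, decider = NA_character_,
         n_candidates = 1L)
  } else {
    list(status = "ambiguous", winner = NA_integer_,
         decider = NA_character_, n_candidates = length(live))
  }
}

.default_heuristics <- c("separation", "ranks", "lineage", "overlap",
                         "proximity", "same_name")

#' Align a single source node
#'
#' Runs candidate generation and the ordered heuristic pipeline for one
#' source node: at each heuristic, rejected candidates are discarded; if
#' any are accepted the set narrows to the accepted ones, and a heuristic
#' that narrows two-or-more candidates to exactly one decides the
#' alignment. A single initial candidate is still subject to the rejection
#' heuristics. Zero survivors means `unmatched`; two or more after all
#' heuristics means `ambiguous`.
#'
#' @inheritParams align_taxonomy
#' @param n Source node id.
#' @param pairs Named integer vector of alignments so far (source id to
#'   workspace id), used by Overlap and Proximity.
#' @return List with `status` (`"aligned"`, `"ambiguous"`, `"unmatched"`),
#'   `winner`, `decider` and `n_candidates`.
#' @export
align_node <- function(src, n, ws, sep = NULL,
                       pairs = stats::setNames(integer(0), character(0))) {
  src_assign <- ws_assign <- NULL
  heuristics <- .default_heuristics
  if (!is.null(sep)) {
    src_assign <- sep_assignment(src, separation_map(src, sep))
    ws_assign <- sep_assignment(ws, separation_map(ws, sep))
  } else {
    heuristics <- setdiff(heuristics, "separation")
  }
  ctx <- list(src = src, ws = ws, sep = sep, src_assign = src_assign,
              ws_assign = ws_assign, pairs = pairs)
  .align_node_pipeline(n, candidates(src, n, ws), ctx, heuristics)
}

#' Align one source taxonomy to the workspace
#'
#' Maps source nodes to workspace nodes by candidate generation on
#' name-strings followed by the ordered heuristics (see [verdicts]).
#' Alignment runs in two passes: tips first, then internal nodes bottom-up,
#' so that tip alignments inform the Overlap heuristic for internal nodes.
#' A single initial candidate is still subjected to the rejection
#' heuristics; a node whose candidate set cannot be narrowed to one is left
#' unaligned (`ambiguous` if more than one survives, `unmatched` if none).
#'
#' @param src Source taxonomy (normalized).
#' @param ws Workspace taxonomy.
#' @param sep Optional separation taxonomy.
#' @param adjustments Optional tibble of `force-align` / `forbid-align`
#'   directives resolved against `src` and `ws` (see [apply_directives()]).
#' @param extra_verdict Optional function `(n, c) -> verdict` run before
#'   all heuristics (used for the same-source-id rule of [assign_ids()]).
#' @return A `tax_alignment`: list with `pairs` (tibble `src_id, ws_id,
#'   decider, n_candidates, pass`), `ambiguous`, `unmatched` (id vectors),
#'   and `telemetry` (tibble `heuristic, wins`, the per-heuristic counts of
#'   multi-candidate decisions).
#' @export
align_taxonomy <- function(src, ws, sep = NULL, adjustments = NULL,
                           extra_verdict = NULL) {
  ws_index <- name_index(ws)
  ws_id_sets <- split(ws_index$id, ws_index$name)
  src_index <- name_index(src)
  src_names_by_id <- split(src_index$name, src_index$id)
  src_assign <- ws_assign <- NULL
  if (!is.null(sep)) {
    src_assign <- sep_assignment(src, separation_map(src, sep))
    ws_assign <- sep_assignment(ws, separation_map(ws, sep))
  }
  heuristics <- .default_heuristics
  if (is.null(sep)) heuristics <- setdiff(heuristics, "separation")
  if (!is.null(extra_verdict)) heuristics <- c("source_id", heuristics)

  forced <- forbidden <- NULL
  if (!is.null(adjustments) && nrow(adjustments)) {
    forced <- .resolve_adjustments(adjustments, "force-align", src, ws)
    forbidden <- .resolve_adjustments(adjustments, "forbid-align", src, ws)
  }

  pairs <- stats::setNames(integer(0), character(0))
  rec_src <- rec_ws <- rec_nc <- rec_pass <- integer(0)
  rec_dec <- character(0)
  ambiguous <- integer(0)
  unmatched <- integer(0)

  ctx <- list(src = src, ws = ws, sep = sep, src_assign = src_assign,
              ws_assign = ws_assign, source_id_verdict = extra_verdict)

  tips <- sort(tax_tip_ids(src))
  internals <- setdiff(tax_postorder(src), tips)
  plan <- list(`1` = tips, `2` = internals)

  for (pass in names(plan)) {
    for (n in plan[[pass]]) {
      key <- as.character(n)
      if (!is.null(forced) && key %in% names(forced)) {
        pairs[key] <- forced[[key]]
        rec_src <- c(rec_src, n)
        rec_ws <- c(rec_ws, forced[[key]])
        rec_dec <- c(rec_dec, "forced")
        rec_nc <- c(rec_nc, NA_integer_)
        rec_pass <- c(rec_pass, as.integer(pass))
        next
      }
      cands <- sort(unique(unlist(ws_id_sets[src_names_by_id[[key]]],
                                  use.names = FALSE)))
      if (!is.null(forbidden) && key %in% names(forbidden)) {
        cands <- setdiff(cands, forbidden[[key]])
      }
      ctx$pairs <- pairs
      res <- .align_node_pipeline(n, cands, ctx, heuristics)
      if (res$status == "aligned") {
        pairs[key] <- res$winner
        rec_src <- c(rec_src, n)
        rec_ws <- c(rec_ws, res$winner)
        rec_dec <- c(rec_dec, res$decider)
        rec_nc <- c(rec_nc, res$n_candidates)
        rec_pass <- c(rec_pass, as.integer(pass))
      } else if (res$status == "ambiguous") {
        ambiguous <- c(ambiguous, n)
      } else {
        unmatched <- c(unmatched, n)
      }
    }
  }

  pair_tbl <- tibble(src_id = rec_src, ws_id = rec_ws, decider = rec_dec,
                     n_candidates = rec_nc, pass = rec_pass)
  wins <- table(factor(pair_tbl$decider, levels = unname(.heuristic_labels)))
  telemetry <- tibble(heuristic = names(wins), wins = as.integer(wins))
  structure(
    list(pairs = pair_tbl, ambiguous = ambiguous, unmatched = unmatched,
         telemetry = telemetry, src_tag = src$tag, ws_tag = ws$tag),
    class = "tax_alignment"
  )
}

# Resolve force/forbid adjustment selectors to (src node -> ws node) maps.
.resolve_adjustments <- function(adjustments, kind, src, ws) {
  rows <- adjustments[adjustments$kind == kind, ]
  if (!nrow(rows)) return(NULL)
  out <- integer(0)
  for (i in seq_len(nrow(rows))) {
    sid <- tryCatch(
      resolve_selector(src, rows$name[i], rows$context[i]),
      error = function(e) NA_integer_
    )
    wid <- tryCatch(
      resolve_selector(ws, rows$target_name[i], rows$target_context[i]),
      error = function(e) NA_integer_
    )
    if (!is.na(sid) && !is.na(wid)) out[as.character(sid)] <- wid
  }
  if (length(out)) out else NULL
}

#' @export
print.tax_alignment <- function(x, ...) {
  cat(sprintf("<alignment %s -> %s: %d aligned, %d ambiguous, %d unmatched>\n",
              x$src_tag, x$ws_tag, nrow(x$pairs), length(x$ambiguous),
              length(x$unmatched)))
  invisible(x)
}

#' Write alignment telemetry as TSV
#'
#' One row per heuristic with its count of multi-candidate wins.
#'
#' @param a A `tax_alignment`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_telemetry <- function(a, path) {
  readr::write_tsv(a$telemetry, path)
  invisible(path)
}
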