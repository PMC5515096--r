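#' Classify an unaligned source node
#'
#' An unaligned source node whose subtree contains no aligned node is a
#' *graft*. Otherwise, let P be the set of workspace parents of the images
#' of its aligned children: more than one parent means the source hierarchy
#' is incompatible with the workspace (*conflict*); exactly one makes the
#' node an *insertion candidate*, which the coverage rule of
#' [merge_taxonomies()] refines to insertion or *absorption*.
#'
#' @param src Source taxonomy.
#' @param n Unaligned source node id.
#' @param a A `tax_alignment` of `src` into the workspace `ws`.
#' @param ws Workspace taxonomy.
#' @return One of `"graft"`, `"conflict"`, `"insertion-candidate"`.
#' @export
classify_source_node <- function(src, n, a, ws) {
  pairs <- stats::setNames(a$pairs$ws_id, a$pairs$src_id)
  if (as.character(n) %in% names(pairs)) abort("node is aligned")
  desc <- setdiff(subtree_ids(src, n), n)
  aligned_desc <- desc[as.character(desc) %in% names(pairs)]
  if (!length(aligned_desc)) return("graft")
  kids <- tax_children_ids(src, n)
  imgs <- pairs[as.character(kids)]
  imgs <- imgs[!is.na(imgs)]
  parents <- unique(vapply(imgs, function(w) {
    p <- tax_parent_id(ws, w)
    if (is.na(p)) -1L else p
  }, integer(1)))
  if (length(parents) > 1L) "conflict" else "insertion-candidate"
}

#' Attachment point for a graft
#'
#' A graft rooted at `r` attaches as a child of the nearest common
#' ancestor of the images of `r`'s aligned source-siblings (for a single
#' image, its parent). The graft is flagged *incertae sedis* when that
#' ancestor is not the parent of every sibling image — i.e. when the exact
#' position among the siblings is unknowable. With no aligned sibling, the
#' graft attaches under the placement of the nearest placed ancestor,
#' always incertae sedis.
#'
#' @param src Source taxonomy.
#' @param r Graft root id in `src`.
#' @param placement Named integer vector mapping placed source ids to
#'   workspace ids (images and copies).
#' @param ws Workspace taxonomy.
#' @param aligned_keys Character keys of `placement` that are alignments
#'   (defaults to all of them).
#' @return List with `node` (workspace attachment id) and `incertae_sedis`.
#' @export
attachment_point <- function(src, r, placement, ws,
                             aligned_keys = names(placement)) {
  par <- tax_parent_id(src, r)
  M <- integer(0)
  if (!is.na(par)) {
    sibs <- setdiff(tax_children_ids(src, par), r)
    keys <- intersect(as.character(sibs), aligned_keys)
    M <- unique(unname(placement[keys]))
  }
  if (length(M)) {
    att <- tryCatch(mrca(ws, M), error = function(e) NA_integer_)
    if (!is.na(att)) {
      inc <- any(vapply(M, function(m) {
        p <- tax_parent_id(ws, m)
        is.na(p) || p != att
      }, logical(1)))
      return(list(node = att, incertae_sedis = inc))
    }
  }
  for (anc in tax_ancestor_ids(src, r)) {
    key <- as.character(anc)
    if (key %in% names(placement)) {
      return(list(node = placement[[key]], incertae_sedis = TRUE))
    }
  }
  abort("graft has no aligned sibling or ancestor (unalignable source root)")
}

# Copy the subtree of src rooted at r into ws under ws parent `under`.
# Ambiguously aligned nodes are elided (never copied); their children are
# hoisted to the copy of their parent. Returns list(ws = updated ws,
# placement = named map of copied src ids to new ws ids).
.copy_subtree <- function(ws, src, r, under, ambiguous, root_flags = character()) {
  nxt <- next_node_id(ws)
  ids <- parents <- srcids <- integer(0)
  flags <- character(0)
  walk <- function(id, parent_ws, extra_flags) {
    if (id %in% ambiguous) {
      for (k in tax_children_ids(src, id)) walk(k, parent_ws, character())
      return(invisible())
    }
    nid <- nxt
    nxt <<- nxt + 1L
    f <- flag_join(c(setdiff(flag_split(src$nodes$flags[.rowof(src, id)])[[1]],
                             "hidden"), extra_flags))
    ids <- c(ids, nid)
    ids <<- ids
    parents <<- c(parents, as.integer(parent_ws))
    srcids <<- c(srcids, id)
    flags <<- c(flags, f)
    for (k in tax_children_ids(src, id)) walk(k, nid, character())
  }
  walk(r, under, root_flags)
  srows <- match(srcids, src$nodes$id)
  ws$nodes <- dplyr::bind_rows(ws$nodes, tibble(
    id = ids, parent = parents, name = src$nodes$name[srows],
    rank = src$nodes$rank[srows], flags = flags, uid = NA_integer_,
    status = src$nodes$status[srows]
  ))
  m <- match(src$synonyms$id, srcids)
  syn <- tibble(id = ids[m[!is.na(m)]],
                name = src$synonyms$name[!is.na(m)],
                type = src$synonyms$type[!is.na(m)])
  if (nrow(syn)) ws$synonyms <- dplyr::bind_rows(ws$synonyms, syn)
  m <- match(src$sources$id, srcids)
  sp <- tibble(id = ids[m[!is.na(m)]],
               tag = src$sources$tag[!is.na(m)],
               src_id = src$sources$src_id[!is.na(m)])
  missing <- setdiff(ids, unique(sp$id))
  if (length(missing)) {
    sp <- dplyr::bind_rows(sp, tibble(
      id = missing, tag = src$tag,
      src_id = as.character(srcids[match(missing, ids)])
    ))
  }
  ws$sources <- dplyr::bind_rows(ws$sources, sp)
  list(ws = ws, placement = stats::setNames(ids, srcids))
}

#' Merge one aligned source into the workspace
#'
#' Implements the structural merge of unaligned source nodes. Aligned
#' nodes contribute synonyms, provenance pairs and (when the workspace
#' lacks one) ranks to their images. Unaligned nodes with aligned
#' descendants are processed bottom-up: a node whose aligned children's
#' images share one workspace parent is an insertion candidate; candidates
#' under a common parent `z` are inserted only if, jointly, their target
#' children cover every proper (non-incertae-sedis) child of `z` —
#' otherwise they are absorbed, so that a higher-priority claim that some
#' child is a proper child of `z` is never lost. Incompatible nodes
#' (aligned children under different parents) are conflicts and are
#' discarded. Maximal unaligned subtrees without aligned descendants are
#' grafted at their [attachment_point()]; ambiguously aligned nodes are
#' skipped and never copied. Insertions are never flagged incertae sedis.
#'
#' @param ws Workspace taxonomy.
#' @param src Normalized source taxonomy.
#' @param a `tax_alignment` of `src` into `ws`.
#' @return List with `taxonomy` (the updated workspace) and `report` (a
#'   one-row `tax_merge_report` tibble with columns `source, total, copied,
#'   aligned, absorbed, conflict, ambiguous, incertae_sedis`).
#' @export
merge_taxonomies <- function(ws, src, a) {
  pairs <- stats::setNames(a$pairs$ws_id, as.character(a$pairs$src_id))
  ambiguous <- a$ambiguous
  total <- node_count(src)
  absorbed <- 0L
  conflict <- 0L
  copied <- 0L
  n_incertae <- 0L

  # aligned nodes: merge metadata into their images (batched)
  if (nrow(a$pairs)) {
    ap <- a$pairs
    wrows <- match(ap$ws_id, ws$nodes$id)
    srows <- match(ap$src_id, src$nodes$id)
    # primary name-strings that differ become synonyms of the image
    differs <- norm_name(src$nodes$name[srows]) != norm_name(ws$nodes$name[wrows])
    syn_add <- dplyr::bind_rows(
      tibble(id = ap$ws_id[differs], name = src$nodes$name[srows][differs],
             type = "synonym"),
      dplyr::inner_join(src$synonyms,
                        tibble(sid = ap$src_id, id2 = ap$ws_id),
                        by = c(id = "sid")) |>
        dplyr::transmute(id = .data$id2, name = .data$name, type = .data$type)
    )
    if (nrow(syn_add)) {
      prim <- stats::setNames(ws$nodes$name, ws$nodes$id)
      syn_add <- syn_add[syn_add$name != prim[as.character(syn_add$id)], ]
      have <- paste0(ws$synonyms$id, "\r", ws$synonyms$name)
      syn_add <- syn_add[!(paste0(syn_add$id, "\r", syn_add$name) %in% have), ]
      syn_add <- dplyr::distinct(syn_add, .data$id, .data$name, .keep_all = TRUE)
      ws$synonyms <- dplyr::bind_rows(ws$synonyms, syn_add)
    }
    src_add <- dplyr::inner_join(src$sources,
                                 tibble(sid = ap$src_id, id2 = ap$ws_id),
                                 by = c(id = "sid")) |>
      dplyr::transmute(id = .data$id2, tag = .data$tag, src_id = .data$src_id)
    ws$sources <- dplyr::distinct(dplyr::bind_rows(ws$sources, src_add))
    fill <- is.na(ws$nodes$rank[wrows])
    ws$nodes$rank[wrows[fill]] <- src$nodes$rank[srows[fill]]
    keep_out <- c("incertae_sedis", "was_container", "hidden", "unplaced")
    has_extra <- which(nzchar(src$nodes$flags[srows]))
    for (i in has_extra) {
      extra <- setdiff(flag_split(src$nodes$flags[srows[i]])[[1]], keep_out)
      for (f in extra) ws <- tax_add_flag(ws, ap$ws_id[i], f)
    }
  }

  # which source subtrees contain aligned nodes
  has_ad <- stats::setNames(logical(node_count(src)), src$nodes$id)
  for (n in tax_postorder(src)) {
    key <- as.character(n)
    kid_keys <- as.character(tax_children_ids(src, n))
    has_ad[key] <- key %in% names(pairs) || any(has_ad[kid_keys])
  }

  placement <- pairs  # src id -> ws id for aligned and (later) copied nodes
  targets <- list()   # src id -> ws ids its content maps to (hoisted)
  decided <- character(0)

  target_of <- function(n) {
    out <- integer(0)
    for (k in tax_children_ids(src, n)) {
      key <- as.character(k)
      if (key %in% names(placement)) {
        out <- c(out, placement[[key]])
      } else if (has_ad[key]) {
        out <- c(out, targets[[key]])
      }
    }
    unique(out)
  }
  parent_set <- function(tt) {
    unique(vapply(tt, function(w) {
      p <- tax_parent_id(ws, w)
      if (is.na(p)) -1L else p
    }, integer(1)))
  }

  post <- tax_postorder(src)
  pending <- post[vapply(post, function(n) {
    key <- as.character(n)
    !(key %in% names(pairs)) && has_ad[key]
  }, logical(1))]

  for (n in pending) {
    key <- as.character(n)
    if (key %in% decided) next
    tt <- target_of(n)
    targets[[key]] <- tt
    if (n %in% ambiguous) {
      decided <- c(decided, key)
      next
    }
    P <- parent_set(tt)
    if (length(P) > 1L) {
      conflict <- conflict + 1L
      decided <- c(decided, key)
      next
    }
    z <- P
    if (z == -1L) {  # images are workspace roots: treat as absorbed container
      absorbed <- absorbed + 1L
      decided <- c(decided, key)
      next
    }
    # joint coverage decision over sibling insertion candidates under z
    par <- tax_parent_id(src, n)
    sibs <- if (is.na(par)) n else tax_children_ids(src, par)
    group <- n
    for (s in setdiff(sibs, n)) {
      skey <- as.character(s)
      if (skey %in% decided || skey %in% names(pairs) || !has_ad[skey] ||
          s %in% ambiguous) next
      st <- target_of(s)
      if (length(st) && identical(parent_set(st), z)) {
        targets[[skey]] <- st
        group <- c(group, s)
      }
    }
    covered <- unique(unlist(c(list(tt), targets[as.character(setdiff(group, n))])))
    zkids <- tax_children_ids(ws, z)
    proper <- zkids[!has_flag(ws, zkids, "incertae_sedis")]
    if (all(proper %in% covered)) {
      for (m in group) {
        mt <- targets[[as.character(m)]]
        nid <- next_node_id(ws)
        row <- src$nodes[.rowof(src, m), ]
        ws <- taxonomy(
          dplyr::bind_rows(ws$nodes, tibble(
            id = nid, parent = z, name = row$name, rank = row$rank,
            flags = flag_join(setdiff(flag_split(row$flags)[[1]],
                                      c("hidden", "incertae_sedis"))),
            uid = NA_integer_, status = row$status
          )),
          ws$synonyms, ws$sources, tag = ws$tag
        )
        syn <- src$synonyms[src$synonyms$id == m, ]
        for (j in seq_len(nrow(syn))) {
          ws <- tax_add_synonym(ws, nid, syn$name[j], syn$type[j])
        }
        ws <- tax_add_sources(ws, nid, node_sources(src, m))
        for (w in mt) ws <- tax_reattach(ws, w, nid)
        placement[as.character(m)] <- nid
        copied <- copied + 1L
        decided <- c(decided, as.character(m))
      }
    } else {
      absorbed <- absorbed + length(group)
      decided <- c(decided, as.character(group))
    }
  }

  # grafts: maximal unaligned, unambiguous subtrees with no aligned nodes
  is_aligned <- function(id) as.character(id) %in% names(pairs)
  graft_roots <- Filter(function(n) {
    key <- as.character(n)
    if (is_aligned(n) || has_ad[key] || n %in% ambiguous) return(FALSE)
    p <- tax_parent_id(src, n)
    is.na(p) || is_aligned(p) || has_ad[as.character(p)] || p %in% ambiguous
  }, tax_preorder(src))

  for (r in graft_roots) {
    att <- tryCatch(
      attachment_point(src, r, placement, ws, aligned_keys = names(pairs)),
      # nothing to attach to anywhere: the subtree becomes a new root of
      # the workspace forest, flagged unplaced
      error = function(e) list(node = NA_integer_, incertae_sedis = FALSE,
                               unplaced = TRUE)
    )
    flags <- c(if (att$incertae_sedis) "incertae_sedis",
               if (isTRUE(att$unplaced)) "unplaced")
    res <- .copy_subtree(ws, src, r, att$node, ambiguous,
                         root_flags = flags)
    ws <- res$ws
    placement[names(res$placement)] <- res$placement
    copied <- copied + length(res$placement)
    if (att$incertae_sedis) n_incertae <- n_incertae + 1L
  }

  n_amb <- total - copied - nrow(a$pairs) - absorbed - conflict
  report <- tibble(
    source = src$tag, total = total, copied = copied,
    aligned = nrow(a$pairs), absorbed = absorbed, conflict = conflict,
    ambiguous = n_amb, incertae_sedis = n_incertae
  )
  class(report) <- c("tax_merge_report", class(report))
  list(taxonomy = validate_taxonomy(ws), report = report)
}

#' Assemble a taxonomy from prioritized sources
#'
#' Folds [merge_taxonomies()] over the sources left to right, starting
#' from an empty workspace: the first source (the separation taxonomy, if
#' given, is seeded first) is copied wholesale; each later source is
#' aligned to the workspace and merged. Per-source pre-alignment directives
#' and final patches are applied; one merge report per source is returned
#' along with per-source alignment telemetry.
#'
#' @param sources List of normalized taxonomies in priority order
#'   (highest first).
#' @param sep Optional separation taxonomy; merged first and used by the
#'   Separation heuristic throughout.
#' @param source_patches Optional named list (by source tag) of directive
#'   lists applied to each source before alignment.
#' @param final_patches Optional directive list applied to the finished
#'   workspace.
#' @param prev Optional previous-version taxonomy carrying uids; when
#'   given, identifiers are carried over with [assign_ids()].
#' @param strict Abort on the first failing directive.
#' @return List with `taxonomy`, `reports` (merge-report tibble, one row
#'   per source), and `alignments` (list of `tax_alignment`s by tag).
#' @export
assemble <- function(sources, sep = NULL, source_patches = list(),
                     final_patches = list(), prev = NULL, strict = FALSE) {
  ws <- NULL
  reports <- list()
  alignments <- list()
  queue <- c(if (!is.null(sep)) list(sep), sources)
  for (src in queue) {
    src <- ensure_provenance(src)
    adjustments <- NULL
    ds <- source_patches[[src$tag]]
    if (!is.null(ds) && length(ds)) {
      pr <- apply_directives(src, ds, strict = strict)
      src <- pr$taxonomy
      adjustments <- pr$adjustments
    }
    if (is.null(ws)) {
      ws <- src
      ws$tag <- "workspace"
      rep1 <- tibble(
        source = src$tag, total = node_count(src), copied = node_count(src),
        aligned = 0L, absorbed = 0L, conflict = 0L, ambiguous = 0L,
        incertae_sedis = 0L
      )
      class(rep1) <- c("tax_merge_report", class(rep1))
      reports[[src$tag]] <- rep1
      next
    }
    al <- align_taxonomy(src, ws, sep = sep, adjustments = adjustments)
    res <- merge_taxonomies(ws, src, al)
    ws <- res$taxonomy
    reports[[src$tag]] <- res$report
    alignments[[src$tag]] <- al
  }
  if (length(final_patches)) {
    pr <- apply_directives(ws, final_patches, strict = strict)
    ws <- pr$taxonomy
  }
  if (!is.null(prev)) {
    ws <- assign_ids(ws, prev, sep = sep)$taxonomy
  }
  reports <- dplyr::bind_rows(reports)
  class(reports) <- c("tax_merge_report", class(reports))
  list(taxonomy = ws, reports = reports, alignments = alignments)
}

#' Write a merge report as TSV
#'
#' @param report A merge-report tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_merge_report <- function(report, path) {
  readr::write_tsv(report, path)
  invisible(path)
}
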