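#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
NULL

# Reserved node flag vocabulary. Flags are an open set of string tags; these
# seven have meaning to the assembly procedure itself.
.reserved_flags <- c(
  "incertae_sedis", "was_container", "extinct", "suppressed",
  "unplaced", "edited", "hidden"
)

.empty_nodes <- function() {
  tibble(
    id = integer(), parent = integer(), name = character(),
    rank = character(), flags = character(), uid = integer(),
    status = character()
  )
}

.empty_synonyms <- function() {
  tibble(id = integer(), name = character(), type = character())
}

.empty_sources <- function() {
  tibble(id = integer(), tag = character(), src_id = character())
}

#' Construct a taxonomy
#'
#' A taxonomy is a rooted node forest carried as three tibbles: `nodes`
#' (one row per taxon record: local id, parent id, primary name-string,
#' optional rank, comma-separated flags, optional persistent uid, optional
#' nomenclatural status), `synonyms` (non-primary name-strings per node)
#' and `sources` (provenance pairs `(tag, src_id)` recording which source
#' taxonomy records contributed the node). Roots have `parent = NA`.
#'
#' @param nodes Tibble with at least columns `id`, `parent`, `name`;
#'   missing optional columns are added.
#' @param synonyms Tibble with columns `id`, `name` and optionally `type`.
#' @param sources Tibble with columns `id`, `tag`, `src_id`.
#' @param tag Identity-space label for the taxonomy (e.g. a source name).
#' @return An object of class `taxonomy`.
#' @export
taxonomy <- function(nodes = .empty_nodes(), synonyms = .empty_synonyms(),
                     sources = .empty_sources(), tag = "tax") {
  nodes <- as_tibble(nodes)
  if (!all(c("id", "parent", "name") %in% names(nodes))) {
    abort("`nodes` needs columns id, parent, name")
  }
  if (!"rank" %in% names(nodes)) nodes$rank <- NA_character_
  if (!"flags" %in% names(nodes)) nodes$flags <- ""
  if (!"uid" %in% names(nodes)) nodes$uid <- NA_integer_
  if (!"status" %in% names(nodes)) nodes$status <- NA_character_
  nodes$id <- as.integer(nodes$id)
  nodes$parent <- as.integer(nodes$parent)
  nodes$flags[is.na(nodes$flags)] <- ""
  nodes$uid <- as.integer(nodes$uid)
  synonyms <- as_tibble(synonyms)
  if (!"type" %in% names(synonyms)) {
    synonyms$type <- rep("synonym", nrow(synonyms))
  }
  synonyms$id <- as.integer(synonyms$id)
  sources <- as_tibble(sources)
  if (nrow(sources)) sources$id <- as.integer(sources$id)
  sources$src_id <- as.character(sources$src_id)
  t <- structure(
    list(tag = tag,
         nodes = nodes[c("id", "parent", "name", "rank", "flags", "uid", "status")],
         synonyms = synonyms[c("id", "name", "type")],
         sources = sources[c("id", "tag", "src_id")]),
    class = "taxonomy"
  )
  t
}

#' @export
#' @rdname taxonomy
is_taxonomy <- function(x) inherits(x, "taxonomy")

#' Validate taxonomy invariants
#'
#' Checks that ids are unique, every non-root parent exists, the parent
#' relation is acyclic (every node reaches a root), primary names are
#' nonempty, no node lists its own primary name among its synonyms, and
#' synonym/source rows refer to existing nodes.
#'
#' @param t A taxonomy.
#' @return `t`, invisibly; errors on violation.
#' @export
validate_taxonomy <- function(t) {
  stopifnot(is_taxonomy(t))
  nd <- t$nodes
  if (anyDuplicated(nd$id)) abort("duplicate node ids")
  if (any(is.na(nd$name) | nd$name == "")) abort("empty primary name-string")
  bad <- !is.na(nd$parent) & !(nd$parent %in% nd$id)
  if (any(bad)) abort(paste0("dangling parent id: ", nd$parent[bad][1]))
  if (any(!is.na(nd$parent) & nd$parent == nd$id)) abort("node is its own parent")
  # acyclicity: iterate parent pointers; depth must stabilize within n steps
  if (nrow(nd)) {
    pos <- match(nd$parent, nd$id)
    cur <- pos
    for (i in seq_len(nrow(nd))) {
      if (all(is.na(cur))) break
      cur <- pos[cur]
    }
    if (!all(is.na(cur))) abort("cycle in parent relation")
  }
  if (nrow(t$synonyms)) {
    if (!all(t$synonyms$id %in% nd$id)) abort("synonym row for unknown node")
    key <- paste0(t$synonyms$id, "\r", t$synonyms$name)
    own <- paste0(nd$id, "\r", nd$name)
    if (any(key %in% own)) abort("primary name duplicated among its synonyms")
  }
  if (nrow(t$sources) && !all(t$sources$id %in% nd$id)) {
    abort("source row for unknown node")
  }
  invisible(t)
}

.rowof <- function(t, id) match(id, t$nodes$id)

#' Basic tree queries
#'
#' @param t A taxonomy.
#' @param id Node id(s).
#' @return `node_count()`: number of nodes. `tax_root_ids()`: ids of roots.
#'   `tax_children_ids()`: ids of `id`'s children in insertion order.
#'   `tax_parent_id()`: parent id or `NA`. `tax_ancestor_ids()`: proper
#'   ancestors of `id`, nearest first. `tax_tip_ids()`: ids of tips
#'   (childless nodes). `subtree_ids()`: `id` and all its descendants.
#' @export
node_count <- function(t) nrow(t$nodes)

#' @rdname node_count
#' @export
tax_root_ids <- function(t) t$nodes$id[is.na(t$nodes$parent)]

#' @rdname node_count
#' @export
tax_children_ids <- function(t, id) {
  t$nodes$id[!is.na(t$nodes$parent) & t$nodes$parent == id]
}

#' @rdname node_count
#' @export
tax_parent_id <- function(t, id) t$nodes$parent[.rowof(t, id)]

#' @rdname node_count
#' @export
tax_ancestor_ids <- function(t, id) {
  out <- integer()
  p <- tax_parent_id(t, id)
  while (!is.na(p)) {
    out <- c(out, p)
    p <- tax_parent_id(t, p)
  }
  out
}

#' @rdname node_count
#' @export
tax_tip_ids <- function(t) {
  setdiff(t$nodes$id, unique(t$nodes$parent[!is.na(t$nodes$parent)]))
}

#' @rdname node_count
#' @export
subtree_ids <- function(t, id) {
  out <- id
  frontier <- id
  while (length(frontier)) {
    kids <- t$nodes$id[!is.na(t$nodes$parent) & t$nodes$parent %in% frontier]
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

#' Ancestor test
#'
#' A node counts as its own ancestor.
#'
#' @param t A taxonomy.
#' @param anc,desc Node ids in `t`.
#' @return Logical scalar.
#' @export
is_ancestor <- function(t, anc, desc) {
  if (is.na(.rowof(t, anc)) || is.na(.rowof(t, desc))) {
    abort("node not in this taxonomy")
  }
  cur <- desc
  while (!is.na(cur)) {
    if (cur == anc) return(TRUE)
    cur <- tax_parent_id(t, cur)
  }
  FALSE
}

#' Most recent common ancestor
#'
#' Returns the smallest node that is a *proper* ancestor of every input
#' node. For a singleton input `{n}` this is `n`'s parent (an error if `n`
#' is a root).
#'
#' @param t A taxonomy.
#' @param ids Nonempty vector of node ids in `t`.
#' @return A node id.
#' @export
mrca <- function(t, ids) {
  ids <- unique(as.integer(ids))
  if (!length(ids)) abort("mrca of empty set")
  if (any(is.na(match(ids, t$nodes$id)))) abort("node not in this taxonomy")
  paths <- lapply(ids, function(i) tax_ancestor_ids(t, i))
  if (length(ids) == 1L) {
    if (!length(paths[[1]])) abort("mrca of a singleton root")
    return(paths[[1]][1])
  }
  common <- Reduce(intersect, paths)
  if (!length(common)) abort("nodes have no common ancestor")
  common[1]  # paths are ordered nearest-first, intersect preserves order
}

# -- names ------------------------------------------------------------------

#' Normalize a name-string for matching
#'
#' Strips diacritics (canonical decomposition, combining marks removed) and
#' collapses internal whitespace. Case is preserved: taxon names are
#' case-significant.
#'
#' @param x Character vector.
#' @return Character vector of the same length.
#' @export
norm_name <- function(x) {
  stringr::str_squish(stringi::stri_trans_general(x, "NFD; [:Nonspacing Mark:] Remove; NFC"))
}

#' Name index of a taxonomy
#'
#' Maps every normalized name-string (primary or synonym) to the nodes
#' carrying it. A *homonym name-string* is one whose entry has more than
#' one node.
#'
#' @param t A taxonomy.
#' @return Tibble with columns `name` (normalized), `id`, `primary`.
#' @export
name_index <- function(t) {
  prim <- tibble(name = norm_name(t$nodes$name), id = t$nodes$id, primary = TRUE)
  syn <- tibble(name = norm_name(t$synonyms$name), id = t$synonyms$id,
                primary = FALSE)
  dplyr::distinct(dplyr::bind_rows(prim, syn))
}

#' All name-strings of one node
#' @param t A taxonomy.
#' @param id Node id.
#' @return Character vector: primary name first, then synonyms.
#' @export
node_names <- function(t, id) {
  c(t$nodes$name[.rowof(t, id)], t$synonyms$name[t$synonyms$id == id])
}

#' @rdname node_names
#' @export
tax_name <- function(t, id) t$nodes$name[.rowof(t, id)]

# -- flags ------------------------------------------------------------------

flag_split <- function(x) {
  out <- strsplit(x, ",", fixed = TRUE)
  lapply(out, function(f) f[nzchar(f)])
}

flag_join <- function(f) paste(unique(f[nzchar(f)]), collapse = ",")

#' Node flags
#'
#' Flags are an open set of string tags stored comma-separated; the tags
#' `incertae_sedis`, `was_container`, `extinct`, `suppressed`, `unplaced`,
#' `edited` and `hidden` are reserved by the assembly procedure.
#'
#' @param t A taxonomy.
#' @param id Node id(s).
#' @param flag A single flag tag.
#' @return `has_flag()`: logical vector. The mutators return the modified
#'   taxonomy.
#' @export
has_flag <- function(t, id, flag) {
  vapply(flag_split(t$nodes$flags[.rowof(t, id)]),
         function(f) flag %in% f, logical(1))
}

#' @rdname has_flag
#' @export
tax_add_flag <- function(t, id, flag) {
  r <- .rowof(t, id)
  t$nodes$flags[r] <- vapply(flag_split(t$nodes$flags[r]),
                             function(f) flag_join(c(f, flag)), character(1))
  t
}

#' @rdname has_flag
#' @export
tax_drop_flag <- function(t, id, flag) {
  r <- .rowof(t, id)
  t$nodes$flags[r] <- vapply(flag_split(t$nodes$flags[r]),
                             function(f) flag_join(setdiff(f, flag)), character(1))
  t
}

# -- mutation ---------------------------------------------------------------

next_node_id <- function(t) if (nrow(t$nodes)) max(t$nodes$id) + 1L else 1L

#' Add a node
#'
#' @param t A taxonomy.
#' @param name Primary name-string (nonempty).
#' @param parent Parent node id, or `NA` for a new root.
#' @param rank Optional rank label.
#' @param flags Comma-separated flag tags.
#' @param synonyms Character vector of synonym name-strings.
#' @param id Local id to use; defaults to one more than the current maximum.
#' @return The taxonomy with the node added; the new id is available as
#'   `attr(, "new_id")`.
#' @export
tax_add_node <- function(t, name, parent = NA, rank = NA_character_,
                         flags = "", synonyms = character(), id = NULL) {
  if (is.na(name) || !nzchar(name)) abort("primary name must be nonempty")
  id <- as.integer(id %||% next_node_id(t))
  if (id %in% t$nodes$id) abort("node id already in use")
  if (!is.na(parent) && is.na(.rowof(t, parent))) abort("unknown parent id")
  t$nodes <- dplyr::bind_rows(t$nodes, tibble(
    id = id, parent = as.integer(parent), name = name,
    rank = as.character(rank), flags = flags, uid = NA_integer_,
    status = NA_character_
  ))
  for (s in synonyms) t <- tax_add_synonym(t, id, s)
  attr(t, "new_id") <- id
  t
}

#' @rdname tax_add_node
#' @param type Synonym kind tag (e.g. `"synonym"`, `"original"`).
#' @export
tax_add_synonym <- function(t, id, name, type = "synonym") {
  if (is.na(.rowof(t, id))) abort("unknown node id")
  if (identical(name, tax_name(t, id))) return(t)  # primary never duplicated
  if (any(t$synonyms$id == id & t$synonyms$name == name)) return(t)
  t$synonyms <- dplyr::bind_rows(t$synonyms,
                                 tibble(id = id, name = name, type = type))
  t
}

#' Move a node (with its subtree) under a new parent
#'
#' @param t A taxonomy.
#' @param id Node to move.
#' @param new_parent New parent id, or `NA` to detach `id` as a root.
#' @return The modified taxonomy; errors if the move would create a cycle.
#' @export
tax_reattach <- function(t, id, new_parent) {
  if (is.na(.rowof(t, id))) abort("unknown node id")
  if (!is.na(new_parent)) {
    if (is.na(.rowof(t, new_parent))) abort("unknown parent id")
    if (new_parent %in% subtree_ids(t, id)) {
      abort("reattachment would create a cycle")
    }
  }
  t$nodes$parent[.rowof(t, id)] <- as.integer(new_parent)
  t
}

#' Remove nodes
#'
#' @param t A taxonomy.
#' @param ids Node ids to remove.
#' @param children Either `"reattach"` (children of a removed node are
#'   reattached to its nearest surviving ancestor) or `"delete"` (whole
#'   subtrees are removed).
#' @return The modified taxonomy.
#' @export
tax_remove_nodes <- function(t, ids, children = c("reattach", "delete")) {
  children <- match.arg(children)
  ids <- unique(as.integer(ids))
  if (children == "delete") {
    ids <- unique(unlist(lapply(ids, subtree_ids, t = t)))
  } else {
    for (id in ids) {
      # nearest ancestor not itself being removed (NA if none)
      anc <- tax_ancestor_ids(t, id)
      keep <- anc[!(anc %in% ids)]
      target <- if (length(keep)) keep[1] else NA_integer_
      kids <- setdiff(tax_children_ids(t, id), ids)
      t$nodes$parent[match(kids, t$nodes$id)] <- target
    }
  }
  t$nodes <- t$nodes[!(t$nodes$id %in% ids), ]
  t$synonyms <- t$synonyms[!(t$synonyms$id %in% ids), ]
  t$sources <- t$sources[!(t$sources$id %in% ids), ]
  t
}

#' Provenance helpers
#'
#' `ensure_provenance()` gives every node lacking provenance the default
#' pair `(taxonomy tag, local id)`. `tax_add_sources()` appends pairs.
#'
#' @param t A taxonomy.
#' @return The modified taxonomy.
#' @export
ensure_provenance <- function(t) {
  missing <- setdiff(t$nodes$id, unique(t$sources$id))
  if (length(missing)) {
    t$sources <- dplyr::bind_rows(t$sources, tibble(
      id = missing, tag = t$tag, src_id = as.character(missing)
    ))
  }
  t
}

#' @rdname ensure_provenance
#' @param id Node id.
#' @param pairs Tibble with columns `tag`, `src_id`.
#' @export
tax_add_sources <- function(t, id, pairs) {
  if (!nrow(pairs)) return(t)
  add <- tibble(id = id, tag = pairs$tag, src_id = as.character(pairs$src_id))
  t$sources <- dplyr::distinct(dplyr::bind_rows(t$sources, add))
  t
}

node_sources <- function(t, id) t$sources[t$sources$id == id, c("tag", "src_id")]

#' Node depths
#' @param t A taxonomy.
#' @return Named integer vector: depth of each node (roots are 1),
#'   names are node ids.
#' @export
tax_depths <- function(t) {
  nd <- t$nodes
  depth <- rep(NA_integer_, nrow(nd))
  names(depth) <- nd$id
  frontier <- which(is.na(nd$parent))
  depth[frontier] <- 1L
  d <- 1L
  while (length(frontier)) {
    kids <- which(!is.na(nd$parent) & nd$parent %in% nd$id[frontier])
    d <- d + 1L
    depth[kids] <- d
    frontier <- kids
  }
  depth
}

#' Traversal orders
#'
#' Deterministic preorder / postorder over the whole forest: roots in id
#' order, children in insertion (row) order.
#'
#' @param t A taxonomy.
#' @return Integer vector of node ids.
#' @export
tax_preorder <- function(t) {
  kids_of <- split(t$nodes$id, factor(t$nodes$parent, levels = t$nodes$id))
  out <- integer(node_count(t))
  k <- 0L
  stack <- sort(tax_root_ids(t))
  while (length(stack)) {
    id <- stack[1]
    stack <- stack[-1]
    k <- k + 1L
    out[k] <- id
    kids <- kids_of[[as.character(id)]]
    if (length(kids)) stack <- c(kids, stack)
  }
  out[seq_len(k)]
}

#' @rdname tax_preorder
#' @export
tax_postorder <- function(t) {
  pre <- tax_preorder(t)
  # children before parents: reverse preorder visits parents first within
  # each path, so a stack-based emit works; simplest is depth-sorted stable
  d <- tax_depths(t)[as.character(pre)]
  pre[order(-d, seq_along(pre))]
}

#' @export
print.taxonomy <- function(x, ...) {
  cat(sprintf("<taxonomy '%s': %d nodes, %d synonyms, %d roots, %d tips>\n",
              x$tag, node_count(x), nrow(x$synonyms),
              length(tax_root_ids(x)), length(tax_tip_ids(x))))
  invisible(x)
}
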