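#' Curator patch directives
#'
#' A directive is one declarative patch instruction applied either to a
#' source taxonomy before alignment or to the assembled workspace as a
#' final patch. Kinds: `add` (new taxon under a parent selector), `prune`
#' (remove a subtree), `rename` (change the primary name, keeping the old
#' as a synonym), `add-synonym`, `reattach` (move to a new parent),
#' `set-flag`, and the alignment adjustments `force-align` /
#' `forbid-align`, which are not applied structurally but recorded and
#' consulted by [align_taxonomy()] before the heuristics run.
#'
#' Selectors are a name-string plus an optional ancestor-context
#' name-string for disambiguating homonyms.
#'
#' @param kind Directive kind.
#' @param name Selector name-string (for `add`: the new taxon's name).
#' @param context Optional ancestor-context name-string.
#' @param parent,parent_context Parent selector (for `add` / `reattach`).
#' @param new_name New primary name (`rename`) or the synonym to add
#'   (`add-synonym`).
#' @param flag Flag tag (`set-flag`).
#' @param target_name,target_context Workspace-side selector for
#'   `force-align` / `forbid-align`.
#' @param rank Optional rank label (`add`).
#' @param type Synonym kind tag (`add-synonym`).
#' @param provenance Free-form provenance text.
#' @return A `directive` object.
#' @export
directive <- function(kind = c("add", "prune", "rename", "add-synonym",
                               "reattach", "set-flag", "force-align",
                               "forbid-align"),
                      name, context = NA, parent = NA, parent_context = NA,
                      new_name = NA, flag = NA, target_name = NA,
                      target_context = NA, rank = NA, type = "synonym",
                      provenance = "") {
  kind <- match.arg(kind)
  if (is.na(name) || !nzchar(name)) abort("directive selector needs a name")
  need <- switch(kind,
    add = "parent", rename = "new_name", `add-synonym` = "new_name",
    reattach = "parent", `set-flag` = "flag",
    `force-align` = "target_name", `forbid-align` = "target_name",
    NULL
  )
  if (!is.null(need)) {
    val <- get(need)
    if (is.na(val) || !nzchar(val)) {
      abort(sprintf("directive kind '%s' needs field '%s'", kind, need))
    }
  }
  structure(
    list(kind = kind, name = name, context = as.character(context),
         parent = as.character(parent),
         parent_context = as.character(parent_context),
         new_name = as.character(new_name), flag = as.character(flag),
         target_name = as.character(target_name),
         target_context = as.character(target_context),
         rank = as.character(rank), type = type, provenance = provenance),
    class = "directive"
  )
}

#' Resolve a selector to a single node
#'
#' Finds the unique node whose primary name or synonym matches `name`
#' (normalized) and which, if `context` is given, descends from a node
#' matching the context. Errors on zero or multiple matches.
#'
#' @param t A taxonomy.
#' @param name Name-string.
#' @param context Optional ancestor-context name-string.
#' @return A node id.
#' @export
resolve_selector <- function(t, name, context = NA) {
  idx <- name_index(t)
  ids <- unique(idx$id[idx$name == norm_name(name)])
  if (!is.null(context) && !is.na(context) && nzchar(context)) {
    ctx_ids <- unique(idx$id[idx$name == norm_name(context)])
    ids <- Filter(function(id) {
      any(vapply(ctx_ids, function(a) a != id && is_ancestor(t, a, id),
                 logical(1)))
    }, ids)
  }
  if (!length(ids)) abort(sprintf("selector '%s' matches no node", name))
  if (length(ids) > 1L) {
    abort(sprintf("selector '%s' is ambiguous (%d matches); add a context",
                  name, length(ids)))
  }
  ids
}

.apply_one_directive <- function(t, d) {
  switch(d$kind,
    add = {
      p <- resolve_selector(t, d$parent, d$parent_context)
      tax_add_node(t, d$name, parent = p,
                   rank = if (is.na(d$rank)) NA_character_ else d$rank,
                   flags = "edited")
    },
    prune = {
      id <- resolve_selector(t, d$name, d$context)
      tax_remove_nodes(t, id, children = "delete")
    },
    rename = {
      id <- resolve_selector(t, d$name, d$context)
      old <- tax_name(t, id)
      t$nodes$name[.rowof(t, id)] <- d$new_name
      t <- tax_add_synonym(t, id, old, type = "original")
      tax_add_flag(t, id, "edited")
    },
    `add-synonym` = {
      id <- resolve_selector(t, d$name, d$context)
      tax_add_synonym(t, id, d$new_name, type = d$type)
    },
    reattach = {
      id <- resolve_selector(t, d$name, d$context)
      p <- resolve_selector(t, d$parent, d$parent_context)
      t <- tax_reattach(t, id, p)
      tax_add_flag(t, id, "edited")
    },
    `set-flag` = {
      id <- resolve_selector(t, d$name, d$context)
      tax_add_flag(t, id, d$flag)
    },
    abort(sprintf("unknown directive kind '%s'", d$kind))
  )
}

#' Apply patch directives
#'
#' Directives are applied in order. Structural kinds modify the taxonomy;
#' `force-align` / `forbid-align` are collected into an adjustments table
#' for [align_taxonomy()]. In lenient mode failures are collected and the
#' remaining directives still run; in strict mode the first failure
#' aborts.
#'
#' @param t A taxonomy.
#' @param ds List of [directive()]s.
#' @param strict Abort on first failure.
#' @return List with `taxonomy`, `applied` (count), `failures` (list of
#'   `(directive, message)`), `adjustments` (tibble of alignment
#'   adjustments).
#' @export
apply_directives <- function(t, ds, strict = FALSE) {
  applied <- 0L
  failures <- list()
  adjustments <- tibble(kind = character(), name = character(),
                        context = character(), target_name = character(),
                        target_context = character())
  for (d in ds) {
    if (d$kind %in% c("force-align", "forbid-align")) {
      adjustments <- dplyr::bind_rows(adjustments, tibble(
        kind = d$kind, name = d$name, context = d$context,
        target_name = d$target_name, target_context = d$target_context
      ))
      applied <- applied + 1L
      next
    }
    res <- tryCatch(
      list(ok = TRUE, t = .apply_one_directive(t, d)),
      error = function(e) list(ok = FALSE, msg = conditionMessage(e))
    )
    if (res$ok) {
      t <- res$t
      applied <- applied + 1L
    } else {
      if (strict) {
        abort(sprintf("directive '%s %s' failed: %s", d$kind, d$name, res$msg))
      }
      failures[[length(failures) + 1L]] <- list(directive = d, message = res$msg)
    }
  }
  list(taxonomy = t, applied = applied, failures = failures,
       adjustments = adjustments)
}

#' Read tabular patch directives
#'
#' Tab-separated directive files with a header row; recognized columns are
#' the arguments of [directive()] (`kind` and `name` required, all others
#' optional). Empty cells become `NA`.
#'
#' @param path TSV file path.
#' @return List of [directive()]s.
#' @export
read_patch_tsv <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = c("", "NA"))
  if (!all(c("kind", "name") %in% names(tab))) {
    abort("patch table needs columns 'kind' and 'name'")
  }
  get_col <- function(col, default = NA) {
    if (col %in% names(tab)) tab[[col]] else rep(default, nrow(tab))
  }
  purrr::map(seq_len(nrow(tab)), function(i) {
    directive(
      kind = tab$kind[i], name = tab$name[i],
      context = get_col("context")[i], parent = get_col("parent")[i],
      parent_context = get_col("parent_context")[i],
      new_name = get_col("new_name")[i], flag = get_col("flag")[i],
      target_name = get_col("target_name")[i],
      target_context = get_col("target_context")[i],
      rank = get_col("rank")[i],
      type = get_col("type", "synonym")[i] %||% "synonym",
      provenance = get_col("provenance", "")[i] %||% ""
    )
  })
}
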