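#' Tabular taxonomy interchange
#'
#' The interchange bundle is a pair of tables in the style of released
#' reference-taxonomy artifacts: a taxonomy table with columns
#' `uid, parent_uid, name, rank, sourceinfo, flags` and a synonyms table
#' with columns `uid, name, type`. `sourceinfo` holds pipe-separated
#' provenance pairs `tag:id`; `flags` is a comma-separated flag list;
#' `parent_uid` is empty for roots. Files are tab-separated with a header
#' row.
#'
#' @name interchange
NULL

.col_or <- function(df, col, default) {
  if (col %in% names(df)) df[[col]] else rep(default, nrow(df))
}

#' Build a taxonomy from an interchange bundle
#'
#' @param bundle A list with elements `taxonomy` and `synonyms` (data
#'   frames as described in [interchange]).
#' @param tag Identity-space tag for the taxonomy.
#' @return A [taxonomy()]; uids become local ids and are also stored in the
#'   `uid` column.
#' @export
read_interchange <- function(bundle, tag = "tax") {
  tt <- as_tibble(bundle$taxonomy)
  st <- as_tibble(if ("synonyms" %in% names(bundle)) bundle$synonyms else .empty_synonyms())
  need <- c("uid", "parent_uid", "name")
  if (!all(need %in% names(tt))) abort("taxonomy table needs uid, parent_uid, name")
  uid <- as.integer(tt$uid)
  if (anyDuplicated(uid)) abort("duplicate uid in taxonomy table")
  pu <- as.character(tt$parent_uid)
  pu[is.na(pu) | pu == ""] <- NA
  parent <- as.integer(pu)
  if (any(!is.na(parent) & !(parent %in% uid))) abort("dangling parent_uid")
  rank <- as.character(.col_or(tt, "rank", NA))
  rank[!is.na(rank) & rank == ""] <- NA
  flags <- as.character(.col_or(tt, "flags", ""))
  flags[is.na(flags)] <- ""
  nd <- tibble(id = uid, parent = parent, name = as.character(tt$name),
               rank = rank, flags = flags, uid = uid,
               status = as.character(.col_or(tt, "status", NA)))
  syn <- if (nrow(st)) {
    tibble(id = as.integer(st$uid), name = as.character(st$name),
           type = as.character(.col_or(st, "type", "synonym")))
  } else .empty_synonyms()
  src <- .parse_sourceinfo(uid, as.character(.col_or(tt, "sourceinfo", "")))
  validate_taxonomy(taxonomy(nd, syn, src, tag = tag))
}

.parse_sourceinfo <- function(ids, info) {
  info[is.na(info)] <- ""
  keep <- nzchar(info)
  if (!any(keep)) return(.empty_sources())
  pieces <- strsplit(info[keep], "|", fixed = TRUE)
  tibble(
    id = rep(ids[keep], lengths(pieces)),
    pair = unlist(pieces)
  ) |>
    dplyr::mutate(
      tag = sub(":.*$", "", .data$pair),
      src_id = sub("^[^:]*:", "", .data$pair)
    ) |>
    dplyr::select("id", "tag", "src_id")
}

#' Serialize a taxonomy to an interchange bundle
#'
#' Rows are ordered by uid; the serialization is lossless for structure,
#' names, ranks, flags, synonyms and provenance.
#'
#' @param t A taxonomy. Nodes lacking a `uid` take their local id.
#' @return A list with tibbles `taxonomy` and `synonyms`.
#' @export
write_interchange <- function(t) {
  uid <- ifelse(is.na(t$nodes$uid), t$nodes$id, t$nodes$uid)
  if (anyDuplicated(uid)) abort("duplicate uids; run assign_ids first")
  uid_of <- stats::setNames(uid, t$nodes$id)
  src <- t$sources
  info <- if (nrow(src)) {
    src |>
      dplyr::mutate(pair = paste0(.data$tag, ":", .data$src_id)) |>
      dplyr::group_by(.data$id) |>
      dplyr::summarise(sourceinfo = paste(.data$pair, collapse = "|"))
  } else tibble(id = integer(), sourceinfo = character())
  tt <- tibble(
    uid = as.integer(uid),
    parent_uid = ifelse(is.na(t$nodes$parent), "",
                        as.character(uid_of[as.character(t$nodes$parent)])),
    name = t$nodes$name,
    rank = ifelse(is.na(t$nodes$rank), "", t$nodes$rank),
    sourceinfo = "",
    flags = t$nodes$flags,
    status = ifelse(is.na(t$nodes$status), "", t$nodes$status)
  )
  m <- match(t$nodes$id, info$id)
  tt$sourceinfo[!is.na(m)] <- info$sourceinfo[m[!is.na(m)]]
  tt <- tt[order(tt$uid), ]
  syn <- tibble(
    uid = as.integer(uid_of[as.character(t$synonyms$id)]),
    name = t$synonyms$name,
    type = t$synonyms$type
  )
  syn <- syn[order(syn$uid, syn$name, method = "radix"), ]
  list(taxonomy = tt, synonyms = syn)
}

#' Read or write an interchange directory
#'
#' The on-disk form is a directory holding `taxonomy.tsv` and
#' `synonyms.tsv` (tab-separated, header row).
#'
#' @param dir Directory path.
#' @param tag Taxonomy tag (read).
#' @param t Taxonomy (write).
#' @return `read_tax_dir()`: a [taxonomy()]. `write_tax_dir()`: `dir`,
#'   invisibly.
#' @export
read_tax_dir <- function(dir, tag = basename(dir)) {
  tt <- readr::read_tsv(file.path(dir, "taxonomy.tsv"),
                        col_types = readr::cols(.default = "c"))
  sp <- file.path(dir, "synonyms.tsv")
  st <- if (file.exists(sp)) {
    readr::read_tsv(sp, col_types = readr::cols(.default = "c"))
  } else NULL
  read_interchange(list(taxonomy = tt, synonyms = st), tag = tag)
}

#' @rdname read_tax_dir
#' @export
write_tax_dir <- function(t, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  b <- write_interchange(t)
  readr::write_tsv(b$taxonomy, file.path(dir, "taxonomy.tsv"))
  readr::write_tsv(b$synonyms, file.path(dir, "synonyms.tsv"))
  invisible(dir)
}

#' Read curated taxon additions (JSON)
#'
#' Additions are machine-generated JSON documents describing new taxon
#' records contributed by curators: each record gives the new name, an
#' optional rank, a parent selector (a name-string plus an optional
#' ancestor-context name-string used to disambiguate homonyms) and
#' free-form provenance (references, curator identity). Each record maps
#' to one `add` patch directive.
#'
#' @param docs A JSON string, a file path, or a list of already-parsed
#'   documents. A document is a list with a `taxa` element (list of
#'   records) or a single record.
#' @return A list of directives (see [directive()]).
#' @export
read_additions <- function(docs) {
  if (is.character(docs)) {
    docs <- lapply(docs, function(d) {
      jsonlite::fromJSON(d, simplifyVector = FALSE)
    })
  }
  if (!is.null(docs$taxa) || !is.null(docs$name)) docs <- list(docs)
  recs <- list()
  for (doc in docs) {
    recs <- c(recs, if (!is.null(doc$taxa)) doc$taxa else list(doc))
  }
  purrr::imap(recs, function(r, i) {
    for (field in c("name", "parent")) {
      v <- r[[field]]
      if (is.null(v) || !is.character(v) || !nzchar(v)) {
        abort(sprintf("additions record %d: missing or invalid field '%s'",
                      i, field))
      }
    }
    directive(
      kind = "add", name = r$name, parent = r$parent,
      parent_context = r$parent_context %||% NA, rank = r$rank %||% NA,
      provenance = paste(c(r$sources, r$curator), collapse = "; ")
    )
  })
}

#' Read an assembly configuration
#'
#' The configuration is a YAML document listing the source taxonomies in
#' priority order (highest priority first), the separation taxonomy, and
#' final patches:
#'
#' ```yaml
#' separation: path/to/separation      # newick file or interchange dir
#' sources:
#'   - tag: ncbi
#'     location: path/to/ncbi
#'     format: interchange             # or "newick"
#'     suppressions: [...]             # optional suppression rules
#'     patches: path/to/patches.tsv    # optional pre-alignment directives
#' final_patches: path/to/final.tsv
#' ```
#'
#' An optional `priority` field per source, if present, must equal the
#' source's 1-based position.
#'
#' @param path Path to the YAML file (or a YAML string).
#' @return A list with elements `sources` (in priority order), `separation`,
#'   `final_patches`, `options`.
#' @export
read_config <- function(path) {
  cfg <- if (file.exists(path)) yaml::read_yaml(path) else yaml::yaml.load(path)
  srcs <- cfg$sources
  if (is.null(srcs) || !length(srcs)) abort("config lists no sources")
  tags <- vapply(srcs, function(s) s$tag %||% "", character(1))
  if (any(!nzchar(tags))) abort("every source needs a tag")
  if (anyDuplicated(tags)) abort("duplicate source tags in config")
  for (i in seq_along(srcs)) {
    fmt <- srcs[[i]]$format %||% "interchange"
    if (!fmt %in% c("interchange", "newick")) {
      abort(sprintf("unknown source format '%s'", fmt))
    }
    srcs[[i]]$format <- fmt
    pr <- srcs[[i]]$priority
    if (!is.null(pr) && as.integer(pr) != i) {
      abort("source priority fields out of order")
    }
    srcs[[i]]$priority <- i
  }
  list(sources = srcs, separation = cfg$separation,
       final_patches = cfg$final_patches, options = cfg$options %||% list())
}
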