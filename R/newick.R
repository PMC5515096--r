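#' Parse a labels-only Newick string
#'
#' Reads the schematic Newick dialect used throughout the package: node
#' labels on tips and internal nodes, single-quoted labels allowed (with
#' `''` escaping), whitespace insignificant outside quotes, no branch
#' lengths. Unlabeled nodes receive generated placeholder names and are
#' flagged `hidden`. A leading `?` on a label is part of the name (the
#' incertae sedis marker is presentation-only on output and is never parsed
#' back as a flag).
#'
#' @param text A single Newick string; the trailing `;` is optional.
#' @param tag Identity-space tag for the resulting taxonomy.
#' @return A [taxonomy()].
#' @export
parse_newick <- function(text, tag = "tax") {
  if (length(text) != 1L || is.na(text)) abort("need a single Newick string")
  s <- sub(";\\s*$", "", trimws(text))
  if (!nzchar(s)) abort("empty Newick input")
  chars <- strsplit(s, "")[[1]]
  pos <- 1L
  n <- length(chars)
  placeholder <- 0L

  peek <- function() if (pos <= n) chars[pos] else ""
  skip_ws <- function() while (pos <= n && grepl("^\\s$", chars[pos])) pos <<- pos + 1L

  read_label <- function() {
    skip_ws()
    if (peek() == "'") {
      pos <<- pos + 1L
      out <- character()
      repeat {
        if (pos > n) abort("unterminated quoted label")
        ch <- chars[pos]
        if (ch == "'") {
          if (pos + 1L <= n && chars[pos + 1L] == "'") {
            out <- c(out, "'"); pos <<- pos + 2L
          } else {
            pos <<- pos + 1L; break
          }
        } else {
          out <- c(out, ch); pos <<- pos + 1L
        }
      }
      return(paste(out, collapse = ""))
    }
    out <- character()
    while (pos <= n && !(chars[pos] %in% c("(", ")", ",", ":", ";"))) {
      out <- c(out, chars[pos]); pos <<- pos + 1L
    }
    trimws(paste(out, collapse = ""))
  }

  nodes <- list()
  new_node <- function(parent) {
    nodes[[length(nodes) + 1L]] <<- list(parent = parent, name = "",
                                         hidden = FALSE)
    length(nodes)
  }

  # returns id of the subtree root parsed at the current position
  parse_clade <- function(parent) {
    skip_ws()
    id <- new_node(parent)  # name filled in once the label is read
    if (peek() == "(") {
      pos <<- pos + 1L
      repeat {
        parse_clade(id)
        skip_ws()
        if (peek() == ",") { pos <<- pos + 1L; next }
        if (peek() == ")") { pos <<- pos + 1L; break }
        abort("unbalanced parentheses in Newick input")
      }
    }
    lab <- read_label()
    skip_ws()
    if (peek() == ":") {  # tolerate and discard a branch length
      pos <<- pos + 1L
      while (pos <= n && grepl("[-0-9.eE+]", chars[pos])) pos <<- pos + 1L
    }
    if (nzchar(lab)) {
      nodes[[id]]$name <<- lab
      nodes[[id]]$hidden <<- FALSE
    } else {
      placeholder <<- placeholder + 1L
      nodes[[id]]$name <<- sprintf(".node%d", placeholder)
      nodes[[id]]$hidden <<- TRUE
    }
    id
  }

  root <- parse_clade(NA_integer_)
  skip_ws()
  if (pos <= n) abort("unbalanced parentheses in Newick input")
  nd <- tibble(
    id = seq_along(nodes),
    parent = vapply(nodes, function(x) as.integer(x$parent), integer(1)),
    name = vapply(nodes, function(x) x$name, character(1)),
    rank = NA_character_,
    flags = vapply(nodes, function(x) if (x$hidden) "hidden" else "", character(1)),
    uid = NA_integer_,
    status = NA_character_
  )
  validate_taxonomy(taxonomy(nd, tag = tag))
}

.quote_label <- function(x) {
  needs <- grepl("[](),:;'[ \t]", x)
  x[needs] <- paste0("'", gsub("'", "''", x[needs]), "'")
  x
}

#' Write a taxonomy as canonical Newick
#'
#' Serialization is deterministic: children are ordered lexicographically
#' by primary name (byte order), so two writes of equal taxonomies are
#' byte-identical. Nodes flagged `incertae_sedis` are rendered with a
#' marker prefix (default `"?"`), mirroring the `?e` notation for
#' uncertainly placed children; the marker is presentation only.
#'
#' @param t A taxonomy with a single root (or use `root_wrap` to wrap a
#'   forest under an artificial root label).
#' @param marker Prefix for incertae sedis nodes; `""` disables it.
#' @param root_wrap Optional label: wrap multiple roots under one node.
#' @return A Newick string ending in `";"`.
#' @export
write_newick <- function(t, marker = "?", root_wrap = NULL) {
  roots <- tax_root_ids(t)
  kids_of <- split(t$nodes$id, factor(t$nodes$parent, levels = t$nodes$id))
  name_of <- stats::setNames(t$nodes$name, t$nodes$id)
  inc <- stats::setNames(vapply(flag_split(t$nodes$flags),
                                function(f) "incertae_sedis" %in% f, logical(1)),
                         t$nodes$id)
  ser <- function(id) {
    kids <- kids_of[[as.character(id)]]
    lab <- .quote_label(name_of[[as.character(id)]])
    if (nzchar(marker) && inc[[as.character(id)]]) lab <- paste0(marker, lab)
    if (is.null(kids) || !length(kids)) return(lab)
    kids <- kids[order(name_of[as.character(kids)], method = "radix")]
    paste0("(", paste(vapply(kids, ser, character(1)), collapse = ","), ")", lab)
  }
  if (length(roots) > 1L) {
    if (is.null(root_wrap)) abort("taxonomy has multiple roots; use root_wrap")
    body <- paste(vapply(sort(roots), ser, character(1)), collapse = ",")
    return(paste0("(", body, ")", .quote_label(root_wrap), ";"))
  }
  paste0(ser(roots), ";")
}

#' Canonical Newick form of a Newick string
#'
#' Convenience for tests and comparisons: parse then re-serialize, so two
#' strings denoting the same labeled tree compare equal byte-for-byte.
#'
#' @param text Newick string.
#' @return Canonical Newick string.
#' @export
canonical_newick <- function(text) write_newick(parse_newick(text), marker = "")
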