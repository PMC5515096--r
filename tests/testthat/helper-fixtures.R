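# Shared fixtures for the suite. The six schematic merge cases: workspace,
# source, expected result (the "?" prefix marks incertae sedis placement).
six_cases <- list(
  list(ws = "((a,b)x,(c,d)y)z", src = "((c,d)y,(e,f)w)z",
       out = "((a,b)x,(c,d)y,(e,f)w)z"),
  list(ws = "((a,b)x,(c,d)y)z", src = "(a,b,c,d)z",
       out = "((a,b)x,(c,d)y)z"),
  list(ws = "(a,b,c,d)z", src = "((a,b)x,(c,d)y)z",
       out = "((a,b)x,(c,d)y)z"),
  list(ws = "((a,b)x,(c,d)y)z", src = "(a,b,c,d,e)z",
       out = "((a,b)x,(c,d)y,?e)z"),
  list(ws = "(a,b,c,d,e)z", src = "((a,b)x,(c,d)y)z",
       out = "(a,b,c,d,e)z"),
  list(ws = "((a,b)x,(c,d)y)z", src = "((a,c)p,(b,d,e)q)z",
       out = "((a,b)x,(c,d)y,?e)z")
)

# Merge a Newick pair: workspace (higher priority) + source.
merge_pair <- function(ws_str, src_str, sep = NULL) {
  ws <- ensure_provenance(parse_newick(ws_str, tag = "S"))
  ws$tag <- "workspace"
  src <- ensure_provenance(parse_newick(src_str, tag = "Sprime"))
  al <- align_taxonomy(src, ws, sep = sep)
  res <- merge_taxonomies(ws, src, al)
  res$alignment <- al
  res
}

# Canonical form of an expected Newick string (sorted children; a literal
# leading "?" in a label sorts identically to the rendered marker).
expect_newick <- function(t, expected) {
  expect_identical(write_newick(t), write_newick(parse_newick(expected)))
}

# Independent ancestor-list oracle: ids of all proper ancestors via raw
# parent-pointer chasing on the node table.
oracle_ancestors <- function(t, id) {
  out <- integer(0)
  p <- t$nodes$parent[match(id, t$nodes$id)]
  while (!is.na(p)) {
    out <- c(out, p)
    p <- t$nodes$parent[match(p, t$nodes$id)]
  }
  out
}
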