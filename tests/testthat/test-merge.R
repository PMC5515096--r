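test_that("unaligned nodes are classified graft / conflict / insertion", {
  # graft: no aligned descendant
  ws <- ensure_provenance(parse_newick(six_cases[[1]]$ws, tag = "S"))
  src <- ensure_provenance(parse_newick(six_cases[[1]]$src, tag = "Sp"))
  al <- align_taxonomy(src, ws)
  w_id <- src$nodes$id[src$nodes$name == "w"]
  expect_equal(classify_source_node(src, w_id, al, ws), "graft")
  # conflict: aligned children under different parents
  ws6 <- ensure_provenance(parse_newick(six_cases[[6]]$ws, tag = "S"))
  src6 <- ensure_provenance(parse_newick(six_cases[[6]]$src, tag = "Sp"))
  al6 <- align_taxonomy(src6, ws6)
  p_id <- src6$nodes$id[src6$nodes$name == "p"]
  expect_equal(classify_source_node(src6, p_id, al6, ws6), "conflict")
  # insertion candidates: aligned children under one parent
  ws3 <- ensure_provenance(parse_newick(six_cases[[3]]$ws, tag = "S"))
  src3 <- ensure_provenance(parse_newick(six_cases[[3]]$src, tag = "Sp"))
  al3 <- align_taxonomy(src3, ws3)
  for (nm in c("x", "y")) {
    nid <- src3$nodes$id[src3$nodes$name == nm]
    expect_equal(classify_source_node(src3, nid, al3, ws3),
                 "insertion-candidate")
  }
  expect_error(classify_source_node(
    src3, src3$nodes$id[src3$nodes$name == "a"], al3, ws3), "aligned")
})

test_that("graft attachment follows the sibling-image NCA rule", {
  # case 1: single sibling image -> proper child of its parent
  ws <- ensure_provenance(parse_newick(six_cases[[1]]$ws, tag = "S"))
  src <- ensure_provenance(parse_newick(six_cases[[1]]$src, tag = "Sp"))
  al <- align_taxonomy(src, ws)
  placement <- stats::setNames(al$pairs$ws_id, al$pairs$src_id)
  att <- attachment_point(src, src$nodes$id[src$nodes$name == "w"],
                          placement, ws)
  expect_equal(tax_name(ws, att$node), "z")
  expect_false(att$incertae_sedis)
  # case 4: sibling images under different parents -> NCA, incertae sedis
  ws4 <- ensure_provenance(parse_newick(six_cases[[4]]$ws, tag = "S"))
  src4 <- ensure_provenance(parse_newick(six_cases[[4]]$src, tag = "Sp"))
  al4 <- align_taxonomy(src4, ws4)
  placement4 <- stats::setNames(al4$pairs$ws_id, al4$pairs$src_id)
  att4 <- attachment_point(src4, src4$nodes$id[src4$nodes$name == "e"],
                           placement4, ws4)
  expect_equal(tax_name(ws4, att4$node), "z")
  expect_true(att4$incertae_sedis)
  # no aligned relative anywhere: error (source root unalignable)
  lone <- ensure_provenance(parse_newick("(q1,q2)q0", tag = "L"))
  expect_error(attachment_point(lone, lone$nodes$id[1],
                                stats::setNames(integer(0), character(0)),
                                ws),
               "unalignable")
})

test_that("the six schematic cases merge to their printed results", {
  for (i in seq_along(six_cases)) {
    cs <- six_cases[[i]]
    res <- merge_pair(cs$ws, cs$src)
    expect_newick(res$taxonomy, cs$out)
  }
  # spot-check the report semantics on cases 5 and 6
  r5 <- merge_pair(six_cases[[5]]$ws, six_cases[[5]]$src)$report
  expect_equal(r5$absorbed, 2)
  expect_equal(r5$copied, 0)
  r6 <- merge_pair(six_cases[[6]]$ws, six_cases[[6]]$src)$report
  expect_equal(r6$conflict, 2)
  expect_equal(r6$incertae_sedis, 1)
})

test_that("merging a copy of the workspace changes nothing", {
  for (seed in c(1, 2, 3)) {
    t <- generate_taxonomy(60, seed = seed, synonym_rate = 0.1)
    t <- ensure_provenance(t)
    copy <- t
    copy$tag <- "copy"
    al <- align_taxonomy(copy, t)
    res <- merge_taxonomies(t, copy, al)
    expect_equal(res$report$copied, 0)
    expect_identical(write_newick(res$taxonomy), write_newick(t))
  }
})

test_that("merge reports partition all processed source nodes", {
  p <- generate_pair(pair_spec(n = 100, overlap = 0.6, seed = 9,
                               homonyms = 2, resolution_asymmetry = 0.3,
                               misplacements = 2))
  res <- assemble(list(p$s, p$sp), sep = p$sep)
  rep <- res$reports
  expect_equal(rep$copied + rep$aligned + rep$absorbed + rep$conflict +
                 rep$ambiguous, rep$total)
  expect_equal(rep$total[rep$source == "beta"], node_count(p$sp))
})

test_that("priority is preserved: earlier sources keep their hierarchy", {
  for (seed in c(4, 5)) {
    p <- generate_pair(pair_spec(n = 80, overlap = 0.6, seed = seed,
                                 misplacements = 3,
                                 resolution_asymmetry = 0.3))
    s <- p$s
    res <- assemble(list(s, p$sp), sep = p$sep)
    ws <- res$taxonomy
    # locate the first source's nodes in the workspace via provenance
    prov <- ws$sources[ws$sources$tag == "alpha", ]
    img <- stats::setNames(prov$id, prov$src_id)[as.character(s$nodes$id)]
    expect_false(any(is.na(img)))
    set.seed(seed)
    for (k in 1:40) {
      pair <- sample(s$nodes$id, 2)
      expect_identical(
        is_ancestor(ws, img[[as.character(pair[1])]],
                    img[[as.character(pair[2])]]),
        is_ancestor(s, pair[1], pair[2])
      )
    }
  }
})

test_that("every workspace node carries provenance from configured sources", {
  p <- generate_pair(pair_spec(n = 70, overlap = 0.5, seed = 10))
  res <- assemble(list(p$s, p$sp), sep = p$sep)
  ws <- res$taxonomy
  expect_setequal(setdiff(ws$nodes$id, unique(ws$sources$id)), integer(0))
  expect_true(all(ws$sources$tag %in% c("separation", "alpha", "beta")))
})

test_that("merging order of non-conflicting lower sources is immaterial for tips", {
  base <- generate_pair(pair_spec(n = 60, overlap = 1, seed = 11))
  s1 <- base$s
  # two disjoint lower sources: split beta's species between them
  sp <- base$sp
  tips <- intersect(tax_tip_ids(sp), sp$nodes$id[
    !is.na(sp$nodes$rank) & sp$nodes$rank == "species"])
  half <- tips[seq_len(floor(length(tips) / 2))]
  s2 <- tax_remove_nodes(sp, half, children = "delete")
  s2$tag <- "lowA"
  s3 <- tax_remove_nodes(sp, setdiff(tips, half), children = "delete")
  s3$tag <- "lowB"
  r1 <- assemble(list(s1, s2, s3), sep = base$sep)
  r2 <- assemble(list(s1, s3, s2), sep = base$sep)
  tipnames <- function(t) sort(t$nodes$name[t$nodes$id %in% tax_tip_ids(t)])
  expect_identical(tipnames(r1$taxonomy), tipnames(r2$taxonomy))
})

test_that("insertion copies keep rank and synonyms; flags merge by union", {
  ws <- ensure_provenance(parse_newick("(a,b,c,d)z", tag = "S"))
  src <- parse_newick("((a,b)x,(c,d)y)z", tag = "Sp")
  xid <- src$nodes$id[src$nodes$name == "x"]
  src$nodes$rank[match(xid, src$nodes$id)] <- "family"
  src <- tax_add_synonym(src, xid, "xalias")
  src <- tax_add_flag(src, xid, "extinct")
  src <- ensure_provenance(src)
  res <- merge_taxonomies(ws, src, align_taxonomy(src, ws))
  wx <- res$taxonomy$nodes$id[res$taxonomy$nodes$name == "x"]
  expect_length(wx, 1)
  expect_equal(res$taxonomy$nodes$rank[match(wx, res$taxonomy$nodes$id)],
               "family")
  expect_true("xalias" %in% res$taxonomy$synonyms$name[
    res$taxonomy$synonyms$id == wx])
  expect_true(has_flag(res$taxonomy, wx, "extinct"))
  expect_false(has_flag(res$taxonomy, wx, "incertae_sedis"))
})

test_that("unaligned children of an absorbed node still graft", {
  # x would insert but is absorbed (e must stay a proper child of z);
  # its unaligned child n grafts relative to its aligned siblings
  res <- merge_pair("(a,b,c,d,e)z", "((a,b,n)x,(c,d)y)z")
  expect_equal(res$report$absorbed, 2)
  t <- res$taxonomy
  n_id <- t$nodes$id[t$nodes$name == "n"]
  expect_length(n_id, 1)
  expect_equal(tax_name(t, tax_parent_id(t, n_id)), "z")
})

test_that("aligned nodes donate synonyms, provenance and ranks to images", {
  ws <- ensure_provenance(parse_newick("((s1)g)f", tag = "high"))
  src <- parse_newick("((s1)g)f", tag = "low")
  g <- src$nodes$id[src$nodes$name == "g"]
  src$nodes$rank[match(g, src$nodes$id)] <- "genus"
  src <- tax_add_synonym(src, g, "gsyn")
  src <- ensure_provenance(src)
  res <- merge_taxonomies(ws, src, align_taxonomy(src, ws))
  wg <- res$taxonomy$nodes$id[res$taxonomy$nodes$name == "g"]
  expect_equal(res$taxonomy$nodes$rank[match(wg, res$taxonomy$nodes$id)],
               "genus")
  expect_true("gsyn" %in% res$taxonomy$synonyms$name[
    res$taxonomy$synonyms$id == wg])
  expect_setequal(node_sources(res$taxonomy, wg)$tag, c("high", "low"))
})

test_that("fully disjoint sources union as a forest", {
  ws <- ensure_provenance(parse_newick("(a1,a2)rootA", tag = "A"))
  src <- ensure_provenance(parse_newick("(b1,b2)rootB", tag = "B"))
  res <- merge_taxonomies(ws, src, align_taxonomy(src, ws))
  t <- res$taxonomy
  expect_equal(length(tax_root_ids(t)), 2)
  expect_setequal(t$nodes$name[t$nodes$id %in% tax_tip_ids(t)],
                  c("a1", "a2", "b1", "b2"))
  rb <- t$nodes$id[t$nodes$name == "rootB"]
  expect_true(has_flag(t, rb, "unplaced"))
})
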