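test_that("candidate generation equals a brute-force scan", {
  ws <- generate_taxonomy(60, seed = 41, synonym_rate = 0.3,
                          diacritic_rate = 0.2)
  src <- generate_taxonomy(40, seed = 42, synonym_rate = 0.3)
  # graft a few shared names so some candidate sets are nonempty
  src$nodes$name[5:10] <- ws$nodes$name[11:16]
  idx <- name_index(ws)
  for (n in src$nodes$id) {
    got <- candidates(src, n, ws, idx)
    names_n <- norm_name(node_names(src, n))
    brute <- sort(Filter(function(w) {
      any(norm_name(node_names(ws, w)) %in% names_n)
    }, ws$nodes$id))
    expect_identical(got, as.integer(brute))
  }
  expect_length(candidates(src, src$nodes$id[2], parse_newick("(q1,q2)q0")), 0)
})

test_that("the separation verdict distinguishes disjoint, equal and nested", {
  sep <- parse_newick("((Coleoptera)Insecta,(Decapoda)Crustacea,Lepidoptera)Metazoa")
  sid <- function(nm) sep$nodes$id[sep$nodes$name == nm]
  assign_src <- stats::setNames(c(sid("Coleoptera"), sid("Lepidoptera"),
                                  sid("Metazoa"), NA),
                                c("1", "2", "3", "4"))
  assign_ws <- stats::setNames(c(sid("Decapoda"), sid("Lepidoptera"),
                                 sid("Lepidoptera")),
                               c("10", "11", "12"))
  # beetle vs decapod: disjoint
  expect_equal(separation_verdict(1, 10, sep, assign_src, assign_ws), "reject")
  # both Lepidoptera
  expect_equal(separation_verdict(2, 11, sep, assign_src, assign_ws), "accept")
  # Metazoa vs Lepidoptera: nested
  expect_equal(separation_verdict(3, 12, sep, assign_src, assign_ws), "no-info")
  # unassigned
  expect_equal(separation_verdict(4, 11, sep, assign_src, assign_ws), "no-info")
})

test_that("disparate ranks reject genus-or-below vs family-or-above", {
  src <- parse_newick("(a)g")
  ws <- parse_newick("(b)h")
  set_rank <- function(t, nm, r) {
    t$nodes$rank[t$nodes$name == nm] <- r
    t
  }
  src1 <- set_rank(src, "g", "genus")
  ws1 <- set_rank(ws, "h", "family")
  expect_equal(ranks_verdict(src1$nodes$id[src1$nodes$name == "g"],
                             ws1$nodes$id[ws1$nodes$name == "h"], src1, ws1),
               "reject")
  src2 <- set_rank(src, "g", "species")
  ws2 <- set_rank(ws, "h", "species")
  expect_equal(ranks_verdict(src2$nodes$id[src2$nodes$name == "g"],
                             ws2$nodes$id[ws2$nodes$name == "h"], src2, ws2),
               "no-info")
  expect_equal(ranks_verdict(src$nodes$id[src$nodes$name == "g"],
                             ws1$nodes$id[ws1$nodes$name == "h"], src, ws1),
               "no-info")
})

test_that("lineage verdict matches an ancestor-name-intersection oracle", {
  src <- parse_newick("((('Bufo bufo')Bufo)Bufonidae)Amphibia", tag = "a")
  ws <- parse_newick("((('Bufo bufo')Bufo)Anura)Chordata", tag = "b")
  n <- src$nodes$id[src$nodes$name == "Bufo bufo"]
  c1 <- ws$nodes$id[ws$nodes$name == "Bufo bufo"]
  expect_equal(lineage_verdict(n, c1, src, ws), "accept")
  ws2 <- parse_newick("(('Bufo bufo')UnrelatedGenus)OtherFamily", tag = "c")
  c2 <- ws2$nodes$id[ws2$nodes$name == "Bufo bufo"]
  expect_equal(lineage_verdict(n, c2, src, ws2), "no-info")
  # oracle over a generated pair: accept iff quasi-parent name of one side
  # occurs in the other side's ancestor names
  p <- generate_pair(pair_spec(n = 50, overlap = 1, seed = 43))
  for (n in sample(p$sp$nodes$id, 12)) {
    for (c in sample(p$s$nodes$id, 4)) {
      got <- lineage_verdict(n, c, p$sp, p$s)
      anc_names_ws <- norm_name(unlist(lapply(
        oracle_ancestors(p$s, c), node_names, t = p$s)))
      anc_names_src <- norm_name(unlist(lapply(
        oracle_ancestors(p$sp, n), node_names, t = p$sp)))
      qp_src <- anc_names_src[1]  # no hidden nodes in these fixtures
      qp_ws <- anc_names_ws[1]
      want <- if ((!is.na(qp_src) && qp_src %in% anc_names_ws) ||
                  (!is.na(qp_ws) && qp_ws %in% anc_names_src)) "accept"
              else "no-info"
      expect_equal(got, want)
    }
  }
})

test_that("overlap verdict follows subtree membership of images", {
  src <- parse_newick("((t1,t2)inner,(t3,t4)other)root", tag = "s")
  ws <- parse_newick("((w1,w2)cand,(w3,w4)else)top", tag = "w")
  id_s <- function(nm) src$nodes$id[src$nodes$name == nm]
  id_w <- function(nm) ws$nodes$id[ws$nodes$name == nm]
  pairs <- stats::setNames(c(id_w("w1"), id_w("w2"), id_w("w3")),
                           c(id_s("t1"), id_s("t2"), id_s("t3")))
  expect_equal(overlap_verdict(id_s("inner"), id_w("cand"), src, ws, pairs),
               "accept")
  expect_equal(overlap_verdict(id_s("other"), id_w("cand"), src, ws, pairs),
               "reject")
  no_aligned <- stats::setNames(integer(0), character(0))
  expect_equal(overlap_verdict(id_s("inner"), id_w("cand"), src, ws,
                               no_aligned), "no-info")
  # brute-force oracle on a generated pair with its true alignment
  p <- generate_pair(pair_spec(n = 60, overlap = 1, seed = 44))
  truth <- stats::setNames(p$truth$s_id, p$truth$sp_id)
  internals <- setdiff(p$sp$nodes$id, tax_tip_ids(p$sp))
  for (n in internals) {
    for (c in sample(p$s$nodes$id, 3)) {
      got <- overlap_verdict(n, c, p$sp, p$s, truth)
      desc <- setdiff(subtree_ids(p$sp, n), n)
      aligned <- desc[as.character(desc) %in% names(truth)]
      imgs <- truth[as.character(aligned)]
      c_sub <- subtree_ids(p$s, c)
      want <- if (!length(aligned)) "no-info"
              else if (any(imgs %in% c_sub)) "accept"
              else if (any(truth %in% c_sub)) "reject"
              else "no-info"
      expect_equal(got, want)
    }
  }
})

test_that("proximity accepts candidates under the nearest aligned ancestor's image", {
  src <- parse_newick("((n)p)r", tag = "s")
  ws <- parse_newick("((c1)zp,(c2)other)top", tag = "w")
  id_s <- function(nm) src$nodes$id[src$nodes$name == nm]
  id_w <- function(nm) ws$nodes$id[ws$nodes$name == nm]
  pairs <- stats::setNames(id_w("zp"), id_s("p"))
  expect_equal(proximity_verdict(id_s("n"), id_w("c1"), src, ws, pairs),
               "accept")
  expect_equal(proximity_verdict(id_s("n"), id_w("c2"), src, ws, pairs),
               "no-info")
  none <- stats::setNames(integer(0), character(0))
  expect_equal(proximity_verdict(id_s("n"), id_w("c1"), src, ws, none),
               "no-info")
})

test_that("same-name-string accepts only primary/primary equality", {
  src <- parse_newick("(x)g", tag = "s")
  ws <- parse_newick("(x)h", tag = "w")
  n <- src$nodes$id[src$nodes$name == "x"]
  c1 <- ws$nodes$id[ws$nodes$name == "x"]
  expect_equal(same_name_verdict(n, c1, src, ws), "accept")
  # synonym-only match
  ws2 <- parse_newick("(y)h", tag = "w2")
  c2 <- ws2$nodes$id[ws2$nodes$name == "y"]
  ws2 <- tax_add_synonym(ws2, c2, "x")
  expect_equal(same_name_verdict(n, c2, src, ws2), "no-info")
  # names differing only by diacritics compare equal (normalization contract)
  src3 <- parse_newick("('Strombergia')g", tag = "s3")
  ws3 <- normalize_taxonomy(parse_newick("('Strömbergia')h", tag = "w3"))
  expect_equal(same_name_verdict(
    src3$nodes$id[src3$nodes$name == "Strombergia"],
    ws3$nodes$id[ws3$nodes$name == "Strombergia"], src3, ws3), "accept")
})

test_that("single candidates still face rejection; ties stay ambiguous", {
  # 1 candidate, no rejections: aligned
  src <- parse_newick("(a)g", tag = "s")
  ws <- parse_newick("(a)h", tag = "w")
  res <- align_node(src, src$nodes$id[src$nodes$name == "a"], ws)
  expect_equal(res$status, "aligned")
  expect_true(is.na(res$decider))
  # single candidate rejected by disparate ranks
  src2 <- parse_newick("(a)g", tag = "s")
  src2$nodes$rank[src2$nodes$name == "a"] <- "genus"
  ws2 <- parse_newick("(a)h", tag = "w")
  ws2$nodes$rank[ws2$nodes$name == "a"] <- "family"
  res2 <- align_node(src2, src2$nodes$id[src2$nodes$name == "a"], ws2)
  expect_equal(res2$status, "unmatched")
  # 2 candidates, separation resolves to one
  sep <- parse_newick("(Insecta,Crustacea)Metazoa", tag = "sep")
  src3 <- parse_newick("((dup)gs)Insecta", tag = "s3")
  ws3 <- parse_newick("(((dup)g1)Insecta,((dup)g2)Crustacea)root", tag = "w3")
  res3 <- align_node(src3, src3$nodes$id[src3$nodes$name == "dup"], ws3,
                     sep = sep)
  expect_equal(res3$status, "aligned")
  expect_equal(res3$decider, "Separation")
  expect_equal(res3$n_candidates, 2L)
  # two indistinguishable candidates stay ambiguous
  src4 <- parse_newick("(dup)g", tag = "s4")
  ws4 <- parse_newick("((dup)p1,(dup)p2)r", tag = "w4")
  res4 <- align_node(src4, src4$nodes$id[src4$nodes$name == "dup"], ws4)
  expect_equal(res4$status, "ambiguous")
})

test_that("self-alignment is the identity with full coverage", {
  for (seed in c(1, 2, 3)) {
    t <- generate_taxonomy(70, seed = seed, synonym_rate = 0.2)
    al <- align_taxonomy(t, t)
    expect_equal(nrow(al$pairs), node_count(t))
    expect_length(al$ambiguous, 0)
    expect_length(al$unmatched, 0)
    expect_true(all(al$pairs$src_id == al$pairs$ws_id))
  }
})

test_that("alignment recovers ground truth on noise-free pairs", {
  for (seed in c(4, 5)) {
    p <- generate_pair(pair_spec(n = 60, overlap = 1, seed = seed))
    al <- align_taxonomy(p$sp, p$s, sep = p$sep)
    got <- stats::setNames(al$pairs$ws_id, al$pairs$src_id)
    truth <- stats::setNames(p$truth$s_id, p$truth$sp_id)
    expect_true(all(names(truth) %in% names(got)))
    expect_true(all(got[names(truth)] == truth))
    expect_length(al$ambiguous, 0)
  }
})

test_that("telemetry wins sum to the number of multi-candidate alignments", {
  p <- generate_pair(pair_spec(n = 100, overlap = 0.7, seed = 6,
                               homonyms = 2, synonym_rate = 0.2))
  al <- align_taxonomy(p$sp, p$s, sep = p$sep)
  multi <- sum(!is.na(al$pairs$n_candidates) & al$pairs$n_candidates >= 2)
  expect_equal(sum(al$telemetry$wins), multi)
  # partition: every processed source node lands in exactly one bucket
  expect_equal(nrow(al$pairs) + length(al$ambiguous) + length(al$unmatched),
               node_count(p$sp))
  expect_length(intersect(al$pairs$src_id, al$ambiguous), 0)
  expect_length(intersect(al$pairs$src_id, al$unmatched), 0)
})

test_that("forbid-align keeps the pair out; force-align puts it in", {
  ws <- ensure_provenance(parse_newick("((sharedname)g1)r", tag = "ws"))
  src <- ensure_provenance(parse_newick("((sharedname)g2)r", tag = "src"))
  n <- src$nodes$id[src$nodes$name == "sharedname"]
  w <- ws$nodes$id[ws$nodes$name == "sharedname"]
  adj <- apply_directives(src, list(
    directive("forbid-align", name = "sharedname", target_name = "sharedname")
  ))$adjustments
  al <- align_taxonomy(src, ws, adjustments = adj)
  expect_false(any(al$pairs$src_id == n & al$pairs$ws_id == w))
  adj2 <- apply_directives(src, list(
    directive("force-align", name = "g2", target_name = "g1")
  ))$adjustments
  al2 <- align_taxonomy(src, ws, adjustments = adj2)
  g2 <- src$nodes$id[src$nodes$name == "g2"]
  g1 <- ws$nodes$id[ws$nodes$name == "g1"]
  expect_true(any(al2$pairs$src_id == g2 & al2$pairs$ws_id == g1))
})

test_that("no aligned pair crosses disjoint separation taxa", {
  for (seed in c(7, 8)) {
    p <- generate_pair(pair_spec(n = 80, overlap = 0.6, seed = seed,
                                 cross_sep_homonyms = 3))
    al <- align_taxonomy(p$sp, p$s, sep = p$sep)
    src_assign <- sep_assignment(p$sp, separation_map(p$sp, p$sep))
    ws_assign <- sep_assignment(p$s, separation_map(p$s, p$sep))
    for (i in seq_len(nrow(al$pairs))) {
      a <- src_assign[[as.character(al$pairs$src_id[i])]]
      b <- ws_assign[[as.character(al$pairs$ws_id[i])]]
      if (!is.na(a) && !is.na(b)) {
        expect_true(a == b || is_ancestor(p$sep, a, b) ||
                      is_ancestor(p$sep, b, a))
      }
    }
  }
})
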