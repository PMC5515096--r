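#' Deterministic synthetic taxonomies
#'
#' Generators for random taxonomies and taxonomy pairs with known ground
#' truth, used throughout the test suite in place of full-scale source
#' downloads. All randomness is seeded explicitly and the R RNG state is
#' restored on exit, so the same seed always yields byte-identical
#' fixtures. Names come from a synthetic Latin-binomial grammar (with an
#' optional diacritic injection rate) so that normalization is exercised
#' realistically.
#'
#' @name fixtures
NULL

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

.syllables <- c("ba", "ce", "do", "fu", "ga", "hi", "lo", "mi", "na", "po",
                "ra", "su", "ta", "ve", "xa", "zo", "qui", "bre", "cor", "del")

.make_word <- function(nsyl = 2L) {
  paste(sample(.syllables, nsyl, replace = TRUE), collapse = "")
}

.cap <- function(x) paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))

.rank_suffix <- c(phylum = "ophyta", class = "opsida", order = "ales",
                  family = "idae")

.inject_diacritic <- function(x) {
  swaps <- c(a = "á", e = "é", o = "ö", u = "ü")
  for (ch in sample(names(swaps))) {
    if (grepl(ch, x)) {
      return(sub(ch, swaps[[ch]], x))
    }
  }
  x
}

# Draw a fresh name for `rank` not already in `used`.
.fresh_name <- function(rank, used, genus = NULL, diacritic_rate = 0) {
  repeat {
    nm <- switch(rank,
      species = {
        ep <- .make_word(sample(2:3, 1))
        if (stats::runif(1) < diacritic_rate) ep <- .inject_diacritic(ep)
        paste(genus, ep)
      },
      genus = .cap(.make_word(sample(2:3, 1))),
      .cap(paste0(.make_word(2L), .rank_suffix[[rank]]))
    )
    if (!(nm %in% used)) return(nm)
  }
}

.gen_ladder <- c("kingdom", "phylum", "class", "order", "family", "genus",
                 "species")

#' Generate a random taxonomy
#'
#' Grows a rooted taxonomy with a plausible rank ladder (kingdom down to
#' species) and unique names, deterministically for a fixed seed.
#'
#' @param n Node budget (total nodes, including the root); at least 1.
#' @param seed Integer seed.
#' @param tag Taxonomy tag.
#' @param homonyms Number of within-taxonomy homonym name-strings to
#'   inject (pairs of nodes forced to share a primary name).
#' @param synonym_rate Probability that a node receives a synonym.
#' @param diacritic_rate Probability that a species epithet carries a
#'   diacritic mark.
#' @return A [taxonomy()].
#' @export
generate_taxonomy <- function(n, seed = 1L, tag = "synth", homonyms = 0L,
                              synonym_rate = 0, diacritic_rate = 0) {
  stopifnot(n >= 1)
  .with_seed(seed, {
    ids <- 1L
    parents <- NA_integer_
    nms <- "Synthetobiota"
    ranks <- "kingdom"
    used <- "Synthetobiota"
    syn_id <- integer(0)
    syn_name <- character(0)
    while (length(ids) < n) {
      open <- which(ranks != "species")
      pick <- if (length(open) == 1L) open else sample(open, 1)
      crank <- .gen_ladder[match(ranks[pick], .gen_ladder) + 1L]
      genus <- if (crank == "species") nms[pick] else NULL
      nm <- .fresh_name(crank, used, genus, diacritic_rate)
      used <- c(used, nm)
      nid <- length(ids) + 1L
      ids <- c(ids, nid)
      parents <- c(parents, ids[pick])
      nms <- c(nms, nm)
      ranks <- c(ranks, crank)
      if (stats::runif(1) < synonym_rate) {
        alt <- .fresh_name(crank, used, genus)
        used <- c(used, alt)
        syn_id <- c(syn_id, nid)
        syn_name <- c(syn_name, alt)
      }
    }
    t <- taxonomy(
      tibble(id = ids, parent = parents, name = nms, rank = ranks),
      tibble(id = syn_id, name = syn_name, type = "synonym"),
      tag = tag
    )
    k <- as.integer(homonyms)
    if (k > 0) {
      ids <- t$nodes$id[-1]
      if (length(ids) >= 2) {
        for (i in seq_len(k)) {
          pair <- sample(ids, 2)
          if (tax_parent_id(t, pair[1]) != tax_parent_id(t, pair[2])) {
            t$nodes$name[.rowof(t, pair[2])] <- tax_name(t, pair[1])
          }
        }
      }
    }
    validate_taxonomy(ensure_provenance(t))
  })
}

#' Specification for a generated taxonomy pair
#'
#' @param n Node budget per taxonomy.
#' @param overlap Fraction of the budget shared between the two
#'   taxonomies (the ground-truth core), in `[0, 1]`.
#' @param homonyms Within-taxonomy homonym name-strings injected into the
#'   first taxonomy.
#' @param cross_sep_homonyms Homonym name-strings injected *across*
#'   separation groups: the same new name placed in disjoint major clades
#'   of the two taxonomies (never a true match).
#' @param synonym_rate Probability that a shared node gains an extra
#'   synonym in the second taxonomy.
#' @param resolution_asymmetry Probability that a shared internal node
#'   gains an intermediate child (e.g. a subfamily) in the second taxonomy
#'   only.
#' @param misplacements Number of shared species moved to a different
#'   genus (within the same major clade) in the second taxonomy.
#' @param seed Integer seed.
#' @return A `pair_spec` list.
#' @export
pair_spec <- function(n = 60, overlap = 1, homonyms = 0L,
                      cross_sep_homonyms = 0L, synonym_rate = 0,
                      resolution_asymmetry = 0, misplacements = 0L,
                      seed = 1L) {
  stopifnot(overlap >= 0, overlap <= 1, synonym_rate >= 0, synonym_rate <= 1,
            resolution_asymmetry >= 0, resolution_asymmetry <= 1,
            homonyms <= n, cross_sep_homonyms <= n, misplacements <= n)
  structure(list(n = n, overlap = overlap, homonyms = homonyms,
                 cross_sep_homonyms = cross_sep_homonyms,
                 synonym_rate = synonym_rate,
                 resolution_asymmetry = resolution_asymmetry,
                 misplacements = misplacements, seed = seed),
            class = "pair_spec")
}

.sep_groups <- c("Animalia", "Plantae", "Fungi")

# grow `extra` additional nodes onto taxonomy t, returning the updated
# taxonomy; rows are accumulated and bound once
.grow_extras <- function(t, extra, used) {
  ids <- t$nodes$id
  ranks <- t$nodes$rank
  nms <- t$nodes$name
  nid <- max(ids)
  add_id <- add_parent <- integer(0)
  add_name <- add_rank <- character(0)
  while (extra > 0) {
    open <- which(!is.na(ranks) & ranks != "species" & ranks != "kingdom")
    pick <- if (length(open) == 1L) open else sample(open, 1)
    crank <- .gen_ladder[match(ranks[pick], .gen_ladder) + 1L]
    genus <- if (crank == "species") nms[pick] else NULL
    nm <- .fresh_name(crank, used, genus)
    used <- c(used, nm)
    nid <- nid + 1L
    add_id <- c(add_id, nid)
    add_parent <- c(add_parent, ids[pick])
    add_name <- c(add_name, nm)
    add_rank <- c(add_rank, crank)
    ids <- c(ids, nid)
    ranks <- c(ranks, crank)
    nms <- c(nms, nm)
    extra <- extra - 1L
  }
  if (length(add_id)) {
    t$nodes <- dplyr::bind_rows(t$nodes, tibble(
      id = add_id, parent = add_parent, name = add_name, rank = add_rank,
      flags = "", uid = NA_integer_, status = NA_character_
    ))
  }
  list(taxonomy = t, used = used)
}

#' Generate a pair of overlapping taxonomies with ground truth
#'
#' Builds two source taxonomies sharing a ground-truth core (an
#' `overlap` fraction of the node budget), under a small set of major
#' clades mirrored by a matching separation taxonomy, then injects
#' homonyms, synonyms, one-sided resolution asymmetries and misplacements
#' per the spec.
#'
#' @param spec A [pair_spec()].
#' @return List with `s` and `sp` (the two taxonomies), `truth` (tibble
#'   `s_id, sp_id` of true correspondences), and `sep` (separation
#'   taxonomy).
#' @export
generate_pair <- function(spec) {
  .with_seed(spec$seed, {
    n_core <- max(length(.sep_groups) + 1L, round(spec$overlap * spec$n))
    # core: root plus the major groups, then growth
    t <- taxonomy(tag = "core")
    t <- tax_add_node(t, "Lifeoidea", parent = NA, rank = "kingdom")
    used <- c("Lifeoidea", .sep_groups)
    for (g in .sep_groups) {
      t <- tax_add_node(t, g, parent = 1L, rank = "phylum")
    }
    res <- .grow_extras(t, n_core - node_count(t), used)
    core <- res$taxonomy
    used <- res$used
    core_ids <- core$nodes$id

    extra_each <- spec$n - n_core

    s <- core
    s$tag <- "alpha"
    res <- .grow_extras(s, extra_each, used)
    s <- res$taxonomy
    used <- res$used

    sp <- core
    sp$tag <- "beta"
    res <- .grow_extras(sp, extra_each, used)
    sp <- res$taxonomy
    used <- res$used

    # the root and major-group scaffold is shared by construction and is
    # not part of the ground truth proper
    scaffold <- seq_len(1L + length(.sep_groups))
    truth_ids <- setdiff(core_ids, scaffold)
    truth <- tibble(s_id = truth_ids, sp_id = truth_ids)

    # synonyms on shared nodes of sp
    if (spec$synonym_rate > 0) {
      for (id in core_ids[-1]) {
        if (stats::runif(1) < spec$synonym_rate) {
          nm <- .fresh_name(sp$nodes$rank[.rowof(sp, id)], used,
                            genus = "Alt")
          used <- c(used, nm)
          sp <- tax_add_synonym(sp, id, nm)
        }
      }
    }

    # one-sided resolution: splice an intermediate node above some of a
    # core internal node's children, in sp only
    if (spec$resolution_asymmetry > 0) {
      internals <- intersect(core_ids,
                             setdiff(sp$nodes$id, tax_tip_ids(sp)))
      for (id in internals) {
        kids <- tax_children_ids(sp, id)
        prank <- sp$nodes$rank[.rowof(sp, id)]
        if (length(kids) >= 2 && !is.na(prank) && prank %in%
              c("order", "family") && stats::runif(1) < spec$resolution_asymmetry) {
          nm <- .fresh_name("family", used)
          used <- c(used, nm)
          sp <- tax_add_node(sp, nm, parent = id, rank = NA_character_)
          mid <- attr(sp, "new_id")
          take <- sample(kids, max(2, length(kids) - 1))
          for (k in take) sp <- tax_reattach(sp, k, mid)
        }
      }
    }

    # misplacements: move a shared species to another genus in the same
    # major clade, in sp only
    if (spec$misplacements > 0) {
      sp_assign <- sep_assignment(sp, tibble(
        sep_id = match(.sep_groups, .sep_groups),
        node_id = sp$nodes$id[match(.sep_groups, sp$nodes$name)]
      ))
      species <- intersect(core_ids, sp$nodes$id[
        !is.na(sp$nodes$rank) & sp$nodes$rank == "species"])
      genera <- sp$nodes$id[!is.na(sp$nodes$rank) & sp$nodes$rank == "genus"]
      moved <- 0L
      shuffled <- if (length(species) > 1L) sample(species) else species
      for (id in shuffled) {
        if (moved >= spec$misplacements) break
        g <- tax_parent_id(sp, id)
        others <- genera[genera != g &
                           sp_assign[as.character(genera)] ==
                             sp_assign[[as.character(id)]]]
        if (length(others)) {
          tgt <- if (length(others) == 1L) others else sample(others, 1)
          sp <- tax_reattach(sp, id, tgt)
          moved <- moved + 1L
        }
      }
    }

    # cross-separation homonyms: same new binomial under disjoint major
    # clades of s and sp; never a true correspondence
    if (spec$cross_sep_homonyms > 0) {
      group_node <- function(t, g) t$nodes$id[t$nodes$name == g]
      pick_genus_in <- function(t, g) {
        ids <- intersect(subtree_ids(t, group_node(t, g)),
                         t$nodes$id[!is.na(t$nodes$rank) &
                                      t$nodes$rank == "genus"])
        if (!length(ids)) {
          t <- tax_add_node(t, .fresh_name("genus", used),
                            parent = group_node(t, g), rank = "genus")
          return(list(t = t, id = attr(t, "new_id")))
        }
        list(t = t, id = if (length(ids) == 1L) ids else sample(ids, 1))
      }
      for (i in seq_len(spec$cross_sep_homonyms)) {
        gs <- sample(.sep_groups, 2)
        a <- pick_genus_in(s, gs[1]); s <- a$t
        b <- pick_genus_in(sp, gs[2]); sp <- b$t
        nm <- paste(.cap(.make_word(2)), .make_word(3))
        while (nm %in% used) nm <- paste(.cap(.make_word(2)), .make_word(3))
        used <- c(used, nm)
        s <- tax_add_node(s, nm, parent = a$id, rank = "species")
        sp <- tax_add_node(sp, nm, parent = b$id, rank = "species")
      }
    }

    # within-taxonomy homonyms in s: exactly the requested count, each a
    # pair of tips under different parents (sibling duplicates would be
    # folded by normalization)
    if (spec$homonyms > 0) {
      tips <- tax_tip_ids(s)
      parents <- s$nodes$parent[match(tips, s$nodes$id)]
      injected <- 0L
      while (injected < spec$homonyms) {
        stopifnot(length(unique(parents)) >= 2)
        a <- tips[1]
        b <- tips[which(parents != parents[1])[1]]
        s$nodes$name[.rowof(s, b)] <- tax_name(s, a)
        drop <- tips %in% c(a, b)
        tips <- tips[!drop]
        parents <- parents[!drop]
        injected <- injected + 1L
      }
    }

    sep <- parse_newick(
      sprintf("(%s)Lifeoidea;", paste(.sep_groups, collapse = ",")),
      tag = "separation"
    )
    list(
      s = validate_taxonomy(ensure_provenance(s)),
      sp = validate_taxonomy(ensure_provenance(sp)),
      truth = truth,
      sep = sep
    )
  })
}

# -- canned narrative fixtures ----------------------------------------------

#' Canned fixtures for the classic merge narratives
#'
#' Small hand-built taxonomy pairs reproducing well-known situations from
#' reference-taxonomy assembly: the genus *Bufo* union graft (two sources
#' each holding species the other lacks), the *Fissurellidae* subfamily
#' insertion (a lower-priority source refining a family into subfamilies),
#' the *Melyridae* incertae sedis placement (two genera whose subfamily is
#' unknowable), and the Insecta hierarchy conflict (a lower-priority
#' grouping incompatible with the workspace, discarded). Each returns the
#' two taxonomies in priority order plus the expected outcome encoded in
#' the test suite.
#'
#' @return A list of taxonomies (`high` has priority over `low`).
#' @name canned_fixtures
NULL

#' @rdname canned_fixtures
#' @export
fixture_bufo <- function() {
  high <- parse_newick(
    "(('Bufo bufo','Bufo gargarizans','Bufo spinosis')Bufo)Amphibia;",
    tag = "ncbi"
  )
  low <- parse_newick(
    "(('Bufo bufo','Bufo gargarizans','Bufo luchunnicus')Bufo)Amphibia;",
    tag = "gbif"
  )
  list(high = ensure_provenance(high), low = ensure_provenance(low))
}

#' @rdname canned_fixtures
#' @export
fixture_fissurellidae <- function() {
  high <- parse_newick(
    "((Hemitoma,Emarginula,Fissurella,Diodora)Fissurellidae)Mollusca;",
    tag = "ncbi"
  )
  low <- parse_newick(
    paste0("(((Hemitoma,Emarginula)Emarginulinae,",
           "(Fissurella,Diodora)Hemitominae)Fissurellidae)Mollusca;"),
    tag = "worms"
  )
  list(high = ensure_provenance(high), low = ensure_provenance(low))
}

#' @rdname canned_fixtures
#' @export
fixture_melyridae <- function() {
  high <- parse_newick(
    paste0("(((Malachius)Malachiinae,(Dasytes)Dasytinae,",
           "(Melyris)Melyrinae)Melyridae)Coleoptera;"),
    tag = "ncbi"
  )
  low <- parse_newick(
    "((Malachius,Dasytes,Melyris,Trichoceble,Danacaea)Melyridae)Coleoptera;",
    tag = "gbif"
  )
  list(high = ensure_provenance(high), low = ensure_provenance(low))
}

#' @rdname canned_fixtures
#' @export
fixture_insecta <- function() {
  high <- parse_newick(
    "((Archaeognatha)Monocondylia,(Pterygota,Zygentoma)Dicondylia)Insecta;",
    tag = "ncbi"
  )
  low <- parse_newick(
    "((Archaeognatha,Thysanura)Apterygota,Pterygota)Insecta;",
    tag = "worms"
  )
  thys <- low$nodes$id[low$nodes$name == "Thysanura"]
  low <- tax_add_synonym(low, thys, "Zygentoma")
  list(high = ensure_provenance(high), low = ensure_provenance(low))
}
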