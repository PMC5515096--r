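---
title: "Assembling a synthetic taxonomy: model, heuristics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembling a synthetic taxonomy: model, heuristics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxmerge)
```

This vignette explains the science and the engineering behind `taxmerge`:
what the assembly procedure assumes, what each tunable parameter means,
what the synthetic-data generator does and does not emulate, and where the
design was genuinely open and a choice had to be made.

## The model

A *taxonomy* here is a rooted node forest. Each node is one taxon record:
a primary name-string, a set of synonym name-strings, an optional rank, a
parent, open-ended string flags, and provenance pairs `(source tag,
source record id)`. Names are treated purely as character sequences —
no nomenclatural-code semantics, no authority strings. A *homonym
name-string* is any name carried (as primary) by more than one node in
the same taxonomy; this is deliberately broader than nomenclatural
homonymy, because clerical duplicates and cross-kingdom reuse cause the
same alignment problem.

Assembly folds prioritized sources into a workspace, two phases per
source: **alignment** (find which source nodes already exist in the
workspace) and **merge** (add structure for the rest). Priority resolves
conflicts: the earlier source's hierarchy always wins, so insertions may
refine but never rearrange what an earlier source asserted.

The package treats the asymmetry of errors seriously: a false identity
(putting a snail record on a flatworm node) corrupts every downstream
use, while a false split merely duplicates a taxon. All tie-breaks
therefore favor *not aligning*: a node whose candidate set cannot be
narrowed to exactly one survivor stays unaligned, and ambiguous nodes are
never copied into the workspace at all.

## Normalization

Four normalizations run on every imported source
(`normalize_taxonomy()`):

1. **Diacritics** are stripped (Unicode NFD, combining marks removed);
   the original spelling is kept as a synonym. Synonym spellings are left
   verbatim — the name index normalizes at lookup time, so matching is
   unaffected and no information is destroyed.
2. **Containers** ("incertae sedis", "environmental samples", plus any
   configured names; exact, case-insensitive match) are dissolved: their
   children move to the container's parent and are flagged
   `was_container`. A container at a root is an error, since there is no
   parent to receive the children.
3. **Subgenera homonymous with their genus** are renamed "X subgenus X",
   with the original kept as a synonym.
4. **Same-named siblings** are merged, lowest local id surviving (a
   determinism choice; the sources give no principled winner), with
   children, synonyms and provenance unioned, repeated to a fixed point.

Suppression rules are configuration, not code: predicates
(`name-contains`, `status-equals`, `rank-in`, `provenance-equals`) paired
with an action (`drop-record` or `flag-suppressed`). Dropping a record
reattaches its children to the nearest surviving ancestor — except
`rank-in` suppressions (infraspecific cleanups), which delete whole
subtrees, since an orphaned variety under a deleted subspecies is noise
rather than signal. Whether record-level suppression should ever delete
subtrees is genuinely underdetermined; the choice above keeps valid
descendants and is isolated in one function. Extinct annotation follows
the sole-provenance heuristic: a record whose only provenance is a
configured (e.g. paleontological) source is flagged `extinct`.

## Alignment

Candidates are generated by name: every workspace node sharing any
normalized name-string with the source node. The ordered heuristics then
filter. Order matters and is fixed: Separation, Disparate ranks, Lineage,
Overlap, Proximity, Same name-string. Each returns accept / reject /
no-info per candidate; rejected candidates are discarded, and a heuristic
that narrows two-or-more candidates to exactly one decides the
alignment (that decision is what the telemetry counts). A single initial
candidate is *not* trusted automatically — it still faces the rejection
heuristics.

The published description names these heuristics but does not define
them operationally, so their exact semantics here are this package's own,
kept behind a narrow verdict interface so any one can be swapped:

* **Separation** compares the nodes' nearest separation-aligned
  ancestors. Disjoint separation taxa → reject; equal → accept; nested or
  unassigned → no information. The separation taxonomy itself is mapped
  into each taxonomy by a restricted pipeline (name candidates filtered
  by containment under the image of the nearest mapped separation
  ancestor, then primary-name preference).
* **Disparate ranks** rejects genus-or-below vs. family-or-above. The
  boundary is a judgment call: it blocks the classic genus/higher-taxon
  homonym class while tolerating rank noise around species level.
* **Lineage** accepts when the source node's *quasi-parent* name (nearest
  ancestor that is not a generated placeholder) occurs among the
  candidate's ancestors' names, or symmetrically.
* **Overlap** accepts when the source subtree contains an aligned node
  whose image lies inside the candidate's subtree; rejects when both
  sides contain aligned material but none of it matches up; reports
  no-info when the source subtree has no aligned nodes, and also in the
  residual case where the candidate subtree holds no images at all —
  a deliberate conservative reading, since silence is weaker evidence
  than contradiction.
* **Proximity** accepts candidates under the image of the source node's
  nearest aligned ancestor and never rejects.
* **Same name-string** accepts exact primary/primary equality after
  normalization.

Alignment runs in two passes — tips first, then internal nodes bottom-up
— so Overlap has tip evidence when internal nodes are considered. Pass
one is strictly tips; species with infraspecific children are handled in
pass two, where Overlap applies to them too.

## Merge

Unaligned nodes take one of four fates:

* **Graft**: a maximal unaligned subtree with no aligned member. It
  attaches below the nearest common ancestor of its aligned siblings'
  images (for one sibling image, that image's parent), flagged
  *incertae sedis* exactly when that ancestor is not the parent of every
  sibling image — i.e. when the data cannot say which subgroup the graft
  belongs to. With no aligned sibling, it attaches under the nearest
  placed ancestor, always incertae sedis; with no placed relative at all
  (fully disjoint sources) it becomes a new root flagged `unplaced`, so a
  merge of disjoint taxonomies is their forest union.
* **Insertion**: an unaligned internal node whose aligned children's
  images share one workspace parent; a copy is spliced between that
  parent and the images, adding resolution without rearranging anything.
  Insertions are never incertae sedis, by construction.
* **Absorption**: sibling insertion candidates under a workspace parent
  `z` are accepted *jointly* only when their target children cover every
  proper (non-incertae-sedis) child of `z`. Otherwise all of them are
  absorbed (discarded): accepting them would strand a higher-priority
  proper child of `z` beneath uncertainty. The published account gives
  only one worked example of this situation, which at least two general
  rules reproduce; the coverage rule above is the stricter of the two
  and lives behind `classify_source_node()` so the policy is swappable.
* **Conflict**: aligned children's images under different workspace
  parents; the node's hierarchy is discarded, and its unaligned children
  graft (typically incertae sedis) under the common ancestor of the
  images.

Ambiguously aligned nodes are skipped entirely — never copied — including
when they occur inside a graft subtree, where their children are hoisted
to the copy of their parent. Merge reports count every source node into
exactly one of: aligned, copied, absorbed, conflict, ambiguous.

## Identifiers

Version-to-version identifier stability is itself an alignment problem:
the previous version is aligned to the new workspace with the standard
pipeline plus one extra rule, placed first because it is the strongest
evidence available: accept a candidate sharing any provenance pair with
the previous-version node. Aligned nodes inherit their old identifier;
everything else gets a fresh one, minted above the previous maximum in
depth-first order with children in canonical name order, so reassembly of
identical inputs is an exact fixed point (zero minted). The previous
version is never merged — it exists only to donate identifiers — so an
identifier persists only while its taxon continues to occur in some
source.

## Patches

Curator interventions are declarative directives (`add`, `prune`,
`rename`, `add-synonym`, `reattach`, `set-flag`, `force-align`,
`forbid-align`) with name-plus-ancestor-context selectors, applied
per-source before alignment and to the workspace after assembly. The
historical practice of patching with arbitrary executable statements is
deliberately not supported: every effect those patches achieve is
expressible in the declarative set, which keeps patch files portable and
auditable. Strict mode aborts on the first failing directive; lenient
mode collects failures and continues.

## The synthetic-data generator

Tests and the acceptance script run on generated fixtures
(`generate_taxonomy()`, `generate_pair()`), not on real source downloads.
A generated pair shares a ground-truth core (an `overlap` fraction of the
node budget) under a root and three major clades mirrored by a matching
separation taxonomy; onto this the generator injects, in exact counts or
per-node rates: within-taxonomy homonyms, cross-separation homonyms
(the same new binomial planted in disjoint major clades — never a true
match), extra synonyms, one-sided resolution asymmetries (an intermediate
node spliced above some children on one side only), and misplacements
(a shared species moved to another genus within its major clade). Names
come from a syllable grammar producing plausible Latin binomials, with a
configurable diacritic rate so normalization is exercised. All randomness
is seed-threaded and the R RNG state is restored afterwards.

Default study conditions used by the test suite and acceptance script:
pairs of 50–120 nodes, overlap 0.5–1, up to 3 injected homonyms of each
kind, synonym rate 0.1, seeds 1–20. These sizes keep the full property
suites within a couple of minutes while every structural situation
(graft, insertion, absorption, conflict, incertae sedis, forest union)
still arises.

What the generator does *not* emulate — and therefore what green tests do
not show about real data: realistic name misspellings and authority
strings, rank vocabularies that disagree between sources, the heavy-tail
size distribution of real genera, multi-million-node scale, and source-
specific artifacts (sequence-cluster tips, nomenclatural status codes
beyond a plain `status` field). Results on real sources will depend on
exactly those messy features; the fixtures validate the *logic*, not the
field behavior.

## Numerical and representational choices

* Children are kept in insertion order internally; Newick output sorts
  children lexicographically (byte order, locale-independent), making
  serializations byte-comparable across platforms.
* The incertae sedis marker (`?` prefix) is presentation only; parsing
  never turns it back into a flag. The interchange format's flags column
  is authoritative.
* `mrca()` uses proper-ancestor semantics with a singleton rule (the mrca
  of one node is its parent), which is what graft attachment needs; as a
  consequence, mrca distributes over set union only for incomparable
  inputs, and the property tests state it that way.
* Name matching is case-sensitive and diacritic-insensitive; container
  detection is the one case-insensitive comparison, since container
  labels vary freely in capitalization.
* Ranks use a fixed ~40-level ladder (union of the common database
  vocabularies); unranked nodes compare to nothing and never trigger the
  rank heuristic.
* A taxonomy is plain data: three tibbles (nodes, synonyms, provenance)
  behind a small S3 class, with `tidy()`/`glance()`/`autoplot()` methods.
  Tree mutation goes through functions rather than pipelines because a
  taxonomy is not naturally a single flat table, but every result
  surface (alignments, reports, statistics) is a tibble.

## Known limitations

* Candidate generation is strictly name-based, so a record renamed
  between versions with no shared synonym cannot retain its identifier
  even when provenance matches; the same-source-id rule only
  disambiguates among name candidates.
* Heuristic semantics are faithful to the published *names* and worked
  examples but are this package's own formalizations; on inputs outside
  the documented cases, another implementation of the same description
  could differ.
* The absorption coverage rule is evaluated among sibling candidates
  only; cousin insertion candidates under the same workspace parent are
  decided in separate groups.
* Performance targets are desk-scale experiments (thousands of nodes),
  not the multi-million-record scale of production reference-taxonomy
  builds.
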