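# taxmerge

Assembly of a single synthetic reference taxonomy from two or more source
taxonomies supplied in priority order.

Large biodiversity and phylogenetics projects need one taxonomy that
covers all of life, but no single source provides both broad taxonomic
coverage and phylogenetically informed higher-level structure. The
practical answer is synthesis: combine a sequence-aware taxonomy (rich in
OTUs, good higher-level resolution) with one or more traditional all-life
catalogues (rich in described species), and rebuild the combination from
scratch whenever a source updates. The hard part is deciding when a record
in one source *is* the same taxon as a record in another, given only
name-strings, synonyms, approximate ranks and classification context —
while homonym name-strings (the same name used for unrelated taxa) make
naive name matching dangerous.

`taxmerge` implements that synthesis as a repeatable pipeline for R. It is
aimed at people building or studying reference taxonomies: maintainers of
project-specific backbones, and anyone experimenting with alignment and
merge policies on taxonomies of any size.

## Method

Sources S₁, S₂, … Sₙ are ordered by priority and folded pairwise into a
workspace U:

    U₀ = empty,  U₁ = U₀ + S₁,  U₂ = U₁ + S₂, …

Each combination U + S′ has two phases:

**Alignment.** Every source node gets candidate workspace nodes sharing
any name-string (primary or synonym, diacritic-stripped). An ordered
sequence of heuristics then filters the candidates, each returning
accept / reject / no-information per candidate:

1. **Separation** — never align nodes placed in disjoint major clades of a
   small curated *separation taxonomy* (e.g. Fungi vs. Metazoa);
2. **Disparate ranks** — never align a genus-or-below to a
   family-or-above;
3. **Lineage** — prefer candidates whose classification shares a nearby
   ancestor name;
4. **Overlap** — for internal nodes, prefer candidates whose subtree
   contains images of already-aligned descendants (alignment runs tips
   first, then internal nodes, so this evidence exists);
5. **Proximity** — prefer candidates under the image of the node's nearest
   aligned ancestor;
6. **Same name-string** — prefer exact primary-name matches.

A node aligns only when exactly one candidate survives; a single candidate
must still pass the rejection heuristics, and unresolvable ties stay
unaligned rather than risk a wrong identity.

**Merge.** Unaligned source nodes are added structurally: subtrees with no
aligned member are **grafted** beside the images of their aligned siblings
(at the siblings' nearest common ancestor; flagged *incertae sedis* when
that ancestor is not the siblings' direct parent); internal nodes whose
aligned children share one workspace parent are **inserted** as new
resolution, unless accepting them would demote a higher-priority proper
child (then they are **absorbed** and discarded); nodes whose aligned
children sit under different workspace parents are **conflicts** and their
hierarchy is ignored. Curator patch directives apply before alignment and
after assembly, and persistent identifiers carry over from the previous
version by aligning it to the new one (preferring candidates that share a
source-record id), with fresh identifiers minted for everything else.

## A worked example

Two versions of the toad genus *Bufo*, each holding a species the other
lacks:

```r
library(taxmerge)

ncbi <- ensure_provenance(parse_newick(
  "(('Bufo bufo','Bufo spinosis')Bufo)Amphibia;", tag = "ncbi"))
gbif <- ensure_provenance(parse_newick(
  "(('Bufo bufo','Bufo luchunnicus')Bufo)Amphibia;", tag = "gbif"))

res <- assemble(list(ncbi, gbif))   # ncbi has priority
write_newick(res$taxonomy)
#> (('Bufo bufo','Bufo luchunnicus','Bufo spinosis')Bufo)Amphibia;

res$reports
#> # A tibble: 2 × 8
#>   source total copied aligned absorbed conflict ambiguous incertae_sedis
#>   <chr>  <int>  <int>   <int>    <int>    <int>     <int>          <int>
#> 1 ncbi       4      4       0        0        0         0              0
#> 2 gbif       4      1       3        0        0         0              0
```

The first source is copied wholesale (4 nodes). Of GBIF's 4 nodes, 3 align
(*Amphibia*, *Bufo*, *Bufo bufo*) and 1 — *Bufo luchunnicus* — is grafted
as a sibling of its siblings' images, so the combined genus holds the
union of species. Stable identifiers and broom-style accessors:

```r
v <- assign_ids(res$taxonomy)
head(tidy(v$taxonomy)[, c("id", "parent", "name", "uid")], 3)
#>      id parent name        uid
#> 1     1     NA Amphibia      1
#> 2     2      1 Bufo          2
#> 3     3      2 Bufo bufo     3

glance(res$taxonomy)[, c("total", "tips", "internal", "homonym_names")]
#>   total  tips internal homonym_names
#> 1     5     3        2             0
```

`merge_taxonomies()`, `align_taxonomy()`, `normalize_taxonomy()`,
`apply_directives()` and `assign_ids()` expose the individual stages;
`exec/taxmerge` wraps the pipeline for shell use
(`taxmerge assemble --config config.yml --out out/`).

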