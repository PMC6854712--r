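---
title: "Search-database construction and protein-group consensus annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Search-database construction and protein-group consensus annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaprot)
```

## The problem

Metaproteomics identifies the proteins expressed by whole microbial
communities by matching MS/MS spectra against a protein search database.
Two steps routinely undermine downstream interpretation. First, the
search database itself: public repositories are far too broad for any
one habitat, inflating search time and the false-discovery rate, so a
curated, habitat-scoped FASTA has to be assembled from several sources.
Second, the *protein inference issue*: an identified peptide often maps
to many homologous proteins, so proteomics software reports *protein
groups* — sets of proteins sharing peptides — and any annotation drawn
from a single best alignment hit of a single member is unreliable
whenever the top hits disagree taxonomically or functionally.

`metaprot` addresses both steps. It builds combined search databases
(merge, exact-identity deduplication, MD5 header hashing,
taxonomy- and function-scoped subsetting from a pluggable local protein
source), and it computes *consensus* annotations per protein group from
many alignment hits rather than the first one: a lowest-common-ancestor
(LCA) taxonomic consensus and a most-frequent-name functional consensus.

## The annotation model

Evidence enters as tabular alignment output (the BLAST/Diamond
"outfmt 6" dialect) of group-member proteins against a reference
collection, optionally carrying subject taxon ids (`staxids`). Per query
protein, hits are filtered by a retention policy with two parameters:

* `min_bitscore` (default **80** bits) — hits below the threshold are
  discarded. The bitscore is log-scaled and comparable across searches,
  which makes it preferable to raw scores or e-values for a fixed
  cutoff.
* `max_hits` (default **20**) — after thresholding, hits are sorted by
  descending bitscore and only the best `max_hits` are kept. Twenty
  retained hits is a robust operating point: enough votes to damp
  outliers and false positives, while larger windows add little.

Ties in bitscore are broken by ascending e-value, then by file order.
The tie rule is a design choice of this package: the alignment format
guarantees neither unique scores nor a canonical order, and the
annotation must be deterministic to be testable. Filtering is applied
per query protein, before any group-level pooling, because alignment
output is keyed by query; the hit cap therefore bounds the influence of
any single member on the group's consensus.

### Taxonomic consensus

The retained hits of all members of a group are pooled. A hit listing
several subject taxa is first collapsed to the LCA of its own taxa, so
one alignment row casts exactly one vote and multi-mapped subjects
cannot dominate the pool. The group annotation is the strict LCA of the
pooled taxa over the loaded NCBI-style taxonomy — the deepest node that
is an ancestor-or-self of every voting taxon — with no minimum-support
or top-percent relaxation. Strictness is deliberately conservative:
conflicting evidence moves the annotation toward the root rather than
picking a side.

Taxon ids are resolved through the taxonomy's `merged.dmp` redirects.
A hit is counted *unresolvable* (and excluded) only when none of its
taxa resolve; a partially resolvable taxon list is collapsed to the LCA
of its resolvable subset, which loses the least evidence. A group none
of whose retained hits carries a resolvable taxon is reported
`unassigned`, never silently dropped.

### Functional consensus

Each retained hit votes with the annotation label of its subject
accession, looked up in an accession-to-name table (UniProt recommended
names, or COG identifiers). Labels are normalized before voting —
whitespace trimmed and collapsed, comparison case-folded — but the
reported winner keeps the most frequent original casing, because
curated names differ in trivial formatting far more often than in
substance. Hits whose subject is absent from the lookup table abstain
(partial tables are the norm; treating them as errors would make real
lookups unusable), and "uncharacterized protein"-style labels vote like
any other: excluding them silently would bias results toward
better-annotated clades. The winner is the label with most votes; ties
break by the larger summed bitscore among the tied labels, then by the
lexicographically smallest label. A group with no votes at all is
reported `hypothetical/unknown` with support 0.

When several functional references are searched (e.g. UniProt and COG),
each source is reported in its own columns and never merged into a
single vote — the two vocabularies are not commensurable.

## Database construction

`merge_databases()` concatenates FASTA sources in order, upper-casing
sequences and stripping a trailing stop (`*`). `deduplicate()` removes
exactly identical sequences, keeping the first occurrence in stream
order (determinism again; no rule is inherent in the data). The
optional containment mode also absorbs a sequence equal to a substring
of an already-kept longer one; clustering below 100% identity is out of
scope — it belongs to dedicated clustering tools and changes the
database's identification behaviour in ways a database builder should
not silently decide. `hash_headers()` replaces every description line
by the MD5 digest of its exact bytes, yielding uniform fixed-width
headers and a smaller database, with a two-column map to restore the
originals; a digest collision is a hard error rather than a silent
merge, and headers that already look like digests (32 hex characters)
are left alone with a warning so the pipeline is idempotent end to end.
The digest is computed over the full description line, not just the
accession, because the header as a whole is what downstream software
displays.

Scoped databases are built against a *protein source* interface with
two queries: by taxon id, and by gene/protein name with an optional
clade restriction (membership decided by an ancestor test in the
taxonomy). The package ships a local implementation backed by a FASTA
plus accession-to-taxon and accession-to-label tables; name matching is
a case-insensitive whole-word match on the normalized label. Whole-word
is a documented stand-in for repository-side name search, whose exact
semantics are not standardized; remote retrieval is an extension point,
not shipped, so everything here runs and tests offline.

## The synthetic-data generator

`generate_taxonomy()` emits a random rooted tree in the NCBI taxdump
dialect (fields separated by `"\t|\t"`, rows terminated `"\t|"`),
acyclic by construction because every node's parent precedes it, with
ranks assigned top-down from the standard ladder, plus a root-path
index used by oracle tests. `generate_scenario()` plants, per protein
group, a true taxon and a true function label, and fabricates every
input the pipeline consumes: member FASTA, group table, annotation map,
and taxonomic/functional alignment tables.

Generated evidence straddles the retention defaults on purpose:
on-target hits draw bitscores uniformly from 90–200 (comfortably
retained) and carry the planted taxon or one of its descendants — the
first on-target hit always carries the planted taxon itself, so the
noise-free group LCA equals the planted taxon exactly; off-target hits
(a fraction `noise` of the scoring hits, all sharing one wrong label
per group, taxa from a clade disjoint from the planted one) draw from
80–150; decoy hits draw from 40–79.4 and must be removed by the default
threshold. With `noise < 0.5` the planted label holds a strict
arithmetic majority, so label recovery is guaranteed, while the LCA
under noise legitimately retreats toward the root. All files are
byte-identical for identical seeds (a single fully specified RNG stream
per scenario).

What the generator does *not* emulate: sequences are random strings
over the amino-acid alphabet with no evolutionary structure, bitscores
are drawn independently of the sequences, and hit counts per group are
balanced. Passing the recovery suites therefore demonstrates the
correctness of the bookkeeping, filtering, LCA and voting logic — not
annotation accuracy on real community data, which depends on reference
completeness and alignment quality outside this package's control.

## Numerical and design notes

* Node depths are computed once at taxonomy load by a level-order pass
  (equivalent to memoized parent walks); LCA queries then climb with
  depth equalization. No Euler-tour preprocessing: trees at this scale
  make O(depth) queries perfectly adequate, and the code stays simple.
* Taxon-id lookup uses a direct-index vector (ids up to 1e8), the
  cheapest O(1) structure at NCBI scale.
* Test problem sizes: the LCA oracle sweep uses 50 random trees of 10
  to 200 nodes and checks every unordered pair against a brute-force
  root-path intersection; recovery suites use 25 groups with 10 scoring
  hits each. These sizes exercise all code paths while keeping the full
  suite in well under a minute.
* Degenerate inputs have defined behaviour: empty alignment files parse
  to empty tables; an empty group list annotates to an empty table; an
  empty FASTA source list merges to an empty stream; `lca` of a
  singleton is the element itself; an empty taxon set is a contract
  violation, not `NA`.
* The CLI resolves options as flags over config file over built-in
  defaults and records the effective values in a run manifest next to
  each output, so every run is auditable. Outputs are written to a
  temporary file and renamed, so readers never observe partial files.
  Stage composition is left to the shell — the subcommands are
  deliberately plain filters rather than a workflow engine.

## Known limitations

* Only exact (100%) identity deduplication; no sub-identity clustering.
* Only MD5 header hashing; other algorithms are rejected rather than
  approximated. A header that is itself 32 hex characters would be
  mistaken for an already-hashed header and skipped.
* Scientific names only are loaded from `names.dmp`; synonyms and other
  name classes are ignored, and no rank normalization across taxonomy
  versions is attempted.
* The per-query hit cap is applied before group pooling; a group with
  many members can therefore accumulate more than `max_hits` votes.

## A worked example

```{r example}
dir <- tempfile()
taxo <- generate_taxonomy(n_internal = 6, n_leaves = 10, seed = 1, dir = dir)
tree <- load_taxonomy(taxo$paths$nodes, taxo$paths$names, taxo$paths$merged)

truth <- scenario_truth(c("G1", "G2"), taxo$leaves[1:2],
                        c("Chaperone protein DnaK", "60 kDa chaperonin"),
                        noise = 0.3, seed = 1)
sc <- generate_scenario(truth, tree, file.path(dir, "scenario"))

groups <- read_protein_groups(sc$paths$groups)
tax_hits <- read_alignments(sc$paths$tax_aln)
fun_hits <- read_alignments(sc$paths$fun_aln,
                            columns = outfmt6_columns(staxids = FALSE))
amap <- read_annotation_map(sc$paths$annotation)

annotate_groups(groups, tax_hits,
                list(uniprot = list(hits = fun_hits, annotation = amap)),
                tree)
```

Both planted labels are recovered despite 30% off-target hits; the LCA
retreats toward the root exactly as far as the conflicting taxonomic
evidence forces it to.
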