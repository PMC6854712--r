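# metaprot

Curated protein search databases and consensus protein-group annotation
for metaproteomics.

Metaproteomics matches community MS/MS spectra against a FASTA search
database and reports identifications as **protein groups** — sets of
homologous proteins sharing identified peptides. Both ends of that
workflow are fragile: public repositories are too broad to serve as
habitat-specific search databases, and annotating a group from the single
best alignment hit of a single member is unreliable whenever the top hits
disagree (the *protein inference issue*). `metaprot` is for
metaproteomics practitioners who need (a) a reproducible way to assemble
a combined, deduplicated, compactly-headered search database from several
FASTA sources, scoped by taxon ids or by gene/protein names, and (b)
automated, deterministic **consensus** annotation of protein groups from
many alignment hits instead of the first one.

## The method

Per query protein, tabular alignment hits (BLAST/Diamond outfmt-6
dialect) are filtered by a retention policy — bitscore ≥ 80 bits, at most
20 hits, both configurable — with deterministic tie-breaking (descending
bitscore, then ascending e-value, then file order). Per group *G* with
retained hit set *H(G)* pooled over its members:

* **Taxonomy:** each hit contributes one taxon (a multi-taxon hit is
  pre-collapsed to the LCA of its own taxa); the group's annotation is
  the strict lowest common ancestor
  `LCA({tax(h) : h ∈ H(G)})`
  over an NCBI-style taxonomy (`nodes.dmp`/`names.dmp`/`merged.dmp`),
  i.e. the deepest node that is an ancestor-or-self of every voting
  taxon. No resolvable evidence ⇒ `unassigned`.
* **Function:** each hit votes with the normalized annotation label
  (UniProt recommended name, or COG id) of its subject accession;
  `label(G) = argmax_l #{h : label(h) = l}`, ties broken by summed
  bitscore, then lexicographic order. No votes ⇒ `hypothetical/unknown`.
  Multiple functional references are reported side by side, never merged.

Database construction composes `merge → deduplicate → hash_headers`:
exact (100%) identity deduplication keeping first occurrences, and MD5
hashing of full description lines with a restorable header map. The
pipeline is idempotent on its own output.

## Worked example

Generate a synthetic scenario with planted truth (two groups, 30%
off-target hits per group) and annotate it:

```r
library(metaprot)

dir <- tempfile()
taxo <- generate_taxonomy(n_internal = 6, n_leaves = 10, seed = 1, dir = dir)
tree <- load_taxonomy(taxo$paths$nodes, taxo$paths$names, taxo$paths$merged)

truth <- scenario_truth(c("G1", "G2"), taxo$leaves[1:2],
                        c("Chaperone protein DnaK", "60 kDa chaperonin"),
                        noise = 0.3, seed = 1)
sc <- generate_scenario(truth, tree, file.path(dir, "scenario"))

groups   <- read_protein_groups(sc$paths$groups)
tax_hits <- read_alignments(sc$paths$tax_aln)
fun_hits <- read_alignments(sc$paths$fun_aln,
                            columns = outfmt6_columns(staxids = FALSE))
amap     <- read_annotation_map(sc$paths$annotation)

annotate_groups(groups, tax_hits,
                list(uniprot = list(hits = fun_hits, annotation = amap)),
                tree)
#>   group_id lca_taxon_id lca_rank lca_name  lca_lineage tax_hits_used
#> 1       G1            1  no rank     root no rank:root            10
#> 2       G2            1  no rank     root no rank:root            10
#>   tax_hits_unresolvable          uniprot_label uniprot_support uniprot_used
#> 1                     0 Chaperone protein DnaK               7           10
#> 2                     0      60 kDa chaperonin               7           10
```

Each group pooled 10 retained hits (`uniprot_used`); the planted label
wins with 7 votes against 3 off-target votes (`uniprot_support`), while
the taxonomic LCA retreats to the root because the off-target hits come
from a disjoint clade — conflicting evidence makes the taxonomy
conservative rather than wrong. With `noise = 0` both groups annotate to
their planted leaf taxon.

The same run from the shell:

```sh
inst/cli/metaprot fixtures --out-dir fix --seed 1 --groups 5
inst/cli/metaprot annotate --groups fix/groups.tsv \
    --tax-aln fix/taxonomy_hits.tsv --taxonomy-dir fix \
    --func-aln up=fix/functional_hits.tsv:fix/functional_map.tsv \
    --out annotations.tsv
```

Every subcommand writes a `*.manifest.yaml` recording the effective
parameters (flags beat config file beat defaults).

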