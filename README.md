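# guidecraft

Reference-free CRISPR sgRNA design for any organism with a genome
sequence.

Most guide-design web tools make you pick a pre-indexed reference
species before they will score off-targets — and the overwhelming
majority of sequenced genomes, plant genomes especially, are not on
those lists. `guidecraft` removes that dependency: you hand it a
genome as FASTA, it builds a genome-wide protospacer uniqueness
database, and from then on every design run marks guides that occur
more than once in *your* genome, enumerates candidate off-target sites
within a bounded number of base differences, and scores them with a
cutting-frequency-determination (CFD) style penalty model. It is
aimed at wet-lab biologists working on non-model organisms, and at
anyone who wants a scriptable, fully deterministic design pipeline.

## The model in brief

For a PAM model with IUPAC pattern $P$ (e.g. NGG for SpCas9, 3' of a
20-nt spacer; TTTV for Cas12a, 5' of a 23-nt spacer), a **candidate
guide** is any spacer-length window adjacent to a $P$-matching window
on either strand of the target. The pipeline then computes, per guide
$g$:

* **Uniqueness** — the genome-wide count $c(g)$ of PAM-adjacent
  occurrences of the spacer sequence; $c(g) = 1$ is unique, anything
  else is reported as `not_unique` (marked, never dropped).
* **Off-target sites** — every PAM-adjacent site $s$ on either strand
  with Hamming distance $d(g, s) < 5$ (user-settable bound; the
  on-target locus is excluded). Each site is scored
  $\mathrm{CFD}(g,s) = p_{\mathrm{PAM}}(s) \prod_{i \in \mathrm{mm}} p_i(g_i \to s_i)$,
  a product of per-position mismatch penalties times a PAM penalty,
  with $\mathrm{CFD} = 1$ exactly for a perfect match with canonical
  PAM.
* **Specificity** — the aggregate
  $1 / (1 + \sum_s \mathrm{CFD}(g,s))$ over all off-target hits.
* **Quality flags** — GC fraction; a `!` marker for runs of four or
  more consecutive T's (a Pol III terminator risk) or A's; a hairpin
  flag from an exhaustive inverted-repeat scan; and a pluggable linear
  activity score over the spacer-plus-flanks context.

Guides are ranked (unique first, then specificity, then activity,
then position) and written as TSV reports plus an SVG position map.
A shared-guide mode returns spacers present in *every* member of a
gene group, for multiplex editing of polygenic traits; extraction
helpers pull promoter/mRNA/CDS/UTR sequences straight from a GFF3
annotation. The packaged CFD and activity weight tables are synthetic,
provenance-tagged stand-ins with the right structure — substitute
published tables via the `mismatch_path`/`pam_path`/`path` arguments
for production scoring.

## Worked example

```r
library(guidecraft)

genome <- random_genome(1, 50000, seed = 1)        # stand-in for your FASTA
target <- substr(genome[[1]], 5001, 6000)           # a 1-kb gene of interest

index  <- build_index(genome, "SpCas9-NGG")         # reusable uniqueness DB
design <- design_for_sequence(target, index, genome,
                              design_params(), target_id = "geneA")
glance(design)
```

```
# A tibble: 1 x 8
  target_id target_length n_guides n_unique n_poly_ta n_hairpin mean_specificity total_offtargets
  <chr>             <int>    <int>    <int>     <int>     <int>            <dbl>            <int>
1 geneA              1000      103      103         6        21            1.000                2
```

The 1-kb target yields 103 candidate NGG guides, all genome-unique
(`n_unique == n_guides`); only two near-match off-target sites exist
in the whole 50-kb genome (`total_offtargets 2`), so mean specificity
rounds to 1.000; six guides carry the poly-T/A `!` warning and 21
fold a potential hairpin under the default stem/loop parameters.
`tidy(design)` gives the per-guide table, `autoplot(design)` the
position map, and

```r
write_report_set(design, "geneA")
```

writes `geneA.guides.tsv`, `geneA.offtargets.tsv` and
`geneA.geneA.map.svg`.

The same pipeline is scriptable from a shell via the launcher in
`inst/cli/` (`fixtures`, `build-db`, `extract`, `design`, `shared`,
`offtarget`, `primers`, `scaffold` subcommands):

```sh
GC=$(Rscript -e 'cat(system.file("cli","guidecraft.R",package="guidecraft"))')
Rscript "$GC" build-db --genome genome.fa --pam SpCas9-NGG --out genome.db
Rscript "$GC" design --genome genome.fa --db genome.db --targets genes.fa --out run
```

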