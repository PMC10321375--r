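---
title: "guidecraft: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{guidecraft: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(guidecraft)
```

## The problem and the approach

Designing a single-guide RNA (sgRNA) means choosing a spacer that
directs a Cas nuclease to one locus and, as far as possible, nowhere
else. Web tools typically require the user to pick a pre-indexed
reference species before they will evaluate off-targets, which leaves
most sequenced organisms unsupported. `guidecraft` works
reference-free: any genome supplied as FASTA is indexed into a
protospacer uniqueness database, and all downstream evaluation —
uniqueness marking, bounded-mismatch off-target search, CFD-style
scoring — runs against that user-supplied sequence set.

The pipeline has five stages, each exposed as ordinary functions over
tibbles so they compose with the pipe:

1. **Candidate enumeration** (`enumerate_protospacers()`): every
   window of the model's spacer length adjacent to an IUPAC PAM match
   on either strand. Coordinates are 0-based half-open internally and
   converted to 1-based inclusive only in report files; windows
   containing `N` are skipped rather than expanded (expansion would
   inflate the candidate space with no information gain).
2. **Uniqueness** (`build_index()`, `occurrence_count()`): a
   genome-wide table of PAM-adjacent spacer occurrence counts, in
   guide orientation. Uniqueness is defined on the spacer sequence
   alone — the sgRNA does not include the PAM — and only PAM-adjacent
   occurrences are counted; PAM-less exact duplicates are the
   off-target search's job. A spacer and its reverse complement are
   distinct keys. The index serialises to a versioned plain-text
   table with the genome digest in its header, so a design run can
   verify it was built from the same sequence set (a mismatch is a
   hard error, not a warning).
3. **Off-target search** (`find_offtargets()`): every PAM-adjacent
   site on either strand with spacer Hamming distance strictly below
   the bound. The default bound reports 0–4 base differences
   ("less than five"); the CLI flag `--max-mismatch` is inclusive and
   maps to bound `value + 1`. Matching is delegated to the C-level
   bounded-mismatch matcher in Biostrings (`matchPattern(max.mismatch
   = ...)`), which we preferred over a hand-rolled pigeonhole seed
   index: it is exact, already optimised, and keeps the package free
   of a second index structure. An independent hand-written exhaustive
   scanner lives in the test-suite and must agree with the search
   field-by-field on every fixture.
4. **Scoring** (`cfd_score()`, `specificity_score()`,
   `activity_score()`, flags): described below.
5. **Ranking and reporting** (`design_for_sequence()`,
   `write_report_set()`): deterministic ordering, TSV + SVG output.

## Scoring model

The CFD-style off-target score of a site $s$ for guide $g$ is

$$\mathrm{CFD}(g, s) \;=\; p_{\mathrm{PAM}}(s)\;\prod_{i \,:\, g_i \ne s_i} p_i(g_i \to s_i),$$

a product over mismatched positions of a per-position,
per-base-change penalty in $[0,1]$, multiplied by a penalty for the
site's PAM. A perfect match with the canonical PAM scores exactly
1.0, and adding a mismatch can never raise the score. Positions are
numbered 1..spacer-length from the 5' end of the spacer in guide
orientation.

Off-target sites may carry a *near-canonical* PAM: the admission
pattern is the canonical pattern with its most 5'-proximal single-base
position widened to N (NGG becomes NNG), and non-canonical PAMs are
down-weighted through $p_{\mathrm{PAM}}$. `pam_mode = "canonical"`
restricts admission to the canonical pattern instead. Patterns with no
single-base position (near-PAMless SpRY) relax to themselves.

**Provenance of the packaged tables.** The penalty tables ship as
editable TSVs (`cfd_mismatch_synthetic.tsv`, `cfd_pam_synthetic.tsv`)
and are *synthetic stand-ins*, named and source-tagged as such: they
reproduce the structural properties the scoring contract needs
(penalties in $(0,1)$, PAM-proximal mismatches penalised more
strongly, transversions more than transitions, canonical PAM at 1.0)
but are not transcribed from any publication. Substitute a published
table via `penalty_table(mismatch_path=, pam_path=)` for production
use; every score is a plain table lookup, so the engine never
hard-codes the numbers. The same applies to the linear activity
model's weight table (`activity_weights_synthetic.tsv`).

The per-guide aggregate is $\mathrm{specificity} = 1/(1 + \sum_s
\mathrm{CFD}(g,s))$ over the hit list with the on-target locus
excluded: 1.0 with no off-targets, strictly decreasing in any hit's
score. This aggregate form is this package's own choice (the
field reports per-site scores; an aggregate is needed for ranking).

## Quality flags and activity

* **Poly-T/A**: flagged iff the spacer contains `TTTT` or `AAAA` — two
  homopolymer conditions, not a mixed A/T run. Four consecutive T's
  are the canonical Pol III terminator concern; A-runs are flagged
  symmetrically. The flag is a warning marker rendered as `!` in
  reports; flagged guides are reported, never dropped.
* **Hairpin**: exhaustive inverted-repeat scan over the spacer plus a
  configurable scaffold — true iff a stem of `min_stem` (default 4)
  nucleotides has its reverse complement downstream with a loop of at
  least `min_loop` (default 3). These defaults are conservative
  screening values, not thermodynamics; minimum-free-energy folding is
  out of scope.
* **Activity**: a pluggable linear scorer over a 30-nt context (4-nt
  5' flank, 20-nt spacer at positions 5–24, PAM, 3-nt 3' flank):
  intercept + positional one-nucleotide weights + positional
  dinucleotide weights + a GC-count term over the spacer, with the
  GC term split into below-10 and above-10 slopes. When a candidate
  sits too close to the target's edge for a full context, activity is
  reported as missing (`.` in files) rather than imputed, and missing
  activities rank last at their tie level.

## Ranking and determinism

The ranking key is: genome-unique first (when `require_unique`,
default on), then specificity descending, then activity descending
(missing last), then position ascending, with `(start, strand)` as the
final tie-break — a total, locale-independent order. There is no
randomness anywhere in the design path, and report files are written
with fixed 6-decimal formatting, Unix newlines and UTF-8, so two runs
on identical inputs are byte-identical (the test-suite asserts this at
the byte level, TSVs and SVG alike).

Non-unique guides are retained and printed with the literal token
`not_unique`; "prefer unique" is implemented as rank priority, not as
a filter.

## On-target exclusion

When a target is supplied with its genomic locus, that interval is
excluded from the hit list. When the target is a raw sequence, the
pipeline locates exact full-length occurrences of the target in the
genome (both strands) and excludes those. A consequence worth knowing:
a spliced mRNA sequence does not occur contiguously in the genome, so
its guides' own exonic sites are then counted as mismatch-0 hits; for
spliced targets, prefer designing on the gene/CDS regions or pass
`target_locus` explicitly.

## Shared guides and batch mode

`shared_guides()` returns spacers that occur with a valid PAM in
*every* member of a gene group (the strict all-genes reading; a
fractional threshold is deliberately not offered). Uniqueness
generalises naturally: a shared guide is ideal when its genome-wide
count equals the number of target genes, each occurrence accounted for
by one target; any surplus occurrence surfaces as a mismatch-0
off-target hit. `batch_design()` is by construction identical to
independent per-target runs, iterated in input order.

## Sequence extraction

`load_annotation()` accepts GFF3 only (the plant-genomics standard;
GTF is out of scope), converts to 0-based half-open coordinates at
the boundary, picks the longest transcript per gene (ties broken by
lexicographically smallest ID), takes UTRs from explicit features
when present and derives them as exon-minus-CDS otherwise. Extraction
returns sequences 5'→3' in transcript orientation; the promoter is
`promoter_len` (default 2000 nt, the common plant convention) bases
upstream of the transcription start, truncated at the record
boundary rather than padded.

## Primers and structure templates

Primer design enumerates all candidate flanking primers within length
(18–25 nt), Tm (55–65 °C), GC (0.40–0.60) and pair-ΔTm (≤ 3 °C)
constraints, using the deterministic GC closed form
Tm = 64.9 + 41·(GC − 16.4)/length rather than nearest-neighbour
thermodynamics — it is exactly testable and replaceable. A light 3'
cross-dimer screen rejects pairs with ≥ 4 complementary bases against
a primer's last 5 nt. The product is taken to span the forward
primer's 5' end through the reverse primer's 5' end on the template
(the conventional amplicon definition). The hairpin/GOLD structure
templates are opaque named insertions from an editable config; the
packaged sequences are placeholders flagged in their `source_tag` and
must be replaced with validated sequences before wet-lab use — the
mechanism (templated insertion at a declared position) is what the
package provides.

## The synthetic-data generator

`random_genome()` draws i.i.d. nucleotides at a target GC content;
`plant_sites()` writes spacer+PAM cassettes (optionally with seeded
mismatch edits) and then re-randomises any accidental background
window within the configured Hamming distance of the spacer, so the
returned truth table is *exact*, not probabilistic — a brute-force
scan of the edited genome finds the planted sites and nothing else
within the bound. `toy_annotation()` lays out multi-exon genes with
explicit UTR/CDS structure and returns both GFF3 text and matching
truth models. All generators are pure functions of their parameters
and seed and leave the global RNG untouched.

What the fixtures do *not* emulate: repeat families, segmental
duplications, GC isochores, sequencing gaps. Passing tests on these
fixtures demonstrates algorithmic correctness (agreement with
exhaustive search, exact counting, determinism), not biological
performance of the synthetic scoring weights on real genomes.

## Problem sizes and numerical choices

The test-suite exercises 100-kb genomes (uniqueness and off-target
oracle equivalence, 50 random guides at bounds 1..6), 20–50-kb
genomes for pipeline tests, and 1000-pair random checks of the CFD
product rule; these sizes give exhaustive-oracle coverage while
keeping a full run in the minutes range on one CPU. Floating-point
report fields are fixed at 6 decimals for diff-stability; CFD
comparisons in tests use exact table arithmetic (the score is a short
product of table entries, so no tolerance is needed beyond machine
epsilon).

## Known limitations

* Bulge (insertion/deletion) off-targets are not searched; the bound
  is Hamming distance only.
* Chromatin accessibility and experimental off-target evidence are
  not integrated.
* The shipped CFD/activity weights are synthetic stand-ins (see
  above); absolute score values are not biologically calibrated until
  a published table is substituted.
* The uniqueness database counts PAM-adjacent occurrences only; this
  is a deliberate definition choice, with PAM-less duplicates handled
  by the off-target search.
* `--threads` is accepted but single-threaded; all operations are
  deterministic and sized for desk-scale genomes (tens of megabases
  index fine; whole large plant genomes will want patience or
  per-chromosome runs).
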