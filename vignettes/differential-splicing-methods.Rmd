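---
title: "Cell-type-resolved differential splicing: models, filters, and design choices"
author: "snSplice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-type-resolved differential splicing: models, filters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind snSplice, the
meaning and defaults of its tunable parameters, what the synthetic-data
generator does and does not emulate, and the design decisions taken
where the method left genuine freedom.

# The data model

The unit of observation is a single deduplicated long read: a
(sample, condition, cell type, barcode) label, a UMI, an assigned gene,
an aligned genomic span, and an ordered **intron chain** — the list of
splice junctions in the alignment, each written as 1-based inclusive
intronic coordinates. Coordinates are 1-based inclusive everywhere
inside the package (the GTF convention); only BED output converts to
0-based half-open at the boundary, which keeps all internal arithmetic
free of off-by-one conversions. Barcode calling, mapping, and
splice-site correction are upstream concerns: the read table is the
contract with the mapper, and junction matching downstream is
coordinate-exact (a `--junction-tolerance`-style wobble is deliberately
not applied; a mapper that emits corrected, annotation-consistent
junctions is assumed).

# Read-level cleaning

**UMI deduplication.** Nanopore-class error rates corrupt UMIs, so
reads whose UMI lies within Levenshtein distance 3 (i.e. "less than 4")
of a more frequent UMI are discarded. Two choices deserve notice:

* *Scope.* UMIs are compared within a (barcode, gene) group by default
  — a UMI collision is only meaningful within one cell and gene. The
  scope is exposed (`scope = "barcode"`, `"global"`) for users whose
  upstream pipeline assigned UMIs differently.
* *Retained-set comparison.* UMIs are ranked by read count (ties broken
  lexicographically, which makes the result invariant to row order) and
  each UMI is compared against the already-retained set, not against
  all input UMIs. Otherwise a chain of mutually-close low-count UMIs
  could eliminate one another even after their high-count "attractor"
  was removed.

**Rare-chain filtering.** A read whose exact, gene-scoped intron chain
(the empty chain of a mono-exonic read forms its own class) occurs
fewer than 5 times across all samples pooled is discarded. The order —
dedup first, chain filter second — matters and is fixed.

# Exon events and Ψ

An **alternative exon** is an internal exon (flanked by junctions on
both sides in at least one transcript or read) that is entirely
included in some reads and entirely excluded in others. Candidates come
from the annotation's internal exons and from *observed* exons —
read-chain segments bounded by two junctions — which captures cryptic
exons absent from the annotation. An unannotated candidate must appear
in flanked form in ≥ 2 distinct reads (configurable) to suppress
single-read artifacts.

Classification of a read against an exon is deliberately conservative:

* **Inclusion** requires the read to cover the whole exon with
  junctions matching *both* boundaries, or — for truncated reads
  starting/ending strictly inside the exon — a junction matching the
  one boundary the read covers. A read ending inside the exon with no
  adjacent junction is uninformative: degraded 3′/5′ ends must not
  vote. A read starting exactly at the exon boundary cannot support the
  upstream junction and is likewise uninformative.
* **Exclusion** requires a *single* junction whose intron covers the
  exon plus ≥ 50 bases of flank on each side (`flank`, default 50). A
  read that skips the exon via two stacked junctions — an intervening
  exon within the flank — is uninformative, a conservative reading of
  the "neither the exon nor 50 bases to either side" rule.
* `total` counts every read overlapping the exon's locus, informative
  or not; it is the denominator of the coverage filter.

Ψ = inclusion/(inclusion + exclusion), and ΔΨ = Ψ_case − Ψ_control, so
negative values mean more skipping in disease.

# The test cascade

Per cell type (or any stratum — subtype-resolved analyses reuse the
same code path with a different grouping column, and pseudobulk is just
the counts summed over cell types with sample identity kept):

1. *Eligibility*: pooled Ψ across both conditions within [0.05, 0.95]
   (`psiBounds`; the bounds are applied to the pooled Ψ, which is the
   natural reading of an unqualified "a Ψ" and is configurable),
   ≥ 10 informative reads per condition (`minReadsPerCondition`), and
   coverage (inclusion + exclusion)/total ≥ 0.8 (`coverageMin`).
2. *Test*: Fisher's exact two-sided p on the pooled 2×2 table. The
   "chi-squared criterion" is implemented as Cochran's rule — all four
   expected counts ≥ 5 — the standard validity criterion for 2×2
   approximations; gated-out exons keep their p but are excluded from
   the multiple-testing family so that m reflects only assessed tests.
3. *FDR*: Benjamini–Yekutieli, valid under arbitrary dependence (exons
   of one gene are anything but independent), per cell type.
4. *Per-sample filters*: support (≥ ⌈2n/3⌉ samples per group with an
   informative read) and ordering (in the direction of the pooled
   difference, ≥ ⌈2n/3⌉ of the higher group's informative samples must
   each strictly exceed ≥ ⌈2m/3⌉ of the lower group's). Ceiling is used
   for the two-thirds rules and ties count against passing — both the
   conservative, deterministic choice; at the design's n = 6 ceiling
   and floor coincide anyway. Samples with zero informative reads are
   excluded from both sides of the ordering rule.
5. *Call*: significant iff q ≤ 0.05, |ΔΨ| ≥ 0.20, and every filter
   passes. The full table, including ineligible exons with their
   per-filter flags, is always returned.

**Age-matched robustness.** Cohorts of this kind are rarely
age-balanced. `ageMatchedCheck()` picks, once, the 4-per-group subsets
minimizing the group mean-age difference (exhaustive search over the
C(6,4)² pairs), recomputes ΔΨ on the subset, and requires the same sign
and ≥ 50% of the full magnitude. Groups smaller than the subset leave
the flag undefined without failing the exon.

# Splice-site usage

Introns sharing a gene, strand, and acceptor but differing in donor
form a donor group (acceptors symmetric; donor/acceptor identity is
strand-aware). The two sites with the highest totals across all samples
(ties broken toward the lower genomic coordinate — ΔΨ magnitude is
unaffected by which label wins) define a 2×2 case/control table. A
group is discarded when either condition is empty in that table or when
the table captures < 80% of the group's grand total — both thresholds
read literally as grand totals, not per-condition. BY families are per
(cell type, site kind); calls need q ≤ 0.05 and |ΔΨ| ≥ 0.10. Intron
counts are derived from the read chains internally, and an import path
accepts an external per-intron count table from a transcript
quantification tool.

# Cross-stratum analyses

* **Masking**: a cell-type-significant exon is masked when not
  significant in pseudobulk under identical criteria. Exons untested in
  pseudobulk count as masked and are reported separately, so a user can
  apply either denominator convention. The fraction gets a Wilson score
  95% CI (a CI method must be chosen; Wilson behaves well at the small
  counts involved).
* **ΔΨ correlation** between strata: Pearson r over exons with defined
  ΔΨ in both, Fisher-z CI, by default restricted to exons significant
  in ≥ 1 stratum. Fewer than 3 pairs or zero variance yield an explicit
  "undefined" row rather than a number.
* **Expression overlap**: over genes tested for both splicing and
  expression, the 2×2 of (≥ 1 significant exon) × (DE at
  |log2FC| ≥ 0.1, FDR ≤ 0.05), Fisher p and the sample odds ratio
  (a·d)/(b·c); with a zero cell, the Haldane–Anscombe +0.5 correction
  is reported alongside and flagged.

# Probe design

For every junction of every transcript, 70 spliced bases per side are
collected, walking across adjacent exons of the *same transcript* when
an exon is shorter than 70 bases; windows shorter than 130 bases (near
transcript ends) are discarded, and no compensation is taken from the
other side. Transcripts sharing a junction but differing in neighboring
exons each yield a candidate, then candidates are deduplicated by
sequence within the gene. The final 120-mer must contain the junction
breakpoint; the selection score — 1 if GC ∈ [0.30, 0.70], else 0, ties
broken by junction centrality then leftmost offset — is a transparent,
testable proxy for a vendor's proprietary hybridization optimizer and
is injectable (`scorer=`). Mappability is likewise an injected oracle
(default: exact string matching of the 120-mer and its reverse
complement against the supplied genome); applying the > 5-hits filter
to the final 120-mer (the synthesized sequence) rather than the window
is a choice, and both hit counts are reported. Genes keeping fewer than
5 probes are dropped entirely.

# The synthetic-data generator

`simulateDataset()` emulates the cohort design the analysis targets:
6 case and 6 control donors, several cell types with per-sample cell
counts, negative-binomial read depth per (cell, gene) (the field lacks
a canonical per-exon depth law; NB mean/dispersion are configurable,
default mean 2, size 2), planted per-(gene, cell type, condition)
inclusion probabilities, optional planted donor-site usage, and
per-sample heterogeneity as a Beta deviation around the group Ψ with
concentration 300 (per-sample sd ≈ 0.03 at Ψ = 0.5 — enough
inter-individual spread to exercise the two-thirds rules without
drowning modest planted effects). Default donor ages mirror an
age-imbalanced cohort (case mean 67.5, control mean 78.8 years) so the
age-matched check is exercised realistically. Reads are full
intron-chain records: sequencing error is modeled only on UMIs (each
read gets a UMI unique at pairwise distance > 3 within its
(barcode, gene) group, so noise-free data pass deduplication unchanged;
`injectUmiNoise()` then substitutes bases at a configurable per-read
rate). A fixed seed makes the output byte-identical.

What the generator does **not** emulate — and what passing tests
therefore cannot show about real data: capture efficiency and probe
bias, TSS/poly(A) variation and 3′/5′ degradation (simulated reads are
full-length; truncated-read classification is exercised by constructed
fixtures instead), base-call errors inside the read body, mapping and
splice-site placement errors, doublets and ambient RNA, and realistic
gene-expression differences (DE inputs to the overlap analysis are
planted directly).

# Validation problem sizes and numerical choices

The test suite validates the statistics against independent oracles
(full hypergeometric enumeration for Fisher's p at margins ≤ 40 to
1e-10; the hand step-up formula for BY; an O(n²) all-pairs scan for UMI
dedup) and the pipeline against planted truth at sizes chosen to be
decisive yet desk-scale: null calibration with 500 exons × 12 samples
over 10 seeds (significant fraction of gated exons ≤ 0.05); power and
recovery with 50 exons at ΔΨ = ±0.4 and ≈ 300 informative reads per
condition; a masking construction with the effect confined to a cell
type holding 10% of reads at ≈ 150 informative minor-cell reads per
condition (enough that the cell-type call itself is comfortably
powered); and donor-usage shifts of 0.3 at ≈ 600 reads per condition.
At 300 informative reads the binomial sampling sd of ΔΨ is ≈ 0.04, so
the ±0.10 recovery bound sits near 2.5 sd — tight enough to be
meaningful, loose enough to be reachable.

Degenerate inputs are handled explicitly rather than silently: Ψ with
zero informative reads is NA and flagged; a zero-margin 2×2 has
undefined p and fails the gate; an empty group fails the ordering
filter; correlation with < 3 pairs or zero variance reports why it is
undefined; probe design without a mappability source is a hard error.

# Known limitations

* Age is handled only through the subset robustness check; there is no
  continuous covariate adjustment.
* Junction matching has no wobble window, by design; inputs from
  mappers without splice-site correction will undercount events.
* Exclusion requires a single spanning intron, so exotic skipping paths
  contribute no exclusion evidence.
* Coordinated exon pairs, TSS/poly(A) testing, and annotation-free
  transcript assembly are out of scope.
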