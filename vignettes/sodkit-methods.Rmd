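---
title: "Methods: promoter scanning, expression quantification and inference in sodkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: promoter scanning, expression quantification and inference in sodkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sodkit)
```

sodkit implements the computational arm of a common study design in insect
immunology: characterise the Cu,Zn superoxide dismutase (SOD) gene family of
a beetle *in silico* (promoter cis-elements, gene architecture), then measure
its response to immune priming *in vivo* (RT-qPCR relative expression, total
SOD enzyme activity, survival), with classical ANOVA/post-hoc inference on
top. This vignette documents the models, conventions and numerical choices,
and what the package's validation does and does not establish.

## Promoter motif scanning

Cis-elements are expressed as degenerate IUPAC consensus strings — the
antioxidant responsive element ARE (`TGACNNNGC`), its half site hARE
(`TGACNNN`) and the xenobiotic responsive element XRE (`TGCRCNC`) ship as
the default set; others can be supplied as a two-column TSV. Matching is by
**subset semantics**: a subject position satisfies a pattern position iff
the subject letter's base set is contained in the pattern letter's set. A
genomic `N` (masked base) therefore matches only a pattern `N`, so masked
regions can never inflate counts. Both orientations are scanned; reverse
hits are matches of the reverse-complemented pattern reported in
forward-window coordinates with strand `-`.

Three conventions matter for reproducing a published count table:

* **Window.** The scanned window is the `window_nt` bases immediately 5' of
  the start codon (not of the transcription start site), so it typically
  covers part of the 5' UTR and any 5'-UTR intron. The default is 1000 nt —
  the span in which reported cis-element censuses of these genes
  concentrate — while 2000 nt is a common full analysis span; `window_nt`
  is a config knob.
* **Overlaps.** All overlapping occurrences are counted. Any deterministic
  overlap-suppression rule interacts unpredictably with degenerate
  patterns, so nothing is suppressed.
* **Nesting.** Motifs are counted independently: because `TGACNNN` is a
  prefix of `TGACNNNGC`, every full ARE site necessarily also contributes
  one hARE count in the same orientation. This is the only convention that
  can be stated without access to the original scanning code, and it is
  applied uniformly.

The scanner encodes letters as 4-bit base masks and tests
`AND(subject, pattern) == subject` per position. It is validated against an
independently written position-by-position set-based enumerator on
thousands of random (window, pattern) pairs, and against planted-motif
ground truth (below).

## Gene architecture

`summarize_architecture()` splices the exons of each gene model into the
mature transcript, locates the CDS on it and reports:

* **ORF length** in nt, with the convention that the ORF **includes the
  stop codon**, hence protein length = ORF/3 − 1. This convention
  reproduces the published pairs 615 nt → 204 aa and 501 nt → 166 aa.
  Public annotations occasionally print protein lengths inconsistent with
  their own ORF arithmetic; when an `annotated_protein_aa` column is
  present and disagrees, the gene is flagged `length_discrepancy` rather
  than silently corrected (two of the four default loci carry this flag on
  purpose).
* **UTR lengths** from the CDS position on the mature transcript;
  `utr5 + orf + utr3` always equals the spliced length.
* **Intron classes** (5' UTR, CDS, 3' UTR) from the genomic position of
  each intron relative to the CDS span, strand-aware.
* **Poly-adenylation signals**: 1-based start positions of `AATAAA` on the
  mature transcript at or after the first 3'-UTR base, overlaps included.
  Only the canonical hexamer is searched by default (the signal is a
  config string, so `ATTAAA` can be added). Positions are reported on the
  mature transcript because that is how they are conventionally quoted.
* **Deduced molecular weight** from average (not monoisotopic) residue
  masses plus one water, matching the "deduced MW" convention for
  conceptual translations.

A gene whose spliced CDS is not a canonical ORF (no ATG, internal stop,
frame error) is reported with an `invalid_orf` flag, not an error, since
annotation defects are data, not bugs.

## Relative expression (2^-ddCt)

Technical replicates are averaged per sample × gene × biological
replicate; a spread above 0.5 cycles is flagged but never auto-dropped
(the tolerance is a parameter; the value is a common bench rule of thumb).
For target gene *g*, reference *r* (default `rp49`) and calibrator cell
*c* (default the untreated naive/naive cell):

dCt = Ct_g − Ct_r, ddCt = dCt − dCt(c), RQ = 2^−ddCt.

Calibration is **per biological replicate** by default — replicate *k* of
every cell is calibrated against replicate *k* of the calibrator — because
the design consists of independent experiments; a pooled-calibrator mode
(`per_replicate = FALSE`) is available, and is also the documented fallback
(with a warning) when a calibrator replicate is missing. Summaries are mean
± SE (sd/√n) on the linear RQ scale, matching the usual "mean of three
independent experiments ± SE" presentation; log2-scale summaries are
returned alongside. The RQ formula assumes perfect doubling per cycle
(the Livak method); measured primer efficiencies act as QC only:
`standard_curve_efficiency()` fits Ct on log10 quantity by OLS and reports
efficiency `10^(−1/slope)`, with the conventional acceptance bound of 1.9.

## ANOVA, Student–Newman–Keuls and survival comparisons

Treatment cells are compared by classical one-way ANOVA (`stats::aov`)
followed by a Student–Newman–Keuls (SNK) stepwise post hoc written for this
package:

* The studentized range CDF is computed by direct double numerical
  integration — the inner normal-range probability with adaptive
  quadrature, the outer integral over the chi-distributed scale with
  96-node Gauss–Legendre — and inverted by bisection to 1e−5 on the
  quantile. The identity q(α, 2, ν) = √2·t(1−α/2, ν) and R's `qtukey`
  serve as independent cross-checks in the test suite, never as the
  implementation.
* Means are sorted; spans are tested widest-first against
  q(α, p, df)·√(MSE/ñ), with ñ the harmonic mean group size (the standard
  unbalanced extension). Once a span is non-significant, all nested spans
  are declared non-significant untested (stepwise closure), which makes
  the decision set internally consistent and, at k = 2, makes SNK exactly
  the pooled-variance t-test.

Survival is scored once per experiment as a per-cell proportion and
summarised as mean ± SE across experiments; cells are compared by
two-sided Wilcoxon rank-sum tests on the per-experiment proportions
(the unit of observation the figure-style summaries imply), exact by
enumeration when both groups have ≤ 8 observations without ties, otherwise
the normal approximation with tie correction. Raw p-values mirror the
common reporting practice; Holm-adjusted values are always returned
alongside because many pairs are tested.

## SOD activity from NBT inhibition

One unit of SOD is the enzyme amount giving 50% inhibition of NBT
reduction. Per sample, percent inhibition is
100·(A_blank − A_sample)/A_blank, clamped into [0, 100] with a flag
(negative inhibition is assay noise and must not propagate into negative
activity). Readings at duplicate amounts are tie-averaged; the curve must
then be non-decreasing and bracket 50%. The 50% point x50 is found by
piecewise-linear interpolation on the (amount, inhibition) axes — a
log-amount mode exists — and volumetric activity is 1/x50 U/µL. Total
protein comes from a Lowry standard line (absorbance on concentration,
OLS, inverted at the sample absorbance; extrapolation beyond the standard
range is flagged), and specific activity is units·1000/protein in U/mg.
Piecewise-linear interpolation was chosen over a parametric logistic fit
because the unit definition is itself point-based; with readings spanning
20–80% inhibition the interpolation error is within a few percent of a
true logistic curve's x50, which the validation suite checks.

## The synthetic study

`write_synthetic_bundle()` generates every input the pipeline consumes
plus `truth.json`, a machine-readable ground-truth ledger. Its defaults
*are* the study conditions the package is validated under:

* **Loci**: four Tribolium-like Cu,Zn-SOD genes with the published
  architecture (soda 462 nt ORF, 326/100 nt UTRs, one 5'-UTR intron,
  poly-A at 879; sodb1 615 nt ORF with five exons and a ~2 kb 5'-UTR
  intron; sodb2 501 nt ORF, poly-A at 721, on the minus strand; sodc
  684 nt ORF, 662/36 nt UTRs) and the published promoter census (soda:
  one reverse ARE, 6/3 hARE, one forward XRE; sodb: two reverse hARE;
  sodc: 2/3 hARE). Where printed numbers are internally inconsistent
  (soda/sodc protein lengths; sodc intron count vs exon count; two poly-A
  positions that fall outside their own 3' UTRs), the generator keeps the
  self-consistent quantities and the architecture module flags the rest —
  the package reproduces the inconsistency honestly instead of resolving
  it.
* **Expression**: 3 priming × 3 challenge cells, genes soda/sodb/sodc plus
  an infection-responsive AMP control and the rp49 reference, 3 biological
  replicates, duplicate wells. Reference Ct ~ N(20, σ); target Ct adds a
  baseline dCt of 3 cycles minus log2(fold); technical replicates add
  N(0, σ/2); σ defaults to 0.2 cycles, a typical SYBR-green
  reproducibility figure. With σ = 0 the pipeline returns every planted
  fold exactly.
* **Activity**: logistic (Hill) inhibition curves centred on the true x50,
  sampled geometrically around it; Lowry standards on an exact line plus
  noise.
* **Survival**: binomial draws per cell per experiment (default 30
  individuals, 3 experiments), with primed-infected cells surviving at
  0.85 vs 0.55–0.60 for unprimed infected cells.

Planted motif counts are never trusted from the plan: the final window is
re-scanned by an independent naive matcher and *that* census is the truth
(background rejection-plus-masking caps at a fixed number of attempts, so
truth stays exact even in pathological corners). Every generator is a pure
function of (seed, plan); one master seed fans out to per-dataset sub-seeds
through a fixed splitting rule, so bundles regenerate byte-identically.

What the synthetic study does **not** emulate: realistic GC content or
codon usage, amplification-efficiency differences between primer pairs
(the generator assumes perfect doubling, as does the analysis), Ct
censoring at high cycle numbers, inter-plate effects, overdispersed
survival, or isoform-resolved enzyme activity. Passing the recovery suite
therefore shows the *computations* are correct under the stated model, not
that the model captures every failure mode of real bench data.

## Validation problem sizes

The shipped validation suite runs the scanner-versus-enumerator comparison
on 1,000 random windows up to 2 kb, recovers 50 randomized planted loci
exactly, checks the k = 2 SNK/t-test identity on 500 random datasets and
the familywise error rate on 2,000 null simulations (k = 3, n = 10,
observed rate ≤ 0.07 at α = 0.05), and measures twofold ddCt recovery over
200 simulated experiments. With three biological replicates an interval of
±2 estimated SEs is a t₂-type interval (~80% coverage by construction), so
recovery is assessed against the model-implied sampling SE of the RQ mean,
under which ~95% of simulations recover the planted fold.

## Known limitations

* The Pfaffl efficiency-corrected RQ model is out of scope; efficiencies
  are QC only.
* Gene models are single-isoform; overlapping transcript variants are
  represented as separate loci.
* The survival analysis is a single-time-point proportion comparison, not
  a time-to-event model.
* SNK controls the familywise error only under the complete null; like all
  SNK procedures it can exceed α under partial nulls. It is provided
  because it is the field's conventional post hoc for this design.
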