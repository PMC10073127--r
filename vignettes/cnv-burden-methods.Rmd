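---
title: "Methods: multi-caller CNV consensus and case-control burden association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-caller CNV consensus and case-control burden association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvburden)
```

## The problem

Whole-genome sequencing resolves copy-number variants (CNVs) far smaller
than array-based methods — down to the "small genomic deletion" scale of a
few hundred to a few thousand bp. At that scale no single caller is
reliable: read-depth callers (CNVnator-like), split-read/discordant-pair
callers (Delly2/Lumpy-like) and model-based depth callers (cn.MOPS,
GATK-gCNV-like) each have their own false-positive spectrum and breakpoint
uncertainty. The standard remedy is consensus calling: run several tools
per sample, keep only events that at least two tools agree on, and test
case-control association on the resulting regions.

`cnvburden` implements that whole chain as a tested pipeline:

1. **Call-level quality filtering.** CNVnator calls must satisfy three
   rules, all strict inequalities: `e-val1 < 1e-3` and `e-val2 < 1e-3`;
   `q0 < 0.5` and `q0 != -1` (q0 is the fraction of reads mapped with zero
   quality; −1 is the tool's undefined sentinel); and, for deletion calls
   only, `norm_rd < 0.75 * (1 + q0)`, where `norm_rd` is the normalized
   read depth (diploid ≈ 1.0). Calls from the other callers were produced
   with their default parameters, which *is* their filter — they pass
   through unchanged.
2. **Per-sample consensus merging.** Within one sample and event type,
   calls from different callers are linked when their *reciprocal* overlap
   strictly exceeds 0.5, i.e. `min(shared/len(a), shared/len(b)) > 0.5`.
   Connected components of this graph (merging chains transitively) become
   consensus CNVs spanning the union of their members; support counts
   *distinct callers*, and components with support < 2 are discarded.
3. **Breakpoint-union segmentation.** All samples' consensus start/end
   positions are pooled per chromosome and the covered genome is cut at
   every boundary. The resulting *atomic regions* are the largest
   intervals on which every sample's copy state is constant; they
   partition the consensus footprint exactly (asserted in bp by the test
   suite).
4. **Repeat exclusion.** Regions covered ≥ 50% by the merged
   centromere/telomere/segmental-duplication track are removed — these are
   the parts of the genome where depth-based calling is untrustworthy.
5. **Association.** Each region is tested twice — loss carriers vs rest
   and gain carriers vs rest — with a two-sided Fisher exact test on the
   2×2 carrier table (cells: case carriers, case non-carriers, control
   carriers, control non-carriers). Samples with conflicting states at a
   region (both a deletion and a duplication consensus covering it) are
   excluded from that region's denominators.
6. **Burden summary.** Among regions with `p < 1e-5`, the odds-ratio
   distributions of losses and gains are contrasted with a two-sided
   Wilcoxon rank-sum test on the log odds ratios.
7. **Multi-cohort selection.** A locus is reported when it passes every
   gate: whole-primary-cohort `p < 1e-5`; each case batch tested against
   the shared controls at nominal `p < 0.05` with the same odds-ratio
   direction; and a validation-cohort region — called with CNVnator only —
   matched by reciprocal overlap > 0.5 with `p < 0.05` and the same
   direction.

## Statistical definitions

**Fisher's exact test.** With margins fixed, the two-sided p-value is the
sum of hypergeometric probabilities of all tables whose probability is no
greater than that of the observed table (minimum-likelihood rule), with a
relative tolerance of 1e-7 on the comparison. This is the conventional
definition; one-sided-doubling variants differ and are not used. The
implementation is a direct `dhyper` sum over the table support and is
checked in the test suite against a `choose()`-based full enumeration
oracle (agreement to 1e-10 over every table with total N ≤ 40 and 1,000
random larger tables) and against `stats::fisher.test`.

**Odds ratio.** `OR = (a·d)/(b·c)`. When any cell is zero — and only
then — 0.5 is added to every cell (Haldane–Anscombe), making the OR and
its log-variance finite. The 95% CI is Wald:
`exp(log(OR) ± 1.96·sqrt(1/a + 1/b + 1/c + 1/d))` on the corrected cells.
The Wald form was chosen for closed-form testability; with the cohort
sizes involved its coverage is adequate for directionality, which is all
the selection gates use.

**Rank-sum comparison.** `stats::wilcox.test` on log odds ratios, exact
when both groups have ≤ 10 untied values, otherwise the normal
approximation with tie correction and no continuity correction (so that
identical samples give p = 1 exactly).

**Multiple testing.** Selection follows raw thresholds (`1e-5` primary,
`0.05` per batch and validation), matching how such multi-cohort designs
gate loci; Benjamini–Hochberg q-values are reported alongside every result
row but are not used for selection.

## Decisions where the design was genuinely open

* **"&gt; 50% identical overlap" is reciprocal.** One-way overlap would
  merge any small call into any giant call; reciprocal overlap is the
  standard SV-merging criterion and is exposed as `min_overlap`.
* **Consensus interval = union of members, not intersection.** The union
  preserves every member's breakpoints for segmentation; the choice is
  documented and the merger is parameterized enough to audit it.
* **The deletion depth rule reads `norm_rd < 0.75·(1 + q0)`**, treating
  the filtered quantity as the normalized-depth column in diploid units.
  An alternative reading (depth in copy-number units, threshold
  `1.5·(1+q0)`) is expressible by setting `del_rd_factor = 1.5`.
* **Carrier status, not copy-number category, fills the 2×2 table.** The
  pipeline dichotomizes each cell to carrier/non-carrier per event class,
  which is what a Fisher 2×2 test requires; a 3-level copy-number test is
  out of scope.
* **Per-batch gate = nominal p < 0.05 + direction concordance.** The
  batch-consistency step is stated qualitatively in such designs; the
  weakest defensible quantitative reading was adopted and both the
  threshold (`p_batch`) and the concordance requirement are parameters.
* **Validation regions are matched by reciprocal overlap > 0.5**, the same
  rule as call merging, for internal consistency; an unmatched region
  fails validation rather than erroring.
* **The burden rank-sum compares significant losses vs significant
  gains** on the log-OR scale — the comparands are a parameter-free
  interpretation of contrasting "OR < 1 gains" with "OR > 1 losses".
* **No minimum region length.** Near-coincident boundaries can produce
  regions of a few bp; they are kept, since the segmentation definition
  states no floor, and the association simply sees fewer carriers there.

## The simulator: what it emulates, and what it does not

`simulation_config()` defaults *are* the study conditions the pipeline
targets:

| parameter | default | meaning |
|---|---|---|
| cohorts | 210 + 100 cases / 100 controls primary; 100/100 validation | two case batches; validation called with CNVnator only |
| genome | 2 chromosomes × 5 Mb | desk-scale while exercising multi-chromosome logic |
| planted loci | 3 deletions, 1.2–1.5 kb | carrier frequency 0.5 in cases, 0.15 in controls |
| background | Poisson(5) events/sample | group-independent: a built-in null |
| background lengths | log-normal, meanlog log(1500), sdlog 0.6 | small-CNV scale, ~0.4–6 kb |
| callers | 5, sensitivity 0.9, 1 FP/sample, jitter SD 20 bp | breakpoints perturbed independently at both ends |
| quality fields | CNVnator only: `norm_rd` N(0.5, 0.05) loss / N(1.5, 0.10) gain, `q0` ~ Beta(1, 9), e-values ≤ 1e-4 for true calls | half of false calls draw large e-values, so the e-value filter removes some |
| repeat track | 10% of each chromosome | telomere blocks at both ends, one centromere block, random segmental-duplication blocks; never overlapping planted loci |

Carriers are heterozygous — one-copy loss (depth ≈ 0.5) or one-copy gain
(≈ 1.5); homozygous states are not simulated, which keeps copy-state
assignment binary per event class. Background events are resampled if they
would overlap a planted locus or another event of the same sample, so
planted loci have clean boundaries in truth.

The *noiseless* configuration (`noiseless_config()`) is the exact-recovery
limit used by the identity tests: sensitivity 1, jitter 0, no false calls,
and quality fields drawn so the CNVnator filter never removes a true call
(q0 ~ Beta(1, 99), e-values below 1e-6). Without the last part the limit
would not be noiseless: with q0 ~ Beta(1, 9) about 0.2% of true calls
fail `q0 < 0.5`, which matters in the single-caller validation branch.

What the simulator does **not** emulate — and therefore what passing tests
do *not* show about real data: read-level evidence (mappability,
GC-coverage waves), caller-specific error correlation (simulated callers
err independently; real depth-based callers fail together in hard
regions), homozygous and multi-allelic copy states, population structure
and batch-specific depth differences, and breakpoint microhomology. The
pipeline's statistical behavior under those conditions must be judged on
real callsets.

## Numerical and degenerate-input choices

* All public coordinates are 0-based half-open; the CNVnator text dialect
  (1-based fully closed) is shifted exactly once, on read, and shifted
  back on write. Chromosome names are opaque tokens — no `chr`
  normalization is attempted, so tracks and callsets must agree.
* Numeric columns are written with `%.17g`, making every writer/reader
  pair a bit-exact round trip.
* Jittered breakpoints are clamped to the chromosome and to `start < end`;
  a call whose jitter pushes its reciprocal overlap with truth below the
  merge threshold is a realistic failure mode and is *not* clamped away.
* Tables that recur across regions (very common: most null regions have
  one carrier) are tested once and the result reused; this is a pure
  memoization with no statistical effect.
* Empty inputs flow through every stage (empty callsets give empty
  consensus, zero regions, empty result tables); a class with no
  significant results makes the burden rank-sum `NA` rather than an error.

## Problem sizes used by the checks

The test suite and the acceptance script run the full design —
610 samples, five callers, ~2,500–3,000 atomic regions per study — in a
few seconds per simulated study. The selection-recovery property is
evaluated over 100 seeded studies; the exact-test oracle comparison covers
all 135,751 tables with total ≤ 40 plus 1,000 random tables with totals up
to 200; the type-I-error check pools two null studies (> 5,000 tests).
The analysis scripts under `analysis/` use 10 seeds for their recovery
table, enough to display the behavior without repeating the full
acceptance computation.

## Known limitations

* The Wald CI is first-order; for cells of 1–2 counts its coverage is
  approximate (directionality, which selection uses, is unaffected).
* Support counts distinct callers but all callers are weighted equally; a
  real analysis might trust split-read breakpoints over depth breakpoints.
* The secondary cohort's single-caller branch inherits CNVnator's full
  false-positive spectrum; the validation gate is therefore asymmetric
  (it can only reject, never rescue, a primary locus).
* Region identifiers encode coordinates (`chr1:1000-2000`), so regions
  from different runs compare by string only when the segmentation is
  identical; cross-run matching should use reciprocal overlap, as the
  selection stage does.
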