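---
title: "Methods: kidney mRNA-protein concordance on an ordinal scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kidney mRNA-protein concordance on an ordinal scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kidneyconcord)
```

## The problem

Bulk RNA-seq reports kidney transcript abundance on a continuous scale
(nTPM), while immunohistochemistry (IHC) reports protein expression as a
semi-quantitative, pathologist-read call — Not detected, Low, Medium or
High — per kidney cell population, with an antibody reliability grade.
Because IHC has a narrow staining dynamic range and antibody-dependent
failure modes, mRNA and IHC protein calls for the same gene frequently
disagree. This package quantifies that disagreement: it puts both
platforms on one ordinal scale, pairs them per gene within the glomerular
and tubular compartments, tabulates concordance, tests independence, and
re-examines the extreme disagreements against two independent platforms
(compartment-resolved mass-spectrometry spectral counts and an external
compartment RNA-seq dataset).

## The procedure and its assumptions

1. **IHC filtering.** Records whose antibody reliability is "Uncertain"
   are excluded; only the "cells in glomeruli" and "cells in tubules"
   populations are kept (exact string match — "distal tubules" is a
   different population, not a substring match). The other five annotated
   kidney cell types carry too few measurements to be useful.
2. **Discretization of nTPM.** Genes with nTPM = 0 are Not detected. The
   strictly positive values are split into tertiles: Low `(0, t1]`,
   Medium `(t1, t2]`, High `(t2, Inf)`, where `t1`, `t2` are the 1/3 and
   2/3 empirical quantiles of the positive values. Quantiles use linear
   interpolation between order statistics (probability `p` at rank
   `1 + (n - 1)p`, `stats::quantile` type 7). Upper-closed intervals make
   boundary values deterministic; zero is the only Not-detected rule.
   Tertiles are computed on the full kidney transcript set before any
   pairing, so the category boundaries do not depend on IHC coverage.
3. **Pairing.** Transcripts and compartment IHC records are inner-joined
   on the stable gene identifier (gene-name joins, exact and
   case-insensitive, are available for tables without identifiers). Each
   gene contributes at most one pair per compartment; genes on only one
   side are counted in an `unmatched` diagnostic, never silently lost.
4. **Concordance accounting.** Pairs with identical categories are
   concordant. Two extreme-discordance classes are singled out: protein
   Not detected with detected mRNA, and mRNA Not detected with an IHC
   signal; all other disagreements are `discordant_other`. Counts are
   reported with percentages of the compartment pair total, rounded half
   away from zero to two decimals and rendered `"N (P%)"`.
5. **Independence test.** A Pearson chi-square test without continuity
   correction is run on the full 4x4 table, including the Not-detected
   row and column; the table used is recorded in the JSON output so
   alternatives are auditable. All-zero rows/columns are dropped before
   the degrees of freedom are computed, and a validity flag marks
   expected counts below 5.
6. **Cross-platform validation.** Among protein-null pairs, mRNA
   detection is nTPM > 0 (strict variant nTPM >= 1) and MS validation is
   a compartment-matched mean spectral count >= 1 (tubular IHC maps to
   the tubulointerstitial MS compartment). Among RNA-null pairs, external
   RNA-seq detection is TPM > 0 (strict TPM >= 1). Validation percentages
   use the compartment pair total as denominator. Genes absent from a
   validation table are reported separately from genes present but below
   threshold, because the two are otherwise indistinguishable. Nested
   counts are checked for monotonicity and a violation is a hard error.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `ntpm_detect` | 0 (exclusive) | mRNA detection bound, nTPM |
| `ntpm_strict` | 1 (inclusive) | strict mRNA bound, nTPM |
| `spectral_min` | 1 (inclusive) | MS evidence bound, mean spectral count |
| `tpm_detect` | 0 (exclusive) | external RNA detection bound, TPM |
| `tpm_strict` | 1 (inclusive) | strict external RNA bound, TPM |
| `keep_cell_types` | glomerular + tubular populations | IHC cell types kept |
| `join_by` | `gene_id` | pairing key |

Raising any bound can only shrink its validated count; this monotonicity
is property-tested.

## What the synthetic generator emulates

Real HPA-style inputs require downloads and fixed upstream versions, so
the test bed is a latent-Gaussian simulator with recorded ground truth.
Per gene it draws a standard-normal transcript score and one protein
score per compartment with correlation `rho`; nTPM is zero when the
transcript score falls in the lowest `p_zero_rna` quantile (latent
thresholding, so cross-platform non-detection co-occurs when `rho > 0`)
and lognormal above it; protein categories come from cutpoints at the
cumulative protein marginals; spectral counts are negative-binomial
around the protein latent, with half of the IHC-null genes forced
MS-silent so both validated and unvalidated nulls are planted; external
TPM tracks nTPM with lognormal noise, and a planted fraction of RNA-null
genes receives positive external TPM, mostly below 1.

Defaults were fixed once to mirror the whole-kidney marginal structure
the pipeline targets: 18.67% zero-nTPM genes; lognormal parameters
(mu = 1.843, sigma = 1.729) chosen so the positive-nTPM tertile
boundaries sit near 3 and 13 nTPM; protein marginals 53.7/18.6/20.1/7.6%
matching a glomerular IHC split; 15% Uncertain antibody calls; 55.3% of
genes present in both tables; `rho = 0.6`, which yields the moderate
positive association the platforms actually show. The generator also
plants decoy IHC rows (non-kidney tissue, non-compartment cell types)
that the filters must remove.

The generator does **not** emulate: antibody-specific failure mechanisms
(cross-reactivity, epitope masking), inter-observer variability in IHC
scoring, compositional mismatch between the bulk RNA sample and the
compartments, or shared-sample correlation between the validation
platforms and the primary data. Passing tests therefore demonstrate that
the pipeline's accounting is exact and its statistics calibrated under a
realistic marginal and dependence structure — not that real kidney data
meet the generator's assumptions.

Ground-truth checking re-derives the true transcript categories with the
tertile thresholds the pipeline itself published. This is deliberate:
the generator's latent cutpoints are not forced to coincide with the
empirical tertiles, and tying truth to the published thresholds keeps
the oracle free of distributional assumptions. The optional
`cutpoint_mode = "empirical_tertiles"` places the protein cutpoints at
empirical latent quantiles instead; in the perfect-correlation limit
with matched marginals this makes mRNA and protein categories coincide
exactly, a useful degenerate check (with theoretical cutpoints the
boundary ranks differ by order sqrt(n), so exact coincidence is
unattainable by construction).

## Numerical choices and degenerate inputs

- **Rounding.** Percentages round half away from zero at two decimals
  (base `round()` is half-to-even). This convention reproduces every
  internally consistent reference percentage from its printed count.
- **Quantile ties.** With heavily tied or constant positive values the
  tertile thresholds may coincide (`t1 = t2`); categorization stays
  well-defined because intervals are upper-closed, and the partition
  property (category counts sum to the sample size) holds regardless.
- **Degenerate tables.** A contingency table that collapses to a single
  row or column after dropping zero margins has no defined independence
  test; the pipeline records the test as unavailable rather than
  fabricating a p-value. An empty join is a warning (an error in strict
  mode), and an all-zero summary refuses to serialize.
- **Duplicates.** Duplicate IHC keys keep the highest ordinal level
  (conservative toward detection, deterministic); duplicate quantitative
  keys keep the arithmetic mean. Strict mode turns both into errors.
- **Determinism.** Outputs are sorted by (compartment, gene); re-running
  with identical inputs yields byte-identical files, and the generator
  restores the caller's RNG state.

## Known limitations

- The reference analysis's exact tertile split (5481/5452/5465 on 16,398
  positive genes) implies ties or a different quantile convention
  upstream; the printed one-decimal boundaries cannot disambiguate, so
  exact replication of that split is not claimed — the package fixes the
  type-7 convention and documents it.
- One published glomerular row (strict-nTPM, "3773 (33.46%)") is
  internally inconsistent — 3773/11157 recomputes to 33.82% — and is
  excluded from exact-reproduction checks; the consistency auditor flags
  it instead.
- Gene matching is exact (identifier first, then case-insensitive
  symbol); no alias resolution is attempted, so symbol drift between
  platforms surfaces in the `unmatched` diagnostics.
- The chi-square test is asymptotic; with very sparse tables the
  validity flag is raised but no exact test is substituted.

## Problem sizes used in the test suite

Unit and property tests run on samples of 10-10,000 values. End-to-end
oracle checks use 20 generator seeds at 2,000 genes; the type-I-error
calibration uses 1,000 seeds at 2,000 genes (the 4x4 test's asymptotics
are comfortable at the ~900 pairs per seed this yields); marginal
goodness-of-fit checks use 20,000 genes. The acceptance script runs the
generator at its 20,000-gene default. These sizes were chosen so the
whole suite exercises every code path at Monte-Carlo error small enough
for the stated bounds while completing in minutes on one CPU.
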