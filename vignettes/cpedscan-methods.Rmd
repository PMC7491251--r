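---
title: "Distance-dependent co-expression on bacterial chromosomes: models and methods"
author: "cpedscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cpedscan methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model

`cpedscan` quantifies how the co-expression of two positions on a circular
bacterial chromosome depends on the genomic distance between them, and asks
whether that dependence is periodic, how credible each periodicity is, and
whether it can be explained away by transcription orientation, regulator
binding, or 3C contact structure.

The unit of analysis is the genomic **bin** (500 bp by default; a sliding
1,000/500 bp tiling is available via `binGrid(binWidth = 1000, step = 500)`
— both conventions appear in practice and the choice is exposed rather than
hidden). Per sample, fragment counts per bin are normalised to fragments
per million; bins overlapping rRNA/tRNA/tmRNA are nulled because rRNA
depletion differs between libraries and would bias both the per-million
scale and the correlation structure. By default masked bins are also
*excluded from the per-million denominator* — nulling them while leaving
them in the denominator would retain exactly the bias that motivates the
masking; `maskDenominator = "include"` restores the naive scale for
comparison. Replicates are averaged per growth phase *after*
normalisation.

The **CPED profile** of bin *i* is `r(i, L) = cor(x_i, x_{i+L})` over the
phase-averaged conditions (complete cases, Pearson; `NA` when a partner is
masked, fewer than 3 complete pairs remain, or a vector is constant). With
the canonical five growth phases each coefficient is extremely noisy
(sd ≈ 0.5 under the null); all inference therefore happens on averages
over many bins. Profiles are stored as a bins × lags band (±200 kbp); the
full n² matrix is never materialised except at the coarse 5 kbp resolution
of the 3C comparison.

## Periodicity estimation

Window-averaged profiles (400 kbp windows sliding at 5 kbp, circular wrap)
are scanned for a dominant wavelength in 10–70 kbp by the classical
Lomb–Scargle periodogram — chosen because masked bins leave holes at
arbitrary lags and the estimator is defined for exactly that case. The
frequency grid spans `[1/periodMax, 1/periodMin]` at spacing
`1/(oversampling × span)` with 4× oversampling; ties resolve to the smaller
period; `PNmax = −ln(p)` with `p` clipped at `1e-300`.

Four numerical choices matter, and each was driven by a measured
miscalibration rather than taste. They are all parameters of
`scanConfig()`:

* **Folding** (`fold = TRUE`). The two-sided window-averaged profile is
  nearly an even function of lag — `r̄(+L)` and `r̄(−L)` average almost the
  same set of pairs — so its sine components carry almost no information
  and peak powers follow a heavier-tailed law than the Exp(1) the
  false-alarm formula assumes (measured ~40–50% of pure-noise windows
  above PNmax 3). Profiles are folded to one sided, weighted by the
  per-lag bin counts, before the periodogram. Displayed profiles
  (`averageProfiles()`) remain two-sided.
* **Minimum lag** (`minLag = periodMin`). Operon co-transcription puts a
  large decaying correlation spike at |lag| below ~15 kbp. That spike is
  broadband power, not in-band periodicity, and it alone drives nearly
  every pure-noise window above threshold. Lags shorter than the smallest
  searchable period are excluded from periodogram input — a direct
  extension of excluding lag 0 (self-correlation).
* **False-alarm method** (`fapMethod = "baluev"`). The classic
  `p = 1 − (1 − e^(−z))^M` with `M = nFreqs/oversampling` under-covers a
  band-limited maximum by the missing `√z` tail factor (~2–3× too many
  false alarms on iid input). The default is the Baluev band-limited
  bound `τ = ΔF·T_eff·√z·e^(−z)`, `p = 1 − (1 − e^(−z))·e^(−τ)`; the
  simple effective-count formula remains available (`"horne"`), and both
  preserve the anchor PNmax > 3 ⇔ p < 0.05, which fixes the natural log.
* **Normalisation** (`normalization = "null-variance"`). The profile's
  *empirical* variance is itself built from few independent numbers
  (bins × phases), fluctuates per window, and lets whole genomes flag
  jointly. Under the null the variance of a mean of `n_L` sample
  correlations over `m` conditions is known: `1/((m−1)·n_L)`. Normalising
  power by this fixed quantity restores calibration (measured: ~7% of
  iid windows and ~9% of full-generator pure-noise windows above PNmax 3,
  against ~12%/~21% with the sample variance) and prevents genuine signal
  from deflating its own significance. `"sample-variance"` is the
  classical normalisation and the one that matches a DFT periodogram
  exactly on complete uniform profiles (the oracle-equivalence test).

The **shuffled-genome null** (`randomizationNull()`) assigns every bin a
random unique position (one genome-wide bijection per replicate, masked
bins travelling with their values; 400 replicates by default), recomputes
band and scan, and pools window PNmax values — an empirical complement to
the analytic false-alarm probability that shares none of its assumptions.

## Falsification analyses

**Orientation.** Transcription-induced supercoiling is directional:
positive supercoils ahead of RNA polymerase promote downstream expression,
negative supercoils behind inhibit upstream. If that drove the observed
correlations, profiles re-expressed relative to transcription direction
(CCW bins mirrored; ambiguous/orientation-free bins discarded — about two
thirds on a real genome) would be asymmetric. `supercoilingContrast()`
reports the per-lag oriented/unoriented difference and a summary asymmetry
(mean over lags of `r̄(+L) − r̄(−L)` on the oriented profile) with a
combined CI. "Clockwise" means the forward strand of the reference; the
convention is a parameter. Note that any *latent-factor product* model of
co-expression yields an exactly even averaged profile (an autocorrelation),
so the generator cannot plant a directional signal; the directional test
case in the acceptance suite constructs the oriented correlation structure
directly.

**Regulators.** For each TF/sigma factor/NAP with more than 20 target bins
(±500 bp flanks), the pairwise coefficients are partitioned into At (both
bins at targets), Between (mock sites at the circular midpoint toward each
site's clockwise successor — the simplest reading of "moved between real
sites in a clockwise manner", isolated behind `betweenSites()`), Random
(100 same-size uniform draws) and Without (no contact with target bins).
Rank-sum tests make "At is higher" operational. `exclusionReprofile()`
removes every coefficient touching a target bin and re-estimates the
periodogram: periodicity carried by those bins collapses, periodicity
independent of them survives with its peak intact.

**3C association.** Expression is re-binned to the 5 kbp resolution of the
contact map by summing raw counts before re-normalising (FPM is not
additive; a coarse bin is masked if any constituent was). All unmasked
pairs more than 20 kbp apart (strictly; removes operons and
supercoiling-gradient reach) are grouped by contact frequency —
equal-width intervals on log10 contact, which produces the "unequal-sized"
groups; quantile grouping is the alternative — and each group's mean
correlation is rank-sum-tested against the lowest-contact group with
Bonferroni correction. No matrix balancing is performed; matrices are
consumed as published.

## The synthetic world

`makeTruth()` fixes the stated world: a circular genome split into equal
regions, each with one latent factor whose anchors are spaced the planted
period apart; operon blocks (gamma lengths, mean 3 kbp, exponential gaps,
mean 2 kbp — E. coli-like cover) with strands; structural-RNA intervals
(5 kbp, one per ~700 kbp, the rRNA-operon density) whose counts are
inflated 100× so masking failures are loud; and regulator maps (one
coupled to region-1 anchors, one uniform, one below the 20-bin threshold).

`simulateExpression()` draws, for bin *b* and sample *(p, replicate)*:

    log mu = baseline_g + a · w(b, k) · f(k, p) + eps

with `g` the bin's signal group (operon members share one *signal* —
baseline and coupling — while `eps ~ N(0, noiseSd)` is per bin: noise is
measurement, not biology), `f(k, p) ~ N(0, 1)` shared between replicates,
and `w(b, k)` a triangular kernel of distance to the nearest anchor. The
kernel half-width defaults to `period/2`, which makes the averaged CPED a
smooth wave at the planted period; a half-width of one bin concentrates
the signal in anchor bins only (useful for the exclusion test, available
as a parameter, but statistically undetectable as an averaged-profile
periodicity at realistic noise). Intensities are scaled to the library
size (2e6 fragments) and counts drawn Poisson; `countModel = "expected"`
returns the continuous intensities for analytic oracles. Defaults — 5
phases × 2 replicates, `noiseSd = 0.2`, 500 bp bins — are the canonical
experiment's shape.

`simulateContacts()` builds a symmetric distance-decay matrix
(`(d/binWidth)^(−1)` by default — the short-range decay regime of
bacterial 3C maps), multiplies same-family anchor-pair contacts by
`couplingBoost`, and applies symmetric log-normal noise; with
`couplingBoost = 1` contacts carry no information about co-expression
(the null case for the association test).

One second-order property of the generator deserves a note because it is a
property of real FPM data too: when the coupled bins are a large share of
the library, the per-sample total itself tracks the latent factor, and
dividing by it imprints a faint (amplitude ~0.01) copy of the periodic
structure on *every* bin. Constructions that need the planted structure
to be strictly confined to known bins (the regulator-exclusion test)
therefore couple only a small region of a larger genome. Contact boosting
in `simulateContacts()` marks only anchor families with nonzero coupling
amplitude — its purpose is to make the spatially close pairs exactly the
co-expressed ones.

What the generator does *not* emulate: read-level artefacts (GC bias,
mappability), genuine growth-phase autocorrelation between conditions,
macrodomain boundaries, or any mechanistic model of supercoiling or
polymerase kinetics. A green test therefore establishes that the pipeline
recovers what was planted under the stated noise — not that the biological
mechanism is real.

## Degenerate inputs and tie-breaks

Constant or < 3-complete-pair vectors give `NA` correlations; constant
profiles give zero power and p = 1; equal peak powers resolve to the
smaller period; empty contact groups merge into their lower neighbour with
a warning; bins exactly antipodal on the circle take the positive lag
sign. Windows with fewer than 8 usable lag points are skipped and logged
in the scan's `"skipped"` attribute. All randomised operations
(`randomizationNull()`, Random subsets, the generator) take explicit seeds
and restore the caller's RNG state.

## Known limitations

With five phases the per-pair correlation noise is irreducible (sd ≈ 0.5);
everything rests on averaging, so short regions and heavily masked windows
are unreliable and are skipped rather than guessed. The analytic
false-alarm calibration is approximate for correlation-of-correlation
profiles even after the null-variance normalisation (~7–9% at the nominal
5% on pure noise); conclusions about marginal peaks should lean on the
shuffled-genome null. The orientation analysis can only detect asymmetries
expressible in the averaged profile; the regulator analysis inherits
whatever incompleteness the target table has; and the 3C association is
correlational — it cannot distinguish "contacts cause co-expression" from
any common cause.
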