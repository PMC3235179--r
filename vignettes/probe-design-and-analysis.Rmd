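---
title: "Designing and evaluating a two-color transcriptome microarray"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and evaluating a two-color transcriptome microarray}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(probekit)
```

probekit covers the full life cycle of a custom two-color oligonucleotide
microarray for a sequenced organism: designing 60-mer probes from a
transcript catalogue, screening their specificity against any (newer)
annotation release, simulating two-channel hybridizations with realistic
technical structure, and analysing feature intensities through to
differential-expression, concordance and knockout calls. This vignette
explains the models and procedures behind each stage, the parameters that
matter, and the choices made where the design was genuinely open.

## Probe design

### Search space and scores

Every transcript is scanned with a sliding window of `probe_length`
(default 60 nt, the standard length for long-oligo expression arrays).
Windows containing `N` are excluded outright: a probe with an undetermined
base cannot be synthesized as specified. Each window is annotated with

* **GC content**, `100 * (G + C) / length`;
* **melting temperature**, from the salt-adjusted long-oligo formula

  $$T_m = 81.5 + 16.6\,\log_{10}[\mathrm{Na}^+] + 0.41\,\mathrm{GC\%} -
  600/L \quad (^\circ\mathrm{C});$$

* **position score**, `(start + probe_length) / transcript_length`,
  which is 1 for a window ending at the 3' terminus and decreases toward
  the 5' end.

The Tm formula is an approximation that depends only on GC, length and
sodium concentration; it deliberately avoids nearest-neighbour duplex
models (out of scope here, as is secondary-structure screening). At the
default `na_molar = 0.3` mol/L it maps GC 40% to 79.2 °C and GC 60% to
87.4 °C for a 60-mer, so the default GC band [40, 60]% and Tm band
[80, 90] °C jointly admit a non-empty window strictly inside the GC band
(roughly GC 43.3--60% at probe length 60). Tight Tm uniformity is what
permits a single hybridization temperature across the array.

The 3' preference encodes the fact that reverse-transcription-based
labeling chemistries start from the 3' end of the message, so 3'-proximal
probes are more robust to partial-length cDNA. Its strength is set by
`position_weight` (default 0.3) in the composite score

```
composite = (1 - w) * gc_centrality + w * position_score
```

where `gc_centrality` falls linearly from 1 at the midpoint of the GC band
to 0 at its edges. The weight is a compromise: `w = 0` ignores labeling
bias entirely, `w = 1` would crowd probes into the (often lower-quality)
3' UTR.

### Filtering and selection

`filter_candidates()` keeps windows inside both bands and without a
homopolymer run longer than `max_homopolymer` (default 6 nt; long runs
cause synthesis slippage and non-specific sticking — a standard oligo
hygiene rule, configurable because it is not part of the band model).
`select_probes()` then takes candidates greedily by descending composite
score, accepting a candidate only if its interval is at least
`min_spacing` (default 10 nt) away from every accepted one, and stops at
`k` probes (default 3). Independent, spatially separated probes per
transcript are what allows per-transcript averaging and knockout calling
downstream. Ties are broken deterministically (more 3'-ward start, then
lexicographically smaller sequence), so a design is byte-reproducible.

Coverage is reported as the fraction of transcripts with at least one
probe; transcripts shorter than the probe, or without any admissible
window (e.g. extreme composition), simply contribute zero probes.

## Specificity screening

A probe is only useful if its signal can be attributed to one transcript.
`find_hits()` performs an exhaustive ungapped scan: every offset of every
transcript (sense strand) is scored by Hamming distance, and all
alignments within `max_mm` mismatches are reported. Exhaustiveness is the
point — the scan is defined to be identical to a position-by-position
brute-force search, and the test suite verifies that equivalence on random
instances. Gapped or spliced alignment is out of scope; probes live in
transcript space, and targets are labeled cRNA from the same strand, which
is why the search is sense-strand only.

`classify_probes()` applies the specificity rule at `max_mm = 3`:

* **single** — perfect alignment to exactly one transcript and no other
  transcript within 3 mismatches;
* **multiple** — two or more transcripts carry a perfect or near hit
  (potential cross-hybridization);
* **none** — no perfect target. A probe whose only alignment is one near
  hit is also `none` — it has no assignable target transcript — but is
  flagged `near_only` in the calls table for transparency.

`N` counts as a mismatch against everything, including another `N`:
an undetermined base can never certify identity. `reannotate_probe_set()`
runs the classification for a whole design against a new catalogue and
reports the three class fractions — the in-silico check of how a probe set
survives an annotation update.

## The hybridization simulator

`simulate_transcriptome()`, `simulate_expression()` and
`simulate_hybridization()` form a seeded generator whose one master seed
fixes everything, so every analysis stage can be tested against known
truth without any external data.

The intensity model, on the log2 scale, for probe *i* of transcript *t*
in replicate *r*:

```
log2 cy3_fg = ref(t)  + phi_i + eps
log2 cy5_fg = trt(t)  + phi_i + eps' + d(A)
```

* `ref`, `trt` are absolute true abundances: `baseline_log2` (default 10)
  plus a per-transcript spread (`abundance_sd`, default 1.0 log2 units).
  The spread is shared by both channels, so it moves a feature's mean
  intensity A but not its ratio M. A truly differential transcript's
  treatment abundance is shifted by exactly `effect_log2` (default 2, a
  four-fold change), up or down with equal probability, for a
  `floor(frac_de * n)` subset.
* `phi_i ~ N(0, affinity_sd^2)` is a per-probe affinity, fixed across
  replicates — probes differ reproducibly in brightness, which is why
  ratios, not intensities, are analysed.
* `eps ~ N(0, noise_sd^2)` is fresh per measurement. The defaults
  (`noise_sd = 0.25`, `affinity_sd = 0.5`) place the replicate
  log2-ratio variability in the 20--35% relative band typical of
  well-behaved two-color replicates; they are configuration, not fact.
* `d(A) = c0 + c1 A + c2 A^2` is an intensity-dependent dye bias added to
  the red channel, evaluated at the feature's bias-free mean log
  intensity. The default `(5.3, -1.0, 0.05)` is a parabola with its
  vertex at A = 10, i.e. an offset of about +0.3 log2 units at mid
  intensities rising toward both extremes. The quadratic term is
  deliberate: a constant or linear bias could be removed by
  median-centering, whereas curvature is exactly what motivates robust
  local regression.
* Backgrounds are lognormal, `2^N(bg_log2_mean, bg_log2_sd)` (defaults 6
  and 0.5), per feature and channel. Knockout transcripts contribute
  **background-only foregrounds in both channels** rather than exact
  zeros — scanners report background at empty spots.

`simulate_self_self()` generates the dye-test design: both channels from
the reference profile, dye bias still applied, so any nonzero M is purely
technical. The simulator does **not** model spatial artifacts, scanner
saturation, print-tip effects, or dye-swap designs; passing tests
therefore certify the statistical pipeline under this noise model, not
robustness to every failure mode of real scanned arrays.

## The analysis pipeline

`analyze_experiment()` chains the stages; each is exported on its own.

1. **Detection.** A feature is used only if its foreground strictly
   exceeds `bg_mean + detection_k * bg_sd` (default `k = 2`) in *both*
   channels, with the background moments estimated per replicate and
   channel from the feature backgrounds. Requiring both channels protects
   ratio estimates from division by background.
2. **MA computation.** Net intensities are background-subtracted and
   floored at `floor` (default 1 unit) before logs, so M and A are always
   finite; `M = log2(r/g)`, `A = 0.5 log2(rg)`.
3. **Lowess normalization** per replicate: a robust locally-weighted
   linear fit of M on A (tri-cube kernel over the `lowess_span = 0.3`
   nearest fraction, 3 robustness iterations) is subtracted from M.
   Fewer than 10 detected features is an error — a local fit is
   meaningless there and a global-median fallback should be used
   deliberately, not silently.
4. **Aggregation.** All detected observations of a transcript — its
   probes times the replicates — are pooled; mean, sample SD and count
   are recorded. No nested probe/replicate model is fitted: the design
   philosophy is that k independent probes are exchangeable reporters of
   one transcript. Transcripts with zero detected observations are
   excluded and listed, not errors.
5. **Testing.** A two-sided one-sample t-test of the normalized ratios
   against 0. This is the minimal test matching a single-orientation
   replicate design. Degenerate inputs follow fixed rules so noiseless
   simulations cannot crash the pipeline: fewer than 2 observations or a
   zero-variance/zero-mean sample give p = 1; zero variance with nonzero
   mean gives the smallest positive representable p.
6. **Holm--Bonferroni** correction over all tested transcripts — the
   family is "what was detected in this experiment" — followed by the DE
   rule: adjusted p below `alpha = 0.05` **and** |mean M| at least
   `min_abs_log2 = 1` (two-fold). Direction is the sign of the mean
   ratio.

### Downstream operations

* `timecourse_average()` averages per-time-point mean ratios over the
  available time points, the usual way multi-day starvation series are
  reported as one value per gene.
* `hierarchical_cluster()` is agglomerative clustering with Euclidean
  distance and Ward linkage (`ward.D2`, the variance-minimizing form
  appropriate for Euclidean input), cut at a requested number of groups;
  deterministic for a fixed row order.
* `concordance()` compares direction categories (up/down/none) between
  two platforms over shared transcripts, restricted to transcripts called
  DE on at least one platform — comparing platforms on transcripts
  neither finds interesting would only inflate agreement.
* `detect_knockout()` consumes per-probe detection flags;
  `summarize_probe_detection()` produces them by majority over
  replicates, which keeps a single noisy replicate from deciding a
  presence call. A transcript is `absent` when no probe is detected in
  the mutant while at least one is in the control, `present` when both
  samples detect it, `indeterminate` otherwise (including the
  undetected-in-both case, where the data simply say nothing).

## Problem sizes and verification

The package's checks run at desk scale, chosen so the full suite
completes in well under an hour on one CPU while keeping every
statistical check adequately powered: a 1,000-transcript reference
transcriptome (500--2,000 nt, GC 0.5) for the design constraints;
100 random probe/transcriptome instances for the brute-force equivalence
of the mismatch scanner; 200 seeded self-self experiments of 100
transcripts for the familywise-error check; three 200-transcript
experiments for DE recovery at a four-fold effect; and a single
10,000-feature self-self array for the dye-bias curvature removal. The
vignette states these sizes as the package's own verification conditions;
all numerical claims about behaviour are the ones the test suite and
`scripts/acceptance.R` actually compute.

## Worked example

```{r example, eval = FALSE}
library(probekit)

tx <- simulate_transcriptome(200, c(500, 2000), 0.5, seed = 7)
design <- design_array(tx, design_params())
glance(design)
autoplot(design) # GC and Tm histograms

probes <- tidy(design)
glance(reannotate_probe_set(probes, tx))

sp <- sim_params(n_transcripts = 200, seed = 7)
profile <- simulate_expression(tx, sp)
fit <- analyze_experiment(simulate_hybridization(probes, profile, sp),
                          probes)
glance(fit)
autoplot(fit) # MA plots before/after lowess
```

## Known limitations

* The Tm model is a GC/length/salt approximation; two probes with equal
  GC get equal Tm regardless of sequence order.
* Specificity is ungapped and sense-strand; a transcript variant hitting
  a probe through a gapped alignment would not be flagged.
* The pooled t-test ignores probe-level random effects; with very few
  replicates a moderated (shrinkage) test would be more powerful, but is
  deliberately out of scope.
* The simulator's noise model is Gaussian on the log scale with a smooth
  dye bias; real arrays add spatial and saturation artifacts it does not
  emulate.
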