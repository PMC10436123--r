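---
title: "Methods: from GPS traces to within-person greenspace–affect associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from GPS traces to within-person greenspace-affect associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(greenspaceEMA)
```

## The problem

Does spending time in greener places track with how people feel on that same
day? `greenspaceEMA` implements a smartphone-based pipeline for that
question, aimed at digital-phenotyping studies that collect, per participant,
(1) continuous GPS traces, (2) brief ecological momentary assessment (EMA)
surveys of affect, and (3) ambient-audio transcripts of everyday speech. The
reference design is a two-group study — 20 participants with a schizophrenia
spectrum disorder (SSD) and 14 controls — followed for 7 days, with GPS fixes
every 6 minutes, three EMA prompts per day, and 5-minute audio windows every
half hour.

Exposure is quantified by the normalized difference vegetation index
computed from near-infrared and visible reflectance,

$$NDVI = \frac{NIR - VIS}{NIR + VIS} \in [-1, 1],$$

negative over water, near 1 over dense vegetation. Affect is measured twice:
actively, as 6-point EMA ratings of happiness, sadness and anxiety; and
passively, as the percentage of spoken words falling in dictionary affect
categories (positive affect; negative affect with anxiety, anger and sadness
subcategories), in the style of word-count text analysis tools.

## The exposure pipeline and its decisions

Per participant the chain is: provider filter → home detection → home
removal → raster linkage → negative exclusion → daily mean → log →
person-mean centering. Several steps require choices the design leaves open;
the package's defaults, all exposed as parameters, are:

* **Provider filter.** `network-passive` and `gps-passive` fixes are
  dropped; they report cached or cell-tower positions of much lower quality.
* **Home detection.** Home is the modal (lat, lon) bin among fixes between
  9 PM and 6 AM, pooled across the whole study (one home per participant;
  the window is interpreted by clock time, so it crosses midnight). Raw GPS
  floats almost never repeat, so "most frequent coordinate pair" is made
  operational by rounding both coordinates to `bin_precision` decimals
  (default 3, ≈110 m bins); the reported home is the centroid of the fixes
  in the winning bin, and ties go to the bin observed first. On simulated
  receivers with 10 m jitter this lands within a few meters of truth.
* **Home removal.** All fixes within `home_radius` (default 100 m,
  haversine on the WGS84 sphere) of the home are removed before linkage, so
  daily exposure reflects places visited, not the residential backdrop.
  `radius = 0` recovers literal exact-coordinate removal.
* **Raster linkage.** Nearest-cell lookup under the pixel-is-area
  convention with half-open cell bounds (a point on an interior boundary
  belongs to the cell with the larger index). No interpolation: NDVI is a
  surface proxy, not a smooth field, and averaging across cell boundaries
  would blur water/land contrasts. Out-of-extent points and nodata cells are
  dropped with counts reported.
* **Negative exclusion.** Negative NDVI (water) point values are excluded
  *per fix, before* the daily mean, so a ferry commute does not delete a
  whole day.
* **Daily mean and log.** Days are local midnight-to-midnight (one study
  time zone, half-open `[00:00, 24:00)`, shared by every module). The daily
  mean is the unweighted average over retained fixes. Daily means are
  strongly right-skewed, so models use the natural log (the base only
  rescales raw coefficients; standardized estimates are base-invariant).
  Zero-mean days are floored at `1e-4` inside the log and flagged rather
  than dropped — dropping would conflate exposure level with missingness.
* **Person-mean centering.** `log_ndvi` is split into a person mean and a
  within-person deviation summing to zero per participant; the deviation is
  the predictor of the multilevel models, so slopes reflect *greener days
  than one's own average*, not *greener people*.
* **Travel days.** A day is flagged when any fix leaves the study region
  (default: the raster extent; the metro-area boundary of a real deployment
  is not something the package can know). Flagged days feed a sensitivity
  rerun, mirroring the practice of refitting with travel days excluded.
* **Time at home** is fixes-within-radius × epoch / 60 hours, computed on
  the *unfiltered* trace (after provider filtering an epoch may have no fix
  and the product undercounts). It enters the models only as a sensitivity
  covariate.

## Speech scoring

Transcripts are segmented into social interactions: a new interaction starts
after a lapse in speech of 20 seconds or longer (the boundary case splits),
or on a change of interlocutor when an interlocutor id is present; segments
with no participant utterance are discarded, and utterances annotated as
pet- or infant-directed speech, singing or self-talk are dropped when the
input carries such flags. Scoring is a word count: tokens (lowercased,
whitespace-split, edge punctuation stripped, internal apostrophes kept) match
lexicon patterns by equality or, for trailing-`*` stems, by prefix; each
token counts at most once per category; category scores are percentages of
total words, which normalizes for how much was spoken. Daily scores are
token-weighted — total matches over total words — which is exactly equal to
rescoring the concatenated day and never overweights short segments.

The proprietary dictionary of the commercial tool is not redistributable, so
the package ships a small open lexicon (~100 patterns) in the same format;
the scoring algebra, which is what the analysis depends on, is identical.
The negative-affect total counts only the anxiety/anger/sadness
subcategories by default (general negative words such as "hurt" or "ugly"
are listed separately and enabled by `inclusive_negative = TRUE`), since the
analysis of interest treats those subcategories as the negative signal.

## EMA processing

Responses on the 6-point scale ("Not at all" … "Extremely") are coded 0–5;
the observed group means of roughly 0.5–3.2 are only consistent with 0-based
coding, but the coding is a parameter. Validation rejects out-of-range
affect responses and duplicate (participant, timestamp, item) rows. Daily
affect is the arithmetic mean of each item's answered prompts per local day;
unanswered items are missing, never zero. Group summary tables are
two-stage: participant means across days first, then group mean (SD) of
those, so participants with more compliant days do not dominate.

## The association battery

* **Group differences**: Wilcoxon rank-sum on participant-level means,
  exact when the pooled sample is ≤ 12 with no ties, otherwise the normal
  approximation with tie and continuity corrections; two-tailed.
* **Screening**: Spearman correlations (Pearson on midranks, t
  approximation) of study-mean exposure against affect and speech
  variables; magnitudes ≥ 0.30 are flagged as moderate signals worth
  follow-up modeling. No multiplicity correction is applied — the battery is
  exploratory with a two-tailed α = .05 convention.
* **Daily-level models**: per group and outcome, a linear mixed model
  `outcome ~ centered_log_ndvi + (1 | participant)` fitted by maximum
  likelihood, Wald CIs and p-values. Standardized coefficients multiply the
  raw slope by SD(predictor)/SD(outcome) on the analysis sample (total SDs;
  a within-person-SD variant is available via `std = "within"`). ML-plus-
  Wald matches the reporting style of mainstream multilevel software; REML
  is an option. The outcome — a daily mean of ordinal items — is treated as
  continuous, matching the linear two-level model family; ordinal links are
  out of scope. Singular or non-converging fits are returned with
  `converged = FALSE`, never silently replaced.

`fit_two_level()` validates that the predictor is person-centered (per-
participant means within 1e-6 of zero) and can re-center it on the analysis
sample (`recenter = TRUE`), which `analysis_report()` uses because missing
outcomes shift the analyzed subset.

## The synthetic cohort generator

The generator exists so every stage is testable with known truth; its
defaults are the study conditions, not knobs: 20 + 14 participants, 7 days,
6-minute GPS epochs, three prompt windows (10–1, 2–5, 5–8) with a 90-minute
minimum gap, a 9 PM–6 AM night window, and a raster whose land NDVI has mean
0.14 and SD 0.065.

* **Raster**: a smoothed Gaussian field rank-transformed so land cells
  follow a Beta distribution rescaled to [0, 1] with exactly the target
  mean and SD (a truncated normal would bias the mean by more than the
  Monte-Carlo error of a 10⁴-cell grid); the lowest-lying `water_fraction`
  of cells become water with negative NDVI. The band pair holds total
  reflectance constant at 0.6 so `compute_ndvi()` recovers the surface
  exactly.
* **Mobility**: nights at home plus one daily excursion (mean 8 h away,
  leaving mid-morning) following a Brownian-bridge random walk from and back
  to home, everything jittered by 10 m Gaussian receiver noise in a local
  metric frame. "1 Hz every 6 minutes" is modeled as one representative fix
  per epoch — daily means are burst-invariant, so collapsing a burst to its
  centroid changes nothing downstream. Exposure *truth* per day is defined
  by running the package's own preprocessing at the true home, which is what
  makes pipeline-vs-truth tests exact.
* **EMA**: latent affect per prompt is
  `intercept_i + β·centered_log_ndvi + residual`, rounded and clipped to
  0–5. The residual is prompt-level, so a zero-noise configuration yields
  identical responses. The injected `within_effect_b` is *standardized on
  the observed daily-mean scale*: because round-and-clip attenuates a latent
  slope, the generator root-finds the latent β whose induced observed-scale
  standardized slope equals the target, using closed-form normal-bin
  expectations over stratified normal quadrature (no simulation, fully
  deterministic, memoized per configuration). Item intercepts default to
  2.9 / 0.65 / 0.85 (happy / sad / anxious), mid-scale for happiness and
  near the floor for the negative items, as such data look in practice.
* **Transcripts**: conversation windows on the 5-minutes-per-half-hour
  grid (35% of windows contain speech), alternating speakers, mostly short
  gaps with occasional ≥ 20 s lapses so the segmenter has real work; each
  token is an affect-category word with probability
  `base + effect × exposure-deviation-in-SDs` (truncated at zero), else a
  neutral filler. Category words are verified against the shipped lexicon
  and fillers verified to match nothing.
* **Missingness** is completely-at-random EMA nonresponse (default 0);
  informative missingness and realistic routine mobility (Lévy flights,
  weekday structure) are deliberately not modeled, so passing tests say
  nothing about those features of real data. Nothing about real satellite
  imagery (clouds, compositing, seasonal change) is emulated either.

`simulate_daily_cohort()` is a daily-level fast path for replication
studies: it draws person means and day deviations of log NDVI directly
(SDs 0.22 / 0.20, chosen to mirror the spread the full per-fix generator
produces at its defaults) and reuses the same calibrated response sampler,
skipping raster, traces and transcripts. Thousands of cohorts fit in
seconds, with the same meaning of the injected effect.

## Numerical choices and degenerate inputs

Ties in home-detection bins break by earliest first occurrence; ties in
ranks use midranks. Rounding of latent responses is R's round-half-even.
Spearman with a constant ranking, empty rank-sum samples, fewer than 3
pairs, unlabeled participants, non-centered predictors, negative removal
radii, non-positive log floors and epochs, infeasible prompt schedules, and
homes outside the raster all raise immediate, specific errors. Empty traces
after home removal, days with all fixes on water, and segments without
participant speech propagate as absent rows, never as zeros. The log floor
(1e-4) and the centering tolerance (1e-6, per-participant mean) are the only
numeric tolerances in the pipeline itself.

## Verification scale

The test suite checks the estimator's operating characteristics at the
study's own scale (34 participants × 7 days): 200 replicate cohorts with an
injected within-person standardized slope of −0.40 on anxiety (mean estimate
recovered within ±0.05, 95% CI coverage between 0.92 and 0.98), and 1,000
null cohorts (rejection rate at α = .05 within 0.035–0.065). Recovery and
error-rate replications use the daily-level fast path; the full per-fix
pipeline is verified end-to-end separately (exact agreement with the truth
table, byte-identical reruns under a fixed seed). One known operating
caveat: with only 34 clusters, ML-Wald inference is mildly anticonservative
(empirical type-I error slightly above 5%, CI coverage slightly below 95%) —
the expected small-sample behavior of this estimator family.

## Limitations

The headline numbers of any real deployment (group means, specific
coefficients) depend on private participant data; this package reproduces
the *method*, and its synthetic effects are calibrated constructs, not
re-estimates of published coefficients. Exposure is an unweighted mean over
retained fixes (not time-weighted), buffer-based exposure variants (e.g.
NDVI within 250 m of each fix) are not implemented, and the lexicon is a
small open stand-in whose absolute percentages are not comparable to
commercial-dictionary output, though the pipeline algebra is.
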