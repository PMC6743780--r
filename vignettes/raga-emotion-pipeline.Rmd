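---
title: "Quantifying tonality and rhythm cues in musical emotion ratings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tonality and rhythm cues in musical emotion ratings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ragacues)
```

## The problem

Hindustani ragas are melodic frameworks performed over a continuously
sounded tonic drone, first in a rhythmically free stage (*alaap*) and then
at a faster tempo with percussion (*gat*). Because the two stages share
their tonal material and differ in rhythm, a raga is a natural experiment
for separating two candidate carriers of musical emotion: **tonality**
(which pitch classes the melody occupies relative to the tonic) and
**rhythm** (how clearly pulsed the presentation is). `ragacues`
implements the full analysis chain for this design — stimulus
quantification, listener-group comparison, robust variance partitioning,
and a cross-group odds ratio of cue reliance — together with a synthetic
stimulus-and-survey generator so the entire chain can be exercised and
validated without any external recordings or human data.

## Tonality: pitch track, interval histogram, m/M ratio

A melodic excerpt is reduced to a pitch estimate every 30 ms. Each voiced
frame is expressed in cents against the tonic $f_0$:

$$\mathrm{Pitch(cents)} = 1200 \log_2 (f_1 / f_0),$$

collected into 100-cent bins labeled −1200 to 2400 (three octaves around
the central one; frames outside $[-1250, 2450)$ are dropped and counted),
and folded into a single octave by pitch class: each folded class $k \in
\{0, 100, \dots, 1100\}$ sums the bins whose labels are congruent to $k$
modulo 1200. The label range −1200..2400 contains 37 bins; the 2400
label, one pitch class above the top full octave, folds into class 0 with
−1200, 0 and 1200, so folding conserves the total count. The komal re
(minor second) class, for instance, collects the −1100, 100 and 1300
bins.

The **tonality ratio** is the summed folded occupancy of the five minor
(komal) classes {100, 300, 600, 800, 1000} over the seven major (shuddh)
classes {0, 200, 400, 500, 700, 900, 1100}. Occupancy is used as a
proportion, which makes the ratio invariant to uniform rescaling of the
counts; a profile with no major-class mass yields an explicit
undefined/infinite flag rather than a silent division. Bins are centered
on their labels (label ± 50 cents), so just-intonation deviations of up
to a quartertone still map to the intended swara.

Two pitch-track routes exist. The generator returns the **ground-truth**
track of every synthetic excerpt, and this is the default route for
tonality work (the computation of scientific interest starts at the
pitch track). For real WAV input, `estimate_pitch_track()` provides a
frame-wise FFT-autocorrelation estimator (40 ms frames, normalized
autocorrelation peak in 80–1000 Hz, parabolic lag interpolation, voicing
by peak clarity ≥ 0.5 and frame energy). With a strong drone this
estimator can lock onto the tonic rather than the melody; that is a
documented limitation, not a target of the validation suite.

## Rhythm: pulse clarity and event density

The onset-strength envelope is the half-wave-rectified spectral flux of a
short-time Fourier transform (1024-sample Hann window, 256-sample hop).
**Pulse clarity** is one minus the normalized Shannon entropy of the
envelope's fluctuation power spectrum restricted to 0.25–10 Hz — the band
of rhythmic fluctuation: a clearly pulsed excerpt concentrates envelope
power at the beat rate and its harmonics (low entropy, clarity near 1),
free-rhythm material spreads it (clarity near 0). At least 5 s of audio
is required. **Event density** is detected onsets per second; onsets are
local maxima of the lightly smoothed flux exceeding the median plus 1.5
standard deviations, separated by ≥ 120 ms.

This operationalization follows the verbal definition of pulse clarity
as fluctuation-spectrum entropy; its absolute values are specific to
these choices (band, window, entropy normalization by the log bin count),
so the package's validation asserts only orderings and contrasts — gat
renditions must outscore matched alaap renditions on both descriptors —
never particular numeric values from other toolchains.

## The synthetic stimulus generator

`generate_raga_audio()` renders a mono 22,050 Hz 16-bit excerpt: a
harmonic drone at the tonic (261.5 Hz by default), a melody of discrete
harmonic tones with attack/decay envelopes, and — in gat mode — a
percussive click layer on the beat grid. Alaap mode draws inter-onset
intervals from a capped exponential at `event_rate` (default 0.5 notes/s)
with no percussion; gat mode uses an isochronous grid (default 1.5
notes/s) with small timing jitter (5% of the inter-onset interval) plus
the click layer. Notes are legato: each sustains to the next onset, and
the returned ground-truth pitch track lists the sounding pitch per 30 ms
frame.

Swaras are assigned to notes by a duration-weighted quota: note durations
are drawn first, then processed longest-first, each assigned to the
pitch class with the largest remaining deficit against the target time
share given by `swara_weights`. A raga rendition presents its prescribed
swaras in balanced proportion — a performance is not an i.i.d. draw — and
the quota scheme realizes exactly that: rendered occupancy tracks the
prescribed weights to well under a total-variation distance of 0.05 at
three minutes, and the tonality of alaap and gat renditions of the same
raga agrees to better than 0.02, the two generator contracts the
validation suite enforces. Octave placement (±1 octave, probabilities
0.15/0.7/0.15) and five-limit just-intonation cent offsets per swara
complete the pitch.

The default stimulus set is 12 synthetic ragas whose prescribed m/M
ratios span 0 to 1.4, each rendered in both modes — 24 excerpts ordered
by tonal ratio, mirroring the study design this package operationalizes.

What the generator does **not** emulate: sarod timbre, ornamentation
(meend, glides between notes), tempo drift, expressive microtiming, or
room acoustics. Passing tests on this audio therefore validate the
pipeline's arithmetic and its orderings, not robustness to concert
recordings.

## The survey simulator

`simulate_ratings()` produces the long rating table of a 0–4 Likert
survey: per participant, a familiarity score drawn from the group's
distribution (defaults: mean 2.86, SD 1.09 for the enculturated group;
1.99, 1.02 for the non-enculturated; rounded and clipped to 0–4), then
per rated excerpt and emotion a rating
$\mathrm{round}(\beta_0 + \beta_T\,t + \beta_R\,r + \beta_F\,f +
\varepsilon)$ clipped to 0–4, with $\varepsilon \sim N(0,
\texttt{noise\_sd}^2)$, `noise_sd` defaulting to 0.8 rating units — our
choice of a realistic ordinal-noise level; no per-raga variances are
available to calibrate against, so it is documented here and exposed in
the parameters object. Group sizes default to 143 and 112. Participants
complete 2, 3 or 4 of the survey's alternating alaap/gat blocks
(probabilities 0.30/0.15/0.55, starting mode counterbalanced); this
opt-out structure is what makes the per-excerpt mean familiarity of the
actual raters vary across excerpts, which in turn is what lets
familiarity enter a 24-row regression as an excerpt-level covariate at
all.

The default `"cross_cultural"` coefficient scenario makes tonality
dominant for group E and rhythm dominant for group NE, with slopes laid
out so each corner of the (tonality, rhythm) design space has one
clearly dominant emotion — calm for low-m/M alaap, happy for low-m/M
gat, sad for high-m/M alaap, tensed for high-m/M gat — as ragas carry
distinct dominant emotions; this keeps modal labels stable across
independent samples from one process. The contrast between the groups is
deliberately strong (a clear ground truth for validating cue-attribution
recovery), stronger than real listener groups, whose mean ratings are
largely indistinguishable; consequently the *universality* verdict on
this scenario is negative. The `"null"` scenario — both groups share one
coefficient set and one familiarity distribution — is the calibration
counterpart: every between-group null is true, and it underlies the
type-I-error and CI-coverage checks.

## Group comparison and the universality rule

For each group a 24 × 8 mean rating matrix is built (excerpt × emotion;
cells average that group's raters). Label use is compared via the modal
label of each excerpt — by default each participant votes for their
maximum-rated emotion(s), and the most-voted label(s) win; ties are
returned as sets and two groups *agree* when their sets intersect (the
alternative argmax-of-means definition is also implemented). Label
distributions are compared by the two-sample Kolmogorov–Smirnov test;
with a 5-point discrete scale ties are pervasive, so the asymptotic
p-value is used and should be read as approximate.

Intensity is compared cell-wise: 8 emotions × 12 ragas × 2 modes = 192
two-sided comparisons per family, by Welch's t (parametric) and the
Wilcoxon rank-sum test with continuity correction (non-parametric).
Zero-variance cells, which a discrete instrument can produce, are
handled explicitly (identical constant samples give t = 0, p = 1).
Each family's 192 p-values are jointly adjusted by the Hochberg step-up
procedure — sort ascending, $\tilde p_{(m)} = p_{(m)}$,
$\tilde p_{(i)} = \min(\tilde p_{(i+1)}, (m - i + 1)\,p_{(i)})$, capped
at 1 — and **universality** is declared when strictly more than half of
the adjusted p-values exceed 0.05 (96 of 192 is not enough; the rule is
a strict majority).

## Robust regression and the variance partition

Per emotion × group, the 24 mean excerpt ratings are regressed on
tonality (continuous), rhythm (0 = alaap, 1 = gat) and mean rater
familiarity by iteratively reweighted least squares with Tukey's
bisquare $\psi$: tuning constant $c = 4.685$ (95% Gaussian efficiency),
scale re-estimated each iteration as $\mathrm{median}|e| / 0.6745$,
convergence when the largest coefficient change falls below $10^{-8}$
(relative to coefficient magnitude) within 50 iterations. Numerical
choices worth noting: initialization is the OLS solution; an exact fit
(robust scale numerically zero relative to the response scale) stops
with unit weights; a rank-deficient design errors naming the offending
columns; and supplying fixed case weights short-circuits to a single
weighted least-squares solve, so unit weights reproduce OLS exactly —
the identity the test suite exploits.

No standard definition exists for "percent variance explained by one
predictor" under robust regression, so the package adopts and documents
one: the **leave-one-predictor-out difference in robust R²**, where both
R² values are computed on robust-weighted data under the final
full-model IWLS weights and the reduced model is refit by weighted least
squares with those frozen weights; the difference is clipped at 0. This
unique-contribution definition is invariant to affine rescaling of the
response and recovers the generating variance decomposition for
orthogonal predictors. The reported per-predictor F is the partial
(leave-one-out) F on the same weighted data; the df columns report the
full-model pair (parameters, n − parameters) = (4, 20) for the 24-row
design, the labeling convention of published variance-partition tables
for this design (the partial F itself has 1 and n − parameters degrees
of freedom). These are documented alternatives, not claims of
equivalence to any particular prior computation.

As a model-agnostic cross-check replacing an external machine-learning
replication, `permutation_importance()` permutes one predictor's column
at a time (≥ 100 permutations, seeded) and reports the mean increase in
the weighted mean squared residual under the fitted coefficients; its
ranking agrees with the variance partition on the default scenarios.

## The odds ratio

Per emotion, reliance on tonality versus rhythm is contrasted across
groups:

$$\mathrm{OR} = \frac{\%\mathrm{Var}(T, E) / \%\mathrm{Var}(R, E)}
                    {\%\mathrm{Var}(T, NE) / \%\mathrm{Var}(R, NE)}.$$

Swapping the groups maps OR to 1/OR exactly, and a common positive
rescaling of one group's two inputs cancels. Any non-positive input
(possible after clipping) yields a flagged undefined result rather than
an infinity. Because no CI construction is prescribed for a ratio of
variance proportions, the package uses a **percentile bootstrap over
excerpts**: resample the 24 excerpts with replacement, refit both
groups' regressions, recompute the OR per replicate (default 2000;
replicates with a degenerate design — one presentation mode only, no
tonality spread, or an undefined OR — are dropped and counted, with a
warning past 20%). The p-value is a normal approximation on the log-OR
scale using the bootstrap SE, Hochberg-adjusted across the eight
emotions. Heterogeneity across emotions is assessed Cochran-Q-style on
log ORs with the bootstrap variances; a pooled common odds ratio is
sanctioned only when the heterogeneity p exceeds 0.05.

```{r odds-ratio-example}
ex <- example_variance_partition()
or <- compute_odds_ratio(ex$tonality_e[1], ex$rhythm_e[1],
                         ex$tonality_ne[1], ex$rhythm_ne[1])
round(as.numeric(or), 2)  # calm
```

## Problem sizes and validation scales

The validation suite runs the chain at the scales the design calls for:
tonality recovery on all 12 ragas in both modes at the full 3-minute
excerpt duration (ground-truth pitch tracks); the rhythm contrast on all
12 raga pairs from 60 s of rendered audio per excerpt — the rhythm
descriptors are stable from about a minute; regression recovery and
cue-dominance ordering over 200 simulated 24-row replicates per group
profile at noise SD 0.2; family-wise type-I control over 200 null-survey
replicates at the full 143/112 group sizes; CI coverage over 100 null
surveys at reduced group sizes (30/30) with 300 bootstrap replicates.
Exhaustive oracles back the discrete procedures: the Hochberg
implementation is compared against a brute-force double-loop evaluation
of the step-up definition over all permutations of p-vectors up to
length 8, and the KS statistic against direct ECDF enumeration.

## Known limitations

- The pitch estimator is a deliberately simple autocorrelation method;
  it is not a melody extractor and can lock onto a strong drone.
  Ground-truth tracks are the supported route for synthetic work.
- Pulse clarity values are specific to this operationalization; compare
  orderings, not absolute numbers, across toolchains.
- The KS p-value on 5-point data is asymptotic under heavy ties.
- The bootstrap CI resamples excerpts, not raters; rater-level
  uncertainty enters only through the mean matrices.
- The simulator's linear-plus-rounding rating model omits participant
  random effects and any tonality × rhythm interaction; it validates
  recovery, not realism.
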