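# ragacues

Tonality and rhythm cues in cross-cultural ratings of musical emotion.

`ragacues` is an R package for a question in auditory cognition: when
listeners from different cultural backgrounds report the *same* emotions
for a piece of melodic music, are they reading the same acoustic cues?
Hindustani *ragas* are uniquely suited to the question because each raga
is performed in two stages — the rhythmically free *alaap* and the pulsed,
percussion-backed *gat* — that share their tonal material while differing
in rhythm. The package provides, end to end:

- **Stimulus quantification.** A melodic excerpt with a known tonic is
  reduced to a frame-wise pitch track (30 ms hop), expressed in cents
  relative to the tonic, `Pitch(cents) = 1200·log2(f1/f0)`, binned into a
  three-octave tonic-interval histogram (100-cent bins, −1200..2400),
  folded into one octave by pitch class, and summarized by the **tonality
  ratio m/M**: summed occupancy of the five minor (komal) pitch classes
  over the seven major (shuddh) classes. Rhythm is summarized by **pulse
  clarity** (one minus the normalized Shannon entropy of the
  onset-envelope fluctuation spectrum, 0.25–10 Hz) and **event density**
  (note onsets per second).
- **Synthetic stimuli with ground truth.** A generator renders
  drone-plus-melody excerpts (tonic 261.5 Hz, just-intonation offsets,
  WAV output) in both alaap and gat modes, with the true pitch track and
  onset list returned alongside the audio, plus a simulator for a 0–4
  Likert emotion survey over two listener groups ("E" enculturated,
  "NE" non-enculturated).
- **Group comparison.** 24×8 mean rating matrices (excerpt × emotion),
  modal-label agreement, Kolmogorov–Smirnov label-distribution tests, and
  the full family of 192 Welch / Wilcoxon intensity comparisons with
  Hochberg step-up correction; *universality* is declared when strictly
  more than half of the adjusted p-values exceed 0.05.
- **Cue attribution.** Per emotion × group, mean excerpt ratings are
  regressed on tonality, rhythm (alaap/gat as 0/1) and familiarity by
  iteratively reweighted least squares with Tukey's bisquare
  (c = 4.685, MAD scale), and each predictor's unique contribution is the
  leave-one-predictor-out difference in robust R², in percent.
- **The odds ratio.** The cross-group contrast of cue reliance,

  ```
  OR = [%Var(Tonality, E) / %Var(Rhythm, E)] /
       [%Var(Tonality, NE) / %Var(Rhythm, NE)]
  ```

  with a percentile bootstrap CI over excerpts, Hochberg-adjusted
  p-values, and a Cochran-Q heterogeneity check before any pooling.

## Worked example

```r
library(ragacues)

# the classic worked example: odds ratios from a published-style
# percent-variance partition table
ex <- example_variance_partition()
or <- compute_odds_ratio(ex$tonality_e[1], ex$rhythm_e[1],
                         ex$tonality_ne[1], ex$rhythm_ne[1])
round(as.numeric(or), 2)
#> [1] 19.96    # calm: (33.41/9.69) / (10.22/59.15)

# a full synthetic run: 24 excerpts, two simulated listener groups
cfg <- pipeline_config(out_dir = "demo", seed = 42, duration_s = 30,
                       n_boot = 200)
res <- run_pipeline(cfg)
```

The run writes `features.csv`, `ratings.csv`, `comparisons.csv`,
`variance_partition.csv`, `odds_ratios.csv`, `verdict.json` and a
markdown report. With the default simulation scenario (enculturated
raters weight tonality, non-enculturated raters weight rhythm) the
report's odds-ratio table comes out, for example:

```
emotion | OR    | 95% CI          | adj. p
calm    | 49.68 | (22.35, 124.15) | 3.1e-19
sad     | 50.95 | (20.86, 159.79) | 1.2e-16
happy   | 45.35 | (15.04, 127.45) | 2.3e-11
```

Every odds ratio is far above 1: the simulated enculturated group's
ratings are explained by tonality, the non-enculturated group's by
rhythm, and the statistic recovers that asymmetry from the ratings
alone. A `"null"` scenario (identical generative processes for both
groups) is provided for calibration checks; under it the comparison
family flags essentially nothing after correction and the odds-ratio
CIs cover 1.

There is also a thin command-line wrapper:

```sh
Rscript inst/cli/ragacues.R all --seed 42 --out demo
```

## Package layout

| Area | Files |
| ---- | ----- |
| synthesis & ground truth | `R/synth.R`, `R/wav.R`, `R/ratings-sim.R` |
| acoustic features | `R/pitch.R`, `R/histogram.R`, `R/rhythm.R`, `R/features.R` |
| rating analysis | `R/rating-analysis.R` |
| robust regression & partition | `R/robust.R` |
| odds ratio | `R/oddsratio.R` |
| orchestration | `R/pipeline.R`, `inst/cli/ragacues.R` |

The methods vignette (`vignettes/raga-emotion-pipeline.Rmd`) documents
the model choices, parameter defaults, and known limitations.
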