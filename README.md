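# lexicross

Paired case-crossover analysis of social-media language change before
hospital visits.

## The problem

Language posted on social media shifts in the weeks before people seek
hospital care — more somatic and anxious/depressed wording, fewer informal
"netspeak" markers. Detecting that shift at the individual level is
confounded by everything that makes people's language differ from each
other. `lexicross` is for biostatisticians and computational health
researchers who want a tested, reproducible implementation of the
case-crossover answer to that confounding: **each patient serves as their
own control**.

For every patient two events are anchored — the **true event** (the most
recent qualifying hospital visit) and a **null event** (a random date).
Each event gets two 30-day windows separated by a 15-day gap, ending the
day before the event. With window feature vectors $x$, the analysis
quantities are

```
change        = x(recent) − x(earlier)            (per event)
diff-of-diff  = change(true) − change(null)       (per patient)
```

Per-feature inference is a two-tailed paired t-test on the diff-of-diffs
with Benjamini–Hochberg FDR correction and paired Cohen's
$d_z = \bar d / s_d$ (95% CI). Forecasting — *does language change predict
that a visit is coming?* — classifies change vectors (true vs null) with a
PCA-reduced linear ensemble (random forest + SVM + gradient boosting +
logistic regression, probabilities averaged), evaluated by
patient-exclusive 5-fold cross-validation (pooled out-of-fold AUC, F1 at
0.5), with a ridge-logistic active control.

Window features: LIWC-style dictionary relative frequencies (trailing-`*`
stem wildcards), topic loadings from a supplied topic-word table
(word-level mixture `Σ_w f(w) p(t|w)`), weighted-lexicon construct scores
(valence, arousal, anxious, depressed, extraverted), and posting meta
statistics (3-hour clock bins, post counts, mean post length).

Because real post/EMR data of this kind are not shareable, the package
includes a synthetic cohort generator (Poisson post streams over a mixture
vocabulary, one visit per patient) that injects multiplicative shifts of
chosen dictionary categories in the 30 pre-visit days, with a closed-form
expected $d_z$ (`expected_effect()` / `calibrate_multiplier()`) so the
whole pipeline is validated against known truth.

## Worked example

One command runs the synthetic demo end to end (200 patients, a
health-language shift calibrated to an expected $d_z$ of 0.5 before each
visit):

```r
library(lexicross)
manifest <- run_pipeline(demo_config(n_patients = 200, seed = 1),
                         output_dir = "demo_run")
fit <- attr(manifest, "fit")
print(fit)
```

```
Case-crossover language analysis (ED arm)
  patients: 200 (true + null event each)
  ensemble 5-fold CV: AUC = 0.628, F1 = 0.564
  ridge control:      AUC = 0.665, F1 = 0.631
  significant features (BH alpha = 0.05): 2 of 43
```

The forecasters separate pre-visit from pre-random change months well
above chance (pooled out-of-fold AUC ≈ 0.63–0.67 at this injected effect
size; chance is 0.5), and the differential table recovers the injected
signal:

```r
print(fit$differential, n = 4)
```

```
Differential language features: 43 features, 2 significant at BH alpha = 0.05
           feature cohens_d     p_bh mean_diff_of_diff d_ci_low d_ci_high
1      dict:health    0.490 2.43e-09           0.00647   0.3435     0.637
2      lex:anxious    0.267 4.54e-03           0.00274   0.1259     0.408
3 meta:posts_09_12    0.164 3.03e-01           0.74500   0.0248     0.304
4        topic:t10    0.156 3.05e-01           0.00213   0.0167     0.296
  significant
1        TRUE
2        TRUE
3       FALSE
4       FALSE
```

`dict:health` is the shifted category: its estimated $d_z$ (0.49)
brackets the injected 0.5, and the anxiety lexicon — which weights health
words — follows. Everything
is written to `demo_run/`: posts/events/truth, a cohort manifest,
the feature matrix, `differential_report.csv` (increase/decrease sections,
style before topics), `roc.csv`, `evaluation.json`, and `manifest.json`
with md5 hashes of every output — rerunning the same seed reproduces the
hashes byte for byte.

The same functions accept real inputs: `read_posts()` (JSONL/CSV),
`read_events()`, `read_dictionary()` (LIWC-style `.dic` or CSV),
`read_topic_table()`, `read_lexicon()`, then `casecross(posts, events,
arm, resources, config)`.

See `vignettes/language-case-crossover.Rmd` for the model, its
assumptions, and every numerical choice.

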