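---
title: "Case-crossover analysis of language change before hospital visits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Case-crossover analysis of language change before hospital visits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lexicross)
```

## The design

`lexicross` implements a paired case-crossover analysis of social-media
language: does what a patient writes change in the weeks before a hospital
visit, relative to how their language drifts at an arbitrary time? In a
case-crossover design each patient serves as their own control, which
removes all time-invariant between-person confounding (vocabulary, posting
style, platform habits).

Two events are anchored per patient:

* the **true event** — the patient's most recent hospital visit that
  satisfies the inclusion rule below;
* the **null event** — a random date whose lookback period satisfies the
  same rule and, by default, does not overlap the true event's period.

Each event anchors two 30-day windows separated by a 15-day gap, ending the
day before the event (the event day itself is excluded). For each window a
feature vector is computed; the analysis quantities are

* **change** = recent-window features − earlier-window features, and
* **diff-of-diff** = change before the true event − change before the null
  event,

so a positive diff-of-diff means the feature rose more sharply before the
visit than it did before an arbitrary date.

**Inclusion rule.** A window pair is usable only when both its windows hold
at least `min_posts_per_window` posts. The default is 21 — a strict reading
of "more than 20 posts" — and it is a config knob. When the most recent
visit fails the rule we scan back to the most recent *qualifying* visit
(maximizing cohort size); `strict_recent_only = TRUE` instead drops the
patient, since either reading of the design is defensible.

**Null-event sampling.** Candidate dates are drawn uniformly from the part
of the patient's posting span where a full 75-day lookback exists. We
forbid overlap between the null and true periods by default: overlap would
leak case-window language into the control and bias the paired contrast
toward zero. `allow_null_overlap = TRUE` restores unconstrained sampling.
Sampling gives up after `max_null_draws` (200) failed candidates and drops
the patient, logged.

## Features

Each window is summarized by four groups (the open-vocabulary n-gram block
is optional and off by default):

* **Dictionary relative frequencies** (`dict:*`): for each closed-vocabulary
  category, matched tokens divided by total window tokens. Patterns are
  literal words or stems with a trailing `*` (prefix match). A token in two
  categories counts once in each.
* **Topic loadings** (`topic:*`): a word-level mixture,
  $\mathrm{loading}(t) = \sum_w f(w)\,p(t\mid w)$, where $p(t \mid w)$ is
  the topic table's weight for $w$ normalized over topics and $f(w)$ the
  word's relative frequency among in-vocabulary tokens. This is the
  standard lexicon-style approximation to per-document topic posteriors; it
  is deterministic, fast, and adequate for loading *differences*, but it is
  not posterior inference, and we do not claim it reproduces any particular
  LDA implementation's inference step. Topic fitting itself is out of
  scope: the topic-word table is an input.
* **Weighted-lexicon scores** (`lex:*`): intercept plus
  frequency-weighted sums, for valence/arousal/anxiety/depression/
  extraversion-style construct lexica supplied as word-weight tables.
* **Meta features** (`meta:*`): posts per half-open 3-hour clock bin (a
  12:00:00 post falls in the 12–15 bin), total posts, mean tokens per post.

The tokenizer is fixed and documented (lowercase, URL stripping, a small
emoticon set kept as tokens, apostrophe contractions kept whole) because
upstream tokenization choices change dictionary counts; it is the package's
reference tokenizer, swappable only by featurizing pre-tokenized windows.
Relative-frequency denominators always use the unigram token count.

## Inference

Per feature, the per-patient diff-of-diffs $d_i$ are tested with a
two-tailed paired t-test; p-values are Benjamini–Hochberg adjusted jointly
across all testable features (the conservative choice when feature groups
are analyzed together) at $\alpha = 0.05$. The effect size is the paired
Cohen's $d_z = \bar d / s_d$ — chosen because its numerator is exactly the
reported mean diff-of-diff; $d_{av}$ is available as an option. The default
95% CI for $d_z$ uses the normal-approximation standard error
$\sqrt{1/n + d_z^2/(2n)}$, with a noncentral-t inversion behind the
`ci = "nct"` flag; a t-based CI for the raw mean difference is emitted
alongside. Features with zero-variance diff-of-diffs (e.g. a constant meta
count) are reported as non-testable rather than dropped, so table arity is
stable.

## Forecasting

The classifier sees one change vector per (patient, event), labeled 1 for
true events and 0 for null events — two rows per patient. Evaluation is
patient-exclusive 5-fold cross-validation: folds partition *patients*, so
no individual contributes to both training and testing. Inside each fold,
training rows are standardized (unit variance is needed because dictionary
frequencies, lexicon scores and post counts live on different scales) and
PCA-reduced to the smallest number of components reaching 95% cumulative
explained variance; both statistics come from the training fold only. The
forecaster is a linear ensemble — the unweighted mean of predicted
probabilities from a random forest, a radial SVM with Platt scaling,
gradient boosting, and plain logistic regression, all with pinned default
hyperparameters (no tuning, no user bias). Probabilities, not ranks, are
averaged. Reported metrics are the pooled out-of-fold AUC (per-fold AUCs
and their mean are kept alongside), and F1 at a fixed 0.5 threshold. A
ridge-penalized logistic regression run under the identical protocol serves
as the active control; its penalty is chosen by seeded internal
cross-validation on the training fold.

## The synthetic cohort generator

Real post/EMR data of this kind cannot be shared, so the package ships a
generator whose statistical structure matches what the analysis assumes,
with effects of *known analytic size*:

* posts: homogeneous Poisson process per patient, default 1.5 posts/day
  over 365 days (≈45 posts per 30-day window, comfortably above the 21-post
  rule, mirroring an active-poster cohort);
* post lengths: zero-truncated Poisson, mean 12 words;
* words: i.i.d. draws from a Zipf-weighted ~200-word vocabulary containing
  an 8-category dictionary (health, informal, family, leisure, negative and
  positive emotion, social, sleep), a 20-topic table and five lexica, all
  built deterministically (`default_synthetic_resources()`);
* one visit per patient, uniform over the last 90 days of history so a full
  75-day lookback and a disjoint null period always exist;
* the injected effect: inside the 30 days before the visit (exactly the
  recent true window, not the gap) the chosen category's word emission
  probabilities are multiplied by `m` and the vocabulary renormalized.

With baseline category probability $p_0$, the shifted probability is
$p_1 = m p_0 / (1 + (m-1)p_0)$, and with $N$ expected tokens per window the
category's relative frequency is approximately binomial, so the per-patient
diff-of-diff has mean $p_1 - p_0$ and variance
$(3p_0(1-p_0) + p_1(1-p_1))/N$ (three null windows, one shifted window),
giving the delta-method oracle

$$d_z \approx \frac{p_1 - p_0}
{\sqrt{\left(3p_0(1-p_0) + p_1(1-p_1)\right)/N}}.$$

`expected_effect()` evaluates this and `calibrate_multiplier()` inverts it,
so tests can inject a shift of *chosen* expected $d_z$ and check recovery.
The tests verify the oracle against brute-force simulation (it agrees
within a few percent; the neglected terms are the Poisson variability of
$N$ and the renormalization of non-category words, both $O(p_0)$).

What the generator does **not** emulate: grammar and word order (features
here are bag-of-words), burstiness and topic drift within a patient,
between-patient vocabulary heterogeneity, multiple visits, demographic
covariates. Passing tests therefore show the *pipeline* is correct and
calibrated — not that real social-media language carries this much signal.

## Numerical and design choices

* All dates are naive local calendar dates; no timezone arithmetic.
  Date-only timestamps get 12:00 so they fall in a defined posting bin.
* Post-to-window assignment uses the post's calendar date with inclusive
  interval endpoints.
* Seeds: one master seed per run; every stage derives its own stream with
  fixed offsets, so regenerating the null events cannot perturb true-event
  quantities. A rerun with the same config is byte-identical.
* Standardization guards constant columns (sd 0 → 1); PCA keeps at least
  two components because some downstream learners require them.
* Zero-variance features become typed `lexicross_degenerate` errors at the
  statistic level and "non-testable" rows at the table level.
* BH is applied jointly across all features of all groups, the
  conservative default when the analysis is reported as one table.

## Simulation-study sizes

The packaged checks use cohorts chosen to make their targets measurable:
null forecasting calibration at n = 400 patients (a null AUC's 95% band is
then well inside [0.45, 0.55]); false-discovery calibration over 200
seeded differential runs at n = 60 patients with 160-day histories (BH's
FDR guarantee does not depend on n, so many small replicates beat few
large ones); parameter recovery and the effect-size/AUC grid at n = 200
patients with injected effects calibrated to $d_z \in \{0, 0.25, 0.5,
1\}$. The demo pipeline runs at n = 200.

## Worked example

```{r, eval = FALSE}
library(lexicross)

manifest <- run_pipeline(demo_config(n_patients = 200, seed = 1),
                         output_dir = "demo_run")
fit <- attr(manifest, "fit")
print(fit)
summary(fit)
plot(fit)                      # pooled out-of-fold ROC curves
head(coef(fit))                # per-feature Cohen's d_z
```

The same objects are available piecewise — `generate_cohort()`,
`assemble_cohort()`, `featurize_cohort()`, `differential_table()`,
`grouped_cv_evaluate()` — for real post/event/dictionary inputs read with
`read_posts()`, `read_events()`, `read_dictionary()`, `read_topic_table()`
and `read_lexicon()`.

## Known limitations

* The word-level topic mixture is an approximation to per-post topic
  inference (see above).
* One true event per patient; repeated visits and time-stratified referent
  schemes are out of scope.
* The paired t-test assumes approximately normal diff-of-diffs;
  permutation or mixed-effects alternatives are not provided.
* The ensemble uses pinned default hyperparameters by design; no
  hyperparameter search is performed.
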