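---
title: "Simulated federated averaging for AECOPD severity classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated federated averaging for AECOPD severity classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fedcopd)
```

## The problem

Records of patients with chronic obstructive pulmonary disease (COPD) are
scattered across hospitals of different sizes and levels, and privacy
legislation makes pooling the raw records into one training set difficult or
illegal. Federated averaging (FedAvg) sidesteps the pooling: each hospital
trains a local copy of a shared model on its own data and uploads only the
model parameters; a coordinating server averages the uploads and broadcasts
the result back. `fedcopd` simulates this loop in-process for a binary
severity classification task — mild (label 0) versus severe (label 1) acute
exacerbation of COPD (AECOPD) — together with the isolated per-site training
baseline it is compared against, a synthetic cohort generator standing in for
the private hospital data, and the usual classification metric battery.

Everything is seeded and deterministic: the same configuration and master
seed reproduce every parameter, prediction and report bit for bit.

## Model and training rule

The backbone is a small fully connected network. By default it maps the 40
standardized clinical features through hidden layers of 32 and 16 ReLU units
to a single logistic-sigmoid output $p_j \in (0,1)$, the predicted
probability that patient $j$ belongs to the severe group. The loss is the
mean binary cross-entropy

$$L(\theta) = -\frac{1}{N}\sum_j \big[\,y_j \log p_j + (1-y_j)\log(1-p_j)\,\big],$$

and each local update is one plain gradient-descent step
$\theta \leftarrow \theta - \eta \nabla L(\theta)$ on a minibatch — no
momentum, weight decay or adaptive rates, so the update exchanged between
sites is exactly the quantity under study. Gradients are exact analytic
backpropagation; the test suite checks them against central finite
differences at relative error below $10^{-5}$.

One **communication round** consists of: every client runs $E$ local epochs
of minibatch SGD from the current global parameters; the server replaces the
global parameters with the elementwise arithmetic mean
$\theta^{r+1} = \frac{1}{K}\sum_{k=1}^{K} \theta_k^{r}$; each client then
scores its local test set with the new global parameters. The unweighted mean
is the default because the aggregation is defined that way where it is
defined precisely; a sample-size-weighted mean is available via
`fl_config(weighted = TRUE)` for unbalanced shards, but is off by default.

The tunable hyperparameters, with their defaults (the published settings):

| parameter | meaning | default |
|---|---|---|
| `k` | clients (simulated hospitals) per round, all participating | 3 |
| `rounds` | communication rounds $r$ | 350 |
| `epochs` | local epochs $E$ per round | 5 |
| `batch_size` | minibatch size $B$ (records) | 10 |
| `eta` | learning rate $\eta$ | 0.001 |
| `split` | local train:test ratio $T$ | 7:3 |
| `hidden` | hidden-layer widths | 32, 16 |

Iterations per epoch are the derived $\lceil n_\text{train}/B\rceil$; the
last short batch is kept. Each epoch uses one seeded shuffle of the training
rows.

## The isolated baseline ("CML")

The comparison arm trains the identical backbone on each shard alone, with
matched settings: the same architecture, the same shared initialization, the
same local split, and a **matched gradient-pass budget** of $r \cdot E$
epochs per client. The budget match is a deliberate design choice: the
original description does not say how long the baseline trains, and matching
the number of gradient passes ensures any federated advantage cannot be
attributed to extra optimization. The label "CML" is kept in reports for
fidelity with the source terminology, where it denotes per-site isolated
training (not true centralization of pooled data).

The baseline consumes the same derived per-(client, round) seeds in blocks of
$E$ epochs, which makes a $K = 1$ federation bitwise identical to local
training — a property the acceptance suite asserts exactly.

## What the synthetic generator emulates

No public record-level data exist for this task, so `generate_cohort()`
reproduces the published group-level structure:

* group sizes 220 (mild) and 188 (severe), 408 records in total;
* exact per-group sex counts (188/32 male/female mild, 157/31 severe), so the
  totals of 345 male and 63 female reproduce exactly at the defaults;
* seven vital signs (age, hospitalizations, systolic and diastolic pressure,
  temperature, pulse, respiratory rate), each published as a 95% confidence
  interval of the group mean. Assuming normal-theory intervals
  ($\bar{x} \pm 1.959964\, s/\sqrt{n}$), `ci_to_moments()` inverts each
  interval at the printed group size to a population mean and standard
  deviation, and records are drawn from that normal per group;
* 33 filler features, standard normal and identically distributed in both
  groups, padding the schema to the 40 modeling columns. The real feature
  list beyond the published vitals is unknown, so the fillers are an explicit
  convention, not an inference: all discriminative signal comes from the
  published vitals (sex is kept as a demographic column but is not a model
  input);
* optional per-cell missingness (`missing_rate`) to exercise the cleaning
  filters: features with more than 10% missing cells are dropped first
  (strictly greater — a feature at exactly 10% survives), then records with
  any remaining missing cell are excluded.

Continuous draws are truncated by inverse-CDF sampling to broad physiological
bounds (age 18–110 years, systolic 60–260 mmHg, diastolic 30–150 mmHg,
temperature 30–45 °C, pulse 20–220 bpm, respiratory rate 5–60 breaths/min).
The bounds were chosen so they cut negligible probability mass (worst case
about 0.1% for the severe-group respiratory rate), which keeps the configured
intervals recoverable: the test suite verifies that the empirical 95% CI of
each group mean, rescaled to the printed group size, matches the configured
interval within three Monte-Carlo standard errors. The hospitalization count
is deliberately **not** truncated: its interval inverts to mean 6.5 and
standard deviation about 7.0 in the severe group (coefficient of variation
above 1), and no normal truncated at zero can attain that dispersion — a
left-truncation would inflate the group mean by about two hospitalizations
and silently break the generator's fidelity contract. The occasional negative
draw is the honest price of matching the published moments with a marginal
normal; users who prefer hard bounds can set them per feature via
`feature_spec()`.

What the generator does **not** model: correlations between features (only
marginal intervals are published), the skewness real count and vital-sign
data certainly have, longitudinal structure, site-level distribution shift
(shards are drawn by simple random sampling from one population, the same
device used in the original study), or informative missingness. Passing
tests therefore demonstrate that the *mechanism* — federation versus isolated
training under data scarcity — behaves as claimed on data with the published
first- and second-moment structure; they are not evidence about any
particular real-world cohort.

## Reproducibility plumbing

All randomness flows from one master seed through `derive_seed()`, a
sequential integer-folding mix (modulus $2^{31}-1$): the shared
initialization uses `derive_seed(seed, "init")` and client $k$ in round $r$
uses `derive_seed(seed, "client", k, "round", r)`. Clients therefore evolve
independently and reproducibly, and the federated and baseline arms consume
identical seed streams. Each client standardizes features with its own
training-set mean and standard deviation — no cross-client statistics are
shared, preserving the privacy premise — and applies the same transform to
its test set.

Numerical conventions: probabilities are clipped to
$[10^{-7}, 1-10^{-7}]$ before any logarithm; weights initialize
$\mathcal{N}(0, 1/\text{fan-in})$ with zero biases; the decision threshold is
0.5 with ties mapping to the positive (severe) class; metrics with degenerate
denominators (no predicted positives, no true positives) return 0 with a
warning rather than an error, so sweeps over tiny test sets complete; AUC
uses the Mann–Whitney rank formulation with ties credited 0.5; repeated-run
confidence intervals are the normal approximation
$\bar{x} \pm 1.959964\, s/\sqrt{m}$.

## What the experiments show — and when

`run_comparison()` executes the full pipeline (generate → clean → partition →
split → both training arms → metrics) and reports per-client and macro
metrics plus absolute improvements in percentage points. Two findings from
the package's own test battery are worth stating here because they shape how
the defaults should be read:

* At the default 350 rounds the federated arm beats isolated training on
  macro accuracy consistently (about +3 to +5 percentage points across master
  seeds on the default synthetic cohort), with a bootstrap 95% CI of the mean
  improvement excluding zero over 20 seeds.
* At 50 rounds or fewer the federated arm shows **no** advantage on this
  cohort — averaging has not yet converged — matching the round-sweep
  behaviour reported for the original system. The acceptance suite therefore
  tests the directional claim at the default 350 rounds and separately
  asserts the shape (the advantage at 350 rounds exceeds the advantage at 10
  rounds).

Problem sizes in the test battery are scaled to desk runtime as the package's
own choice: the directional test uses 20 master seeds at the default
configuration, the shape test 10 seeds, the generator-fidelity check $10^4$
draws per group, and the data-scarcity trend check (federated advantage as
per-client samples shrink) runs at three sample sizes with a small seed set.
`run_randomized_trials()` reproduces the 100-randomized-test style of summary
at whatever scale the caller affords.

## Known limitations

* The published system's hidden-layer sizes, activation and initialization
  are unstated; the defaults here are declared conventions, and results at
  other widths may differ in level (not, in our experiments, in direction).
* Marginal-normal synthetic data bound what these experiments can say about
  real records; in particular the absolute metric levels (accuracy around
  0.6–0.67 at the defaults) should not be compared numerically against
  results on the private clinical data.
* The federation is simulated in one process. There is no transport layer,
  no stragglers or dropouts, and no cryptographic protection — privacy is by
  data locality only, as in the modeled design.
* Evaluation uses each client's local test split; with 41-record test sets
  the per-client metrics are noisy, which is why headline comparisons average
  over many master seeds.
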