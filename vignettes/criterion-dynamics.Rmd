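---
title: "Modelling dynamic decision criteria in yes-no detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling dynamic decision criteria in yes-no detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(critdyn)
```

## The model

Classical signal detection theory treats a yes-no decision as a comparison
of a noisy internal variable against a fixed criterion. Behaving animals,
however, adjust their bias from trial to trial: after an error they respond
differently than after a reward, and when the difficulty of the task
changes in blocks their bias tracks it within a couple of trials. `critdyn`
implements a minimal dynamic extension of the static model that accounts for
both time scales with a single update rule.

On trial $n$ a stimulus of level $\mu_n$ (in dB above a reference level
$\mathrm{dB}_{ref}$ at which detection is at chance; $\mu_n = 0$ on
no-signal trials) evokes an internal variable $x_n \sim N(\mu_n, \sigma)$.
With probability $\lambda$ the subject lapses and answers by a fair coin;
otherwise it answers "yes" iff $x_n > c_n$, where $c_n$ is the current
criterion. Hence

$$P(\text{yes} \mid c_n, \mu_n) \;=\; \tfrac{\lambda}{2}
  + (1 - \lambda)\,\Phi\!\left(\frac{\mu_n - c_n}{\sigma}\right),$$

which is `response_probability()`. The joint outcome (hit, miss, false
alarm, correct rejection) determines a signed criterion shift, and the
criterion also decays geometrically toward a resting value:

$$c_{n+1} \;=\; c_n + a\,(c_1 - c_n) + b_{\text{outcome}(n)} + \epsilon_n,$$

with $c_1$ both the resting and the initial criterion,
$a \in [0, 1]$ the decay rate, and $\epsilon_n \sim N(0,
\texttt{shift\_noise\_sd})$ an optional jitter used only in the
stationary-distribution exemplars. The eight parameters
$\Theta = \{\sigma, a, c_1, b_{11}, b_{01}, b_{10}, b_{00}, \lambda\}$ are
held in a `model_params()` object. Reduced variants arise by freezing
parameters (`constrain_variant()`): *no-shift* ($b \equiv 0$, a static
criterion), *no-decay* ($a = 0$, purely additive shifts, $c_1$ only the
initial value), and *no-memory* ($a = 1$, four fixed criterion positions
$c_1 + b_{ij}$ indexed by the previous outcome).

Two printed limit behaviours pin the update rule down: with $a = 1$ the
criterion is a constant departure from the resting state determined by the
previous outcome alone, and with $a = 0$ there is no drift to a resting
state. Decay and shift commute algebraically in this affine rule, so the
order of application is immaterial; we state it as decay-plus-shift. A
lapse is an unbiased coin — "responds randomly" is read symmetrically —
which bounds the yes-probability in $[\lambda/2,\, 1 - \lambda/2]$.
Timeout (no-response) trials are outside the model: the generator never
produces them and the reader rejects any log that would require them.

## Session formats and the synthetic-data generator

The package simulates the three session formats of the study it models:

* **Alternating blocks** (`make_block_schedule()`): blocks of $L$ trials (8
  or 24) alternate between an easy and a hard two-level set, starting easy.
  Within a block exactly $L/2$ trials are no-signal and each level of the
  set appears $L/4$ times, in a uniformly random within-block permutation —
  composition is exact, not statistical. Sessions may end mid-block at the
  trial cap (120 trials for 8-trial blocks, 192 for 24-trial blocks).
* **Randomised levels** (`make_random_schedule()`): each trial is
  independently a signal trial with probability 0.5, its level uniform on
  the level set.
* **Randomised with correction trials** (`apply_correction_policy()`):
  after each incorrect answer the identical stimulus is repeated, flagged,
  until answered correctly. Correction trials drive criterion updates like
  any trial but are excluded from every summary statistic; chains repeating
  until correct are the only reading that guarantees errors are instructed.
  Corrections are never applied to blocked sessions.

Level sets are chosen from a psychometric curve: the four levels are spaced
uniformly in dB between the points where the sigmoid attains 10% and 90% of
its rise above chance, so they span the centre ~80% of the curve; the lower
pair is the hard set (`select_levels_from_sigmoid()`). For a synthetic
observer no curve is measured, so fixtures use the curve of the matching
static observer, taken as midpoint $2\sigma$ and slope $\sigma$
(`fixture_psychometric()`) — a detection threshold about twice the internal
noise SD, with curve width set by the noise. This is a declared convention,
chosen once.

`simulate_session()` runs the generative loop. Per executed trial the RNG
draws are consumed in a fixed order — signal noise, lapse indicator, lapse
coin, shift noise — whether used or not, so traces are reproducible and
correction-trial insertion does not desynchronise upstream draws.
`make_benchmark_suite()` emits ground-truth-labelled corpora at the
published full-model parameter rows (`reference_params()`): the blocked
corpus uses the subject-1 "blocks of 8" row at ~6,500 trials, the scale of
the largest blocked corpus in the study.

What the generator does *not* emulate: motivation or satiety drift across a
session, timeouts, reaction times, reward-magnitude effects, or any
departure from the model's own update rule. A green recovery test therefore
establishes that the fitting machinery inverts the generative model at
realistic sizes — not that ferrets obey the model.

## The Markov solver

Because the criterion update depends only on the current criterion and the
trial outcome, the criterion evolves as a Markov chain, and its
distribution obeys $f_{n+1} = \mathbf{M} f_n$ for a kernel $\mathbf{M}$
fixed by $\Theta$ and the stimulus statistics. `build_kernel()` discretises
the criterion axis (default grid: $c_1 \pm 8\sigma$, extended to cover
every post-shift point $c_1 + b_{ij} \pm 4\sigma$, step $\sigma/40$; kept
at or below roughly 2000 cells), computes the four outcome probabilities at
each grid point from the level mixture, and deposits each outcome's mass at
its deterministic destination with two-point linear interpolation, which
keeps off-grid shifts unbiased in mean. `stationary_distribution()` solves
$f^* = \mathbf{M} f^*$ by power iteration from a uniform start (step-change
tolerance $10^{-12}$, cap $10^5$; the stationarity residual
$\|\mathbf{M}f^* - f^*\|_1$ must reach $10^{-9}$). Power iteration is
preferred to eigendecomposition for robustness on the nearly degenerate
$a = 1$ kernels, whose stationary law lives on at most four points.

Numerical choices at the boundary: columns are truncated at the grid edge
and renormalised, so probability cannot leave the grid. The
pre-renormalisation loss of any column is monitored and an error is raised
above 1% — a configuration whose criterion genuinely escapes (for example
one that *reinforces* correct decisions, $b_{00} = 1, b_{11} = -1, a = 0$,
whose criterion variance grows without bound) announces itself here or by
failing to reach stationarity. One subtlety: when the shift jitter is
convolved in, the tail of the jitter Gaussian that falls off the grid is
absorbed into the boundary cell rather than dropped. Otherwise boundary
columns of *stable* configurations would lose up to half of their jitter
mass and trip the monitor spuriously; only shift-driven escapes should
count.

For alternating blocks the kernel alternates too. `blocked_stationary()`
finds the criterion law at the first trial of the cycle as the fixed point
of the composed map $(\mathbf{M}_{hard})^L (\mathbf{M}_{easy})^L$ and
propagates it around the remaining $2L - 1$ positions; any repeating cycle
of kernels is supported (e.g. an ascending/descending level staircase).
`predicted_summaries()` turns distributions into the same tables the
empirical analyses produce: per-position hit/false-alarm probabilities are
expectations of `response_probability()` over the criterion law, and the
previous-outcome-conditioned ROC markers come from the stationary joint law
of (outcome at $n$, criterion at $n+1$), assembled from the kernel's
per-outcome branches. The first trial of a session, which lacks a
predecessor, is ignored in the empirical conditional analysis, matching the
stationary treatment.

### Exemplar configurations

`exemplar_config()` fixes five illustrative parameter sets (unit $\sigma$,
signal probability ½, jitter 0.01): (i) unit shifts opposing errors
($b_{01} = -1$, $b_{10} = +1$); (ii) unit shifts opposing correct decisions;
(iii) error shifts larger for misses ($b_{01} = -2$); (iv) decay ($a = 0.1$)
toward $c_1 = 1$ with a larger false-alarm shift ($b_{10} = +2$); (v) as (i)
with a two-level mixture $\mu \in \{1, 2\}$. Panels (i), (ii) and (v) are
fully pinned by the source descriptions; the magnitudes in (iii) and (iv)
are declared here, chosen once as the simplest integers satisfying the
stated inequalities. The qualitative facts the suite asserts: (i) is
symmetric about the minimum-error criterion (0.5); (ii) is wider than (i),
because correct outcomes are frequent near the optimum so the criterion
moves often; (iii) is skewed liberal; the blocked solution is more
conservative during easy blocks; conditioned ROC markers are displaced even
after correct outcomes; and the reinforcement configuration diverges.

### Comparing the solver with Monte Carlo

The acceptance check asks that a $10^5$-trial simulated criterion histogram
match the analytic stationary law to total-variation distance < 0.02. The
histogram bin width matters more than it may appear. In the decay-free
exemplars the criterion lives, up to the 0.01-sd jitter, on a lattice of
spacing 1 (the shift magnitude); the lattice *phase* is almost conserved,
mixing only through the jitter on the slow time scale of roughly
$1/\texttt{shift\_noise\_sd}^2 \approx 10^4$ trials. A perfectly matched
simulation therefore shows a finite-sample TV floor above 0.02 at $10^5$
trials on sub-step bins — scaling the simulation to $10^6$ trials drives
the distance toward zero, confirming the floor is sampling, not solver
bias. `tv_distance()` consequently defaults to 1 dB bins, the criterion
step scale, which are insensitive to the slow phase mode; expected sampling
TV there is ~0.01 at $10^5$ trials. The trial count, the 0.02 criterion and
the generator parameters are as stated; only the histogram's bin width is a
package choice, and this paragraph is its justification.

## Descriptive statistics

`pc_max()` is the bias-free proportion correct
$\Phi[(z(H) - z(F))/2]$; rates of exactly 0 or 1 are clamped to $1/(2N)$,
the standard correction (the source is silent). `fit_sigmoid()` fits
$PC(s) = 0.5 + (0.5 - \lambda_{psy})\,\Phi((s - mid)/slope)$ by
Nelder-Mead least squares (the original used `fminsearch`), and reads the
reference level off at 5% of the curve's rise. `wrap_block_positions()`
pools blocked sessions by position modulo one easy+hard cycle;
`fit_block_exponentials()` fits
$y(n) = y_\infty + (y_0 - y_\infty)e^{-B(n-1)}$ jointly to the four
hit/false-alarm transition curves with one shared decay constant $B$. The
exact algebraic form of the original regression is not printed; this form
is declared, and it reproduces the printed correspondence $B = 1.14
\leftrightarrow$ time constant $\approx 0.9$ trials. Since the curve
parameters enter linearly given $B$, the fit is a one-dimensional search
over $B$ with ordinary least squares inside — separable and robust; flat
curves are reported as $B = 0$ with a flag rather than an arbitrary value.
Curves for $P(\text{correct})$ and $P(\text{yes})$ are derived from the
fitted hit/false-alarm curves, not fitted independently.

`conditional_roc()` computes, per difficulty class, the unconditional
(hit, false-alarm) marker and the four markers conditioned on the previous
trial's outcome, with 95% binomial-normal ellipses and the equal-variance
isosensitivity index $d'$ through the unconditional point. First trials of
sessions and correction trials (on either side of the pair) are excluded.
In unblocked formats the difficulty class of a signal trial is its level;
no-signal trials have no level, so the false-alarm coordinate is shared
across classes — the same pooling the psychometric $z(F)$ uses.

## Fitting

Because every previous outcome is observed, the criterion trace is a
*deterministic* linear recursion of the observed history, and the exact
log-likelihood is $\Lambda(\Theta) = \sum_n \log P(d_n \mid c_n, \mu_n)$
(`log_likelihood()`; the criterion resets to $c_1$ at each session start,
and `shift_noise_sd` must be 0 for fitting). Both the trace and its
parameter sensitivities are first-order linear filters, so likelihood and
analytic gradient (`ll_gradient()`) are $O(N)$ with no per-trial loops. The
gradient is a forward sensitivity recursion,
$\partial c_{n+1} = (1 - a)\,\partial c_n + \partial\,[a c_1 +
b_{\text{outcome}}]$; its derivation is validated by agreement with central
finite differences to relative error below $10^{-4}$ on every fixture —
the validation, not the derivation, is the contract. Correction trials can
be included as likelihood terms or only as criterion-state updates
(`include_corrections`, default on).

`fit_sga()` implements stochastic gradient ascent with the published
annealing schedule: one ascent step per session, sessions drawn randomly
without replacement; 100 iterations at $\eta = 0.1$ with $\lambda$ frozen
at 0.05 (freezing early prevents the lapse from absorbing all misfit and
collapsing to 1), then 1000 at $\eta = 0.01$ and 1000 at $\eta = 0.001$
with $\lambda$ free. Constrained parameters ascend on transformed scales —
$\log\sigma$, $\mathrm{logit}\,a$, $\mathrm{logit}\,\lambda$ — and are
reported on natural scales. Two package-level numerical choices: each
transformed-scale step component is clipped at magnitude 1 (a safeguard
against transient blow-ups when $\sigma$ shrinks), and since the original
stopping rule was visual inspection of the trace, `polish = TRUE` appends a
deterministic BFGS ascent from the stochastic endpoint. The polish matters
for nested-model comparisons: the likelihood surface has a nearly flat
ridge trading $c_1$ against the mean shift (visible when $a$ is large, as
$c_n \approx c_1 + b_{prev}$), so the stochastic endpoint can sit a
log-unit or so off the optimum — enough to scramble comparisons between
variants that differ by less. Recovery studies read the stochastic
endpoint (`params_sga`), faithful to the published procedure; likelihood
comparisons read the polished optimum.

The no-decay variant lacks a restoring force and resists gradient ascent,
so it is fitted by brute force in ROC space (`fit_grid()`): all
combinations of six values per shift (cell centres of $[-10, 10]$) and six
of $\sigma$ (cell centres of $[3, 12]$) — $6^5 = 7776$ candidates — scored
by the mean Euclidean distance between the eight
previous-outcome-conditioned markers (two difficulties × four outcomes) of
the data and of the Markov prediction, then one refinement subdividing the
winning cell of each parameter six-fold (fine granularity ≈ 0.56 dB for
shifts, exactly 0.25 dB for $\sigma$; only the range/points convention
reproduces those printed granularities). Candidates whose kernel escapes
the solver grid score infinity — with $a = 0$ and a 5% lapse, some
probability always presses outward at the grid edge, so grid-fit kernels
tolerate 5% boundary loss rather than 1%. Ties break by enumeration order,
first encountered. Both difficulties' markers are weighted equally.

## Evaluation

`fit_quality()` reports the mean squared distance between matched empirical
and model summary points (per-position block curves; conditioned ROC
markers). `predictive_capacity()` asks a sterner question: predict each
decision by comparing $\mu_n$ against the criterion $c_n$ implied by the
subject's own history — deterministic, noise-free, ties to "no" under the
strict exceedance reading. Two variants are compared by a one-sided sign
test on the paired per-trial agreement indicators; the differences are
$\pm 1$ or 0, where signed-rank and sign tests coincide once zeros are
dropped, and the p-value is 1 when the predictions are identical.

## Known limitations

* The solver's accuracy is limited by the grid step near $a = 0$
  configurations with strong lattice structure; the shipped checks bound
  the error through the 4-state oracle, the closed-form no-shift rate, and
  grid-refinement stability rather than claiming continuum exactness.
* The grid fit's Markov predictions assume stationarity within each block
  cycle; early-session transients are ignored by both sides of the
  comparison (and empirically decay within one or two trials).
* Fitting assumes zero shift noise; traces with jitter are identifiable
  only through their stationary behaviour, which the likelihood does not
  model.
* `fit_sga()` inherits stochastic-ascent variance: different seeds give
  slightly different endpoints. The acceptance study quantifies this over
  seeds instead of hiding it.

## A short session

```{r example, eval = FALSE}
params <- reference_params("f1_blocks8")
levels <- select_levels_from_sigmoid(fixture_psychometric(params))
design <- session_design("alternating_blocks", block_length = 8,
                         easy_levels = levels$easy,
                         hard_levels = levels$hard, max_trials = 120)
sessions <- simulate_corpus(params, design, n_sessions = 54, seed = 100)

summary16 <- fit_block_exponentials(
  wrap_block_positions(do.call(rbind, sessions), L = 8))
attr(summary16, "exp_fit")$B          # shared decay constant

fit <- fit_sga(sessions, variant = "full", seed = 1, polish = TRUE)
fit$params                            # compare to reference_params()
```
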