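---
title: "Models and methods behind audaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind audaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical machinery
it implements: the psychometric model, the two adaptive procedures, the
MCMC refitting layer, the derived scores, the robust regression layer,
and the synthetic-cohort generator — together with the numerical
choices and their rationale, what the validation suites do and do not
demonstrate, and known limitations.

## The psychometric model

Every stage shares one observer model: the probability of a correct
response at stimulus value $x$ is

$$p(x) = \gamma + (1 - \gamma - \lambda)\,
  \frac{1}{1 + e^{-\beta (x - \alpha)}}$$

with midpoint $\alpha$ (stimulus units), slope $\beta > 0$ (inverse
stimulus units), guess rate $\gamma$ and lapse rate $\lambda$. Two
conventions deserve a note, because the literature is not uniform:

* **Slope parameterization.** We use the rate $\beta$ in
  $e^{-\beta(x-\alpha)}$ rather than a "spread" parameter. This makes
  the slope a positive rate, which is exactly what a gamma prior
  describes — the refitting layer's slope prior then has a direct
  interpretation.
* **Lapse convention.** The lapse lowers only the upper asymptote
  ($p \in [\gamma, 1-\lambda]$), the standard forced-choice convention:
  an inattentive observer still guesses at chance, so lapses cannot
  push performance below the guess rate.

Each task declares the axis its track runs on. Ratio-like dimensions —
percent frequency/F0 difference, interaural phase in degrees — are
tracked as $\log_{10}$ values, because discrimination thresholds for
such dimensions are approximately log-normally distributed and the
regression layer models their logs; level-like dimensions (AM depth in
dB re 100%, SNR in dB) stay linear. The per-task choice is
configuration (`task_spec()`), not hard-coded, since reasonable
implementations differ here.

The "1/4 point" threshold used in speech-reception sensitivity
analyses is defined as the stimulus at which the *underlying logistic*
equals 0.25 — approximately 25% correct only for an observer with zero
guess rate. `threshold_at_p()` exposes both this fractional-range
definition and a raw performance-level criterion.

## Adaptive procedures

**UML.** The updated maximum-likelihood procedure keeps a discrete-grid
posterior over $(\alpha, \beta, \lambda)$ (the guess rate is fixed by
the response-alternative count). After each response the posterior is
updated with the Bernoulli likelihood; all grid arithmetic is done in
log space with log-sum-exp normalization, so $10^4$-trial runs cannot
underflow. The next stimulus is one of four *sweetpoints* computed from
the posterior-mean parameter estimate: the minimizers of the asymptotic
variance proxy $p(x)(1-p(x)) / (\partial p/\partial\theta)^2$ for the
midpoint (one point), the slope (two points, one on each side of the
midpoint, where the derivative with respect to the slope vanishes), and
the lapse (whose proxy decreases monotonically with performance, so its
sweetpoint is the upper stimulus bound). We compute these by dense
lattice search (1001 points across the task bounds) rather than by
transcribing closed forms: the closed-form sweetpoints exist for this
family, but the lattice search reproduces them to lattice resolution
(verified against continuous optimization in the test suite), is
insensitive to parameterization mistakes, and costs microseconds.

Design choices:

* *Posterior mean, not mode,* as the point estimate driving sweetpoint
  placement — it moves smoothly as data accrue, whereas the mode jumps
  between grid cells.
* *Tie-breaks:* with equal posterior mass the lower-index cell wins
  implicitly through deterministic arithmetic; runs are exactly
  reproducible given a seed.
* *Grids and priors are per-task configuration* with defaults of
  61 × 41 × 5 points over task-specific ranges. One consequence worth
  stating: "accuracy to one grid cell" is only meaningful relative to
  the chosen resolution. The convergence property test runs on a
  21-point midpoint grid (2-dB cells for the AM task), chosen so that
  one cell is comparable to the posterior uncertainty attainable from
  a 160-trial track; on a finer grid the same estimates are produced
  but "one cell" becomes an arbitrary yardstick no estimator could
  meet.
* *Stimulus selection* among the four sweetpoints follows the 2-down
  1-up rule (two consecutive correct responses move one sweetpoint
  down, an error moves one up, clamped to the ends), which concentrates
  sampling near 70.7% correct; the first trial is the task's protocol
  starting value (100% AM depth, 10%/80% frequency/F0 difference, 180°
  IPD, +7/+10 dB SNR for the speech tasks).
* *Practice blocks* run with their own throwaway UML state and are
  flagged `is_practice`; they never reach the fitting layer, mirroring
  the exclusion of familiarization data from analysis.

**Transformed up-down staircase.** The audiometry-style 2-down 1-up
staircase converges on the level where $p(\text{correct}) = 0.5^{1/2}
\approx 0.707$. The threshold estimate is the mean of the
measurement-phase reversal levels. Two properties of this estimator
shaped the validation setup: it carries a transient from the starting
level that dies off over reversals, and a small dwell-asymmetry bias
that shrinks with step size. The equilibrium check therefore uses a
small final step (0.5 dB against an observer whose logistic spread is
~2.5 dB) and a long measurement phase (40 reversals after 6 initial
reversals at a 2-dB step) — the regime in which the mean-reversal
estimator is within a percentage point of its asymptotic target. Step
sizes and reversal counts are configuration, as they vary between
laboratories.

## Psychometric refitting by MCMC

After data collection each track's pooled responses (typically two
80-trial blocks) are refit with JAGS under the Bernoulli likelihood,
with trials aggregated to binomial counts per unique stimulus value
(adaptive tracks revisit few values, so this is a large constant-factor
saving). Priors: Normal on the midpoint on the task's axis, gamma on
the slope, gamma on the lapse truncated to $[0, 0.2)$. The truncation
bound is our choice, not a published value: on short tracks the lapse
and midpoint are partially confounded, and an unbounded lapse lets a
few early errors at high stimulus values masquerade as a huge lapse
with an absurd midpoint. Midpoint and slope priors are centred on
across-track preliminary maximum-likelihood fits (lapse held at 0.02
for stability); tracks with all-identical responses carry no
information about either parameter and are excluded from centring with
a warning.

Sampling uses 4 chains by default with an effective-sample-size floor
of 10,000 for the fitted parameters and a Gelman–Rubin cutoff of 1.01,
with a retry-and-double policy; fits that still fail are returned
flagged so downstream stages can exclude them. Validation suites lower
the floor (150–300) and chain count (2) for speed; this is a
configuration of the same code path, not a separate implementation.
Fitted midpoints beyond the physically presentable range (e.g. AM
depths above 100%) are reported untruncated — listeners genuinely
unable to do a task are informative, and truncation would bias the
regression layer; a sensitivity analysis with censoring can be built by
filtering the threshold table.

The lapse matters: the test suite demonstrates on simulated lapsing
observers (λ = 0.08) that refitting with a free lapse leaves the
midpoint approximately unbiased while a lapse-fixed-at-zero fit
inflates it.

## Derived scores

* **Noise exposure.** One unit of cumulative exposure is 2080 hours
  (8 h × 5 d × 52 wk) at 90 dBA; activities add on an equal-energy
  basis, $10^{(L-90)/10}$ per dBA, and the total is analysed as
  $\log_{10}$ units.
* **Consonance preference.** Dyad pleasantness ratings (−3..+3, 0.1
  steps; perfect fifth vs tritone over eight equal-temperament roots
  from D3 146.83 Hz to A3 220 Hz) are z-scored within listener across
  all conditions, averaged across roots, and differenced (fifth minus
  tritone) per dyad level. Listeners with zero rating spread have
  undefined preference and are flagged rather than scored. Practice
  ratings are excluded before z-scoring — the within-listener
  normalization should reflect only the data entering analysis.
* **Cognitive components.** The four test scores are standardized
  (n−1 denominator throughout the package) and the correlation matrix
  eigendecomposed; the first two components serve as regression
  covariates. Loadings are oriented so each component's
  largest-magnitude loading is positive — a pure reporting convention,
  with the usual caveat that component orientation is sign-unstable in
  small samples when two loadings have comparable magnitude.
* **Musical practice** is analysed as cube-root years (right-skew);
  **SSQ12** as the mean of its 12 items.

## Robust mixed-effects regression

The inferential core. For each model family the outcome (log
transformed for ratio-scale thresholds, then standardized) is modelled
as

$$y_i \sim t_\nu\!\left(\mathbf{x}_i^\top \mathbf{b} + u_{s(i)},\,
\sigma\right)$$

with per-subject random intercepts $u_s \sim N(0, \sigma_u^2)$.
Categorical condition factors are coded with *unweighted effect
coding* (each non-reference level an indicator column, the reference
level −1 everywhere), so the intercept is the unweighted grand mean
and coefficients are level deviations. Continuous covariates are
standardized *before* interaction products are formed (the Friedrich
convention — products of standardized parents, never standardized
products; the two differ on skewed covariates, which the test suite
checks explicitly). Stored means and sds allow coefficients to be
rescaled to natural units: the contrast layer reports covariate slopes
per 10 raw units (per decade of age, per 10 dB of audiometric shift)
and exponentiates log-outcome contrasts to factor changes.

Priors follow an estimation-first philosophy: coefficients of
analytical interest (covariate main effects and covariate × condition
interactions) get the shrinkage prior $t(1, 0, 0.1)$ on the
standardized scale — most mass near zero, reflecting the expectation
of small effects, but Cauchy tails that let strong data escape the
shrinkage; nuisance structure (intercept, condition main effects,
factor × factor terms) gets a very broad prior (Normal with sd 100,
realized as a t with 1000 df). Unstated hyperparameters are our
choices: residual normality $\nu = 1 + \text{Exponential}(29)$ (prior
mean 30, allowing both near-Normal and heavy-tailed regimes), residual
scale uniform on (0, 10) in sd units, random-intercept sd half-t(3, 1).
There is no multiplicity correction beyond the 99%-CI convention — the
model estimates, it does not test.

**Sampling.** Both the Student-t residuals and the t priors are
expressed as scale mixtures of normals, and JAGS's `glm` module is
loaded so coefficient and random-effect updates are conjugate block
updates instead of univariate slice sweeps — an order-of-magnitude
speedup at identical posteriors (the marginal model is unchanged by the
mixture representation). Convergence gates (ESS floor, Gelman–Rubin)
apply to the coefficients, the "main parameters of interest";
diagnostics for $\nu$, $\sigma$, $\sigma_u$ are reported but do not
gate, since $\nu$ mixes slowly without affecting coefficient
inference. Initial values come from a least-squares fit, jittered
across chains. Rank-deficient designs fail fast, naming the collinear
columns.

Nine model families mirror the test battery: AM detection (level ×
modulation-rate factors), frequency discrimination (level × frequency,
with the audiometric covariate matched per row to the stimulus
frequency), F0 discrimination, envelope and fine-structure IPD
detection, competing-sentence reception (level × masker offset, plus
offset × cognitive/musical interactions), digit-triplet reception,
interval ratings (level × interval, plus interval × cognitive/musical
interactions), and the SSQ12 questionnaire (one row per subject, no
random effects).

Two structural checks anchor the implementation: in the Normal limit
(residuals Normal, broad priors) posterior medians match `lme4`
maximum-likelihood estimates on a 102-subject design to within MC
error; and derived per-condition slopes are invariant to the choice of
effect-coding reference level.

## The synthetic cohort

The generator is first-class, tested code — it defines the study
conditions under which everything else is validated.

* **Predictors** come from a Gaussian copula over nine latent
  variables (age, four audiometric summaries, log noise exposure,
  musical practice, two cognitive components) with pairwise targets
  set to the published correlation structure of the emulated study
  where printed (age × 2-kHz threshold 0.44, age × high-frequency
  average 0.84, age × log exposure 0.02, ...); the few audiometric
  cross-frequency pairs that are not printed are package defaults
  consistent with the printed ones. The target matrix must be positive
  definite or generation fails before sampling. Marginals: ages
  uniform within three bands (18.8–39, 40–59, 60–73.6), allocated by
  latent rank so bands are exactly balanced at n/3 each with a 27:7
  female:male ratio per band; audiometric thresholds
  truncated-Normal, respecting the selection caps (≤20 dB HL in the
  low-frequency region); log₁₀ exposure Normal(0.3, 0.75), spanning
  more than three decades at n = 102; practice years gamma
  (right-skewed). Monotone marginal transforms preserve the copula's
  rank structure; Pearson correlations on transformed scales are
  attenuated by a few hundredths relative to the latent targets,
  which the self-check (`cohort_selfcheck()`) reports.
* **Cognitive scores** are built from the two latent components with
  loadings chosen so the observed correlation-matrix PCA recovers
  ~50% and ~24% variance on the first two components, with the second
  a reading-span vs forward-span contrast; scores are rounded to
  integers on realistic test scales. The cohort's `cog1`/`cog2`
  columns are computed from the generated scores by the package's own
  PCA, exactly as the analysis would.
* **Thresholds** are the generative counterpart of the regression
  model: linear predictor (condition offsets + covariate effects,
  with age referenced to 20 years) plus a subject intercept plus a
  Student-t residual, on the task's tracked axis. Effect-size
  defaults use reported posterior medians where available (3.7 dB
  level offset and 0.7 dB/decade high-minus-low differential for
  50-Hz AM detection; audiometric effects on speech reception) and
  plausible magnitudes elsewhere; all are overridable through
  `cohort_truth()`.
* **Trial-level data** are produced by running the real UML engine
  against each subject's generating psychometric function (midpoint
  from the threshold table, slope and lapse from the task truth), so
  the simulated logs have exactly the structure the fitting layer
  expects — including flagged practice blocks, protocol starting
  SNRs, and digit triplets drawn from 1–9 excluding 7 without
  repeats.
* **Ratings** are generated by back-solving the raw rating separation
  from the target preference and the rating noise, so that the
  z-scored preference recovers the generating value in expectation
  (the test suite checks the round trip); ratings are snapped to the
  −3..+3, 0.1-step scale.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: within-subject threshold correlations across
tasks beyond those induced by shared predictors and the subject
intercept; session, order and learning effects; non-stationary lapsing;
floor/ceiling response strategies in the rating task; and any
measurement model for the audiogram itself (audiometric covariates are
generated, not measured by the simulated staircase). Conclusions about
real cohorts still require real cohorts; the generator's job is to make
the machinery falsifiable.

## Validation strategy and problem sizes

The suite validates statistical guarantees, not just code paths:

* *Exactness:* sequential UML updating equals a brute-force batch
  posterior to 10⁻¹² per cell (100 random histories).
* *Calibration:* psychometric refits are checked by drawing 200
  simulated listeners from the fitting priors, running 160-trial UML
  tracks, and verifying 99% midpoint-interval coverage; the regression
  layer is checked by full prior-predictive calibration on one family
  (the digit-triplet design, 102 subjects × 2 levels, 200 replicates)
  — every generating parameter, including residual scale, normality
  and random-intercept sd, is drawn from the model's own priors, which
  makes nominal coverage exact in expectation and any systematic
  deviation a sampler or implementation defect. Chains are shortened
  for these suites (2 chains, reduced ESS floors).
* *Robustness and shrinkage:* under 5% gross outliers the Student-t
  model beats the Normal model on coefficient RMSE (100 paired
  replicates); under a true-zero coefficient the shrinkage prior
  yields narrower 99% intervals than the broad prior in ≥90% of 100
  replicates.
* *Equilibria:* 1000 staircase tracks (~1.6 × 10⁵ trials) put the
  tracked performance level within a percentage point of 70.7%; UML
  trial placement equilibrates near the same level.

These sizes were chosen so the whole suite runs in minutes on one CPU
while keeping Monte-Carlo error well inside each assertion's margin.

## Known limitations

* Sweetpoints are recomputed each trial by lattice search; for
  real-time use at kilohertz trial rates one would cache or use the
  closed forms. Irrelevant at simulation scale.
* The regression layer fits intercept-only random effects; random
  condition slopes are not implemented (the emulated design, with two
  tracks per condition collapsed to one threshold, cannot identify
  them anyway).
* The lapse upper bound (0.2) and the residual-normality hyperprior
  are defaults with stated rationale, not published values; analyses
  sensitive to them should vary them through `pf_prior_spec()` /
  `prior_config()`.
* JAGS's `glm` block samplers occasionally mix slowly when the
  residual scale sits near its prior bound; the retry-and-double
  policy plus the flagged-fit pathway are the guardrails.
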