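---
title: "Methods: multiverse analysis of age effects on decision-making under uncertainty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiverse analysis of age effects on decision-making under uncertainty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agespec)
```

# The analysis problem

Age differences in decision-making under uncertainty can be
operationalized in many defensible ways: different tasks (risky inflation
of balloons vs. inter-temporal trade-offs), different behavioral indices,
different neural contrasts, different volumes of interest, and different
covariate adjustments.  A specification-curve (multiverse) analysis makes
this garden of forking paths explicit by fitting *every* combination and
summarizing the whole curve of estimates, instead of reporting one
hand-picked model.

`agespec` implements that machinery end to end on synthetic data: a cohort
generator with known ground truth, task simulators with scoring, the
exhaustive regression engine, a permutation-based global test, and a
correlation-network summary.  Because the generator's truth is known, every
statistical property of the pipeline (estimator equivalence, type-I
calibration, power, parameter recovery) is testable.

# The specification space

A specification always contains age as the predictor, one of 24 outcomes,
and one subset of five covariates, giving $24 \times 2^5 = 768$ models.
Each is fitted by OLS:

$$ z(y) \;=\; \beta\, z(\mathrm{age}) \;+\; \sum_{c \in C} \gamma_c\, x_c \;+\; \varepsilon $$

**Standardization.** Outcome and age are z-scored on the rows complete for
the model's variables; continuous covariates are z-scored too
(`standardize_covariates = TRUE`, switchable, since conventions differ
across published multiverse analyses); binary gender enters as coded 0/1 so
its coefficient stays interpretable as a group contrast.  With no
covariates, $\beta$ then equals the Pearson correlation exactly — a
property the tests assert to $10^{-10}$.

**Missing data.** Per-specification complete-case analysis.  Income is the
one covariate with missingness (7 of 175 by default), so exactly the
income-containing half of the space loses rows (168 vs. 175).

**Inference.** Two-sided t-test on $\beta$ with residual
degrees of freedom $n - k - 2$ ($k$ covariates, intercept, age).  A
specification is significant at $p \le \alpha$ with $\alpha = 0.05$;
significant fits split into positive and negative by the sign of $\beta$.
The curve summary reports the three counts (with percentages rounded to
two decimals) and the median $\beta$ across all specifications.

**Numerics.** Fits use a partitioned (Frisch–Waugh) QR solver: the
covariate block is projected out of outcome and age once, and the age
coefficient, its standard error and the fit statistics are recovered from
the residualized vectors.  This is algebraically identical to the full
regression (asserted against an independent normal-equations solver to
$10^{-8}$ in the tests) and makes the permutation loop cheap, because the
outcome-side projection can be reused across resamples.  Rank-deficient
designs (constant covariate, age collinear with covariates) raise a
singular-fit error rather than silently dropping terms.  Curve ordering
ties are broken by canonical specification order so output is
deterministic.

# The global permutation test

Significance of the curve as a whole is assessed against a null in which
age is unrelated to every outcome while everything else (outcome
correlations, missingness) is preserved: the age column is replaced by a
with-replacement draw from itself, the identical 768-model analysis is run,
and the number of significant specifications is recorded; over
`n_resamples = 500` such datasets, the global p-value is the fraction
yielding a *strictly larger* count than observed.

Two conventions deserve comment, both switchable:

- **Resampling mode.** With-replacement resampling is the default;
  a classical without-replacement permutation (`replace = FALSE`) is also
  provided.  The two behave near-identically here because only the
  age-outcome link is broken either way.
- **Exceedance convention.** The strict "greater than" count with a plain
  ratio $p = m/N$ is the default.  It is worth knowing that this
  convention has no calibration guarantee: a strict-ratio p-value can be
  exactly 0, and when the null distribution of significant counts is
  heavily tied — which happens in *small* specification spaces, where the
  ~$2^k$ specifications per outcome move together and counts jump in
  blocks — rejecting at $p \le \alpha$ can exceed $\alpha$ substantially.
  The tie-robust convention `exceedance = "weak"` (count $\ge$ observed),
  optionally with the $(m+1)/(N+1)$ correction (`add_one = TRUE`), is the
  one with a validity guarantee, and it is what the package's calibration
  tests evaluate.  For a full-width curve (768 specifications, counts
  nearly continuous) the two conventions give practically identical
  p-values; e.g. 7 exceedances of 500 is $p = 0.014$ either way.

Per-resample seeds are derived from the master seed up front, so results
are independent of execution order.

**Calibration experiment sizes.** The test suite calibrates the global test
on a scaled design — 6 outcomes, 3 covariates, 100 resamples, $n = 175$,
200 null replicates for the type-I rate and 60 replicates for power with a
0.4 standardized effect on half the outcomes — sizes chosen to give
informative Monte-Carlo error (binomial SE ≈ 1.5 percentage points on the
type-I rate) at a few minutes of compute.

# The synthetic cohort

The generator emulates the study's variable structure with choices made
once and documented here:

- **Age**: uniform on [16.15, 81.38] years.  Only the range and moments of
  the real sample are known; uniform maximizes information per participant
  across the lifespan and keeps $z(\mathrm{age})$ well conditioned.
- **Gender**: Bernoulli(0.5314), coded 1 = female.
- **Education**: ordinal 1–8 with a bell-shaped probability profile,
  treated as numeric in regressions (OLS needs numeric covariates and no
  coding convention is canonical).
- **Income**: log-normal (median 5000/month, log-sd 0.5) rounded to 50,
  with exactly `n_income_missing = 7` values masked completely at random
  *after* outcome generation — missingness carries no signal.
- **Numeracy**: Binomial(8, 0.6); **working memory**: Binomial(75, 0.65).
  Binomial marginals respect the hard score ranges [0, 8] and [0, 75] by
  construction (no clipping step that would distort tails).
- **Outcomes**: each of the 24 outcomes is a linear combination of the
  z-scored predictors with configurable standardized slopes plus a
  residual.  Residuals are equicorrelated within *contrast blocks* (the
  four VOIs of each neural contrast; behavioral indices are singleton
  blocks) at `within_block_correlation = 0.6`, reflecting the empirical
  pattern that VOI markers correlate strongly within contrast and little
  across.  Residual scale is $\sqrt{1 - \sum \beta^2}$ (floored at 0.05,
  times `noise_sd`), so outcomes have approximately unit variance and an
  injected slope of 0.4 is recovered as a standardized coefficient of 0.4
  — the parameter-recovery tests check this within $3/\sqrt{n}$ at
  $n = 2000$.
- **Defaults**: all ground-truth effects are 0, matching a predominantly
  null world; effects are injected explicitly where a test or example
  needs them.

What the generator does **not** emulate: non-uniform age distributions,
informative income missingness, covariate intercorrelations (age-cognition
decline, age-income gradients) unless configured via `covariate_effects`,
item-level task noise in the directly generated behavioral columns, and
any voxel-level structure behind the neural contrast values (they are
unitless standardized magnitudes).  Passing tests therefore certify the
*analysis machinery* — estimator correctness, calibration, bookkeeping —
not distributional realism of any particular empirical dataset.

# The BART simulator

Three balloon types: linear reward, exponential reward, control (never
paid).  Explosion points are drawn uniformly on the integers 1..16
("maximum capacity 16 pumps").  **Explosion semantics**: the pump whose
count equals the explosion point triggers the explosion; a cash-out
strictly before it succeeds.  Intending 16 pumps therefore always ends in
an explosion — the last survivable strategy is cashing out at 15.  Under
this convention a fixed pump target $t$ explodes with probability exactly
$t/16$, which the tests verify against binomial error.

Rewards: the linear balloon pays 0.05 CHF per successful pump; the
exponential balloon pays $b\,g^{j-1}$ for the $j$-th pump with defaults
$b = 0.01$, $g = 1.6$.  The defaults are a configurable stand-in
satisfying the design's defining property: the cumulative exponential
payoff at capacity exceeds the linear one (30.73 vs. 0.80 CHF at 16
pumps), so exponential balloons reward exploration in the long run while
paying less per early pump.  Cumulative exponential reward is convex in
pump count (second differences $\ge 0$), tested against a brute-force sum.

Session scoring produces the standard indices; the primary risk index is
the *adjusted* average number of pumps, the mean over cash-out trials
only, which is undefined (NA) for a session with no cash-out and invariant
to explosion trials by construction.  Trial counts per session default to
15 reward trials per type plus 10 control trials; money is kept at full
precision internally and rounded only for reporting.  Inter-trial timing
is not simulated (irrelevant to every index).

# The delay discounting task

The design crosses five delay pairings — (0, 2), (0, 4), (2, 4), (2, 6),
(4, 6) weeks — with eight percentage differences (1, 3, 5, 10, 15, 25, 35,
50 percent), two trials per cell: 80 trials.  Sooner amounts are drawn
from a normal distribution with mean 22.5 and SD 8 truncated to [5, 40]
("a normal distribution between five and 40" is ambiguous; a uniform
option is provided), rounded to coin resolution 0.05; the later amount
applies the cell's percentage and is rounded to 0.01, so the percentage
rule holds to ±0.005.  The two trials per cell use independent amount
draws.  All participants see the same design in randomized order.

For the neural contrasts the (4, 6) pairing is dropped to balance trial
counts, leaving 32 trials with a today option (*immediacy* set) and 32
trials whose sooner option is in two weeks (*delay* set).

The synthetic chooser is a hyperbolic discounter with softmax noise:
$SV = A/(1 + k\,d)$ and
$P(\text{sooner}) = \mathrm{logit}^{-1}((SV_s - SV_l)/\tau)$.  At
indifference the probability is exactly one half; at $\tau = 0$ the
chooser is deterministic.  Scoring is model-free — no $k$ is fitted — and
the primary index is the proportion of immediate choices out of the 32
today-option trials.

# The correlation network

Pearson correlations over all study variables use pairwise-complete
observations with per-pair n recorded (income pairs use 168 rows, others
175, at the defaults).  The edge list keeps unordered pairs with
$|r| \ge 0.15$, threshold inclusive, with the sign retained for
solid/dashed rendering.  Undefined correlations (constant column) are
flagged and never become edges.  `plot_network()` draws a generic
force-directed layout for orientation only; node placement is cosmetic and
not a calibrated reproduction of any published figure.

# The pipeline

`run_pipeline()` executes cohort → (optional) task simulation → curve →
permutation → network from one `run_config()`, writing every artifact
(CSV/JSON) plus a manifest; identical configuration and seed give
byte-identical summaries.  Behavioral outcome columns can come either from
the parametric generator (default — keeps statistical calibration exact)
or from task simulation (`tasks$simulate = TRUE`: agent traits → simulated
sessions → scored indices), which separates statistical properties from
task mechanics while the tests pin their cross-consistency.

# Known limitations

- Calibration statements are Monte-Carlo estimates at the stated sizes,
  not proofs; the strict-exceedance default should not be used for formal
  inference in small specification spaces (see above).
- The generator's unit-variance construction makes slopes and correlations
  coincide; real data with heteroskedastic outcomes would decouple them.
- `analysis_n()` and the per-spec row accounting assume income is the only
  incomplete variable, as in the emulated design; other missingness
  patterns are handled correctly by the complete-case fitter but not by
  the bookkeeping helper's income shortcut.
- The exponential reward parametrization is a documented stand-in; any
  schedule with growing per-pump payoffs can be supplied via
  `reward_exponential()`.
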