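---
title: "Methods: GA covariate search with an internal FO estimator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GA covariate search with an internal FO estimator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gacovsel)
```

This vignette documents the model, the search procedure, the numerical
choices and the design decisions behind `gacovsel`, at the level of detail
a maintainer or reviewer needs to judge what the package does and does not
establish.

## The population model

The structural model is a one-compartment disposition with linear
elimination after a single intravenous bolus,

$$f(t) = \frac{D}{V}\,e^{-(CL/V)\,t},$$

parameterized by clearance $CL$ and volume $V$. Individual parameters are

$$P_i = \theta_P \cdot \prod_k m_k(x_{ik}) \cdot e^{\eta_{P,i}},
\qquad \eta_i \sim \mathcal N(0, \Omega),$$

with $\Omega$ the full $2\times2$ covariance of the log-normal random
effects and $m_k$ the covariate multipliers of the candidate model.
Observations carry combined residual error,
$y_{ij} = f_{ij}(1+\varepsilon^{prop}_{ij}) + \varepsilon^{add}_{ij}$.

### Covariate relationship library

Continuous covariates are centered at a reference $x^{ref}$ (the dataset
median unless overridden in the configuration; this follows the stepwise
covariate modeling conventions popularized by PsN, which is also where the
four shapes come from):

| form | multiplier | coefficients |
|---|---|---|
| linear | $1+\theta(x-x^{ref})$ | 1 |
| exponential | $e^{\theta(x-x^{ref})}$ | 1 |
| power | $(x/x^{ref})^{\theta}$ | 1 |
| piece-wise linear | $1+\theta_1(x-x^{ref})^- + \theta_2(x-x^{ref})^+$ | 2 |

Categorical covariates enter linearly, $1+\theta_c$ for each non-reference
category $c$ (reference = most common category). Both branches of the
piece-wise form equal 1 at the breakpoint, so the multiplier is continuous.
Multipliers on one parameter combine multiplicatively; a non-positive
product (possible for linear terms) is flagged and treated as inadmissible
by the estimator.

## Encoding and fitness

Each parameter–covariate pair is a gene of $\lceil\log_2 N\rceil$ bits,
where $N$ counts the pair's options *including absence*. This convention —
absence is one of the $N$ options — is adopted because it is the only
reading under which a categorical pair (absent/linear) needs exactly one
bit and a continuous pair testing all four shapes needs three; the
alternative (absence on top of $N$ tested shapes) is deliberately not
supported, to keep one canonical genotype map. Binary value 0 means "not
included"; value $k\ge1$ selects the $k$-th allowed relationship in the
configured order. Gene order is frozen at configuration time (declared
parameter order, declared covariate order within parameter) and can be
archived as JSON (`space_to_json()`), because the genotype–phenotype map is
meaningless without it.

Fitness of candidate $c$:

$$fit_c = -\bigl(obj_c + 3.84\,(N_c + ic_c)\bigr),$$

- $obj_c$: the backend's objective function value (−2 log-likelihood
  scale);
- $N_c$: number of *covariate* coefficients. Structural $\theta$s and
  variance parameters are excluded: they are common to every candidate and
  with 3.84 $= \chi^2_{0.05,1}$ the penalty then reads "each extra
  coefficient must buy one significant likelihood-ratio test";
- $ic_c = \tfrac12\sum_k\sum_{i\ne j}|\rho_{ij}|$ over continuous
  covariates included on the same parameter. The absolute value is a
  deliberate choice: summing signed correlations would *reward* negatively
  correlated pairs, the opposite of the penalty's purpose (discouraging
  redundant, collinear covariates on one parameter). Correlations are
  Pearson, computed once per dataset on the per-subject baseline covariate
  table.

Failed, crashed or timed-out evaluations receive a sentinel fitness equal
to the worst converged fitness observed so far in the run minus 1000 — far
below any model that estimates, but finite, so selection still ranks a
generation containing failures.

## The search

Per generation: tournament selection (two members sampled with
replacement; the fitter wins with probability $p_s$), single-point
crossover with probability $p_c$ (cut point uniform on the interior
positions $1..l_{chr}-1$, so a firing crossover always recombines),
independent per-bit mutation with probability $p_m$, then gene repair, then
elitism. Defaults ($p_s=0.75$, $p_c=0.7$, $p_m=0.025$, 10% elitism,
$n_{chr}=30$, 50 generations) are the configuration used throughout the
evaluation study.

Decisions the algorithm statement leaves open, fixed here for determinism:

- **Repair** replaces a non-coding gene by the modal value of that gene
  position among the previous generation's elite (the top `elite_frac` by
  fitness — the only "best subset" the algorithm already defines), ties
  broken toward the lowest binary value. At initialization, when no elite
  exists, non-coding genes are resampled uniformly over coding values; in
  fact the initializer samples genes uniformly over coding values in the
  first place, so phenotypes are uniform at generation 0 and repair at
  init is a no-op.
- **Operator order**: crossover, then mutation, then repair, then elitism.
- **Elitism** copies the top `round(elite_frac * n_chr)` chromosomes of
  the evaluated previous generation into the first offspring slots
  (offspring are unevaluated when elites are inserted, so no slot is
  distinguishable; a fixed slot choice keeps runs reproducible). Elites
  remain eligible as parents in the same generation.
- The returned solution is the **best-ever** evaluated model over the whole
  run, not the final generation's best.

### Clustered initialization

A small population explores a $2^{44}$-point space (the full evaluation
study) very unevenly if drawn at random. The initializer draws
`oversample_factor * n_chr` (default 20×) random coding chromosomes,
deduplicates them, computes pairwise Jaccard distances
$Jd=(b+c)/(a+b+c)$ (both-zero vectors defined as distance 0), clusters
them agglomeratively and cuts at $n_{chr}$ clusters, then draws one member
per cluster. The linkage is **average (UPGMA)** — unspecified by the
algorithm statement; average linkage is the standard choice for binary
heterogeneity and resists the chaining that single linkage shows on
Hamming-like distances. The package's test suite verifies, over 20 paired
seeds, that the clustered start has a larger mean pairwise Jaccard distance
than a random start of the same size.

### Cache and timeout

Evaluated chromosomes are stored in a lookup table keyed by bitstring;
duplicates (elites, re-discovered models) cost nothing. From generation 2
onward each evaluation receives a runtime budget equal to the 95th
percentile of the runtimes of all previously *converged* models, updated
every generation; exceeding it aborts the fit with the sentinel fitness.
For the internal FO backend "runtime" is the **objective-evaluation
count**, not wall-clock time — the policy is then fully deterministic and
machine-independent, while honoring the same percentile update rule. The
oracle backend reports runtime 0, so the timeout never fires on it.
Evaluation results are independent of evaluation order and of the number
of workers because each fit's random restarts are seeded from the run seed
plus a hash of the chromosome's bitstring.

Interactive "continue the run?" workflows are replaced by resumability:
`run_ga(..., out_dir =)` flushes the per-generation statistics, the lookup
table and a state file after every generation, and `run_ga_resume()`
extends a finished run by further generations from that state.

## The FO estimator

The internal backend maximizes the marginal likelihood of the model
linearized around $\eta=0$ (the classical first-order approximation):
per subject, $y_i \sim \mathcal N\!\bigl(f_i,\; G_i\Omega G_i^\top +
R_i\bigr)$ with $G_i = \partial f_i/\partial\eta|_0$ (available in closed
form for this structural model) and
$R_i = \mathrm{diag}(\sigma_{add}^2 + \sigma_{prop}^2 f_{ij}^2)$. The
determinant and quadratic form are evaluated through the Woodbury identity
on the $2\times2$ capacitance matrix, which is valid for any positive
semi-definite $\Omega$ (including $\Omega=0$, where the objective reduces
to weighted least squares) and makes the objective loop-free across
subjects. The test suite checks this closed form against brute-force
adaptive Gauss–Hermite integration of the same linearized density to
$10^{-6}$.

Optimization is `nlminb` over unconstrained transforms: log structural
parameters, raw covariate coefficients, log-Cholesky $\Omega$, log residual
SDs. Starting values: structural parameters from a naive-pooled log-linear
regression, covariate coefficients at 0, $\Omega$ at $0.1\,I$, plus seeded
jittered restarts (3 by default). Inside a GA run the backend instead uses
a single start warm-started at the base model's structural and variance
estimates and a relative tolerance of $10^{-6}$: candidate ranking needs
objective differences of order 1 (the 3.84 penalty unit), so the looser
tolerance costs nothing in selection accuracy and cuts the evaluation count
several-fold. "Converged" for this backend means the optimizer returned a
finite objective within its budget; FO has no covariance step here.

Two properties of FO matter for interpreting results. First, FO is a
linearization: with the study's inter-individual variances (0.2–0.25) its
objective differs from an exact marginal likelihood, and part of the
linearization error is absorbed into inflated residual-error estimates.
Fixed effects — in particular the covariate coefficients — are recovered
essentially unbiased at the study's designs (verified by simulation in the
test suite), but $\sigma$ estimates should not be read as estimates of the
generating noise. Second, because the linearization error is systematic,
richly parameterized covariate models can genuinely reduce the FO objective
beyond what the generating model implies; the search on FO therefore tends
to select more covariate terms than a NONMEM-based workflow would. The GA
surface, cache, timeout and fitness are independent of the backend, which
is exactly why the backend is pluggable (`fo_backend()`,
`oracle_backend()`, or an external NONMEM workflow via `write_nmtran()`).

## The simulated evaluation study

`simulate_pk()` reproduces the design on which the search is evaluated:
$n$ subjects, single iv bolus (default 100 amount units), sampling at
0.25, 0.5, 1, 2, 3, 6, 10, 24 h (rich), or the 5-point (0.25, 0.5, 2, 6,
24 h) / 3-point (0.25, 2, 6 h) subsets. Covariates: SEX fair Bernoulli;
AGE normal(45, 12); BMI, CR, HT log-normal with medians 25 kg/m²,
0.9 mg/dL and 1.75/1.62 m (male/female, HT location sex-specific); WT, BSA
and CRCL derived exactly as $WT=BMI\cdot HT^2$,
$BSA=\sqrt{HT\cdot100\cdot WT/3600}$ and the creatinine-clearance formula.
The distribution parameters are the package's own choice of a plausible
adult population (the original study's tabulated values are not public);
all are exposed via `covariate_sim_params()` and none is treated as a
reference value by any test.

The generating ("true") covariate model is CRCL and BMI exponential on CL,
BSA exponential and SEX linear on V. Generating values: $CL=0.608$,
$V=2.28$, $\theta_{BMI}=0.224$, $\theta_{BSA}=0.0676$,
$\theta_{SEX}=-0.347$, $\omega^2_{CL}=0.2$, $\omega^2_{V}=0.25$,
correlation 0.0497, $\sigma_{add}=0.106$,
$\sigma_{prop}=\sqrt{0.00036}\approx0.019$.

Two defaults required a judgment call:

- **CRCL formula.** The package defaults to the Cockcroft–Gault form
  $(140-AGE)\cdot WT/(72\cdot CR)$. A variant that multiplies by AGE
  instead of subtracting it (`crcl_formula = "as_printed"`) is provided
  for completeness, but it yields clearances around 6,500 mL/min — an
  order of magnitude beyond physiology — for which no exponential
  coefficient produces a sane model, so it is not the default.
- **CRCL coefficient.** On the Cockcroft–Gault scale (SD ≈ 25 mL/min) a
  coefficient of order 0.2–0.3 per mL/min would make $e^{\theta(x-x^{ref})}$
  span several orders of magnitude across subjects. The default is
  $\theta_{CRCL}=0.01$ per mL/min, giving a per-SD effect (~0.25)
  comparable to the other generating effects. Like every generating value
  it is a `sim_true_values()` default, overridable and never asserted
  against.

What the generator does **not** emulate: covariate measurement error or
time-varying covariates, dropout/BLQ handling (negative simulated
concentrations are retained and counted), multi-compartment kinetics,
infusions or multiple dosing, and real-data quirks such as irregular
sampling. Passing tests therefore demonstrate correctness of the search
machinery and the estimator under the stated generative model, not
performance on arbitrary clinical datasets.

## Stepwise comparator

`run_scm()` implements generic forward-inclusion (α = 0.05) /
backward-elimination (α = 0.01) over the same search space, with
chi-square critical values at the candidate's actual degrees of freedom
(1 for single-coefficient forms, 2 for piece-wise linear, $k-1$ for a
$k$-category covariate). `relationship_order` controls the order in which
shapes are tested and breaks ties (first in order wins) — permuting it can
change the selected model when candidates are correlated or tied, which is
the known order-dependence of stepwise searches that motivates a global
method. This is a faithful generic SCM, not a bit-for-bit PsN replica
(no gradual relations or state files).

## Problem sizes and numerical choices in the test suite

The suite verifies the search end-to-end at sizes chosen to keep a full
run in minutes on one core: exhaustive enumeration + GA on the 14-bit
worked-example space (2,500 phenotypes); operator statistics over $10^5$
Monte-Carlo draws (3σ bands); initialization diversity over 20 paired
seeds; estimator recovery over 20 simulated replicates of the rich design
at $n=50$ subjects (3 Monte-Carlo-SE bands on the covariate coefficients);
and five end-to-end GA runs (44-bit space, $n_{chr}=16$, 15 generations,
$n=50$) checking that the strong generating effects (BMI on CL, SEX on V)
are selected in the majority of replicates and that the selected model
never has a worse AIC than the covariate-free base model. Ties, degenerate
inputs (constant covariates, all-zero chromosomes, zero $\Omega$) and the
cache/timeout bookkeeping all have dedicated unit tests.

## Known limitations

- The internal estimator is FO only (no FOCE/SAEM) and supports the
  one-compartment iv-bolus model; other structural models require an
  external backend via the NM-TRAN writer.
- AIC as reported counts fixed effects only (structural + covariate
  coefficients), matching how the evaluation study's information criteria
  are computed; variance parameters are not counted, and the count used is
  always exposed (`n_theta`).
- The correlation penalty uses baseline covariates and Pearson correlation;
  monotone-but-nonlinear redundancy is only partially captured.
- Parallel evaluation uses forked workers (`parallel::mclapply`) and is
  therefore serial on Windows.
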