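---
title: "Modelling the age of the world's oldest person"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the age of the world's oldest person}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recordage)
```

## The model

The age of the world's oldest living person, written $Y_t$, is a Markov
process: it grows linearly at slope one while the record holder survives,
and drops to the age of the next-oldest living person at the moment the
record holder dies.  `recordage` models the population behind this process
with two ingredients.

**Births.** Individuals enter the population according to an inhomogeneous
Poisson process.  With entry age $E$ (0, 30 or 60 years), the rate at which
people reach age $E$ at calendar time $t$ is modelled as exponential,
$\lambda_E(t) = C_E e^{\kappa_E t}$, with $t$ in decimal calendar years.
The packaged constants (`default_birth_intensity()`) come from log-linear
regressions of United Nations annual cohort counts since 1950 and are
treated as fixed; `fit_exponential_intensity()` exists for users with their
own cohort series.

**Lifespans.** Remaining lifetimes past the entry age follow a
gamma-Gompertz law: a Gompertz baseline hazard $a e^{bx}$ with
multiplicative gamma frailty of variance $\gamma$, giving survival
$$1 - F(x) = \Bigl(1 + \tfrac{a\gamma}{b}(e^{bx}-1)\Bigr)^{-1/\gamma},$$
whose population hazard plateaus at $b/\gamma$ at extreme ages — the
feature that matters for supercentenarian records.  A Makeham term $c$
(age-independent extrinsic mortality) is carried through all distribution
code but fixed at zero in the fitted model: at ages above 105 it is
unidentifiable from titleholder data, and freeing it (or the rate of aging
$b$) drives the likelihood optimizer into degenerate laws (see below).
The level parameter declines by entry cohort,
$a_E(t) = K_E e^{-\alpha_E (t - 2000)}$, anchored at the year 2000 so the
constants stay on a readable scale.

**The record-age distribution.** Thinning the entry process by survival
gives the rate of people aged $u$ alive at time $t$, and with it the exact
distribution of $Y_t$:
$$P(Y_t < x) = \exp\Bigl(-\int_x^{\infty}
  \lambda_E(t-u+E)\,\bigl(1-F^E_{t-u+E}(u-E)\bigr)\,du\Bigr),$$
the probability that nobody older than $x$ is alive.  Everything the
package reports — densities, exceedance probabilities, the transition
kernel of $Y_t$, titleholder likelihoods — reduces to this exponent
integral.  The integrand's level parameter varies with the integration
variable (each age belongs to a different cohort), so the exponent is
evaluated by adaptive quadrature; no closed form applies.

**The homogeneous model.** With a constant birth rate $\lambda$ and a
time-constant law, $Y_t$ is stationary and everything is explicit in the
integrated survival $G(x) = \int_x^\infty (1-F)$: the record-age density
$h(x) = e^{-\lambda G(x)}\lambda(1-F(x))$ with an atom $m = e^{-\lambda G(0)}$
at zero, the successor (jump) law, the density of ages at which record
holders die (the peaks chain), and the reign-length density

$$r(w) = \frac{\int_0^\infty h(y)\,f(y+w)\,dy
  + m\,(f * \mathrm{Exp}(\lambda))(w)}
  {\int_0^\infty h(y)(1-F(y))\,dy + m}.$$

The $m$-weighted term — the density of a lifespan convolved with an
exponential waiting time — covers reigns that start from an empty
population; reigns are measured from the previous holder's death, so
vacancy spells are charged to the next holder.

## The survival integral and the hypergeometric function

$G(x)$ has a closed form for the gamma-Gompertz-Makeham family,
$$\int_x^\infty (1-F(u))\,du = \Bigl(\tfrac{b}{a\gamma}\Bigr)^{1/\gamma}
  \frac{e^{-(c+b/\gamma)x}}{b/\gamma+c}\;
  {}_2F_1\!\Bigl(\tfrac1\gamma, \tfrac1\gamma+\tfrac cb;
  1+\tfrac1\gamma+\tfrac cb; \tfrac{a\gamma-b}{a\gamma}e^{-bx}\Bigr),$$
which `survival_integral()` uses by default; all factors are combined in
log space because realistic parameters produce prefactors like
$(b/a\gamma)^{1/\gamma} \sim e^{120}$.  No installed R package provides the
Gauss hypergeometric function, so `hyp2f1()` is implemented here with three
regimes: the Gauss series for moderate arguments; for the typical large
negative argument, a Pfaff transformation to $w = z/(z-1) \in (0,1)$
followed by the series; and, when $w$ is within about $10^{-5}$ of 1 (where
the series needs $>2\times10^4$ terms), a log-scaled fixed Gauss-Legendre
evaluation of the Euler integral representation in $\log t$ coordinates,
panelled around the integrand's bump and plateau.  The unit tests pin all
three regimes against frozen 50-digit reference values, and adaptive
quadrature of $1-F$ remains available both as `method = "quadrature"` and
as the independent oracle in the test suite (agreement is at or below
$10^{-11}$ relative across the packaged parameter ranges).

One identity is used for speed in frozen-parameter computations: with an
exponential birth rate and a *frozen* law, the exponent integral is itself
a survival integral with the growth rate folded into the Makeham slot,
$\int_x^\infty \lambda(t-u)(1-F(u))\,du = C e^{\kappa t}
\int_x^\infty e^{-\kappa u}(1-F(u))\,du$, so the fixed-point iteration runs
entirely on the closed form.

## Fitting titleholder data

A titleholder history is a list of triples $(t_i, y_i, z_i)$: the incumbent
dies at time $t_i$ at age $y_i$ and the successor is $z_i$ years old.
Consecutive triples must agree on the successor's birth date,
$t_i - z_i = t_{i+1} - y_{i+1}$; `validate_records()` enforces this with a
tolerance of 0.01 years, since day-resolved ages rounded to decimal years
carry up to 1/365 year of slack.  Dates convert to decimal years through a
single routine using 365.2425-day years.

The likelihood of a transition is the death density of the incumbent
(conditioned on having reached the previous successor age) times the jump
density of the successor's age.  Chaining transitions telescopes the
conditioning survival factors, leaving the full-sample log-likelihood with
one exponent integral per record over $[z_i, y_i]$ plus a final survival
term for the last successor — evaluated, like every per-record factor, at
age $z_n - E$ under the cohort that reached the entry age at
$t_n - z_n + E$, a convention the test suite pins down numerically through
the telescoping identity.
Each record's integrand is smooth on a short interval, so a fixed 25-point
Gauss-Legendre rule per record replaces adaptive quadrature; the unit tests
check it against an independent adaptive transcription to $10^{-8}$.  The
parameter-free terms $n\log C + \sum_i \kappa(t_i - z_i + E)$ are omitted
during optimization and restored via `include_constants = TRUE` when
absolute values are compared.

`fit_parameters()` maximizes over $(\alpha, K, \gamma)$ with $b$ fixed,
optimizing in log-parameter space so positivity needs no constraints.
Nelder-Mead is restarted with a dynamically rescaled tolerance: starting
from $10^{-3}$, after each run the tolerance is multiplied by the ratio of
successive improvements clamped to $[0.1, 1]$, warm-starting from the
incumbent optimum, and the loop stops when the improvement falls below
$10^{-6}$ or after 12 rounds.  Default starting values
$(\alpha, K, \gamma) = (0.01, 10^{-4}, 0.1)$ are order-of-magnitude guesses
for the entry-age-0 column; both the schedule constants and the start are
configurable.  Why fix $b$: freeing it (with or without a Makeham term)
reproducibly drives $K$ below $10^{-10}$ — a law with essentially no
mortality before age 100 that fits the observed tail but is useless as a
lifespan distribution.  Titleholder data only constrain ages roughly
107–123, so the four-parameter family is unidentifiable there; the test
suite asserts this failure mode and the guard that warns when the
optimizer enters it.  `sensitivity_scan()` refits across
$E \in \{0,30,60\}$ and $b \in \{0.09, 0.11, 0.13, 0.15\}$; the fitted
$\gamma$ increases with the imposed $b$ (the plateau $b/\gamma$ is what the
tail actually pins down).

## Approximations for the mean age and reign length

The mean of $Y_t$ under the exact distribution involves a level parameter
that changes along the integration variable.  `mean_age_fixed_point()`
instead freezes the level at $a_E(t-d)$ and chooses the delay $d$
self-consistently: $d$ is the fixed point of "the mean age computed with
the cohort level of $t-d$".  Ten iterations are the default; the map
contracts fast because the record-age distribution is concentrated
(standard deviation about 1.5 years), and the iterates' increments are
asserted to shrink in the tests.  The reported standard deviation uses the
same frozen-parameter density, and the atom at zero (below $10^{-12}$ under
the fitted parameters) is ignored in moments.

Reign lengths at a calendar year reuse this freeze:
`frozen_homogeneous_spec()` builds the homogeneous model with the level
frozen at $a_E(t-d^*)$ and the birth rate frozen, by default, at
$\lambda_E(t-d^*)$ — the rate experienced by the record holder's own cohort,
matching the frozen-cohort logic of the fixed point.  The alternative
convention $\lambda_E(t)$ is exposed as `freeze = "current"`; the two
differ by about 0.013 years here, inside the reported tolerance.

## The simulator

`simulate_population()` draws the marked-Poisson representation directly:
birth times by thinning against the window supremum of the intensity
(checked on a fine grid), lifespans by inverse-cdf sampling — closed-form
for the gamma-Gompertz, root-finding with a Makeham term.  One integer seed
expands into two substreams (points, marks) so populations are comparable
across lifespan laws.  `extract_record_trajectory()` uses the fact that, in
birth order, record holders are exactly the individuals whose death time
exceeds every earlier death time, turning extraction into a sort and a
running maximum; derived triples satisfy the consistency relation exactly,
by construction.

At world scale the birth process is of order $10^{10}$ individuals over the
relevant window, so `make_synthetic_titleholders()` simulates only the
thinned process of people reaching age 105 (entry-rate
$\lambda(s-105)(1-F_{s-105}(105))$, lifespans from the conditional law) —
the record process above 105 is unchanged, and under the packaged
parameters the record age stays above 106 except with probability below
$e^{-10}$.  Simulation starts 130 years before the observation window
(survival beyond 130 is under $10^{-10}$ for all shipped laws), so the
initial record holder is correct.

What the generator does *not* emulate: age misreporting and validation lag
in real titleholder lists, the post-1950 flattening of world birth counts
(the exponential intensity is an extrapolated fit), and any dependence
between lifespans.  Passing recovery tests therefore show that the
estimator inverts the model's own mechanism at realistic sample sizes
(about 50–60 transitions per 65-year window), not that real lists are free
of curation artefacts.

## Numerical choices

* Ages are truncated at `x_max = 150` years in the exact-model integrals;
  survival beyond 150 is below $10^{-12}$ for every shipped law.  The
  quadrature oracle for the survival integral instead extends its upper
  limit adaptively, because generic test laws with very low mortality keep
  substantial mass beyond 150.
* Adaptive quadrature runs at relative tolerance $10^{-10}$ (absolute
  $10^{-12}$); outer integrals over record-age densities are split into
  panels around the age $x^*$ solving $\Lambda_t(x^*) = 1$, where the
  density concentrates, with a fixed 192-node Gauss-Legendre fallback for
  panels whose double-exponential ramps upset the adaptive rule.
* Grid-based densities (`age_distribution()`, used for density series and
  CSV export) accumulate the exponent with per-interval Simpson increments
  (midpoint evaluations), keeping normalization within $10^{-6}$ at the
  default 0.05-year step.
* Tail survival is always computed on the log scale; forming `1 - cdf`
  loses all relative precision once survival drops below $10^{-8}$, which
  is the regime record dynamics live in.
* Finite-difference checks of the stationary ODEs are evaluated where the
  densities carry mass.  Outside the support the densities underflow to
  exactly zero and a scale-free residual becomes 0/0; inside, residuals
  sit at $10^{-7}$ with step $10^{-3}$ years.
* Test problem sizes: the distributional Kolmogorov-Smirnov checks use one
  long homogeneous run with $5\times10^4$ record transitions (a small
  birth rate, so the population stays near $8\times10^5$ points), and
  parameter recovery uses a fixed-seed battery of ten 65-year synthetic
  histories; recovery is asserted at the battery level (median relative
  error within 15% for $\alpha$ and $\gamma$, every $K$ within a factor
  two), matching the dispersion a single 60-transition window actually
  carries.

## Known limitations

* The exponential birth intensity is an extrapolation; predictions decades
  ahead inherit it.  Cohorts relevant for records up to about 2060 were
  born before 1950, i.e. inside the data the constants were fit on, so the
  near-term predictions are interpolations in cohort time.
* No parameter uncertainty is propagated: the package reports maximum
  likelihood point estimates, and predicted bands reflect process noise
  only.
* The entry-age columns are separate model fits; there is no joint
  likelihood across entry ages.
* `make_synthetic_titleholders()` supports entry age 0; the higher entry
  ages are fitted to the same record data, not simulated.
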