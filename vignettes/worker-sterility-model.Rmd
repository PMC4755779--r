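---
title: "Colony genetics of worker sterility under multiple queen mating"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Colony genetics of worker sterility under multiple queen mating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplosterile)
```

## The question and the model

In haplodiploid social insects (ants, bees, wasps) females develop from
fertilized eggs and males from unfertilized ones, so unmated workers can lay
male eggs in direct competition with the queen's male eggs. `haplosterile`
analyses when natural selection favours an allele *a* that switches this
worker reproduction off — making workers non-reproductive ("sterile") — for
a queen that mates `n` times, and whether such an allele, once fixed, is
evolutionarily stable against re-invasion by the reproductive wild-type
allele *A*.

The population is described at the level of colonies. A colony is labelled
by its queen's genotype (*AA*, *Aa* or *aa*) and the number `m` of her `n`
matings that were with mutant males, giving `3(n+1)` colony types with
frequencies `X[g,m]` on the simplex. Two colony-level phenotype functions
of the sterile-worker fraction `z` drive everything:

* `p_z` — the fraction of the colony's male eggs laid by the queen when a
  fraction `z` of workers are sterile. By definition `p_1 = 1` (no workers
  lay eggs, so every male is queen-laid); `p_0 < 1` is expected but any
  values in `[0, 1]` are accepted. Monotonicity in `z` is biologically
  natural but deliberately not enforced (an opt-in check exists), because
  queen–worker conflict can plausibly make the male share rise
  non-linearly.
* `r_z` — the colony's reproductive rate (efficiency) at sterile fraction
  `z`, normalised to `r_0 = 1`. Worker sterility can only be favoured if
  it buys colony efficiency somewhere (`r_z > 1` for some `z`), and `r_z`
  need not be monotone: an intermediate optimum is allowed.

Under a recessive allele only *aa* workers are sterile, so the sterile
fraction of a colony follows from Mendelian bookkeeping: 0 for *AA*-queen
colonies, `m/(2n)` for *Aa*-queen colonies, `m/n` for *aa*-queen colonies.
Under a dominant allele *Aa* workers are sterile too (`m/n`, `(m+n)/(2n)`
and 1 respectively). These fractions are exact rationals and are used as
lookup keys into the `p`/`r` tables — stored as canonical fraction strings
(`"1/4"`), never floats, so that keys cannot alias.

Each colony type contributes gynes and drones to population-wide mating
pools in proportion to its frequency times its efficiency `r_z`, with male
contributions split `p_z` to the queen's eggs and `1 - p_z` to worker-laid
eggs. Gynes mate `n` times at random in the drone pool, founding new
colonies at rate `choose(n,m) x_g yA^(n-m) ya^m`, while a density-dependent
death rate `phi = (x_AA + x_Aa + x_aa)(yA + ya)^n` holds the total colony
number constant. The per-capita constants of the unscaled model (gyne and
drone viability, carrying capacity) cancel out of every invasion and
stability condition and are fixed to 1 by rescaling; only `p` values and
ratios of `r` values matter. The flow conserves the simplex identically:
`sum(colony_rhs(state, params))` is zero to round-off at any state, which
is property-tested rather than enforced by renormalising inside the
solver — stored trajectory states are renormalised only on output, and only
when accumulated drift exceeds `1e-12`, so integrator problems stay
visible.

## Invasion and stability conditions

Perturbing the all-wild-type equilibrium with a rare *a* allele and the
all-mutant equilibrium with a rare *A* allele gives four conditions, all
implemented in closed form or as small Jacobians:

* **Recessive invasion.** The linearisation at the all-*A* state has a zero
  dominant eigenvalue (a rare recessive allele is phenotypically silent at
  first order, since *aa* workers require two rare alleles to meet), so the
  verdict lives at second order of the perturbation expansion. The
  resulting condition is a single threshold on `r_{1/(2n)}/r_0`
  (`recessive_invasion_threshold()`), reducing at `n = 1` to
  `(6+2p_0)/(5+3p_0)` and at `n = 2` to `(6+3p_0)/(5+3p_0+p_{1/4})`. At
  `n = 1` the queen's male share in half-sterile colonies, `p_{1/2}`,
  cancels exactly — queen and workers there both lay half *A*, half *a*
  males — and the package property-tests that invariance.
* **Recessive stability.** First-order: a 2×2 Jacobian over the
  (*aa*,n−1; *Aa*,n) perturbation. The allele is stable iff both
  eigenvalues are negative (trace < 0 and determinant > 0). Because the
  matrix has the form `K - r_1 I` with `K` free of `r_1`, the critical
  efficiency of fully sterile colonies is simply the dominant eigenvalue of
  `K`: `recessive_stability_critical_r1()` root-finds it (bracketed,
  tolerance `1e-10`) and cross-checks the closed-form quadratic root
  `(2r_1 - n(1-p)a)(2r_1 - b) = 2ab` internally.
* **Dominant invasion.** First-order 2×2 Jacobian over (*AA*,1; *Aa*,0);
  its determinant condition is algebraically the closed form
  `(r_{1/2}/r_0)(1 + p_{1/2} r_{1/n}/r_0) > 2`, an identity the
  implementation asserts at every call.
* **Dominant stability.** Second-order, with the closed form
  `r_1/r_{(2n-1)/(2n)} > (2 + 3n - n p_{(2n-1)/(2n)})/(2(n+1))`.

All inequalities are strict and a margin of exactly zero reports "does not
hold": the boundary is measure-zero, and the phenotypically silent allele
(`p = 1`, `r = 1` everywhere) then sits exactly on all four thresholds, a
useful calibration that the tests assert for `n` up to 10.
`classify_regime()` combines the two dominance-appropriate conditions into
the four qualitative regimes: fixation of sterility (invades, stable),
coexistence (invades, unstable), bistability (no invasion, stable) and
elimination (neither).

```{r conditions}
m <- model_params(1, "recessive", phenotype_functions(
  p = c("0" = 0.5, "1/2" = 0.75),
  r = c("1/2" = 1.0869, "1" = 1.1521)))
classify_regime(m)
```

## Numerical validation by simulation

The analytic conditions are second-order perturbation results; the package
validates them against direct integration of the full dynamics
(`deSolve`, adaptive `lsoda`/`lsodar`; defaults `rtol = 1e-10`,
`atol = 1e-12` for trajectories, `1e-8`/`1e-10` for the oracles, where only
a sign-like verdict is needed). `oracle_invasion()` perturbs the resident
equilibrium with `epsilon` of singly-mismated queens and integrates with
root-stopping until the rare-type mass (frequency of colony types carrying
at least one copy of the rare allele) crosses `min(100*epsilon, 0.25)`
("grows") or `epsilon/100` ("declines").

Two numerical choices deserve explanation:

* *The 0.25 cap on the growth cutoff.* An allele that invades but is not
  stable converges to an interior coexistence attractor whose mutant mass
  can sit well below 1 (0.39 in one of the worked parameter sets), so a
  cutoff at `100*epsilon = 1` or even 0.5 would never be reached; mass
  exceeding 0.25 from a perturbation of `1e-2` or less is unambiguous
  growth, and no declining trajectory approaches it.
* *Case-dependent defaults.* The second-order cases (recessive invasion,
  dominant stability) have algebraic, not exponential, transients: the time
  to grow or decay scales like `1/epsilon`. They therefore default to the
  larger perturbation `epsilon = 1e-2` and a horizon of `1e6` rescaled time
  units, while the first-order cases use `1e-3` and `1e4`. The long horizon
  is cheap — the adaptive solver takes very large steps on the slow
  manifold — and a verdict that still has not resolved is reported as
  `inconclusive`, never coerced.

`concordance_sweep()` draws random phenotype tables (p uniform on `[0,1]`,
r uniform on `[0.8, 1.4]`, a range wide enough to put every condition on
both sides of its threshold), discards draws with any condition margin
within 0.01 of a boundary, and requires every conclusive oracle verdict to
match the analytic conditions. The shipped validation suite runs 50 retained
parameter sets per (n, dominance) stratum for `n` in {1, 2} — 200 sets, 400
oracle runs, about 15 s — a size chosen to exercise both dominance modes
and both mate numbers well past the worked examples; at that size all 400
verdicts have historically been conclusive-or-consistent with zero
disagreements.

## Parameter-space experiments

The experiments randomise the two decisive efficiencies `(r_z1, r_z2)` from
a bivariate normal with mean `mu = 1` and common standard deviation
`sigma` — 0.1 for the invasion comparison (where thresholds sit within a
few percent of 1) and 0.2 for the regime experiment — either uncorrelated
("procedure 1") or with correlation `rho = 0.8` ("procedure 2", reflecting
that efficiencies at nearby sterile fractions should co-vary). Draws are
deliberately not truncated at zero: negative efficiencies (probability
`pnorm(-5)` at `sigma = 0.2`) are classified against the thresholds like
any other draw but are never integrated. For the recessive invasion
scenario both mate-number conditions are univariate thresholds, so the four
outcome probabilities are exact products/differences of normal CDF values —
the correlated case uses an in-package bivariate normal CDF computed by
one-dimensional quadrature (absolute tolerance `1e-8`) — and Monte Carlo
(default `1e6` draws, binomial standard errors) serves as the cross-check.
The regime experiment is Monte-Carlo-first because its stability boundary
is a quadratic curve in the `(r_{1/2}, r_1)` plane.

```{r table1}
invasion_outcome_probabilities(
  "recessive", p = c("0" = 0.2, "1/4" = 0.4),
  proc = sampling_procedure(sigma = 0.1, rho = 0.8), method = "analytic")
```

## What the model does and does not emulate

The dynamics are deterministic and infinite-population: colony output
fractions are exact expectations, so there is no drift, no demographic
stochasticity and no mutation process (alleles enter only through initial
conditions). Mating is panmictic. The sex ratio is held fixed by
construction — worker-laid male eggs compete only with queen-laid male
eggs — which is precisely the modelling choice that isolates the
queen–worker conflict over male parentage from sex-ratio evolution; tests
passing here say nothing about scenarios where worker reproduction also
displaces female eggs, about worker policing, or about finite-colony noise.
The phenotype functions are free tables, so empirical `p_z`/`r_z` curves
can be plugged in directly once measured.

## Practical notes and limitations

* The mate number is capped at 20 by default (tables grow linearly, but
  beyond tens of matings the model's premises are strained); raise
  `max_n` explicitly to override.
* Fraction keys in configs must be exact (`"1/4"`, or decimals like `0.25`
  that are exactly representable); YAML users should quote the model key
  `"n"`, which bare YAML 1.1 would read as a boolean.
* Config files reproducing every worked figure and table scenario ship
  under `system.file("extdata", "configs", package = "haplosterile")`;
  values that the published captions do not print (for example `p_{1/2}`
  in the dominant-allele experiment) are marked as synthetic choices in
  the config comments and are excluded from quantitative validation.
* Boundary parameter sets (margins exactly zero) classify to the
  non-invading/unstable side by convention; the oracles cannot resolve
  them either way, and report `inconclusive`.
* The regime Monte-Carlo experiment is defined for the single-mating
  recessive case, matching the published experiment; other cases error
  rather than silently extrapolate.
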