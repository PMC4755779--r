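#' Selection dynamics of colony-type frequencies
#'
#' The colony frequencies X_{g,m} follow a density-constrained birth-death
#' flow: new colonies of type (g, m) are founded at rate
#' `choose(n, m) * x_g * y_A^(n-m) * y_a^m` (a gyne of genotype g mating n
#' times at random in the drone pool), and all colonies die at the common
#' density-dependent rate `phi = (x_AA + x_Aa + x_aa) * (y_A + y_a)^n`,
#' which holds the total frequency at 1: the right-hand side sums to zero
#' identically, so the flow stays on the simplex.
#'
#' @inheritParams pool_matrix
#' @return `colony_rhs()`: named numeric vector of time derivatives.
#' @examples
#' m <- model_params(1, "recessive",
#'   phenotype_functions(p = c("0" = 0.5, "1/2" = 0.7),
#'                       r = c("1/2" = 1.0869, "1" = 1.1521)))
#' colony_rhs(pure_state(1, "A"), m)  # fixed point: all zeros
#' @export
colony_rhs <- function(state, params) {
  state <- check_state(state, params$n)
  drv <- make_rhs(params)
  drv(0, state, NULL)[[1]]
}

# closure used by both the exported rhs and the integrator: precomputes the
# pool matrix and binomial weights once
make_rhs <- function(params) {
  P <- pool_matrix(params)
  n <- params$n
  m <- 0:n
  binom <- choose(n, m)
  gidx <- list(x_AA = 1L, x_Aa = 2L, x_aa = 3L)
  function(t, X, parms) {
    pools <- P %*% X
    if (any(!is.finite(pools))) {
      abort("non-finite gamete pools encountered during integration",
            state = X, time = t)
    }
    yA <- pools[4L]; ya <- pools[5L]
    mate <- binom * yA^(n - m) * ya^m
    births <- c(pools[1L] * mate, pools[2L] * mate, pools[3L] * mate)
    phi <- (pools[1L] + pools[2L] + pools[3L]) * (yA + ya)^n
    list(births - phi * X)
  }
}

#' Integrate the selection dynamics
#'
#' Adaptive solution of the colony-frequency flow from a simplex initial
#' state (via \pkg{deSolve}). Stored states are renormalised back onto the
#' simplex whenever accumulated solver drift exceeds `drift_tol` (the raw
#' integration itself is never touched, so solver problems stay visible);
#' the largest drift seen is recorded. If the trajectory approaches one of
#' the two absorbing monomorphic states within `absorb_tol` the returned
#' object is flagged.
#'
#' @inheritParams pool_matrix
#' @param initial simplex frequency vector (see [population_state()]).
#' @param horizon end time, in the rescaled time units of the model.
#' @param rtol,atol relative and absolute solver tolerances.
#' @param n_out number of stored output times (equally spaced over the
#'   horizon), or a numeric vector of times to store.
#' @param drift_tol renormalise stored states when `|sum(X) - 1|` exceeds this.
#' @param absorb_tol flag absorbing-state proximity below this distance.
#' @param method a [deSolve::ode()] integration method.
#' @return object of class `sterility_trajectory`: list with `times`,
#'   `states` (matrix, one row per stored time), `params`, `max_drift`,
#'   `absorbed` (`NA`, `"A"` or `"a"`). [tidy()] gives a long tibble.
#' @examples
#' m <- model_params(1, "recessive",
#'   phenotype_functions(p = c("0" = 0.5, "1/2" = 0.7),
#'                       r = c("1/2" = 1.0869, "1" = 1.1521)))
#' tr <- simulate_dynamics(m, invasion_state(1, 1e-2), horizon = 200)
#' glance(tr)
#' @export
simulate_dynamics <- function(params, initial, horizon = 1e4,
                              rtol = 1e-10, atol = 1e-12, n_out = 201L,
                              drift_tol = 1e-12, absorb_tol = 1e-10,
                              method = "lsoda") {
  stopifnot(inherits(params, "sterility_model"))
  initial <- check_state(initial, params$n)
  if (length(horizon) != 1L || horizon <= 0) abort("horizon must be positive")
  times <- if (length(n_out) > 1L) sort(unique(c(0, n_out))) else
    seq(0, horizon, length.out = max(2L, as.integer(n_out)))
  drv <- make_rhs(params)
  sol <- deSolve::ode(y = initial, times = times, func = drv, parms = NULL,
                      method = method, rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    abort("ODE solver failed before reaching the horizon",
          last_time = max(sol[, 1]), last_state = sol[nrow(sol), -1])
  }
  st <- unname(sol[, -1, drop = FALSE])
  colnames(st) <- names(initial)
  drift <- abs(rowSums(st) - 1)
  renorm <- drift > drift_tol
  if (any(renorm)) {
    st[renorm, ] <- pmax(st[renorm, , drop = FALSE], 0) /
      rowSums(pmax(st[renorm, , drop = FALSE], 0))
  }
  final <- st[nrow(st), ]
  absorbed <- NA_character_
  if (sum(abs(final - pure_state(params$n, "A"))) < absorb_tol) absorbed <- "A"
  if (sum(abs(final - pure_state(params$n, "a"))) < absorb_tol) absorbed <- "a"
  structure(list(times = sol[, 1], states = st, params = params,
                 max_drift = max(drift), absorbed = absorbed),
            class = "sterility_trajectory")
}

#' @export
print.sterility_trajectory <- function(x, ...) {
  cat(sprintf(
    "<sterility_trajectory> n = %d (%s), %d states over t = [%g, %g]%s\n",
    x$params$n, x$params$dominance, length(x$times), min(x$times),
    max(x$times),
    if (is.na(x$absorbed)) "" else sprintf(", absorbed at all-%s", x$absorbed)
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.sterility_trajectory <- function(x, ...) {
  labels <- colnames(x$states)
  tibble(
    time = rep(x$times, times = length(labels)),
    colony = rep(labels, each = length(x$times)),
    frequency = as.vector(x$states)
  )
}

#' @exportS3Method generics::glance
glance.sterility_trajectory <- function(x, ...) {
  final <- x$states[nrow(x$states), ]
  tibble(
    n = x$params$n,
    dominance = x$params$dominance,
    horizon = max(x$times),
    mutant_mass = mutant_mass(final, x$params$n),
    mutant_allele_freq = mutant_allele_frequency(final, x$params),
    max_drift = x$max_drift,
    absorbed = x$absorbed
  )
}

# total frequency of colony types carrying at least one a allele
# (queen genotype or stored sperm): everything except AA,0
mutant_mass <- function(state, n) {
  unname(1 - state[["AA0"]])
}

# total frequency of colony types carrying at least one A allele:
# everything except aa,n
wildtype_mass <- function(state, n) {
  unname(1 - state[[paste0("aa", n)]])
}

#' Mutant-allele frequency in the mating pools
#'
#' A reporting statistic for trajectories: the frequency of the sterility
#' allele a among gametes, computed from the gamete pools with the haploid
#' drone pool weighted to the same total size as the diploid gyne pool:
#' `(x_Aa + 2 x_aa + x_tot * y_a / y_tot) / (3 x_tot)` where
#' `x_tot = x_AA + x_Aa + x_aa` and `y_tot = y_A + y_a`. Monotone summary
#' only; invasion/stability verdicts never use it.
#'
#' @inheritParams pool_matrix
#' @return a number in `[0, 1]`.
#' @export
mutant_allele_frequency <- function(state, params) {
  g <- gamete_pools(state, params)
  xtot <- g[["x_AA"]] + g[["x_Aa"]] + g[["x_aa"]]
  ytot <- g[["y_A"]] + g[["y_a"]]
  if (xtot <= 0 || ytot <= 0) {
    abort("allele frequency is undefined: empty gyne or drone pool")
  }
  (g[["x_Aa"]] + 2 * g[["x_aa"]] + xtot * g[["y_a"]] / ytot) / (3 * xtot)
}

#' Simulation-based invasion and stability oracles
#'
#' Numerical counterparts of the analytic conditions, used to validate
#' them. `oracle_invasion()` perturbs the all-A equilibrium with a fraction
#' epsilon of AA queens that made one mating with a mutant male and
#' integrates until the mutant mass (frequency of colony types carrying at
#' least one a allele) either grows past `min(100 * epsilon, 0.5)`
#' (verdict `"grows"`) or collapses below `epsilon / 100` (`"declines"`);
#' reaching the horizon first gives `"inconclusive"`. `oracle_stability()`
#' perturbs the all-a equilibrium symmetrically and tracks the wild-type
#' mass, so `"grows"` there means the sterility allele is NOT stable.
#'
#' Recessive invasion and dominant stability are second-order (the
#' linearisation at the resident equilibrium has a zero dominant
#' eigenvalue), so their transients lengthen like 1/epsilon: the default
#' epsilon is larger (1e-2, as against 1e-3 for the first-order cases) and
#' the default horizon much longer (1e6 rescaled time units, as against
#' 1e4) — cheap, because the adaptive solver takes very large steps on the
#' slow manifold. The growth cutoff is capped at 0.25 because an invading
#' allele that is not stable settles at an interior coexistence attractor
#' whose mutant mass can sit well below 1.
#'
#' @inheritParams simulate_dynamics
#' @param epsilon perturbation size in (0, 0.05]; default chosen by case as
#'   described above.
#' @return object of class `oracle_verdict`: list with `outcome`
#'   (`"grows"`, `"declines"` or `"inconclusive"`), `final_mutant_mass`
#'   (the tracked rare-type mass at termination), `horizon_used`,
#'   `time_reached` and `epsilon`.
#' @export
oracle_invasion <- function(params, epsilon = NULL, horizon = NULL,
                            rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "sterility_model"))
  epsilon <- epsilon %||% (if (params$dominance == "recessive") 1e-2 else 1e-3)
  # recessive invasion is second-order: algebraic transients need ~1/epsilon
  horizon <- horizon %||% (if (params$dominance == "recessive") 1e6 else 1e4)
  run_oracle(params, invasion_state(params$n, epsilon),
             mass_fn = function(X) 1 - X[1L], # all but AA,0
             epsilon = epsilon, horizon = horizon, rtol = rtol, atol = atol)
}

#' @rdname oracle_invasion
#' @export
oracle_stability <- function(params, epsilon = NULL, horizon = NULL,
                             rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "sterility_model"))
  epsilon <- epsilon %||% (if (params$dominance == "dominant") 1e-2 else 1e-3)
  # dominant stability is the second-order case here
  horizon <- horizon %||% (if (params$dominance == "dominant") 1e6 else 1e4)
  k <- 3L * (params$n + 1L)
  run_oracle(params, stability_state(params$n, epsilon),
             mass_fn = function(X) 1 - X[k], # all but aa,n
             epsilon = epsilon, horizon = horizon, rtol = rtol, atol = atol)
}

run_oracle <- function(params, initial, mass_fn, epsilon, horizon, rtol, atol) {
  check_epsilon(epsilon)
  grow_thr <- min(100 * epsilon, 0.25)
  decline_thr <- epsilon / 100
  drv <- make_rhs(params)
  root <- function(t, X, parms) {
    m <- mass_fn(X)
    c(m - grow_thr, m - decline_thr)
  }
  sol <- deSolve::ode(y = initial, times = c(0, horizon), func = drv,
                      parms = NULL, method = "lsodar", rtol = rtol,
                      atol = atol, rootfunc = root)
  t_end <- sol[nrow(sol), 1]
  final_mass <- mass_fn(sol[nrow(sol), -1])
  outcome <- if (final_mass >= grow_thr * (1 - 1e-6)) "grows"
    else if (final_mass <= decline_thr * (1 + 1e-6)) "declines"
    else "inconclusive"
  structure(list(outcome = outcome, final_mutant_mass = unname(final_mass),
                 horizon_used = horizon, time_reached = unname(t_end),
                 epsilon = epsilon),
            class = "oracle_verdict")
}

#' @export
print.oracle_verdict <- function(x, ...) {
  cat(sprintf(
    "<oracle_verdict> %s (rare-type mass %.3g at t = %.4g of %.4g, epsilon = %g)\n",
    x$outcome, x$final_mutant_mass, x$time_reached, x$horizon_used, x$epsilon
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.oracle_verdict <- function(x, ...) {
  tibble(outcome = x$outcome, final_mutant_mass = x$final_mutant_mass,
         time_reached = x$time_reached, horizon_used = x$horizon_used,
         epsilon = x$epsilon)
}
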