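#' Random sampling of colony-efficiency pairs
#'
#' The parameter-space experiments draw the two efficiency values that
#' decide an outcome, `r_z1` and `r_z2` (z1 < z2), from a bivariate normal
#' distribution with common mean `mu`, common standard deviation `sigma`
#' and correlation `rho` (`rho = 0` gives independent draws — "procedure
#' 1"; the correlated variant with `rho = 0.8` is "procedure 2"). Draws are
#' not truncated: the occasional negative efficiency (probability about
#' `pnorm(-5)` at `sigma = 0.2`) is retained for threshold classification
#' but would never be fed to the ODE solver.
#'
#' @param sigma standard deviation of the efficiency draws (> 0).
#' @param mu mean efficiency (default 1, the baseline `r_0`).
#' @param rho correlation in (-1, 1).
#' @param n_samples number of pairs.
#' @param seed optional integer seed making the draw reproducible.
#' @return `sampling_procedure()`: a list of class `sampling_procedure`.
#'   `sample_efficiency_pairs()`: tibble with columns `r_z1`, `r_z2`.
#' @examples
#' proc <- sampling_procedure(sigma = 0.1, rho = 0.8, n_samples = 1e4, seed = 1)
#' cor(sample_efficiency_pairs(proc))[1, 2]
#' @export
sampling_procedure <- function(sigma, mu = 1, rho = 0, n_samples = 1e6,
                               seed = NULL) {
  if (length(sigma) != 1L || is.na(sigma) || sigma <= 0) {
    abort("sigma must be a single positive number")
  }
  if (length(rho) != 1L || is.na(rho) || abs(rho) >= 1) {
    abort("rho must lie strictly between -1 and 1")
  }
  if (n_samples < 1 || n_samples != round(n_samples)) {
    abort("n_samples must be a positive integer")
  }
  structure(list(mu = mu, sigma = sigma, rho = rho,
                 n_samples = as.integer(n_samples), seed = seed),
            class = "sampling_procedure")
}

#' @rdname sampling_procedure
#' @param proc a [sampling_procedure()] object.
#' @export
sample_efficiency_pairs <- function(proc) {
  stopifnot(inherits(proc, "sampling_procedure"))
  if (!is.null(proc$seed)) set.seed(proc$seed)
  e1 <- rnorm(proc$n_samples)
  e2 <- rnorm(proc$n_samples)
  tibble(
    r_z1 = proc$mu + proc$sigma * e1,
    r_z2 = proc$mu + proc$sigma * (proc$rho * e1 + sqrt(1 - proc$rho^2) * e2)
  )
}

#' Standard bivariate normal CDF
#'
#' `P(Z1 <= h, Z2 <= k)` for standard normal margins with correlation
#' `rho`, by one-dimensional numerical integration of
#' `dnorm(x) * pnorm((k - rho x) / sqrt(1 - rho^2))` over `(-Inf, h]`.
#'
#' @param h,k upper limits (standardised).
#' @param rho correlation in (-1, 1).
#' @param abs_tol absolute integration tolerance.
#' @return a probability.
#' @export
pbvnorm <- function(h, k, rho, abs_tol = 1e-8) {
  if (abs(rho) >= 1) abort("rho must lie strictly between -1 and 1")
  if (rho == 0) return(pnorm(h) * pnorm(k))
  s <- sqrt(1 - rho^2)
  integrate(function(x) dnorm(x) * pnorm((k - rho * x) / s),
            lower = -Inf, upper = h, abs.tol = abs_tol)$value
}

new_outcome_probabilities <- function(labels, probs, se, method, proc,
                                      scenario) {
  structure(
    tibble(outcome = labels, probability = probs, standard_error = se),
    method = method, procedure = proc, scenario = scenario,
    class = c("outcome_probabilities", class(tibble()))
  )
}

#' Outcome probabilities of sterility-allele invasion under random efficiencies
#'
#' Classifies random draws of the two decisive colony-efficiency values by
#' the single-mating (n = 1) and double-mating (n = 2) invasion conditions
#' and returns the probabilities of the four mutually exclusive outcomes:
#' the sterility allele invades for neither, for n = 1 only, for n = 2
#' only, or for both.
#'
#' For a recessive allele the drawn pair is `(r_{1/4}, r_{1/2})` (with
#' `r_0 = 1`) and each condition is a univariate threshold — `r_{1/2}`
#' decides n = 1 and `r_{1/4}` decides n = 2 — so the probabilities reduce
#' to (bivariate) normal CDF values and `method = "analytic"` is exact. For
#' a dominant allele the drawn pair is `(r_{1/2}, r_1)` and the n = 1
#' condition couples both draws, so there is no univariate reduction:
#' requesting the analytic path falls back to Monte Carlo with a warning.
#'
#' @inheritParams required_z_grid
#' @param p named numeric vector (or [phenotype_functions()]) supplying
#'   `p_0` and `p_{1/4}` (recessive) or `p_{1/2}` (dominant).
#' @param proc a [sampling_procedure()].
#' @param method `"analytic"` or `"monte_carlo"`.
#' @return an `outcome_probabilities` tibble (columns `outcome`,
#'   `probability`, `standard_error`; attributes `method`, `procedure`,
#'   `scenario`). Standard errors are 0 on the analytic path.
#' @examples
#' invasion_outcome_probabilities(
#'   "recessive", p = c("0" = 0.2, "1/4" = 0.4),
#'   proc = sampling_procedure(sigma = 0.1), method = "analytic")
#' @export
invasion_outcome_probabilities <- function(dominance = c("recessive", "dominant"),
                                           p, proc,
                                           method = c("analytic", "monte_carlo")) {
  dominance <- match.arg(dominance)
  method <- match.arg(method)
  stopifnot(inherits(proc, "sampling_procedure"))
  if (!inherits(p, "phenotype_functions")) p <- phenotype_functions(p = p)
  labels <- c("neither", "n1_only", "n2_only", "both")

  if (dominance == "recessive") {
    # invade for n = 1  <=>  r_{1/2} (= r_z2) exceeds its threshold
    # invade for n = 2  <=>  r_{1/4} (= r_z1) exceeds its threshold
    c2 <- recessive_invasion_threshold(1, p_at(p, "0"))
    c1 <- recessive_invasion_threshold(2, p_at(p, "0"), p_at(p, "1/4"))
    if (method == "analytic") {
      h1 <- (c1 - proc$mu) / proc$sigma
      h2 <- (c2 - proc$mu) / proc$sigma
      both_below <- pbvnorm(h1, h2, proc$rho)
      probs <- c(both_below,
                 pnorm(h1) - both_below,
                 pnorm(h2) - both_below,
                 1 - pnorm(h1) - pnorm(h2) + both_below)
      return(new_outcome_probabilities(labels, probs, rep(0, 4), "analytic",
                                       proc, "invasion_recessive"))
    }
    draws <- sample_efficiency_pairs(proc)
    inv1 <- draws$r_z2 > c2
    inv2 <- draws$r_z1 > c1
    scenario <- "invasion_recessive"
  } else {
    if (method == "analytic") {
      warn("no univariate analytic reduction for the dominant case; falling back to Monte Carlo")
    }
    p_half <- p_at(p, "1/2")
    draws <- sample_efficiency_pairs(proc)   # (r_{1/2}, r_1), r_0 = 1
    inv1 <- draws$r_z1 * (1 + p_half * draws$r_z2) > 2
    inv2 <- draws$r_z1 * (1 + p_half * draws$r_z1) > 2
    scenario <- "invasion_dominant"
  }
  counts <- c(sum(!inv1 & !inv2), sum(inv1 & !inv2),
              sum(!inv1 & inv2), sum(inv1 & inv2))
  probs <- counts / proc$n_samples
  new_outcome_probabilities(labels, probs,
                            sqrt(probs * (1 - probs) / proc$n_samples),
                            "monte_carlo", proc, scenario)
}

#' Outcome probabilities of the four invasion-by-stability regimes
#'
#' For single mating and a recessive allele, draws `(r_{1/2}, r_1)` (with
#' `r_0 = 1`) and classifies each pair into the four regimes of
#' [classify_regime()]: no invasion and unstable, no invasion but stable
#' (bistability), invasion but unstable (coexistence), invasion and stable.
#' Monte Carlo is the primary method — the stability boundary is a
#' quadratic curve in the `(r_{1/2}, r_1)` plane, so there is no product
#' reduction; the marginal invasion probability is still univariate and can
#' be checked against `1 - pnorm((threshold - mu)/sigma)`.
#'
#' @inheritParams invasion_outcome_probabilities
#' @param n mate number; only n = 1 is supported (the regime experiment of
#'   the single-mating phase diagram).
#' @param p named vector or [phenotype_functions()] supplying `p_0`.
#' @return an `outcome_probabilities` tibble with outcomes
#'   `no_invade_unstable`, `no_invade_stable_bistable`,
#'   `invades_unstable_coexistence`, `invades_and_stable`.
#' @examples
#' regime_outcome_probabilities(
#'   p = c("0" = 0.5), proc = sampling_procedure(sigma = 0.2, n_samples = 1e4,
#'   seed = 1))
#' @export
regime_outcome_probabilities <- function(p, proc, n = 1,
                                         dominance = "recessive",
                                         method = "monte_carlo") {
  n <- check_n(n)
  if (n != 1L || dominance != "recessive") {
    abort("the regime experiment is defined for the single-mating (n = 1) recessive case")
  }
  if (!identical(method, "monte_carlo")) {
    warn("the regime boundary is a quadratic curve; using Monte Carlo")
  }
  stopifnot(inherits(proc, "sampling_procedure"))
  if (!inherits(p, "phenotype_functions")) p <- phenotype_functions(p = p)
  p0 <- p_at(p, "0")
  draws <- sample_efficiency_pairs(proc)   # (r_{1/2}, r_1)
  cls <- classify_regime_vec(draws$r_z1, draws$r_z2, p0)
  counts <- vapply(regime_levels(), function(l) sum(cls == l), numeric(1))
  probs <- counts / proc$n_samples
  new_outcome_probabilities(regime_levels(), unname(probs),
                            sqrt(probs * (1 - probs) / proc$n_samples),
                            "monte_carlo", proc, "regime_recessive_n1")
}

# vectorised n = 1 recessive classification over (r_half, r1) with r_0 = 1;
# must agree with classify_regime() pointwise (property-tested)
classify_regime_vec <- function(r_half, r1, p0) {
  invades <- r_half > recessive_invasion_threshold(1, p0)
  tr <- (-2 * r1 + (1 - p0)) / 2 + (-2 * r1 + r_half) / 2
  det <- ((-2 * r1 + (1 - p0)) / 2) * ((-2 * r1 + r_half) / 2) - r_half / 2
  stable <- tr < 0 & det > 0
  regime_label(invades, stable)
}

#' @export
print.outcome_probabilities <- function(x, ...) {
  cat(sprintf("<outcome_probabilities> %s (%s)\n",
              attr(x, "scenario"), attr(x, "method")))
  NextMethod()
}

#' Phase diagram over two colony-efficiency axes
#'
#' Evaluates the model over a dense grid of two efficiency values (all
#' other r fixed, `r_0 = 1` baseline) and returns a long tibble of grid
#' cells. Two diagram types:
#'
#' * `what = "invasion"`: one logical column `invades_n<k>` per requested
#'   mate number, from the dominance-appropriate invasion condition.
#' * `what = "regime"`: the full four-regime classification for a single
#'   mate number (columns `regime`, `invades`, `stable`).
#'
#' `axes` names the two varied z grid points, e.g. `c("1/4", "1/2")` for
#' the recessive invasion diagram or `c("1/2", "1")` for the single-mating
#' regime diagram. Any other r the conditions need is looked up from
#' `r_fixed`; r at the two axis z values always comes from the grid.
#'
#' @inheritParams required_z_grid
#' @param p named numeric vector or [phenotype_functions()] with every
#'   needed p value.
#' @param axes character of length 2: the z keys of the two varied r values
#'   (ascending z).
#' @param r_z1,r_z2 numeric vectors of axis values.
#' @param n_values mate numbers (`what = "invasion"`), or a single mate
#'   number (`what = "regime"`).
#' @param r_fixed named numeric vector of r values held fixed (baseline
#'   `r_0 = 1` is always included).
#' @param what `"regime"` or `"invasion"`.
#' @return tibble of class `phase_diagram` with columns `r_z1`, `r_z2` and
#'   the classification columns; attributes record axes and parameters.
#' @examples
#' pd <- phase_diagram(p = c("0" = 0.5), axes = c("1/2", "1"),
#'                     r_z1 = seq(0.9, 1.3, by = 0.1),
#'                     r_z2 = seq(0.9, 1.3, by = 0.1))
#' table(pd$regime)
#' @export
phase_diagram <- function(p, axes, r_z1, r_z2, n_values = 1,
                          dominance = c("recessive", "dominant"),
                          r_fixed = c("0" = 1),
                          what = c("regime", "invasion")) {
  dominance <- match.arg(dominance)
  what <- match.arg(what)
  if (length(axes) != 2L) abort("axes must name exactly two z grid points")
  axes <- parse_z(axes)
  if (z_value(axes[1]) >= z_value(axes[2])) abort("axes must be in ascending z order")
  if (!inherits(p, "phenotype_functions")) p <- phenotype_functions(p = p)
  r_fixed <- phen_table(r_fixed, "r")
  if (!("0" %in% names(r_fixed))) r_fixed <- c(r_fixed, "0" = 1)

  grid <- tidyr::expand_grid(r_z1 = r_z1, r_z2 = r_z2)
  r_lookup <- function(z) {
    z <- parse_z(z)
    if (z == axes[1]) return(grid$r_z1)
    if (z == axes[2]) return(grid$r_z2)
    if (z %in% names(r_fixed)) return(rep(r_fixed[[z]], nrow(grid)))
    abort(sprintf("r at z = %s is needed but is neither an axis nor in r_fixed", z))
  }

  invade_for <- function(n) {
    n <- check_n(n)
    if (dominance == "recessive") {
      z_inv <- z_key(1L, 2L * n)
      thr <- recessive_invasion_threshold(n, p_at(p, "0"), p_at(p, z_inv))
      r_lookup(z_inv) / r_fixed[["0"]] > thr
    } else {
      r0 <- r_fixed[["0"]]
      (r_lookup("1/2") / r0) *
        (1 + p_at(p, "1/2") * r_lookup(z_key(1L, n)) / r0) > 2
    }
  }

  if (what == "invasion") {
    for (n in n_values) grid[[paste0("invades_n", n)]] <- invade_for(n)
  } else {
    if (length(n_values) != 1L) abort("what = \"regime\" needs a single mate number")
    n <- check_n(n_values)
    grid$invades <- invade_for(n)
    if (dominance == "recessive") {
      z_prev <- z_key(n - 1L, n)
      a <- r_lookup(z_prev); pprev <- p_at(p, z_prev)
      b <- r_lookup("1/2"); r1 <- r_lookup("1")
      m11 <- (-2 * r1 + n * (1 - pprev) * a) / 2
      m22 <- (-2 * r1 + b) / 2
      grid$stable <- (m11 + m22) < 0 & (m11 * m22 - (n * b / 2) * (a / n)) > 0
    } else {
      z_prev <- z_key(2L * n - 1L, 2L * n)
      grid$stable <- r_lookup("1") / r_lookup(z_prev) >
        (2 + 3 * n - n * p_at(p, z_prev)) / (2 * (n + 1))
    }
    grid$regime <- factor(regime_label(grid$invades, grid$stable),
                          levels = regime_levels())
  }
  structure(grid, axes = axes, dominance = dominance, n_values = n_values,
            p = p, r_fixed = r_fixed, what = what,
            class = c("phase_diagram", class(grid)))
}

#' Analytic regime-boundary curves for the single-mating recessive diagram
#'
#' The two critical curves of the `(r_{1/2}, r_1)` plane: the vertical
#' invasion threshold on `r_{1/2}` and the stability boundary
#' `r_1 = lambda_max(K(r_{1/2}))` along which the dominant stability
#' eigenvalue vanishes.
#'
#' @param p0 queen's baseline male share.
#' @param r_half_range range of `r_{1/2}` over which to trace the curves.
#' @param length_out points per curve.
#' @return tibble with columns `curve`, `r_z1` (`r_{1/2}`), `r_z2` (`r_1`;
#'   `NA` along the vertical invasion boundary).
#' @export
regime_boundaries <- function(p0, r_half_range = c(0.5, 1.5),
                              length_out = 201L) {
  b <- seq(r_half_range[1], r_half_range[2], length.out = length_out)
  crit <- vapply(b, function(bi) {
    recessive_stability_critical_r1(1, p_prev = p0, r_prev = 1, r_half = bi)
  }, numeric(1))
  dplyr::bind_rows(
    tibble(curve = "invasion",
           r_z1 = recessive_invasion_threshold(1, p0), r_z2 = NA_real_),
    tibble(curve = "stability", r_z1 = b, r_z2 = crit)
  )
}
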