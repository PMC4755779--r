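#' Invasion threshold for a recessive sterility allele
#'
#' A rare recessive sterility allele invades the all-wild-type population
#' under n-fold mating if and only if the efficiency ratio
#' `r_{1/(2n)} / r_0` of the one colony type that then produces sterile
#' workers (an Aa queen with one mutant mating, sterile-worker fraction
#' 1/(2n)) to the baseline colony exceeds
#'
#' \deqn{\frac{2(2n-1)(2+n+n p_0)}{2n^2(2+p_0+p_{1/(2n)}) +
#'   n(3+3p_0-2p_{1/(2n)}) - 2(1+p_0)}}
#'
#' At n = 1 this reduces to `(6+2*p0)/(5+3*p0)` — the queen's baseline male
#' share `p0` is the only p that matters, because in Aa1 colonies queen and
#' workers both lay half A, half a males — and at n = 2 to
#' `(6+3*p0)/(5+3*p0+p14)`.
#'
#' @inheritParams required_z_grid
#' @param p0 queen's male share with no sterile workers (`p` at z = 0).
#' @param p_inv `p` at z = 1/(2n). Algebraically absent at n = 1 (any value
#'   gives the same threshold); required for n >= 2.
#' @return the critical value of `r_{1/(2n)} / r_0`.
#' @examples
#' recessive_invasion_threshold(1, p0 = 0)          # 6/5
#' recessive_invasion_threshold(2, p0 = 0.8, p_inv = 0.9)
#' @export
recessive_invasion_threshold <- function(n, p0, p_inv = NULL) {
  n <- check_n(n)
  if (is.null(p_inv)) {
    if (n > 1L) abort("p_inv (p at z = 1/(2n)) is required for n >= 2")
    p_inv <- p0
  }
  stopifnot(p0 >= 0, p0 <= 1, p_inv >= 0, p_inv <= 1)
  den <- 2 * n^2 * (2 + p0 + p_inv) + n * (3 + 3 * p0 - 2 * p_inv) -
    2 * (1 + p0)
  if (den <= 0) abort("degenerate parameters: non-positive threshold denominator")
  2 * (2 * n - 1) * (2 + n + n * p0) / den
}

new_condition_report <- function(condition, holds, margin, decisive,
                                 threshold = NA_real_, value = NA_real_,
                                 details = list()) {
  structure(list(condition = condition, holds = holds, margin = margin,
                 decisive = decisive, threshold = threshold, value = value,
                 details = details),
            class = "condition_report")
}

#' @export
print.condition_report <- function(x, ...) {
  cat(sprintf("<condition_report> %s: %s (margin %+.4g, decisive: %s)\n",
              x$condition, if (x$holds) "holds" else "does not hold",
              x$margin, x$decisive))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.condition_report <- function(x, ...) {
  tibble(condition = x$condition, holds = x$holds, margin = x$margin,
         decisive = x$decisive, threshold = x$threshold, value = x$value)
}

#' Invasion and stability conditions for a sterility allele
#'
#' `invasion_condition()` and `stability_condition()` dispatch on the
#' model's dominance mode; the four underlying tests are also exported.
#' All inequalities are strict: a boundary case (margin exactly 0, e.g. a
#' phenotypically silent allele with p = 1 and r = 1 everywhere) reports
#' `holds = FALSE`.
#'
#' * `recessive_invasion()`: closed form; margin is
#'   `r_{1/(2n)}/r_0 - recessive_invasion_threshold(...)`.
#' * `dominant_invasion()`: dominant eigenvalue of the 2x2 linearisation of
#'   the (AA,1; Aa,0) perturbation at the all-A state (a common positive
#'   factor `r_0^n` is dropped); the allele invades iff it is positive,
#'   which is algebraically the printed closed form
#'   `(r_{1/2}/r_0) (1 + p_{1/2} r_{1/n}/r_0) > 2` when the trace is
#'   negative — the implementation asserts that equivalence at every call.
#' * `recessive_stability()`: the all-a state resists re-invasion by the
#'   wild-type allele iff both eigenvalues of the 2x2 linearisation of the
#'   (aa,n-1; Aa,n) perturbation (factor `r_1^n` dropped) are negative,
#'   i.e. trace < 0 and determinant > 0; margin is minus the dominant
#'   eigenvalue's real part.
#' * `dominant_stability()`: closed form; margin is
#'   `r_1/r_{(2n-1)/(2n)} - (2 + 3n - n p_{(2n-1)/(2n)}) / (2(n+1))`.
#'
#' @inheritParams pool_matrix
#' @return a `condition_report` (see [tidy()] for a one-row tibble form).
#' @examples
#' m <- model_params(1, "recessive",
#'   phenotype_functions(p = c("0" = 0.5, "1/2" = 0.7),
#'                       r = c("1/2" = 1.0869, "1" = 1.1521)))
#' invasion_condition(m)
#' stability_condition(m)
#' @export
invasion_condition <- function(params) {
  stopifnot(inherits(params, "sterility_model"))
  if (params$dominance == "recessive") recessive_invasion(params)
  else dominant_invasion(params)
}

#' @rdname invasion_condition
#' @export
stability_condition <- function(params) {
  stopifnot(inherits(params, "sterility_model"))
  if (params$dominance == "recessive") recessive_stability(params)
  else dominant_stability(params)
}

#' @rdname invasion_condition
#' @export
recessive_invasion <- function(params) {
  stopifnot(inherits(params, "sterility_model"), params$dominance == "recessive")
  n <- params$n
  ph <- params$phenotypes
  thr <- recessive_invasion_threshold(n, p_at(ph, "0"), p_at(ph, z_key(1L, 2L * n)))
  ratio <- r_at(ph, z_key(1L, 2L * n)) / r_at(ph, "0")
  new_condition_report("recessive_invasion", holds = ratio > thr,
                       margin = ratio - thr, decisive = "closed_form",
                       threshold = thr, value = ratio)
}

# 2x2 perturbation Jacobians, with the common positive factor r_resident^n
# dropped (it never changes eigenvalue signs)
dominant_invasion_matrix <- function(n, p_half, r0, r_half, r_1n) {
  matrix(c(-r0, n * p_half * r_half / 2,
           r_1n / n, (-2 * r0 + r_half) / 2),
         nrow = 2, byrow = TRUE)
}

recessive_stability_matrix <- function(n, p_prev, r_prev, r_half, r1) {
  matrix(c((-2 * r1 + n * (1 - p_prev) * r_prev) / 2, n * r_half / 2,
           r_prev / n, (-2 * r1 + r_half) / 2),
         nrow = 2, byrow = TRUE)
}

eig2 <- function(M) {
  tr <- M[1, 1] + M[2, 2]
  det <- M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]
  disc <- tr^2 - 4 * det
  lambda_max <- if (disc >= 0) (tr + sqrt(disc)) / 2 else tr / 2
  list(trace = tr, det = det, lambda_max = lambda_max)
}

#' @rdname invasion_condition
#' @export
dominant_invasion <- function(params) {
  stopifnot(inherits(params, "sterility_model"), params$dominance == "dominant")
  n <- params$n
  ph <- params$phenotypes
  r0 <- r_at(ph, "0")
  r_half <- r_at(ph, "1/2")
  r_1n <- r_at(ph, z_key(1L, n))
  p_half <- p_at(ph, "1/2")
  e <- eig2(dominant_invasion_matrix(n, p_half, r0, r_half, r_1n))
  # closed-form equivalence: det < 0 <=> (r_half/r0)(1 + p_half r_1n/r0) > 2
  closed <- (r_half / r0) * (1 + p_half * r_1n / r0) - 2
  stopifnot(abs((-e$det * 2 / r0) - closed * r0) < 1e-9 * max(1, r0^2, abs(closed)))
  new_condition_report("dominant_invasion", holds = e$lambda_max > 0,
                       margin = e$lambda_max,
                       decisive = if (e$trace < 0) "determinant" else "trace",
                       threshold = 2, value = closed + 2,
                       details = e)
}

#' @rdname invasion_condition
#' @export
recessive_stability <- function(params) {
  stopifnot(inherits(params, "sterility_model"), params$dominance == "recessive")
  n <- params$n
  ph <- params$phenotypes
  z_prev <- z_key(n - 1L, n)
  M <- recessive_stability_matrix(n, p_at(ph, z_prev), r_at(ph, z_prev),
                                  r_at(ph, "1/2"), r_at(ph, "1"))
  e <- eig2(M)
  holds <- e$trace < 0 && e$det > 0
  decisive <- if (e$det <= 0) "determinant"
    else if (e$trace >= 0) "trace" else "determinant"
  new_condition_report("recessive_stability", holds = holds,
                       margin = -e$lambda_max, decisive = decisive,
                       details = e)
}

#' @rdname invasion_condition
#' @export
dominant_stability <- function(params) {
  stopifnot(inherits(params, "sterility_model"), params$dominance == "dominant")
  n <- params$n
  ph <- params$phenotypes
  z_prev <- z_key(2L * n - 1L, 2L * n)
  lhs <- r_at(ph, "1") / r_at(ph, z_prev)
  rhs <- (2 + 3 * n - n * p_at(ph, z_prev)) / (2 * (n + 1))
  new_condition_report("dominant_stability", holds = lhs > rhs,
                       margin = lhs - rhs, decisive = "closed_form",
                       threshold = rhs, value = lhs)
}

#' Critical colony efficiency r_1 for recessive-allele stability
#'
#' The all-sterile (all-a) state is stable iff the efficiency of fully
#' sterile colonies, `r_1`, exceeds a critical value determined by
#' `r_{1/2}`, `r_{(n-1)/n}` and `p_{(n-1)/n}`. The stability Jacobian has
#' the form `K - r_1 * I` with `K` independent of `r_1`, so its dominant
#' eigenvalue is strictly decreasing in `r_1` and the critical value is the
#' unique root, found by bracketed root-finding (tolerance `tol`) and
#' cross-checked internally against the closed-form positive root of
#' `(2 r_1 - n (1 - p) a)(2 r_1 - b) = 2 a b` with `a = r_{(n-1)/n}`,
#' `b = r_{1/2}`.
#'
#' @inheritParams required_z_grid
#' @param p_prev `p` at z = (n-1)/n (this is `p_0` when n = 1).
#' @param r_prev `r` at z = (n-1)/n (this is `r_0 = 1` baseline when n = 1).
#' @param r_half `r` at z = 1/2.
#' @param tol root-finding tolerance.
#' @return the critical `r_1`.
#' @examples
#' recessive_stability_critical_r1(1, p_prev = 0.6, r_prev = 1, r_half = 1.05)
#' @export
recessive_stability_critical_r1 <- function(n, p_prev, r_prev, r_half,
                                            tol = 1e-10) {
  n <- check_n(n)
  stopifnot(p_prev >= 0, p_prev <= 1, r_prev > 0, r_half > 0)
  f <- function(r1) {
    eig2(recessive_stability_matrix(n, p_prev, r_prev, r_half, r1))$lambda_max
  }
  upper <- 10 * max(r_half, r_prev, 1)
  if (f(1e-6) <= 0 || f(upper) >= 0) {
    abort("no positive critical r_1 in the search bracket")
  }
  root <- uniroot(f, c(1e-6, upper), tol = tol)$root
  # trace must be negative at the crossing (otherwise det = 0 there is a
  # complex-pair crossing and the det-based closed form would not apply)
  e <- eig2(recessive_stability_matrix(n, p_prev, r_prev, r_half, root))
  a <- r_prev; b <- r_half
  qa <- 4; qb <- -2 * (n * (1 - p_prev) * a + b)
  qc <- n * (1 - p_prev) * a * b - 2 * a * b
  disc <- qb^2 - 4 * qa * qc
  if (e$trace < 0 && disc >= 0) {
    closed <- (-qb + sqrt(disc)) / (2 * qa)
    stopifnot(abs(root - closed) < 1e-6 * max(1, closed))
  }
  root
}

#' Classify the four-regime outcome for a sterility allele
#'
#' Combines the dominance-appropriate invasion and stability conditions
#' into one of the four qualitative regimes of the selection dynamics:
#'
#' * `invades_and_stable`: the allele spreads from rarity and, once fixed,
#'   resists re-invasion (fixation of worker sterility).
#' * `invades_unstable_coexistence`: both alleles invade each other — the
#'   dynamics settle at an interior (polymorphic) attractor.
#' * `no_invade_stable_bistable`: neither monomorphic state can be invaded;
#'   the outcome depends on the initial condition.
#' * `no_invade_unstable`: the sterility allele neither invades nor, if
#'   fixed, persists.
#'
#' Boundary cases (margin exactly 0) resolve to the non-invading /
#' unstable side.
#'
#' @inheritParams pool_matrix
#' @return object of class `regime_classification`: list with `regime`
#'   (character), `invasion` and `stability` condition reports.
#' @examples
#' m <- model_params(1, "recessive",
#'   phenotype_functions(p = c("0" = 0.5, "1/2" = 0.7),
#'                       r = c("1/2" = 1.0869, "1" = 1.1521)))
#' classify_regime(m)$regime  # "invades_and_stable"
#' @export
classify_regime <- function(params) {
  inv <- invasion_condition(params)
  st <- stability_condition(params)
  regime <- regime_label(inv$holds, st$holds)
  structure(list(regime = regime, invasion = inv, stability = st,
                 params = params),
            class = "regime_classification")
}

regime_label <- function(invades, stable) {
  dplyr::case_when(
    invades & stable ~ "invades_and_stable",
    invades & !stable ~ "invades_unstable_coexistence",
    !invades & stable ~ "no_invade_stable_bistable",
    TRUE ~ "no_invade_unstable"
  )
}

#' All four regime labels in canonical order
#' @return character vector of length 4.
#' @export
regime_levels <- function() {
  c("no_invade_unstable", "no_invade_stable_bistable",
    "invades_unstable_coexistence", "invades_and_stable")
}

#' @export
print.regime_classification <- function(x, ...) {
  cat(sprintf("<regime_classification> %s\n", x$regime))
  cat(sprintf("  invasion : %s (margin %+.4g)\n",
              if (x$invasion$holds) "holds" else "does not hold",
              x$invasion$margin))
  cat(sprintf("  stability: %s (margin %+.4g)\n",
              if (x$stability$holds) "holds" else "does not hold",
              x$stability$margin))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.regime_classification <- function(x, ...) {
  tibble(
    regime = x$regime,
    invades = x$invasion$holds,
    invasion_margin = x$invasion$margin,
    stable = x$stability$holds,
    stability_margin = x$stability$margin,
    n = x$params$n,
    dominance = x$params$dominance
  )
}
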