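test_that("efficiency sampling has the stated moments and correlation", {
  proc <- sampling_procedure(sigma = 0.1, rho = 0, n_samples = 2e5, seed = 101)
  d <- sample_efficiency_pairs(proc)
  se_mean <- 0.1 / sqrt(proc$n_samples)
  expect_lt(abs(mean(d$r_z1) - 1), 4 * se_mean)
  expect_lt(abs(mean(d$r_z2) - 1), 4 * se_mean)
  expect_lt(abs(stats::sd(d$r_z1) - 0.1), 4 * se_mean)
  expect_lt(abs(stats::cor(d$r_z1, d$r_z2)), 4 / sqrt(proc$n_samples))
  proc2 <- sampling_procedure(sigma = 0.2, rho = 0.8, n_samples = 2e5,
                              seed = 102)
  d2 <- sample_efficiency_pairs(proc2)
  expect_lt(abs(stats::cor(d2$r_z1, d2$r_z2) - 0.8), 4 / sqrt(proc2$n_samples))
  # degenerate or out-of-range procedures are rejected
  expect_error(sampling_procedure(sigma = 0), "positive")
  expect_error(sampling_procedure(sigma = 0.1, rho = 1), "between")
})

test_that("identical procedures give bit-identical draws", {
  proc <- sampling_procedure(sigma = 0.2, rho = 0.8, n_samples = 1e4, seed = 7)
  expect_identical(sample_efficiency_pairs(proc), sample_efficiency_pairs(proc))
})

test_that("the bivariate normal CDF reduces and integrates correctly", {
  expect_equal(pbvnorm(0.7, -0.2, 0), pnorm(0.7) * pnorm(-0.2))
  # perfect symmetry and monotonicity in rho at the origin:
  # P(Z1<0, Z2<0) = 1/4 + asin(rho)/(2 pi)
  for (rho in c(-0.5, 0.3, 0.8)) {
    expect_equal(pbvnorm(0, 0, rho), 1 / 4 + asin(rho) / (2 * pi),
                 tolerance = 1e-7)
  }
  # Monte-Carlo cross-check
  set.seed(31)
  d <- sample_efficiency_pairs(sampling_procedure(sigma = 1, rho = 0.6,
                                                  n_samples = 2e5))
  mc <- mean(d$r_z1 - 1 < 0.5 & d$r_z2 - 1 < 1.0)
  expect_lt(abs(pbvnorm(0.5, 1.0, 0.6) - mc), 4 * sqrt(0.25 / 2e5))
})

test_that("analytic and Monte-Carlo invasion probabilities agree", {
  p <- c("0" = 0.2, "1/4" = 0.4)
  proc_mc <- sampling_procedure(sigma = 0.1, n_samples = 4e5, seed = 11)
  ana <- invasion_outcome_probabilities("recessive", p, proc_mc, "analytic")
  mc <- invasion_outcome_probabilities("recessive", p, proc_mc, "monte_carlo")
  expect_equal(sum(ana$probability), 1, tolerance = 1e-9)
  expect_equal(sum(mc$probability), 1, tolerance = 1e-12)
  for (i in 1:4) {
    tol <- 3 * sqrt(ana$probability[i] * (1 - ana$probability[i]) /
                      proc_mc$n_samples)
    expect_lt(abs(ana$probability[i] - mc$probability[i]), max(tol, 1e-4))
  }
  expect_identical(attr(ana, "method"), "analytic")
  expect_identical(attr(mc, "method"), "monte_carlo")
})

test_that("correlated analytic probabilities satisfy inclusion-exclusion", {
  p <- c("0" = 0.2, "1/4" = 0.4)
  proc <- sampling_procedure(sigma = 0.1, rho = 0.8)
  out <- invasion_outcome_probabilities("recessive", p, proc, "analytic")
  c2 <- recessive_invasion_threshold(1, 0.2)
  c1 <- recessive_invasion_threshold(2, 0.2, 0.4)
  # marginals recovered from the four cells
  expect_equal(out$probability[1] + out$probability[3],
               pnorm((c2 - 1) / 0.1), tolerance = 2e-4)
  expect_equal(out$probability[1] + out$probability[2],
               pnorm((c1 - 1) / 0.1), tolerance = 2e-4)
  expect_equal(sum(out$probability), 1, tolerance = 1e-7)
})

test_that("the dominant scenario runs by Monte Carlo (with analytic fallback warning)", {
  p <- c("1/2" = 0.5)
  proc <- sampling_procedure(sigma = 0.2, n_samples = 1e5, seed = 5)
  expect_warning(
    out <- invasion_outcome_probabilities("dominant", p, proc, "analytic"),
    "falling back")
  expect_identical(attr(out, "method"), "monte_carlo")
  expect_equal(sum(out$probability), 1)
  # direct reclassification of the same draws
  d <- sample_efficiency_pairs(proc)
  inv1 <- d$r_z1 * (1 + 0.5 * d$r_z2) > 2
  inv2 <- d$r_z1 * (1 + 0.5 * d$r_z1) > 2
  expect_equal(out$probability[4], mean(inv1 & inv2))
})

test_that("regime probabilities match pointwise classification", {
  proc <- sampling_procedure(sigma = 0.2, n_samples = 2e4, seed = 19)
  out <- regime_outcome_probabilities(c("0" = 0.5), proc)
  expect_equal(sum(out$probability), 1)
  # marginal invasion probability equals the univariate normal tail
  thr <- recessive_invasion_threshold(1, 0.5)
  p_inv <- sum(out$probability[3:4])
  expect_lt(abs(p_inv - (1 - pnorm((thr - 1) / 0.2))),
            3 * sqrt(0.25 / proc$n_samples))
  # the vectorised classifier agrees with classify_regime() on a subsample
  d <- sample_efficiency_pairs(proc)[1:40, ]
  keep <- d$r_z1 > 0 & d$r_z2 > 0
  for (i in which(keep)) {
    expect_identical(
      haplosterile:::classify_regime_vec(d$r_z1[i], d$r_z2[i], 0.5),
      classify_regime(model_n1(d$r_z1[i], d$r_z2[i]))$regime
    )
  }
  expect_error(regime_outcome_probabilities(c("0" = 0.5), proc, n = 2),
               "single-mating")
})

test_that("phase diagrams agree with the scalar thresholds on every row", {
  pd <- phase_diagram(p = c("0" = 0.2, "1/4" = 0.4, "1/2" = 0.6),
                      axes = c("1/4", "1/2"),
                      r_z1 = seq(0.95, 1.35, by = 0.05),
                      r_z2 = seq(0.95, 1.35, by = 0.05),
                      n_values = c(1, 2), what = "invasion")
  c2 <- recessive_invasion_threshold(1, 0.2)
  c1 <- recessive_invasion_threshold(2, 0.2, 0.4)
  expect_equal(pd$invades_n1, pd$r_z2 > c2)  # vertical boundary in r_z2
  expect_equal(pd$invades_n2, pd$r_z1 > c1)  # independent of the other axis
  # regime grid: single cell equals classify_regime
  pd1 <- phase_diagram(p = c("0" = 0.5, "1/2" = 0.75), axes = c("1/2", "1"),
                       r_z1 = 1.0869, r_z2 = 1.1521, what = "regime")
  expect_equal(nrow(pd1), 1)
  expect_identical(as.character(pd1$regime),
                   classify_regime(model_n1(1.0869, 1.1521))$regime)
  # n = 2 regime over (r_{1/2}, r_1): invasion needs r at 1/4, which is
  # neither an axis nor fixed
  expect_error(phase_diagram(p = c("0" = 0.5, "1/4" = 0.6, "1/2" = 0.7),
                             axes = c("1/2", "1"),
                             r_z1 = 1, r_z2 = 1, what = "regime",
                             n_values = 2),
               "needed but")
})

test_that("the critical curves intersect where the worked example says", {
  bd <- regime_boundaries(0.5, r_half_range = c(1.0, 1.2), length_out = 41)
  vert <- bd$r_z1[bd$curve == "invasion"]
  expect_equal(vert, 7 / 6.5, tolerance = 1e-12)
  stab <- bd[bd$curve == "stability", ]
  r1_at_vert <- stats::approx(stab$r_z1, stab$r_z2, xout = vert)$y
  # frozen from the closed-form quadratic: the positive root of
  # (2 r1 - 0.5)(2 r1 - 7/6.5) = 14/6.5 is 1.14207
  expect_equal(r1_at_vert, 1.14207, tolerance = 0.002)
  # as p0 -> 1 the intersection approaches (1, 1)
  bd9 <- regime_boundaries(0.99, r_half_range = c(0.99, 1.05), length_out = 21)
  v9 <- bd9$r_z1[bd9$curve == "invasion"]
  s9 <- bd9[bd9$curve == "stability", ]
  expect_lt(abs(v9 - 1), 0.01)
  expect_lt(abs(stats::approx(s9$r_z1, s9$r_z2, xout = v9)$y - 1), 0.02)
})
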