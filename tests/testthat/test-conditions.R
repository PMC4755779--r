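test_that("recessive invasion thresholds reproduce the worked values", {
  expect_equal(recessive_invasion_threshold(1, p0 = 0), 6 / 5)
  expect_equal(round(recessive_invasion_threshold(1, p0 = 0.8), 3), 1.027)
  expect_equal(round(recessive_invasion_threshold(2, p0 = 0.8, p_inv = 0.9), 3),
               1.012)
  expect_equal(recessive_invasion_threshold(1, p0 = 0.5), 7 / 6.5)
  # neutral boundary: threshold 1 when p is 1 everywhere
  for (n in 1:10) {
    expect_equal(recessive_invasion_threshold(n, 1, 1), 1)
  }
  expect_error(recessive_invasion_threshold(2, 0.5), "p_inv")
})

test_that("the general-n threshold reduces exactly to the n = 1 and 2 forms", {
  set.seed(3)
  for (k in 1:1000) {
    p0 <- runif(1)
    pi <- runif(1)
    expect_equal(recessive_invasion_threshold(1, p0, pi),
                 (6 + 2 * p0) / (5 + 3 * p0), tolerance = 1e-14)
    expect_equal(recessive_invasion_threshold(2, p0, pi),
                 (6 + 3 * p0) / (5 + 3 * p0 + pi), tolerance = 1e-14)
  }
})

test_that("the queen's male share at z = 1/2 never affects n = 1 invasion", {
  for (ph in seq(0, 1, by = 0.1)) {
    rep1 <- recessive_invasion(model_n1(1.0869, 1.1521, p_half = ph))
    rep2 <- recessive_invasion(model_n1(1.0869, 1.1521, p_half = 0.5))
    expect_equal(rep1$margin, rep2$margin)
    expect_identical(rep1$holds, rep2$holds)
  }
})

test_that("invasion margins are strict and signed as documented", {
  rep <- recessive_invasion(model_n1(1.0869, 1.1521))
  expect_true(rep$holds)
  expect_equal(rep$margin, 1.0869 - 7 / 6.5, tolerance = 1e-12)
  # worked no-invade case: r_{1/2} = 0.6
  expect_false(recessive_invasion(model_n1(0.6, 0.9))$holds)
  # exact boundary classifies as not holding
  m <- model_params(2, "recessive", phenotype_functions(
    p = c("0" = 0.2, "1/4" = 0.4, "1/2" = 0.6),
    r = c("1/4" = 1.1, "1/2" = 1.0, "1" = 1.0)))
  b <- recessive_invasion(m)
  expect_equal(b$margin, 0, tolerance = 1e-15)
  expect_false(b$holds)
})

test_that("recessive stability critical r_1 reproduces the worked values", {
  expect_equal(round(recessive_stability_critical_r1(
    1, p_prev = 0.6, r_prev = 1, r_half = 1.05), 3), 1.105)
  expect_equal(round(recessive_stability_critical_r1(
    2, p_prev = 0.9, r_prev = 1.05, r_half = 1.05), 3), 1.087)
  # neutral boundary
  expect_equal(recessive_stability_critical_r1(1, 1, 1, 1), 1,
               tolerance = 1e-9)
  # root-found value agrees with the closed-form quadratic root
  set.seed(17)
  for (k in 1:50) {
    n <- sample(1:3, 1)
    p <- runif(1)
    a <- runif(1, 0.5, 1.5)
    b <- runif(1, 0.5, 1.5)
    root <- recessive_stability_critical_r1(n, p, a, b)
    qroot <- (2 * (n * (1 - p) * a + b) +
                sqrt(4 * (n * (1 - p) * a + b)^2 -
                       16 * (n * (1 - p) * a * b - 2 * a * b))) / 8
    expect_equal(root, qroot, tolerance = 1e-7)
  }
})

test_that("stability reports flip exactly at the critical r_1", {
  mk <- function(r1) model_params(1, "recessive", phenotype_functions(
    p = c("0" = 0.6, "1/2" = 0.8), r = c("1/2" = 1.05, "1" = r1)))
  crit <- recessive_stability_critical_r1(1, 0.6, 1, 1.05)
  expect_true(recessive_stability(mk(crit + 1e-6))$holds)
  expect_false(recessive_stability(mk(crit - 1e-6))$holds)
  # worked example: stable although both efficiencies are below 1
  expect_true(recessive_stability(model_n1(0.6, 0.9))$holds)
})

test_that("dominant invasion equals its closed form via the determinant", {
  mk <- function(p_half, r_half, r1, n = 1) {
    grid <- required_z_grid(n, "dominant")
    p <- setNames(rep(p_half, length(grid)), grid); p["1"] <- 1
    r <- setNames(rep(1, length(grid)), grid)
    r["1/2"] <- r_half; r["1"] <- r1
    if (n == 2) r["1/2"] <- r_half
    model_params(n, "dominant", phenotype_functions(p = p, r = r))
  }
  # direct worked substitutions into the closed form
  expect_true(dominant_invasion(mk(0.5, 1.5, 1.0))$holds)   # 1.5*1.5 > 2
  expect_false(dominant_invasion(mk(0.5, 1.2, 1.2, n = 2))$holds) # 1.92 < 2
  expect_false(dominant_invasion(mk(1.0, 1.0, 1.0))$holds)  # boundary
  # determinant-sign equivalence over random parameters
  set.seed(23)
  for (k in 1:200) {
    n <- sample(1:3, 1)
    m <- mk(runif(1), runif(1, 0.5, 2.5), runif(1, 0.5, 2.5), n = 1)
    rep <- dominant_invasion(m)
    closed_holds <- rep$value > 2
    if (rep$details$trace < 0) {
      expect_identical(rep$holds, closed_holds)
    }
  }
})

test_that("dominant stability threshold matches its printed closed form", {
  mk <- function(p_prev, r_prev, r1, n = 1) {
    grid <- required_z_grid(n, "dominant")
    p <- setNames(rep(p_prev, length(grid)), grid); p["1"] <- 1
    r <- setNames(rep(1, length(grid)), grid)
    r[z_key(2 * n - 1, 2 * n)] <- r_prev; r["1"] <- r1
    model_params(n, "dominant", phenotype_functions(p = p, r = r))
  }
  # n = 1: threshold is (5 - p_{1/2})/4 on r_1/r_{1/2}
  expect_true(dominant_stability(mk(0.5, 1.0, 1.2))$holds)   # 1.2 > 1.125
  expect_false(dominant_stability(mk(0.5, 1.0, 1.1))$holds)
  st <- dominant_stability(mk(0.3, 1.1, 1.4))
  expect_equal(st$threshold, (5 - 0.3) / 4)
  expect_equal(st$value, 1.4 / 1.1)
})

test_that("all four conditions sit exactly on their thresholds for a silent allele", {
  for (n in 1:10) {
    rec <- neutral_model(n, "recessive")
    dom <- neutral_model(n, "dominant")
    for (rep in list(recessive_invasion(rec), recessive_stability(rec),
                     dominant_invasion(dom), dominant_stability(dom))) {
      expect_equal(rep$margin, 0, tolerance = 1e-12)
      expect_false(rep$holds)
    }
  }
})

test_that("raising r_{1/2} never revokes n = 1 recessive invasion", {
  for (p0 in c(0, 0.3, 0.7, 0.95)) {
    reports <- vapply(seq(0.9, 1.6, by = 0.01), function(rh) {
      recessive_invasion(model_n1(rh, 1.1, p0 = p0))$holds
    }, logical(1))
    expect_false(is.unsorted(reports)) # FALSE..FALSE TRUE..TRUE
  }
})

test_that("the four simulation panels classify into four distinct regimes", {
  mods <- panel_models()
  labels <- vapply(mods, function(m) classify_regime(m)$regime, character(1))
  expect_identical(unname(labels["invades_and_stable"]), "invades_and_stable")
  expect_identical(unname(labels["coexistence"]), "invades_unstable_coexistence")
  expect_identical(unname(labels["bistable"]), "no_invade_stable_bistable")
  expect_identical(unname(labels["unstable_no_invade"]), "no_invade_unstable")
  expect_equal(length(unique(labels)), 4)
  # worked bistable case with both efficiencies below 1
  expect_identical(classify_regime(model_n1(0.6, 0.9))$regime,
                   "no_invade_stable_bistable")
})

test_that("tidiers return one-row summaries", {
  cls <- classify_regime(model_n1(1.0869, 1.1521))
  expect_equal(nrow(tidy(cls)), 1)
  expect_true(tidy(cls)$invades)
  expect_named(tidy(invasion_condition(model_n1(1.1, 1.1))),
               c("condition", "holds", "margin", "decisive", "threshold",
                 "value"))
})
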