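# Shared model fixtures, built in code.

# single-mating recessive model with arbitrary-but-valid p_{1/2}
# (it cancels for Aa1 colonies, so it never affects n = 1 results)
model_n1 <- function(r_half, r_1, p0 = 0.5, p_half = 0.75) {
  model_params(1, "recessive", phenotype_functions(
    p = c("0" = p0, "1/2" = p_half),
    r = c("1/2" = r_half, "1" = r_1)
  ))
}

# the four parameter sets of the single-mating simulation panels
panel_models <- function() {
  list(
    invades_and_stable = model_n1(1.0869, 1.1521),
    coexistence = model_n1(1.0869, 1.1321),
    bistable = model_n1(1.0669, 1.1521),
    unstable_no_invade = model_n1(1.0669, 1.1321)
  )
}

# phenotypically silent allele: p = 1 and r = 1 at every required z
neutral_model <- function(n, dominance) {
  grid <- required_z_grid(n, dominance)
  model_params(n, dominance, phenotype_functions(
    p = setNames(rep(1, length(grid)), grid),
    r = setNames(rep(1, length(grid)), grid)
  ))
}

# random full phenotype tables on the required grid
random_model <- function(n, dominance, r_lo = 0.8, r_hi = 1.4) {
  grid <- required_z_grid(n, dominance)
  p <- stats::runif(length(grid))
  r <- stats::runif(length(grid), r_lo, r_hi)
  names(p) <- names(r) <- grid
  p["1"] <- 1
  model_params(n, dominance, phenotype_functions(p = p, r = r))
}

# random point on the colony-type simplex
random_simplex_state <- function(n) {
  x <- stats::rexp(3 * (n + 1))
  population_state(x / sum(x), n)
}

expect_fraction_equal <- function(object, expected) {
  expect_identical(parse_z(object), parse_z(expected))
}
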