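#' Mating-pool abundances from a population of colonies
#'
#' Each colony type contributes gynes and drones to the population-wide
#' mating pools in proportion to its frequency, scaled by its colony
#' efficiency r_z, with queen-laid males weighted by the queen's male share
#' p_z and worker-laid males by 1 - p_z. The five pools (gynes x_AA, x_Aa,
#' x_aa and drones y_A, y_a, in rescaled units) are linear in the state:
#' `gamete_pools(state) == pool_matrix(params) %*% state`.
#'
#' @param params a [model_params()] object.
#' @param state numeric vector of colony-type frequencies in the canonical
#'   order of [colony_types()] (named or unnamed, length 3(n+1)).
#' @return `pool_matrix()`: a 5 x 3(n+1) matrix with rows `x_AA`, `x_Aa`,
#'   `x_aa`, `y_A`, `y_a` and colony-type labels as column names.
#'   `gamete_pools()`: a named numeric vector of the five pool abundances.
#' @examples
#' m <- model_params(1, "recessive",
#'   phenotype_functions(p = c("0" = 0.5, "1/2" = 0.7),
#'                       r = c("1/2" = 1.0869, "1" = 1.1521)))
#' gamete_pools(pure_state(1, "A"), m)
#' @export
pool_matrix <- function(params) {
  stopifnot(inherits(params, "sterility_model"))
  n <- params$n
  ct <- colony_types(n)
  off <- offspring_table(n, params$dominance)
  z <- sterile_fraction(as.character(ct$queen), ct$m, n, params$dominance)
  rz <- r_at(params$phenotypes, z)
  pz <- p_at(params$phenotypes, z)
  P <- matrix(0, nrow = 5L, ncol = nrow(ct),
              dimnames = list(c("x_AA", "x_Aa", "x_aa", "y_A", "y_a"), ct$label))
  for (i in seq_len(nrow(ct))) {
    rows <- off[off$queen == as.character(ct$queen[i]) & off$m == ct$m[i], ]
    fem <- rows[rows$caste == "queen_female", ]
    P[paste0("x_", fem$genotype), i] <- rz[i] * fem$prop
    qm <- rows[rows$caste == "queen_male", ]
    wm <- rows[rows$caste == "worker_male", ]
    male <- c(A = 0, a = 0)
    male[qm$genotype] <- male[qm$genotype] + pz[i] * qm$prop
    if (nrow(wm) > 0) {
      male[wm$genotype] <- male[wm$genotype] + (1 - pz[i]) * wm$prop
    } else {
      # no reproductive workers: all males are queen-laid (z = 1, p_1 = 1)
      male[qm$genotype] <- male[qm$genotype] + (1 - pz[i]) * qm$prop
    }
    P["y_A", i] <- rz[i] * male[["A"]]
    P["y_a", i] <- rz[i] * male[["a"]]
  }
  P
}

#' @rdname pool_matrix
#' @export
gamete_pools <- function(state, params) {
  P <- pool_matrix(params)
  state <- check_state(state, params$n)
  drop(P %*% state)
}

check_state <- function(state, n, tol = 1e-9) {
  k <- 3L * (n + 1L)
  if (length(state) != k) {
    abort(sprintf("state must have length 3(n+1) = %d", k))
  }
  labels <- colony_types(n)$label
  if (!is.null(names(state))) {
    miss <- setdiff(labels, names(state))
    if (length(miss) > 0) {
      abort(sprintf("state is missing colony type(s): %s", paste(miss, collapse = ", ")))
    }
    state <- state[labels]
  } else {
    names(state) <- labels
  }
  if (any(state < -tol)) abort("state frequencies must be non-negative")
  if (abs(sum(state) - 1) > tol) {
    abort(sprintf("state frequencies must sum to 1 (got %.12f)", sum(state)))
  }
  pmax(state, 0)
}

#' Population states on the colony-frequency simplex
#'
#' `population_state()` validates and canonically orders a frequency
#' vector. `pure_state()` returns the two monomorphic equilibria (all-A:
#' only AA queens mated to A males; all-a: only aa queens mated to a males).
#' `invasion_state()` and `stability_state()` are the perturbed initial
#' conditions used throughout: a resident population with an infinitesimal
#' frequency epsilon of queens that made one mating with the other type.
#'
#' @param x named or canonically ordered numeric frequency vector.
#' @inheritParams required_z_grid
#' @param allele `"A"` (wild-type resident) or `"a"` (sterility-allele
#'   resident) for `pure_state()`.
#' @param epsilon perturbation size in (0, 0.05].
#' @return named numeric vector over colony-type labels, summing to 1.
#' @examples
#' invasion_state(1, 1e-2) # AA0 = 0.99, AA1 = 0.01
#' @export
population_state <- function(x, n) check_state(x, n)

#' @rdname population_state
#' @export
pure_state <- function(n, allele = c("A", "a")) {
  n <- check_n(n)
  allele <- match.arg(allele)
  labels <- colony_types(n)$label
  x <- setNames(numeric(length(labels)), labels)
  x[if (allele == "A") "AA0" else paste0("aa", n)] <- 1
  x
}

#' @rdname population_state
#' @export
invasion_state <- function(n, epsilon) {
  check_epsilon(epsilon)
  x <- pure_state(n, "A")
  x["AA0"] <- 1 - epsilon
  x["AA1"] <- epsilon
  x
}

#' @rdname population_state
#' @export
stability_state <- function(n, epsilon) {
  check_epsilon(epsilon)
  x <- pure_state(n, "a")
  x[paste0("aa", n)] <- 1 - epsilon
  x[paste0("aa", n - 1L)] <- epsilon
  x
}

check_epsilon <- function(epsilon) {
  if (length(epsilon) != 1L || is.na(epsilon) || epsilon <= 0 || epsilon > 0.05) {
    abort("epsilon must be a single value in (0, 0.05]")
  }
  invisible(epsilon)
}
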