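#' Queen male-share and colony-efficiency tables
#'
#' The model is driven by two colony-level phenotype functions of the
#' sterile-worker fraction z: `p` (fraction of a colony's male eggs laid by
#' the queen; by definition `p[1] = 1` because with every worker sterile all
#' males are queen-laid) and `r` (the colony's reproductive rate, normalised
#' so that `r[0] = 1` unless another baseline is given explicitly). Both are
#' supplied as tables over the exact fractions z required by the model (see
#' [required_z_grid()]).
#'
#' Values may be given as named numeric vectors (names are fraction keys
#' such as `"1/4"`, or exactly-representable decimals) or as two-column data
#' frames with columns `z` and `p` (or `r`). Monotonicity of `p` is a
#' natural biological assumption but is not required; opt in with
#' `check_monotone_p = TRUE`.
#'
#' @param p,r named numeric vectors or data frames (columns `z` and
#'   `p`/`r`) giving the two phenotype tables.
#' @param check_monotone_p if `TRUE`, require `p` to be non-decreasing in z.
#' @return An object of class `phenotype_functions`: a list with named
#'   numeric vectors `p` and `r`, names being canonical fraction keys.
#' @examples
#' phenotype_functions(p = c("0" = 0.5), r = c("1/2" = 1.09, "1" = 1.15))
#' @export
phenotype_functions <- function(p = NULL, r = NULL, check_monotone_p = FALSE) {
  p <- phen_table(p, "p")
  r <- phen_table(r, "r")
  if ("1" %in% names(p)) {
    if (p[["1"]] != 1) {
      abort("p at z = 1 must equal 1: with all workers sterile every male is queen-laid")
    }
  } else {
    p <- c(p, "1" = 1)
  }
  if (!("0" %in% names(r))) r <- c(r, "0" = 1) # default baseline normalisation
  if (any(p < 0 | p > 1)) abort("p values must lie in [0, 1]")
  if (any(r <= 0)) abort("r values must be positive")
  p <- p[order(z_value(names(p)))]
  r <- r[order(z_value(names(r)))]
  if (check_monotone_p && is.unsorted(p)) {
    abort("p is not a non-decreasing function of z (check_monotone_p = TRUE)")
  }
  structure(list(p = p, r = r), class = "phenotype_functions")
}

phen_table <- function(x, what) {
  if (is.null(x)) return(setNames(numeric(0), character(0)))
  if (is.data.frame(x)) {
    if (!all(c("z", what) %in% names(x))) {
      abort(sprintf("data-frame input for %s needs columns 'z' and '%s'", what, what))
    }
    x <- setNames(x[[what]], x[["z"]])
  }
  if (!is.numeric(x) || is.null(names(x)) || any(names(x) == "")) {
    abort(sprintf("%s must be a named numeric vector or a data frame", what))
  }
  keys <- parse_z(names(x))
  if (anyDuplicated(keys)) {
    abort(sprintf("duplicate z keys in %s table: %s", what,
                  paste(keys[duplicated(keys)], collapse = ", ")))
  }
  setNames(as.numeric(x), keys)
}

#' @export
print.phenotype_functions <- function(x, ...) {
  cat("<phenotype_functions>\n")
  print(tidy(x), ...)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.phenotype_functions <- function(x, ...) {
  zs <- union(names(x$p), names(x$r))
  zs <- zs[order(z_value(zs))]
  tibble(
    z = zs,
    p = unname(x$p[zs]),
    r = unname(x$r[zs])
  )
}

lookup_phen <- function(ph, what, z) {
  tab <- ph[[what]]
  miss <- setdiff(z, names(tab))
  if (length(miss) > 0) {
    abort(sprintf("phenotype table '%s' is missing required z value(s): %s",
                  what, paste(sort(unique(miss)), collapse = ", ")))
  }
  unname(tab[z])
}

#' Evaluate the phenotype tables at given sterile fractions
#'
#' @param ph a [phenotype_functions()] object.
#' @param z character vector of fraction keys (or values [parse_z()] accepts).
#' @return numeric vector of table values; an error names any missing key.
#' @export
p_at <- function(ph, z) lookup_phen(ph, "p", parse_z(z))

#' @rdname p_at
#' @export
r_at <- function(ph, z) lookup_phen(ph, "r", parse_z(z))

#' Sterile fractions required by a model configuration
#'
#' Every z at which the gamete-pool sums evaluate `p` or `r` for mate number
#' `n`. For a recessive sterility allele these are 0, m/(2n) and m/n for
#' m = 0..n; for a dominant allele m/n, (m+n)/(2n) and 1. Both always
#' contain 0 and 1.
#'
#' @param n integer mate number of the queen, `n >= 1`.
#' @param dominance `"recessive"` or `"dominant"`.
#' @return character vector of canonical fraction keys, ascending in value.
#' @examples
#' required_z_grid(2, "recessive") # "0" "1/4" "1/2" "1"
#' @export
required_z_grid <- function(n, dominance = c("recessive", "dominant")) {
  n <- check_n(n)
  dominance <- match.arg(dominance)
  m <- 0:n
  zs <- if (dominance == "recessive") {
    c(z_key(0L, 1L), z_key(m, 2L * n), z_key(m, n))
  } else {
    c(z_key(m, n), z_key(m + n, 2L * n), z_key(1L, 1L))
  }
  zs <- unique(zs)
  zs[order(z_value(zs))]
}

check_n <- function(n, max_n = 20L) {
  if (length(n) != 1L || is.na(n) || n < 1 || n != round(n)) {
    abort("the mate number n must be a single integer >= 1")
  }
  if (n > max_n) {
    abort(sprintf("n = %d exceeds the supported maximum of %d matings (raise max_n to override)",
                  as.integer(n), as.integer(max_n)))
  }
  as.integer(n)
}

#' Colony types for n matings
#'
#' A colony is labelled by its queen's genotype (AA, Aa or aa) and the
#' number m of her n matings that were with mutant (a) males; there are
#' exactly 3(n+1) types, in the canonical order AA,0..n; Aa,0..n; aa,0..n.
#'
#' @inheritParams required_z_grid
#' @return tibble with columns `queen` (factor AA < Aa < aa), `m`, `n` and
#'   `label` (e.g. `"Aa1"`).
#' @export
colony_types <- function(n) {
  n <- check_n(n)
  queen <- factor(rep(c("AA", "Aa", "aa"), each = n + 1L),
                  levels = c("AA", "Aa", "aa"))
  m <- rep(0:n, times = 3L)
  tibble(queen = queen, m = m, n = n, label = paste0(queen, m))
}

#' Sterile-worker fraction of a colony type
#'
#' For a recessive allele only aa workers are sterile, so z is the colony's
#' aa-worker fraction: 0 for AA-queen colonies, m/(2n) for Aa-queen
#' colonies, m/n for aa-queen colonies. For a dominant allele Aa workers
#' are sterile too: m/n, (m+n)/(2n) and 1 respectively. Exact fractions.
#'
#' @param queen character vector of queen genotypes (`"AA"`, `"Aa"`, `"aa"`).
#' @param m integer vector, number of matings with mutant males, `0 <= m <= n`.
#' @inheritParams required_z_grid
#' @return character vector of canonical fraction keys.
#' @examples
#' sterile_fraction("Aa", 1, 1, "recessive") # "1/2"
#' @export
sterile_fraction <- function(queen, m, n, dominance = c("recessive", "dominant")) {
  n <- check_n(n)
  dominance <- match.arg(dominance)
  queen <- as.character(queen)
  if (!all(queen %in% c("AA", "Aa", "aa"))) abort("queen must be AA, Aa or aa")
  m <- as.integer(m)
  if (any(m < 0L | m > n)) abort("m must satisfy 0 <= m <= n")
  if (length(m) != length(queen)) abort("queen and m must have equal length")
  if (dominance == "recessive") {
    num <- ifelse(queen == "AA", 0L, ifelse(queen == "Aa", m, 2L * m))
  } else {
    num <- ifelse(queen == "AA", 2L * m, ifelse(queen == "Aa", m + n, 2L * n))
  }
  z_key(num, rep(2L * n, length(num)))
}

#' Model configuration: matings, dominance and phenotype tables
#'
#' Bundles the mate number n, the dominance mode of the sterility allele and
#' the phenotype tables, after checking that the tables cover every z the
#' model evaluates (see [required_z_grid()]). The per-capita constants of
#' the unscaled model (gyne and drone viability, carrying capacity) are
#' eliminated by rescaling and fixed to 1; only ratios of r values and the
#' p values matter.
#'
#' @inheritParams required_z_grid
#' @param phenotypes a [phenotype_functions()] object, or a list with
#'   elements `p` and `r` passed on to [phenotype_functions()].
#' @param max_n cap on the supported mate number (tables have 3(n+1) colony
#'   types; the default cap of 20 bounds their size).
#' @return object of class `sterility_model`.
#' @examples
#' model_params(1, "recessive",
#'   phenotype_functions(p = c("0" = 0.5, "1/2" = 0.7),
#'                       r = c("1/2" = 1.0869, "1" = 1.1521)))
#' @export
model_params <- function(n, dominance = c("recessive", "dominant"),
                         phenotypes, max_n = 20L) {
  n <- check_n(n, max_n)
  dominance <- match.arg(dominance)
  if (!inherits(phenotypes, "phenotype_functions")) {
    phenotypes <- phenotype_functions(p = phenotypes$p, r = phenotypes$r)
  }
  grid <- required_z_grid(n, dominance)
  for (what in c("p", "r")) {
    miss <- setdiff(grid, names(phenotypes[[what]]))
    if (length(miss) > 0) {
      abort(sprintf(
        "phenotype table '%s' is missing required z value(s) for n = %d (%s allele): %s",
        what, n, dominance, paste(miss, collapse = ", ")
      ))
    }
  }
  structure(list(n = n, dominance = dominance, phenotypes = phenotypes),
            class = "sterility_model")
}

#' @export
print.sterility_model <- function(x, ...) {
  cat(sprintf("<sterility_model> n = %d matings, %s sterility allele\n",
              x$n, x$dominance))
  print(tidy(x$phenotypes), ...)
  invisible(x)
}

#' Relatedness coefficients under n-fold queen mating
#'
#' Classic haplodiploid identity-by-descent coefficients for a female
#' worker: to her son (1/2), to a brother (1/4, independent of n) and to a
#' random sister ((2+n)/(4n), i.e. 3/4 under monandry). These play no role
#' in the dynamics — the model works directly with colony-type frequencies —
#' but anchor the package against the relatedness-heuristic literature.
#'
#' @inheritParams required_z_grid
#' @return tibble with columns `coefficient`, `value` (numeric) and
#'   `fraction` (exact, as a string).
#' @examples
#' relatedness_coefficients(1)$fraction # "1/2" "1/4" "3/4"
#' @export
relatedness_coefficients <- function(n) {
  n <- check_n(n)
  g <- gcd2(2L + n, 4L * n)
  tibble(
    coefficient = c("R_son", "R_brother", "R_sister"),
    value = c(1 / 2, 1 / 4, (2 + n) / (4 * n)),
    fraction = c("1/2", "1/4", paste0((2L + n) %/% g, "/", (4L * n) %/% g))
  )
}
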