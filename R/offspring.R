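#' Offspring proportions for every colony type
#'
#' For each colony type (queen genotype g, m of n matings with mutant
#' males) there are three offspring castes: queen-laid females (future
#' gynes/workers), queen-laid males and worker-laid males. Proportions
#' follow from Mendelian segregation of the queen's alleles and her stored
#' sperm, with sterile workers (aa under a recessive allele; Aa and aa
#' under a dominant allele) contributing no worker-laid males.
#'
#' Rows carry exact integer `weight`/`total` pairs (the unnormalised
#' relative proportions) alongside the numeric proportion `prop`; every
#' non-empty caste distribution satisfies `sum(weight) == total` exactly.
#' Colony types whose reproductive-worker fraction is zero have no
#' worker-male rows at all: all of their males are queen-laid (their sterile
#' fraction is 1, where the queen's male share is 1 by definition).
#'
#' @inheritParams required_z_grid
#' @param queen,m optional filters selecting a single colony type.
#' @return tibble with columns `queen`, `m`, `caste` (`"queen_female"`,
#'   `"queen_male"`, `"worker_male"`), `genotype`, `weight`, `total`, `prop`.
#' @examples
#' offspring_table(1, "recessive", queen = "Aa", m = 1)
#' @export
offspring_table <- function(n, dominance = c("recessive", "dominant"),
                            queen = NULL, m = NULL) {
  n <- check_n(n)
  dominance <- match.arg(dominance)
  ct <- colony_types(n)
  if (!is.null(queen)) ct <- ct[ct$queen %in% queen, ]
  if (!is.null(m)) ct <- ct[ct$m %in% m, ]
  if (nrow(ct) == 0) abort("no colony type matches the queen/m filter")
  rows <- purrr::pmap(list(as.character(ct$queen), ct$m),
                      function(q, mm) colony_offspring_rows(q, mm, n, dominance))
  out <- dplyr::bind_rows(rows)
  out$prop <- out$weight / out$total
  out
}

colony_offspring_rows <- function(q, m, n, dominance) {
  dist_rows <- function(caste, genotype, weight) {
    keep <- weight > 0L
    if (!any(keep)) return(NULL)
    w <- as.integer(weight[keep])
    tibble(queen = q, m = m, caste = caste,
           genotype = genotype[keep], weight = w, total = sum(w))
  }
  females <- switch(q,
    AA = dist_rows("queen_female", c("AA", "Aa"), c(n - m, m)),
    Aa = dist_rows("queen_female", c("AA", "Aa", "aa"), c(n - m, n, m)),
    aa = dist_rows("queen_female", c("Aa", "aa"), c(n - m, m))
  )
  qmales <- switch(q,
    AA = dist_rows("queen_male", "A", 1L),
    Aa = dist_rows("queen_male", c("A", "a"), c(1L, 1L)),
    aa = dist_rows("queen_male", "a", 1L)
  )
  wmales <- if (dominance == "recessive") {
    switch(q,
      AA = dist_rows("worker_male", c("A", "a"), c(2L * n - m, m)),
      Aa = dist_rows("worker_male", c("A", "a"), c(3L * n - 2L * m, n)),
      aa = if (m < n) dist_rows("worker_male", c("A", "a"), c(1L, 1L)) else NULL
    )
  } else {
    # dominant: only AA workers reproduce; none exist in aa-queen colonies,
    # nor in AA,n / Aa,n colonies (every worker then carries an a allele)
    switch(q,
      AA = if (m < n) dist_rows("worker_male", "A", 1L) else NULL,
      Aa = if (m < n) dist_rows("worker_male", "A", 1L) else NULL,
      aa = NULL
    )
  }
  dplyr::bind_rows(females, qmales, wmales)
}
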