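#' Exact sterile-fraction keys
#'
#' Sterile-worker fractions z are dyadic-style rationals of the mate number
#' (m/n, m/2n, ...). They are used as lookup keys into the phenotype tables
#' p_z and r_z, so they are carried as exact reduced fractions rendered as
#' canonical strings ("0", "1/4", "1/2", "1") rather than as floating-point
#' numbers, which would alias (e.g. 1/3) or fail equality tests.
#'
#' `z_key()` builds a canonical key from an integer numerator and
#' denominator; `z_value()` converts keys to numeric; `parse_z()` accepts
#' keys, plain integers ("0", "1") or decimal strings/numbers that are
#' exactly representable as a fraction with denominator up to `max_den`.
#'
#' @param num,den integer numerator and denominator, `0 <= num/den <= 1`.
#' @param z character vector of canonical keys.
#' @param x character or numeric vector to parse.
#' @param max_den largest denominator tried when parsing decimals.
#' @return `z_key()` and `parse_z()` return character keys; `z_value()`
#'   returns numeric values in `[0, 1]`.
#' @examples
#' z_key(2, 4)      # "1/2"
#' z_value("3/4")   # 0.75
#' parse_z(0.25)    # "1/4"
#' @export
z_key <- function(num, den) {
  k <- max(length(num), length(den))
  num <- rep_len(as.integer(num), k)
  den <- rep_len(as.integer(den), k)
  if (any(is.na(num) | is.na(den)) || any(den <= 0L) || any(num < 0L) ||
      any(num > den)) {
    abort("sterile fractions must satisfy 0 <= num/den <= 1 with den >= 1")
  }
  g <- mapply(gcd2, num, den)
  num <- num %/% g
  den <- den %/% g
  ifelse(den == 1L, as.character(num), paste0(num, "/", den))
}

gcd2 <- function(a, b) {
  while (b != 0L) {
    t <- b
    b <- a %% b
    a <- t
  }
  a
}

#' @rdname z_key
#' @export
z_value <- function(z) {
  parts <- strsplit(z, "/", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) == 1L) as.numeric(p) else as.numeric(p[1]) / as.numeric(p[2])
  }, numeric(1))
}

#' @rdname z_key
#' @export
parse_z <- function(x, max_den = 64L) {
  vapply(x, function(xi) {
    if (is.numeric(xi)) return(decimal_to_key(xi, max_den))
    xi <- trimws(as.character(xi))
    if (grepl("^[0-9]+/[0-9]+$", xi)) {
      p <- as.integer(strsplit(xi, "/", fixed = TRUE)[[1]])
      return(z_key(p[1], p[2]))
    }
    if (grepl("^[0-9]+$", xi)) return(z_key(as.integer(xi), 1L))
    if (grepl("^[0-9]*\\.[0-9]+$", xi)) {
      return(decimal_to_key(as.numeric(xi), max_den))
    }
    abort(sprintf("cannot parse sterile fraction %s", deparse(xi)))
  }, character(1), USE.NAMES = FALSE)
}

decimal_to_key <- function(v, max_den) {
  if (is.na(v) || v < 0 || v > 1) {
    abort(sprintf("sterile fraction %s is outside [0, 1]", format(v)))
  }
  for (den in seq_len(max_den)) {
    num <- v * den
    if (num == round(num)) return(z_key(as.integer(round(num)), den))
  }
  abort(sprintf(
    "decimal %s is not exactly representable as a fraction with denominator <= %d; use a \"num/den\" key",
    format(v, digits = 17), max_den
  ))
}
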