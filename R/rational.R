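# Exact non-negative rationals on top of bigint: probabilities and expected
# distances are reported exactly (numerator/denominator) and only rendered to
# decimals on demand.

#' Exact non-negative rational number
#'
#' Probability masses and expected distances in this package are exact
#' rationals: the numerator and denominator are arbitrary-precision integers
#' and the fraction is stored in lowest terms.
#'
#' @param num numerator: a `bigint` or something [bigint()] accepts.
#' @param den denominator (positive), same conventions.
#' @return an object of class `bigq` with fields `num` and `den`.
#' @examples
#' bigq(2, 6)           # stored as 1/3
#' @export
bigq <- function(num, den = 1) {
  num <- bigint(num); den <- bigint(den)
  if (big_is_zero(den)) stop("bigq: zero denominator")
  if (big_is_zero(num)) return(structure(list(num = big_zero(), den = big_one()), class = "bigq"))
  g <- big_gcd(num, den)
  if (!big_eq(g, big_one())) {
    num <- big_divmod(num, g)$q
    den <- big_divmod(den, g)$q
  }
  structure(list(num = num, den = den), class = "bigq")
}

#' @rdname bigq
#' @export
is_bigq <- function(x) inherits(x, "bigq")

bigq_add <- function(a, b) {
  bigq(big_add(big_mul(a$num, b$den), big_mul(b$num, a$den)),
       big_mul(a$den, b$den))
}

bigq_mul <- function(a, b) bigq(big_mul(a$num, b$num), big_mul(a$den, b$den))

# a - b, requiring a >= b
bigq_sub <- function(a, b) {
  bigq(big_sub(big_mul(a$num, b$den), big_mul(b$num, a$den)),
       big_mul(a$den, b$den))
}

bigq_eq <- function(a, b) {
  big_eq(big_mul(a$num, b$den), big_mul(b$num, a$den))
}

#' @export
as.double.bigq <- function(x, ...) {
  n <- as.numeric(x$num); d <- as.numeric(x$den)
  if (is.finite(n) && is.finite(d)) return(n / d)
  10^(big_log10(x$num) - big_log10(x$den))
}

#' Render an exact rational as a rounded decimal string
#'
#' Uses round-half-even on the exact value, so the printed decimal is the
#' correctly rounded representation of the fraction.
#'
#' @param x a `bigq`.
#' @param digits number of decimal places (default 2).
#' @return a character scalar such as `"96.72"`.
#' @export
bigq_decimal <- function(x, digits = 2L) {
  stopifnot(is_bigq(x), digits >= 0)
  scaled <- big_mul(x$num, big_pow_small(10, digits))
  dm <- big_divmod(scaled, x$den)
  q <- dm$q
  twice_r <- big_mul_small(dm$r, 2)
  cmp <- big_cmp(twice_r, x$den)
  round_up <- cmp > 0L || (cmp == 0L && q[1L] %% 2 == 1)
  if (round_up) q <- big_add(q, big_one())
  s <- as.character(q)
  if (digits == 0L) return(s)
  if (nchar(s) <= digits) s <- paste0(strrep("0", digits - nchar(s) + 1L), s)
  paste0(substr(s, 1L, nchar(s) - digits), ".",
         substr(s, nchar(s) - digits + 1L, nchar(s)))
}

#' @export
format.bigq <- function(x, ...) {
  paste0(as.character(x$num), "/", as.character(x$den))
}

#' @export
print.bigq <- function(x, ...) {
  cat("<bigq> ", format(x), " ≈ ", bigq_decimal(x, 4L), "\n", sep = "")
  invisible(x)
}
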