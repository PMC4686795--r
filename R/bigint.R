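# Exact arbitrary-precision non-negative integers.
#
# Representation: a double vector of base-1e6 digits, least significant first,
# no trailing zero digits (the value 0 is the single digit 0).  All digit
# arithmetic stays far below 2^53, so doubles are exact throughout.

.BIG_BASE <- 1e6L
.BIG_BASE_D <- 1e6
.BIG_CHUNK <- 6L

#' Arbitrary-precision non-negative integer
#'
#' Creates an exact big integer from a non-negative numeric scalar (which must
#' be integer-valued and below 2^53) or from a decimal string of any length.
#' All Hultman-number counts produced by this package are `bigint` objects:
#' they routinely exceed 1e150, far beyond what doubles or 64-bit integers
#' can represent exactly.
#'
#' @param x a single non-negative integer-valued number, a decimal string,
#'   or an existing `bigint` (returned unchanged).
#' @return an object of class `bigint`.
#' @examples
#' bigint("123456789012345678901234567890")
#' bigint(42)
#' @export
bigint <- function(x) {
  if (is_bigint(x)) return(x)
  if (is.character(x)) {
    if (length(x) != 1L || !grepl("^[0-9]+$", x))
      stop("bigint: need a single non-negative decimal string")
    s <- sub("^0+(?=.)", "", x, perl = TRUE)
    n <- nchar(s)
    starts <- seq(n, 1L, by = -.BIG_CHUNK)
    d <- vapply(starts, function(e) {
      b <- max(1L, e - .BIG_CHUNK + 1L)
      as.numeric(substr(s, b, e))
    }, numeric(1))
    return(big_norm(d))
  }
  if (is.numeric(x)) {
    if (length(x) != 1L || is.na(x) || x < 0 || x != floor(x) || x >= 2^53)
      stop("bigint: need a single non-negative integer-valued number < 2^53")
    x <- as.numeric(x)
    d <- numeric(0)
    repeat {
      d <- c(d, x %% .BIG_BASE_D)
      x <- x %/% .BIG_BASE_D
      if (x == 0) break
    }
    return(big_norm(d))
  }
  stop("bigint: cannot convert object of class ", class(x)[1L])
}

#' @rdname bigint
#' @export
is_bigint <- function(x) inherits(x, "bigint")

# wrap a digit vector (digits already in range) as a bigint, stripping
# trailing zeros
big_norm <- function(d) {
  n <- length(d)
  while (n > 1L && d[n] == 0) n <- n - 1L
  structure(d[seq_len(n)], class = "bigint")
}

big_zero <- function() structure(0, class = "bigint")
big_one  <- function() structure(1, class = "bigint")

big_is_zero <- function(a) length(a) == 1L && a[1L] == 0

# one increasing-order carry pass; digits may exceed the base arbitrarily
# (they must stay < 2^53)
big_carry <- function(d) {
  i <- 1L
  while (i <= length(d)) {
    if (d[i] >= .BIG_BASE_D) {
      q <- d[i] %/% .BIG_BASE_D
      d[i] <- d[i] - q * .BIG_BASE_D
      if (i == length(d)) d <- c(d, q) else d[i + 1L] <- d[i + 1L] + q
    }
    i <- i + 1L
  }
  d
}

big_add <- function(a, b) {
  la <- length(a); lb <- length(b)
  if (la < lb) { length(a) <- lb; a[is.na(a)] <- 0 }
  else if (lb < la) { length(b) <- la; b[is.na(b)] <- 0 }
  big_norm(big_carry(unclass(a) + unclass(b)))
}

# a - b, requiring a >= b
big_sub <- function(a, b) {
  if (big_cmp(a, b) < 0) stop("big_sub: negative result")
  la <- length(a); lb <- length(b)
  d <- unclass(a)
  d[seq_len(lb)] <- d[seq_len(lb)] - unclass(b)
  # borrow pass
  for (i in seq_len(la - 1L)) {
    if (d[i] < 0) { d[i] <- d[i] + .BIG_BASE_D; d[i + 1L] <- d[i + 1L] - 1 }
  }
  big_norm(d)
}

# multiply by a small non-negative integer k (k < 2^40 or so)
big_mul_small <- function(a, k) {
  if (k == 0 || big_is_zero(a)) return(big_zero())
  big_norm(big_carry(unclass(a) * k))
}

# full schoolbook product
big_mul <- function(a, b) {
  if (big_is_zero(a) || big_is_zero(b)) return(big_zero())
  la <- length(a); lb <- length(b)
  acc <- numeric(la + lb)
  bu <- unclass(b)
  for (i in seq_len(la)) {
    idx <- i:(i + lb - 1L)
    acc[idx] <- acc[idx] + a[i] * bu
    # keep partial sums well below 2^53
    if (i %% 64L == 0L) acc <- big_carry(acc)
  }
  big_norm(big_carry(acc))
}

big_cmp <- function(a, b) {
  la <- length(a); lb <- length(b)
  if (la != lb) return(if (la < lb) -1L else 1L)
  for (i in rev(seq_len(la))) {
    if (a[i] != b[i]) return(if (a[i] < b[i]) -1L else 1L)
  }
  0L
}

big_eq <- function(a, b) big_cmp(a, b) == 0L

# divide by a small positive integer k; returns list(q = bigint, r = double)
big_div_small <- function(a, k) {
  if (k <= 0 || k != floor(k)) stop("big_div_small: k must be a positive integer")
  q <- numeric(length(a))
  r <- 0
  for (i in rev(seq_along(a))) {
    cur <- r * .BIG_BASE_D + a[i]   # r < k <= 1e7 => cur < 1e13, exact
    q[i] <- cur %/% k
    r <- cur %% k
  }
  list(q = big_norm(q), r = r)
}

# long division a = q*b + r, 0 <= r < b; per-digit binary search keeps the
# logic simple and exact (sizes here are tens of digits at most)
big_divmod <- function(a, b) {
  if (big_is_zero(b)) stop("big_divmod: division by zero")
  if (big_cmp(a, b) < 0) return(list(q = big_zero(), r = a))
  if (length(b) == 1L) {
    res <- big_div_small(a, b[1L])
    return(list(q = res$q, r = bigint(res$r)))
  }
  la <- length(a)
  q <- numeric(la)
  r <- big_zero()
  for (i in rev(seq_len(la))) {
    # r <- r * BASE + a[i]
    r <- big_norm(c(a[i], unclass(r)))
    if (big_cmp(r, b) < 0) { q[i] <- 0; next }
    lo <- 1; hi <- .BIG_BASE_D - 1
    while (lo < hi) {
      mid <- (lo + hi + 1) %/% 2
      if (big_cmp(big_mul_small(b, mid), r) <= 0) lo <- mid else hi <- mid - 1
    }
    q[i] <- lo
    r <- big_sub(r, big_mul_small(b, lo))
  }
  list(q = big_norm(q), r = r)
}

big_mod <- function(a, b) big_divmod(a, b)$r

# binary gcd: only needs halving, comparison and subtraction
big_gcd <- function(a, b) {
  if (big_is_zero(a)) return(b)
  if (big_is_zero(b)) return(a)
  shift <- 0L
  is_even <- function(x) x[1L] %% 2 == 0
  half <- function(x) big_div_small(x, 2)$q
  while (is_even(a) && is_even(b)) { a <- half(a); b <- half(b); shift <- shift + 1L }
  while (is_even(a)) a <- half(a)
  while (is_even(b)) b <- half(b)
  while (!big_eq(a, b)) {
    if (big_cmp(a, b) > 0) {
      a <- big_sub(a, b)
      while (is_even(a) && !big_is_zero(a)) a <- half(a)
    } else {
      b <- big_sub(b, a)
      while (is_even(b) && !big_is_zero(b)) b <- half(b)
    }
  }
  for (s in seq_len(shift)) a <- big_mul_small(a, 2)
  a
}

big_pow_small <- function(base, k) {
  out <- big_one()
  b <- bigint(base)
  while (k > 0) {
    if (k %% 2 == 1) out <- big_mul(out, b)
    b <- big_mul(b, b)
    k <- k %/% 2
  }
  out
}

#' @export
as.character.bigint <- function(x, ...) {
  top <- length(x)
  if (top == 1L) return(sprintf("%.0f", x[1L]))
  rest <- vapply(rev(x[-top]), function(d) sprintf("%06.0f", d), character(1))
  paste0(sprintf("%.0f", x[top]), paste(rest, collapse = ""))
}

#' @export
format.bigint <- function(x, ...) as.character(x)

#' @export
print.bigint <- function(x, ...) {
  cat("<bigint> ", as.character(x), "\n", sep = "")
  invisible(x)
}

#' @export
as.double.bigint <- function(x, ...) {
  # exact when the value fits a double; Inf beyond ~1e308
  sum(unclass(x) * .BIG_BASE_D^(seq_along(x) - 1))
}

# base-10 logarithm, usable even when the value overflows a double
big_log10 <- function(a) {
  if (big_is_zero(a)) return(-Inf)
  top <- length(a)
  lead <- a[top]
  if (top > 1L) lead <- lead + a[top - 1L] / .BIG_BASE_D
  log10(lead) + 6 * (top - 1L)
}
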