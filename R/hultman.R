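# The four multichromosomal Hultman-number families, evaluated exactly.
#
# Every family counts matchings (genomes) by the cycle/path profile of their
# breakpoint graph against a fixed identity.  The recurrences run over e, the
# number of unvisited breakpoint-graph vertices, adding one matching edge or
# skipping one vertex at a time.  They are evaluated bottom-up in increasing
# e as "digit-plane" dynamic programs: one numeric array per layer holding a
# whole (c, p[, i, a]) grid of base-1e6 big-integer digit planes, so each
# layer step is a handful of vectorized array operations plus one carry pass.
# All arithmetic is exact; digit values never approach 2^53.

# package-local cache of computed layers/tables
.hultman_cache <- new.env(parent = emptyenv())

# digit planes needed for counts bounded by the number of matchings
# (involutions) on two_n vertices, with headroom
.ndigits_for <- function(two_n) {
  m <- max(2, two_n)
  log10_bound <- (m / 2) * (log10(m) - log10(exp(1))) + sqrt(m) / log(10) + 2
  max(3L, as.integer(ceiling(log10_bound / 6)) + 2L)
}

# carry pass over the last (digit) dimension of an array; errors on overflow
.arr_carry <- function(x) {
  d <- dim(x)
  nd <- d[length(d)]
  m <- matrix(x, ncol = nd)
  for (k in seq_len(nd - 1L)) {
    q <- m[, k] %/% .BIG_BASE_D
    if (any(q > 0)) {
      m[, k] <- m[, k] - q * .BIG_BASE_D
      m[, k + 1L] <- m[, k + 1L] + q
    }
  }
  if (any(m[, nd] >= .BIG_BASE_D)) stop("internal digit-plane overflow")
  array(m, d)
}

# shift an array by +1 along dimension k: result[.., j, ..] = x[.., j-1, ..]
.shift_dim <- function(x, k) {
  d <- dim(x)
  y <- array(0, d)
  if (d[k] < 2L) return(y)
  src <- lapply(d, seq_len); src[[k]] <- seq_len(d[k] - 1L)
  dst <- lapply(d, seq_len); dst[[k]] <- 2L:d[k]
  slab <- do.call(`[`, c(list(x), src, list(drop = FALSE)))
  do.call(`[<-`, c(list(y), dst, list(value = slab)))
}

# ---------------------------------------------------------------------------
# circular scenario: H_C(n, c) = H_C(n-1, c-1) + (2n-2) H_C(n-1, c)

# rows of bigints, row index n, entry index c (cached incrementally)
.hc_rows <- function(n_max) {
  rows <- .hultman_cache$hc_rows
  if (is.null(rows)) rows <- list(list(big_one()))   # n = 0: H_C(0,0) = 1
  while (length(rows) < n_max + 1L) {
    n <- length(rows)                                # building row for this n
    prev <- rows[[n]]
    row <- vector("list", n + 1L)                    # c = 0..n
    for (c in 0:n) {
      v <- big_zero()
      if (c >= 1L && c <= length(prev)) v <- prev[[c]]                # (n-1, c-1)
      if (c + 1L <= length(prev))
        v <- big_add(v, big_mul_small(prev[[c + 1L]], 2 * n - 2))     # (n-1, c)
      row[[c + 1L]] <- v
    }
    rows[[n + 1L]] <- row
  }
  .hultman_cache$hc_rows <- rows
  rows
}

#' Circular multichromosomal Hultman number
#'
#' `H_C(n, c)`: the number of circular genomes on `n` genes whose breakpoint
#' graph against the circular identity decomposes into exactly `c` cycles.
#' Computed by the recurrence
#' `H_C(n, c) = H_C(n-1, c-1) + (2n-2) H_C(n-1, c)` with `H_C(0, 0) = 1`;
#' equal to `2^(n-c) [n c]` with `[n c]` the unsigned Stirling number of the
#' first kind.
#'
#' @param n gene count.
#' @param c cycle count.
#' @return a [bigint()]; out-of-range arguments give 0.
#' @examples
#' hultman_circular(2, 1)   # 2
#' @export
hultman_circular <- function(n, c) {
  if (n < 0 || c < 0 || c > n) return(big_zero())
  .hc_rows(n)[[n + 1L]][[c + 1L]]
}

#' Unsigned Stirling numbers of the first kind
#'
#' `[n k]`: the number of permutations of `n` elements with exactly `k`
#' cycles, by the recurrence `[n k] = [n-1 k-1] + (n-1) [n-1 k]`,
#' `[0 0] = 1`.  Used as the independent closed-form cross-check of
#' [hultman_circular()].
#'
#' @param n,k non-negative integers (out of range gives 0).
#' @return a [bigint()].
#' @export
stirling_first_unsigned <- function(n, k) {
  if (n < 0 || k < 0 || k > n) return(big_zero())
  rows <- .hultman_cache$stirling_rows
  if (is.null(rows)) rows <- list(list(big_one()))
  while (length(rows) < n + 1L) {
    m <- length(rows)
    prev <- rows[[m]]
    row <- vector("list", m + 1L)
    for (j in 0:m) {
      v <- big_zero()
      if (j >= 1L && j <= length(prev)) v <- prev[[j]]
      if (j + 1L <= length(prev)) v <- big_add(v, big_mul_small(prev[[j + 1L]], m - 1))
      row[[j + 1L]] <- v
    }
    rows[[m + 1L]] <- row
  }
  .hultman_cache$stirling_rows <- rows
  rows[[n + 1L]][[k + 1L]]
}

# ---------------------------------------------------------------------------
# general scenario: H_G(n, c, p) = H'_G(2n, c, p) with
#   e even: H'(e,c,p) = H'(e-2,c-1,p) + (e-2) H'(e-2,c,p) + H'(e-1,c,p)
#   e odd:  H'(e,c,p) = (e-1) H'(e-2,c,p) + H'(e-1,c,p-1)

# final layer e = 2n as a (n+1) x (2n+1) x ndigits array
.hg_final <- function(n) {
  key <- sprintf("hg_%d", n)
  hit <- .hultman_cache[[key]]
  if (!is.null(hit)) return(hit)
  nd <- .ndigits_for(2L * n)
  dims <- c(n + 1L, 2L * n + 1L, nd)
  prev2 <- array(0, dims)              # layer e-2 (e-1 = -1 for e = 1)
  prev1 <- array(0, dims); prev1[1L, 1L, 1L] <- 1   # layer e-1 = 0
  if (n == 0L) { .hultman_cache[[key]] <- prev1; return(prev1) }
  for (e in seq_len(2L * n)) {
    cur <- if (e %% 2L == 0L) {
      .shift_dim(prev2, 1L) + (e - 2) * prev2 + prev1
    } else {
      (e - 1) * prev2 + .shift_dim(prev1, 2L)
    }
    cur <- .arr_carry(cur)
    prev2 <- prev1; prev1 <- cur
  }
  .hultman_cache[[key]] <- prev1
  prev1
}

#' General multichromosomal Hultman number
#'
#' `H_G(n, c, p)`: the number of genomes on `n` genes (linear and/or circular
#' chromosomes allowed) whose breakpoint graph against the circular identity
#' has exactly `c` cycles and `p` paths.
#'
#' @param n gene count.
#' @param c cycle count.
#' @param p path count.
#' @return a [bigint()]; out-of-range arguments give 0.
#' @export
hultman_general <- function(n, c, p) {
  if (n < 0 || c < 0 || p < 0) return(big_zero())
  if (n == 0L) return(if (c == 0 && p == 0) big_one() else big_zero())
  if (c > n || p > 2 * n) return(big_zero())
  big_norm(.hg_final(n)[c + 1L, p + 1L, ])
}

# ---------------------------------------------------------------------------
# linear-identity scenario H_L and fixed-linear scenario H_l share the layer
# structure: state (c, p, i[, a]) where i counts identity-unsaturated vertices
# among the unvisited ones and a the unsaturated budget of the matching being
# built.  Branch per i-slice:
#   e = i > 0:          (i-1) shift_p L2[i-2] + shift_p [shift_a] L1[i-1]
#   e + i even, e > i:  shift_c L2[i] + (e-2-i) L2[i] + i L2[i-1] + [shift_a] L1[i]
#   e + i odd,  e > i:  (e-1-i) L2[i] + i shift_p L2[i-1] + shift_p [shift_a] L1[i]
# where the skip-vertex terms (the L1 terms and only those) carry the a-shift
# in the fixed-linear case.

# one engine for both: track_a = FALSE gives H'_L slices (c,p) per i,
# track_a = TRUE gives H'_l slices (c,p,a) per i.  Returns the final layer:
# a list over i = 0..i_max of arrays.  The a dimension can be truncated to
# a_max: a only ever increases along the recursion, so cells with a <= a_max
# never depend on larger a.
.hl_engine <- function(n, i_max, track_a, a_max = 2L * n) {
  nd <- .ndigits_for(2L * n)
  dims <- if (track_a) c(n + 1L, 2L * n + 1L, a_max + 1L, nd)
          else c(n + 1L, 2L * n + 1L, nd)
  P_DIM <- 2L; A_DIM <- 3L
  zero <- array(0, dims)
  base <- zero; base[1L] <- 1            # delta at c = p = (a =) 0
  mk_layer <- function() lapply(0:i_max, function(i) zero)
  prev2 <- mk_layer()
  prev1 <- mk_layer(); prev1[[1L]] <- base   # layer e = 0: only i = 0 legal
  if (n == 0L) return(prev1)
  shift_skip <- if (track_a) function(x) .shift_dim(x, A_DIM) else identity
  for (e in seq_len(2L * n)) {
    cur <- mk_layer()
    for (i in 0:min(i_max, e)) {
      slot <- i + 1L
      acc <- if (i == e) {
        t1 <- if (i >= 2L) (i - 1) * .shift_dim(prev2[[slot - 2L]], P_DIM) else zero
        t1 + .shift_dim(shift_skip(prev1[[slot - 1L]]), P_DIM)
      } else if ((e + i) %% 2L == 0L) {
        t <- .shift_dim(prev2[[slot]], 1L) + (e - 2 - i) * prev2[[slot]] +
          shift_skip(prev1[[slot]])
        if (i >= 1L) t <- t + i * prev2[[slot - 1L]]
        t
      } else {
        t <- (e - 1 - i) * prev2[[slot]] +
          .shift_dim(shift_skip(prev1[[slot]]), P_DIM)
        if (i >= 1L) t <- t + i * .shift_dim(prev2[[slot - 1L]], P_DIM)
        t
      }
      cur[[slot]] <- .arr_carry(acc)
    }
    prev2 <- prev1; prev1 <- cur
  }
  prev1
}

# fetch the final-layer slice for i = 2l, growing the cached engine run as
# needed; a_need is the largest a index that will be read (track_a only)
.hl_slice <- function(n, l, track_a, a_need = 0L) {
  i <- 2L * l
  key <- sprintf("hl_%d_%d", n, as.integer(track_a))
  hit <- .hultman_cache[[key]]
  if (!is.null(hit) && attr(hit, "i_max") >= i &&
      (!track_a || attr(hit, "a_max") >= a_need))
    return(hit[[i + 1L]])
  # small n: compute the full i and a ranges once so parameter sweeps are
  # cheap; large n: compute just what is asked for
  full <- n <= 8L
  i_max <- if (full) 2L * n else max(i, if (!is.null(hit)) attr(hit, "i_max") else 0L)
  a_max <- if (!track_a) 0L
           else if (full) 2L * n
           else max(a_need, if (!is.null(hit)) attr(hit, "a_max") else 0L)
  res <- .hl_engine(n, i_max, track_a, a_max)
  attr(res, "i_max") <- i_max
  attr(res, "a_max") <- a_max
  .hultman_cache[[key]] <- res
  res[[i + 1L]]
}

#' Hultman number for an identity with a fixed number of linear chromosomes
#'
#' `H_L(n, c, p, l)`: the number of genomes on `n` genes whose breakpoint
#' graph against an identity genome having exactly `l` linear chromosomes has
#' `c` cycles and `p` paths.  `H_L(n, c, p, 0) = H_G(n, c, p)`.  The value
#' does not depend on which concrete identity genome with `l` linear
#' chromosomes is chosen.
#'
#' @param n gene count.
#' @param c cycle count.
#' @param p path count.
#' @param l number of linear chromosomes of the identity, `0 <= l <= n`.
#' @return a [bigint()].
#' @export
hultman_linear_identity <- function(n, c, p, l) {
  if (l < 0 || l > max(n, 0)) stop("hultman_linear_identity: need 0 <= l <= n")
  if (n < 0 || c < 0 || p < 0) return(big_zero())
  if (n == 0L) return(if (c == 0 && p == 0) big_one() else big_zero())
  if (c > n || p > 2 * n) return(big_zero())
  big_norm(.hl_slice(n, l, track_a = FALSE)[c + 1L, p + 1L, ])
}

#' Hultman number with fixed linear chromosomes on both sides
#'
#' `H_l(n, c, p, l_i, l_a)`: the number of genomes on `n` genes having
#' exactly `l_a` linear chromosomes whose breakpoint graph against an
#' identity with exactly `l_i` linear chromosomes has `c` cycles and `p`
#' paths.  Summing over `l_a = 0..n` recovers
#' [hultman_linear_identity()]`(n, c, p, l_i)`.
#'
#' @param n gene count.
#' @param c cycle count.
#' @param p path count.
#' @param l_i linear chromosomes of the identity, `0 <= l_i <= n`.
#' @param l_a linear chromosomes of the counted genomes, `0 <= l_a <= n`.
#' @return a [bigint()].
#' @export
hultman_fixed_linear <- function(n, c, p, l_i, l_a) {
  if (l_i < 0 || l_i > max(n, 0)) stop("hultman_fixed_linear: need 0 <= l_i <= n")
  if (l_a < 0 || l_a > max(n, 0)) stop("hultman_fixed_linear: need 0 <= l_a <= n")
  if (n < 0 || c < 0 || p < 0) return(big_zero())
  if (n == 0L) return(if (c == 0 && p == 0) big_one() else big_zero())
  if (c > n || p > 2 * n) return(big_zero())
  big_norm(.hl_slice(n, l_i, track_a = TRUE, a_need = 2L * l_a)[c + 1L, p + 1L, 2L * l_a + 1L, ])
}

# ---------------------------------------------------------------------------
# full tables

.scenarios <- c("circular", "general", "linear_identity", "fixed_linear")

#' Full Hultman table for a scenario
#'
#' Computes every nonzero count of the requested family at once (the
#' underlying dynamic program always fills the whole table; this exposes it).
#'
#' @param scenario one of `"circular"`, `"general"`, `"linear_identity"`,
#'   `"fixed_linear"`.
#' @param n gene count (`n >= 0`).
#' @param l identity linear-chromosome count (scenario `linear_identity`).
#' @param l_i,l_a linear-chromosome counts (scenario `fixed_linear`).
#' @return an object of class `hultman_table`: fields `scenario`, `n`,
#'   `params`, `index` (a data frame of `c` and, except for `circular`, `p`),
#'   `counts` (a list of [bigint()] parallel to the rows of `index`, nonzero
#'   entries only, ordered by `c` then `p`), and `total` (a `bigint`, the
#'   universe size of the scenario).
#' @examples
#' hultman_table("circular", 2)       # counts 2 and 1 at c = 1, 2
#' @export
hultman_table <- function(scenario = .scenarios, n, l = NULL, l_i = NULL, l_a = NULL) {
  scenario <- match.arg(scenario)
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 0L) stop("hultman_table: n must be >= 0")
  if (scenario == "circular") {
    counts <- lapply(0:n, function(c) hultman_circular(n, c))
    keep <- !vapply(counts, big_is_zero, logical(1))
    idx <- data.frame(c = (0:n)[keep])
    counts <- counts[keep]
    params <- list()
  } else {
    fetch <- switch(scenario,
      general = function(c, p) hultman_general(n, c, p),
      linear_identity = {
        if (is.null(l)) stop("hultman_table: scenario 'linear_identity' needs l")
        function(c, p) hultman_linear_identity(n, c, p, l)
      },
      fixed_linear = {
        if (is.null(l_i) || is.null(l_a))
          stop("hultman_table: scenario 'fixed_linear' needs l_i and l_a")
        function(c, p) hultman_fixed_linear(n, c, p, l_i, l_a)
      })
    grid <- expand.grid(p = 0:(2L * max(n, 1L)), c = 0:n)[, c("c", "p")]
    grid <- grid[order(grid$c, grid$p), , drop = FALSE]
    counts <- mapply(fetch, grid$c, grid$p, SIMPLIFY = FALSE)
    keep <- !vapply(counts, big_is_zero, logical(1))
    idx <- grid[keep, , drop = FALSE]
    rownames(idx) <- NULL
    counts <- counts[keep]
    params <- switch(scenario,
      general = list(),
      linear_identity = list(l = as.integer(l)),
      fixed_linear = list(l_i = as.integer(l_i), l_a = as.integer(l_a)))
  }
  total <- Reduce(big_add, counts, big_zero())
  structure(list(scenario = scenario, n = n, params = params,
                 index = idx, counts = counts, total = total),
            class = "hultman_table")
}

#' @export
as.data.frame.hultman_table <- function(x, ...) {
  df <- x$index
  df$count <- vapply(x$counts, as.character, character(1))
  df
}

#' @export
print.hultman_table <- function(x, ...) {
  hdr <- paste0("<hultman_table> scenario = ", x$scenario, ", n = ", x$n)
  if (length(x$params) > 0L)
    hdr <- paste0(hdr, ", ", paste(names(x$params), unlist(x$params),
                                   sep = " = ", collapse = ", "))
  cat(hdr, "\n", sep = "")
  print(as.data.frame(x))
  cat("total: ", as.character(x$total), "\n", sep = "")
  invisible(x)
}
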