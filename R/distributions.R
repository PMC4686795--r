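# Exact distributions and expected values of the algebraic rearrangement
# distance, derived from the Hultman tables.
#
# For a genome A drawn uniformly from a scenario's universe, the algebraic
# distance to the identity is d_a = n - c - p/2, so the distance distribution
# is a direct regrouping of the scenario's Hultman table:
#   circular:  D_C(n, d) = H_C(n, n - d)
#   otherwise: D(n, d)   = sum over c + p/2 = n - d of the Hultman number.
# Distances are half-integers when p is odd; they are stored as twice_d
# integers to stay exact.

#' Number of circular genomes on n genes
#'
#' `(2n - 1)!!`, the number of perfect matchings on 2n vertices.
#'
#' @param n gene count (`n >= 0`); the empty product at `n = 0` gives 1.
#' @return a [bigint()].
#' @export
circular_genome_count <- function(n) {
  if (n < 0) stop("circular_genome_count: n must be >= 0")
  out <- big_one()
  for (j in seq_len(n)) out <- big_mul_small(out, 2 * j - 1)
  out
}

#' Number of matchings on a set of vertices
#'
#' The involution (telephone) count
#' `sum_k v! / (2^k (v - 2k)! k!)` for `v` vertices: the number of matchings,
#' not necessarily perfect, on `v` labelled vertices (OEIS A000085 evaluated
#' at `v`).  This is the universe size of the general and linear-identity
#' scenarios with `v = 2n`.
#'
#' @param vertices an even non-negative integer.
#' @return a [bigint()].
#' @export
matching_count <- function(vertices) {
  v <- as.integer(vertices)
  if (length(v) != 1L || is.na(v) || v < 0L || v %% 2L != 0L)
    stop("matching_count: vertices must be even and >= 0")
  term <- big_one()          # k = 0
  total <- big_one()
  k <- 0L
  while (2L * (k + 1L) <= v) {
    k <- k + 1L
    term <- big_div_small(
      big_mul_small(term, (v - 2 * k + 2) * (v - 2 * k + 1)), 2 * k)$q
    total <- big_add(total, term)
  }
  total
}

#' Exact distribution of the algebraic rearrangement distance
#'
#' @inheritParams hultman_table
#' @return an object of class `distance_distribution` with fields `scenario`,
#'   `n`, `params`, `twice_d` (sorted integer vector of 2*distance), `counts`
#'   (list of [bigint()]), and `universe` (a `bigint`; the scenario's genome
#'   count, i.e. the total of its Hultman table).
#' @examples
#' distance_distribution("circular", 2)
#' @export
distance_distribution <- function(scenario = .scenarios, n, l = NULL,
                                  l_i = NULL, l_a = NULL) {
  scenario <- match.arg(scenario)
  ht <- hultman_table(scenario, n, l = l, l_i = l_i, l_a = l_a)
  idx <- ht$index
  twice_d <- if (scenario == "circular") 2L * (n - idx$c)
             else 2L * n - 2L * idx$c - idx$p
  keys <- sort(unique(twice_d))
  counts <- lapply(keys, function(k) {
    Reduce(big_add, ht$counts[twice_d == k], big_zero())
  })
  structure(list(scenario = scenario, n = ht$n, params = ht$params,
                 twice_d = keys, counts = counts, universe = ht$total),
            class = "distance_distribution")
}

#' Probability mass of a distance
#'
#' @param dist a [distance_distribution()].
#' @param d a half-integer distance.
#' @return a [bigq()]: `count(d) / universe`, reduced; 0 for absent `d`.
#' @export
pmf <- function(dist, d) {
  stopifnot(inherits(dist, "distance_distribution"))
  td <- round(2 * d)
  hit <- match(td, dist$twice_d)
  if (is.na(hit)) return(bigq(0))
  bigq(dist$counts[[hit]], dist$universe)
}

#' Expected algebraic rearrangement distance
#'
#' `E[X_n] = sum_d d P[X_n = d]`, exactly.  Either pass a precomputed
#' [distance_distribution()] or a scenario and its parameters.
#'
#' @param x a `distance_distribution`, or a scenario name.
#' @inheritParams hultman_table
#' @return a [bigq()].
#' @examples
#' expected_distance("circular", 2)   # 2/3
#' @export
expected_distance <- function(x, n = NULL, l = NULL, l_i = NULL, l_a = NULL) {
  dist <- if (inherits(x, "distance_distribution")) x
          else distance_distribution(x, n, l = l, l_i = l_i, l_a = l_a)
  num <- big_zero()
  for (j in seq_along(dist$twice_d))
    num <- big_add(num, big_mul_small(dist$counts[[j]], dist$twice_d[j]))
  bigq(num, big_mul_small(dist$universe, 2))
}

#' Closed-form expected distance for the circular scenario
#'
#' The generating polynomial of the circular Hultman numbers,
#' `sum_c H_C(n, c) x^c = x (x + 2) (x + 4) ... (x + 2n - 2)`, follows
#' directly from the recurrence, and differentiating at `x = 1` gives
#' `E[X_n] = n - sum_{j=0}^{n-1} 1/(2j + 1)` exactly.  This is an analytic
#' oracle independent of the table-based [expected_distance()].
#'
#' @param n gene count (`n >= 0`).
#' @return a [bigq()].
#' @export
expected_circular_closed_form <- function(n) {
  if (n < 0) stop("expected_circular_closed_form: n must be >= 0")
  den <- circular_genome_count(n)              # (2n-1)!!
  num <- big_mul_small(den, n)
  for (j in seq_len(n))                        # j-1 = 0..n-1
    num <- big_sub(num, big_div_small(den, 2 * j - 1)$q)
  bigq(num, den)
}

#' @export
as.data.frame.distance_distribution <- function(x, ...) {
  data.frame(
    scenario = x$scenario,
    n = x$n,
    params = if (length(x$params) > 0L)
      paste(names(x$params), unlist(x$params), sep = "=", collapse = ",") else "",
    d = x$twice_d / 2,
    count = vapply(x$counts, as.character, character(1)),
    probability_exact = vapply(seq_along(x$counts), function(j)
      format(bigq(x$counts[[j]], x$universe)), character(1)),
    probability_float = vapply(seq_along(x$counts), function(j)
      as.numeric(bigq(x$counts[[j]], x$universe)), numeric(1))
  )
}

#' @export
print.distance_distribution <- function(x, ...) {
  cat("<distance_distribution> scenario = ", x$scenario, ", n = ", x$n, sep = "")
  if (length(x$params) > 0L)
    cat(", ", paste(names(x$params), unlist(x$params), sep = " = ", collapse = ", "), sep = "")
  cat("\n")
  print(as.data.frame(x)[, c("d", "count", "probability_exact", "probability_float")])
  cat("universe: ", as.character(x$universe), "\n", sep = "")
  ev <- expected_distance(x)
  cat("expected distance: ", format(ev), " ≈ ", bigq_decimal(ev, 2L), "\n", sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------
# serialization

#' Export a distance distribution or Hultman table
#'
#' TSV columns: `scenario, n, params, d, count, probability_exact,
#' probability_float` (distributions) or the table's index columns plus
#' `count` (Hultman tables).  JSON carries a metadata object and counts as
#' decimal strings, since the counts overflow 64-bit integers.
#'
#' @param x a [distance_distribution()] or [hultman_table()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_tsv_export <- function(x, path) {
  df <- as.data.frame(x)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_export
#' @export
write_json_export <- function(x, path) {
  meta <- list(scenario = x$scenario, n = x$n, params = x$params)
  body <- if (inherits(x, "distance_distribution")) {
    meta$universe <- as.character(x$universe)
    list(metadata = meta, distribution = data.frame(
      d = x$twice_d / 2,
      count = vapply(x$counts, as.character, character(1))))
  } else {
    meta$total <- as.character(x$total)
    df <- x$index
    df$count <- vapply(x$counts, as.character, character(1))
    list(metadata = meta, table = df)
  }
  jsonlite::write_json(body, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
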