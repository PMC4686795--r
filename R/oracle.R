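# R surface of the brute-force oracle: exhaustive enumeration of matchings,
# tabulation of breakpoint-graph decompositions, uniform sampling, and the
# oracle-equivalence check that certifies the recurrences.

.oracle_mode_code <- function(mode) {
  switch(mode, perfect = 0L, all = 1L, fixed_unsaturated = 2L,
         stop("unknown enumeration mode: ", mode))
}

#' Enumerate matchings on a set of vertices
#'
#' Generates every matching of the requested kind exactly once, in a fixed
#' deterministic order (the smallest unassigned vertex is either left
#' unsaturated or paired with each larger partner in turn).  Refuses more
#' than 16 vertices: the point of this function is to be a dumb, exhaustive
#' ground truth, not to scale.
#'
#' @param vertices even number of vertices (`<= 16`).
#' @param mode `"perfect"`, `"all"`, or `"fixed_unsaturated"`.
#' @param unsaturated for mode `"fixed_unsaturated"`: the exact (even) number
#'   of unsaturated vertices each matching must have.
#' @return a list of [matching()] objects (gene count `vertices/2`).
#' @examples
#' length(enumerate_matchings(4, "perfect"))   # 3
#' length(enumerate_matchings(4, "all"))       # 10
#' @export
enumerate_matchings <- function(vertices,
                                mode = c("perfect", "all", "fixed_unsaturated"),
                                unsaturated = 0L) {
  mode <- match.arg(mode)
  rows <- .oracle_enumerate_cpp(as.integer(vertices), .oracle_mode_code(mode),
                                as.integer(unsaturated))
  n <- as.integer(vertices) %/% 2L
  lapply(seq_len(nrow(rows)), function(r) matching_from_pair(n, rows[r, ]))
}

#' Tabulate breakpoint-graph decompositions over an enumerated universe
#'
#' Decomposes `BG(M, identity)` for every matching `M` of the requested kind
#' and counts the resulting (cycles, paths) profiles.  This realizes the
#' Hultman-number definitions literally and is the ground truth every
#' recurrence is certified against.
#'
#' @param identity a [matching()] (or `genome`): the identity side of every
#'   breakpoint graph.
#' @inheritParams enumerate_matchings
#' @return a data frame with columns `cycles`, `paths`, `count` (nonzero
#'   rows only, ordered by `cycles` then `paths`).
#' @examples
#' oracle_tabulate(identity_circular(2), "perfect")
#' @export
oracle_tabulate <- function(identity, mode = c("perfect", "all", "fixed_unsaturated"),
                            unsaturated = 0L) {
  mode <- match.arg(mode)
  if (inherits(identity, "genome")) identity <- genome_to_matching(identity)
  stopifnot(inherits(identity, "matching"))
  nv <- 2L * identity$n
  m <- .oracle_tabulate_cpp(nv, .oracle_mode_code(mode), as.integer(unsaturated),
                            identity$pair)
  idx <- which(m > 0, arr.ind = TRUE)
  out <- data.frame(cycles = idx[, 1L] - 1L, paths = idx[, 2L] - 1L,
                    count = m[idx])
  out <- out[order(out$cycles, out$paths), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Certify a Hultman recurrence against the brute-force oracle
#'
#' Recomputes a scenario's full Hultman table by exhaustive enumeration and
#' compares it, entry by entry, with the recurrence-based table.
#'
#' @inheritParams hultman_table
#' @return a list with elements `pass` (logical), `scenario`, `n`, `params`,
#'   and `comparison`: a data frame of all indices with the oracle and
#'   recurrence counts side by side.
#' @examples
#' verify_scenario("circular", 3)$pass
#' @export
verify_scenario <- function(scenario = .scenarios, n, l = NULL,
                            l_i = NULL, l_a = NULL) {
  scenario <- match.arg(scenario)
  id <- switch(scenario,
    circular = ,
    general = identity_circular(max(n, 1L)),
    linear_identity = identity_linear(n, l),
    fixed_linear = identity_linear(n, l_i))
  mode <- switch(scenario, circular = "perfect", fixed_linear = "fixed_unsaturated",
                 "all")
  unsat <- if (scenario == "fixed_linear") 2L * l_a else 0L
  orc <- oracle_tabulate(id, mode, unsat)
  rec <- hultman_table(scenario, n, l = l, l_i = l_i, l_a = l_a)
  rec_df <- data.frame(
    cycles = rec$index$c,
    paths = if (scenario == "circular") 0L else rec$index$p,
    recurrence = vapply(rec$counts, as.numeric, numeric(1))
  )
  cmp <- merge(orc, rec_df, by = c("cycles", "paths"), all = TRUE)
  cmp$count[is.na(cmp$count)] <- 0
  cmp$recurrence[is.na(cmp$recurrence)] <- 0
  names(cmp)[names(cmp) == "count"] <- "oracle"
  cmp <- cmp[order(cmp$cycles, cmp$paths), , drop = FALSE]
  rownames(cmp) <- NULL
  list(pass = all(cmp$oracle == cmp$recurrence),
       scenario = scenario, n = n,
       params = rec$params, comparison = cmp)
}

#' Sample matchings uniformly at random
#'
#' Perfect matchings are drawn by sequential random pairing (the smallest
#' unpaired vertex is matched with a uniformly chosen free partner), which is
#' exactly uniform over the `(v - 1)!!` perfect matchings.  General matchings
#' use the standard recursive split on involution counts: the smallest
#' unprocessed vertex is left unsaturated with probability `T(m-1)/T(m)`
#' (with `m` vertices remaining and `T` the matching count), otherwise paired
#' with a uniform free partner.
#'
#' @param vertices even number of vertices (no 16-vertex cap: sampling scales).
#' @param size number of matchings to draw.
#' @param mode `"perfect"` or `"all"`.
#' @param seed integer seed; required, so the stream is reproducible and no
#'   hidden global state is involved.  The caller's RNG state is restored on
#'   exit.
#' @return a list of `size` [matching()] objects.
#' @export
sample_matchings <- function(vertices, size, mode = c("perfect", "all"), seed) {
  mode <- match.arg(mode)
  nv <- as.integer(vertices)
  if (is.na(nv) || nv < 0L || nv %% 2L != 0L)
    stop("sample_matchings: vertices must be even and >= 0")
  if (missing(seed)) stop("sample_matchings: seed is required")
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(as.integer(seed))
  n <- nv %/% 2L
  # probability that the smallest of m remaining vertices stays unsaturated
  skip_prob <- if (mode == "all" && nv > 0L) {
    tel <- vector("list", nv + 1L)
    for (m in 0:nv) tel[[m + 1L]] <- matching_count_any(m)
    vapply(1:nv, function(m) as.numeric(bigq(tel[[m]], tel[[m + 1L]])), numeric(1))
  }
  draw <- function() {
    pair <- integer(nv)
    free <- seq_len(nv)
    while (length(free) > 0L) {
      u <- free[1L]
      free <- free[-1L]
      if (mode == "all" && (length(free) == 0L ||
                            stats::runif(1) < skip_prob[length(free) + 1L])) {
        pair[u] <- 0L
        next
      }
      v <- free[sample.int(length(free), 1L)]
      free <- free[free != v]
      pair[u] <- v; pair[v] <- u
    }
    matching_from_pair(n, pair)
  }
  lapply(seq_len(size), function(k) draw())
}

# matching count for any (possibly odd) number of vertices, by the involution
# recurrence T(m) = T(m-1) + (m-1) T(m-2); used by the sampler
matching_count_any <- function(m) {
  if (m <= 1L) return(big_one())
  a <- big_one(); b <- big_one()        # T(0), T(1)
  for (k in 2:m) {
    nxt <- big_add(b, big_mul_small(a, k - 1))
    a <- b; b <- nxt
  }
  b
}
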