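# Genomes, extremity matchings, and the multichromosomal breakpoint graph.
#
# A gene g in 1..n has two extremities: tail (vertex 2g-1) and head (vertex
# 2g).  A genome is a set of chromosomes, each an ordered sequence of signed
# genes, linear (flanked by telomeres) or circular.  Every non-telomeric
# adjacency pairs two extremities, so a genome corresponds one-to-one to a
# matching on the 2n extremity vertices; the matching is perfect exactly when
# all chromosomes are circular.

#' Build a chromosome
#'
#' @param genes vector of nonzero signed integers; the sign encodes gene
#'   orientation.
#' @param linear `TRUE` for a linear chromosome (flanked by telomeres),
#'   `FALSE` for circular.
#' @return an object of class `chromosome`.
#' @export
chromosome <- function(genes, linear = FALSE) {
  genes <- as.integer(genes)
  if (length(genes) == 0L) stop("chromosome: empty gene list")
  if (any(genes == 0L) || anyNA(genes)) stop("chromosome: genes must be nonzero integers")
  dup <- abs(genes)[duplicated(abs(genes))]
  if (length(dup) > 0L)
    stop("chromosome: gene label ", dup[1L], " repeated within a chromosome")
  structure(list(genes = genes, linear = isTRUE(linear)), class = "chromosome")
}

#' Build a genome from chromosomes
#'
#' The absolute gene labels across all chromosomes must be exactly `1..n`,
#' each occurring once.
#'
#' @param chromosomes a list of [chromosome()] objects (or a single one).
#' @param name optional genome name (used by the GRIMM writer).
#' @return an object of class `genome` with fields `chromosomes`, `n`, `name`.
#' @examples
#' genome(list(chromosome(1:3), chromosome(c(-5, 4), linear = TRUE)))
#' @export
genome <- function(chromosomes, name = NULL) {
  if (inherits(chromosomes, "chromosome")) chromosomes <- list(chromosomes)
  if (!is.list(chromosomes) || !all(vapply(chromosomes, inherits, logical(1), "chromosome")))
    stop("genome: need a list of chromosome objects")
  labels <- sort(unlist(lapply(chromosomes, function(ch) abs(ch$genes))))
  n <- length(labels)
  if (n == 0L) stop("genome: no genes")
  if (anyDuplicated(labels)) {
    dup <- labels[duplicated(labels)][1L]
    stop("genome: gene label ", dup, " occurs more than once")
  }
  if (!identical(labels, seq_len(n))) {
    missing <- setdiff(seq_len(max(labels)), labels)[1L]
    stop("genome: gene labels must be exactly 1..n; label ", missing, " is missing")
  }
  structure(list(chromosomes = chromosomes, n = n, name = name), class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat("<genome> n = ", x$n, if (!is.null(x$name)) paste0("  (", x$name, ")"), "\n", sep = "")
  for (ch in x$chromosomes) {
    body <- paste(ch$genes, collapse = " ")
    if (ch$linear) cat("  ( ∘ ", body, " ∘ )\n", sep = "")
    else cat("  ( ", body, " )\n", sep = "")
  }
  invisible(x)
}

#' Number of linear chromosomes of a genome
#' @param g a `genome`.
#' @return integer count.
#' @export
n_linear <- function(g) {
  stopifnot(inherits(g, "genome"))
  sum(vapply(g$chromosomes, function(ch) ch$linear, logical(1)))
}

#' Circular identity genome
#'
#' The reference genome `{(1 2 ... n)}`: one circular chromosome carrying
#' all genes in order.  This is the identity used by the circular and general
#' Hultman numbers.
#'
#' @param n number of genes (`n >= 1`).
#' @return a `genome`.
#' @export
identity_circular <- function(n) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 1L) stop("identity_circular: n must be >= 1")
  genome(chromosome(seq_len(n)), name = "identity_circular")
}

#' Canonical identity genome with a fixed number of linear chromosomes
#'
#' A deterministic genome on genes `1..n` with exactly `l` linear chromosomes:
#' the genes are split into `l` consecutive runs of near-equal length (the
#' remainder going to the first chromosomes), all linear.  With `l = 0` the
#' circular identity is returned.  The Hultman tables are invariant to which
#' concrete genome with `l` linear chromosomes is used (a property the test
#' suite checks), so one canonical choice suffices.
#'
#' @param n number of genes.
#' @param l number of linear chromosomes, `0 <= l <= n`.
#' @return a `genome`.
#' @export
identity_linear <- function(n, l) {
  n <- as.integer(n); l <- as.integer(l)
  if (length(n) != 1L || is.na(n) || n < 1L) stop("identity_linear: n must be >= 1")
  if (length(l) != 1L || is.na(l) || l < 0L || l > n)
    stop("identity_linear: need 0 <= l <= n")
  if (l == 0L) return(identity_circular(n))
  sizes <- rep(n %/% l, l)
  extra <- n %% l
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, ends[-l] + 1L)
  chs <- mapply(function(s, e) chromosome(s:e, linear = TRUE), starts, ends,
                SIMPLIFY = FALSE)
  genome(chs, name = sprintf("identity_linear_%d", l))
}

# tail/head vertex ids for a signed gene occurrence: the extremity seen first
# when reading left-to-right ("left") and the one seen last ("right")
.gene_left  <- function(g) if (g > 0L) 2L * g - 1L else -2L * g
.gene_right <- function(g) if (g > 0L) 2L * g else -2L * g - 1L

#' Extremity matching of a genome
#'
#' One matching edge per non-telomeric adjacency.  A circular chromosome with
#' k genes contributes k edges; a linear one k - 1 edges, leaving its two
#' telomeric extremities unsaturated.  A purely circular genome yields a
#' perfect matching on the 2n extremity vertices.
#'
#' @param g a `genome`.
#' @return a `matching` object (see [matching()]).
#' @export
genome_to_matching <- function(g) {
  stopifnot(inherits(g, "genome"))
  edges <- list()
  for (ch in g$chromosomes) {
    gs <- ch$genes
    k <- length(gs)
    if (k > 1L) {
      for (j in seq_len(k - 1L))
        edges[[length(edges) + 1L]] <- c(.gene_right(gs[j]), .gene_left(gs[j + 1L]))
    }
    if (!ch$linear)
      edges[[length(edges) + 1L]] <- c(.gene_right(gs[k]), .gene_left(gs[1L]))
  }
  if (length(edges) == 0L) return(matching(g$n, matrix(integer(0), ncol = 2L)))
  matching(g$n, do.call(rbind, edges))
}

#' Extremity matching on 2n vertices
#'
#' A set of disjoint unordered vertex pairs over the 2n gene extremities
#' (vertices `1..2n`, tail of gene g = `2g-1`, head = `2g`).  Not necessarily
#' perfect: unsaturated vertices correspond to telomeric adjacencies.
#'
#' @param n gene count (vertex set is `1..2n`).
#' @param edges two-column matrix of vertex pairs (possibly zero rows).
#' @return an object of class `matching` with fields `n` and `pair`, where
#'   `pair[v]` is the partner of vertex `v`, or `0` if unsaturated.
#' @export
matching <- function(n, edges) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 0L) stop("matching: invalid n")
  edges <- matrix(as.integer(edges), ncol = 2L)
  pair <- integer(2L * n)
  if (nrow(edges) > 0L) {
    if (any(edges < 1L) || any(edges > 2L * n)) stop("matching: vertex out of range 1..2n")
    if (any(edges[, 1L] == edges[, 2L])) stop("matching: self-loop edge")
    vs <- c(edges[, 1L], edges[, 2L])
    if (anyDuplicated(vs))
      stop("matching: vertex ", vs[duplicated(vs)][1L], " saturated more than once")
    pair[edges[, 1L]] <- edges[, 2L]
    pair[edges[, 2L]] <- edges[, 1L]
  }
  structure(list(n = n, pair = pair), class = "matching")
}

# matching from a pair/partner vector (internal fast path)
matching_from_pair <- function(n, pair) {
  structure(list(n = as.integer(n), pair = as.integer(pair)), class = "matching")
}

#' @export
print.matching <- function(x, ...) {
  e <- matching_edges(x)
  cat("<matching> n = ", x$n, ", ", nrow(e), " edge(s), ",
      2L * x$n - 2L * nrow(e), " unsaturated\n", sep = "")
  if (nrow(e) > 0L)
    cat("  ", paste(sprintf("%d-%d", e[, 1L], e[, 2L]), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @rdname matching
#' @param m a `matching`.
#' @export
matching_edges <- function(m) {
  v <- which(m$pair > seq_along(m$pair))
  cbind(v, m$pair[v], deparse.level = 0L)
}

#' @rdname matching
#' @export
unsaturated_vertices <- function(m) which(m$pair == 0L)

#' Test genomes (or matchings) for equality
#'
#' Genomes are identified with their extremity matchings: two genomes are
#' equal iff they induce the same adjacency set, which makes equality
#' invariant to chromosome order, circular rotation/reflection, and linear
#' reversal.
#'
#' @param a,b `genome` or `matching` objects on the same gene count.
#' @return logical.
#' @export
genome_equal <- function(a, b) {
  ma <- if (inherits(a, "genome")) genome_to_matching(a) else a
  mb <- if (inherits(b, "genome")) genome_to_matching(b) else b
  stopifnot(inherits(ma, "matching"), inherits(mb, "matching"))
  ma$n == mb$n && identical(ma$pair, mb$pair)
}

#' Decompose the breakpoint graph of two matchings
#'
#' The breakpoint graph BG(A, B) is the union of the two matchings on the
#' shared vertex set (edges keep their colour; a pair present in both
#' matchings contributes two parallel edges).  Every vertex has degree 0, 1
#' or 2, so the graph decomposes uniquely into cycles and paths.  Conventions:
#' a pair of parallel edges is a 2-edge cycle; a vertex unsaturated in both
#' matchings is a 0-edge path (and counts as an even path).
#'
#' @param a,b `matching` objects with equal `n` (or `genome`s, converted).
#' @return an object of class `bg_decomposition` with fields `cycles`,
#'   `paths`, `even_paths` (paths with an even number of edges, the `e` of
#'   the DCJ distance), `path_edge_lengths` (sorted), and
#'   `cycle_edge_lengths` (sorted).
#' @examples
#' a <- genome_to_matching(identity_circular(3))
#' decompose(a, a)   # 3 parallel-edge cycles
#' @export
decompose <- function(a, b) {
  if (inherits(a, "genome")) a <- genome_to_matching(a)
  if (inherits(b, "genome")) b <- genome_to_matching(b)
  stopifnot(inherits(a, "matching"), inherits(b, "matching"))
  if (a$n != b$n) stop("decompose: matchings have different n (", a$n, " vs ", b$n, ")")
  nv <- 2L * a$n
  pa <- a$pair; pb <- b$pair
  visited <- logical(nv)
  cycles <- 0L; path_lengths <- integer(0); cycle_lengths <- integer(0)

  # walk from v following colours alternately, first colour `col` (1 = a);
  # returns edge count and marks vertices; stops at a dead end
  walk_path <- function(v, col) {
    edges <- 0L
    repeat {
      visited[v] <<- TRUE
      nxt <- if (col == 1L) pa[v] else pb[v]
      if (nxt == 0L) return(edges)
      edges <- edges + 1L
      v <- nxt
      col <- 3L - col
    }
  }

  # path components: start at each unvisited vertex of degree <= 1
  deg <- (pa > 0L) + (pb > 0L)
  for (v in seq_len(nv)) {
    if (visited[v] || deg[v] == 2L) next
    col <- if (pa[v] > 0L) 1L else 2L   # degree 0: colour irrelevant
    path_lengths <- c(path_lengths, walk_path(v, col))
  }
  # remaining unvisited vertices all have degree 2: cycles
  for (v in seq_len(nv)) {
    if (visited[v]) next
    edges <- 0L
    cur <- v; col <- 1L
    repeat {
      visited[cur] <- TRUE
      nxt <- if (col == 1L) pa[cur] else pb[cur]
      edges <- edges + 1L
      cur <- nxt
      col <- 3L - col
      if (cur == v && col == 1L) break
    }
    cycles <- cycles + 1L
    cycle_lengths <- c(cycle_lengths, edges)
  }
  structure(list(
    n = a$n,
    cycles = cycles,
    paths = length(path_lengths),
    even_paths = sum(path_lengths %% 2L == 0L),
    path_edge_lengths = sort(path_lengths),
    cycle_edge_lengths = sort(cycle_lengths)
  ), class = "bg_decomposition")
}

#' @export
print.bg_decomposition <- function(x, ...) {
  cat("<breakpoint graph decomposition> n = ", x$n,
      ": ", x$cycles, " cycle(s), ", x$paths, " path(s) (",
      x$even_paths, " even)\n", sep = "")
  invisible(x)
}

.check_same_genes <- function(a, b) {
  stopifnot(inherits(a, "genome"), inherits(b, "genome"))
  if (a$n != b$n)
    stop("genomes have different gene sets: n = ", a$n, " vs ", b$n)
}

#' DCJ distance between two genomes
#'
#' `d(A, B) = n - c - e/2`, where `c` is the number of cycles and `e` the
#' number of even paths (even edge count; 0-edge paths are even) in BG(A, B).
#'
#' @param a,b `genome` objects on the same gene set.
#' @return a half-integer (numeric).
#' @export
dcj_distance <- function(a, b) {
  .check_same_genes(a, b)
  d <- decompose(genome_to_matching(a), genome_to_matching(b))
  a$n - d$cycles - d$even_paths / 2
}

#' Algebraic rearrangement distance between two genomes
#'
#' `d_a(A, B) = n - c - p/2`, with `p` the total number of paths in BG(A, B).
#' Unlike the DCJ distance, path parity does not matter, which is what makes
#' this distance derivable from the Hultman tables.
#'
#' @param a,b `genome` objects on the same gene set.
#' @return a half-integer (numeric).
#' @export
algebraic_distance <- function(a, b) {
  .check_same_genes(a, b)
  d <- decompose(genome_to_matching(a), genome_to_matching(b))
  a$n - d$cycles - d$paths / 2
}
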