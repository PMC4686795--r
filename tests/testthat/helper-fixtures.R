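# Shared test helpers: short bigint accessors, an independent union-find
# component counter, and deterministic random-genome generation.

# decimal string of a count, whatever exact type it is
bi <- function(x) as.character(bigint(x))
big_chr <- function(x) as.character(x)

# independent component counter for the union multigraph of two matchings;
# deliberately shares no code with decompose()
union_find_components <- function(ma, mb) {
  stopifnot(ma$n == mb$n)
  nv <- 2L * ma$n
  parent <- seq_len(nv)
  find <- function(v) {
    while (parent[v] != v) v <- parent[v]
    v
  }
  unite <- function(u, v) {
    ru <- find(u); rv <- find(v)
    if (ru != rv) parent[ru] <<- rv
  }
  for (m in list(ma, mb)) {
    e <- matching_edges(m)
    for (r in seq_len(nrow(e))) unite(e[r, 1L], e[r, 2L])
  }
  length(unique(vapply(seq_len(nv), find, integer(1))))
}

# deterministic random genome on genes 1..n: random signed order, random
# consecutive chromosome breaks, random linear/circular flags
random_genome <- function(n, seed) {
  set.seed(seed)
  perm <- sample(n) * sample(c(-1L, 1L), n, replace = TRUE)
  n_chr <- sample.int(max(1L, n %/% 2L), 1L)
  breaks <- sort(sample.int(n - 1L, min(n_chr - 1L, n - 1L)))
  bounds <- c(0L, breaks, n)
  chs <- lapply(seq_len(length(bounds) - 1L), function(k) {
    chromosome(perm[(bounds[k] + 1L):bounds[k + 1L]],
               linear = runif(1) < 0.5)
  })
  genome(chs)
}

# the two genomes of the paper-style worked example on 9 genes
fixture_worked_example <- function() {
  list(
    a = identity_circular(9),
    b = genome(list(chromosome(c(6L, -1L, 4L, 5L, -2L)),
                    chromosome(c(-9L, 3L, 8L, 7L), linear = TRUE)))
  )
}
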