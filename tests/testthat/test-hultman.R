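# The four Hultman-number recurrences.  Small expected values were computed
# by brute-force enumeration of matchings (the oracle module); the full
# oracle-equivalence sweep lives in test-acceptance.R.

test_that("circular family: base cases, small values and the (2n-1)!! total", {
  expect_equal(bi(hultman_circular(0, 0)), "1")
  expect_equal(bi(hultman_circular(0, 1)), "0")
  expect_equal(bi(hultman_circular(-1, 0)), "0")
  expect_equal(bi(hultman_circular(2, 1)), "2")
  expect_equal(bi(hultman_circular(2, 2)), "1")
  for (n in 0:8) expect_equal(bi(hultman_circular(n, n)), "1")
  expect_equal(bi(hultman_circular(3, 5)), "0")
  expect_equal(bi(hultman_table("circular", 4)$total), "105")  # 7!!
})

test_that("stirling numbers match direct enumeration of small permutations", {
  # all 6 permutations of 3 elements: 2 with one cycle, 3 with two, 1 with three
  expect_equal(bi(stirling_first_unsigned(3, 1)), "2")
  expect_equal(bi(stirling_first_unsigned(3, 2)), "3")
  expect_equal(bi(stirling_first_unsigned(3, 3)), "1")
  expect_equal(bi(stirling_first_unsigned(1, 1)), "1")
  expect_equal(bi(stirling_first_unsigned(4, 0)), "0")
  for (n in 0:8) expect_equal(bi(stirling_first_unsigned(n, n)), "1")
})

test_that("circular counts equal 2^(n-c) times Stirling numbers", {
  for (n in 0:12) for (c in 0:n) {
    rhs <- hultman:::big_mul(hultman:::big_pow_small(2, n - c),
                             stirling_first_unsigned(n, c))
    expect_true(hultman:::big_eq(hultman_circular(n, c), rhs),
                info = sprintf("n=%d c=%d", n, c))
  }
})

test_that("general family: base cases and the two matchings on 2 vertices", {
  expect_equal(bi(hultman_general(0, 0, 0)), "1")
  expect_equal(bi(hultman_general(0, 1, 0)), "0")
  expect_equal(bi(hultman_general(1, 1, 0)), "1")
  expect_equal(bi(hultman_general(1, 0, 1)), "1")
  ht <- hultman_table("general", 1)
  expect_equal(nrow(ht$index), 2L)
  expect_equal(bi(hultman_table("general", 2)$total), "10")  # involutions of 4
})

test_that("no breakpoint-graph component avoids the identity: c + p <= n", {
  for (n in 1:5) for (c in 0:n) for (p in 0:(2 * n)) {
    if (c + p > n)
      expect_equal(bi(hultman_general(n, c, p)), "0",
                   info = sprintf("n=%d c=%d p=%d", n, c, p))
  }
})

test_that("linear-identity family reduces to the general one at l = 0", {
  for (n in 1:4) for (c in 0:n) for (p in 0:n) {
    expect_true(hultman:::big_eq(hultman_linear_identity(n, c, p, 0),
                                 hultman_general(n, c, p)),
                info = sprintf("n=%d c=%d p=%d", n, c, p))
  }
})

test_that("linear-identity family: one gene against an empty identity", {
  expect_equal(bi(hultman_linear_identity(1, 0, 2, 1)), "1")
  expect_equal(bi(hultman_linear_identity(1, 0, 1, 1)), "1")
  expect_equal(bi(hultman_linear_identity(1, 1, 0, 1)), "0")
  expect_equal(bi(hultman_table("linear_identity", 2, l = 1)$total), "10")
  expect_error(hultman_linear_identity(2, 1, 0, 3), "0 <= l <= n")
})

test_that("linear-identity totals do not depend on l", {
  for (n in 1:5) {
    totals <- vapply(0:n, function(l)
      bi(hultman_table("linear_identity", n, l = l)$total), character(1))
    expect_equal(unique(totals), bi(matching_count(2 * n)))
  }
})

test_that("fixed-linear family: small values and the marginal over l_a", {
  expect_equal(bi(hultman_fixed_linear(1, 1, 0, 0, 0)), "1")
  expect_equal(bi(hultman_fixed_linear(1, 0, 1, 0, 1)), "1")
  expect_equal(bi(hultman_fixed_linear(1, 0, 2, 1, 1)), "1")
  expect_error(hultman_fixed_linear(2, 0, 0, 0, 5), "0 <= l_a <= n")
  for (n in 1:5) for (l_i in 0:n) for (c in 0:n) for (p in 0:n) {
    s <- bigint(0)
    for (l_a in 0:n)
      s <- hultman:::big_add(s, hultman_fixed_linear(n, c, p, l_i, l_a))
    expect_true(hultman:::big_eq(s, hultman_linear_identity(n, c, p, l_i)),
                info = sprintf("n=%d li=%d c=%d p=%d", n, l_i, c, p))
  }
})

test_that("the linear-identity table is identity-genome invariant", {
  # several concrete identities with the same number of linear chromosomes
  # (different partitions, orders, orientations) must induce the same table
  variants <- list(
    l1 = list(
      genome(list(chromosome(1:4, linear = TRUE))),
      genome(list(chromosome(c(3, -1, 4, 2), linear = TRUE))),
      genome(list(chromosome(c(2, 1), linear = TRUE), chromosome(c(4, 3)))),
      genome(list(chromosome(1, linear = TRUE), chromosome(c(-3, 2, -4))))),
    l2 = list(
      genome(list(chromosome(1:2, linear = TRUE), chromosome(3:4, linear = TRUE))),
      genome(list(chromosome(c(4, -2, 1), linear = TRUE),
                  chromosome(3, linear = TRUE))),
      genome(list(chromosome(c(2, 3), linear = TRUE),
                  chromosome(c(-1, 4), linear = TRUE)))))
  for (l in 1:2) {
    rec <- hultman_table("linear_identity", 4, l = l)
    expected <- data.frame(cycles = rec$index$c, paths = rec$index$p,
                           count = vapply(rec$counts, as.numeric, numeric(1)))
    for (g in variants[[paste0("l", l)]]) {
      expect_equal(n_linear(g), l)
      tab <- oracle_tabulate(g, "all")
      expect_equal(tab, expected, ignore_attr = TRUE)
    }
  }
})

test_that("full tables carry scenario metadata and exact string counts", {
  ht <- hultman_table("circular", 2)
  df <- as.data.frame(ht)
  expect_equal(df$c, 1:2)
  expect_equal(df$count, c("2", "1"))
  ht0 <- hultman_table("circular", 0)
  expect_equal(as.data.frame(ht0)$count, "1")
  ht_f <- hultman_table("fixed_linear", 2, l_i = 1, l_a = 1)
  expect_equal(ht_f$params, list(l_i = 1L, l_a = 1L))
  expect_error(hultman_table("linear_identity", 2), "needs l")
})

test_that("counts stay exact far beyond double precision", {
  # H_C(n, 1) = 2^(n-1) (n-1)!: check the exact digits at n = 60
  expected <- hultman:::big_mul(
    hultman:::big_pow_small(2, 59),
    Reduce(function(acc, k) hultman:::big_mul_small(acc, k), 1:59, bigint(1)))
  expect_equal(bi(hultman_circular(60, 1)), as.character(expected))
  expect_gt(nchar(bi(hultman_circular(60, 1))), 70)
})
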