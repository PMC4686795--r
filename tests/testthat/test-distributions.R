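# Exact distance distributions, probability masses and expectations.

test_that("universe sizes: double factorials and telephone numbers", {
  expect_equal(bi(circular_genome_count(0)), "1")
  expect_equal(bi(circular_genome_count(2)), "3")
  expect_equal(bi(circular_genome_count(3)), "15")
  expect_equal(bi(matching_count(0)), "1")
  expect_equal(bi(matching_count(2)), "2")
  expect_equal(bi(matching_count(4)), "10")
  expect_equal(bi(matching_count(12)), "140152")
  expect_error(matching_count(3), "even")
  # cross-check against the involution recurrence used by the sampler
  for (m in seq(0, 16, 2))
    expect_true(hultman:::big_eq(matching_count(m),
                                 hultman:::matching_count_any(m)))
})

test_that("small distance distributions match hand-derived tables", {
  d2 <- distance_distribution("circular", 2)
  expect_equal(d2$twice_d, c(0L, 2L))
  expect_equal(vapply(d2$counts, bi, character(1)), c("1", "2"))
  expect_equal(bi(d2$universe), "3")
  g1 <- distance_distribution("general", 1)
  expect_equal(g1$twice_d, c(0L, 1L))    # d = 0 and d = 0.5
  expect_equal(vapply(g1$counts, bi, character(1)), c("1", "1"))
  expect_equal(bi(g1$universe), "2")
})

test_that("only the identity genome sits at distance zero", {
  for (n in 1:8) {
    dd <- distance_distribution("circular", n)
    expect_equal(bi(dd$counts[[match(0L, dd$twice_d)]]), "1")
  }
})

test_that("distributions normalize: counts sum to the universe", {
  check_norm <- function(dd) {
    tot <- Reduce(hultman:::big_add, dd$counts, bigint(0))
    expect_true(hultman:::big_eq(tot, dd$universe))
    probs <- lapply(dd$twice_d / 2, function(d) pmf(dd, d))
    expect_equal(format(Reduce(hultman:::bigq_add, probs)), "1/1")
  }
  for (n in 1:5) {
    check_norm(distance_distribution("circular", n))
    check_norm(distance_distribution("general", n))
    for (l in 0:n) check_norm(distance_distribution("linear_identity", n, l = l))
  }
  for (li in 0:3) for (la in 0:3)
    check_norm(distance_distribution("fixed_linear", 3, l_i = li, l_a = la))
})

test_that("universes equal the closed-form genome counts", {
  for (n in 1:6) {
    expect_true(hultman:::big_eq(distance_distribution("circular", n)$universe,
                                 circular_genome_count(n)))
    expect_true(hultman:::big_eq(distance_distribution("general", n)$universe,
                                 matching_count(2 * n)))
  }
})

test_that("pmf returns reduced exact fractions and 0 off-support", {
  d2 <- distance_distribution("circular", 2)
  expect_equal(format(pmf(d2, 1)), "2/3")
  expect_equal(format(pmf(d2, 0.5)), "0/1")
  expect_equal(format(pmf(d2, 7)), "0/1")
})

test_that("expected distance matches hand-computed small cases", {
  expect_equal(format(expected_distance("circular", 1)), "0/1")
  expect_equal(format(expected_distance("circular", 2)), "2/3")
  # general n = 1: distances 0 and 1/2, each with mass 1/2 -> E = 1/4
  expect_equal(format(expected_distance("general", 1)), "1/4")
})

test_that("recurrence expectation equals the analytic closed form (exact)", {
  for (n in c(0:12, 20, 35, 50)) {
    expect_true(hultman:::bigq_eq(expected_distance("circular", n),
                                  expected_circular_closed_form(n)),
                info = sprintf("n=%d", n))
  }
  # the closed form is n - sum 1/(2j+1): spot-check its value at n = 2
  expect_equal(format(expected_circular_closed_form(2)), "2/3")
  expect_equal(bigq_decimal(expected_circular_closed_form(100), 2), "96.72")
})

test_that("circular distances reach exactly n - 1 and the mass sits high", {
  # perfect vs perfect always has a cycle, so max d = n - c = n - 1
  for (n in 2:8) {
    dd <- distance_distribution("circular", n)
    expect_equal(max(dd$twice_d) / 2, n - 1)
  }
  # right-skew at n = 21: the modal distance is within 3 of n
  dd21 <- distance_distribution("circular", 21)
  probs <- vapply(dd21$counts, as.numeric, numeric(1))
  mode_d <- dd21$twice_d[which.max(probs)] / 2
  expect_lte(abs(21 - mode_d), 3)
})

test_that("exports round-trip tables and distributions", {
  dd <- distance_distribution("circular", 3)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_tsv_export(dd, tsv)
  back <- utils::read.table(tsv, header = TRUE, sep = "\t",
                            colClasses = c(count = "character"))
  expect_equal(back$d, dd$twice_d / 2)
  expect_equal(back$count, vapply(dd$counts, bi, character(1)))
  js <- withr::local_tempfile(fileext = ".json")
  write_json_export(dd, js)
  parsed <- jsonlite::read_json(js)
  expect_equal(parsed$metadata$universe, "15")
  expect_equal(vapply(parsed$distribution, `[[`, "", "count"),
               vapply(dd$counts, bi, character(1)))
  ht <- hultman_table("general", 2)
  js2 <- withr::local_tempfile(fileext = ".json")
  write_json_export(ht, js2)
  parsed2 <- jsonlite::read_json(js2)
  expect_equal(parsed2$metadata$total, "10")
})
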