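test_that("the printed 8-haplotype sample has delta = 1 - 4/8", {
  # six distinct strings, two of them duplicated: U = 8, C = 4, S = 4
  mat <- strings_to_hap(c(sample_strings, sample_strings[c(1, 2)]))
  ci <- classify_interval(mat, 1, 5)
  expect_equal(ci$U, 8L)
  expect_equal(ci$C, 4L)
  expect_equal(ci$S, 4L)
  expect_equal(ci$ambiguous, 0L)
  expect_equal(ci$delta, 0.5)
})

test_that("identical rows are all common; forced ambiguity is detected", {
  mat <- hap_matrix(matrix(rep(c(0L, 1L, 1L), each = 7), nrow = 7))
  ci <- classify_interval(mat, 1, 3)
  expect_equal(ci$U, 7L)
  expect_equal(ci$C, 7L)
  expect_equal(ci$S, 0L)
  expect_equal(ci$delta, 0)

  # "1?" is compatible with both "10" and "11", which conflict
  amb <- strings_to_hap(c("10", "11", "1?"))
  ci2 <- classify_interval(amb, 1, 2)
  expect_equal(ci2$ambiguous, 1L)
  expect_equal(ci2$U, 2L)
  expect_equal(ci2$C, 0L)
  expect_equal(ci2$S, 2L)
  expect_equal(ci2$delta, 1)
  expect_equal(as.character(attr(ci2, "row_class")),
               c("singleton", "singleton", "ambiguous"))
})

test_that("classification matches the first-principles oracle on random data", {
  for (case in list(list(m = 10, n = 8, miss = 0, seed = 101),
                    list(m = 9, n = 7, miss = 0.15, seed = 102),
                    list(m = 12, n = 6, miss = 0.3, seed = 103))) {
    mat <- rand_hap(case$m, case$n, seed = case$seed,
                    missing_rate = case$miss)
    for (j in seq_len(ncol(mat))) {
      for (k in j:ncol(mat)) {
        got <- classify_interval(mat, j, k)
        ref <- oracle_classify(mat, j, k)
        expect_equal(got$U, ref$U)
        expect_equal(got$C, ref$C)
        expect_equal(got$S, ref$S)
        expect_equal(got$ambiguous, ref$ambiguous)
        expect_equal(got$delta, ref$delta)
        expect_equal(as.character(attr(got, "row_class")), ref$class)
      }
    }
  }
})

test_that("score_intervals equals per-interval recomputation, with and without missing data", {
  for (case in list(list(miss = 0, seed = 11), list(miss = 0.1, seed = 12))) {
    mat <- rand_hap(10, 14, seed = case$seed, missing_rate = case$miss)
    sc <- score_intervals(mat, W = 14)
    expect_equal(nrow(sc), 14 * 15 / 2)
    for (i in seq_len(nrow(sc))) {
      expect_equal(sc$delta[i], oracle_delta(mat, sc$start[i], sc$end[i]))
    }
  }
})

test_that("delta is monotone under interval nesting on complete data", {
  for (seed in c(21, 22, 23)) {
    mat <- rand_hap(8, 12, seed = seed)
    sc <- score_intervals(mat, W = 12)
    d <- matrix(NA_real_, 12, 12)
    d[cbind(sc$start, sc$end)] <- sc$delta
    violations <- 0L
    for (j in 1:12) for (k in j:12) {
      sub <- d[j:k, j:k, drop = FALSE]
      violations <- violations + sum(sub > d[j, k] + 1e-12, na.rm = TRUE)
    }
    expect_equal(violations, 0L, info = sprintf("seed %d", seed))
  }
})

test_that("conservation and range invariants hold on every interval", {
  mat <- rand_hap(11, 10, seed = 33, missing_rate = 0.1)
  m <- nrow(mat)
  for (j in 1:10) for (k in j:10) {
    ci <- classify_interval(mat, j, k)
    expect_equal(ci$ambiguous + ci$C + ci$S, m)
    expect_equal(ci$U, ci$C + ci$S)
    expect_true(ci$delta >= 0 && ci$delta <= 1)
  }
})

test_that("single-column intervals of balanced complete columns have delta 0", {
  mat <- hap_matrix(cbind(c(0L, 0L, 1L, 1L), c(1L, 1L, 0L, 0L)))
  expect_equal(interval_diversity(mat, 1, 1), 0)
  expect_equal(interval_diversity(mat, 2, 2), 0)
  expect_error(interval_diversity(mat, 2, 3), class = "hapblockr_bounds_error")
  expect_error(interval_diversity(mat, 0, 1), class = "hapblockr_bounds_error")
})

test_that("good-partner table matches exhaustive recomputation", {
  # identical rows: delta == 0 everywhere, L[i] = 1
  same <- hap_matrix(matrix(rep(c(0L, 1L, 0L, 1L, 1L), 6), nrow = 6,
                            byrow = TRUE))
  gp <- good_partner_table(same, D = 0, W = Inf)
  expect_equal(gp$L, rep(1L, 5))

  # D = 1: only the window constrains, L[i] = max(1, i - W + 1)
  mat10 <- rand_hap(6, 10, seed = 41)
  gp2 <- good_partner_table(mat10, D = 1, W = 3)
  expect_equal(gp2$L, pmax(1L, seq_len(10) - 2L))

  # seeded instances, including missing data, against the oracle
  for (case in list(list(m = 12, n = 20, miss = 0.1, D = 0.2, W = 20,
                         seed = 51),
                    list(m = 8, n = 15, miss = 0, D = 0.2, W = 6,
                         seed = 52),
                    list(m = 10, n = 12, miss = 0.2, D = 0.5, W = 12,
                         seed = 53))) {
    mat <- rand_hap(case$m, case$n, seed = case$seed,
                    missing_rate = case$miss)
    gp <- good_partner_table(mat, D = case$D, W = case$W)
    expect_equal(gp$L, oracle_partner(mat, case$D, case$W))
    # same table when rebuilt from a dense score stream
    sc <- hapblockr:::score_matrix(mat, case$W)
    gp_sc <- hapblockr:::partner_from_score_matrix(sc, case$D, case$W)
    expect_equal(gp_sc$L, gp$L)
    # table invariants
    i <- seq_len(case$n)
    ok <- !is.na(gp$L)
    expect_true(all(gp$L[ok] >= pmax(1, i[ok] - case$W + 1)))
    expect_true(all(gp$L[ok] <= i[ok]))
  }
})

test_that("coverage and diversity limits interconvert", {
  expect_equal(coverage_to_diversity(0.8), 0.2)
  expect_equal(diversity_to_coverage(0.2), 0.8)
})
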