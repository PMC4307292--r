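test_that("one feasible block covering everything is found at k = 1", {
  same <- hap_matrix(matrix(rep(c(0L, 1L, 1L, 0L, 1L, 0L), 5), nrow = 5,
                            byrow = TRUE))
  gp <- good_partner_table(same, D = 0.2, W = Inf)
  dp <- dp_longest_k(gp, 1)
  expect_equal(dp$f[2, ncol(same) + 1], ncol(same))
  seg <- dp_traceback(dp, 1)
  expect_equal(nrow(seg), 1L)
  expect_equal(c(seg$start, seg$end), c(1L, ncol(same)))
})

test_that("when only width-1 blocks are feasible, f(k, n) = min(k, n)", {
  # balanced columns (delta 0 alone) whose pairings are all singletons
  v <- cbind(rep(c(0L, 0L, 1L, 1L), 1), c(0L, 1L, 0L, 1L))
  v <- v[, rep(1:2, length.out = 7)]
  mat <- hap_matrix(v)
  gp <- good_partner_table(mat, D = 0.5, W = Inf)
  for (k in 1:3) {
    dp <- dp_longest_k(gp, k)
    expect_equal(dp$f[k + 1, 8], min(k, 7))
  }
  # and the full cover needs exactly n blocks
  seg <- min_blocks_full_cover(mat, D = 0.5)
  expect_equal(nrow(seg), 7L)
  expect_true(all(seg$width == 1L))
})

test_that("a k budget beyond the useful number of blocks returns fewer blocks", {
  same <- hap_matrix(matrix(rep(c(0L, 1L, 1L, 0L), 4), nrow = 4,
                            byrow = TRUE))
  gp <- good_partner_table(same, D = 0.2, W = Inf)
  dp <- dp_longest_k(gp, 3)
  seg <- dp_traceback(dp, 3)
  expect_equal(nrow(seg), 1L)
  expect_equal(sum(seg$width), 4)
})

test_that("longest-k DP equals the independent recursion oracle", {
  set.seed(61)
  cases <- 25L
  for (i in seq_len(cases)) {
    m <- sample(4:12, 1)
    n <- sample(6:16, 1)
    mat <- rand_hap(m, n, seed = 6000 + i)
    for (D in c(0, 0.2, 0.5)) {
      feas <- oracle_feasible(mat, D)
      gp <- good_partner_table(mat, D = D, W = Inf)
      for (k in 1:3) {
        dp <- dp_longest_k(gp, k)
        expect_equal(dp$f[k + 1, n + 1], oracle_longest_k(feas, k))
        seg <- dp_traceback(dp, k)
        expect_true(verify_segmentation(seg, mat, D = D, W = n))
        expect_equal(sum(seg$width), dp$f[k + 1, n + 1])
        expect_lte(nrow(seg), k)
      }
    }
  }
})

test_that("memoised longest-k oracle agrees with flat subset enumeration on tiny instances", {
  for (i in 1:5) {
    mat <- rand_hap(5, 8, seed = 700 + i)
    feas <- oracle_feasible(mat, 0.4)
    for (k in 1:2) {
      expect_equal(oracle_longest_k(feas, k), oracle_longest_k_flat(feas, k))
    }
  }
})

test_that("f(k, n) is non-decreasing with diminishing increments in k", {
  mat <- rand_hap(8, 14, seed = 71)
  gp <- good_partner_table(mat, D = 0.3, W = Inf)
  dp <- dp_longest_k(gp, 6)
  fk <- dp$f[, 15]
  expect_true(all(diff(fk) >= 0))
  expect_true(all(diff(diff(fk)) <= 1e-9))
})

test_that("min-blocks full cover equals the brute-force minimum", {
  set.seed(81)
  for (i in 1:20) {
    m <- sample(6:12, 1)
    n <- sample(8:20, 1)
    miss <- sample(c(0, 0, 0.1), 1)
    mat <- rand_hap(m, n, seed = 8000 + i, missing_rate = miss)
    for (D in c(0.2, 0.5)) {
      feas <- oracle_feasible(mat, D)
      want <- oracle_min_blocks(feas)
      if (!is.finite(want)) {
        expect_error(min_blocks_full_cover(mat, D = D),
                     class = "hapblockr_uncoverable_error")
      } else {
        seg <- min_blocks_full_cover(mat, D = D)
        expect_equal(nrow(seg), want)
        expect_equal(sum(seg$width), n)
        expect_true(verify_segmentation(seg, mat, D = D, W = n))
      }
    }
  }
})

test_that("an uncoverable column is reported by name", {
  # column 1 has a private allele in a 3-row matrix: delta(1,1) = 1/3 > 0
  mat <- hap_matrix(cbind(c(0L, 0L, 1L), c(0L, 1L, NA)))
  expect_error(min_blocks_full_cover(mat, D = 0),
               "column 1", class = "hapblockr_uncoverable_error")
})

test_that("reported blocks always satisfy the limits they were built under", {
  sim <- simulate_haplotypes(m = 25, n = 40, n_blocks = 4, seed = 91)
  seg <- partition_blocks(sim$matrix, D = 0.2, W = 15)
  expect_true(verify_segmentation(seg, sim$matrix))
  expect_true(all(seg$width <= 15))
  expect_equal(sum(seg$width), 40)
})
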