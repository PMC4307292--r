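test_that("common-haplotype grouping excludes singletons and ambiguous rows", {
  mat <- strings_to_hap(c(sample_strings, sample_strings[c(3, 5)]))
  g <- group_common_haplotypes(mat, 1, 5)
  expect_equal(g$k_groups, 2L)
  expect_equal(lengths(g$groups), c(2L, 2L))
  expect_setequal(unlist(g$groups), c(3L, 5L, 7L, 8L))
  # representatives of complete-data groups are the shared strings
  expect_equal(g$representatives[1, ], c(0L, 0L, 0L, 1L, 1L))
  expect_equal(g$representatives[2, ], c(0L, 0L, 0L, 0L, 1L))

  same <- hap_matrix(matrix(0L, nrow = 5, ncol = 4))
  expect_equal(group_common_haplotypes(same, 1, 4)$k_groups, 1L)
  expect_equal(lengths(group_common_haplotypes(same, 1, 4)$groups), 5L)

  distinct <- strings_to_hap(sample_strings)
  expect_equal(group_common_haplotypes(distinct, 1, 5)$k_groups, 0L)
})

test_that("a single differing locus is forced as the tagSNP", {
  mat <- strings_to_hap(c("00100", "00100", "00000", "00000"))
  g <- group_common_haplotypes(mat, 1, 5)
  expect_equal(g$k_groups, 2L)
  t <- select_tagsnps(g)
  expect_equal(t$loci, 3L)
  expect_equal(t$gamma, 1L)

  one <- hap_matrix(matrix(1L, 4, 3))
  t1 <- select_tagsnps(group_common_haplotypes(one, 1, 3))
  expect_equal(t1$gamma, 0L)
  expect_equal(t1$loci, integer(0))
})

test_that("selection is the lexicographically-first brute-force minimum", {
  set.seed(130)
  checked <- 0L
  seed <- 0L
  while (checked < 40L) {
    seed <- seed + 1L
    sim <- simulate_haplotypes(
      m = sample(10:20, 1), n = sample(6:12, 1), n_blocks = 1,
      founders_per_block = sample(2:6, 1), founder_freqs = NULL,
      singleton_rate = 0.1, missing_rate = 0, seed = 13000 + seed)
    g <- group_common_haplotypes(sim$matrix, 1, ncol(sim$matrix))
    if (g$k_groups < 2L || g$k_groups > 8L) next
    checked <- checked + 1L
    t <- select_tagsnps(g)
    want <- oracle_tagsnp(g$representatives)
    expect_equal(t$loci, as.integer(want)) # lex-first minimum set
    expect_equal(t$gamma, length(want))
    expect_gte(2^t$gamma, g$k_groups)      # information bound
    expect_true(oracle_distinguishes(g$representatives, t$loci))
  }
})

test_that("representatives that no locus separates raise a clear error", {
  # two representatives that differ only where one is missing: no locus
  # strongly distinguishes them (missing acts as a wildcard)
  res <- hapblockr:::cpp_select_tagsnps(
    matrix(c(0L, 0L, NA, 0L), nrow = 2), 1L, 2L)
  expect_false(res$found)
})

test_that("per-block tagSNP totals accumulate over a segmentation", {
  sim <- simulate_haplotypes(m = 24, n = 36, n_blocks = 3, seed = 17,
                             singleton_rate = 0, missing_rate = 0)
  seg <- partition_blocks(sim$matrix, D = 0.2, W = 12)
  seg <- add_tagsnps(seg, sim$matrix)
  expect_true(all(c("k_groups", "n_tags", "tag_loci", "tag_loci_global")
                  %in% names(seg)))
  expect_true(all(2^seg$n_tags >= seg$k_groups))
  expect_true(all(purrr::map2_lgl(seg$tag_loci, seg$tag_loci_global,
                                  ~ all(.y - .x >= 0))))
  # patterns restricted to the tags are pairwise distinct, re-verified
  for (i in seq_len(nrow(seg))) {
    g <- group_common_haplotypes(sim$matrix, seg$start[i], seg$end[i])
    if (g$k_groups >= 2L) {
      expect_true(oracle_distinguishes(g$representatives,
                                       seg$tag_loci[[i]]))
    } else {
      expect_equal(seg$n_tags[i], 0L)
    }
  }
})
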