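new_segmentation <- function(blocks, D, W, n, mode, k = NA_integer_) {
  blocks <- as_tibble(blocks)
  structure(blocks,
            D = D, W = W, n_loci = n, mode = mode, k_budget = k,
            class = c("hap_segmentation", class(tibble())))
}

#' @export
print.hap_segmentation <- function(x, ...) {
  cat(sprintf(
    "<hap_segmentation> %d blocks over %d loci (mode %s, D = %s, W = %d)\n",
    nrow(x), attr(x, "n_loci"), attr(x, "mode"),
    format(attr(x, "D")), attr(x, "W")))
  cat(sprintf("  total length %d, average length %s\n",
              sum(x$end - x$start + 1L),
              if (nrow(x) == 0L) "-" else
                format_num(mean(x$end - x$start + 1L))))
  NextMethod()
}

#' Longest-k-blocks dynamic programme
#'
#' Fills the table `f(k, j)`: the largest total number of SNPs coverable by
#' at most `k` disjoint feasible blocks within the prefix `[1, j]`. The
#' recurrence either skips locus `j` or closes the last block at `j` using
#' its good partner:
#' `f(k, j) = max(f(k, j - 1), f(k - 1, L[j] - 1) + j - L[j] + 1)`.
#' Only the widest feasible block ending at `j`, `[L[j], j]`, is considered;
#' with a monotone diversity function a narrower last block can never beat
#' it for total-length maximisation.
#'
#' @param table a [good_partner_table()].
#' @param k block budget (at least 1).
#' @return an object of class `hap_dp`: list with the `(k+1) x (n+1)` value
#'   matrix `f` (row `r`/column `c` holding `f(r-1, c-1)`), the partner
#'   table, and `k_max = k`.
#' @seealso [dp_traceback()] to extract the optimal segmentation.
#' @export
dp_longest_k <- function(table, k) {
  stopifnot(inherits(table, "good_partner_table"), k >= 1L)
  k <- as.integer(k)
  n <- table$n
  L <- table$L
  f <- matrix(0, nrow = k + 1L, ncol = n + 1L)
  for (kk in seq_len(k)) {
    frow <- f[kk + 1L, ]
    fprev <- f[kk, ]
    for (j in seq_len(n)) {
      skip <- frow[j]
      take <- if (is.na(L[j])) -Inf else fprev[L[j]] + (j - L[j] + 1)
      frow[j + 1L] <- max(skip, take)
    }
    f[kk + 1L, ] <- frow
  }
  structure(list(f = f, table = table, k_max = k), class = "hap_dp")
}

#' @export
print.hap_dp <- function(x, ...) {
  cat(sprintf("<hap_dp> longest-k table up to k = %d over %d loci; f(k, n) = %s\n",
              x$k_max, x$table$n, format(x$f[x$k_max + 1L, x$table$n + 1L])))
  invisible(x)
}

#' Trace back a longest-k segmentation
#'
#' Recovers a segmentation achieving `f(k, n)` from a filled DP table.
#' On ties the skip branch is preferred, which deterministically yields the
#' rightmost-sparse solution with the fewest blocks; fewer than `k` blocks
#' are returned when the value saturates.
#'
#' @param dp a `hap_dp` from [dp_longest_k()].
#' @param k block budget to trace (default: the table's `k_max`).
#' @return a `hap_segmentation` tibble with columns `start`, `end`, `width`
#'   (per-block `delta` is `NA` until enriched; see [partition_blocks()]).
#' @export
dp_traceback <- function(dp, k = dp$k_max) {
  stopifnot(inherits(dp, "hap_dp"), k >= 1L, k <= dp$k_max)
  f <- dp$f
  L <- dp$table$L
  n <- dp$table$n
  kk <- as.integer(k)
  j <- n
  starts <- integer(0)
  ends <- integer(0)
  while (j >= 1L && kk >= 1L) {
    if (f[kk + 1L, j + 1L] == f[kk + 1L, j]) {
      j <- j - 1L # tie or strict: skip branch preferred
    } else {
      starts <- c(L[j], starts)
      ends <- c(j, ends)
      j <- L[j] - 1L
      kk <- kk - 1L
    }
  }
  blocks <- tibble(start = starts, end = ends,
                   width = ends - starts + 1L, delta = NA_real_)
  new_segmentation(blocks, dp$table$D, dp$table$W, n, "longest-k", k)
}

#' Minimum-number-of-blocks full segmentation
#'
#' Partitions all `n` loci into the smallest possible number of feasible
#' blocks (diversity at most `D`, width at most `W`). Unlike the longest-k
#' recurrence, every feasible start in `[L[j], j]` must be considered for
#' the last block, because full coverage changes the trade-off; with
#' missing data each candidate's feasibility is verified from the score
#' table rather than assumed from monotonicity. Ties are broken toward the
#' widest last block.
#'
#' @param mat a [hap_matrix()].
#' @param D diversity upper limit.
#' @param W maximum block width in SNPs.
#' @param scores optional precomputed dense score table from the internal
#'   scorer (used by the reduce stage); computed from `mat` when missing.
#' @return a `hap_segmentation` covering every column, with per-block
#'   `delta`.
#' @export
min_blocks_full_cover <- function(mat, D = 0.2, W = Inf, scores = NULL) {
  n <- if (is.null(scores)) ncol(mat) else nrow(scores)
  W <- as.integer(min(W, n))
  if (is.null(scores)) scores <- score_matrix(mat, W)
  min_blocks_from_scores(scores, D, W)
}

min_blocks_from_scores <- function(scores, D, W) {
  n <- nrow(scores)
  W <- as.integer(min(W, n))
  g <- c(0, rep(Inf, n))
  choice <- integer(n + 1L)
  for (j in seq_len(n)) {
    sseq <- max(1L, j - W + 1L):j
    vals <- scores[cbind(sseq, j - sseq + 1L)]
    tot <- g[sseq] + 1
    tot[is.na(vals) | vals > D] <- Inf
    best <- min(tot)
    if (is.finite(best)) {
      g[j + 1L] <- best
      choice[j + 1L] <- sseq[which(tot == best)[1L]] # widest last block
    }
  }
  if (!is.finite(g[n + 1L])) {
    bad <- which(!is.finite(g)) [1L] - 1L
    abort(sprintf(
      "no feasible full segmentation: column %d cannot be covered under the diversity limit",
      bad),
      class = "hapblockr_uncoverable_error")
  }
  j <- n
  starts <- integer(0)
  ends <- integer(0)
  while (j >= 1L) {
    s <- choice[j + 1L]
    starts <- c(s, starts)
    ends <- c(j, ends)
    j <- s - 1L
  }
  blocks <- tibble(start = starts, end = ends,
                   width = ends - starts + 1L,
                   delta = scores[cbind(starts, ends - starts + 1L)])
  new_segmentation(blocks, D, W, n, "min-blocks")
}

longest_k_from_scores <- function(scores, D, W, k) {
  table <- partner_from_score_matrix(scores, D, W)
  dp <- dp_longest_k(table, k)
  seg <- dp_traceback(dp, k)
  if (nrow(seg) > 0L) {
    seg$delta <- scores[cbind(seg$start, seg$end - seg$start + 1L)]
  }
  seg
}

#' Partition a haplotype matrix into blocks
#'
#' End-to-end partitioner: scores all intervals up to width `W` (optionally
#' on a pool of workers, see [plan_chunks()]), builds the good-partner
#' table, and segments. `mode = "min-blocks"` (the default) covers every
#' locus with the fewest feasible blocks; `mode = "longest-k"` maximises
#' the total length covered by at most `k` blocks and may leave inter-block
#' gaps. Exactly one of `D` (diversity limit) and `alpha` (coverage) may be
#' given; they are linked by `D = 1 - alpha`. Per-block classification
#' counts (`U`, `C`, `S`, `ambiguous`) are attached to the result.
#'
#' @param mat a [hap_matrix()].
#' @param D diversity upper limit in `[0, 1]`.
#' @param alpha common-haplotype coverage in `[0, 1]`; `alpha = 0.8` is the
#'   conventional criterion and equals the default `D = 0.2`.
#' @param W maximum block width in SNPs (default: no cap).
#' @param mode `"min-blocks"` or `"longest-k"`.
#' @param k block budget for `mode = "longest-k"`.
#' @param workers size of the in-process worker pool used for interval
#'   scoring; any value yields identical results.
#' @return a `hap_segmentation` tibble: one row per block with `start`,
#'   `end`, `width`, `delta`, `U`, `C`, `S`, `ambiguous`.
#' @examples
#' sim <- simulate_haplotypes(m = 20, n = 30, n_blocks = 2, seed = 1)
#' partition_blocks(sim$matrix, D = 0.2)
#' @export
partition_blocks <- function(mat, D = NULL, alpha = NULL, W = Inf,
                             mode = c("min-blocks", "longest-k"), k = NULL,
                             workers = 1L) {
  mode <- match.arg(mode)
  D <- resolve_limit(D, alpha)
  n <- ncol(mat)
  W <- as.integer(min(W, n))
  scores_tbl <- score_parallel(mat, W, workers)
  seg <- reduce_select(scores_tbl, D = D, W = W, mode = mode, k = k, n = n)
  enrich_segmentation(seg, mat)
}

resolve_limit <- function(D, alpha) {
  if (!is.null(D) && !is.null(alpha)) {
    abort("give exactly one of `D` and `alpha` (they satisfy D = 1 - alpha)",
          class = "hapblockr_error")
  }
  if (is.null(D)) D <- if (is.null(alpha)) 0.2 else coverage_to_diversity(alpha)
  stopifnot(D >= 0, D <= 1)
  D
}

enrich_segmentation <- function(seg, mat) {
  if (nrow(seg) == 0L) {
    for (cl in c("U", "C", "S", "ambiguous")) seg[[cl]] <- integer(0)
    return(seg)
  }
  cls <- purrr::map2(seg$start, seg$end,
                     function(s, e) classify_interval(mat, s, e))
  at <- attributes(seg)
  seg$U <- vapply(cls, function(x) x$U, integer(1L))
  seg$C <- vapply(cls, function(x) x$C, integer(1L))
  seg$S <- vapply(cls, function(x) x$S, integer(1L))
  seg$ambiguous <- vapply(cls, function(x) x$ambiguous, integer(1L))
  seg$delta <- vapply(cls, function(x) x$delta, numeric(1L))
  attributes(seg) <- utils::modifyList(attributes(seg),
                                       at[c("D", "W", "n_loci", "mode",
                                            "k_budget", "class")])
  seg
}

#' Re-verify a segmentation post hoc
#'
#' Independent check that the reported blocks are sorted, pairwise
#' disjoint, no wider than `W`, and each satisfy `delta <= D` when their
#' diversity is recomputed directly from the matrix.
#'
#' @param seg a `hap_segmentation`.
#' @param mat the matrix it refers to.
#' @param D,W limits to verify against (default: those stored on `seg`).
#' @return `TRUE`, or an error describing the first violated property.
#' @export
verify_segmentation <- function(seg, mat, D = attr(seg, "D"),
                                W = attr(seg, "W")) {
  if (nrow(seg) == 0L) return(TRUE)
  if (is.unsorted(seg$start, strictly = TRUE) ||
      any(seg$start > seg$end)) {
    abort("blocks are not sorted non-degenerate intervals",
          class = "hapblockr_error")
  }
  if (any(utils::head(seg$end, -1L) >= utils::tail(seg$start, -1L))) {
    abort("blocks overlap", class = "hapblockr_error")
  }
  if (any(seg$end - seg$start + 1L > W)) {
    abort("a block exceeds the width cap", class = "hapblockr_error")
  }
  deltas <- purrr::map2_dbl(seg$start, seg$end,
                            function(s, e) interval_diversity(mat, s, e))
  if (any(deltas > D + 1e-12)) {
    abort("a block violates the diversity limit when recomputed",
          class = "hapblockr_error")
  }
  TRUE
}
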