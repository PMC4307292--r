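#' Plan a chunked decomposition of interval scoring
#'
#' Splits the block-start index space `1..n` into contiguous, balanced
#' ranges, one per worker; each worker later scores exactly the intervals
#' whose start falls in its range (all widths up to `W`). Ranges differ in
#' size by at most one start index, and the worker count is clamped to `n`.
#'
#' @param n number of loci.
#' @param W maximum block width in SNPs.
#' @param n_workers requested worker count.
#' @return a tibble with columns `chunk`, `start`, `end`, carrying `W` as
#'   an attribute.
#' @examples
#' plan_chunks(10, W = 5, n_workers = 2) # ranges 1..5 and 6..10
#' @export
plan_chunks <- function(n, W, n_workers) {
  stopifnot(n >= 1L, n_workers >= 1L, W >= 1L)
  w <- as.integer(min(n_workers, n))
  base <- n %/% w
  extra <- n %% w
  sizes <- rep(base, w) + c(rep(1L, extra), rep(0L, w - extra))
  ends <- cumsum(sizes)
  plan <- tibble(chunk = seq_len(w),
                 start = c(1L, utils::head(ends, -1L) + 1L),
                 end = as.integer(ends))
  attr(plan, "W") <- as.integer(min(W, n))
  plan
}

#' Score one chunk of block starts (map stage)
#'
#' Emits the diversity score of every interval whose start lies in
#' `[chunk_start, chunk_end]` and whose width is at most `W`, keyed by
#' `(start, end)`. Pure per worker: no cross-worker state, so the union of
#' all chunk outputs equals the sequential score set key-for-key.
#'
#' @param mat a [hap_matrix()].
#' @param chunk_start,chunk_end 1-based bounds of the start-index range.
#' @param W maximum block width in SNPs.
#' @return a tibble with columns `start`, `end`, `delta`.
#' @export
map_score_chunk <- function(mat, chunk_start, chunk_end, W) {
  stopifnot(chunk_start >= 1L, chunk_end >= chunk_start,
            chunk_end <= ncol(mat))
  score_intervals(mat, W = W, starts = chunk_start:chunk_end)
}

# run the map stage across an in-process pool; a failed chunk is retried
# once on the parent before giving up
score_parallel <- function(mat, W, workers = 1L) {
  n <- ncol(mat)
  plan <- plan_chunks(n, W, workers)
  runs <- if (nrow(plan) == 1L) {
    list(map_score_chunk(mat, plan$start[1L], plan$end[1L], W))
  } else {
    res <- parallel::mclapply(seq_len(nrow(plan)), function(i) {
      map_score_chunk(mat, plan$start[i], plan$end[i], W)
    }, mc.cores = nrow(plan), mc.preschedule = FALSE)
    failed <- which(vapply(res, inherits, logical(1L), "try-error"))
    for (i in failed) {
      res[[i]] <- map_score_chunk(mat, plan$start[i], plan$end[i], W)
    }
    res
  }
  dplyr::bind_rows(runs)
}

#' Select blocks from a merged score stream (reduce stage)
#'
#' Consumes the merged `(start, end, delta)` stream of all map chunks,
#' rebuilds the good-partner table (`L[i]` = smallest feasible start for
#' each locus), and runs the segmentation DP. The output is defined to be
#' identical to the sequential pipeline for every worker count. The stream
#' must cover every interval of width at most `W`; absent keys raise a
#' missing-scores error naming them.
#'
#' @param scores tibble with columns `start`, `end`, `delta` covering all
#'   intervals of width `<= W`.
#' @param D diversity upper limit.
#' @param W maximum block width in SNPs.
#' @param mode `"min-blocks"` or `"longest-k"`.
#' @param k block budget for `"longest-k"`.
#' @param n number of loci (default: inferred as `max(scores$end)`).
#' @return a `hap_segmentation` with per-block `delta`.
#' @export
reduce_select <- function(scores, D, W, mode = c("min-blocks", "longest-k"),
                          k = NULL, n = NULL) {
  mode <- match.arg(mode)
  if (is.null(n)) n <- if (nrow(scores)) max(scores$end) else 0L
  if (n < 1L || nrow(scores) == 0L) {
    abort("empty score stream: nothing to select blocks from",
          class = "hapblockr_error")
  }
  W <- as.integer(min(W, n))
  mat_sc <- matrix(NA_real_, nrow = n, ncol = W)
  widx <- scores$end - scores$start + 1L
  if (any(scores$start < 1L) || any(scores$end > n) || any(widx < 1L) ||
      any(widx > W)) {
    abort("score stream holds keys outside the interval space",
          class = "hapblockr_error")
  }
  mat_sc[cbind(scores$start, widx)] <- scores$delta
  expected <- pmin(W, n - seq_len(n) + 1L)
  js <- rep(seq_len(n), expected)
  ws <- sequence(expected)
  absent <- is.na(mat_sc[cbind(js, ws)])
  if (any(absent)) {
    keys <- paste0("(", js[absent], ",", js[absent] + ws[absent] - 1L, ")")
    abort(sprintf("score stream is missing %d interval(s): %s%s",
                  length(keys),
                  paste(utils::head(keys, 10L), collapse = " "),
                  if (length(keys) > 10L) " ..." else ""),
          class = "hapblockr_missing_scores_error")
  }
  if (mode == "min-blocks") {
    min_blocks_from_scores(mat_sc, D, W)
  } else {
    if (is.null(k)) {
      abort("mode 'longest-k' needs a block budget `k`",
            class = "hapblockr_error")
    }
    longest_k_from_scores(mat_sc, D, W, as.integer(k))
  }
}
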