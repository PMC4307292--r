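#' Classify haplotypes within a marker interval
#'
#' Within the interval `[start, end]` two haplotype rows are *compatible*
#' iff their alleles agree at every locus where both are non-missing. A row
#' is *ambiguous* iff it is compatible with two rows that are themselves
#' incompatible (only possible with missing data). Among the unambiguous
#' rows, a row is *common* iff at least one other unambiguous row is
#' compatible with it, and *singleton* otherwise. The interval diversity is
#' \eqn{\delta = S/U} where `U = C + S` counts the unambiguous rows; by
#' convention \eqn{\delta = 0} when every row is ambiguous (`U = 0`).
#'
#' @param mat a [hap_matrix()].
#' @param start,end 1-based inclusive column indices.
#' @return A one-row tibble with columns `start`, `end`, `U`, `C`, `S`,
#'   `ambiguous` and `delta`, carrying the per-row classification as
#'   attribute `row_class` (factor: ambiguous/common/singleton) and the
#'   common-haplotype group labels as attribute `group` (0 for rows not in
#'   a group).
#' @examples
#' path <- tempfile(fileext = ".txt")
#' writeLines(c("10001", "11100", "00011", "11110", "00001", "01001",
#'              "10001", "11100"), path)
#' mat <- read_allele_matrix(path)
#' classify_interval(mat, 1, 5) # delta = 4/8
#' @export
classify_interval <- function(mat, start, end) {
  check_interval(mat, start, end)
  res <- cpp_classify_interval(unclass(mat), as.integer(start),
                               as.integer(end))
  out <- tibble(start = as.integer(start), end = as.integer(end),
                U = res$U, C = res$C, S = res$S,
                ambiguous = res$ambiguous, delta = res$delta)
  attr(out, "row_class") <- factor(res$row_class, levels = 0:2,
                                   labels = c("ambiguous", "common",
                                              "singleton"))
  attr(out, "group") <- res$group
  out
}

#' Interval diversity
#'
#' \eqn{\delta_S(B) = 1 - C/U = S/U} for the block `B = [start, end]`:
#' the fraction of unambiguous haplotypes that are singletons. Pure and
#' deterministic; 0 when all rows are pairwise compatible.
#'
#' @inheritParams classify_interval
#' @return a single number in `[0, 1]`.
#' @export
interval_diversity <- function(mat, start, end) {
  classify_interval(mat, start, end)$delta
}

#' Score every interval up to a width cap
#'
#' Computes \eqn{\delta} for all intervals `[j, k]` with `j` in `starts`
#' and width `k - j + 1 <= W` (clipped at the last locus). This is the
#' map-stage computation of the chunked decomposition; with
#' `starts = 1:n_loci(mat)` it is the full sequential score set.
#'
#' @param mat a [hap_matrix()].
#' @param W maximum block width in SNPs.
#' @param starts 1-based start indices to score (default: all).
#' @return a tibble with columns `start`, `end`, `delta`, ordered by
#'   `start` then `end`.
#' @export
score_intervals <- function(mat, W, starts = NULL) {
  n <- ncol(mat)
  if (is.null(starts)) starts <- seq_len(n)
  starts <- as.integer(starts)
  stopifnot(all(starts >= 1L), all(starts <= n), W >= 1L)
  W <- as.integer(min(W, n))
  sc <- cpp_score_intervals(unclass(mat), starts, W)
  widths <- pmin(W, n - starts + 1L)
  tibble(
    start = rep(starts, widths),
    end = unlist(lapply(seq_along(starts), function(i)
      starts[i] + seq_len(widths[i]) - 1L), use.names = FALSE),
    delta = unlist(lapply(seq_along(starts), function(i)
      sc[i, seq_len(widths[i])]), use.names = FALSE)
  )
}

# dense n x W score table (score_matrix[s, w] = delta of [s, s+w-1]);
# internal currency shared by the partition DPs and the reduce stage
score_matrix <- function(mat, W) {
  n <- ncol(mat)
  W <- as.integer(min(W, n))
  cpp_score_intervals(unclass(mat), seq_len(n), W)
}

#' Good-partner table
#'
#' For every locus `i`, the good partner `L[i]` is the leftmost start such
#' that the block `[L[i], i]` is feasible: diversity at most `D` and width
#' at most `W`. `L[i]` is `NA` when no feasible block ends at `i` (possible
#' for strict limits such as `D = 0`). With complete data \eqn{\delta} is
#' monotone and a two-pointer sweep is used; with missing data every
#' candidate start in the window is verified directly.
#'
#' @param mat a [hap_matrix()].
#' @param D diversity upper limit in `[0, 1]`.
#' @param W maximum block width in SNPs (default: no cap).
#' @return an object of class `good_partner_table`: list with `L` (integer
#'   vector, `NA` allowed), `D`, `W` and `n`.
#' @export
good_partner_table <- function(mat, D = 0.2, W = Inf) {
  stopifnot(D >= 0, D <= 1, W >= 1)
  n <- ncol(mat)
  W <- as.integer(min(W, n))
  L <- cpp_good_partner(unclass(mat), D, W)
  new_partner_table(L, D, W, n)
}

new_partner_table <- function(L, D, W, n) {
  structure(list(L = L, D = D, W = W, n = n),
            class = "good_partner_table")
}

#' @export
print.good_partner_table <- function(x, ...) {
  cat(sprintf(
    "<good_partner_table> n = %d loci, D = %s, W = %d; %d infeasible loci\n",
    x$n, format(x$D), x$W, sum(is.na(x$L))))
  invisible(x)
}

#' @export
as_tibble.good_partner_table <- function(x, ...) {
  tibble(locus = seq_len(x$n), L = x$L)
}

# L derived from a dense score table (the reduce-side construction)
partner_from_score_matrix <- function(scores, D, W) {
  new_partner_table(cpp_partner_from_scores(scores, D, as.integer(W)),
                    D, as.integer(W), nrow(scores))
}

#' Convert between coverage and the diversity limit
#'
#' The common-haplotype coverage \eqn{\alpha} of a block and its diversity
#' satisfy \eqn{\alpha = 1 - \delta}, so requiring coverage at least
#' \eqn{\alpha} equals requiring \eqn{\delta \le D = 1 - \alpha}. The
#' conventional criterion \eqn{\alpha = 80\%} corresponds to `D = 0.2`.
#'
#' @param alpha coverage in `[0, 1]`.
#' @param D diversity limit in `[0, 1]`.
#' @return the corresponding limit.
#' @export
coverage_to_diversity <- function(alpha) {
  stopifnot(alpha >= 0, alpha <= 1)
  1 - alpha
}

#' @rdname coverage_to_diversity
#' @export
diversity_to_coverage <- function(D) {
  stopifnot(D >= 0, D <= 1)
  1 - D
}
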