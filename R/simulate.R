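#' Simulate a block-structured haplotype matrix with known ground truth
#'
#' Generates an `m x n` 0/1 haplotype matrix organised into planted blocks.
#' Within each block a small set of founder haplotypes is drawn (distinct
#' random 0/1 strings) and every row copies one founder, chosen
#' independently per block with skewed frequencies; a fraction of rows per
#' block is then replaced by i.i.d. uniform alleles (singleton noise), and
#' finally cells are masked to missing at `missing_rate`. Defaults emulate
#' the regime in which the 80%-coverage criterion is informative: three
#' founders per block at frequencies (0.6, 0.3, 0.1) so common haplotypes
#' cover about 90% of rows, 5% singleton noise, 2% missing data.
#'
#' @param m number of haplotype rows.
#' @param n number of SNP loci.
#' @param boundaries internal block edges as the last column of every block
#'   except the final one (sorted, within `1..n-1`); overrides `n_blocks`.
#' @param n_blocks number of equal-width planted blocks used when
#'   `boundaries` is `NULL`.
#' @param founders_per_block founders drawn per block (must satisfy
#'   `founders_per_block <= 2^width` for every block).
#' @param founder_freqs frequency vector of length `founders_per_block`
#'   (normalised internally); `NULL` uses (0.6, 0.3, 0.1) for three
#'   founders, else a geometric profile with ratio 1/2.
#' @param assignment `"sample"` draws each row's founder independently with
#'   `founder_freqs`; `"balanced"` deals founders out as evenly as possible
#'   (a shuffled round-robin), so `founders_per_block = m` yields exactly
#'   one copy of each founder and hence diversity 1 inside each block.
#' @param singleton_rate per-block probability that a row is replaced by
#'   random alleles within that block.
#' @param missing_rate per-cell probability of masking to missing.
#' @param seed integer seed; identical seed and configuration give an
#'   identical matrix. `NULL` uses (and advances) the session RNG.
#' @return list with `matrix` (a [hap_matrix()]) and `truth`: list with
#'   `boundaries` (internal edges), `blocks` (tibble of planted intervals),
#'   `founders` (list of per-block founder matrices), `assignment`
#'   (`m x n_blocks` founder index matrix) and `noise_rows` (list of
#'   per-block noised row indices).
#' @examples
#' sim <- simulate_haplotypes(m = 12, n = 30, n_blocks = 3, seed = 42)
#' sim$truth$boundaries
#' @export
simulate_haplotypes <- function(m = 30L, n = 60L, boundaries = NULL,
                                n_blocks = 3L, founders_per_block = 3L,
                                founder_freqs = NULL,
                                assignment = c("sample", "balanced"),
                                singleton_rate = 0.05, missing_rate = 0.02,
                                seed = NULL) {
  assignment <- match.arg(assignment)
  stopifnot(m >= 1L, n >= 1L, founders_per_block >= 1L,
            singleton_rate >= 0, singleton_rate <= 1,
            missing_rate >= 0, missing_rate <= 1)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  if (is.null(boundaries)) {
    stopifnot(n_blocks >= 1L, n_blocks <= n)
    edges <- floor(seq_len(n_blocks - 1L) * n / n_blocks)
  } else {
    edges <- as.integer(boundaries)
    if (length(edges) &&
        (is.unsorted(edges, strictly = TRUE) ||
         any(edges < 1L) || any(edges >= n))) {
      abort("boundaries must be strictly increasing and inside 1..n-1",
            class = "hapblockr_error")
    }
  }
  starts <- c(1L, edges + 1L)
  ends <- c(edges, n)
  widths <- ends - starts + 1L
  if (any(founders_per_block > 2^widths)) {
    abort("founders_per_block exceeds the number of distinct strings of a block",
          class = "hapblockr_error")
  }
  if (is.null(founder_freqs)) {
    founder_freqs <- if (founders_per_block == 3L) c(0.6, 0.3, 0.1)
      else 0.5^seq_len(founders_per_block)
  }
  stopifnot(length(founder_freqs) == founders_per_block,
            all(founder_freqs > 0))
  founder_freqs <- founder_freqs / sum(founder_freqs)

  alle <- matrix(0L, nrow = m, ncol = n)
  founders <- vector("list", length(starts))
  assign_mat <- matrix(0L, nrow = m, ncol = length(starts))
  noise_rows <- vector("list", length(starts))
  for (b in seq_along(starts)) {
    w <- widths[b]
    # distinct founder strings for this block
    fo <- matrix(sample(0:1, founders_per_block * w, replace = TRUE),
                 nrow = founders_per_block)
    while (anyDuplicated(apply(fo, 1L, paste, collapse = ""))) {
      dup <- which(duplicated(apply(fo, 1L, paste, collapse = "")))
      fo[dup, ] <- sample(0:1, length(dup) * w, replace = TRUE)
    }
    founders[[b]] <- fo
    assign_mat[, b] <- if (assignment == "sample") {
      sample.int(founders_per_block, m, replace = TRUE,
                 prob = founder_freqs)
    } else {
      sample(rep_len(seq_len(founders_per_block), m))
    }
    alle[, starts[b]:ends[b]] <- fo[assign_mat[, b], , drop = FALSE]
    noisy <- which(runif(m) < singleton_rate)
    noise_rows[[b]] <- noisy
    if (length(noisy)) {
      alle[noisy, starts[b]:ends[b]] <-
        sample(0:1, length(noisy) * w, replace = TRUE)
    }
  }
  if (missing_rate > 0) {
    alle[matrix(runif(m * n) < missing_rate, m, n)] <- NA_integer_
  }
  list(matrix = hap_matrix(alle),
       truth = list(boundaries = edges,
                    blocks = tibble(start = starts, end = ends),
                    founders = founders,
                    assignment = assign_mat,
                    noise_rows = noise_rows))
}

#' Score recovery of planted block boundaries
#'
#' Fraction of planted internal edges matched by an internal edge of the
#' found segmentation within `tol` loci. Internal edges are the block end
#' columns except the last; a truth with a single block has no internal
#' edges and scores 1 vacuously, while an empty found edge set against a
#' non-empty truth scores 0.
#'
#' @param found a `hap_segmentation` (full cover expected but not
#'   required).
#' @param truth the `truth` element of [simulate_haplotypes()] (or any list
#'   with a `boundaries` integer vector).
#' @param tol match tolerance in loci (default 0: exact).
#' @return a fraction in `[0, 1]`.
#' @export
score_boundary_recovery <- function(found, truth, tol = 0L) {
  planted <- truth$boundaries
  if (length(planted) == 0L) return(1)
  found_edges <- utils::head(found$end, -1L)
  if (length(found_edges) == 0L) return(0)
  mean(vapply(planted, function(e) any(abs(found_edges - e) <= tol),
              logical(1L)))
}
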