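#' Construct a haplotype matrix
#'
#' The canonical container for phased biallelic haplotype data: an
#' \eqn{m \times n} integer matrix with one row per haplotype (phased
#' chromosome) and one column per SNP locus. Cells are 0 (major allele),
#' 1 (minor allele) or `NA` (missing). Columns are addressed 1-based and
#' inclusive throughout the package, so the interval `[j, k]` contains
#' columns `j, j+1, ..., k`.
#'
#' @param alleles integer (or coercible) matrix over \{0, 1, NA\}.
#' @param row_ids optional character vector of haplotype labels (length m).
#' @param locus_ids optional character vector of SNP identifiers (length n).
#' @param positions optional numeric vector of base-pair coordinates
#'   (length n, non-decreasing).
#' @return A `hap_matrix`: the integer matrix with `row_ids`, `locus_ids`
#'   and `positions` attributes.
#' @examples
#' mat <- hap_matrix(rbind(c(0, 1, 1), c(0, 1, 1), c(1, 0, 0)))
#' n_loci(mat)
#' maf(mat)
#' @export
hap_matrix <- function(alleles, row_ids = NULL, locus_ids = NULL,
                       positions = NULL) {
  if (!is.matrix(alleles)) alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  m <- nrow(alleles)
  n <- ncol(alleles)
  if (m < 1L || n < 1L) {
    abort("a haplotype matrix needs at least one row and one column",
          class = "hapblockr_error")
  }
  bad <- !is.na(alleles) & !(alleles %in% c(0L, 1L))
  if (any(bad)) {
    abort("allele cells must be 0, 1 or missing", class = "hapblockr_error")
  }
  if (is.null(row_ids)) row_ids <- paste0("hap", seq_len(m))
  if (is.null(locus_ids)) locus_ids <- paste0("snp", seq_len(n))
  stopifnot(length(row_ids) == m, length(locus_ids) == n)
  if (!is.null(positions)) {
    stopifnot(length(positions) == n)
    if (is.unsorted(positions)) {
      abort("positions must be non-decreasing", class = "hapblockr_error")
    }
  }
  dimnames(alleles) <- NULL
  structure(alleles,
            row_ids = row_ids, locus_ids = locus_ids, positions = positions,
            class = c("hap_matrix", "matrix", "array"))
}

#' @export
print.hap_matrix <- function(x, ...) {
  cat(sprintf("<hap_matrix> %d haplotypes x %d loci; %.2f%% missing\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  k <- min(ncol(x), 20L)
  r <- min(nrow(x), 8L)
  strs <- apply(unclass(x)[seq_len(r), seq_len(k), drop = FALSE], 1L,
                function(v) paste(ifelse(is.na(v), "?", v), collapse = ""))
  cat(paste0("  ", strs, if (k < ncol(x)) " ..." else "", collapse = "\n"),
      "\n")
  if (r < nrow(x)) cat(sprintf("  ... %d more rows\n", nrow(x) - r))
  invisible(x)
}

#' @rdname hap_matrix
#' @param x a `hap_matrix`.
#' @export
n_loci <- function(x) ncol(x)

#' @rdname hap_matrix
#' @export
n_haplotypes <- function(x) nrow(x)

#' @rdname hap_matrix
#' @export
locus_ids <- function(x) attr(x, "locus_ids")

#' @rdname hap_matrix
#' @export
positions <- function(x) attr(x, "positions")

#' Per-locus minor allele frequency
#'
#' Frequency of the rarer allele among non-missing cells of each column.
#' For matrices coded by [read_hapmap_phased()] this equals the frequency
#' of allele 1 and never exceeds 0.5.
#'
#' @param x a `hap_matrix`.
#' @return numeric vector of length `n_loci(x)` in `[0, 0.5]` (`NaN` for
#'   all-missing columns).
#' @export
maf <- function(x) {
  f1 <- colMeans(unclass(x) == 1L, na.rm = TRUE)
  pmin(f1, 1 - f1)
}

#' Drop rare SNP columns
#'
#' Optional common-SNP filter: keeps columns whose minor allele frequency is
#' at least `min_maf`. The default 0 keeps every column, so filtering is
#' strictly opt-in.
#'
#' @param x a `hap_matrix`.
#' @param min_maf minimum minor allele frequency in `[0, 0.5]`.
#' @return a `hap_matrix` restricted to the retained columns.
#' @export
filter_common_snps <- function(x, min_maf = 0) {
  if (min_maf <= 0) return(x)
  keep <- which(maf(x) >= min_maf)
  if (length(keep) == 0L) {
    abort("no locus passes the MAF filter", class = "hapblockr_error")
  }
  subset_loci(x, keep)
}

#' @rdname hap_matrix
#' @param cols integer vector of column indices to keep (in order).
#' @export
subset_loci <- function(x, cols) {
  hap_matrix(unclass(x)[, cols, drop = FALSE],
             row_ids = attr(x, "row_ids"),
             locus_ids = attr(x, "locus_ids")[cols],
             positions = if (!is.null(positions(x))) positions(x)[cols])
}

check_interval <- function(x, start, end) {
  n <- ncol(x)
  if (!(length(start) == 1L && length(end) == 1L &&
        start >= 1L && end >= start && end <= n)) {
    abort(sprintf("invalid interval [%s, %s] for a %d-locus matrix",
                  start, end, n),
          class = "hapblockr_bounds_error")
  }
  invisible(TRUE)
}
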