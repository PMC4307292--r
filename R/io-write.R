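#' Write a haplotype matrix as plain 0/1/? text
#'
#' Inverse of [read_allele_matrix()]: one line per haplotype, one character
#' per locus, `?` for missing.
#'
#' @param x a [hap_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_allele_matrix <- function(x, path) {
  v <- unclass(x)
  chars <- matrix(as.character(v), nrow(v), ncol(v))
  chars[is.na(v)] <- "?"
  writeLines(apply(chars, 1L, paste, collapse = ""), path)
  invisible(path)
}

#' Write a haplotype matrix in HapMap3 phased text layout
#'
#' Emits one line per SNP (rsID, position, one nucleotide per haplotype)
#' coding allele 0 as `A`, allele 1 as `G` and missing as `N`. Because
#' [read_hapmap_phased()] recodes by observed frequency, reading the file
#' back reproduces `x` exactly when `x` is majority-coded (per-column
#' frequency of allele 1 at most 0.5, the invariant the reader itself
#' guarantees).
#'
#' @param x a [hap_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hapmap_phased <- function(x, path) {
  v <- unclass(x)
  pos <- positions(x)
  if (is.null(pos)) pos <- seq_len(ncol(v))
  nt <- matrix("N", nrow(v), ncol(v))
  nt[!is.na(v) & v == 0L] <- "A"
  nt[!is.na(v) & v == 1L] <- "G"
  lines <- c(
    paste(c("rsID", "position", attr(x, "row_ids")), collapse = " "),
    vapply(seq_len(ncol(v)), function(i)
      paste(c(locus_ids(x)[i], format(pos[i], scientific = FALSE),
              nt[, i]), collapse = " "), character(1L)))
  writeLines(lines, path)
  invisible(path)
}

#' Write a block segmentation to TSV or BED
#'
#' TSV output echoes the package's 1-based inclusive SNP indices and appends
#' a summary footer (as `#`-prefixed lines) with the block count, total and
#' average block length, and the tagSNP total. BED output converts to
#' 0-based half-open coordinates; when the matrix carries base-pair
#' positions these are used, otherwise SNP indices serve as coordinates.
#' Per-block diversity and tagSNP count ride along as extra columns.
#'
#' @param seg a segmentation (see [partition_blocks()]).
#' @param mat the [hap_matrix()] the segmentation refers to.
#' @param path output path.
#' @param format `"tsv"` or `"bed"`.
#' @param chrom chromosome label used in BED output.
#' @return `path`, invisibly.
#' @export
write_blocks <- function(seg, mat, path, format = c("tsv", "bed"),
                         chrom = "hap") {
  format <- match.arg(format)
  blocks <- as_tibble(seg)
  if (nrow(blocks) > 0L && max(blocks$end) > ncol(mat)) {
    abort("segmentation refers to columns beyond the matrix",
          class = "hapblockr_bounds_error")
  }
  n_tags <- if ("n_tags" %in% names(blocks)) blocks$n_tags
            else rep(NA_integer_, nrow(blocks))
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (format == "bed") {
    pos <- positions(mat)
    if (is.null(pos)) {
      start0 <- blocks$start - 1L
      end1 <- blocks$end
    } else {
      start0 <- pos[blocks$start] - 1
      end1 <- pos[blocks$end]
    }
    writeLines(sprintf("track name=hapblocks description=\"%s\"",
                       "haplotype blocks (delta, n_tags in cols 5-6)"), con)
    if (nrow(blocks) > 0L) {
      writeLines(sprintf("%s\t%s\t%s\tblock_%d\t%s\t%s",
                         chrom, format(start0, scientific = FALSE,
                                       trim = TRUE),
                         format(end1, scientific = FALSE, trim = TRUE),
                         seq_len(nrow(blocks)),
                         format_num(blocks$delta),
                         ifelse(is.na(n_tags), ".",
                                as.character(n_tags))), con)
    }
    return(invisible(path))
  }
  tag_str <- if ("tag_loci_global" %in% names(blocks)) {
    vapply(blocks$tag_loci_global, function(t)
      if (length(t) == 0L) "." else paste(t, collapse = ","), character(1L))
  } else rep(".", nrow(blocks))
  writeLines(paste(c("block_id", "start", "end", "width", "delta",
                     "n_tags", "tag_loci"), collapse = "\t"), con)
  if (nrow(blocks) > 0L) {
    writeLines(sprintf("block_%d\t%d\t%d\t%d\t%s\t%s\t%s",
                       seq_len(nrow(blocks)), blocks$start, blocks$end,
                       blocks$end - blocks$start + 1L,
                       format_num(blocks$delta),
                       ifelse(is.na(n_tags), ".", as.character(n_tags)),
                       tag_str), con)
  }
  width <- blocks$end - blocks$start + 1L
  writeLines(c(
    sprintf("# No. of Blocks\t%d", nrow(blocks)),
    sprintf("# Length\t%d", sum(width)),
    sprintf("# Avg. Length\t%s",
            if (nrow(blocks) == 0L) "0" else format_num(mean(width))),
    sprintf("# Tag SNP\t%s",
            if (all(is.na(n_tags))) "." else
              as.character(sum(n_tags, na.rm = TRUE)))), con)
  invisible(path)
}

# deterministic, locale-independent number formatting for reports
format_num <- function(x) {
  out <- formatC(x, digits = 6L, format = "g")
  trimws(out)
}
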