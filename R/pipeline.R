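#' Table-style block summary
#'
#' Summarises a segmentation the way chromosome-scale block tables are
#' reported: blocks grouped by width (`< 15`, `15 to 30`, `> 30` SNPs) with
#' block count, summed length, average length, the percentage of all
#' blocks, and the percentage of covered SNPs, plus a `Total` row.
#'
#' @param seg a `hap_segmentation` (tagSNP columns, if present, feed the
#'   `tag_total` attribute).
#' @return a tibble with one row per width class and a total row;
#'   attributes `tag_total` and (when computable) `max_blocks_window`.
#' @export
summarize_blocks <- function(seg) {
  width <- seg$end - seg$start + 1L
  cls <- cut(width, breaks = c(0, 14.5, 30.5, Inf),
             labels = c("< 15", "15 to 30", "> 30"))
  covered <- sum(width)
  rows <- lapply(levels(cls), function(lv) {
    w <- width[cls == lv]
    tibble(class = lv, n_blocks = length(w), length = sum(w),
           avg_length = if (length(w)) mean(w) else NA_real_,
           pct_blocks = if (nrow(seg)) 100 * length(w) / nrow(seg) else 0,
           pct_snps = if (covered) 100 * sum(w) / covered else 0)
  })
  out <- dplyr::bind_rows(c(rows, list(tibble(
    class = "Total", n_blocks = nrow(seg), length = covered,
    avg_length = if (nrow(seg)) mean(width) else NA_real_,
    pct_blocks = if (nrow(seg)) 100 else 0,
    pct_snps = if (covered) 100 else 0))))
  attr(out, "tag_total") <- if ("n_tags" %in% names(seg))
    sum(seg$n_tags, na.rm = TRUE) else NA_integer_
  out
}

#' Maximum number of blocks in a sliding position window
#'
#' The largest number of blocks intersecting any fixed-size base-pair
#' window; defined only when the matrix carries positions. This package's
#' explicit definition of a "max blocks" summary figure.
#'
#' @param seg a `hap_segmentation`.
#' @param mat the [hap_matrix()] with positions.
#' @param window_bp window size in base pairs (default 1 Mb).
#' @return an integer, or `NA` when positions are absent.
#' @export
max_blocks_window <- function(seg, mat, window_bp = 1e6) {
  pos <- positions(mat)
  if (is.null(pos) || nrow(seg) == 0L) return(NA_integer_)
  bs <- pos[seg$start]
  be <- pos[seg$end]
  # a window starting at each block start captures the local maximum
  max(vapply(bs, function(w0)
    sum(be >= w0 & bs <= w0 + window_bp), integer(1L)))
}

#' Coverage tables underlying the block/tagSNP efficiency curves
#'
#' Orders blocks by decreasing length and reports, for each 10% increment
#' of the covered region, how many blocks (and what percentage) are needed,
#' how many tagSNPs those blocks carry, and the number of covered SNPs per
#' tagSNP. These are the summary tables behind the usual
#' coverage-versus-blocks and SNPs-per-tagSNP figures.
#'
#' @param seg a `hap_segmentation`, ideally with tagSNP columns.
#' @return a tibble with columns `coverage_pct`, `n_blocks`, `pct_blocks`,
#'   `n_tags`, `pct_tags`, `snps_per_tag`.
#' @export
coverage_tables <- function(seg) {
  if (nrow(seg) == 0L) {
    return(tibble(coverage_pct = numeric(0), n_blocks = integer(0),
                  pct_blocks = numeric(0), n_tags = integer(0),
                  pct_tags = numeric(0), snps_per_tag = numeric(0)))
  }
  width <- seg$end - seg$start + 1L
  tags <- if ("n_tags" %in% names(seg)) seg$n_tags else rep(NA_integer_,
                                                            nrow(seg))
  ord <- order(-width, seg$start)
  cum_len <- cumsum(width[ord])
  cum_tags <- cumsum(tags[ord])
  total <- sum(width)
  tag_total <- sum(tags)
  purrr::map_dfr(seq(10, 100, by = 10), function(pct) {
    need <- which(cum_len >= pct / 100 * total)[1L]
    tibble(coverage_pct = pct,
           n_blocks = need,
           pct_blocks = 100 * need / nrow(seg),
           n_tags = cum_tags[need],
           pct_tags = if (!is.na(tag_total) && tag_total > 0)
             100 * cum_tags[need] / tag_total else NA_real_,
           snps_per_tag = if (!is.na(cum_tags[need]) && cum_tags[need] > 0)
             cum_len[need] / cum_tags[need] else NA_real_)
  })
}

#' Run the end-to-end pipeline
#'
#' Reads phased haplotype data, partitions it into blocks, selects tagSNPs,
#' and writes the block report (TSV and BED), the tagSNP table, the
#' width-class summary, the coverage tables, and a JSON run manifest that
#' records every parameter so the invocation is reproducible. On failure
#' any partial outputs are removed.
#'
#' @param input a [hap_matrix()] or a path.
#' @param format input format for paths: `"auto"` (by extension and
#'   content), `"hapmap"`, `"matrix"` or `"vcf"`.
#' @param out_prefix path prefix for all output files.
#' @inheritParams partition_blocks
#' @param min_maf optional common-SNP filter threshold (default 0: off).
#' @param max_gamma passed to [select_tagsnps()].
#' @param seed recorded in the manifest and set before partitioning (the
#'   pipeline itself is deterministic).
#' @param chrom chromosome label for BED output.
#' @return the enriched `hap_segmentation`, invisibly, with the written
#'   file paths as attribute `files`.
#' @export
run_pipeline <- function(input, out_prefix,
                         format = c("auto", "hapmap", "matrix", "vcf"),
                         D = NULL, alpha = NULL, W = Inf,
                         mode = c("min-blocks", "longest-k"), k = NULL,
                         workers = 1L, min_maf = 0, max_gamma = NULL,
                         seed = NULL, chrom = "hap") {
  format <- match.arg(format)
  mode <- match.arg(mode)
  Dres <- resolve_limit(D, alpha)
  mat <- if (inherits(input, "hap_matrix")) input
         else read_haplotypes(input, format)
  mat <- filter_common_snps(mat, min_maf)
  if (!is.null(seed)) set.seed(seed)
  files <- paste0(out_prefix, c("_blocks.tsv", "_blocks.bed",
                                "_tagsnps.tsv", "_summary.tsv",
                                "_coverage.tsv", "_manifest.json"))
  names(files) <- c("blocks_tsv", "blocks_bed", "tagsnps", "summary",
                    "coverage", "manifest")
  ok <- FALSE
  on.exit(if (!ok) unlink(files))
  seg <- partition_blocks(mat, D = Dres, W = W, mode = mode, k = k,
                          workers = workers)
  seg <- add_tagsnps(seg, mat, max_gamma = max_gamma)
  write_blocks(seg, mat, files[["blocks_tsv"]], format = "tsv")
  write_blocks(seg, mat, files[["blocks_bed"]], format = "bed",
               chrom = chrom)
  write_tagsnp_table(seg, mat, files[["tagsnps"]])
  summ <- summarize_blocks(seg)
  mbw <- max_blocks_window(seg, mat)
  con <- file(files[["summary"]], "wt")
  utils::write.table(as.data.frame(summ), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(c(sprintf("# Tag SNP\t%d", attr(summ, "tag_total")),
               if (!is.na(mbw)) sprintf("# Max. Blocks (1Mb)\t%d", mbw)),
             con)
  close(con)
  utils::write.table(as.data.frame(coverage_tables(seg)),
                     files[["coverage"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest <- list(
    package = "hapblockr",
    version = as.character(utils::packageVersion("hapblockr")),
    input = if (inherits(input, "hap_matrix")) "<in-memory matrix>"
            else normalizePath(input),
    format = format, m = nrow(mat), n = ncol(mat),
    D = Dres, alpha = diversity_to_coverage(Dres),
    W = if (is.finite(W)) as.integer(min(W, ncol(mat))) else ncol(mat),
    mode = mode, k = k, workers = as.integer(workers),
    min_maf = min_maf, max_gamma = max_gamma, seed = seed,
    outputs = as.list(files[names(files) != "manifest"]))
  jsonlite::write_json(manifest, files[["manifest"]], auto_unbox = TRUE,
                       pretty = TRUE, null = "null", digits = NA)
  ok <- TRUE
  attr(seg, "files") <- files
  invisible(seg)
}

read_haplotypes <- function(path, format = "auto") {
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf"
    else {
      first <- readLines(path, n = 1L, warn = FALSE)
      if (grepl("^[01?]+$", trimws(first))) "matrix" else "hapmap"
    }
  }
  switch(format,
         hapmap = read_hapmap_phased(path),
         matrix = read_allele_matrix(path),
         vcf = read_phased_vcf(path))
}

write_tagsnp_table <- function(seg, mat, path) {
  ids <- locus_ids(mat)
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(paste(c("block_id", "start", "end", "k_groups", "gamma",
                     "tag_local", "tag_global", "tag_ids"),
                   collapse = "\t"), con)
  if (nrow(seg) > 0L) {
    writeLines(sprintf(
      "block_%d\t%d\t%d\t%d\t%d\t%s\t%s\t%s",
      seq_len(nrow(seg)), seg$start, seg$end, seg$k_groups, seg$n_tags,
      vapply(seg$tag_loci, function(t)
        if (length(t)) paste(t, collapse = ",") else ".", character(1L)),
      vapply(seg$tag_loci_global, function(t)
        if (length(t)) paste(t, collapse = ",") else ".", character(1L)),
      vapply(seg$tag_loci_global, function(t)
        if (length(t)) paste(ids[t], collapse = ",") else ".",
        character(1L))), con)
  }
  writeLines(sprintf("# Tag SNP\t%d", sum(seg$n_tags, na.rm = TRUE)), con)
  invisible(path)
}
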