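#' Tidy a segmentation
#'
#' Returns the per-block table as a plain tibble, with list-columns of tag
#' loci flattened to comma-separated strings.
#'
#' @param x a `hap_segmentation`.
#' @param ... unused.
#' @return a tibble with one row per block.
#' @export
tidy.hap_segmentation <- function(x, ...) {
  out <- as_tibble(unclass_seg(x))
  for (col in c("tag_loci", "tag_loci_global")) {
    if (col %in% names(out)) {
      out[[col]] <- vapply(out[[col]], function(t)
        if (length(t)) paste(t, collapse = ",") else "", character(1L))
    }
  }
  out
}

#' Glance at a segmentation
#'
#' One-row summary of a block partition: block count, total and average
#' length, fraction of loci covered, tagSNP total, and the run limits.
#'
#' @param x a `hap_segmentation`.
#' @param ... unused.
#' @return a one-row tibble.
#' @export
glance.hap_segmentation <- function(x, ...) {
  width <- x$end - x$start + 1L
  tibble(
    n_blocks = nrow(x),
    total_length = sum(width),
    avg_length = if (nrow(x)) mean(width) else NA_real_,
    coverage = sum(width) / attr(x, "n_loci"),
    tag_total = if ("n_tags" %in% names(x)) sum(x$n_tags, na.rm = TRUE)
                else NA_integer_,
    D = attr(x, "D"),
    W = attr(x, "W"),
    mode = attr(x, "mode"))
}

unclass_seg <- function(x) {
  class(x) <- setdiff(class(x), "hap_segmentation")
  x
}
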