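#' Group the common haplotypes of a block
#'
#' Returns the compatibility classes of the common (unambiguous,
#' represented more than once) haplotype rows within `[start, end]`. With
#' complete data these are exactly the classes of identical substrings
#' with multiplicity at least 2; singleton and ambiguous rows are always
#' excluded. Each group is summarised by its consensus string (per-locus
#' majority allele over the group's rows, missing cells ignored, ties
#' toward the major allele), which for complete data is the group's shared
#' string.
#'
#' @inheritParams classify_interval
#' @return an object of class `hap_grouping`: list with `groups` (list of
#'   row-index vectors), `k_groups`, `representatives` (a `k_groups x
#'   width` 0/1/NA matrix), and the interval.
#' @export
group_common_haplotypes <- function(mat, start, end) {
  cls <- classify_interval(mat, start, end)
  grp <- attr(cls, "group")
  ids <- sort(unique(grp[grp > 0L]))
  groups <- lapply(ids, function(g) which(grp == g))
  width <- end - start + 1L
  reps <- matrix(NA_integer_, nrow = length(groups), ncol = width)
  sub <- unclass(mat)[, start:end, drop = FALSE]
  for (i in seq_along(groups)) {
    rows <- sub[groups[[i]], , drop = FALSE]
    ones <- colSums(rows == 1L, na.rm = TRUE)
    zeros <- colSums(rows == 0L, na.rm = TRUE)
    reps[i, ] <- ifelse(ones + zeros == 0L, NA_integer_,
                        ifelse(ones > zeros, 1L, 0L))
  }
  structure(list(groups = groups, k_groups = length(groups),
                 representatives = reps, start = start, end = end),
            class = "hap_grouping")
}

#' @export
print.hap_grouping <- function(x, ...) {
  cat(sprintf("<hap_grouping> block [%d, %d]: %d common-haplotype groups (sizes %s)\n",
              x$start, x$end, x$k_groups,
              paste(lengths(x$groups), collapse = ", ")))
  invisible(x)
}

# do the chosen loci tell all representatives apart? two patterns count as
# distinct only if they disagree at a locus where both are non-missing
distinguishes <- function(reps, loci) {
  sub <- reps[, loci, drop = FALSE]
  kg <- nrow(sub)
  for (a in seq_len(kg - 1L)) {
    for (b in (a + 1L):kg) {
      diff <- !is.na(sub[a, ]) & !is.na(sub[b, ]) & sub[a, ] != sub[b, ]
      if (!any(diff)) return(FALSE)
    }
  }
  TRUE
}

# next gamma-combination of 1..w in lexicographic order, NULL when done
next_combination <- function(comb, w) {
  g <- length(comb)
  i <- g
  while (i >= 1L && comb[i] == w - g + i) i <- i - 1L
  if (i < 1L) return(NULL)
  comb[i] <- comb[i] + 1L
  if (i < g) comb[(i + 1L):g] <- comb[i] + seq_len(g - i)
  comb
}

#' Select a minimal tagSNP set for a block
#'
#' Finds the smallest set `T` of loci within the block whose joint allele
#' patterns distinguish all common-haplotype groups, by enumerating
#' gamma-combinations of the block's loci in lexicographic order for
#' gamma rising from the information-theoretic floor
#' `ceiling(log2(k_groups))` (`2^|T| >= k_groups` always holds, so smaller
#' sets need not be tried). The result is the lexicographically smallest
#' minimum-cardinality set. Blocks with at most one group need no tagSNPs.
#'
#' @param grouping a `hap_grouping` from [group_common_haplotypes()].
#' @param max_gamma largest set size to try before aborting (default:
#'   `min(20, block width)`); guards against combinatorial blow-up.
#' @return an object of class `hap_tagsnps`: list with `loci` (sorted
#'   block-local indices), `gamma = length(loci)` and `k_groups`.
#' @export
select_tagsnps <- function(grouping, max_gamma = NULL) {
  stopifnot(inherits(grouping, "hap_grouping"))
  width <- grouping$end - grouping$start + 1L
  if (is.null(max_gamma)) max_gamma <- min(20L, width)
  kg <- grouping$k_groups
  if (kg <= 1L) {
    return(structure(list(loci = integer(0), gamma = 0L, k_groups = kg),
                     class = "hap_tagsnps"))
  }
  reps <- grouping$representatives
  gamma0 <- max(1L, as.integer(ceiling(log2(kg))))
  res <- cpp_select_tagsnps(reps, gamma0, as.integer(max_gamma))
  if (!res$found) {
    abort(sprintf(
      "no locus set of size <= %d distinguishes the %d common-haplotype groups",
      max_gamma, kg),
      class = "hapblockr_no_tagsnp_error")
  }
  structure(list(loci = as.integer(res$loci), gamma = length(res$loci),
                 k_groups = kg),
            class = "hap_tagsnps")
}

#' @export
print.hap_tagsnps <- function(x, ...) {
  cat(sprintf("<hap_tagsnps> gamma = %d tagSNPs distinguishing %d groups: {%s}\n",
              x$gamma, x$k_groups, paste(x$loci, collapse = ", ")))
  invisible(x)
}

#' Attach tagSNP selections to a segmentation
#'
#' Runs [group_common_haplotypes()] and [select_tagsnps()] on every block
#' and adds the columns `k_groups`, `n_tags`, `tag_loci` (block-local,
#' list-column) and `tag_loci_global` (absolute column indices,
#' list-column). Blocks with no common-haplotype groups contribute zero
#' tagSNPs to any total.
#'
#' @param seg a `hap_segmentation`.
#' @param mat the matrix it refers to.
#' @param max_gamma passed to [select_tagsnps()].
#' @return `seg` with tagSNP columns added.
#' @export
add_tagsnps <- function(seg, mat, max_gamma = NULL) {
  at <- attributes(seg)
  if (nrow(seg) == 0L) {
    seg$k_groups <- integer(0)
    seg$n_tags <- integer(0)
    seg$tag_loci <- list()
    seg$tag_loci_global <- list()
  } else {
    sel <- purrr::map2(seg$start, seg$end, function(s, e) {
      g <- group_common_haplotypes(mat, s, e)
      t <- select_tagsnps(g, max_gamma = max_gamma)
      list(k_groups = g$k_groups, n_tags = t$gamma, loci = t$loci,
           global = t$loci + s - 1L)
    })
    seg$k_groups <- vapply(sel, function(x) as.integer(x$k_groups),
                           integer(1L))
    seg$n_tags <- vapply(sel, function(x) as.integer(x$n_tags), integer(1L))
    seg$tag_loci <- lapply(sel, function(x) x$loci)
    seg$tag_loci_global <- lapply(sel, function(x) x$global)
  }
  attributes(seg) <- utils::modifyList(attributes(seg),
                                       at[c("D", "W", "n_loci", "mode",
                                            "k_budget", "class")])
  seg
}
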