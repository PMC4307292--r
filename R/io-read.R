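#' Read a HapMap3 phased-haplotype text file
#'
#' Expects the HapMap3 phased format: a header line of column labels
#' followed by one line per SNP holding the rsID, the base-pair position,
#' and one nucleotide per phased chromosome. The matrix is transposed so
#' rows are haplotypes and columns are SNPs, and each column is recoded to
#' 0/1: the more frequent nucleotide becomes 0 (major) and the other 1
#' (minor). Frequency ties are broken by coding the lexicographically
#' smaller nucleotide as 0. The characters `N`, `?`, `-` and `.` are read
#' as missing.
#'
#' @param path path to the phased-haplotype text file.
#' @return a [hap_matrix()] with locus ids, positions and haplotype labels
#'   taken from the file.
#' @seealso [read_allele_matrix()], [read_phased_vcf()]
#' @export
read_hapmap_phased <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) {
    abort(sprintf("'%s': need a header and at least one SNP line", path),
          class = "hapblockr_parse_error")
  }
  header <- strsplit(trimws(lines[1L]), "[ \t]+")[[1L]]
  hap_labels <- header[-(1:2)]
  n_hap <- length(hap_labels)
  if (n_hap < 1L) {
    abort(sprintf("'%s': header names no haplotype columns", path),
          class = "hapblockr_parse_error")
  }
  body <- lines[-1L]
  n_snp <- length(body)
  ids <- character(n_snp)
  pos <- numeric(n_snp)
  raw <- matrix("", nrow = n_snp, ncol = n_hap)
  missing_codes <- c("N", "?", "-", ".")
  for (i in seq_len(n_snp)) {
    f <- strsplit(trimws(body[i]), "[ \t]+")[[1L]]
    if (length(f) != n_hap + 2L) {
      abort(sprintf("'%s' line %d: expected %d fields, found %d",
                    path, i + 1L, n_hap + 2L, length(f)),
            class = "hapblockr_parse_error")
    }
    ids[i] <- f[1L]
    pos[i] <- suppressWarnings(as.numeric(f[2L]))
    if (is.na(pos[i])) {
      abort(sprintf("'%s' line %d: position '%s' is not numeric",
                    path, i + 1L, f[2L]),
            class = "hapblockr_parse_error")
    }
    raw[i, ] <- toupper(f[-(1:2)])
  }
  bad <- matrix(!(raw %in% c("A", "C", "G", "T", missing_codes)),
                nrow(raw), ncol(raw))
  if (any(bad)) {
    i <- which(bad, arr.ind = TRUE)[1L, 1L]
    abort(sprintf("'%s' line %d: unexpected allele character '%s'",
                  path, i + 1L, raw[bad][1L]),
          class = "hapblockr_parse_error")
  }
  raw[raw %in% missing_codes] <- NA_character_
  coded <- matrix(NA_integer_, nrow = n_snp, ncol = n_hap)
  for (i in seq_len(n_snp)) {
    obs <- raw[i, ]
    tab <- table(obs[!is.na(obs)])
    if (length(tab) > 2L) {
      abort(sprintf(
        "'%s' line %d (%s): %d distinct alleles, biallelic SNPs required",
        path, i + 1L, ids[i], length(tab)),
        class = "hapblockr_biallelic_error")
    }
    if (length(tab) == 0L) next # all missing: leave NA
    # major allele = more frequent; ties -> lexicographically smaller
    nm <- names(tab)[order(-as.integer(tab), names(tab))]
    coded[i, ] <- ifelse(is.na(obs), NA_integer_,
                         ifelse(obs == nm[1L], 0L, 1L))
  }
  hap_matrix(t(coded), row_ids = hap_labels, locus_ids = ids,
             positions = pos)
}

#' Read a plain 0/1/? allele matrix
#'
#' One line per haplotype, one character per locus, over the alphabet
#' \{0, 1, ?\}; `?` becomes missing. Lines must all have the same length.
#'
#' @param path path to the text file.
#' @return a [hap_matrix()].
#' @export
read_allele_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    abort(sprintf("'%s' holds no haplotype rows", path),
          class = "hapblockr_parse_error")
  }
  lines <- trimws(lines)
  widths <- nchar(lines)
  if (length(unique(widths)) != 1L) {
    i <- which(widths != widths[1L])[1L]
    abort(sprintf("'%s' line %d: %d characters where line 1 has %d",
                  path, i, widths[i], widths[1L]),
          class = "hapblockr_parse_error")
  }
  chars <- do.call(rbind, strsplit(lines, "", fixed = TRUE))
  bad <- matrix(!(chars %in% c("0", "1", "?")), nrow(chars), ncol(chars))
  if (any(bad)) {
    ij <- which(bad, arr.ind = TRUE)[1L, ]
    abort(sprintf("'%s' line %d column %d: illegal character '%s'",
                  path, ij[1L], ij[2L], chars[ij[1L], ij[2L]]),
          class = "hapblockr_parse_error")
  }
  alle <- matrix(NA_integer_, nrow(chars), ncol(chars))
  alle[chars == "0"] <- 0L
  alle[chars == "1"] <- 1L
  hap_matrix(alle)
}

#' Read a phased VCF into a haplotype matrix
#'
#' Converts a phased, biallelic VCF through the allele-matrix path: each
#' sample contributes two haplotype rows (`<sample>_A`, `<sample>_B`) taken
#' from the two sides of the phased genotype. Unphased genotypes (`/`
#' separator) are rejected rather than imputed, and records with more than
#' one ALT allele raise a biallelic-violation error. `.` alleles become
#' missing.
#'
#' @param path path to a VCF (plain or bgzipped).
#' @return a [hap_matrix()] with locus ids (ID field, else `chrom:pos`) and
#'   positions.
#' @export
read_phased_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = 7L,
                dimnames = list(NULL, c("CHROM", "POS", "ID", "REF", "ALT",
                                        "QUAL", "FILTER")))
  if (nrow(fix) == 0L) {
    abort(sprintf("'%s' holds no variant records", path),
          class = "hapblockr_parse_error")
  }
  if (any(grepl(",", fix[, "ALT"], fixed = TRUE))) {
    abort("multiallelic records present; biallelic SNPs required",
          class = "hapblockr_biallelic_error")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt) || ncol(gt) == 0L) {
    abort(sprintf("'%s' carries no genotype columns", path),
          class = "hapblockr_parse_error")
  }
  gt[is.na(gt)] <- ".|."
  if (any(grepl("/", gt, fixed = TRUE))) {
    abort("unphased genotypes ('/') present; phased haplotypes required",
          class = "hapblockr_parse_error")
  }
  parts <- strsplit(as.vector(gt), "|", fixed = TRUE)
  bad_len <- lengths(parts) != 2L
  if (any(bad_len)) {
    abort("genotypes must be diploid 'a|b' calls",
          class = "hapblockr_parse_error")
  }
  side <- function(i) {
    x <- vapply(parts, `[[`, character(1L), i)
    x[x == "."] <- NA_character_
    if (any(!is.na(x) & !(x %in% c("0", "1")))) {
      abort("allele indices other than 0/1 present; biallelic SNPs required",
            class = "hapblockr_biallelic_error")
    }
    matrix(as.integer(x), nrow = nrow(gt), ncol = ncol(gt))
  }
  a <- side(1L)
  b <- side(2L)
  # interleave the two haplotypes of each sample
  alle <- matrix(NA_integer_, nrow = 2L * ncol(gt), ncol = nrow(gt))
  alle[seq(1L, by = 2L, length.out = ncol(gt)), ] <- t(a)
  alle[seq(2L, by = 2L, length.out = ncol(gt)), ] <- t(b)
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[noid, "CHROM"], ":", fix[noid, "POS"])
  hap_matrix(alle,
             row_ids = as.vector(rbind(paste0(colnames(gt), "_A"),
                                       paste0(colnames(gt), "_B"))),
             locus_ids = ids,
             positions = as.numeric(fix[, "POS"]))
}
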