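#' Construct a genotype matrix
#'
#' The central in-memory container of the package: biallelic SNP calls for a
#' set of sites by a set of diploid individuals. Calls are coded as counts of
#' the alternate allele: `0` (hom-ref), `1` (het), `2` (hom-alt), `NA`
#' (missing). Sites must be sorted by chromosome then position, with strictly
#' increasing positions within a chromosome.
#'
#' @param calls Integer matrix, sites in rows, samples in columns, values in
#'   `{0, 1, 2, NA}`.
#' @param sites Data frame with columns `chrom`, `pos` (1-based bp), and
#'   optionally `id`, `ref`, `alt`.
#' @param samples Character vector of sample identifiers (defaults to the
#'   column names of `calls`).
#' @param contigs Optional named numeric vector of contig lengths in bp
#'   (typically from the VCF header); used as chromosome sizes downstream.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, sites, samples = colnames(calls),
                            contigs = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(samples)) {
    samples <- paste0("S", seq_len(ncol(calls)))
  }
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  if (!all(c("chrom", "pos") %in% names(sites))) {
    stop("`sites` must have columns 'chrom' and 'pos'")
  }
  sites$chrom <- as.character(sites$chrom)
  sites$pos <- as.numeric(sites$pos)
  if (is.null(sites$id)) sites$id <- rep(NA_character_, nrow(sites))
  if (is.null(sites$ref)) sites$ref <- rep("A", nrow(sites))
  if (is.null(sites$alt)) sites$alt <- rep("C", nrow(sites))
  if (nrow(sites) != nrow(calls)) {
    stop("nrow(calls) must equal nrow(sites)")
  }
  if (length(samples) != ncol(calls)) {
    stop("length(samples) must equal ncol(calls)")
  }
  bad <- calls[!is.na(calls)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L))) {
    stop("calls must be 0, 1, 2 or NA")
  }
  if (any(sites$pos < 1)) stop("positions must be >= 1")
  colnames(calls) <- samples
  rownames(calls) <- NULL
  gm <- structure(
    list(calls = calls, sites = sites, samples = as.character(samples),
         contigs = contigs),
    class = "genotype_matrix"
  )
  .check_sorted(gm)
  gm
}

.check_sorted <- function(gm) {
  s <- gm$sites
  for (chr in unique(s$chrom)) {
    p <- s$pos[s$chrom == chr]
    if (is.unsorted(p, strictly = TRUE)) {
      i <- which(diff(p) <= 0)[1]
      stop(sprintf(
        "sites not strictly sorted within chromosome %s (offending position %s)",
        chr, format(p[i + 1], scientific = FALSE)))
    }
  }
  invisible(gm)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d sites x %d samples over %d chromosome(s)\n",
              nrow(x$calls), ncol(x$calls), length(unique(x$sites$chrom))))
  mr <- mean(is.na(x$calls))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * mr))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Per-site alternate allele frequency
#'
#' Frequencies use non-missing calls only: the denominator is twice the
#' number of non-missing genotypes at the site.
#'
#' @param gm A [genotype_matrix()].
#' @return Numeric vector of ALT allele frequencies (NaN where all missing).
#' @export
site_alt_freq <- function(gm) {
  n_obs <- rowSums(!is.na(gm$calls))
  alt <- rowSums(gm$calls, na.rm = TRUE)
  alt / (2 * n_obs)
}

#' Per-site minor allele frequency
#'
#' @param gm A [genotype_matrix()].
#' @return Numeric vector in `[0, 0.5]` (NaN where all calls missing).
#' @export
site_maf <- function(gm) {
  p <- site_alt_freq(gm)
  pmin(p, 1 - p)
}

#' Per-site missing-call rate
#'
#' @param gm A [genotype_matrix()].
#' @return Numeric vector of the fraction of samples with a missing call.
#' @export
site_missing_rate <- function(gm) {
  rowMeans(is.na(gm$calls))
}

#' Subset a genotype matrix by site and/or sample
#'
#' @param gm A [genotype_matrix()].
#' @param sites Site index vector (logical or integer).
#' @param samples Sample index vector (logical, integer or character).
#' @return A [genotype_matrix()].
#' @export
subset_gm <- function(gm, sites = NULL, samples = NULL) {
  if (is.null(sites)) sites <- seq_len(nrow(gm$calls))
  if (is.null(samples)) samples <- seq_along(gm$samples)
  if (is.character(samples)) {
    idx <- match(samples, gm$samples)
    if (anyNA(idx)) {
      stop("unknown sample(s): ", paste(samples[is.na(idx)], collapse = ", "))
    }
    samples <- idx
  }
  genotype_matrix(gm$calls[sites, samples, drop = FALSE],
                  gm$sites[sites, , drop = FALSE],
                  gm$samples[samples],
                  contigs = gm$contigs)
}

#' Read a two-column sample metadata table
#'
#' Expects a TSV with at least the columns `sample_id` and `group` (a header
#' line is required). Each sample must carry exactly one group label.
#'
#' @param path Path to a tab-separated file.
#' @return Data frame with columns `sample_id` and `group`.
#' @export
read_sample_metadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(md))) {
    stop("metadata must have columns 'sample_id' and 'group'")
  }
  if (anyDuplicated(md$sample_id)) {
    stop("duplicated sample_id in metadata: ",
         paste(unique(md$sample_id[duplicated(md$sample_id)]), collapse = ", "))
  }
  md
}

.group_samples <- function(metadata, group) {
  ids <- metadata$sample_id[metadata$group == group]
  if (!length(ids)) stop("unknown or empty group: ", group)
  ids
}
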