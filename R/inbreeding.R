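#' Autosomal length covered by SNPs
#'
#' Default denominator for F_ROH: the summed first-to-last SNP span per
#' contig, in Mb. Supply a published constant instead where one is
#' available for the assembly at hand.
#'
#' @param gm A [genotype_matrix()].
#' @return Length in Mb.
#' @export
autosomal_length_mb <- function(gm) {
  spans <- tapply(gm$sites$pos, gm$sites$chrom,
                  function(p) max(p) - min(p) + 1)
  sum(spans) / 1e6
}

#' ROH-based genomic inbreeding coefficient
#'
#' F_ROH = L_ROH / L_au: the summed length of an individual's runs of
#' homozygosity over the autosomal genome length covered by SNPs.
#'
#' @param segments Segment data frame from [call_roh()].
#' @param sample Sample identifier.
#' @param L_au_mb Autosomal length in Mb (see [autosomal_length_mb()]).
#' @return F_ROH as a fraction in `[0, 1]`.
#' @export
f_roh <- function(segments, sample, L_au_mb) {
  if (L_au_mb <= 0) stop("L_au_mb must be > 0")
  seg <- segments[segments$sample_id == sample, , drop = FALSE]
  sum(seg$length_bp) / 1e6 / L_au_mb
}

#' Excess-homozygosity inbreeding coefficient
#'
#' F_HOM = (O_hom - E_hom) / (N_sites - E_hom), the method-of-moments
#' estimator from observed vs expected homozygous genotype counts. Over the
#' sites non-missing in the sample (and with at least two non-missing
#' cohort calls), O_hom counts homozygous calls and E_hom sums
#' 1 - 2pq * n/(n-1), with p, q the cohort allele frequencies and n the
#' non-missing allele count at the site (small-sample correction).
#'
#' @param gm A [genotype_matrix()] (cohort used for allele frequencies).
#' @param sample Sample identifier.
#' @return A list with `O_hom`, `E_hom`, `N_sites` and `F_HOM` (NA when the
#'   denominator degenerates).
#' @export
f_hom <- function(gm, sample) {
  j <- match(sample, gm$samples)
  if (is.na(j)) stop("unknown sample id: ", sample)
  g <- gm$calls[, j]
  n_obs <- rowSums(!is.na(gm$calls))
  use <- !is.na(g) & n_obs >= 2
  p <- site_alt_freq(gm)[use]
  n_alleles <- 2 * n_obs[use]
  o_hom <- sum(g[use] != 1L)
  e_hom <- sum(1 - 2 * p * (1 - p) * n_alleles / (n_alleles - 1))
  n_sites <- sum(use)
  fh <- if (isTRUE(all.equal(n_sites, e_hom))) NA_real_ else {
    (o_hom - e_hom) / (n_sites - e_hom)
  }
  list(O_hom = o_hom, E_hom = e_hom, N_sites = n_sites, F_HOM = fh)
}

#' Per-individual inbreeding table
#'
#' Computes F_ROH and F_HOM for every sample of the matrix (or a subset)
#' and returns one record per individual.
#'
#' @param gm A [genotype_matrix()].
#' @param segments Segment data frame from [call_roh()].
#' @param L_au_mb Autosomal length in Mb; defaults to
#'   [autosomal_length_mb()] of `gm`.
#' @param samples Optional subset of sample identifiers.
#' @return Data frame with columns `sample_id`, `L_ROH_mb`, `L_au_mb`,
#'   `F_ROH`, `O_hom`, `E_hom`, `N_sites`, `F_HOM`.
#' @export
inbreeding_table <- function(gm, segments, L_au_mb = NULL, samples = NULL) {
  if (is.null(L_au_mb)) L_au_mb <- autosomal_length_mb(gm)
  if (is.null(samples)) samples <- gm$samples
  rows <- lapply(samples, function(s) {
    fh <- f_hom(gm, s)
    seg <- segments[segments$sample_id == s, , drop = FALSE]
    data.frame(sample_id = s, L_ROH_mb = sum(seg$length_bp) / 1e6,
               L_au_mb = L_au_mb, F_ROH = f_roh(segments, s, L_au_mb),
               O_hom = fh$O_hom, E_hom = fh$E_hom, N_sites = fh$N_sites,
               F_HOM = fh$F_HOM, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pearson correlation between F_ROH and F_HOM within a group
#'
#' @param records Data frame from [inbreeding_table()].
#' @param metadata Optional data frame from [read_sample_metadata()]; with
#'   `group`, restricts to that group's individuals.
#' @param group Optional group label.
#' @return Pearson r, or NA when fewer than two complete pairs remain or a
#'   coefficient has zero variance.
#' @export
correlate_f <- function(records, metadata = NULL, group = NULL) {
  if (!is.null(group)) {
    ids <- .group_samples(metadata, group)
    records <- records[records$sample_id %in% ids, , drop = FALSE]
  }
  ok <- stats::complete.cases(records$F_ROH, records$F_HOM)
  x <- records$F_ROH[ok]; y <- records$F_HOM[ok]
  if (length(x) < 2 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(NA_real_)
  }
  stats::cor(x, y)
}
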