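#' Pairwise genotype-dosage LD (r-squared)
#'
#' Composite (genotype-dosage) linkage disequilibrium: for every
#' same-chromosome SNP pair within `max_dist_bp`, the squared Pearson
#' correlation of alternate-allele dosages (0/1/2) over the individuals
#' non-missing at both sites. Phase is never used. Sites monomorphic in the
#' group, and pairs with fewer than two complete observations or zero
#' within-pair variance, are skipped.
#'
#' @param gm A [genotype_matrix()].
#' @param metadata Optional metadata; with `group`, restricts to that
#'   group's individuals.
#' @param group Optional group label.
#' @param max_dist_bp Maximum pair distance (default 1 Mb).
#' @return Data frame with columns `chrom`, `dist_bp`, `r2`.
#' @export
pairwise_r2 <- function(gm, metadata = NULL, group = NULL,
                        max_dist_bp = 1e6) {
  if (!is.null(group)) {
    gm <- subset_gm(gm, samples = .group_samples(metadata, group))
  }
  if (length(gm$samples) < 2) stop("need at least 2 individuals")
  D <- gm$calls
  poly <- apply(D, 1, function(x) {
    x <- x[!is.na(x)]
    length(x) >= 2 && stats::var(x) > 0
  })
  out <- list()
  for (chr in unique(gm$sites$chrom)) {
    idx <- which(gm$sites$chrom == chr & poly)
    if (length(idx) < 2) next
    pos <- gm$sites$pos[idx]
    for (a in seq_len(length(idx) - 1)) {
      b_max <- findInterval(pos[a] + max_dist_bp, pos)
      if (b_max <= a) next
      jr <- (a + 1):b_max
      r <- suppressWarnings(stats::cor(
        D[idx[a], ], t(D[idx[jr], , drop = FALSE]),
        use = "pairwise.complete.obs"))
      r2 <- as.numeric(r)^2
      keep <- !is.na(r2)
      if (!any(keep)) next
      out[[length(out) + 1]] <- data.frame(
        chrom = chr, dist_bp = pos[jr][keep] - pos[a], r2 = r2[keep],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), dist_bp = numeric(),
                      r2 = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Bin LD pairs by distance
#'
#' Groups (distance, r-squared) pairs into half-open distance bins
#' `[k*w, (k+1)*w)` and reports the mean r-squared per non-empty bin,
#' together with the recombination fraction at the bin midpoint under a
#' constant genetic map (`cm_per_mb`, default 1 cM/Mb).
#'
#' @param pairs Data frame from [pairwise_r2()].
#' @param bin_width_bp Bin width (default 50 kb).
#' @param cm_per_mb Genetic-map conversion factor.
#' @return Data frame: `bin_start_bp`, `bin_end_bp`, `mid_bp`, `mean_r2`,
#'   `n_pairs`, `c_morgans`.
#' @export
ld_decay <- function(pairs, bin_width_bp = 5e4, cm_per_mb = 1.0) {
  if (!nrow(pairs)) stop("no LD pairs to bin")
  k <- floor(pairs$dist_bp / bin_width_bp)
  mean_r2 <- tapply(pairs$r2, k, mean)
  n_pairs <- tapply(pairs$r2, k, length)
  kk <- as.numeric(names(mean_r2))
  mid <- (kk + 0.5) * bin_width_bp
  data.frame(bin_start_bp = kk * bin_width_bp,
             bin_end_bp = (kk + 1) * bin_width_bp,
             mid_bp = mid,
             mean_r2 = as.numeric(mean_r2),
             n_pairs = as.integer(n_pairs),
             c_morgans = mid / 1e6 * cm_per_mb / 100,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Expected r-squared under the Sved relation
#'
#' E\[r2\] = 1 / (alpha + 4 N c) for effective size N and recombination
#' fraction c (Morgans). The forward map inverted by [ne_from_ld()].
#'
#' @param ne Effective population size.
#' @param c_morgans Recombination fraction (Morgans).
#' @param alpha Mating-system constant (1 for random mating including
#'   selfing; 2 excluding selfing).
#' @return Expected r-squared.
#' @export
sved_r2 <- function(ne, c_morgans, alpha = 1) {
  1 / (alpha + 4 * ne * c_morgans)
}

#' Effective population size from binned LD
#'
#' Inverts the Sved relation per distance bin: after subtracting the
#' chromosome-sample correction 1/(2n) from the bin mean r-squared
#' (floored at `eps`), Ne = (1/(4c)) (1/r2_adj - alpha), reported for the
#' generation t = 1/(2c) to which a bin of recombination fraction c looks
#' back. Negative estimates are floored at zero with a warning.
#'
#' @param bins Data frame from [ld_decay()] (needs `mean_r2`, `c_morgans`,
#'   and optionally `n_pairs`).
#' @param sample_n Number of genotyped individuals behind the r-squared
#'   values (used for the 1/(2n) adjustment).
#' @param alpha Mating-system constant (default 1).
#' @param eps Floor for the adjusted r-squared.
#' @return Data frame: `t_generations`, `ne`, `c_morgans`, `mean_r2`,
#'   `r2_adj`, sorted by `t_generations`.
#' @export
ne_from_ld <- function(bins, sample_n, alpha = 1, eps = 1e-12) {
  if (sample_n < 2) stop("sample_n must be >= 2")
  bins <- bins[bins$c_morgans > 0, , drop = FALSE]
  if (!nrow(bins)) stop("no bins with positive recombination fraction")
  r2_adj <- pmax(bins$mean_r2 - 1 / (2 * sample_n), eps)
  ne <- (1 / (4 * bins$c_morgans)) * (1 / r2_adj - alpha)
  if (any(ne < 0)) {
    warning(sum(ne < 0), " bin(s) gave negative Ne; floored at 0")
    ne <- pmax(ne, 0)
  }
  out <- data.frame(t_generations = 1 / (2 * bins$c_morgans), ne = ne,
                    c_morgans = bins$c_morgans, mean_r2 = bins$mean_r2,
                    r2_adj = r2_adj, row.names = NULL,
                    stringsAsFactors = FALSE)
  out[order(out$t_generations), , drop = FALSE]
}
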