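#' ROH detection parameters
#'
#' Parameter set for the sliding-window run-of-homozygosity scan, in the
#' PLINK `--homozyg` parameterization commonly used for livestock WGS data:
#' 50-SNP windows allowing up to 2 heterozygous and 5 missing calls, a
#' minimum run of 100 SNPs and 500 kb, at most 50 kb per SNP within a run,
#' and a maximum gap of 1000 kb between consecutive run SNPs.
#' `hit_proportion` is the per-SNP window-hit threshold above which a SNP is
#' considered part of a homozygous stretch (tool default 0.05).
#'
#' @param window_snps SNPs per sliding window.
#' @param max_het_per_window Maximum heterozygous calls allowed per window.
#' @param max_missing_per_window Maximum missing calls allowed per window.
#' @param min_snps Minimum number of SNPs in a reported run.
#' @param min_length_kb Minimum run length (kb).
#' @param max_density_kb_per_snp Maximum kb per SNP within a run.
#' @param max_gap_kb Maximum gap (kb) between consecutive run SNPs; a larger
#'   gap splits the run (a gap of exactly this size is allowed).
#' @param hit_proportion Minimum fraction of passing windows covering a SNP.
#' @return A list of class `roh_params`.
#' @export
roh_params <- function(window_snps = 50, max_het_per_window = 2,
                       max_missing_per_window = 5, min_snps = 100,
                       min_length_kb = 500, max_density_kb_per_snp = 50,
                       max_gap_kb = 1000, hit_proportion = 0.05) {
  stopifnot(window_snps >= 1, max_het_per_window >= 0,
            max_missing_per_window >= 0, min_snps >= 0, min_length_kb > 0,
            max_density_kb_per_snp > 0, max_gap_kb > 0,
            hit_proportion > 0, hit_proportion <= 1)
  structure(list(window_snps = as.integer(window_snps),
                 max_het_per_window = as.integer(max_het_per_window),
                 max_missing_per_window = as.integer(max_missing_per_window),
                 min_snps = as.integer(min_snps),
                 min_length_kb = min_length_kb,
                 max_density_kb_per_snp = max_density_kb_per_snp,
                 max_gap_kb = max_gap_kb,
                 hit_proportion = hit_proportion),
            class = "roh_params")
}

#' @export
print.roh_params <- function(x, ...) {
  cat("ROH scan parameters:\n")
  for (nm in names(x)) cat(sprintf("  %-24s %g\n", nm, x[[nm]]))
  invisible(x)
}

# rolling window pass indicator for one chromosome's genotype vector;
# returns the per-SNP fraction of covering windows that pass
.hit_fraction_chr <- function(g, params) {
  n <- length(g)
  het <- as.integer(!is.na(g) & g == 1L)
  mis <- as.integer(is.na(g))
  w <- params$window_snps
  if (n < w) {
    pass <- sum(het) <= params$max_het_per_window &&
      sum(mis) <= params$max_missing_per_window
    return(rep(as.numeric(pass), n))
  }
  ch0 <- c(0, cumsum(het)); cm0 <- c(0, cumsum(mis))
  nw <- n - w + 1
  j <- seq_len(nw)  # window j covers SNPs j .. j+w-1
  hc <- ch0[j + w] - ch0[j]
  mc <- cm0[j + w] - cm0[j]
  pass <- as.numeric(hc <= params$max_het_per_window &
                       mc <= params$max_missing_per_window)
  cp <- c(0, cumsum(pass))
  i <- seq_len(n)
  a <- pmax(1L, i - w + 1L)
  b <- pmin(i, nw)
  (cp[b + 1] - cp[a]) / (b - a + 1)
}

#' Per-SNP window hit fraction for one sample
#'
#' For each SNP, the fraction of `window_snps`-sized windows covering it
#' (within its chromosome) whose heterozygous and missing call counts stay
#' within the allowances. SNPs near chromosome ends are covered by fewer
#' windows and use the fraction over the existing ones; a chromosome with
#' fewer SNPs than the window size is evaluated as a single truncated
#' window.
#'
#' @param gm A [genotype_matrix()].
#' @param sample Sample identifier.
#' @param params A [roh_params()] object.
#' @return Numeric vector, one hit fraction per site of `gm` in site order.
#' @export
window_scan <- function(gm, sample, params = roh_params()) {
  j <- match(sample, gm$samples)
  if (is.na(j)) stop("unknown sample id: ", sample)
  g <- gm$calls[, j]
  out <- numeric(nrow(gm$calls))
  for (chr in unique(gm$sites$chrom)) {
    idx <- which(gm$sites$chrom == chr)
    out[idx] <- .hit_fraction_chr(g[idx], params)
  }
  out
}

.empty_segments <- function() {
  data.frame(sample_id = character(), chrom = character(),
             start_pos = numeric(), end_pos = numeric(),
             n_snps = integer(), length_bp = numeric(),
             stringsAsFactors = FALSE)
}

# split a vector of candidate site indices (one chromosome, consecutive in
# the site order) into runs: a non-candidate SNP or a bp gap > max_gap ends
# the run
.candidate_runs <- function(cand_idx, pos, max_gap_bp) {
  if (!length(cand_idx)) return(list())
  brk <- diff(cand_idx) > 1L | diff(pos[cand_idx]) > max_gap_bp
  split(cand_idx, cumsum(c(0L, brk)))
}

.trim_run <- function(run, g) {
  ok <- !is.na(g[run]) & g[run] != 1L
  if (!any(ok)) return(integer())
  run[min(which(ok)):max(which(ok))]
}

#' Call runs of homozygosity
#'
#' Sliding-window ROH caller. Per sample and chromosome, SNPs whose window
#' hit fraction reaches `hit_proportion` form candidate runs (broken by any
#' intervening below-threshold SNP, and wherever the gap between consecutive
#' run SNPs exceeds `max_gap_kb`); each run is trimmed at both ends to its
#' outermost homozygous non-missing SNP, and runs failing the minimum SNP
#' count, minimum length or SNP density rules are discarded. Length is the
#' inclusive bp span of the first to last SNP of the run.
#'
#' @param gm A [genotype_matrix()] (typically after [filter_sites()]).
#' @param params A [roh_params()] object.
#' @param samples Optional subset of sample identifiers.
#' @return Data frame of segments with columns `sample_id`, `chrom`,
#'   `start_pos`, `end_pos`, `n_snps`, `length_bp`, sorted by
#'   (sample, chromosome, start).
#' @export
call_roh <- function(gm, params = roh_params(), samples = NULL) {
  if (is.null(samples)) samples <- gm$samples
  if (nrow(gm$calls) == 0) return(.empty_segments())
  chrom_of <- gm$sites$chrom
  pos <- gm$sites$pos
  res <- list()
  for (s in samples) {
    frac <- window_scan(gm, s, params)
    j <- match(s, gm$samples)
    g <- gm$calls[, j]
    for (chr in unique(chrom_of)) {
      idx <- which(chrom_of == chr)
      cand <- idx[frac[idx] >= params$hit_proportion]
      runs <- .candidate_runs(cand, pos, params$max_gap_kb * 1000)
      for (run in runs) {
        run <- .trim_run(run, g)
        if (!length(run)) next
        n_snps <- length(run)
        len <- pos[run[n_snps]] - pos[run[1]] + 1
        if (n_snps < params$min_snps) next
        if (len < params$min_length_kb * 1000) next
        if (len / n_snps > params$max_density_kb_per_snp * 1000) next
        res[[length(res) + 1]] <- data.frame(
          sample_id = s, chrom = chr, start_pos = pos[run[1]],
          end_pos = pos[run[n_snps]], n_snps = n_snps, length_bp = len,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(res)) return(.empty_segments())
  out <- do.call(rbind, res)
  chr_rank <- match(out$chrom, unique(chrom_of))
  out <- out[order(match(out$sample_id, samples), chr_rank, out$start_pos), ]
  rownames(out) <- NULL
  out
}

#' Brute-force ROH caller (testing oracle)
#'
#' Same contract as [call_roh()] for a single sample, computed by direct
#' enumeration: every window's het/missing counts are recounted from
#' scratch, per-SNP hit fractions are accumulated window by window, and
#' candidate runs are assembled with an explicit element-wise walk. No
#' rolling sums or vectorized shortcuts are shared with [call_roh()].
#' Refuses matrices above 5000 sites.
#'
#' @param gm A [genotype_matrix()].
#' @param sample Sample identifier.
#' @param params A [roh_params()] object.
#' @return Data frame of segments as in [call_roh()].
#' @export
brute_force_roh <- function(gm, sample, params = roh_params()) {
  if (nrow(gm$calls) > 5000) {
    stop("brute_force_roh refuses instances above 5000 SNPs")
  }
  j <- match(sample, gm$samples)
  if (is.na(j)) stop("unknown sample id: ", sample)
  g_all <- gm$calls[, j]
  res <- list()
  for (chr in unique(gm$sites$chrom)) {
    idx <- which(gm$sites$chrom == chr)
    g <- g_all[idx]
    p <- gm$sites$pos[idx]
    n <- length(g)
    w <- min(params$window_snps, n)
    hits <- rep(0, n); covers <- rep(0, n)
    for (start in seq_len(n - w + 1)) {
      win <- start:(start + w - 1)
      n_het <- 0; n_mis <- 0
      for (k in win) {
        if (is.na(g[k])) n_mis <- n_mis + 1
        else if (g[k] == 1L) n_het <- n_het + 1
      }
      ok <- n_het <= params$max_het_per_window &&
        n_mis <= params$max_missing_per_window
      for (k in win) {
        covers[k] <- covers[k] + 1
        if (ok) hits[k] <- hits[k] + 1
      }
    }
    cand <- (hits / covers) >= params$hit_proportion
    i <- 1
    while (i <= n) {
      if (!cand[i]) { i <- i + 1; next }
      run <- i
      while (i < n && cand[i + 1] &&
             (p[i + 1] - p[i]) <= params$max_gap_kb * 1000) {
        i <- i + 1
        run <- c(run, i)
      }
      i <- i + 1
      while (length(run) && (is.na(g[run[1]]) || g[run[1]] == 1L)) {
        run <- run[-1]
      }
      while (length(run) &&
             (is.na(g[run[length(run)]]) || g[run[length(run)]] == 1L)) {
        run <- run[-length(run)]
      }
      if (!length(run)) next
      len <- p[run[length(run)]] - p[run[1]] + 1
      if (length(run) >= params$min_snps &&
          len >= params$min_length_kb * 1000 &&
          len / length(run) <= params$max_density_kb_per_snp * 1000) {
        res[[length(res) + 1]] <- data.frame(
          sample_id = sample, chrom = chr, start_pos = p[run[1]],
          end_pos = p[run[length(run)]], n_snps = length(run),
          length_bp = len, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(res)) return(.empty_segments())
  out <- do.call(rbind, res)
  out <- out[order(match(out$chrom, unique(gm$sites$chrom)), out$start_pos), ]
  rownames(out) <- NULL
  out
}

#' Write ROH segments to a TSV file
#'
#' @param segments Segment data frame from [call_roh()].
#' @param path Output path.
#' @param bed Also write a 0-based half-open BED version alongside
#'   (`<path>.bed`).
#' @return `path`, invisibly.
#' @export
write_roh <- function(segments, path, bed = FALSE) {
  utils::write.table(segments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (bed) {
    bd <- data.frame(chrom = segments$chrom,
                     start = format(segments$start_pos - 1,
                                    scientific = FALSE, trim = TRUE),
                     end = format(segments$end_pos, scientific = FALSE,
                                  trim = TRUE),
                     name = segments$sample_id)
    utils::write.table(bd, paste0(path, ".bed"), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
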