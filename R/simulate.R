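#' Simulation configuration
#'
#' Describes a synthetic diploid population with planted autozygosity:
#' background genotypes are drawn site-independently under Hardy-Weinberg
#' from a uniform allele-frequency law, and autozygous tracts are planted
#' directly (copying model) to hit per-individual target inbreeding levels.
#' Tract lengths follow the standard theory — exponential with mean 1/(2g)
#' Morgans for inbreeding g generations back, converted at `cm_per_mb` —
#' or a fixed length. Group-shared tracts at chosen loci emulate ROH
#' islands. All randomness flows through the single mandatory `seed`.
#'
#' @param n_individuals Number of diploid individuals.
#' @param chrom_lengths_bp Named numeric vector of chromosome lengths (bp).
#' @param snp_density_per_mb SNPs per Mb (uniform placement).
#' @param freq_range Background alternate-allele frequency law: uniform on
#'   this interval.
#' @param groups Character vector of group labels per individual (recycled;
#'   default one group `"pop"`).
#' @param target_f Per-individual target inbreeding F* in `[0, 1)`
#'   (recycled).
#' @param tract_mode Either `list(mode = "generations", g = <gens>)` for
#'   exponential tract lengths with mean 1/(2g) Morgans, or
#'   `list(mode = "fixed", length_bp = <bp>)`.
#' @param min_tract_bp Lower truncation for sampled tract lengths.
#' @param islands Optional data frame (`group`, `chrom`, `start`, `end`,
#'   `carrier_fraction`): a shared tract at that locus is planted in the
#'   given fraction of the group.
#' @param het_noise_rate Per-SNP heterozygote error rate inside tracts.
#' @param tract_missing_rate Per-SNP missing rate inside tracts.
#' @param background_missing_rate Per-SNP missing rate outside tracts.
#' @param cm_per_mb Genetic-map conversion (cM per Mb).
#' @param seed Integer RNG seed (mandatory).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 20,
                       chrom_lengths_bp = stats::setNames(rep(1e8, 5),
                                                          paste0("chr", 1:5)),
                       snp_density_per_mb = 300,
                       freq_range = c(0.05, 0.5),
                       groups = "pop",
                       target_f = 0,
                       tract_mode = list(mode = "generations", g = 75),
                       min_tract_bp = 1e5,
                       islands = NULL,
                       het_noise_rate = 0.005,
                       tract_missing_rate = 0.002,
                       background_missing_rate = 0.01,
                       cm_per_mb = 1.0,
                       seed) {
  if (missing(seed)) stop("`seed` is mandatory for reproducibility")
  stopifnot(n_individuals >= 1, all(chrom_lengths_bp > 0),
            snp_density_per_mb > 0,
            length(freq_range) == 2, freq_range[1] > 0, freq_range[2] <= 0.5,
            all(target_f >= 0), all(target_f < 1),
            het_noise_rate >= 0, het_noise_rate <= 1,
            tract_missing_rate >= 0, tract_missing_rate <= 1,
            background_missing_rate >= 0, background_missing_rate <= 1,
            min_tract_bp > 0, cm_per_mb > 0)
  if (!tract_mode$mode %in% c("generations", "fixed")) {
    stop("tract_mode$mode must be 'generations' or 'fixed'")
  }
  if (is.null(names(chrom_lengths_bp))) {
    names(chrom_lengths_bp) <- paste0("chr", seq_along(chrom_lengths_bp))
  }
  structure(list(
    n_individuals = as.integer(n_individuals),
    chrom_lengths_bp = chrom_lengths_bp,
    snp_density_per_mb = snp_density_per_mb,
    freq_range = freq_range,
    groups = rep_len(groups, n_individuals),
    target_f = rep_len(target_f, n_individuals),
    tract_mode = tract_mode,
    min_tract_bp = min_tract_bp,
    islands = islands,
    het_noise_rate = het_noise_rate,
    tract_missing_rate = tract_missing_rate,
    background_missing_rate = background_missing_rate,
    cm_per_mb = cm_per_mb,
    seed = as.integer(seed)), class = "sim_config")
}

# one tract length in bp under the configured law
.draw_tract_bp <- function(cfg) {
  if (cfg$tract_mode$mode == "fixed") {
    len <- cfg$tract_mode$length_bp
    if (length(len) > 1) len <- sample(len, 1)
    return(len)
  }
  g <- cfg$tract_mode$g
  repeat {
    morgans <- stats::rexp(1, rate = 2 * g)
    bp <- morgans * 100 / cfg$cm_per_mb * 1e6  # Morgans -> cM -> Mb -> bp
    if (bp >= cfg$min_tract_bp) return(bp)
  }
}

.overlaps_any <- function(chrom, start, end, tracts) {
  if (!nrow(tracts)) return(FALSE)
  same <- tracts$chrom == chrom
  any(same & tracts$start <= end & tracts$end >= start)
}

#' Simulate a genotype population with planted autozygosity
#'
#' @param cfg A [sim_config()].
#' @return A list with `gm` (a [genotype_matrix()]) and `truth`, a list of
#'   class `sim_truth` holding the planted tracts
#'   (`sample_id`, `chrom`, `start`, `end`, `island`), the island table,
#'   per-individual realized `f_true` (planted bp over genome bp), the
#'   group labels, and the configuration.
#' @export
simulate_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  genome_bp <- sum(cfg$chrom_lengths_bp)
  chroms <- names(cfg$chrom_lengths_bp)
  samples <- sprintf("ind%02d", seq_len(cfg$n_individuals))

  # site map
  site_list <- lapply(chroms, function(chr) {
    len <- cfg$chrom_lengths_bp[[chr]]
    n <- max(2, round(len / 1e6 * cfg$snp_density_per_mb))
    data.frame(chrom = chr, pos = sort(sample.int(len, n)),
               stringsAsFactors = FALSE)
  })
  sites <- do.call(rbind, site_list)
  ns <- nrow(sites)
  p_alt <- stats::runif(ns, cfg$freq_range[1], cfg$freq_range[2])
  sites$id <- sprintf("snp%d", seq_len(ns))
  sites$ref <- "A"
  sites$alt <- "C"

  calls <- matrix(stats::rbinom(ns * cfg$n_individuals, 2, p_alt),
                  nrow = ns, ncol = cfg$n_individuals)

  # island carriers chosen once per island
  island_carriers <- list()
  if (!is.null(cfg$islands) && nrow(cfg$islands)) {
    for (k in seq_len(nrow(cfg$islands))) {
      isl <- cfg$islands[k, ]
      members <- which(cfg$groups == isl$group)
      if (!length(members)) stop("island group has no members: ", isl$group)
      n_carrier <- round(isl$carrier_fraction * length(members))
      island_carriers[[k]] <- sort(sample(members, n_carrier))
    }
  }

  tract_rows <- list()
  f_true <- numeric(cfg$n_individuals)
  for (i in seq_len(cfg$n_individuals)) {
    tracts <- data.frame(chrom = character(), start = numeric(),
                         end = numeric(), island = logical(),
                         stringsAsFactors = FALSE)
    if (length(island_carriers)) {
      for (k in seq_along(island_carriers)) {
        if (!i %in% island_carriers[[k]]) next
        isl <- cfg$islands[k, ]
        tracts <- rbind(tracts, data.frame(
          chrom = isl$chrom, start = isl$start, end = isl$end,
          island = TRUE, stringsAsFactors = FALSE))
      }
    }
    target_bp <- cfg$target_f[i] * genome_bp
    total_bp <- sum(tracts$end - tracts$start + 1)
    tries <- 0
    while (total_bp < target_bp) {
      len <- min(.draw_tract_bp(cfg), max(cfg$chrom_lengths_bp) - 1)
      chr <- sample(chroms, 1, prob = cfg$chrom_lengths_bp)
      chr_len <- cfg$chrom_lengths_bp[[chr]]
      if (len >= chr_len) next
      start <- sample.int(chr_len - ceiling(len), 1)
      end <- start + round(len) - 1
      if (.overlaps_any(chr, start, end, tracts)) {
        tries <- tries + 1
        if (tries > 5000) {
          stop("target F* unreachable: cannot place non-overlapping tracts")
        }
        next
      }
      tracts <- rbind(tracts, data.frame(chrom = chr, start = start,
                                         end = end, island = FALSE,
                                         stringsAsFactors = FALSE))
      total_bp <- total_bp + (end - start + 1)
    }
    f_true[i] <- total_bp / genome_bp

    # apply tracts to the genotype column
    covered <- logical(ns)
    for (t in seq_len(nrow(tracts))) {
      idx <- which(sites$chrom == tracts$chrom[t] &
                     sites$pos >= tracts$start[t] &
                     sites$pos <= tracts$end[t])
      if (!length(idx)) next
      covered[idx] <- TRUE
      hom_alt <- stats::runif(length(idx)) < p_alt[idx]
      calls[idx, i] <- ifelse(hom_alt, 2L, 0L)
      if (cfg$het_noise_rate > 0) {
        flip <- stats::runif(length(idx)) < cfg$het_noise_rate
        calls[idx[flip], i] <- 1L
      }
      if (cfg$tract_missing_rate > 0) {
        drop <- stats::runif(length(idx)) < cfg$tract_missing_rate
        calls[idx[drop], i] <- NA_integer_
      }
    }
    if (cfg$background_missing_rate > 0) {
      bg <- which(!covered)
      drop <- bg[stats::runif(length(bg)) < cfg$background_missing_rate]
      calls[drop, i] <- NA_integer_
    }
    if (nrow(tracts)) {
      tracts$sample_id <- samples[i]
      tract_rows[[length(tract_rows) + 1]] <- tracts
    }
  }

  tracts_all <- if (length(tract_rows)) {
    out <- do.call(rbind, tract_rows)
    out[, c("sample_id", "chrom", "start", "end", "island")]
  } else {
    data.frame(sample_id = character(), chrom = character(),
               start = numeric(), end = numeric(), island = logical(),
               stringsAsFactors = FALSE)
  }

  gm <- genotype_matrix(calls, sites, samples,
                        contigs = cfg$chrom_lengths_bp)
  truth <- structure(list(tracts = tracts_all,
                          islands = cfg$islands,
                          f_true = stats::setNames(f_true, samples),
                          groups = stats::setNames(cfg$groups, samples),
                          config = cfg),
                     class = "sim_truth")
  list(gm = gm, truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("sim_truth: %d planted tracts in %d individuals, mean F_true %.4f\n",
              nrow(x$tracts), length(x$f_true), mean(x$f_true)))
  invisible(x)
}

#' Write simulator outputs to files
#'
#' Writes the genotype VCF (seed recorded in the header), the truth tracts
#' as BED, per-individual realized inbreeding as TSV, and a JSON copy of
#' the configuration.
#'
#' @param sim Result of [simulate_population()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_simulation <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- sim$truth$config
  write_vcf(sim$gm, file.path(out_dir, "genotypes.vcf.gz"),
            extra_header = sprintf("##rohscan_sim_seed=%d", cfg$seed))
  tr <- sim$truth$tracts
  utils::write.table(
    data.frame(chrom = tr$chrom,
               start = format(tr$start - 1, scientific = FALSE, trim = TRUE),
               end = format(tr$end, scientific = FALSE, trim = TRUE),
               name = tr$sample_id),
    file.path(out_dir, "truth_tracts.bed"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(sample_id = names(sim$truth$f_true),
               group = sim$truth$groups,
               f_true = sim$truth$f_true),
    file.path(out_dir, "truth_f.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  cfg_json <- cfg
  class(cfg_json) <- NULL
  jsonlite::write_json(cfg_json, file.path(out_dir, "sim_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

# summed bp overlap of [s1,e1] with a set of intervals
.overlap_bp <- function(s1, e1, starts, ends) {
  ov <- pmin(e1, ends) - pmax(s1, starts) + 1
  sum(ov[ov > 0])
}

#' End-to-end pipeline check against simulation truth
#'
#' Runs detection, inbreeding and (when islands were planted) island
#' discovery on a simulated population and scores the results against the
#' recorded truth: tract recall and segment precision at 50 percent
#' reciprocal bp-overlap, the mean absolute F_ROH error, and per planted
#' island whether exactly one called island overlaps the locus.
#'
#' @param cfg A [sim_config()].
#' @param params A [roh_params()].
#' @param top_fraction Island threshold fraction (see
#'   [island_threshold()]).
#' @return A list report: `n_segments`, `recall`, `precision`,
#'   `mean_f_error`, `f_table`, and `island_hits` (NULL without islands).
#' @export
end_to_end_check <- function(cfg, params = roh_params(),
                             top_fraction = 0.005) {
  sim <- simulate_population(cfg)
  seg <- call_roh(sim$gm, params)
  truth <- sim$truth

  # recall: planted tract recovered when called segments of the same
  # individual cover >= 50% of its bp
  tr <- truth$tracts
  rec <- logical(nrow(tr))
  for (k in seq_len(nrow(tr))) {
    s <- seg[seg$sample_id == tr$sample_id[k] & seg$chrom == tr$chrom[k], ]
    ov <- .overlap_bp(tr$start[k], tr$end[k], s$start_pos, s$end_pos)
    rec[k] <- ov >= 0.5 * (tr$end[k] - tr$start[k] + 1)
  }
  # precision: called segment is true when >= 50% of its bp lies in tracts
  prec <- logical(nrow(seg))
  for (k in seq_len(nrow(seg))) {
    t <- tr[tr$sample_id == seg$sample_id[k] & tr$chrom == seg$chrom[k], ]
    ov <- .overlap_bp(seg$start_pos[k], seg$end_pos[k], t$start, t$end)
    prec[k] <- ov >= 0.5 * seg$length_bp[k]
  }

  inb <- inbreeding_table(sim$gm, seg)
  f_table <- data.frame(sample_id = inb$sample_id, f_roh = inb$F_ROH,
                        f_true = as.numeric(truth$f_true[inb$sample_id]))

  island_hits <- NULL
  if (!is.null(truth$islands) && nrow(truth$islands)) {
    md <- data.frame(sample_id = names(truth$groups),
                     group = truth$groups, stringsAsFactors = FALSE)
    island_hits <- lapply(seq_len(nrow(truth$islands)), function(k) {
      isl <- truth$islands[k, ]
      called <- find_islands(seg, sim$gm, md, isl$group, top_fraction)
      hit <- called$chrom == isl$chrom & called$start_pos <= isl$end &
        called$end_pos >= isl$start
      list(group = isl$group, n_called = nrow(called), n_overlapping =
             sum(hit), exactly_one = nrow(called) == 1 && sum(hit) == 1)
    })
  }

  list(n_segments = nrow(seg),
       recall = if (nrow(tr)) mean(rec) else NA_real_,
       precision = if (nrow(seg)) mean(prec) else NA_real_,
       mean_f_error = mean(abs(f_table$f_roh - f_table$f_true)),
       f_table = f_table,
       island_hits = island_hits)
}
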