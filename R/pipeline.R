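#' Run the full ROH analysis pipeline
#'
#' Orchestrates filter -> detect -> stats -> inbreeding -> islands ->
#' LD/Ne on a VCF, writing one TSV per stage plus a JSON run manifest
#' (package version, parameters, input checksums, output checksums) to
#' `out_dir`. A stage whose output file already exists is skipped and its
#' file reused (`overwrite = TRUE` forces recomputation), so stages are
#' individually re-runnable. A failing stage aborts with the stage named;
#' earlier outputs are retained.
#'
#' @param vcf Path to the input VCF (`.vcf`/`.vcf.gz`).
#' @param metadata Path to the sample metadata TSV (`sample_id`, `group`).
#' @param out_dir Output directory.
#' @param gtf Optional GTF/GFF path for island gene annotation.
#' @param island_groups Groups to scan for islands (default: all groups in
#'   the metadata).
#' @param params A [roh_params()].
#' @param max_missing,min_maf Site filters (see [filter_sites()]).
#' @param L_au_mb Autosomal length override for F_ROH (default: derived
#'   from SNP coverage).
#' @param top_fraction,min_island_snps Island settings.
#' @param ld_group Group used for LD decay and Ne (default: the largest).
#' @param ld_max_dist_bp,ld_bin_width_bp LD settings.
#' @param overwrite Recompute stages whose outputs already exist.
#' @return The manifest, invisibly.
#' @export
run_roh_pipeline <- function(vcf, metadata, out_dir, gtf = NULL,
                             island_groups = NULL, params = roh_params(),
                             max_missing = 0.1, min_maf = 0.05,
                             L_au_mb = NULL, top_fraction = 0.005,
                             min_island_snps = 2, ld_group = NULL,
                             ld_max_dist_bp = 1e6, ld_bin_width_bp = 5e4,
                             overwrite = FALSE) {
  for (f in c(vcf, metadata, gtf)) {
    if (!file.exists(f)) stop("input file not found: ", f)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  md <- read_sample_metadata(metadata)
  if (is.null(island_groups)) island_groups <- unique(md$group)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  paths <- list(
    filtered = file.path(out_dir, "filtered.vcf.gz"),
    roh = file.path(out_dir, "roh.tsv"),
    ind = file.path(out_dir, "individual_summary.tsv"),
    breed = file.path(out_dir, "breed_summary.tsv"),
    inb = file.path(out_dir, "inbreeding.tsv"),
    islands = file.path(out_dir, "islands.tsv"),
    occurrence = file.path(out_dir, "occurrence.tsv"),
    ld = file.path(out_dir, "ld_decay.tsv"),
    ne = file.path(out_dir, "ne.tsv"))
  stages_run <- character()

  gm <- stage("filter", {
    if (file.exists(paths$filtered) && !overwrite) {
      read_vcf(paths$filtered)
    } else {
      g <- filter_sites(read_vcf(vcf), max_missing, min_maf, verbose = TRUE)
      write_vcf(g, paths$filtered)
      stages_run <- c(stages_run, "filter")
      g
    }
  })
  bad <- setdiff(gm$samples, md$sample_id)
  if (length(bad)) stop("samples missing from metadata: ",
                        paste(bad, collapse = ", "))

  seg <- stage("detect", {
    if (file.exists(paths$roh) && !overwrite) {
      utils::read.delim(paths$roh, stringsAsFactors = FALSE,
                        colClasses = c(chrom = "character"))
    } else {
      s <- call_roh(gm, params)
      write_roh(s, paths$roh, bed = TRUE)
      stages_run <- c(stages_run, "detect")
      s
    }
  })

  stage("stats", {
    ind <- do.call(rbind, lapply(gm$samples,
                                 function(s) summarize_individual(seg, s)))
    utils::write.table(ind, paths$ind, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    br <- do.call(rbind, lapply(unique(md$group), function(g) {
      b <- summarize_breed(seg, md, g)
      data.frame(group = g, n_individuals = b$n_individuals,
                 mn_roh = b$mn_roh, al_roh_mb = b$al_roh_mb,
                 t(b$mean_sum_mb), check.names = FALSE)
    }))
    utils::write.table(br, paths$breed, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    stages_run <- c(stages_run, "stats")
  })

  inb <- stage("inbreeding", {
    x <- inbreeding_table(gm, seg, L_au_mb = L_au_mb)
    utils::write.table(x, paths$inb, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    stages_run <- c(stages_run, "inbreeding")
    x
  })

  stage("islands", {
    all_isl <- list()
    occ <- data.frame(chrom = gm$sites$chrom, pos = gm$sites$pos)
    for (g in island_groups) {
      isl <- find_islands(seg, gm, md, g, top_fraction, min_island_snps)
      occ[[g]] <- attr(isl, "track")$occurrence
      if (!is.null(gtf)) isl <- annotate_genes(isl, gtf)
      if (nrow(isl)) {
        isl$group <- g
        isl$threshold <- attr(isl, "threshold")
        all_isl[[g]] <- isl
      }
    }
    out <- if (length(all_isl)) do.call(rbind, all_isl) else {
      data.frame(chrom = character(), start_pos = numeric(),
                 end_pos = numeric(), n_snps = integer(),
                 group = character())
    }
    utils::write.table(out, paths$islands, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(occ, paths$occurrence, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    stages_run <- c(stages_run, "islands")
  })

  stage("ld_ne", {
    if (is.null(ld_group)) {
      ld_group <- names(which.max(table(md$group[md$sample_id %in%
                                                   gm$samples])))
    }
    pr <- pairwise_r2(gm, md, ld_group, max_dist_bp = ld_max_dist_bp)
    bins <- ld_decay(pr, bin_width_bp = ld_bin_width_bp)
    utils::write.table(bins, paths$ld, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    n_ind <- sum(md$group == ld_group & md$sample_id %in% gm$samples)
    ne <- ne_from_ld(bins, sample_n = n_ind)
    utils::write.table(ne, paths$ne, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    stages_run <- c(stages_run, "ld_ne")
  })

  manifest <- list(
    package = "rohscan",
    version = as.character(utils::packageVersion("rohscan")),
    inputs = list(vcf = vcf, metadata = metadata, gtf = gtf),
    input_md5 = as.list(tools::md5sum(c(vcf, metadata, gtf))),
    parameters = c(unclass(params),
                   list(max_missing = max_missing, min_maf = min_maf,
                        L_au_mb = L_au_mb, top_fraction = top_fraction,
                        min_island_snps = min_island_snps,
                        ld_max_dist_bp = ld_max_dist_bp,
                        ld_bin_width_bp = ld_bin_width_bp)),
    stages = c("filter", "detect", "stats", "inbreeding", "islands",
               "ld_ne"),
    output_md5 = as.list(tools::md5sum(unlist(paths)[file.exists(
      unlist(paths))])))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(manifest)
}
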