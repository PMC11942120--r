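#' Read genotypes from a VCF file
#'
#' Loads a (possibly gzipped) VCF 4.x file into a [genotype_matrix()].
#' Only biallelic SNP records (single-nucleotide REF and ALT) are retained;
#' genotype phase is ignored; half-calls (e.g. `./1`) and any genotype
#' containing `.` are treated as missing. Contig lengths are taken from the
#' `##contig` header lines when present.
#'
#' @param path Path to a `.vcf` or `.vcf.gz` file.
#' @param samples Optional character vector restricting the sample set.
#' @param keep_contigs Optional allow-list of contig names (e.g. the
#'   autosomes); records on other contigs are dropped.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, samples = NULL, keep_contigs = NULL) {
  if (!file.exists(path)) stop("cannot read VCF: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("VCF contains no variant records: ", path)

  snv <- grepl("^[ACGT]$", fix$REF) & grepl("^[ACGT]$", fix$ALT)
  fix <- fix[snv, , drop = FALSE]
  gt <- v@gt[snv, , drop = FALSE]
  if (nrow(fix) == 0) stop("no biallelic SNP records in ", path)

  key <- paste(fix$CHROM, fix$POS)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicated record at ", sub(" ", ":", d))
  }

  contigs <- .contigs_from_meta(v@meta)
  if (!is.null(keep_contigs)) {
    keep <- fix$CHROM %in% keep_contigs
    fix <- fix[keep, , drop = FALSE]
    gt <- gt[keep, , drop = FALSE]
    contigs <- contigs[names(contigs) %in% keep_contigs]
  }

  gt_samples <- colnames(gt)[-1]  # first column is FORMAT
  if (!is.null(samples)) {
    miss <- setdiff(samples, gt_samples)
    if (length(miss)) stop("sample(s) not in VCF: ", paste(miss, collapse = ", "))
    gt <- gt[, c("FORMAT", samples), drop = FALSE]
    gt_samples <- samples
  }

  gtf <- vcfR::extract.gt(
    methods::new("vcfR", meta = v@meta, fix = as.matrix(fix), gt = gt),
    element = "GT")
  calls <- .code_gt(gtf)

  sites <- data.frame(chrom = fix$CHROM, pos = as.numeric(fix$POS),
                      id = fix$ID, ref = fix$REF, alt = fix$ALT,
                      stringsAsFactors = FALSE)
  # error with the offending record if input is unsorted
  ord_ok <- !unlist(tapply(sites$pos, factor(sites$chrom, unique(sites$chrom)),
                           function(p) is.unsorted(p, strictly = TRUE)))
  if (!all(ord_ok)) {
    stop("VCF not position-sorted on contig ",
         names(ord_ok)[!ord_ok][1])
  }
  genotype_matrix(calls, sites, gt_samples, contigs = contigs)
}

.contigs_from_meta <- function(meta) {
  ln <- grep("^##contig=", meta, value = TRUE)
  if (!length(ln)) return(NULL)
  ids <- sub(".*ID=([^,>]+).*", "\\1", ln)
  lens <- suppressWarnings(as.numeric(
    ifelse(grepl("length=", ln), sub(".*length=([0-9]+).*", "\\1", ln), NA)))
  stats::setNames(lens, ids)
}

.code_gt <- function(gtf) {
  g <- gsub("|", "/", gtf, fixed = TRUE)
  calls <- matrix(NA_integer_, nrow(g), ncol(g))
  calls[g == "0/0"] <- 0L
  calls[g == "0/1" | g == "1/0"] <- 1L
  calls[g == "1/1"] <- 2L
  colnames(calls) <- colnames(gtf)
  calls
}

#' Write a genotype matrix to VCF
#'
#' Emits a minimal VCF 4.2 file with a GT-only FORMAT field. Output is
#' gzip-compressed when `path` ends in `.gz`, plain text otherwise.
#' `read_vcf(write_vcf(gm))` reproduces the calls matrix exactly.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output path (`.vcf` or `.vcf.gz`).
#' @param extra_header Optional character vector of extra `##` header lines
#'   (e.g. a simulation-seed record).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path, extra_header = NULL) {
  meta <- c("##fileformat=VCFv4.2",
            "##source=rohscan",
            extra_header,
            '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  if (!is.null(gm$contigs)) {
    meta <- c(meta, sprintf("##contig=<ID=%s,length=%d>", names(gm$contigs),
                            as.integer(gm$contigs)))
  }
  gt_str <- matrix("./.", nrow(gm$calls), ncol(gm$calls))
  gt_str[gm$calls == 0L] <- "0/0"
  gt_str[gm$calls == 1L] <- "0/1"
  gt_str[gm$calls == 2L] <- "1/1"
  s <- gm$sites
  fix <- cbind(s$chrom, format(s$pos, scientific = FALSE, trim = TRUE),
               ifelse(is.na(s$id), ".", s$id), s$ref, s$alt, ".", "PASS", ".",
               "GT")
  body <- apply(cbind(fix, gt_str), 1, paste, collapse = "\t")
  header <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", "FORMAT", gm$samples), collapse = "\t")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c(meta, header, body), con)
  invisible(path)
}

#' Site-level quality filters
#'
#' Removes sites with missing-call rate at or above `max_missing` or minor
#' allele frequency below `min_maf` (boundary semantics: a site with missing
#' rate exactly `max_missing` is removed; a site with MAF exactly `min_maf`
#' is retained). MAF is computed from non-missing calls only. Site order is
#' preserved, so the operation is idempotent.
#'
#' @param gm A [genotype_matrix()].
#' @param max_missing Missing-rate cutoff (default 0.1).
#' @param min_maf MAF cutoff (default 0.05).
#' @param verbose Emit a one-line filter report via `message()`.
#' @return The filtered [genotype_matrix()]; a `filter_report` attribute
#'   records the number of sites removed per criterion.
#' @export
filter_sites <- function(gm, max_missing = 0.1, min_maf = 0.05,
                         verbose = FALSE) {
  if (nrow(gm$calls) == 0) stop("empty genotype matrix")
  mr <- site_missing_rate(gm)
  maf <- site_maf(gm)
  fail_missing <- mr >= max_missing
  fail_maf <- is.nan(maf) | maf < min_maf
  keep <- !(fail_missing | fail_maf)
  out <- subset_gm(gm, sites = keep)
  report <- list(n_input = nrow(gm$calls),
                 n_removed_missing = sum(fail_missing),
                 n_removed_maf = sum(fail_maf),
                 n_retained = sum(keep))
  attr(out, "filter_report") <- report
  if (verbose) {
    message(sprintf(
      "filter_sites: %d sites in, %d failed missing>=%.3g, %d failed MAF<%.3g, %d retained",
      report$n_input, report$n_removed_missing, max_missing,
      report$n_removed_maf, min_maf, report$n_retained))
  }
  out
}
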