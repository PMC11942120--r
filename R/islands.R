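#' Per-SNP in-ROH occurrence within a group
#'
#' For every SNP of the matrix, the fraction of the group's individuals
#' that have at least one run of homozygosity whose span contains the SNP
#' position — the hotspot statistic whose upper tail defines ROH islands.
#'
#' @param segments Segment data frame from [call_roh()].
#' @param gm A [genotype_matrix()] supplying the site coordinates.
#' @param metadata Data frame from [read_sample_metadata()].
#' @param group Group label.
#' @return A list of class `occurrence_track`: `group`, `n` (group size),
#'   and `occurrence`, a numeric vector aligned with the sites of `gm`
#'   taking values in `{0, 1/n, ..., 1}`.
#' @export
snp_occurrence <- function(segments, gm, metadata, group) {
  ids <- .group_samples(metadata, group)
  counts <- integer(nrow(gm$sites))
  chrom <- gm$sites$chrom
  pos <- gm$sites$pos
  for (s in ids) {
    seg <- segments[segments$sample_id == s, , drop = FALSE]
    covered <- logical(length(counts))
    for (k in seq_len(nrow(seg))) {
      idx <- which(chrom == seg$chrom[k] & pos >= seg$start_pos[k] &
                     pos <= seg$end_pos[k])
      covered[idx] <- TRUE
    }
    counts <- counts + covered
  }
  structure(list(group = group, n = length(ids),
                 occurrence = counts / length(ids)),
            class = "occurrence_track")
}

#' @export
print.occurrence_track <- function(x, ...) {
  cat(sprintf("occurrence_track: group '%s' (n = %d), %d SNPs, max occurrence %.3f\n",
              x$group, x$n, length(x$occurrence), max(x$occurrence)))
  invisible(x)
}

#' Top-fraction occurrence threshold
#'
#' The island threshold is the occurrence value of the k-th highest SNP,
#' k = ceiling(top_fraction * n_snps); SNPs at or above it are retained, so
#' ties at the threshold can push the retained set slightly past the
#' nominal fraction. SNPs covered by no ROH at all (occurrence 0) are never
#' retained, even when sparse coverage drags the order-statistic threshold
#' to zero. A constant track (including all-zero) is degenerate: "top" is
#' meaningless and no SNP is retained.
#'
#' @param track An `occurrence_track` from [snp_occurrence()], or a bare
#'   numeric occurrence vector.
#' @param top_fraction Upper tail defining islands (default 0.005, i.e. the
#'   top 0.5 percent of SNPs by occurrence).
#' @return A list: `threshold` (NA when degenerate), `retained` (site
#'   indices, increasing), `degenerate` (logical).
#' @export
island_threshold <- function(track, top_fraction = 0.005) {
  occ <- if (inherits(track, "occurrence_track")) track$occurrence else track
  stopifnot(top_fraction > 0, top_fraction <= 1)
  n <- length(occ)
  if (!n) return(list(threshold = NA_real_, retained = integer(),
                      degenerate = TRUE))
  if (max(occ) == min(occ)) {
    # constant track (including all-zero): "top" is meaningless
    return(list(threshold = NA_real_, retained = integer(),
                degenerate = TRUE))
  }
  k <- ceiling(top_fraction * n)
  thr <- sort(occ, decreasing = TRUE)[k]
  # a SNP covered by no ROH at all can never be part of an island, so a
  # zero threshold retains only the positive-occurrence SNPs
  retained <- which(occ >= thr & occ > 0)
  list(threshold = thr, retained = retained, degenerate = FALSE)
}

#' Merge retained SNPs into ROH islands
#'
#' Maximal runs of strictly adjacent retained SNPs (consecutive site
#' indices on one chromosome) become islands; runs with fewer than
#' `min_island_snps` SNPs are dropped. With `bridge_bp > 0`, two runs
#' separated by below-threshold SNPs are merged when the bp gap between
#' their flanking retained SNPs is at most `bridge_bp` (off by default).
#'
#' @param retained Increasing site indices of above-threshold SNPs.
#' @param sites Site data frame of the genotype matrix (`chrom`, `pos`).
#' @param min_island_snps Minimum retained SNPs per island (default 2).
#' @param bridge_bp Maximum bp gap bridged across non-retained SNPs
#'   (default 0 = strict adjacency).
#' @return Data frame: `chrom`, `start_pos`, `end_pos`, `n_snps`.
#' @export
merge_islands <- function(retained, sites, min_island_snps = 2,
                          bridge_bp = 0) {
  empty <- data.frame(chrom = character(), start_pos = numeric(),
                      end_pos = numeric(), n_snps = integer(),
                      stringsAsFactors = FALSE)
  if (!length(retained)) return(empty)
  retained <- sort(retained)
  chrom <- sites$chrom[retained]
  pos <- sites$pos[retained]
  adjacent <- diff(retained) == 1L |
    (diff(pos) >= 0 & diff(pos) <= bridge_bp)
  brk <- !(adjacent & chrom[-1] == chrom[-length(chrom)])
  run_id <- cumsum(c(0L, brk))
  rows <- lapply(split(seq_along(retained), run_id), function(i) {
    if (length(i) < min_island_snps) return(NULL)
    data.frame(chrom = chrom[i[1]], start_pos = pos[i[1]],
               end_pos = pos[i[length(i)]], n_snps = length(i),
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Find ROH islands for a group
#'
#' Convenience wrapper: occurrence track, top-fraction threshold, island
#' merging, in one call.
#'
#' @inheritParams snp_occurrence
#' @inheritParams island_threshold
#' @inheritParams merge_islands
#' @return Data frame of islands (possibly empty) with an attribute
#'   `threshold` (the occurrence cutoff, NA when degenerate).
#' @export
find_islands <- function(segments, gm, metadata, group, top_fraction = 0.005,
                         min_island_snps = 2, bridge_bp = 0) {
  track <- snp_occurrence(segments, gm, metadata, group)
  th <- island_threshold(track, top_fraction)
  isl <- merge_islands(th$retained, gm$sites, min_island_snps, bridge_bp)
  attr(isl, "threshold") <- th$threshold
  attr(isl, "track") <- track
  isl
}

#' Annotate islands with overlapping genes
#'
#' Reads gene features from a GTF/GFF annotation and assigns to each island
#' every gene whose interval overlaps the island span by at least one bp
#' (strand ignored).
#'
#' @param islands Island data frame from [merge_islands()] /
#'   [find_islands()].
#' @param gtf_path Path to a GTF or GFF3 file with `gene` features (or
#'   features carrying a `gene_id` attribute).
#' @return `islands` with added columns `n_genes` and `gene_ids`
#'   (comma-separated).
#' @export
annotate_genes <- function(islands, gtf_path) {
  if (!file.exists(gtf_path)) stop("annotation file not found: ", gtf_path)
  ann <- rtracklayer::import(gtf_path)
  if (!length(ann)) stop("no features in annotation: ", gtf_path)
  genes <- .gene_ranges(ann)
  islands$n_genes <- 0L
  islands$gene_ids <- ""
  if (!nrow(islands)) return(islands)
  isl_gr <- GenomicRanges::GRanges(
    islands$chrom, IRanges::IRanges(islands$start_pos, islands$end_pos))
  hits <- GenomicRanges::findOverlaps(isl_gr, genes, ignore.strand = TRUE)
  for (i in seq_len(nrow(islands))) {
    ids <- genes$gene_id[S4Vectors::subjectHits(hits)[
      S4Vectors::queryHits(hits) == i]]
    ids <- unique(ids)
    islands$n_genes[i] <- length(ids)
    islands$gene_ids[i] <- paste(ids, collapse = ",")
  }
  islands
}

.gene_ranges <- function(ann) {
  if ("type" %in% names(S4Vectors::mcols(ann)) &&
      any(ann$type == "gene")) {
    genes <- ann[ann$type == "gene"]
  } else {
    genes <- ann
  }
  if (!"gene_id" %in% names(S4Vectors::mcols(genes))) {
    stop("annotation lacks gene_id attributes")
  }
  # one range per gene_id (features of a gene collapsed to their span)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(genes)),
                   start = BiocGenerics::start(genes),
                   end = BiocGenerics::end(genes),
                   gene_id = genes$gene_id, stringsAsFactors = FALSE)
  ids <- unique(df$gene_id)
  lo <- tapply(df$start, df$gene_id, min)[ids]
  hi <- tapply(df$end, df$gene_id, max)[ids]
  chr <- df$chrom[match(ids, df$gene_id)]
  rng <- GenomicRanges::GRanges(chr, IRanges::IRanges(lo, hi))
  rng$gene_id <- ids
  rng
}
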