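#' @keywords internal
.roh_classes <- function() {
  # half-open [lo, hi) in Mb; a 1.0-Mb run falls in the 1.0-1.5 class
  data.frame(label = c("0.5-1.0", "1.0-1.5", "1.5-2.0", ">2.0"),
             lo = c(0.5, 1.0, 1.5, 2.0), hi = c(1.0, 1.5, 2.0, Inf),
             stringsAsFactors = FALSE)
}

.class_of <- function(length_mb) {
  cl <- .roh_classes()
  findInterval(length_mb, cl$lo)
}

#' Per-individual ROH summary
#'
#' Totals and a decomposition into the four conventional length classes
#' (0.5-1.0, 1.0-1.5, 1.5-2.0 and >2.0 Mb, boundaries half-open on the
#' left). Class counts sum to the total count and class lengths to the
#' total length exactly.
#'
#' @param segments Segment data frame from [call_roh()].
#' @param sample Sample identifier (segments of other samples are ignored).
#' @return One-row data frame: `sample_id`, `n_roh`, `total_length_mb`, and
#'   per-class `n_*` / `mb_*` columns.
#' @export
summarize_individual <- function(segments, sample) {
  seg <- segments[segments$sample_id == sample, , drop = FALSE]
  len_mb <- seg$length_bp / 1e6
  cls <- .class_of(len_mb)
  cl <- .roh_classes()
  n_cls <- tabulate(cls, nbins = nrow(cl))
  mb_cls <- vapply(seq_len(nrow(cl)), function(k) sum(len_mb[cls == k]),
                   numeric(1))
  out <- data.frame(sample_id = sample, n_roh = nrow(seg),
                    total_length_mb = sum(len_mb), stringsAsFactors = FALSE)
  for (k in seq_len(nrow(cl))) {
    out[[paste0("n_", cl$label[k])]] <- n_cls[k]
    out[[paste0("mb_", cl$label[k])]] <- mb_cls[k]
  }
  out
}

#' Per-breed ROH summary
#'
#' Group-level aggregation over the individuals carrying the given metadata
#' label: mean ROH count per individual (MN_ROH), mean length per ROH
#' (AL_ROH), the mean sum of ROH per length class (class total over all
#' group members divided by group size), and per-chromosome ROH counts.
#' Individuals with no ROH contribute zeros.
#'
#' @param segments Segment data frame from [call_roh()].
#' @param metadata Data frame from [read_sample_metadata()].
#' @param group Group label to aggregate.
#' @return A list with elements `group`, `n_individuals`, `mn_roh`,
#'   `al_roh_mb`, `mean_sum_mb` (named by length class) and `chrom_counts`.
#' @export
summarize_breed <- function(segments, metadata, group) {
  ids <- .group_samples(metadata, group)
  seg <- segments[segments$sample_id %in% ids, , drop = FALSE]
  n <- length(ids)
  len_mb <- seg$length_bp / 1e6
  cls <- .class_of(len_mb)
  cl <- .roh_classes()
  mean_sum <- vapply(seq_len(nrow(cl)), function(k) sum(len_mb[cls == k]) / n,
                     numeric(1))
  names(mean_sum) <- cl$label
  chrom_counts <- if (nrow(seg)) table(seg$chrom) else table(character())
  list(group = group, n_individuals = n,
       mn_roh = nrow(seg) / n,
       al_roh_mb = if (nrow(seg)) mean(len_mb) else NA_real_,
       mean_sum_mb = mean_sum,
       chrom_counts = chrom_counts)
}

#' Map ROH length to generations since the common ancestor
#'
#' Under the standard theory, autozygous segment length after g generations
#' is exponentially distributed with mean 1/(2g) Morgans, so a segment of a
#' given genetic length points back g = 1/(2 * length in Morgans)
#' generations. Physical length is converted at `cm_per_mb` (default
#' 1 cM/Mb): 0.5 Mb corresponds to 100 generations, 1.0 Mb to 50, 2.0 Mb
#' to 25.
#'
#' @param length_mb Segment length(s) in Mb (> 0).
#' @param cm_per_mb Genetic-map conversion factor (cM per Mb).
#' @return Generations `g` (numeric, vectorized).
#' @export
generations_from_length <- function(length_mb, cm_per_mb = 1.0) {
  if (any(length_mb <= 0)) stop("length_mb must be > 0")
  morgans <- length_mb * cm_per_mb / 100
  1 / (2 * morgans)
}

#' Inverse of [generations_from_length()]
#'
#' @param g Generations since the common ancestor (> 0).
#' @param cm_per_mb Genetic-map conversion factor (cM per Mb).
#' @return Expected segment length in Mb.
#' @export
length_from_generations <- function(g, cm_per_mb = 1.0) {
  if (any(g <= 0)) stop("g must be > 0")
  100 / (2 * g * cm_per_mb)
}

#' Percentage of chromosome length covered by ROH, per group
#'
#' For each chromosome, the group mean over individuals of
#' (summed ROH length on that chromosome) / (chromosome length), in
#' percent. Chromosome lengths come from the genotype matrix contig
#' records.
#'
#' @param segments Segment data frame from [call_roh()].
#' @param contigs Named numeric vector of chromosome lengths (bp).
#' @param metadata Data frame from [read_sample_metadata()].
#' @param group Group label.
#' @return Named numeric vector (percent per chromosome).
#' @export
chrom_roh_percent <- function(segments, contigs, metadata, group) {
  ids <- .group_samples(metadata, group)
  seg <- segments[segments$sample_id %in% ids, , drop = FALSE]
  out <- stats::setNames(numeric(length(contigs)), names(contigs))
  if (nrow(seg)) {
    tot <- tapply(seg$length_bp, seg$chrom, sum)
    out[names(tot)] <- tot / length(ids)
  }
  100 * out / contigs
}
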