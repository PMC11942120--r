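# shared fixture builders for the suite

# quick genotype matrix: calls is sites x samples; positions default to a
# 5-kb grid on one chromosome
make_gm <- function(calls, pos = NULL, chrom = "chr1", samples = NULL,
                    contigs = NULL) {
  calls <- as.matrix(calls)
  n <- nrow(calls)
  if (is.null(pos)) pos <- seq_len(n) * 5000
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(calls)))
  genotype_matrix(calls, data.frame(chrom = rep_len(chrom, n), pos = pos),
                  samples, contigs = contigs)
}

# a single-sample homozygous chromosome with n SNPs over span_bp
hom_chrom_gm <- function(n, span_bp, geno = 0L) {
  pos <- round(seq(1, span_bp, length.out = n))
  make_gm(matrix(rep(geno, n), ncol = 1), pos = pos)
}

# randomized single-sample ROH instance with planted homozygous runs,
# het/missing noise and randomized scan parameters (oracle equivalence)
random_roh_instance <- function(seed) {
  set.seed(seed)
  n <- sample(200:1000, 1)
  n_chr <- sample(1:2, 1)
  sizes <- as.vector(stats::rmultinom(1, n, rep(1, n_chr)))
  sizes[sizes < 2] <- 2
  sites <- do.call(rbind, lapply(seq_len(n_chr), function(c) {
    m <- sizes[c]
    data.frame(chrom = paste0("chr", c),
               pos = sort(sample.int(m * sample(2000:8000, 1), m)))
  }))
  n <- nrow(sites)
  g <- sample(c(0L, 1L, 2L, NA), n, replace = TRUE,
              prob = c(0.3, 0.4, 0.25, 0.05))
  for (k in seq_len(sample(0:3, 1))) {       # plant homozygous runs
    len <- min(sample(50:400, 1), n)
    start <- sample.int(max(1, n - len), 1)
    idx <- start:min(n, start + len - 1)
    len <- length(idx)
    g[idx] <- sample(c(0L, 2L), len, replace = TRUE)
    noise <- runif(len) < runif(1, 0, 0.04)
    g[idx][noise] <- sample(c(1L, NA), sum(noise), replace = TRUE)
  }
  gm <- genotype_matrix(matrix(g, ncol = 1), sites, "s1")
  params <- roh_params(
    window_snps = sample(c(20, 50), 1),
    max_het_per_window = sample(0:3, 1),
    max_missing_per_window = sample(0:5, 1),
    min_snps = sample(c(25, 50, 100), 1),
    min_length_kb = sample(c(100, 300, 500), 1),
    max_density_kb_per_snp = sample(c(50, 100), 1),
    max_gap_kb = sample(c(100, 500, 1000), 1))
  list(gm = gm, params = params)
}

# minimal GTF with gene features
write_toy_gtf <- function(path, genes) {
  lines <- sprintf(
    '%s\ttoy\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s"; gene_name "%s";',
    genes$chrom, genes$start, genes$end,
    if (is.null(genes$strand)) "+" else genes$strand,
    genes$gene_id, genes$gene_id)
  writeLines(lines, path)
  path
}

make_metadata <- function(samples, groups) {
  data.frame(sample_id = samples, group = rep_len(groups, length(samples)),
             stringsAsFactors = FALSE)
}
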