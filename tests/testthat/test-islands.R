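# a 1-sample-per-row segment table covering [start, end] on chr1
cover_seg <- function(ids, start, end) {
  data.frame(sample_id = ids, chrom = "chr1", start_pos = start,
             end_pos = end, n_snps = 100, length_bp = end - start + 1,
             stringsAsFactors = FALSE)
}

test_that("occurrence counts individuals whose ROH cover each SNP", {
  n <- 20
  ids <- sprintf("i%02d", 1:n)
  gm <- make_gm(matrix(0L, 50, n, dimnames = list(NULL, ids)),
                samples = ids)
  md <- make_metadata(ids, "g")
  # SNPs at 5kb grid; cover positions 50k-100k (sites 10..20) in 13 members
  seg <- cover_seg(ids[1:13], 5e4, 1e5)
  tr <- snp_occurrence(seg, gm, md, "g")
  expect_equal(tr$n, 20)
  expect_equal(tr$occurrence[10:20], rep(0.65, 11))
  expect_equal(tr$occurrence[c(1:9, 21:50)], rep(0, 39))
  # no ROH at all: all zeros
  expect_equal(snp_occurrence(seg[0, ], gm, md, "g")$occurrence, rep(0, 50))
  expect_error(snp_occurrence(seg, gm, md, "nope"), "unknown or empty")
})

test_that("occurrence is invariant to individual order and duplication", {
  ids <- sprintf("i%02d", 1:10)
  gm <- make_gm(matrix(0L, 30, 10), samples = ids)
  md <- make_metadata(ids, "g")
  seg <- cover_seg(ids[c(2, 5, 9)], 2e4, 6e4)
  base <- snp_occurrence(seg, gm, md, "g")$occurrence
  shuf <- snp_occurrence(seg[sample(nrow(seg)), ], gm, md, "g")$occurrence
  expect_equal(shuf, base)
  # duplicate every individual under new ids: track unchanged
  ids2 <- c(ids, sprintf("j%02d", 1:10))
  gm2 <- make_gm(matrix(0L, 30, 20), samples = ids2)
  seg2 <- rbind(seg, transform(seg, sample_id = sub("i", "j", sample_id)))
  dup <- snp_occurrence(seg2, gm2, make_metadata(ids2, "g"), "g")$occurrence
  expect_equal(dup, base)
})

test_that("the top-fraction threshold retains the k highest SNPs plus ties", {
  set.seed(4)
  occ <- sample(seq(0.001, 1, length.out = 1000))  # 1000 distinct values
  th <- island_threshold(occ, top_fraction = 0.005)
  expect_false(th$degenerate)
  expect_equal(sort(occ[th$retained], decreasing = TRUE),
               sort(occ, decreasing = TRUE)[1:5])
  expect_equal(length(th$retained), 5)

  # ties at the threshold are all retained
  occ2 <- c(rep(0.9, 12), seq(0.01, 0.5, length.out = 988))
  th2 <- island_threshold(occ2, 0.005)
  expect_equal(length(th2$retained), 12)

  # constant tracks (zero or not) are degenerate: no islands
  expect_true(island_threshold(rep(0, 500))$degenerate)
  expect_true(island_threshold(rep(0.4, 500))$degenerate)

  # one covered SNP among zeros: only it can be an island seed
  occ3 <- c(rep(0, 999), 1)
  th3 <- island_threshold(occ3, 0.005)
  expect_equal(th3$retained, 1000L)
})

test_that("adjacent retained SNPs merge into islands, short runs drop", {
  sites <- data.frame(chrom = "chr1", pos = seq_len(50) * 1e4)
  isl <- merge_islands(c(10, 11, 12, 40), sites)
  expect_equal(nrow(isl), 1)   # singleton at 40 dropped
  expect_equal(isl$n_snps, 3)
  expect_equal(isl$start_pos, 1e5)
  expect_equal(isl$end_pos, 1.2e5)

  expect_equal(nrow(merge_islands(integer(), sites)), 0)
  all_in <- merge_islands(1:50, sites)
  expect_equal(nrow(all_in), 1)
  expect_equal(all_in$n_snps, 50)

  # runs never span a chromosome boundary
  sites2 <- data.frame(chrom = rep(c("c1", "c2"), each = 5),
                       pos = rep(1:5 * 1e4, 2))
  split2 <- merge_islands(4:7, sites2)
  expect_equal(split2$chrom, c("c1", "c2"))

  # optional bp bridge joins runs across a below-threshold SNP
  bridged <- merge_islands(c(10, 11, 13, 14), sites, bridge_bp = 5e4)
  expect_equal(nrow(bridged), 1)
  strict <- merge_islands(c(10, 11, 13, 14), sites)
  expect_equal(nrow(strict), 2)
})

test_that("island SNP sets conserve the retained set minus dropped runs", {
  set.seed(11)
  for (i in 1:10) {
    sites <- data.frame(chrom = "chr1", pos = sort(sample.int(1e6, 300)))
    retained <- sort(sample.int(300, 40))
    isl <- merge_islands(retained, sites, min_island_snps = 2)
    in_island <- retained[vapply(retained, function(r) {
      any(sites$pos[r] >= isl$start_pos & sites$pos[r] <= isl$end_pos)
    }, logical(1))]
    runs <- split(retained, cumsum(c(0, diff(retained) > 1)))
    kept <- unlist(runs[vapply(runs, length, 1L) >= 2], use.names = FALSE)
    expect_equal(in_island, if (is.null(kept)) integer() else kept)
    expect_equal(sum(isl$n_snps), length(kept))
  }
})

test_that("genes are annotated by 1-bp interval overlap, strand ignored", {
  gtf <- write_toy_gtf(file.path(tempdir(), "toy.gtf"), data.frame(
    chrom = "chr1", start = c(1000, 5000, 9000),
    end = c(1999, 5999, 9999), gene_id = c("gA", "gB", "gC"),
    strand = c("+", "-", "+")))
  isl <- data.frame(chrom = "chr1", start_pos = 1500, end_pos = 5200,
                    n_snps = 10)
  ann <- annotate_genes(isl, gtf)
  expect_equal(ann$n_genes, 2)
  expect_equal(ann$gene_ids, "gA,gB")

  # a gene ending one bp before the island start is excluded
  isl2 <- data.frame(chrom = "chr1", start_pos = 2000, end_pos = 2500,
                     n_snps = 5)
  expect_equal(annotate_genes(isl2, gtf)$n_genes, 0)
  # single-bp touch counts
  isl3 <- data.frame(chrom = "chr1", start_pos = 1999, end_pos = 2500,
                     n_snps = 5)
  expect_equal(annotate_genes(isl3, gtf)$gene_ids, "gA")

  expect_error(annotate_genes(isl, "does-not-exist.gtf"), "not found")
})

test_that("a planted group-shared tract is recovered as exactly one island", {
  islands <- data.frame(group = "g", chrom = "chr1", start = 5e6, end = 7e6,
                        carrier_fraction = 0.8)
  cfg <- sim_config(n_individuals = 20, chrom_lengths_bp = c(chr1 = 2.5e7,
                                                             chr2 = 2.5e7),
                    snp_density_per_mb = 200, groups = "g", target_f = 0.02,
                    tract_mode = list(mode = "fixed", length_bp = 1e6),
                    islands = islands, seed = 31)
  sim <- simulate_population(cfg)
  seg <- call_roh(sim$gm)
  md <- make_metadata(sim$gm$samples, "g")
  isl <- find_islands(seg, sim$gm, md, "g")
  expect_equal(nrow(isl), 1)
  expect_equal(isl$chrom, "chr1")
  expect_lte(isl$start_pos, 7e6)
  expect_gte(isl$end_pos, 5e6)
})
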