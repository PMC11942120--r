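test_that("simulation is deterministic under a fixed seed, down to the VCF", {
  cfg <- sim_config(n_individuals = 5, chrom_lengths_bp = c(c1 = 1e7),
                    target_f = 0.1,
                    tract_mode = list(mode = "generations", g = 30),
                    seed = 77)
  a <- simulate_population(cfg)
  b <- simulate_population(cfg)
  expect_identical(a$gm$calls, b$gm$calls)
  expect_identical(a$truth$tracts, b$truth$tracts)
  fa <- file.path(tempdir(), "sim_a.vcf")
  fb <- file.path(tempdir(), "sim_b.vcf")
  write_vcf(a$gm, fa); write_vcf(b$gm, fb)
  expect_identical(readLines(fa), readLines(fb))
  expect_error(sim_config(n_individuals = 2), "seed")
})

test_that("F* = 0 yields no tracts and Hardy-Weinberg heterozygosity", {
  cfg <- sim_config(n_individuals = 30, chrom_lengths_bp = c(c1 = 2e7),
                    snp_density_per_mb = 200, target_f = 0,
                    background_missing_rate = 0, seed = 6)
  sim <- simulate_population(cfg)
  expect_equal(nrow(sim$truth$tracts), 0)
  expect_equal(unname(sim$truth$f_true), rep(0, 30))
  # expected het rate under the uniform(0.05, 0.5) frequency law:
  # E[2p(1-p)] integrated over the law, within 3 binomial SEs
  p <- seq(0.05, 0.5, length.out = 1e4)
  e_het <- mean(2 * p * (1 - p))
  n_calls <- length(sim$gm$calls)
  obs <- mean(sim$gm$calls == 1L)
  expect_lt(abs(obs - e_het), 3 * sqrt(e_het * (1 - e_het) / n_calls) + 3e-3)
})

test_that("planted tract totals accumulate to the target inbreeding", {
  cfg <- sim_config(n_individuals = 5,
                    chrom_lengths_bp = setNames(rep(1e8, 5),
                                                paste0("c", 1:5)),
                    snp_density_per_mb = 30, target_f = 0.1,
                    tract_mode = list(mode = "generations", g = 25),
                    seed = 9)
  sim <- simulate_population(cfg)
  tr <- sim$truth$tracts
  per_ind <- tapply(tr$end - tr$start + 1, tr$sample_id, sum)
  expect_true(all(per_ind >= 40e6 & per_ind <= 60e6))
  expect_true(all(sim$truth$f_true >= 0.1))
  # tracts never overlap within an individual
  for (s in unique(tr$sample_id)) {
    t <- tr[tr$sample_id == s, ]
    for (chr in unique(t$chrom)) {
      tc <- t[t$chrom == chr, ]
      tc <- tc[order(tc$start), ]
      if (nrow(tc) > 1) expect_true(all(diff(tc$start) >
                                          head(tc$end - tc$start, -1)))
    }
  }
})

test_that("tract lengths follow the exponential 1/(2g)-Morgan law", {
  # negligible truncation and low genome occupancy (so overlap rejection
  # cannot bias lengths): the raw exponential mean is visible
  cfg <- sim_config(n_individuals = 40, chrom_lengths_bp = c(c1 = 1e8),
                    snp_density_per_mb = 20, target_f = 0.05,
                    tract_mode = list(mode = "generations", g = 75),
                    min_tract_bp = 1, seed = 10)
  sim <- simulate_population(cfg)
  lens <- with(sim$truth$tracts, end - start + 1)
  expect_gt(length(lens), 200)
  expect_equal(mean(lens) / 1e6, 100 / 150, tolerance = 0.1)
})

test_that("the truncated law keeps every tract above the floor", {
  cfg <- sim_config(n_individuals = 10, chrom_lengths_bp = c(c1 = 5e7),
                    snp_density_per_mb = 20, target_f = 0.1,
                    tract_mode = list(mode = "generations", g = 75),
                    seed = 16)
  tr <- simulate_population(cfg)$truth$tracts
  expect_true(all(tr$end - tr$start + 1 >= 1e5))
})

test_that("end-to-end check: ample tracts are fully recovered", {
  cfg <- sim_config(n_individuals = 6, chrom_lengths_bp = c(c1 = 5e7),
                    target_f = 0.08,
                    tract_mode = list(mode = "fixed", length_bp = 1.6e6),
                    het_noise_rate = 0, tract_missing_rate = 0,
                    background_missing_rate = 0, seed = 18)
  rep <- end_to_end_check(cfg)
  expect_equal(rep$recall, 1)
  expect_equal(rep$precision, 1)
  expect_lt(rep$mean_f_error, 0.01)
})

test_that("end-to-end check: sub-threshold tracts are never called", {
  cfg <- sim_config(n_individuals = 6, chrom_lengths_bp = c(c1 = 5e7),
                    target_f = 0.03,
                    tract_mode = list(mode = "fixed", length_bp = 3e5),
                    seed = 19)
  rep <- end_to_end_check(cfg)
  expect_equal(rep$recall, 0)
  expect_equal(rep$n_segments, 0)
})

test_that("end-to-end reports are reproducible under a fixed seed", {
  cfg <- sim_config(n_individuals = 5, chrom_lengths_bp = c(c1 = 4e7),
                    target_f = c(0, 0.05, 0.1, 0.1, 0.2),
                    tract_mode = list(mode = "fixed", length_bp = 1.2e6),
                    seed = 20)
  expect_identical(end_to_end_check(cfg), end_to_end_check(cfg))
})

test_that("tract het noise degrades recall monotonically (non-strictly)", {
  recalls <- vapply(c(0, 0.02, 0.05), function(noise) {
    cfg <- sim_config(n_individuals = 8, chrom_lengths_bp = c(c1 = 5e7),
                      target_f = 0.1,
                      tract_mode = list(mode = "fixed", length_bp = 1e6),
                      het_noise_rate = noise, seed = 22)
    end_to_end_check(cfg)$recall
  }, numeric(1))
  expect_true(all(diff(recalls) <= 0))
  expect_equal(recalls[1], 1)
})

test_that("old inbreeding yields mostly short detected ROH", {
  cfg <- sim_config(n_individuals = 10, chrom_lengths_bp = c(c1 = 1e8,
                                                             c2 = 1e8),
                    target_f = 0.1,
                    tract_mode = list(mode = "generations", g = 100),
                    seed = 23)
  sim <- simulate_population(cfg)
  seg <- call_roh(sim$gm)
  expect_gt(nrow(seg), 50)
  share_short <- mean(seg$length_bp < 1e6)
  expect_gt(share_short, 0.5)
})

test_that("write_simulation emits VCF, truth files and a config copy", {
  cfg <- sim_config(n_individuals = 3, chrom_lengths_bp = c(c1 = 5e6),
                    target_f = 0.1,
                    tract_mode = list(mode = "fixed", length_bp = 8e5),
                    seed = 24)
  sim <- simulate_population(cfg)
  out <- file.path(tempdir(), "simout")
  write_simulation(sim, out)
  expect_true(all(file.exists(file.path(out, c(
    "genotypes.vcf.gz", "truth_tracts.bed", "truth_f.tsv",
    "sim_config.json")))))
  back <- read_vcf(file.path(out, "genotypes.vcf.gz"))
  expect_identical(unname(back$calls), unname(sim$gm$calls))
  cfg_back <- jsonlite::read_json(file.path(out, "sim_config.json"))
  expect_equal(cfg_back$seed, 24)
})
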