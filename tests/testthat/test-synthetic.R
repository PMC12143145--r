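test_that("generation is byte-deterministic given config and seed", {
  cfg <- sim_config(seed = 7, n_true = 10, n_decoy = 10,
                    flank_mutation_rate = 0)
  g1 <- generate_transcriptome(cfg)
  g2 <- generate_transcriptome(cfg)
  expect_identical(g1, g2)
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(g1$transcripts, f1); write_fasta(g2$transcripts, f2)
  expect_identical(readLines(f1), readLines(f2))
  # and MS1/MS2/expression streams are individually reproducible
  expect_identical(simulate_ms1(g1$truth), simulate_ms1(g2$truth))
  expect_identical(simulate_ms2(g1$truth), simulate_ms2(g2$truth))
  expect_identical(simulate_expression(g1$truth),
                   simulate_expression(g2$truth))
})

test_that("a planted 35-residue precursor occupies a 108 nt CDS", {
  cfg <- sim_config(seed = 3, n_true = 12, n_decoy = 0)
  g <- generate_transcriptome(cfg)
  p <- g$truth$precursors
  span <- p$cds_end - p$cds_start + 1L
  expect_identical(span, 3L * (nchar(p$protein) + 1L))
  expect_identical(span[nchar(p$protein) == 35L],
                   rep(108L, sum(nchar(p$protein) == 35L)))
  # every planted core obeys the family rules and its mass is recomputable
  expect_true(all(nchar(p$core) >= 5 & nchar(p$core) <= 16))
  expect_true(all(substr(p$core, nchar(p$core), nchar(p$core))
                  %in% c("P", "A")))
  expect_identical(p$theoretical_mz,
                   vapply(p$core, function(s)
                     ion_mz(peptide_mass(s, cyclic = TRUE), "M+H"),
                     numeric(1), USE.NAMES = FALSE))
})

test_that("mining pristine synthetic transcriptomes recovers every core", {
  cfg <- sim_config(seed = 21, n_true = 10, n_decoy = 20,
                    flank_mutation_rate = 0)
  g <- generate_transcriptome(cfg)
  ann <- suppressMessages(
    scan_precursors(six_frame_orfs(g$transcripts),
                    build_flank_profiles(g$references)))
  hit <- match(g$truth$precursors$transcript_id, ann$transcript_id)
  expect_true(!anyNA(hit))
  expect_identical(ann$core[hit], g$truth$precursors$core)
})

test_that("the ground-truth manifest round-trips losslessly", {
  cfg <- sim_config(seed = 13, n_true = 5, n_decoy = 2)
  g <- generate_transcriptome(cfg)
  f <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(g$truth, f)
  back <- read_ground_truth(f)
  expect_equal(back$precursors, g$truth$precursors, tolerance = 0)
  expect_equal(unclass(back$config), unclass(g$truth$config))
})

test_that("MS1 error is zero at ppm_sigma 0 and calibrated otherwise", {
  cfg0 <- sim_config(seed = 9, n_true = 6, n_decoy = 0, ppm_sigma = 0,
                     n_noise_peaks = 0)
  g <- generate_transcriptome(cfg0)
  p <- simulate_ms1(g$truth)
  expect_identical(nrow(p), 6L)   # no noise: exactly one peak per core
  expect_equal(ppm_error(g$truth$precursors$theoretical_mz, p$mz),
               rep(0, 6))
  # signed ppm deviations have SD near the configured sigma (n = 500)
  cfg2 <- sim_config(seed = 9, n_true = 500, n_decoy = 0, ppm_sigma = 2,
                     n_noise_peaks = 0)
  g2 <- generate_transcriptome(cfg2)
  p2 <- simulate_ms1(g2$truth)
  dev <- (p2$mz / g2$truth$precursors$theoretical_mz - 1) * 1e6
  expect_gt(sd(dev), 1.6)   # 3-sigma band for the SD of 500 normal draws
  expect_lt(sd(dev), 2.4)
})

test_that("MS2 dropout controls the matched fraction of true fragments", {
  cfg <- sim_config(seed = 15, n_true = 3, n_decoy = 0, ppm_sigma = 0,
                    ms2_dropout = 0, n_noise_fragments = 0)
  g <- generate_transcriptome(cfg)
  sp <- simulate_ms2(g$truth)
  for (i in 1:3)
    expect_identical(score_ms2(g$truth$precursors$core[i], sp[[i]])$score, 1)
  # full dropout leaves a noise-only spectrum scoring 0
  cfg1 <- sim_config(seed = 15, n_true = 3, n_decoy = 0, ms2_dropout = 1,
                     n_noise_fragments = 5)
  g1 <- generate_transcriptome(cfg1)
  sp1 <- simulate_ms2(g1$truth)
  expect_identical(nrow(sp1[[1]]$fragments), 5L)
  expect_identical(score_ms2(g1$truth$precursors$core[1], sp1[[1]])$score, 0)
  # binomial sampling: mean score over seeds near 1 - dropout
  res <- lapply(1:40, function(s) {
    cfgd <- sim_config(seed = 3000 + s, n_true = 2, n_decoy = 0,
                       ppm_sigma = 0, ms2_dropout = 0.5,
                       n_noise_fragments = 0)
    gd <- generate_transcriptome(cfgd)
    spd <- simulate_ms2(gd$truth)
    vapply(1:2, function(i) {
      sc <- score_ms2(gd$truth$precursors$core[i], spd[[i]])
      c(sc$score, sc$n_predicted)
    }, numeric(2))
  })
  m <- do.call(cbind, res)
  # SE of the mean of Binomial(d, 0.5)/d scores with per-core d
  se <- sqrt(sum(0.25 / m[2, ])) / ncol(m)
  expect_lt(abs(mean(m[1, ]) - 0.5), 3 * se)
})

test_that("planted expression correlation is recovered in expectation", {
  cfg <- sim_config(seed = 1, rho = 1)
  ex <- simulate_expression(expression_stub(cfg), cfg)
  res <- rank_candidates(ex$expression, ex$metabolites, ex$tissues)
  planted <- merge(res, ex$gene_truth, by.x = c("gene", "metabolite"),
                   by.y = c("gene", "metabolite"))
  expect_equal(planted$r, rep(1, nrow(planted)))
  # decoys stay uncorrelated on average
  cfg2 <- sim_config(seed = 2)
  ex2 <- simulate_expression(expression_stub(cfg2), cfg2)
  dec <- ex2$expression[grep("decoy", rownames(ex2$expression)), ]
  rs <- apply(dec, 1, function(x) pearson_r(x, ex2$metabolites[1, ]))
  expect_lt(mean(abs(rs)), 0.5)
})

test_that("configuration validation refuses silent nondeterminism", {
  expect_error(sim_config(), "seed is mandatory")
  expect_error(sim_config(seed = 1, ms2_dropout = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(seed = 1, ppm_sigma = -1), ">= 0")
  expect_error(sim_config(seed = 1, tissues = "root", replicates = 2),
               "at least 3 samples")
})
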