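hb_target <- function(core = "GLPIGAPWG") {
  data.frame(core = core, adduct = "M+H",
             mz = ion_mz(peptide_mass(core, cyclic = TRUE), "M+H"),
             stringsAsFactors = FALSE)
}

test_that("MS1 matching reproduces a published-style observation", {
  peaks <- data.frame(mz = c(849.4598, 400.1), intensity = c(1e6, 1e3))
  m <- match_ms1(hb_target(), peaks, tol_ppm = 5)
  expect_identical(nrow(m), 1L)
  expect_identical(m$theoretical_mz, 849.4618)
  expect_identical(m$ppm, 2.3544)
  # the same pair fails a 1 ppm tolerance
  expect_identical(nrow(match_ms1(hb_target(), peaks, tol_ppm = 1)), 0L)
})

test_that("match sets are monotone in tolerance and sorted by ppm", {
  set.seed(23)
  targets <- do.call(rbind, lapply(c("IFGGLPPP", "HTWGSSTP", "VIFGDVGP"),
                                   hb_target))
  peaks <- data.frame(
    mz = targets$mz[sample(1:3, 40, replace = TRUE)] *
      (1 + rnorm(40, 0, 4e-6)),
    intensity = rlnorm(40, 10, 1))
  tols <- c(1, 2, 5, 10)
  prev <- NULL
  for (tol in tols) {
    m <- match_ms1(targets, peaks, tol_ppm = tol)
    expect_true(all(m$ppm <= tol))
    expect_true(!is.unsorted(m$ppm))
    if (!is.null(prev)) {
      key <- paste(m$core, m$observed_mz)
      expect_true(all(paste(prev$core, prev$observed_mz) %in% key))
    }
    prev <- m
  }
})

test_that("empty inputs yield empty matches, not errors", {
  expect_identical(nrow(match_ms1(hb_target(),
                                  data.frame(mz = numeric(),
                                             intensity = numeric()), 5)), 0L)
  expect_identical(nrow(match_ms1(hb_target()[0, ],
                                  data.frame(mz = 1, intensity = 1), 5)), 0L)
  expect_error(match_ms1(hb_target(), data.frame(mz = 1, intensity = 1), 0),
               "tol_ppm")
})

test_that("an exact self-spectrum scores 1 and pure noise scores 0", {
  core <- "HTWGSSTP"
  pred <- predict_ms2_fragments(core)
  self <- data.frame(mz = pred$mz, intensity = 1)
  s <- score_ms2(core, self, tol_ppm = 10)
  expect_identical(s$score, 1)
  expect_identical(s$n_matched, s$n_predicted)
  # noise >= 50 ppm away from every prediction
  noise <- data.frame(mz = pred$mz * (1 + 8e-5), intensity = 1)
  expect_identical(score_ms2(core, noise, tol_ppm = 10)$score, 0)
})

test_that("half of the distinct predictions gives a score of one half", {
  core <- "WGSATH"   # all-distinct b-ion m/z values
  pred <- predict_ms2_fragments(core)
  expect_identical(nrow(pred), as.integer(nchar(core)^2 - nchar(core) + 1L))
  half <- pred$mz[seq_len(nrow(pred)) %% 2 == 1]
  s <- score_ms2(core, data.frame(mz = half, intensity = 1), tol_ppm = 10)
  expect_equal(s$score, length(half) / nrow(pred))
})

test_that("MS2 annotations carry the best assignment per observed fragment", {
  core <- "GLPIGAPWG"
  pred <- predict_ms2_fragments(core)
  spec <- data.frame(mz = c(pred$mz[3], 123.456), intensity = c(10, 1))
  s <- score_ms2(core, spec, tol_ppm = 10)
  expect_equal(s$annotations$matched_mz[1], pred$mz[3])
  expect_true(is.na(s$annotations$matched_mz[2]))
  expect_error(score_ms2(core, data.frame(mz = numeric(),
                                          intensity = numeric())),
               "no fragments")
  expect_error(score_ms2("A", spec), "length >= 2")
})
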