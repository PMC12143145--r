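mk_orfs <- function(proteins) {
  data.frame(transcript_id = paste0("t", seq_along(proteins)),
             frame = "+1", start = 1L,
             end = 3L * (nchar(proteins) + 1L),
             protein = proteins, stringsAsFactors = FALSE)
}

test_that("a PreHB-like precursor is segmented at residues 14-21", {
  prof <- build_flank_profiles(reference_set(6))
  ann <- scan_precursors(mk_orfs(hb_precursor()), prof)
  expect_identical(nrow(ann), 1L)
  expect_identical(ann$core, "IFGGLPPP")
  expect_identical(ann$core_start, 14L)
  expect_identical(ann$core_end, 21L)
  expect_identical(ann$leader, HB_LEADER)
  expect_identical(ann$follower, HB_FOLLOWER)
  expect_identical(ann$core_mz, 779.4450)
})

test_that("the two core rules are enforced on every emitted annotation", {
  prof <- build_flank_profiles(reference_set(6))
  # terminal residue must be Pro or Ala
  bad_term <- hb_precursor(core = "IFGGLPPG")
  expect_identical(nrow(scan_precursors(mk_orfs(bad_term), prof)), 0L)
  # core length must be 5..16
  too_long <- hb_precursor(core = "IFGGLPPPIFGGLPPPP")   # 17 residues
  expect_identical(nrow(scan_precursors(mk_orfs(too_long), prof)), 0L)
  too_short <- hb_precursor(core = "IFGP")               # 4 residues
  expect_identical(nrow(scan_precursors(mk_orfs(too_short), prof)), 0L)
  # and a property over generator output: every emitted core conforms
  g <- generate_transcriptome(sim_config(seed = 19, n_true = 8, n_decoy = 10))
  ann <- suppressMessages(
    scan_precursors(six_frame_orfs(g$transcripts),
                    build_flank_profiles(g$references)))
  expect_true(all(nchar(ann$core) >= 5 & nchar(ann$core) <= 16))
  expect_true(all(substr(ann$core, nchar(ann$core), nchar(ann$core))
                  %in% c("P", "A")))
})

test_that("non-matching flanks are rejected even with a legal core", {
  prof <- build_flank_profiles(reference_set(6))
  scrambled <- paste0("MRRRRRRRRRRRR", "IFGGLPPP", "KKKKKKKKKKKKKK")
  expect_identical(nrow(scan_precursors(mk_orfs(scrambled), prof)), 0L)
})

test_that("similarity filtering annotates and floors candidates", {
  prof <- build_flank_profiles(reference_set(6))
  refs <- setNames(reference_set(3)$protein, reference_set(3)$id)
  ann <- scan_precursors(mk_orfs(hb_precursor()), prof, references = refs)
  expect_identical(ann$best_reference, "ref_1")  # identical to ref_1
  expect_gt(ann$similarity_score, 100)
  high_floor <- scan_precursors(mk_orfs(hb_precursor()), prof,
                                references = refs, min_similarity = 1e6)
  expect_identical(nrow(high_floor), 0L)
})

test_that("dereplicate collapses rotational duplicates, keeps best scorer", {
  prof <- build_flank_profiles(reference_set(6))
  # two rotations of the same ring that both satisfy the terminal rule
  two <- c(hb_precursor(core = "YFLDGPPP"), hb_precursor(core = "PYFLDGPP"))
  ann <- scan_precursors(mk_orfs(two), prof)
  expect_identical(nrow(ann), 2L)
  d <- dereplicate(ann)
  expect_identical(nrow(d), 1L)
  expect_identical(d$core_canonical, "DGPPPYFL")
  expect_identical(d$group_size, 2L)
  expect_identical(d$members, "t1;t2")
  # all-distinct input passes through unchanged in size
  distinct <- scan_precursors(
    mk_orfs(c(hb_precursor("IFGGLPPP"), hb_precursor("HTWGSSTP"))), prof)
  expect_identical(nrow(dereplicate(distinct)), 2L)
  # empty input stays empty
  expect_identical(nrow(dereplicate(orbimine:::empty_annotations())), 0L)
})
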