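test_that("cyclic and linear monoisotopic masses match hand-computed sums", {
  # cyclic: plain residue sum (head-to-tail closure loses one water)
  expect_equal(peptide_mass("GLPIGAPWG", cyclic = TRUE), 848.454475)
  # linear GG: 2 x 57.021464 + water
  expect_equal(peptide_mass("GG", cyclic = FALSE), 132.053493)
  tab <- residue_mass_table()
  expect_equal(tab$proton, 1.007276)
  expect_equal(tab$water, 18.010565)
  expect_equal(tab$residues[["L"]], tab$residues[["I"]])
  expect_equal(tab$residues[["L"]], 113.084064)
})

test_that("invalid sequences are rejected with the offending position", {
  expect_error(peptide_mass("X"), "non-canonical residue 'X' at position 1")
  expect_error(peptide_mass("GLXPI"), "position 3")
  expect_error(peptide_mass(""), "at least one residue")
})

test_that("adduct m/z arithmetic adds or removes one proton", {
  expect_equal(ion_mz(848.454475, "M+H"), 849.461751)
  # linear follower peptide observed in negative mode
  m <- peptide_mass("SQELINGDDISLMV", cyclic = FALSE)
  expect_equal(ion_mz(m, "M-H"), 1531.731948)
  # M+H and M-H differ by exactly two protons for any mass
  for (mass in c(1, 500.123456, 848.454475))
    expect_equal(ion_mz(mass, "M+H") - ion_mz(mass, "M-H"), 2 * 1.007276)
  expect_error(ion_mz(848.45, "M+H", charge = 2), "charge")
  expect_error(ion_mz(-1, "M+H"), "> 0")
})

test_that("round_mz rounds half-up at the fourth decimal", {
  expect_identical(round_mz(849.461751), 849.4618)
  expect_identical(round_mz(785.4192175), 785.4192)
  expect_identical(round_mz(1.0), 1.0)
  expect_identical(round_mz(2.00005), 2.0001)   # half-up, not half-even
  expect_identical(round_mz(2.00015), 2.0002)
})

test_that("ppm error uses the 4-dp-rounded theoretical value", {
  expect_equal(ppm_error(849.461751, 849.4598), 2.3544)
  expect_equal(ppm_error(779.4450, 779.4449), 0.1283)
  expect_equal(ppm_error(854.3791, 854.3791), 0)
  expect_error(ppm_error(0, 1), "> 0")
  # magnitude only, symmetric displacement
  expect_equal(ppm_error(500, 500.001), ppm_error(500, 499.999))
  # linear scaling with the m/z displacement at fixed theoretical
  expect_equal(ppm_error(500, 500.002), 2 * ppm_error(500, 500.001))
})

test_that("canonical rotation unifies rotational synonyms of a cyclic core", {
  expect_identical(canonical_rotation("YFLDGPPP"), "DGPPPYFL")
  expect_identical(canonical_rotation("LDGPPPYF"), "DGPPPYFL")
  expect_identical(canonical_rotation("HTWGSSTP"),
                   canonical_rotation("WGSSTPHT"))
  expect_identical(canonical_rotation("A"), "A")
  # idempotent
  expect_identical(canonical_rotation(canonical_rotation("GLPIGAPWG")),
                   canonical_rotation("GLPIGAPWG"))
  expect_error(canonical_rotation("IFGGLPPP", cyclic = FALSE), "cyclic")
})

test_that("cyclic mass is exactly rotation invariant and one water below linear", {
  set.seed(11)
  for (i in 1:25) {
    len <- sample(5:16, 1)
    core <- paste(sample(c("A","C","D","E","F","G","H","I","K","L","M","N",
                           "P","Q","R","S","T","V","W","Y"), len,
                         replace = TRUE), collapse = "")
    m <- peptide_mass(core, cyclic = TRUE)
    for (rot in orbimine:::rotations(core))
      expect_identical(peptide_mass(rot, cyclic = TRUE), m)
    expect_equal(peptide_mass(core, cyclic = FALSE) - m, 18.010565)
  }
})
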