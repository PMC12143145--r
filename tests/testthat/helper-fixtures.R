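# Shared fixtures built in code.

# A PreHB-like precursor: synthetic 13-residue leader, the IFGGLPPP core at
# residues 14-21, and the published follower at 22-35.
HB_LEADER <- "MGVDKSELATFYR"
HB_CORE <- "IFGGLPPP"
HB_FOLLOWER <- "SQELINGDDISLMV"
hb_precursor <- function(core = HB_CORE) paste0(HB_LEADER, core, HB_FOLLOWER)

# Deterministic reverse translation (first codon per residue, alphabetical),
# independent of the generator's randomized codon choice.
aa_to_cds <- function(protein, stop_codon = "TAA") {
  gc <- Biostrings::GENETIC_CODE
  first_codon <- vapply(split(names(gc), as.character(gc)),
                        function(x) sort(x)[1], character(1))
  res <- strsplit(protein, "", fixed = TRUE)[[1]]
  paste0(paste(first_codon[res], collapse = ""), stop_codon)
}

# Embed a CDS in fixed flanking sequence.
embed_cds <- function(cds, u5 = "GGGCC", u3 = "AATTC") paste0(u5, cds, u3)

revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

# Reference set for profile building: n precursors with consensus flanks and
# varying rule-conforming cores.
reference_set <- function(n = 6) {
  cores <- c("IFGGLPPP", "GLPIGAPWG", "YFLDGPPP", "HTWGSSTP", "VIFGDVGP",
             "SFLPVNA", "GGYLPA", "WWKLNP")[seq_len(n)]
  data.frame(id = paste0("ref_", seq_len(n)),
             protein = vapply(cores, hb_precursor, character(1)),
             core_start = nchar(HB_LEADER) + 1L,
             core_end = nchar(HB_LEADER) + nchar(cores),
             stringsAsFactors = FALSE)
}

# Exhaustive affine-gap local alignment oracle, independent of sw_score's
# rolling-row formulation: maximises a full-matrix GLOBAL affine alignment
# over every pair of substrings (the definition of local alignment).
oracle_local_score <- function(a, b, open = 11, ext = 1,
                               sub = orbimine:::blosum62()) {
  ra <- strsplit(a, "")[[1]]; rb <- strsplit(b, "")[[1]]
  best <- 0
  for (i1 in seq_along(ra)) for (i2 in i1:length(ra))
    for (j1 in seq_along(rb)) for (j2 in j1:length(rb)) {
      s <- oracle_global(ra[i1:i2], rb[j1:j2], open, ext, sub)
      if (s > best) best <- s
    }
  best
}

oracle_global <- function(ra, rb, open, ext, sub) {
  n <- length(ra); m <- length(rb)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); Ix <- M; Iy <- M
  M[1, 1] <- 0
  for (i in seq_len(n)) Ix[i + 1, 1] <- -(open + ext * i)
  for (j in seq_len(m)) Iy[1, j + 1] <- -(open + ext * j)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    sc <- sub[ra[i], rb[j]]
    M[i + 1, j + 1] <- sc + max(M[i, j], Ix[i, j], Iy[i, j])
    Ix[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, Ix[i, j + 1] - ext)
    Iy[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Iy[i + 1, j] - ext)
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# Small ground-truth stub for expression simulation tests.
expression_stub <- function(cfg) {
  structure(list(precursors = data.frame(id = "p1", core = "IFGGLPPP",
                                         stringsAsFactors = FALSE),
                 config = cfg), class = "ground_truth")
}
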