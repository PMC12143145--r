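# Validate a peptide string over the 20 canonical one-letter codes.
# Returns the vector of residues; errors name the offending character
# and its position.
check_peptide <- function(seq) {
  if (length(seq) != 1L || !is.character(seq) || is.na(seq))
    stop("peptide sequence must be a single character string")
  if (nchar(seq) < 1L)
    stop("peptide sequence must contain at least one residue")
  res <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!(res %in% AA_CODES))
  if (length(bad))
    stop(sprintf("non-canonical residue '%s' at position %d in '%s'",
                 res[bad[1]], bad[1], seq))
  res
}

#' Monoisotopic mass of a cyclic or linear peptide
#'
#' For a head-to-tail cyclic peptide the mass is the plain sum of residue
#' masses: closing the N-to-C amide bond eliminates one water relative to the
#' linear peptide. For a linear peptide one water is added back for the free
#' termini. Full precision is kept; use [round_mz()] only when reporting.
#'
#' @param seq Peptide as a one-letter-code string (20 canonical residues).
#' @param cyclic Logical; `TRUE` (default) for a head-to-tail macrocycle,
#'   `FALSE` for a linear peptide.
#' @param table A [residue_mass_table()].
#' @return Monoisotopic mass in Da (numeric scalar, unrounded).
#' @examples
#' peptide_mass("IFGGLPPP")                 # heterophyllin B ring
#' peptide_mass("SQELINGDDISLMV", cyclic = FALSE)  # its linear follower
#' @seealso [ion_mz()], [ppm_error()], [canonical_rotation()]
#' @export
peptide_mass <- function(seq, cyclic = TRUE, table = residue_mass_table()) {
  res <- check_peptide(seq)
  # summing in sorted order makes the result independent of residue order,
  # so rotations of a cyclic sequence give bit-identical masses
  m <- sum(sort(unname(table$residues[res])))
  if (!cyclic) m <- m + table$water
  m
}

#' m/z of a singly charged adduct ion
#'
#' Converts a neutral monoisotopic mass to the m/z of its singly protonated
#' (`M+H`, positive mode) or deprotonated (`M-H`, negative mode) ion. Only
#' charge 1 is supported: orbitides in the 5-16 residue range are observed
#' as singly charged species.
#'
#' @param mass Neutral monoisotopic mass in Da (> 0).
#' @param adduct `"M+H"` or `"M-H"`.
#' @param charge Ion charge; must be 1.
#' @param table A [residue_mass_table()] (source of the proton mass).
#' @return m/z (numeric, unrounded).
#' @examples
#' ion_mz(peptide_mass("GLPIGAPWG"), "M+H")  # 849.461751
#' @export
ion_mz <- function(mass, adduct = c("M+H", "M-H"), charge = 1L,
                   table = residue_mass_table()) {
  adduct <- match.arg(adduct)
  if (!identical(as.integer(charge), 1L))
    stop("only singly charged ions (charge = 1) are supported")
  if (any(!is.finite(mass)) || any(mass <= 0))
    stop("mass must be finite and > 0")
  if (adduct == "M+H") mass + table$proton else mass - table$proton
}

#' Round an m/z value to 4 decimal places, half-up
#'
#' Reporting convention for theoretical and observed m/z: round-half-up at
#' the 4th decimal (unlike base R's round-half-to-even). A small guard
#' absorbs binary representation error of decimal inputs so that values
#' ending in an exact 5 at the 5th decimal round up.
#'
#' @param mz Numeric vector of finite m/z values.
#' @return `mz` rounded half-up to 4 decimals.
#' @examples
#' round_mz(849.461751)  # 849.4618
#' @export
round_mz <- function(mz) {
  if (any(!is.finite(mz))) stop("mz must be finite")
  scaled <- mz * 1e4
  f <- floor(scaled)
  sign_up <- (scaled - f) >= (0.5 - 1e-6)
  (f + as.numeric(sign_up)) / 1e4
}

#' Relative mass error in parts per million
#'
#' `|theoretical - observed| / theoretical * 1e6`, where the theoretical m/z
#' is first rounded to 4 decimals ([round_mz()]): instrument software reports
#' errors against the 4-dp theoretical value, and only this convention
#' reproduces published ppm figures from their printed m/z pairs. The result
#' is reported as a magnitude (no sign), rounded to 4 decimals.
#'
#' @param theoretical Theoretical m/z (> 0); rounded to 4 dp internally.
#' @param observed Observed m/z.
#' @return Non-negative ppm error, rounded to 4 decimals. Vectorized with
#'   the usual recycling.
#' @examples
#' ppm_error(849.461751, 849.4598)  # 2.3544
#' @export
ppm_error <- function(theoretical, observed) {
  if (any(!is.finite(theoretical)) || any(theoretical <= 0))
    stop("theoretical m/z must be finite and > 0")
  if (any(!is.finite(observed)))
    stop("observed m/z must be finite")
  t4 <- round_mz(theoretical)
  round_mz(abs(t4 - observed) / t4 * 1e6)
}

#' Canonical rotation of a cyclic peptide sequence
#'
#' A head-to-tail cyclic peptide has no N- or C-terminus, so any rotation of
#' its one-letter string names the same molecule (the backbone is
#' directional, so reversals are *not* equivalent). The canonical form is the
#' lexicographically smallest rotation; two cyclic sequences are the same
#' molecule iff their canonical rotations are equal.
#'
#' @param seq Character vector of cyclic peptide sequences.
#' @param cyclic Must be `TRUE`; a linear sequence has a fixed terminus and
#'   is rejected.
#' @return Character vector of canonical rotations (idempotent).
#' @examples
#' canonical_rotation(c("YFLDGPPP", "LDGPPPYF"))  # both "DGPPPYFL"
#' @export
canonical_rotation <- function(seq, cyclic = TRUE) {
  if (!isTRUE(cyclic))
    stop("canonical_rotation is defined only for cyclic sequences")
  vapply(seq, function(s) {
    check_peptide(s)
    n <- nchar(s)
    if (n == 1L) return(s)
    rot <- vapply(seq_len(n), function(i)
      paste0(substr(s, i, n), substr(s, 1L, i - 1L)), character(1))
    min(rot)
  }, character(1), USE.NAMES = FALSE)
}

# All n rotations of a sequence, rotation i starting at residue i.
rotations <- function(seq) {
  n <- nchar(seq)
  vapply(seq_len(n), function(i)
    paste0(substr(seq, i, n), substr(seq, 1L, i - 1L)), character(1))
}
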