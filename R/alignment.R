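#' Smith-Waterman local alignment score
#'
#' Affine-gap local alignment (Gotoh algorithm) with BLOSUM62 scoring and
#' BLASTP default gap costs: a gap of length k costs `gap_open + k *
#' gap_extend`. Used to rank candidate precursor ORFs by similarity to known
#' precursor peptides without requiring an external aligner.
#'
#' @param a,b Amino-acid strings (canonical residues).
#' @param gap_open Gap opening penalty (positive; default 11).
#' @param gap_extend Gap extension penalty per residue (positive; default 1).
#' @param substitution 20+ letter substitution matrix; default BLOSUM62.
#' @return Best local alignment score (numeric scalar, >= 0).
#' @export
sw_score <- function(a, b, gap_open = 11, gap_extend = 1,
                     substitution = blosum62()) {
  ra <- check_peptide(a); rb <- check_peptide(b)
  n <- length(ra); m <- length(rb)
  S <- substitution[ra, rb, drop = FALSE]
  H <- numeric(m + 1L)          # current row, H[j+1] = score ending at (i, j)
  Hprev <- numeric(m + 1L)      # previous row
  Fv <- rep(-Inf, m + 1L)       # vertical gap state, per column
  best <- 0
  for (i in seq_len(n)) {
    e <- -Inf                   # horizontal gap state, per row
    H[1] <- 0
    for (j in seq_len(m)) {
      e <- max(H[j] - gap_open - gap_extend, e - gap_extend)
      Fv[j + 1L] <- max(Hprev[j + 1L] - gap_open - gap_extend,
                        Fv[j + 1L] - gap_extend)
      h <- max(0, Hprev[j] + S[i, j], e, Fv[j + 1L])
      H[j + 1L] <- h
      if (h > best) best <- h
    }
    tmp <- Hprev; Hprev <- H; H <- tmp
  }
  best
}

#' Best local-alignment similarity to a set of reference precursors
#'
#' Aligns a candidate ORF protein against each reference with [sw_score()]
#' and returns the best score and reference; ties are broken by the first
#' reference in input order.
#'
#' @param protein Candidate amino-acid string.
#' @param references Named character vector of reference precursor proteins
#'   (names are reference ids; unnamed references are numbered).
#' @param ... Passed to [sw_score()].
#' @return List with `score` (best score), `reference` (its id), and
#'   `scores` (named vector of all scores, input order).
#' @export
reference_similarity <- function(protein, references, ...) {
  if (length(references) == 0L) stop("empty reference set")
  if (is.null(names(references)))
    names(references) <- paste0("ref_", seq_along(references))
  scores <- vapply(references, function(r) sw_score(protein, r, ...),
                   numeric(1))
  i <- which.max(scores)   # first maximum: input-order tie-break
  list(score = unname(scores[i]), reference = names(references)[i],
       scores = scores)
}
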