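#' Build position-weight profiles for the conserved precursor flanks
#'
#' Orbitide precursors share a conserved N-terminal leader and C-terminal
#' follower around a hypervariable core. This builds one position-specific
#' log-odds profile per flank from a set of reference precursors with known
#' core boundaries: per position, `log2(((count + pc) / (N + 20 pc)) /
#' background)`. All references must yield equal-length leaders and
#' equal-length followers (references are pre-aligned or generated with
#' fixed-length flanks).
#'
#' The acceptance threshold for a scanned flank is a fraction of the maximum
#' attainable profile score (the sum over positions of the best per-position
#' log-odds); no threshold is dictated by the underlying biology, so it is
#' explicit, documented configuration.
#'
#' @param references A data.frame with columns `protein`, `core_start`,
#'   `core_end` (1-based residue coordinates of the core within each
#'   precursor protein). At least 2 rows.
#' @param pseudocount Added to every residue count at every position
#'   (default 1).
#' @param background Named numeric vector of background residue frequencies
#'   over the 20 canonical residues; default uniform 0.05.
#' @param threshold_frac Fraction of the maximum attainable score used as
#'   the acceptance threshold for each flank (default 0.6).
#' @return An object of class `flank_profile`: list with `leader` and
#'   `follower` log-odds matrices (20 x width), `leader_threshold`,
#'   `follower_threshold`, `leader_length`, `follower_length`,
#'   `pseudocount`, `background`, `threshold_frac`.
#' @export
build_flank_profiles <- function(references, pseudocount = 1,
                                 background = NULL, threshold_frac = 0.6) {
  stopifnot(is.data.frame(references),
            all(c("protein", "core_start", "core_end") %in% names(references)))
  if (nrow(references) < 2L)
    stop("at least 2 reference precursors are required")
  if (is.null(background))
    background <- stats::setNames(rep(0.05, 20), AA_CODES)
  if (!setequal(names(background), AA_CODES))
    stop("background must be named over the 20 canonical residues")
  background <- background[AA_CODES]
  leaders <- substr(references$protein, 1L, references$core_start - 1L)
  followers <- substring(references$protein, references$core_end + 1L)
  if (length(unique(nchar(leaders))) != 1L)
    stop("reference leaders have inconsistent lengths: ",
         paste(unique(nchar(leaders)), collapse = ", "))
  if (length(unique(nchar(followers))) != 1L)
    stop("reference followers have inconsistent lengths: ",
         paste(unique(nchar(followers)), collapse = ", "))
  lw <- pwm_logodds(leaders, pseudocount, background)
  fw <- pwm_logodds(followers, pseudocount, background)
  structure(list(
    leader = lw, follower = fw,
    leader_length = ncol(lw), follower_length = ncol(fw),
    leader_threshold = threshold_frac * sum(apply(lw, 2, max)),
    follower_threshold = threshold_frac * sum(apply(fw, 2, max)),
    pseudocount = pseudocount, background = background,
    threshold_frac = threshold_frac,
    n_references = nrow(references)), class = "flank_profile")
}

# 20 x width log-odds matrix from equal-length sequences.
pwm_logodds <- function(seqs, pseudocount, background) {
  width <- nchar(seqs[1])
  n <- length(seqs)
  mat <- matrix(0, nrow = 20, ncol = width, dimnames = list(AA_CODES, NULL))
  chars <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  for (j in seq_len(width)) {
    counts <- table(factor(chars[, j], levels = AA_CODES))
    prob <- (as.numeric(counts) + pseudocount) / (n + 20 * pseudocount)
    mat[, j] <- log2(prob / background)
  }
  mat
}

#' Score a sequence block against one flank profile
#'
#' Sum of per-position log-odds; the block must have the profile's width
#' and contain only canonical residues.
#'
#' @param block Character string of the profile's width.
#' @param pwm A 20-row log-odds matrix (from [build_flank_profiles()]).
#' @return Numeric score.
#' @export
score_flank <- function(block, pwm) {
  res <- check_peptide(block)
  if (length(res) != ncol(pwm))
    stop(sprintf("block width %d does not match profile width %d",
                 length(res), ncol(pwm)))
  sum(pwm[cbind(match(res, rownames(pwm)), seq_along(res))])
}

#' @export
print.flank_profile <- function(x, ...) {
  cat(sprintf(
    "Flank profile from %d references: leader %d aa (threshold %.2f), follower %d aa (threshold %.2f)\n",
    x$n_references, x$leader_length, x$leader_threshold,
    x$follower_length, x$follower_threshold))
  cat(sprintf("  pseudocount %g, threshold fraction %g of maximum score\n",
              x$pseudocount, x$threshold_frac))
  invisible(x)
}
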