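#' Match predicted ions to observed MS1 peaks within a ppm tolerance
#'
#' Reports every (target, peak) pair whose [ppm_error()] is at most
#' `tol_ppm`; one peak may match several targets and vice versa. The match
#' set is monotone in the tolerance.
#'
#' @param targets Data.frame with columns `core`, `adduct` and `mz`
#'   (theoretical m/z); extra columns are carried through.
#' @param peaks Data.frame with columns `mz`, `intensity` and optionally
#'   `rt` (e.g. from [read_peaks()]).
#' @param tol_ppm Tolerance in ppm (> 0); default 5 (observed orbitide
#'   errors on a high-resolution Orbitrap are ~2 ppm or less, so 5 leaves
#'   headroom).
#' @return Data.frame of matches sorted by ppm ascending (ties: intensity
#'   descending): `core`, `adduct`, `theoretical_mz` (4 dp), `observed_mz`,
#'   `intensity`, `rt`, `ppm`.
#' @export
match_ms1 <- function(targets, peaks, tol_ppm = 5) {
  if (!is.finite(tol_ppm) || tol_ppm <= 0) stop("tol_ppm must be > 0")
  empty <- data.frame(core = character(), adduct = character(),
                      theoretical_mz = numeric(), observed_mz = numeric(),
                      intensity = numeric(), rt = numeric(), ppm = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(targets) || !nrow(peaks)) return(empty)
  stopifnot(all(c("core", "adduct", "mz") %in% names(targets)),
            all(c("mz", "intensity") %in% names(peaks)))
  rt <- if ("rt" %in% names(peaks)) peaks$rt else rep(NA_real_, nrow(peaks))
  ti <- rep(seq_len(nrow(targets)), times = nrow(peaks))
  pi <- rep(seq_len(nrow(peaks)), each = nrow(targets))
  ppm <- ppm_error(targets$mz[ti], peaks$mz[pi])
  keep <- ppm <= tol_ppm
  if (!any(keep)) return(empty)
  out <- data.frame(core = targets$core[ti[keep]],
                    adduct = targets$adduct[ti[keep]],
                    theoretical_mz = round_mz(targets$mz[ti[keep]]),
                    observed_mz = peaks$mz[pi[keep]],
                    intensity = peaks$intensity[pi[keep]],
                    rt = rt[pi[keep]], ppm = ppm[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$ppm, -out$intensity), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Score an MS2 spectrum against the ring-opened fragment model of a core
#'
#' The score is the fraction of distinct predicted fragment m/z values (from
#' [predict_ms2_fragments()], coincident predictions merged) that are hit by
#' at least one observed fragment within `tol_ppm`. Intensities are carried
#' through for reporting but do not weight the score.
#'
#' @param core Cyclic peptide sequence (length >= 2).
#' @param spectrum Either a data.frame of fragments (`mz`, `intensity`) or a
#'   spectrum list with elements `precursor_mz` and `fragments` (as returned
#'   by [read_peaks()] for MGF input). Must contain at least one fragment.
#' @param tol_ppm Fragment tolerance in ppm (> 0); default 10.
#' @param series Fragment series to predict (default `"b"`).
#' @param table A [residue_mass_table()].
#' @return List with `score` in \[0, 1\], `n_predicted`, `n_matched`,
#'   `predicted` (the prediction table with a `matched` flag), and
#'   `annotations` (the observed fragments with their best assignment:
#'   `matched_mz`, `residues`, `series`, `k`, `ppm`; `NA` if unassigned).
#' @export
score_ms2 <- function(core, spectrum, tol_ppm = 10, series = "b",
                      table = residue_mass_table()) {
  if (!is.finite(tol_ppm) || tol_ppm <= 0) stop("tol_ppm must be > 0")
  frags <- if (is.data.frame(spectrum)) spectrum else spectrum$fragments
  if (is.null(frags) || !nrow(frags))
    stop("spectrum contains no fragments")
  stopifnot("mz" %in% names(frags))
  pred <- predict_ms2_fragments(core, series = series, collapse = TRUE,
                                table = table)
  # ppm of every observed fragment against every prediction
  np <- nrow(pred); no <- nrow(frags)
  pm <- matrix(ppm_error(rep(pred$mz, times = no), rep(frags$mz, each = np)),
               nrow = np, ncol = no)
  hit <- pm <= tol_ppm
  matched <- rowSums(hit) > 0
  pred$matched <- matched
  best <- apply(pm, 2, which.min)
  best_ppm <- pm[cbind(best, seq_len(no))]
  assigned <- best_ppm <= tol_ppm
  ann <- data.frame(
    mz = frags$mz,
    intensity = if ("intensity" %in% names(frags)) frags$intensity else NA_real_,
    matched_mz = ifelse(assigned, pred$mz[best], NA_real_),
    residues = ifelse(assigned, pred$residues[best], NA_character_),
    series = ifelse(assigned, pred$series[best], NA_character_),
    k = ifelse(assigned, pred$k[best], NA_integer_),
    ppm = ifelse(assigned, best_ppm, NA_real_),
    stringsAsFactors = FALSE)
  list(score = sum(matched) / np, n_predicted = np, n_matched = sum(matched),
       predicted = pred, annotations = ann)
}
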