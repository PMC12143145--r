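#' Predict ring-opened fragment ions of a cyclic peptide
#'
#' Under collision-induced dissociation a head-to-tail cyclic peptide first
#' opens at one of its n amide bonds; each of the n resulting linearizations
#' then fragments into the usual N-terminal acylium (b-ion) ladder. With no
#' free C-terminus there is no y-series; a-ions (b minus CO, 27.994915 Da)
#' can be added on request. For every opening this emits b_1..b_n of that
#' linearization at charge 1; b_n telescopes to the cyclic [M+H]+ for every
#' opening.
#'
#' Predicted m/z values within `merge_tol` Da are merged (proline-rich cores
#' produce many coincident ladder ions); the first occurrence in (opening,
#' series, k) order represents the group and the provenance of all merged
#' ions is retained.
#'
#' @param core Cyclic peptide sequence (length >= 2); the ring is opened at
#'   every position.
#' @param series Character subset of `c("b", "a")`; default b-ions only.
#' @param collapse If `TRUE` (default) merge coincident m/z values; if
#'   `FALSE` return the full n x n ladder table.
#' @param merge_tol Da window within which predictions are considered the
#'   same ion (default 1e-4).
#' @param table A [residue_mass_table()].
#' @return Data.frame ordered by (opening, k): `opening` (0-based index of
#'   the opened bond, 0 = before the first residue of `core` as written),
#'   `series`, `k`, `residues` (the fragment's residue string), `mz`
#'   (unrounded), and when collapsed `n_sources` and `sources` (e.g.
#'   `"o0.b2;o5.b3"`).
#' @examples
#' frag <- predict_ms2_fragments("IFGGLPPP")
#' max(frag$mz)  # the cyclic [M+H]+, 779.445038
#' @export
predict_ms2_fragments <- function(core, series = "b", collapse = TRUE,
                                  merge_tol = 1e-4,
                                  table = residue_mass_table()) {
  res <- check_peptide(core)
  n <- length(res)
  if (n < 2L)
    stop("fragment prediction requires a cyclic core of length >= 2")
  if (!all(series %in% c("b", "a")) || !length(series))
    stop("series must be a non-empty subset of c('b', 'a')")
  rows <- vector("list", n)
  for (o in 0:(n - 1L)) {
    lin <- c(res, res)[(o + 1L):(o + n)]
    bmz <- cumsum(table$residues[lin]) + table$proton
    frag_res <- vapply(seq_len(n), function(k)
      paste(lin[1:k], collapse = ""), character(1))
    df <- data.frame(opening = o, series = "b", k = seq_len(n),
                     residues = frag_res, mz = unname(bmz),
                     stringsAsFactors = FALSE)
    if ("a" %in% series) {
      da <- df; da$series <- "a"; da$mz <- da$mz - CO_MASS
      df <- rbind(df, da)
    }
    if (!("b" %in% series)) df <- df[df$series == "a", , drop = FALSE]
    rows[[o + 1L]] <- df
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$opening, out$k, out$series), , drop = FALSE]
  rownames(out) <- NULL
  if (!collapse) return(out)
  # greedy merge in emission order: stable, deterministic
  rep_mz <- numeric(0)
  group <- integer(nrow(out))
  for (i in seq_len(nrow(out))) {
    hit <- which(abs(rep_mz - out$mz[i]) <= merge_tol)
    if (length(hit)) group[i] <- hit[1]
    else { rep_mz <- c(rep_mz, out$mz[i]); group[i] <- length(rep_mz) }
  }
  first <- match(seq_along(rep_mz), group)
  src <- vapply(seq_along(rep_mz), function(g) {
    idx <- which(group == g)
    paste(sprintf("o%d.%s%d", out$opening[idx], out$series[idx], out$k[idx]),
          collapse = ";")
  }, character(1))
  coll <- out[first, , drop = FALSE]
  coll$n_sources <- tabulate(group, nbins = length(rep_mz))
  coll$sources <- src
  rownames(coll) <- NULL
  coll
}
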