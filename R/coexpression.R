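#' Pearson correlation with guard rails
#'
#' Sample Pearson correlation between two numeric vectors, rejecting the
#' degenerate inputs that silently produce `NA` in [stats::cor()]: unequal
#' lengths, fewer than 3 points, or a zero-variance vector.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param xname,yname Labels used in error messages (e.g. gene/metabolite
#'   ids).
#' @return Pearson r in \[-1, 1\].
#' @export
pearson_r <- function(x, y, xname = "x", yname = "y") {
  if (length(x) != length(y))
    stop(sprintf("length mismatch between %s (%d) and %s (%d)",
                 xname, length(x), yname, length(y)))
  if (length(x) < 3L) stop("at least 3 paired samples are required")
  if (stats::sd(x) == 0) stop(sprintf("zero variance in %s", xname))
  if (stats::sd(y) == 0) stop(sprintf("zero variance in %s", yname))
  as.numeric(stats::cor(x, y))
}

#' Rank tailoring-gene candidates by expression-metabolite correlation
#'
#' Computes the Pearson correlation between every gene's expression and
#' every metabolite's abundance across the shared samples, flags strong
#' candidates (r above `strong`, the threshold used for cyclase candidates)
#' and network edges (r above `edge`), and records whether gene and
#' metabolite peak in the same tissue (`root_coexpressed` in the intended
#' use, orbitides being root-dominant). No p-values or multiple-testing
#' correction are applied: candidates are ranked by r alone, and the score
#' thresholds are the only filter.
#'
#' Correlation is computed across individual replicate samples by default;
#' `level = "tissue_mean"` first averages replicates within each tissue.
#'
#' @param expr Numeric matrix, genes x samples (rownames = gene ids,
#'   colnames = sample ids).
#' @param metab Numeric matrix, metabolites x samples over the same sample
#'   set.
#' @param tissues Named character vector mapping sample id to tissue label.
#' @param strong Strong-candidate threshold (strict; default 0.90).
#' @param edge Network-edge threshold (strict; default 0.50).
#' @param level `"replicate"` (default) or `"tissue_mean"`.
#' @return Data.frame sorted by r descending: `gene`, `metabolite`, `r`,
#'   `n`, `strong`, `edge`, `gene_max_tissue`, `metabolite_max_tissue`,
#'   `root_coexpressed`.
#' @export
rank_candidates <- function(expr, metab, tissues, strong = 0.90, edge = 0.50,
                            level = c("replicate", "tissue_mean")) {
  level <- match.arg(level)
  stopifnot(is.matrix(expr), is.matrix(metab))
  if (!setequal(colnames(expr), colnames(metab))) {
    only_e <- setdiff(colnames(expr), colnames(metab))
    only_m <- setdiff(colnames(metab), colnames(expr))
    stop("sample sets differ between expression and metabolite tables; ",
         "unmatched: ",
         paste(c(only_e, only_m), collapse = ", "))
  }
  metab <- metab[, colnames(expr), drop = FALSE]
  if (is.null(names(tissues)) || !all(colnames(expr) %in% names(tissues)))
    stop("tissues must be a named vector covering every sample")
  tiss <- tissues[colnames(expr)]
  # tissue means always needed for the max-tissue comparison
  emean <- sapply(unique(tiss), function(tt)
    rowMeans(expr[, tiss == tt, drop = FALSE]))
  mmean <- sapply(unique(tiss), function(tt)
    rowMeans(metab[, tiss == tt, drop = FALSE]))
  emean <- matrix(emean, nrow = nrow(expr),
                  dimnames = list(rownames(expr), unique(tiss)))
  mmean <- matrix(mmean, nrow = nrow(metab),
                  dimnames = list(rownames(metab), unique(tiss)))
  if (level == "tissue_mean") { ex <- emean; mx <- mmean }
  else { ex <- expr; mx <- metab }
  combos <- expand.grid(g = seq_len(nrow(ex)), m = seq_len(nrow(mx)))
  r <- mapply(function(g, m)
    pearson_r(ex[g, ], mx[m, ], rownames(ex)[g], rownames(mx)[m]),
    combos$g, combos$m)
  gmax <- colnames(emean)[max.col(emean, ties.method = "first")]
  mmax <- colnames(mmean)[max.col(mmean, ties.method = "first")]
  out <- data.frame(
    gene = rownames(ex)[combos$g],
    metabolite = rownames(mx)[combos$m],
    r = r, n = ncol(ex),
    strong = r > strong, edge = r > edge,
    gene_max_tissue = gmax[combos$g],
    metabolite_max_tissue = mmax[combos$m],
    stringsAsFactors = FALSE)
  out$root_coexpressed <- out$gene_max_tissue == out$metabolite_max_tissue
  out <- out[order(-out$r), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export the thresholded gene-metabolite network as an edge list
#'
#' Writes edges `(gene, metabolite, r)` for all pairs with r strictly above
#' the threshold, sorted by r descending, as a TSV loadable by standard
#' network viewers.
#'
#' @param results Data.frame from [rank_candidates()].
#' @param path Output TSV path.
#' @param threshold Strict edge threshold on r (default 0.50).
#' @return The edge data.frame, invisibly.
#' @export
export_network <- function(results, path, threshold = 0.50) {
  edges <- results[results$r > threshold, c("gene", "metabolite", "r"),
                   drop = FALSE]
  edges <- edges[order(-edges$r), , drop = FALSE]
  rownames(edges) <- NULL
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(edges)
}
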