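#' Monoisotopic residue mass table
#'
#' Loads the table of monoisotopic amino-acid residue masses (the mass each
#' residue contributes to a peptide chain, i.e. the free amino-acid mass minus
#' one water) together with the proton and water monoisotopic masses used for
#' adduct and cyclization arithmetic. The default table ships with the package
#' as a plain-text file so it is auditable and can be overridden.
#'
#' Residue masses are pinned at 6 decimal places; this precision is required
#' to reproduce 4-decimal m/z values for peptides in the orbitide size range
#' (5-16 residues) without drift.
#'
#' @param path Path to a tab-separated file with columns `code` and `mass`.
#'   Must contain exactly the 20 canonical one-letter residue codes plus the
#'   special rows `proton` and `water`. `NULL` (default) uses the table
#'   shipped with the package.
#' @return An object of class `residue_mass_table`: a list with elements
#'   `residues` (named numeric vector of the 20 residue masses in Da),
#'   `proton` and `water` (scalars, Da).
#' @examples
#' tab <- residue_mass_table()
#' tab$residues[["G"]]   # glycine residue, 57.021464 Da
#' tab$water             # 18.010565 Da lost on head-to-tail cyclization
#' @export
residue_mass_table <- function(path = NULL) {
  if (is.null(path)) {
    cached <- .orbimine_cache$residue_table
    if (!is.null(cached)) return(cached)
    path <- system.file("extdata", "residue_masses.tsv", package = "orbimine",
                        mustWork = TRUE)
    use_cache <- TRUE
  } else {
    use_cache <- FALSE
  }
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("code", "mass") %in% names(raw)))
    stop("residue mass table must have columns 'code' and 'mass'")
  masses <- stats::setNames(as.numeric(raw$mass), raw$code)
  special <- c("proton", "water")
  if (!all(special %in% names(masses)))
    stop("residue mass table must contain 'proton' and 'water' rows")
  residues <- masses[setdiff(names(masses), special)]
  if (!setequal(names(residues), AA_CODES) || length(residues) != 20L)
    stop("residue mass table must contain exactly the 20 canonical residues")
  if (any(!is.finite(masses)) || any(masses <= 0))
    stop("all masses must be finite and strictly positive")
  tab <- structure(
    list(residues = residues[AA_CODES],
         proton = unname(masses[["proton"]]),
         water  = unname(masses[["water"]])),
    class = "residue_mass_table")
  if (use_cache) .orbimine_cache$residue_table <- tab
  tab
}

#' @export
print.residue_mass_table <- function(x, ...) {
  cat("Monoisotopic residue mass table (20 canonical residues)\n")
  cat(sprintf("  proton %.6f Da, water %.6f Da\n", x$proton, x$water))
  print(round(x$residues, 6))
  invisible(x)
}

# The 20 canonical one-letter codes, fixed order.
AA_CODES <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Monoisotopic CO mass: converts b-ions to a-ions.
CO_MASS <- 27.994915

.orbimine_cache <- new.env(parent = emptyenv())

# BLOSUM62 from Biostrings, loaded once.
blosum62 <- function() {
  m <- .orbimine_cache$blosum62
  if (is.null(m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62
    .orbimine_cache$blosum62 <- m
  }
  m
}
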