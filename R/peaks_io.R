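#' Read MS1 peak tables or MS2 spectra from disk
#'
#' TSV/CSV files must have columns `mz` and `intensity` (and optionally
#' `rt`, retention time in minutes); rows are returned in file order and
#' malformed rows are reported with their line number. MGF files use the
#' `BEGIN IONS` / `PEPMASS=` / `END IONS` dialect; each block becomes one
#' spectrum.
#'
#' @param path Input file.
#' @param format `"tsv"`, `"csv"` or `"mgf"`; default guesses from the file
#'   extension.
#' @return For `tsv`/`csv`: a data.frame of MS1 peaks (`mz`, `intensity`,
#'   `rt`). For `mgf`: a list of spectra, each a list with `title`,
#'   `precursor_mz`, `charge` and `fragments` (data.frame `mz`,
#'   `intensity`).
#' @export
read_peaks <- function(path, format = NULL) {
  if (!file.exists(path)) stop("peak file not found: ", path)
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  if (!format %in% c("tsv", "csv", "mgf"))
    stop("unknown peak format '", format, "' (expected tsv, csv or mgf)")
  if (format == "mgf") return(read_mgf(path))
  df <- if (format == "tsv") utils::read.delim(path, stringsAsFactors = FALSE)
        else utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("mz", "intensity") %in% names(df)))
    stop(path, ": peak table must have columns 'mz' and 'intensity'")
  for (col in intersect(c("mz", "intensity", "rt"), names(df))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop(sprintf("%s: non-numeric %s at line %d", path, col, bad[1] + 1L))
    df[[col]] <- v
  }
  bad <- which(!is.finite(df$mz) | df$mz <= 0)
  if (length(bad))
    stop(sprintf("%s: non-positive or missing m/z at line %d", path, bad[1] + 1L))
  bad <- which(!is.finite(df$intensity) | df$intensity < 0)
  if (length(bad))
    stop(sprintf("%s: negative or missing intensity at line %d", path, bad[1] + 1L))
  if (!"rt" %in% names(df)) df$rt <- NA_real_
  df[, c("mz", "intensity", "rt")]
}

read_mgf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  spectra <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    line <- trimws(lines[i])
    if (line == "BEGIN IONS") {
      title <- NA_character_; pep <- NA_real_; charge <- NA_integer_
      frags <- list()
      i <- i + 1L
      repeat {
        if (i > n) stop(sprintf("%s: unterminated BEGIN IONS block", path))
        line <- trimws(lines[i])
        if (line == "END IONS") break
        if (grepl("^TITLE=", line)) {
          title <- sub("^TITLE=", "", line)
        } else if (grepl("^PEPMASS=", line)) {
          pep <- suppressWarnings(as.numeric(
            strsplit(sub("^PEPMASS=", "", line), "\\s+")[[1]][1]))
          if (is.na(pep))
            stop(sprintf("%s: malformed PEPMASS at line %d", path, i))
        } else if (grepl("^CHARGE=", line)) {
          charge <- suppressWarnings(as.integer(
            sub("\\+$", "", sub("^CHARGE=", "", line))))
        } else if (grepl("^[A-Z]+=", line)) {
          # other headers ignored
        } else if (nzchar(line)) {
          xy <- suppressWarnings(as.numeric(strsplit(line, "[[:space:]]+")[[1]]))
          if (length(xy) < 1L || any(is.na(xy[1:min(2, length(xy))])))
            stop(sprintf("%s: malformed fragment line %d", path, i))
          if (xy[1] <= 0)
            stop(sprintf("%s: non-positive fragment m/z at line %d", path, i))
          frags[[length(frags) + 1L]] <-
            c(xy[1], if (length(xy) >= 2) xy[2] else NA_real_)
        }
        i <- i + 1L
      }
      if (is.na(pep))
        stop(sprintf("%s: BEGIN IONS block without PEPMASS (ends line %d)",
                     path, i))
      fr <- if (length(frags)) {
        m <- do.call(rbind, frags)
        data.frame(mz = m[, 1], intensity = m[, 2])
      } else data.frame(mz = numeric(), intensity = numeric())
      spectra[[length(spectra) + 1L]] <-
        list(title = title, precursor_mz = pep, charge = charge,
             fragments = fr)
    }
    i <- i + 1L
  }
  spectra
}

#' Write MS2 spectra to an MGF file
#'
#' @param spectra List of spectra as returned by [read_peaks()] for MGF
#'   input (`title`, `precursor_mz`, optional `charge`, `fragments`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines("BEGIN IONS", con)
    if (!is.null(sp$title) && !is.na(sp$title))
      writeLines(paste0("TITLE=", sp$title), con)
    writeLines(sprintf("PEPMASS=%.6f", sp$precursor_mz), con)
    if (!is.null(sp$charge) && !is.na(sp$charge))
      writeLines(sprintf("CHARGE=%d+", sp$charge), con)
    fr <- sp$fragments
    if (nrow(fr))
      writeLines(sprintf("%.6f %.1f", fr$mz, fr$intensity), con)
    writeLines("END IONS", con)
  }
  invisible(path)
}

#' Write an MS1 peak table as TSV
#'
#' @param peaks Data.frame with `mz`, `intensity`, optionally `rt`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  out <- data.frame(mz = sprintf("%.6f", peaks$mz),
                    intensity = sprintf("%.3f", peaks$intensity))
  if ("rt" %in% names(peaks)) out$rt <- sprintf("%.4f", peaks$rt)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
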