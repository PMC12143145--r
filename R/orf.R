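#' Read transcript sequences from a FASTA file
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] returning a named
#' character vector (uppercased), the form consumed by [six_frame_orfs()].
#' Record ids are truncated at the first whitespace.
#'
#' @param path Path to a nucleotide FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_transcripts <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  x <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(x))
  names(seqs) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(seqs)))
    stop("duplicate transcript ids in ", path)
  seqs
}

#' Write named sequences to FASTA
#'
#' @param seqs Named character vector (nucleotide or amino acid).
#' @param path Output path.
#' @param type `"dna"` or `"aa"`.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, type = c("dna", "aa")) {
  type <- match.arg(type)
  x <- if (type == "dna") Biostrings::DNAStringSet(seqs)
       else Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Find short open reading frames in all six frames
#'
#' Scans both strands and all three frames of each transcript for ORFs
#' (ATG through the first in-frame stop, standard genetic code) whose
#' encoded protein falls in a length window. Orbitide precursor CDSs are
#' extremely short (~108 bp, i.e. a ~35-residue precursor), so the default
#' window brackets that size and keeps the candidate set small.
#'
#' Codons containing `N` are untranslatable: a reading that hits one is
#' terminated there and discarded rather than guessed. Nested ORFs (an
#' internal ATG sharing the same stop) are all reported if within the
#' length window.
#'
#' @param transcripts Named character vector of A/C/G/T/N sequences (or a
#'   single unnamed sequence).
#' @param min_len,max_len Protein length window in residues (Met included,
#'   stop excluded); `min_len >= 5`.
#' @return A data.frame with one row per ORF: `transcript_id`, `frame`
#'   (+1/+2/+3/-1/-2/-3), `start`, `end` (1-based inclusive nucleotide
#'   coordinates on the forward strand, spanning ATG through stop), and
#'   `protein`.
#' @examples
#' tx <- c(t1 = paste0("AA", "ATG", strrep("GGC", 29), "TGA", "CC"))
#' six_frame_orfs(tx, min_len = 25, max_len = 60)  # one 30-residue ORF
#' @export
six_frame_orfs <- function(transcripts, min_len = 25L, max_len = 60L) {
  if (min_len < 5L) stop("min_len must be >= 5")
  if (max_len < min_len) stop("max_len must be >= min_len")
  if (is.null(names(transcripts))) {
    if (length(transcripts) > 1L) stop("multiple transcripts must be named")
    names(transcripts) <- "transcript_1"
  }
  out <- vector("list", length(transcripts))
  for (ti in seq_along(transcripts)) {
    id <- names(transcripts)[ti]
    fwd <- toupper(transcripts[[ti]])
    if (!nzchar(fwd)) stop("empty sequence for transcript ", id)
    if (grepl("[^ACGTN]", fwd))
      stop(sprintf("transcript %s contains characters outside A/C/G/T/N", id))
    L <- nchar(fwd)
    rev <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
    rows <- list()
    for (strand in c("+", "-")) {
      s <- if (strand == "+") fwd else rev
      for (off in 0:2) {
        n_codon <- (L - off) %/% 3L
        if (n_codon < 2L) next
        starts <- off + 3L * (seq_len(n_codon) - 1L) + 1L
        codons <- substring(s, starts, starts + 2L)
        aa <- GENETIC_CODE_VEC[codons]       # NA for codons containing N
        orf_rows <- find_orfs_in_frame(aa, min_len, max_len)
        if (is.null(orf_rows)) next
        for (k in seq_len(nrow(orf_rows))) {
          i <- orf_rows$start_codon[k]; j <- orf_rows$stop_codon[k]
          s1 <- starts[i]; s2 <- starts[j] + 2L   # span incl. stop codon
          if (strand == "+") {
            a <- s1; b <- s2; frame <- sprintf("+%d", off + 1L)
          } else {
            a <- L - s2 + 1L; b <- L - s1 + 1L; frame <- sprintf("-%d", off + 1L)
          }
          rows[[length(rows) + 1L]] <- data.frame(
            transcript_id = id, frame = frame, start = a, end = b,
            protein = orf_rows$protein[k], stringsAsFactors = FALSE)
        }
      }
    }
    out[[ti]] <- if (length(rows)) do.call(rbind, rows) else NULL
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(transcript_id = character(), frame = character(),
                      start = integer(), end = integer(),
                      protein = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Given the translated codon vector of one frame (NA = untranslatable,
# "*" = stop), return ATG->first-stop ORFs within the length window.
find_orfs_in_frame <- function(aa, min_len, max_len) {
  n <- length(aa)
  # breaks: stops end an ORF validly; NAs terminate without an end
  met <- which(!is.na(aa) & aa == "M")
  if (!length(met)) return(NULL)
  stop_or_na <- which(is.na(aa) | aa == "*")
  rows <- list()
  for (i in met) {
    nxt <- stop_or_na[stop_or_na > i]
    if (!length(nxt)) next
    j <- nxt[1]
    if (is.na(aa[j])) next                 # ran into an N codon: terminated
    len <- j - i                           # residues incl. Met, excl. stop
    if (len < min_len || len > max_len) next
    rows[[length(rows) + 1L]] <- data.frame(
      start_codon = i, stop_codon = j,
      protein = paste(aa[i:(j - 1L)], collapse = ""),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

GENETIC_CODE_VEC <- local({
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
})
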