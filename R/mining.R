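#' Segment candidate ORFs into leader / core / follower precursor annotations
#'
#' For each ORF, places the leader block near the N-terminus (start offset
#' 0..`max_slide`) and the follower block near the C-terminus (end offset
#' 0..`max_slide`), flush against the core in between, and accepts a
#' segmentation when both flank profile scores reach their thresholds and
#' the core obeys the two family rules: length within `core_len_range`
#' (5-16 residues) and a C-terminal Pro or Ala. Every accepted segmentation
#' is emitted, ranked by the sum of flank scores (ties: longer core, then
#' more N-terminal core start). ORFs too short to hold leader + minimal
#' core + follower are skipped; their count is reported on stderr.
#'
#' Each annotation carries the predicted singly protonated m/z of its core
#' as a head-to-tail macrocycle.
#'
#' @param orfs Data.frame from [six_frame_orfs()].
#' @param profile A [build_flank_profiles()] object.
#' @param max_slide Maximum offset of the leader start / follower end from
#'   the protein termini (default 2).
#' @param core_len_range Allowed core length, inclusive (default `c(5, 16)`).
#' @param core_terminal Allowed final core residues (default `c("P", "A")`).
#' @param references Optional named character vector of reference precursor
#'   proteins; when given, each annotated ORF also carries its best
#'   [reference_similarity()] score and annotations below `min_similarity`
#'   are dropped.
#' @param min_similarity Similarity floor applied when `references` is
#'   given (default `-Inf`, i.e. report-only).
#' @param table A [residue_mass_table()].
#' @return Data.frame of precursor annotations: `transcript_id`, `frame`,
#'   `cds_start`, `cds_end`, `leader`, `core`, `follower`, `core_start`,
#'   `core_end` (residue coordinates within the precursor), `leader_score`,
#'   `follower_score`, `score`, `similarity_score`, `best_reference`,
#'   `core_mz` (4-dp [M+H]+ of the cyclic core).
#' @export
scan_precursors <- function(orfs, profile, max_slide = 2L,
                            core_len_range = c(5L, 16L),
                            core_terminal = c("P", "A"),
                            references = NULL, min_similarity = -Inf,
                            table = residue_mass_table()) {
  stopifnot(inherits(profile, "flank_profile"))
  lk <- profile$leader_length; fk <- profile$follower_length
  min_n <- lk + core_len_range[1] + fk
  rows <- list()
  n_skipped <- 0L
  for (i in seq_len(nrow(orfs))) {
    p <- orfs$protein[i]
    n <- nchar(p)
    if (n < min_n) { n_skipped <- n_skipped + 1L; next }
    for (ls in 1L:(1L + max_slide)) {
      le <- ls + lk - 1L
      if (le >= n) break
      leader <- substr(p, ls, le)
      lscore <- score_flank(leader, profile$leader)
      if (lscore < profile$leader_threshold) next
      for (fe in seq.int(max(n - max_slide, le + 1L), n)) {
        fs <- fe - fk + 1L
        core <- substr(p, le + 1L, fs - 1L)
        clen <- nchar(core)
        if (fs <= le + 1L || clen < core_len_range[1] || clen > core_len_range[2]) next
        if (!(substr(core, clen, clen) %in% core_terminal)) next
        follower <- substr(p, fs, fe)
        fscore <- score_flank(follower, profile$follower)
        if (fscore < profile$follower_threshold) next
        rows[[length(rows) + 1L]] <- data.frame(
          transcript_id = orfs$transcript_id[i], frame = orfs$frame[i],
          cds_start = orfs$start[i], cds_end = orfs$end[i],
          leader = leader, core = core, follower = follower,
          core_start = le + 1L, core_end = fs - 1L,
          leader_score = lscore, follower_score = fscore,
          score = lscore + fscore, stringsAsFactors = FALSE)
      }
    }
  }
  if (n_skipped > 0L)
    message(sprintf("scan_precursors: skipped %d ORF(s) shorter than %d residues",
                    n_skipped, min_n))
  if (!length(rows)) return(empty_annotations())
  ann <- do.call(rbind, rows)
  if (!is.null(references)) {
    sims <- lapply(seq_len(nrow(ann)), function(k) {
      full <- paste0(ann$leader[k], ann$core[k], ann$follower[k])
      reference_similarity(full, references)
    })
    ann$similarity_score <- vapply(sims, `[[`, numeric(1), "score")
    ann$best_reference <- vapply(sims, `[[`, character(1), "reference")
    ann <- ann[ann$similarity_score >= min_similarity, , drop = FALSE]
  } else {
    ann$similarity_score <- NA_real_
    ann$best_reference <- NA_character_
  }
  if (!nrow(ann)) return(empty_annotations())
  ann$core_mz <- round_mz(ion_mz(
    vapply(ann$core, peptide_mass, numeric(1), cyclic = TRUE, table = table),
    "M+H", table = table))
  ord <- order(-ann$score, -nchar(ann$core), ann$core_start)
  ann <- ann[ord, , drop = FALSE]
  rownames(ann) <- NULL
  ann
}

empty_annotations <- function() {
  data.frame(transcript_id = character(), frame = character(),
             cds_start = integer(), cds_end = integer(),
             leader = character(), core = character(), follower = character(),
             core_start = integer(), core_end = integer(),
             leader_score = numeric(), follower_score = numeric(),
             score = numeric(), similarity_score = numeric(),
             best_reference = character(), core_mz = numeric(),
             stringsAsFactors = FALSE)
}

#' Collapse rotationally duplicate cyclic cores
#'
#' Two mined cores that are rotations of one another name the same cyclic
#' molecule. Annotations are grouped by [canonical_rotation()] of the core;
#' the highest-scoring annotation represents each group, with group size and
#' member transcripts recorded.
#'
#' @param annotations Data.frame from [scan_precursors()].
#' @return One representative row per distinct cyclic core, with added
#'   columns `core_canonical`, `group_size` and `members`
#'   (semicolon-separated transcript ids), sorted by score.
#' @export
dereplicate <- function(annotations) {
  if (!nrow(annotations)) {
    out <- annotations
    out$core_canonical <- character(0)
    out$group_size <- integer(0)
    out$members <- character(0)
    return(out)
  }
  canon <- canonical_rotation(annotations$core)
  keep <- integer(0)
  sizes <- integer(0)
  members <- character(0)
  for (cc in unique(canon)) {
    idx <- which(canon == cc)
    best <- idx[which.max(annotations$score[idx])]
    keep <- c(keep, best)
    sizes <- c(sizes, length(idx))
    members <- c(members,
                 paste(unique(annotations$transcript_id[idx]), collapse = ";"))
  }
  out <- annotations[keep, , drop = FALSE]
  out$core_canonical <- canon[keep]
  out$group_size <- sizes
  out$members <- members
  out <- out[order(-out$score), , drop = FALSE]
  rownames(out) <- NULL
  out
}
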