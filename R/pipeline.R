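# Full configuration schema: key -> c(type, default or NA for required/optional)
RUN_CONFIG_SCHEMA <- list(
  transcripts       = list(type = "path",    required = TRUE),
  references        = list(type = "path",    required = TRUE),
  ms1               = list(type = "path",    required = FALSE),
  ms2               = list(type = "path",    required = FALSE),
  expression        = list(type = "path",    required = FALSE),
  metabolites       = list(type = "path",    required = FALSE),
  out_dir           = list(type = "string",  default = "orbimine_out"),
  profile_threshold = list(type = "number",  default = 0.6,  min = 0, max = 1),
  tol_ppm_ms1       = list(type = "number",  default = 5,    min = 1e-6, max = 1000),
  tol_ppm_ms2       = list(type = "number",  default = 10,   min = 1e-6, max = 1000),
  strong_r          = list(type = "number",  default = 0.90, min = -1, max = 1),
  edge_r            = list(type = "number",  default = 0.50, min = -1, max = 1),
  adduct            = list(type = "string",  default = "M+H",
                           choices = c("M+H", "M-H")),
  a_ions            = list(type = "logical", default = FALSE),
  max_slide         = list(type = "number",  default = 2,  min = 0, max = 10),
  min_orf           = list(type = "number",  default = 25, min = 5, max = 1000),
  max_orf           = list(type = "number",  default = 60, min = 5, max = 1000),
  min_core          = list(type = "number",  default = 5,  min = 1, max = 100),
  max_core          = list(type = "number",  default = 16, min = 1, max = 100),
  correlation_level = list(type = "string",  default = "replicate",
                           choices = c("replicate", "tissue_mean")),
  seed              = list(type = "number",  default = 1),
  log_level         = list(type = "string",  default = "info",
                           choices = c("quiet", "info", "debug"))
)

#' Validate a pipeline configuration
#'
#' Reads a YAML or JSON configuration (or takes a list), checks every key
#' against the documented schema, fills defaults, and rejects unknown keys
#' outright (with a closest-match suggestion) so that typos cannot silently
#' disable an option. Referenced input paths are checked for existence at
#' run start by [run_discovery()], not here.
#'
#' Recognised keys: `transcripts` and `references` (required input paths),
#' `ms1`, `ms2`, `expression`, `metabolites` (optional input paths),
#' `out_dir`, `profile_threshold`, `tol_ppm_ms1`, `tol_ppm_ms2`,
#' `strong_r`, `edge_r`, `adduct`, `a_ions`, `max_slide`, `min_orf`,
#' `max_orf`, `min_core`, `max_core`, `correlation_level`, `seed`,
#' `log_level`.
#'
#' @param config Path to a `.yaml`/`.yml`/`.json` file, or a named list.
#' @return Fully defaulted, validated configuration of class `run_config`.
#'   The source file's MD5 (when read from disk) is stored as attribute
#'   `config_hash`.
#' @export
validate_config <- function(config) {
  hash <- NA_character_
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    ext <- tolower(tools::file_ext(config))
    cfg <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(config)
           else if (ext == "json") jsonlite::read_json(config,
                                                       simplifyVector = TRUE)
           else stop("config must be YAML or JSON, got .", ext)
    hash <- unname(tools::md5sum(config))
  } else if (is.list(config)) {
    cfg <- config
  } else stop("config must be a file path or a named list")
  if (is.null(names(cfg)) && length(cfg))
    stop("config must be a named mapping")
  errors <- character(0)
  unknown <- setdiff(names(cfg), names(RUN_CONFIG_SCHEMA))
  for (k in unknown) {
    d <- utils::adist(k, names(RUN_CONFIG_SCHEMA))
    near <- names(RUN_CONFIG_SCHEMA)[which.min(d)]
    errors <- c(errors,
                if (min(d) <= 3)
                  sprintf("unknown key '%s' (did you mean '%s'?)", k, near)
                else sprintf("unknown key '%s'", k))
  }
  out <- list()
  for (k in names(RUN_CONFIG_SCHEMA)) {
    sch <- RUN_CONFIG_SCHEMA[[k]]
    if (!k %in% names(cfg) || is.null(cfg[[k]])) {
      if (isTRUE(sch$required)) {
        errors <- c(errors, sprintf("missing required key '%s' (a path)", k))
      } else {
        out[[k]] <- if (!is.null(sch$default)) sch$default else NA
      }
      next
    }
    v <- cfg[[k]]
    if (length(v) != 1L) {
      errors <- c(errors, sprintf("'%s' must be a single value", k)); next
    }
    ok <- switch(sch$type,
      path = , string = is.character(v),
      number = is.numeric(v),
      logical = is.logical(v))
    if (!ok) {
      errors <- c(errors, sprintf("'%s' must be of type %s", k,
                                  sub("path", "string (a path)", sch$type)))
      next
    }
    if (!is.null(sch$min) && (v < sch$min || v > sch$max)) {
      errors <- c(errors, sprintf("'%s' = %s out of range [%g, %g]",
                                  k, format(v), sch$min, sch$max))
      next
    }
    if (!is.null(sch$choices) && !v %in% sch$choices) {
      errors <- c(errors, sprintf("'%s' must be one of: %s", k,
                                  paste(sch$choices, collapse = ", ")))
      next
    }
    out[[k]] <- v
  }
  if (length(errors))
    stop("invalid configuration:\n  - ", paste(errors, collapse = "\n  - "))
  structure(out, class = "run_config", config_hash = hash)
}

log_stage <- function(cfg, stage, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full orbitide discovery pipeline
#'
#' Orchestrates mine -> mass -> MS1 match -> MS2 score -> correlate over
#' the inputs named in the configuration and writes intermediate tables
#' plus a final discovery report (TSV + JSON) into `out_dir`. Optional
#' inputs simply leave their report columns empty. All input paths are
#' checked before any stage runs; logs go to stderr and never into the
#' report files, which are byte-reproducible given config + inputs + seed.
#'
#' The references file is a TSV with columns `id`, `protein`,
#' `core_start`, `core_end` (pre-segmented precursor proteins used to build
#' the flank profiles). Expression/metabolite TSVs have the feature id in
#' the first column and one column per sample, named `<tissue>_<replicate>`.
#'
#' @param config A path, list, or validated `run_config`.
#' @return Invisibly, a list of class `discovery_report`: `candidates`
#'   (the per-candidate evidence table), `correlations`, `network`, `meta`
#'   (config hash, package version, seed, thresholds), and the paths of
#'   the files written.
#' @export
run_discovery <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  # pre-flight: every referenced input must exist before any stage runs
  for (k in c("transcripts", "references", "ms1", "ms2", "expression",
              "metabolites")) {
    p <- cfg[[k]]
    if (!is.na(p) && !file.exists(p))
      stop(sprintf("input '%s' not found: %s", k, p))
  }
  if (!is.na(cfg$expression) != !is.na(cfg$metabolites))
    stop("expression and metabolites must be provided together")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(as.integer(cfg$seed))

  log_stage(cfg, "mine", "reading transcripts from %s", cfg$transcripts)
  transcripts <- read_transcripts(cfg$transcripts)
  orfs <- six_frame_orfs(transcripts, min_len = cfg$min_orf,
                         max_len = cfg$max_orf)
  log_stage(cfg, "mine", "%d ORFs in %d transcripts", nrow(orfs),
            length(transcripts))
  refs <- utils::read.delim(cfg$references, stringsAsFactors = FALSE)
  profile <- build_flank_profiles(refs, threshold_frac = cfg$profile_threshold)
  ann <- scan_precursors(orfs, profile, max_slide = cfg$max_slide,
                         core_len_range = c(cfg$min_core, cfg$max_core))
  cand <- dereplicate(ann)
  log_stage(cfg, "mine", "%d annotations, %d distinct cyclic cores",
            nrow(ann), nrow(cand))
  write_tsv(ann, file.path(cfg$out_dir, "annotations.tsv"))

  # theoretical ions of every distinct core
  cand$theoretical_mz <- vapply(cand$core_canonical, function(s)
    ion_mz(peptide_mass(s, cyclic = TRUE), cfg$adduct), numeric(1))

  matches <- NULL
  cand$best_observed_mz <- NA_real_
  cand$best_ppm <- NA_real_
  cand$best_rt <- NA_real_
  if (!is.na(cfg$ms1)) {
    peaks <- read_peaks(cfg$ms1)
    targets <- data.frame(core = cand$core_canonical, adduct = cfg$adduct,
                          mz = cand$theoretical_mz, stringsAsFactors = FALSE)
    matches <- match_ms1(targets, peaks, tol_ppm = cfg$tol_ppm_ms1)
    log_stage(cfg, "match", "%d MS1 matches at %g ppm", nrow(matches),
              cfg$tol_ppm_ms1)
    write_tsv(matches, file.path(cfg$out_dir, "ms1_matches.tsv"))
    if (nrow(matches)) {
      first <- match(cand$core_canonical, matches$core)  # best: sorted by ppm
      cand$best_observed_mz <- matches$observed_mz[first]
      cand$best_ppm <- matches$ppm[first]
      cand$best_rt <- matches$rt[first]
    }
  }

  cand$ms2_score <- NA_real_
  if (!is.na(cfg$ms2)) {
    spectra <- read_peaks(cfg$ms2, format = "mgf")
    series <- if (isTRUE(cfg$a_ions)) c("b", "a") else "b"
    pmz <- vapply(spectra, `[[`, numeric(1), "precursor_mz")
    for (i in seq_len(nrow(cand))) {
      sel <- which(ppm_error(rep(cand$theoretical_mz[i], length(pmz)), pmz)
                   <= cfg$tol_ppm_ms1)
      if (!length(sel)) next
      scores <- vapply(sel, function(s) {
        if (!nrow(spectra[[s]]$fragments)) return(NA_real_)
        score_ms2(cand$core_canonical[i], spectra[[s]],
                  tol_ppm = cfg$tol_ppm_ms2, series = series)$score
      }, numeric(1))
      if (any(!is.na(scores)))
        cand$ms2_score[i] <- max(scores, na.rm = TRUE)
    }
    log_stage(cfg, "ms2", "scored %d candidates against %d spectra",
              sum(!is.na(cand$ms2_score)), length(spectra))
  }

  correlations <- NULL; network <- NULL
  if (!is.na(cfg$expression)) {
    em <- read_matrix_tsv(cfg$expression)
    mm <- read_matrix_tsv(cfg$metabolites)
    tissues <- stats::setNames(sub("_[^_]*$", "", colnames(em)), colnames(em))
    correlations <- rank_candidates(em, mm, tissues,
                                    strong = cfg$strong_r, edge = cfg$edge_r,
                                    level = cfg$correlation_level)
    write_tsv(correlations, file.path(cfg$out_dir, "correlations.tsv"))
    network <- export_network(correlations,
                              file.path(cfg$out_dir, "network.tsv"),
                              threshold = cfg$edge_r)
    log_stage(cfg, "correlate", "%d gene-metabolite pairs, %d edges, %d strong",
              nrow(correlations), nrow(network), sum(correlations$strong))
  }

  cand$theoretical_mz <- round_mz(cand$theoretical_mz)
  report_cols <- c("core_canonical", "group_size", "members", "transcript_id",
                   "frame", "cds_start", "cds_end", "leader", "core",
                   "follower", "leader_score", "follower_score", "score",
                   "theoretical_mz", "best_observed_mz", "best_ppm",
                   "best_rt", "ms2_score")
  report <- cand[, report_cols, drop = FALSE]
  write_tsv(report, file.path(cfg$out_dir, "report.tsv"))
  meta <- list(package = "orbimine",
               version = as.character(utils::packageVersion("orbimine")),
               config_hash = attr(cfg, "config_hash"),
               seed = cfg$seed,
               adduct = cfg$adduct,
               thresholds = cfg[c("profile_threshold", "tol_ppm_ms1",
                                  "tol_ppm_ms2", "strong_r", "edge_r")])
  jsonlite::write_json(
    list(meta = meta, candidates = report,
         top_correlations = if (!is.null(correlations))
           utils::head(correlations, 25) else NULL),
    file.path(cfg$out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  log_stage(cfg, "report", "wrote %s", file.path(cfg$out_dir, "report.json"))
  invisible(structure(
    list(candidates = report, ms1_matches = matches,
         correlations = correlations, network = network, meta = meta,
         out_dir = cfg$out_dir),
    class = "discovery_report"))
}

#' @export
print.discovery_report <- function(x, ...) {
  cat(sprintf("orbimine discovery report: %d candidate cyclic cores\n",
              nrow(x$candidates)))
  cat(sprintf("  with MS1 support (ppm <= tol): %d; with MS2 score: %d\n",
              sum(!is.na(x$candidates$best_ppm)),
              sum(!is.na(x$candidates$ms2_score))))
  if (!is.null(x$correlations))
    cat(sprintf("  coexpression: %d pairs, %d strong (r > %g)\n",
                nrow(x$correlations), sum(x$correlations$strong),
                x$meta$thresholds$strong_r))
  cat("  output dir:", x$out_dir, "\n")
  invisible(x)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Feature-by-sample TSV: first column is the feature id.
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1]]
  m
}
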