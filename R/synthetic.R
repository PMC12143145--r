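# Fixed flank consensus sequences for the generator. The leader is an
# artificial 13-mer (it must begin with Met so the planted CDS starts at
# ATG); the follower is the 14-residue heterophyllin B follower peptide,
# the one follower sequence with a published identity.
LEADER_CONSENSUS <- "MGVDKSELATFYR"
FOLLOWER_CONSENSUS <- "SQELINGDDISLMV"

#' Configuration for the synthetic data generator
#'
#' Bundles and validates every knob of the generator. The defaults are the
#' benchmark conditions used throughout the package's recovery tests: 20
#' planted precursors among 200 decoy transcripts, 5% flank mutation per
#' position, 2 ppm mass error, 20% MS2 fragment dropout, a 4-tissue x
#' 3-replicate expression layout and a planted gene-metabolite correlation
#' of 0.95.
#'
#' @param seed Mandatory integer master seed; every stochastic component
#'   derives its own stream from it, so outputs are byte-reproducible.
#' @param n_true Number of planted precursor transcripts (default 20).
#' @param n_decoy Number of decoy transcripts with no planted precursor
#'   (default 200).
#' @param flank_mutation_rate Per-position substitution probability applied
#'   to the leader/follower consensus in each planted precursor (default
#'   0.05). Position 1 of the leader (the initiator Met) is exempt.
#' @param core_len_range Planted core length range, inclusive (default
#'   `c(5, 16)`).
#' @param core_terminal Alphabet of the final core residue (default
#'   `c("P", "A")`).
#' @param ppm_sigma SD of the relative m/z error, in ppm, applied to MS1
#'   peaks and MS2 fragments (default 2).
#' @param ms2_dropout Probability that a predicted fragment is missing from
#'   a simulated MS2 spectrum (default 0.2).
#' @param n_noise_peaks Uniform background peaks added to the MS1 table
#'   (default 100).
#' @param n_noise_fragments Background fragments per MS2 spectrum
#'   (default 5).
#' @param tissues Tissue labels (default flower, leaf, stem, root).
#' @param replicates Replicates per tissue (default 3).
#' @param rho Planted Pearson correlation between true tailoring-gene
#'   expression and metabolite abundance (default 0.95).
#' @param n_tailoring Number of true tailoring genes (default 5).
#' @param n_decoy_genes Number of uncorrelated decoy genes (default 50).
#' @param n_metabolites Number of simulated metabolites (default 4,
#'   root-dominant like the measured orbitides).
#' @param n_references Reference precursors emitted for profile building
#'   (default 10).
#' @param utr_range Length range of the random UTR on each side of a
#'   planted CDS, in nt (default `c(60, 200)`).
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_true = 20L, n_decoy = 200L,
                       flank_mutation_rate = 0.05,
                       core_len_range = c(5L, 16L),
                       core_terminal = c("P", "A"),
                       ppm_sigma = 2, ms2_dropout = 0.2,
                       n_noise_peaks = 100L, n_noise_fragments = 5L,
                       tissues = c("flower", "leaf", "stem", "root"),
                       replicates = 3L, rho = 0.95,
                       n_tailoring = 5L, n_decoy_genes = 50L,
                       n_metabolites = 4L,
                       n_references = 10L,
                       utr_range = c(60L, 200L)) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("seed is mandatory: the generator refuses silent nondeterminism")
  seed <- as.integer(seed)
  if (flank_mutation_rate < 0 || flank_mutation_rate > 1)
    stop("flank_mutation_rate must lie in [0, 1]")
  if (ms2_dropout < 0 || ms2_dropout > 1)
    stop("ms2_dropout must lie in [0, 1]")
  if (ppm_sigma < 0) stop("ppm_sigma must be >= 0")
  if (rho < -1 || rho > 1) stop("rho must lie in [-1, 1]")
  if (length(tissues) * replicates < 3L)
    stop("at least 3 samples (tissues x replicates) are required")
  structure(list(
    seed = seed, n_true = as.integer(n_true), n_decoy = as.integer(n_decoy),
    flank_mutation_rate = flank_mutation_rate,
    core_len_range = as.integer(core_len_range),
    core_terminal = core_terminal,
    ppm_sigma = ppm_sigma, ms2_dropout = ms2_dropout,
    n_noise_peaks = as.integer(n_noise_peaks),
    n_noise_fragments = as.integer(n_noise_fragments),
    tissues = tissues, replicates = as.integer(replicates), rho = rho,
    n_tailoring = as.integer(n_tailoring),
    n_decoy_genes = as.integer(n_decoy_genes),
    n_metabolites = as.integer(n_metabolites),
    n_references = as.integer(n_references),
    utr_range = as.integer(utr_range)), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "Synthetic data config (seed %d): %d true + %d decoy transcripts,\n",
    x$seed, x$n_true, x$n_decoy))
  cat(sprintf(
    "  flank mutation %.3g, ppm sigma %.3g, MS2 dropout %.3g, %d x %d samples, rho %.3g\n",
    x$flank_mutation_rate, x$ppm_sigma, x$ms2_dropout,
    length(x$tissues), x$replicates, x$rho))
  invisible(x)
}

# Per-component RNG streams: adding one component does not perturb others.
sub_seed <- function(seed, component) {
  as.integer((as.double(seed) %% 65011L + 1) * 30011 + component * 7919) %% 2147483647L
}

mutate_flank <- function(seq, rate, keep_first = FALSE) {
  res <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- stats::runif(length(res)) < rate
  if (keep_first) hit[1] <- FALSE
  for (i in which(hit))
    res[i] <- sample(setdiff(AA_CODES, res[i]), 1L)
  paste(res, collapse = "")
}

random_core <- function(len_range, terminal) {
  len <- sample(len_range[1]:len_range[2], 1L)
  body <- sample(AA_CODES, len - 1L, replace = TRUE)
  paste(c(body, sample(terminal, 1L)), collapse = "")
}

# Reverse-translate a protein with uniformly random synonymous codons.
reverse_translate <- function(protein) {
  res <- strsplit(protein, "", fixed = TRUE)[[1]]
  codons <- vapply(res, function(a) sample(CODONS_BY_AA[[a]], 1L), character(1))
  paste(codons, collapse = "")
}

CODONS_BY_AA <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), as.character(gc))
})

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

#' Generate a synthetic transcriptome with planted orbitide precursors
#'
#' Each of the `n_true` transcripts embeds a complete precursor CDS -- ATG +
#' 13-residue leader (mutated consensus, Met kept) + core (random residues,
#' length 5-16, terminal Pro/Ala) + 14-residue follower + stop -- inside
#' random UTR sequence, on a randomly chosen strand (a 35-residue precursor
#' thus yields a 108 bp CDS span). Decoy transcripts are plain random
#' sequence with no planted segmentation. A set of reference precursor
#' proteins (same construction) is emitted for flank-profile building.
#'
#' @param cfg A [sim_config()].
#' @return List with `transcripts` (named character vector), `truth` (class
#'   `ground_truth`: data.frame `precursors` with transcript id, strand,
#'   CDS coordinates, segmentation and theoretical cyclic \[M+H\]+), and
#'   `references` (data.frame `id`, `protein`, `core_start`, `core_end`).
#' @export
generate_transcriptome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(sub_seed(cfg$seed, 1L))
  lk <- nchar(LEADER_CONSENSUS); fk <- nchar(FOLLOWER_CONSENSUS)
  precs <- vector("list", cfg$n_true)
  transcripts <- character(0)
  for (i in seq_len(cfg$n_true)) {
    leader <- mutate_flank(LEADER_CONSENSUS, cfg$flank_mutation_rate,
                           keep_first = TRUE)
    follower <- mutate_flank(FOLLOWER_CONSENSUS, cfg$flank_mutation_rate)
    core <- random_core(cfg$core_len_range, cfg$core_terminal)
    protein <- paste0(leader, core, follower)
    cds <- paste0(reverse_translate(protein),
                  sample(c("TAA", "TAG", "TGA"), 1L))
    u5 <- random_dna(sample(cfg$utr_range[1]:cfg$utr_range[2], 1L))
    u3 <- random_dna(sample(cfg$utr_range[1]:cfg$utr_range[2], 1L))
    full <- paste0(u5, cds, u3)
    a <- nchar(u5) + 1L; b <- nchar(u5) + nchar(cds)
    strand <- sample(c("+", "-"), 1L)
    if (strand == "-") {
      L <- nchar(full)
      full <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(full)))
      ab <- c(L - b + 1L, L - a + 1L); a <- ab[1]; b <- ab[2]
    }
    id <- sprintf("tx_true_%03d", i)
    transcripts[id] <- full
    precs[[i]] <- data.frame(
      id = sprintf("prec_%03d", i), transcript_id = id, strand = strand,
      cds_start = a, cds_end = b,
      leader = leader, core = core, follower = follower, protein = protein,
      theoretical_mz = ion_mz(peptide_mass(core, cyclic = TRUE), "M+H"),
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(cfg$n_decoy)) {
    id <- sprintf("tx_decoy_%03d", i)
    transcripts[id] <- random_dna(sample(250:450, 1L))
  }
  refs <- data.frame(
    id = sprintf("ref_%02d", seq_len(cfg$n_references)),
    protein = vapply(seq_len(cfg$n_references), function(i) {
      paste0(mutate_flank(LEADER_CONSENSUS, cfg$flank_mutation_rate, TRUE),
             random_core(cfg$core_len_range, cfg$core_terminal),
             mutate_flank(FOLLOWER_CONSENSUS, cfg$flank_mutation_rate))
    }, character(1)),
    stringsAsFactors = FALSE)
  refs$core_start <- lk + 1L
  refs$core_end <- nchar(refs$protein) - fk
  truth <- structure(list(precursors = do.call(rbind, precs),
                          config = cfg), class = "ground_truth")
  list(transcripts = transcripts, truth = truth, references = refs)
}

#' Write / read a ground-truth manifest (lossless JSON round trip)
#'
#' @param truth A `ground_truth` object from [generate_transcriptome()].
#' @param path JSON path.
#' @return `read_ground_truth()` returns the `ground_truth` object;
#'   `write_ground_truth()` returns `path` invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  cfg <- unclass(truth$config)
  jsonlite::write_json(
    list(precursors = truth$precursors, config = cfg),
    path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(sim_config, raw$config)
  structure(list(precursors = as.data.frame(raw$precursors),
                 config = cfg), class = "ground_truth")
}

#' Simulate an MS1 peak table from planted precursors
#'
#' One peak per planted core at `theoretical * (1 + eps)` with
#' `eps ~ Normal(0, ppm_sigma * 1e-6)`, log-normal intensities and uniform
#' retention times, plus uniform background peaks over the occupied m/z
#' range.
#'
#' @param truth `ground_truth` from [generate_transcriptome()].
#' @param cfg The matching [sim_config()] (defaults to the one stored in
#'   `truth`).
#' @return Data.frame `mz`, `intensity`, `rt`, `source` (precursor id or
#'   `"noise"`). Drop `source` before writing an instrument-style table.
#' @export
simulate_ms1 <- function(truth, cfg = truth$config) {
  stopifnot(inherits(truth, "ground_truth"))
  set.seed(sub_seed(cfg$seed, 2L))
  # peaks are planted on the 4-dp reporting grid of the theoretical m/z,
  # so at ppm_sigma = 0 the reported ppm error is exactly zero
  th <- round_mz(truth$precursors$theoretical_mz)
  n <- length(th)
  eps <- stats::rnorm(n, 0, cfg$ppm_sigma * 1e-6)
  planted <- data.frame(
    mz = th * (1 + eps),
    intensity = stats::rlnorm(n, log(1e6), 0.5),
    rt = stats::runif(n, 1, 20),
    source = truth$precursors$id, stringsAsFactors = FALSE)
  if (cfg$n_noise_peaks > 0L) {
    rng <- range(th) * c(0.9, 1.1)
    noise <- data.frame(
      mz = stats::runif(cfg$n_noise_peaks, rng[1], rng[2]),
      intensity = stats::rlnorm(cfg$n_noise_peaks, log(1e4), 1),
      rt = stats::runif(cfg$n_noise_peaks, 1, 20),
      source = "noise", stringsAsFactors = FALSE)
    planted <- rbind(planted, noise)
  }
  rownames(planted) <- NULL
  planted
}

#' Simulate MS2 spectra of the planted cores
#'
#' For each planted core the predicted ring-opened b-ions (coincident m/z
#' merged) are retained independently with probability `1 - ms2_dropout`,
#' jittered with the configured ppm error, and mixed with uniform noise
#' fragments. The precursor m/z of each spectrum is the simulated MS1 peak
#' of the same precursor. If every fragment drops out, a noise-only
#' spectrum is still emitted.
#'
#' @param truth `ground_truth` from [generate_transcriptome()].
#' @param cfg The matching [sim_config()].
#' @param ms1 MS1 table from [simulate_ms1()]; recomputed from the same
#'   seed when omitted.
#' @return List of spectra (`title` = precursor id, `precursor_mz`,
#'   `charge`, `fragments`), writable with [write_mgf()].
#' @export
simulate_ms2 <- function(truth, cfg = truth$config,
                         ms1 = simulate_ms1(truth, cfg)) {
  stopifnot(inherits(truth, "ground_truth"))
  set.seed(sub_seed(cfg$seed, 3L))
  prec <- truth$precursors
  spectra <- vector("list", nrow(prec))
  for (i in seq_len(nrow(prec))) {
    pred <- predict_ms2_fragments(prec$core[i])
    keep <- stats::runif(nrow(pred)) >= cfg$ms2_dropout
    mz <- pred$mz[keep]
    mz <- mz * (1 + stats::rnorm(length(mz), 0, cfg$ppm_sigma * 1e-6))
    inten <- stats::rlnorm(length(mz), log(1e5), 0.7)
    pmz <- ms1$mz[match(prec$id[i], ms1$source)]
    if (cfg$n_noise_fragments > 0L) {
      nmz <- stats::runif(cfg$n_noise_fragments, 50, pmz)
      mz <- c(mz, nmz)
      inten <- c(inten, stats::rlnorm(cfg$n_noise_fragments, log(1e3), 1))
    }
    ord <- order(mz)
    spectra[[i]] <- list(
      title = prec$id[i], precursor_mz = pmz, charge = 1L,
      fragments = data.frame(mz = mz[ord], intensity = inten[ord]))
  }
  spectra
}

# Expected sample correlation between a fixed (sample-standardized) vector
# u and u + c*z with z iid standard normal, over n samples. Writing z in
# terms of its in-sample regression on u (coefficient a ~ N(0, 1/(n-1)))
# and an orthogonal remainder (sum of squares ~ chi^2_{n-2}), the sample r
# is (1 + c a) / sqrt(1 + 2 c a + c^2 (a^2 + w/(n-1))) and its expectation
# is a smooth 2-D integral, exact for any fixed u.
expected_sample_r <- function(cc, n) {
  inner <- function(a) vapply(a, function(ai)
    stats::integrate(function(w) stats::dchisq(w, n - 2) *
      (1 + cc * ai) / sqrt(1 + 2 * cc * ai + cc^2 * (ai^2 + w / (n - 1))),
      0, Inf, rel.tol = 1e-9)$value, numeric(1))
  stats::integrate(function(a) stats::dnorm(a, 0, 1 / sqrt(n - 1)) * inner(a),
                   -Inf, Inf, rel.tol = 1e-8)$value
}

# Noise-to-signal SD ratio c such that the EXPECTED sample Pearson r of
# gene = base + c*sd(base)*noise equals the planted rho at this sample
# size. Solved once per (rho, n) and cached. The naive c = sqrt(1/rho^2-1)
# targets the population r instead and leaves a small-sample bias of the
# same order as the recovery tolerance.
calibrate_noise_factor <- function(rho, n) {
  if (rho >= 1) return(0)
  if (rho <= 0)
    stop("planted rho must be positive (tailoring genes track the metabolite)")
  key <- sprintf("noise_c_%.10g_%d", rho, n)
  hit <- .orbimine_cache[[key]]
  if (!is.null(hit)) return(hit)
  cc <- stats::uniroot(function(cc) expected_sample_r(cc, n) - rho,
                       c(1e-9, 1), extendInt = "downX", tol = 1e-9)$root
  .orbimine_cache[[key]] <- cc
  cc
}

#' Simulate tissue expression and metabolite tables with planted correlation
#'
#' Metabolites follow a root-dominant tissue profile (high root mean, low
#' elsewhere) with multiplicative replicate noise, mirroring measured
#' orbitide distributions. True tailoring genes are generated as affine
#' functions of their metabolite plus Normal noise whose SD is calibrated
#' (with a first-order small-sample bias correction) so the expected sample
#' Pearson r equals the planted `rho`. Decoy genes are independent
#' log-normal noise.
#'
#' @param truth `ground_truth` from [generate_transcriptome()].
#' @param cfg The matching [sim_config()].
#' @return List with `expression` (genes x samples), `metabolites`
#'   (metabolites x samples), `tissues` (named sample -> tissue vector) and
#'   `gene_truth` (data.frame `gene`, `role`, `rho`, `metabolite`).
#' @export
simulate_expression <- function(truth, cfg = truth$config) {
  stopifnot(inherits(truth, "ground_truth"))
  set.seed(sub_seed(cfg$seed, 4L))
  samples <- paste(rep(cfg$tissues, each = cfg$replicates),
                   rep(seq_len(cfg$replicates), length(cfg$tissues)),
                   sep = "_")
  tiss <- stats::setNames(rep(cfg$tissues, each = cfg$replicates), samples)
  ns <- length(samples)
  metab_ids <- sprintf("metab_%02d", seq_len(cfg$n_metabolites))
  metab <- matrix(0, cfg$n_metabolites, ns,
                  dimnames = list(metab_ids, samples))
  for (m in seq_len(cfg$n_metabolites)) {
    tissue_means <- stats::setNames(
      ifelse(cfg$tissues == "root", stats::runif(1, 20, 40),
             stats::runif(length(cfg$tissues), 1, 8)),
      cfg$tissues)
    means <- tissue_means[tiss]
    metab[m, ] <- pmax(means + stats::rnorm(ns, 0, 0.1 * means), 0)
  }
  genes <- list(); roles <- list()
  cc <- calibrate_noise_factor(cfg$rho, ns)
  for (g in seq_len(cfg$n_tailoring)) {
    m <- ((g - 1L) %% cfg$n_metabolites) + 1L
    slope <- stats::runif(1, 0.5, 2)
    base <- slope * metab[m, ]
    noise <- if (cc == 0 || stats::sd(base) == 0) rep(0, ns)
             else stats::rnorm(ns, 0, cc * stats::sd(base))
    id <- sprintf("gene_cyc_%02d", g)
    genes[[id]] <- 50 + base + noise
    roles[[id]] <- data.frame(gene = id, role = "cyclase-like",
                              rho = cfg$rho, metabolite = metab_ids[m],
                              stringsAsFactors = FALSE)
  }
  for (g in seq_len(cfg$n_decoy_genes)) {
    id <- sprintf("gene_decoy_%03d", g)
    genes[[id]] <- stats::rlnorm(ns, log(10), 1)
    roles[[id]] <- data.frame(gene = id, role = "decoy", rho = 0,
                              metabolite = NA_character_,
                              stringsAsFactors = FALSE)
  }
  expr <- do.call(rbind, genes)
  colnames(expr) <- samples
  list(expression = expr, metabolites = metab, tissues = tiss,
       gene_truth = do.call(rbind, unname(roles)))
}
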