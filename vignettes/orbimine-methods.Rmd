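---
title: "Methods: gene-guided orbitide discovery with orbimine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-guided orbitide discovery with orbimine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orbimine)
```

## The model

Orbitides are gene-encoded: a ribosomal precursor peptide carries a
conserved leader, a hypervariable core and a conserved follower, and a
serine-protease cyclase (a PCY1 homolog) excises the follower and ligates
the core head-to-tail. Two sequence rules characterize the family's cores:
they are 5–16 residues long, and the residue presented to the cyclase — the
last core residue — is always Pro or Ala. `orbimine` turns these
observations into a screening pipeline: find short ORFs, demand
profile-matching flanks and a rule-conforming core, predict the macrocycle's
mass, and corroborate with MS1/MS2 evidence and gene–metabolite
coexpression.

### Mass arithmetic

A head-to-tail macrocycle has mass equal to the plain sum of monoisotopic
residue masses; cyclization eliminates the water that linear peptides carry
as free termini:

$$M_\text{cyclic} = \sum_i m(r_i), \qquad
  M_\text{linear} = M_\text{cyclic} + 18.010565.$$

The residue table is pinned at 6 decimal places and ships as a plain-text
file (`inst/extdata/residue_masses.tsv`); 5-decimal tables drift visibly in
the 4th decimal of an 800+ Da peptide, so the extra digit is load-bearing.
Only singly charged \[M+H\]\+ / \[M−H\]\− species are modeled: orbitides in
this size range are observed at z = 1, and multiply charged or modified
species are out of scope.

Two reporting conventions matter for reproducing published numbers and are
implemented explicitly rather than left to chance:

* **Rounding** is half-up at the 4th decimal (`round_mz()`), not R's
  half-to-even.
* **ppm error** (`ppm_error()`) divides by the *4-dp-rounded* theoretical
  m/z and is reported as a magnitude. Recomputing published
  observed/theoretical pairs reproduces their printed ppm values only under
  this convention.

Numerically, `peptide_mass()` sums residues in sorted order, which makes the
mass of a cyclic sequence bit-identical under rotation — an equality the
dereplication logic relies on — instead of merely equal to within an ulp.

A cyclic sequence has no terminus, so rotations name the same molecule;
`canonical_rotation()` picks the lexicographically smallest rotation.
Reversals are *not* identified: the peptide backbone is directional.

### Precursor mining

`six_frame_orfs()` translates both strands in all three frames with the
standard genetic code and reports every ATG-to-stop ORF whose protein falls
in a length window (default 25–60 residues, bracketing the ~35-residue
precursors implied by ~108 bp CDSs). Codons containing N are treated as
untranslatable: a reading that hits one is dropped, never guessed. Nested
ATGs are all reported; coordinates are 1-based inclusive on the forward
strand and include the stop codon, so a 35-residue precursor spans exactly
3 × 36 = 108 nt.

Flank conservation is modeled as one position-weight matrix per flank
(`build_flank_profiles()`), with +1 pseudocounts against a uniform 0.05
background:

$$s_j(a) = \log_2 \frac{(c_{j,a} + 1)/(N + 20)}{0.05}.$$

References must yield equal-length leaders and followers — the generator
produces fixed-length flanks, and real reference sets are expected to be
pre-aligned upstream; building alignments from ragged real flanks is out of
scope. The acceptance threshold per flank is a fraction (default 0.6) of the
maximum attainable profile score. No biological constant dictates this
number, so it is explicit configuration with a documented default chosen to
tolerate a few substitutions per flank (at 5% per-position mutation over a
13-residue leader, the expected score loss is well below the 40% margin)
while rejecting random sequence, whose expected per-position score is
negative.

`scan_precursors()` slides the leader start and follower end up to
`max_slide` (default 2) residues from the protein termini, keeps
segmentations where both flank scores pass and the core obeys the two family
rules, and emits *all* acceptable segmentations ranked by flank score sum
(ties: longer core, then more N-terminal start). Multiple-testing control is
deliberately absent — score thresholds are the only filter, and the report
states them.

Similarity to known precursors is scored by an in-package Smith–Waterman
(Gotoh affine-gap) with BLOSUM62 and BLAST-default gap costs (open 11,
extend 1), so no external aligner binary is needed. The implementation is
verified in the test suite against an exhaustive dynamic-programming oracle
on every instance up to 8×8 and against an independent aligner
implementation.

### MS confirmation

Under CID a head-to-tail macrocycle ring-opens at each of its n amide
bonds; each linearization then yields an N-terminal acylium (b-ion) ladder.
With no free C-terminus there is no y-series; a-ions (b − CO, 27.994915 Da)
are optional and off by default. `predict_ms2_fragments()` emits all n
ladders; the full ladder of every opening telescopes to the cyclic
\[M+H\]\+, a structural identity the tests assert exactly. Predictions
within 10⁻⁴ Da are merged (proline-rich cores produce many coincident
ladder ions) with provenance retained.

`match_ms1()` reports every target–peak pair within the ppm tolerance
(default 5 ppm; observed orbitide errors on a high-resolution instrument run
~2 ppm, so the default leaves headroom without inviting noise), sorted by
ppm then intensity. `score_ms2()` scores the fraction of distinct predicted
m/z values hit by at least one observed fragment within tolerance (default
10 ppm); intensities are carried for reporting but never weight the score,
since no intensity model is defensible from first principles here.

### Coexpression ranking

`rank_candidates()` computes Pearson r between each gene and each
metabolite across samples, flags r > 0.90 (strong cyclase candidates) and
r > 0.50 (network edges) with strict inequalities, and records whether a
gene peaks in the same tissue as the metabolite (root-dominant for
orbitides). Whether the correlation should run over individual replicates
or tissue means is genuinely ambiguous in practice, so both are provided
(`level = "replicate"` is the default; `"tissue_mean"` is one switch away)
and neither is asserted as canonical. No p-values or multiple-testing
correction are attached: the ranking is by r alone, stated openly in the
outputs.

## The synthetic data generator

`sim_config()` + `generate_transcriptome()` / `simulate_ms1()` /
`simulate_ms2()` / `simulate_expression()` produce ground-truthed inputs
for every stage. Defaults are the package's benchmark conditions: 20
planted precursors among 200 decoys, 5% flank mutation per position, 2 ppm
mass error, 20% MS2 fragment dropout, 100 MS1 noise peaks, a 4-tissue ×
3-replicate layout and a planted gene–metabolite correlation of 0.95.

Choices worth knowing:

* The leader consensus (`MGVDKSELATFYR`) is an **artificial** string — no
  leader sequence is published for this family's best-studied precursor —
  while the follower consensus (`SQELINGDDISLMV`) is the published
  heterophyllin B follower. Position 1 of the leader is exempt from
  mutation so the planted CDS always starts with ATG.
* Planted CDSs use uniformly random synonymous codons, random TAA/TAG/TGA
  stops, random UTRs (60–200 nt per side) and a random strand. Decoys are
  plain random nucleotide sequence: the chance that a random ORF passes
  both flank profiles at threshold is negligible, and the recovery tests
  confirm zero decoy hits at benchmark settings.
* MS1 peaks are planted on the 4-dp reporting grid of the theoretical m/z
  before the relative error is applied, so zero configured noise yields
  exactly zero reported ppm. Noise peaks are uniform over the occupied m/z
  range — the simplest defensible null.
* Each spectrum's precursor m/z in `simulate_ms2()` is the MS1 peak of the
  same precursor, taken from (or recomputed identically to) the
  `simulate_ms1()` output.
* Expression noise for true tailoring genes is calibrated so that the
  **expected sample correlation** equals the planted ρ. Because the
  metabolite vector is fixed within a replicate, the usual bivariate-normal
  small-sample bias correction is wrong here (it has the opposite sign);
  instead the conditional expectation
  E[cor(u, u + c·z)] — a smooth two-dimensional integral over the
  regression coefficient of the noise on the signal (normal) and the
  orthogonal remainder (χ²) — is solved for c by root finding and cached
  per (ρ, n). At ρ = 0.95 and n = 12 the residual bias is ~4 × 10⁻⁵,
  negligible against the recovery test's 3-standard-error band.
* Random streams are per-component (transcriptome, MS1, MS2, expression),
  derived from the master seed, so adding one output does not perturb the
  others; identical config + seed gives byte-identical artifacts.

What the generator does **not** emulate: read-level RNA-seq, retention-time
structure, isotope envelopes, correlated instrument noise, multi-core
precursors (some species carry several cores per precursor; this family's
architecture is single-core), and homology structure among decoys. Passing
recovery tests therefore demonstrate the pipeline's logic and calibration,
not its performance on a real, messier transcriptome.

## Pipeline and reproducibility

`validate_config()` reads YAML/JSON, fills documented defaults, range-checks
every value and rejects unknown keys with a closest-match suggestion —
typos fail loudly instead of silently disabling an option.
`run_discovery()` checks every input path before any stage runs, logs to
stderr only, and writes intermediate TSVs plus a final report (TSV + JSON)
whose bytes are reproducible given config + inputs + seed; for that reason
the report metadata records the config hash, package version and seed but
no timestamps. Missing optional inputs (MS2, expression) leave their report
columns empty rather than failing.

Problem sizes used by the shipped tests — a 20 + 200 transcript benchmark,
500-peak error-calibration runs, 200-replicate correlation recovery — were
chosen as the smallest sets at which the stochastic assertions have
comfortable statistical margins; all run in seconds.

## Known limitations and open edges

* Two published ppm values for these compounds (0.4057 and 2.3071) are
  inconsistent with recomputation from their own printed m/z pairs (they
  recompute to 0.4507 and 2.0371, plausibly digit transpositions). The
  package reproduces the self-consistent values and deliberately does not
  "fix" the inconsistent ones; they are excluded from the verification
  suite.
* SRM quantifier transitions reported for heterophyllin B (m/z 203.035 and
  226.129) do not correspond to simple b/a ions of any canonical ring
  opening; their assignment (internal fragments or neutral losses) is not
  derivable from available information and is left unmodeled.
* Charge states above 1, PTMs, isotope envelopes and disulfide-bonded
  cyclotides are out of scope by design.
* The mining stage assumes single-core precursors with fixed-length,
  pre-aligned flanks; multi-core architectures would need a segmentation
  generalization.
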