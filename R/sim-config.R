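#' Configuration of the synthetic multi-omic study
#'
#' One validated object drives every generator, so that a single seed fixes
#' the whole synthetic dataset bit-for-bit. The defaults describe the study
#' conditions the generators emulate: 50 spiked true interactors at 16-fold
#' bait enrichment among 2,000 proteins quantified in 11 bait vs 13 control
#' IPs; three factor cistromes of 1,000 peaks on a two-chromosome 100 Mb toy
#' genome (kept sparse relative to the 50 kb gene-linking windows, as a real
#' genome is), 40% of A/B peaks planted at shared factor-C motif loci that
#' collapse fourfold in the C knockout at a mean depth of 50 reads per peak;
#' and 2,000 genes of which those adjacent to dependent co-bound sites are
#' co-upregulated twofold with probability 0.6 in both the A-knockout and
#' B-knockdown arms.
#'
#' @param seed Integer master seed.
#' @param n_proteins,n_true_interactors,n_dna_bridged Protein counts;
#'   `n_dna_bridged <= n_true_interactors <= n_proteins`.
#' @param interactor_effect Linear fold-enrichment of true interactors in
#'   bait over control IPs.
#' @param missingness_steepness,missingness_midpoint Logistic
#'   missing-not-at-random parameters on log2 intensity: P(missing) =
#'   plogis(-steepness * (log2 intensity - midpoint)).
#' @param n_bait_samples,n_control_samples IP sample counts per nuclease
#'   stratum.
#' @param genome Named numeric vector of chromosome lengths (bp).
#' @param n_peaks_per_factor,peak_width Peak counts and fixed width (bp).
#' @param frac_cobound Proportion of A/B peaks planted at shared C-motif
#'   loci.
#' @param dependency_effect Fold signal reduction of dependent peaks in the
#'   C knockout.
#' @param read_depth Mean ChIP reads per planted peak.
#' @param chip_library_size Mapped reads per ChIP library (sets the rpm
#'   scale).
#' @param n_genes Gene count.
#' @param coupling_pi Probability a gene adjacent to a dependent co-bound
#'   site is planted as co-upregulated.
#' @param de_effect Linear fold change of planted genes.
#' @param dispersion Negative-binomial dispersion of expression counts.
#' @param n_samples_expression Named vector of replicate counts per
#'   expression condition (`control_A`, `KO_A`, `control_B`, `KD_B`).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_proteins = 2000L,
                       n_true_interactors = 50L,
                       n_dna_bridged = 20L,
                       interactor_effect = 16,
                       missingness_steepness = 0.8,
                       missingness_midpoint = 24,
                       n_bait_samples = 11L,
                       n_control_samples = 13L,
                       genome = c(chr1 = 6e7, chr2 = 4e7),
                       n_peaks_per_factor = 1000L,
                       peak_width = 200L,
                       frac_cobound = 0.4,
                       dependency_effect = 4,
                       read_depth = 50,
                       chip_library_size = 1e7,
                       n_genes = 2000L,
                       coupling_pi = 0.6,
                       de_effect = 2,
                       dispersion = 0.05,
                       n_samples_expression = c(
                         control_A = 2L, KO_A = 3L,
                         control_B = 3L, KD_B = 3L
                       )) {
  cfg <- list(
    seed = {
      stop_if_not_scalar_number(seed, "seed")
      if (seed != as.integer(seed)) abort("`seed` must be an integer.")
      as.integer(seed)
    },
    n_proteins = stop_if_not_count(n_proteins, "n_proteins"),
    n_true_interactors = stop_if_not_count(n_true_interactors, "n_true_interactors"),
    n_dna_bridged = as.integer(n_dna_bridged),
    interactor_effect = stop_if_not_scalar_number(interactor_effect, "interactor_effect", positive = TRUE),
    missingness_steepness = stop_if_not_scalar_number(missingness_steepness, "missingness_steepness"),
    missingness_midpoint = stop_if_not_scalar_number(missingness_midpoint, "missingness_midpoint"),
    n_bait_samples = stop_if_not_count(n_bait_samples, "n_bait_samples"),
    n_control_samples = stop_if_not_count(n_control_samples, "n_control_samples"),
    genome = genome,
    n_peaks_per_factor = stop_if_not_count(n_peaks_per_factor, "n_peaks_per_factor"),
    peak_width = stop_if_not_count(peak_width, "peak_width"),
    frac_cobound = stop_if_not_proportion(frac_cobound, "frac_cobound"),
    dependency_effect = stop_if_not_scalar_number(dependency_effect, "dependency_effect", positive = TRUE),
    read_depth = stop_if_not_scalar_number(read_depth, "read_depth", positive = TRUE),
    chip_library_size = stop_if_not_scalar_number(chip_library_size, "chip_library_size", positive = TRUE),
    n_genes = stop_if_not_count(n_genes, "n_genes"),
    coupling_pi = stop_if_not_proportion(coupling_pi, "coupling_pi"),
    de_effect = stop_if_not_scalar_number(de_effect, "de_effect", positive = TRUE),
    dispersion = stop_if_not_scalar_number(dispersion, "dispersion", positive = TRUE),
    n_samples_expression = n_samples_expression
  )
  if (cfg$n_dna_bridged < 0) abort("`n_dna_bridged` must be >= 0.")
  if (cfg$n_true_interactors > cfg$n_proteins) {
    abort("`n_true_interactors` must be <= `n_proteins`.")
  }
  if (cfg$n_dna_bridged > cfg$n_true_interactors) {
    abort("`n_dna_bridged` must be <= `n_true_interactors`.")
  }
  if (is.null(names(genome)) || any(!nzchar(names(genome))) || any(genome <= 0)) {
    abort("`genome` must be a named vector of positive chromosome lengths.")
  }
  needed <- c("control_A", "KO_A", "control_B", "KD_B")
  if (!all(needed %in% names(n_samples_expression)) ||
    any(n_samples_expression[needed] < 2)) {
    abort("`n_samples_expression` needs >= 2 replicates for each of control_A, KO_A, control_B, KD_B.")
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<sim_config> seed %d\n",
      "  proteomics: %d proteins, %d interactors (%d DNA-bridged) at %gx, %d bait vs %d control\n",
      "  cistromes:  %d peaks/factor (width %d) on %s; frac_cobound %.2f, KO collapse %gx, depth %g\n",
      "  expression: %d genes, coupling_pi %.2f, effect %gx, dispersion %g\n"
    ),
    x$seed, x$n_proteins, x$n_true_interactors, x$n_dna_bridged,
    x$interactor_effect, x$n_bait_samples, x$n_control_samples,
    x$n_peaks_per_factor, x$peak_width,
    paste(sprintf("%s:%g", names(x$genome), x$genome), collapse = ","),
    x$frac_cobound, x$dependency_effect, x$read_depth,
    x$n_genes, x$coupling_pi, x$de_effect, x$dispersion
  ))
  invisible(x)
}
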