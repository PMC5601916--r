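# Small programmatic fixtures shared across test files.

tiny_quant <- function(values, conditions, nuclease = "none", stage = "imputed") {
  samples <- tibble::tibble(
    sample_id = colnames(values),
    condition = conditions,
    nuclease = nuclease
  )
  protein_quant(values, samples, stage = stage)
}

rand_cistrome <- function(n, seed = 1, chroms = c("chr1", "chr2"),
                          chrom_len = 1e6, width_range = c(100, 500),
                          library_size = 1e6, factor_name = "X",
                          condition = "control") {
  withr::with_seed(seed, {
    w <- sample(width_range[1]:width_range[2], n, replace = TRUE)
    start <- sample.int(chrom_len - max(w), n, replace = TRUE)
    cistrome(
      tibble::tibble(
        peak_id = sprintf("%s%04d", factor_name, seq_len(n)),
        chrom = sample(chroms, n, replace = TRUE),
        start = start, end = start + w,
        reads = rpois(n, 40), input_reads = rpois(n, 5)
      ),
      factor_name = factor_name, condition = condition,
      library_size = library_size
    )
  })
}

rand_genes <- function(n, seed = 1, chroms = c("chr1", "chr2"), chrom_len = 1e6) {
  withr::with_seed(seed, {
    len <- sample(1000:20000, n, replace = TRUE)
    start <- sample.int(chrom_len - max(len), n, replace = TRUE)
    tibble::tibble(
      gene_id = sprintf("G%04d", seq_len(n)),
      chrom = sample(chroms, n, replace = TRUE),
      start = start, end = start + len,
      strand = sample(c("+", "-"), n, replace = TRUE)
    )
  })
}

small_sim_config <- function(seed = 1, ...) {
  args <- list(
    seed = seed,
    n_proteins = 80, n_true_interactors = 8, n_dna_bridged = 3,
    n_bait_samples = 4, n_control_samples = 4,
    genome = c(chr1 = 1.2e7, chr2 = 8e6),
    n_peaks_per_factor = 120, n_genes = 300
  )
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

rand_dna <- function(n, seed = 1) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = ""))
}
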