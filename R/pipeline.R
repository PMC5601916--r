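#' Default pipeline configuration
#'
#' Every printed analysis threshold is a named key: the 10-fold / P 0.01
#' interactor gate, the eightfold Benzonase retention cutoff, imputation
#' width 0.25 / downshift 2.0, the 2 / 1.5 rpm and threefold-over-input peak
#' filters, 50% reciprocal overlap with 1 rpm cross-factor signal, the
#' twofold knockout-dependency cutoff, 200 bp motif windows, the 1.7-fold /
#' P 0.05 expression gate, and the 100 kb nearest-gene and -50 kb TSS /
#' TES +2 kb linking windows. Synthetic-generator keys mirror
#' [sim_config()].
#'
#' @param seed Master seed recorded in the config.
#' @return Nested named list understood by [run_all()].
#' @export
default_run_config <- function(seed = 1L) {
  sc <- sim_config(seed = seed)
  list(
    seed = as.integer(seed),
    synthetic = sc[setdiff(names(sc), "seed")],
    interactome = list(
      fold_cutoff = 10, p_cutoff = 0.01, retain_fold = 8,
      impute_width = 0.25, impute_downshift = 2.0,
      digest_min_len = 6L, digest_max_len = 30L
    ),
    cistrome = list(
      min_rpm_a = 2, min_rpm_b = 1.5, min_rpm_c = 2, input_fold = 3,
      min_frac = 0.5, min_other_rpm = 1,
      dependency_fold = 2, pseudocount = 0.1, ko_artifact_ratio = 0.5
    ),
    motifs = list(window_width = 200L, threshold_frac = 0.8),
    expression = list(fold_cutoff = 1.7, p_cutoff = 0.05),
    integration = list(
      upstream = 50000, downstream = 2000, max_dist = 100000,
      include_anti_correlated = FALSE
    )
  )
}

#' Read and validate a YAML pipeline configuration
#'
#' Unknown keys are rejected by name; missing keys fall back to
#' [default_run_config()] values.
#'
#' @param path Path to a YAML file (or a pre-parsed list).
#' @return Validated config list.
#' @export
read_run_config <- function(path) {
  user <- if (is.character(path)) yaml::read_yaml(path) else path
  if (!is.list(user)) abort("config must be a YAML mapping.")
  defaults <- default_run_config(seed = user$seed %||% 1L)
  merge_section <- function(def, usr, where) {
    unknown <- setdiff(names(usr), names(def))
    if (length(unknown)) {
      abort(sprintf(
        "unknown config field(s) %s in '%s'.",
        paste(unknown, collapse = ", "), where
      ))
    }
    for (k in names(usr)) {
      if (is.list(def[[k]]) && !is.list(usr[[k]]) && !(k %in% c("genome", "n_samples_expression"))) {
        abort(sprintf("config field '%s.%s' must be a mapping.", where, k))
      }
      def[[k]] <- if (is.list(def[[k]]) && is.list(usr[[k]]) &&
        !k %in% c("genome", "n_samples_expression")) {
        merge_section(def[[k]], usr[[k]], paste0(where, ".", k))
      } else if (k %in% c("genome", "n_samples_expression")) {
        unlist(usr[[k]])
      } else {
        usr[[k]]
      }
    }
    def
  }
  cfg <- merge_section(defaults, user, "config")
  # re-validate the synthetic block through the constructor
  do.call(sim_config, c(list(seed = cfg$seed), cfg$synthetic))
  cfg
}

config_sim <- function(cfg) {
  do.call(sim_config, c(list(seed = cfg$seed), cfg$synthetic))
}

require_inputs <- function(out_dir, files, produced_by) {
  missing <- files[!file.exists(file.path(out_dir, files))]
  if (length(missing)) {
    abort(sprintf(
      "missing upstream output(s) %s: run stage '%s' first.",
      paste(missing, collapse = ", "), produced_by
    ))
  }
}

PIPELINE_STAGES <- c(
  "simulate", "interactome", "cistrome", "motifs", "expression", "integrate"
)

#' Run the full analysis pipeline
#'
#' Executes simulate, interactome, cistrome, motifs, expression and
#' integrate in order. Every stage reads its inputs from files in `out_dir`
#' written by earlier stages and writes its own outputs there, so deleting
#' and re-running a downstream subset reproduces identical files. A
#' manifest (config snapshot, seed, per-stage output checksums, package
#' version) is returned and written as `manifest.json`; rerunning with the
#' same config yields a byte-identical manifest.
#'
#' @param config A config list, a YAML path, or `NULL` for
#'   [default_run_config()].
#' @param out_dir Output directory (created if needed).
#' @param stages Subset of stages to run, in pipeline order.
#' @param quiet Suppress per-stage progress messages.
#' @return The manifest, invisibly.
#' @export
run_all <- function(config = NULL, out_dir = "corepressmap_run",
                    stages = PIPELINE_STAGES, quiet = FALSE) {
  cfg <- if (is.null(config)) default_run_config() else read_run_config(config)
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  runners <- list(
    simulate = stage_simulate, interactome = stage_interactome,
    cistrome = stage_cistrome, motifs = stage_motifs,
    expression = stage_expression, integrate = stage_integrate
  )
  manifest_stages <- list()
  for (st in PIPELINE_STAGES[PIPELINE_STAGES %in% stages]) {
    t0 <- Sys.time()
    outputs <- runners[[st]](cfg, out_dir)
    dt <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    if (!quiet) {
      message(sprintf("[corepressmap] stage %-11s %6.1fs  (%d files)", st, dt, length(outputs)))
    }
    hashes <- as.list(tools::md5sum(file.path(out_dir, outputs)))
    names(hashes) <- outputs
    manifest_stages[[st]] <- list(name = st, outputs = hashes)
  }

  manifest <- list(
    package = "corepressmap",
    version = as.character(packageVersion("corepressmap")),
    seed = cfg$seed,
    config = cfg,
    stages = unname(manifest_stages)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(manifest)
}

stage_simulate <- function(cfg, out_dir) {
  sc <- config_sim(cfg)
  sim <- simulate_all(sc, emit_sequence = TRUE)
  seed_comment <- sprintf("seed: %d", sc$seed)

  write_peptides_tsv(sim$proteomics$peptides, file.path(out_dir, "peptides.tsv"), seed_comment)
  write_fasta(sim$proteomics$proteins, file.path(out_dir, "proteins.fasta"), type = "AA")
  write_fasta(sim$cistromes$genome_seq, file.path(out_dir, "genome.fasta"), type = "DNA")

  files <- c("peptides.tsv", "proteins.fasta", "genome.fasta")
  for (nm in names(sim$cistromes$cistromes)) {
    cis <- sim$cistromes$cistromes[[nm]]
    bed <- sprintf("peaks_%s.bed", nm)
    sig <- sprintf("signal_%s.tsv", nm)
    write_bed(cis, file.path(out_dir, bed))
    write_signal_tsv(cis, file.path(out_dir, sig), seed_comment)
    files <- c(files, bed, sig)
  }
  write_jaspar(builtin_pwms(), file.path(out_dir, "pwms.jaspar"))
  write_gene_models(sim$gene_models, file.path(out_dir, "genes.tsv"), seed_comment)
  write_counts_tsv(sim$expression$counts, file.path(out_dir, "counts.tsv"), seed_comment)
  readr::write_tsv(sim$expression$samples, file.path(out_dir, "samples.tsv"))
  jsonlite::write_json(
    list(
      true_interactors = sim$truth$true_interactors,
      dna_bridged = sim$truth$dna_bridged,
      dependent_peaks = sim$truth$dependent_peaks,
      cobound_pairs = sim$truth$cobound_pairs,
      coregulated_genes = sim$truth$coregulated_genes,
      linked_genes = sim$truth$linked_genes
    ),
    file.path(out_dir, "truth.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  c(files, "pwms.jaspar", "genes.tsv", "counts.tsv", "samples.tsv", "truth.json")
}

stage_interactome <- function(cfg, out_dir) {
  require_inputs(out_dir, c("peptides.tsv", "proteins.fasta"), "simulate")
  p <- cfg$interactome
  peptides <- read_peptides_tsv(file.path(out_dir, "peptides.tsv"))
  proteins <- read_fasta(file.path(out_dir, "proteins.fasta"), type = "AA")
  digests <- theoretical_peptide_counts(proteins, p$digest_min_len, p$digest_max_len)

  quant <- compute_ibaq(peptides, digests) %>%
    log2_median_normalize() %>%
    impute_missing(
      width = p$impute_width, downshift = p$impute_downshift,
      seed = cfg$seed
    )
  untreated <- test_enrichment(quant, "none") %>%
    call_interactors(p$fold_cutoff, p$p_cutoff)
  benzonase <- test_enrichment(quant, "benzonase")
  mnase <- test_enrichment(quant, "mnase")
  classes <- classify_nuclease_sensitivity(
    untreated, benzonase, mnase,
    retain_fold = p$retain_fold, fold_cutoff = p$fold_cutoff
  )

  out <- untreated %>%
    left_join(digests, by = "protein_id") %>%
    left_join(select(classes, "protein_id", "nuclease_class"), by = "protein_id") %>%
    mutate(nuclease_class = tidyr::replace_na(.data$nuclease_class, "not_interactor")) %>%
    select(
      "protein_id",
      n_peptides = "n_theoretical", "log2_enrichment",
      "p_value", "adj_p", "is_interactor", "nuclease_class"
    )
  readr::write_tsv(out, file.path(out_dir, "interactome.tsv"))
  readr::write_tsv(
    tibble(
      protein_id = untreated$protein_id,
      log2_enrichment = untreated$log2_enrichment,
      neg_log10_p = -log10(untreated$p_value)
    ),
    file.path(out_dir, "volcano.tsv")
  )
  c("interactome.tsv", "volcano.tsv")
}

read_run_cistrome <- function(out_dir, name, factor_name, condition, genome) {
  read_cistrome(
    file.path(out_dir, sprintf("peaks_%s.bed", name)),
    file.path(out_dir, sprintf("signal_%s.tsv", name)),
    factor_name = factor_name, condition = condition, genome = genome
  )
}

stage_cistrome <- function(cfg, out_dir) {
  p <- cfg$cistrome
  genome <- config_sim(cfg)$genome
  need <- as.vector(t(outer(
    c("A_control", "A_ko_c", "B_control", "B_ko_c", "C_control", "C_ko_c"),
    c("peaks_%s.bed", "signal_%s.tsv"),
    function(n, f) sprintf(f, n)
  )))
  require_inputs(out_dir, need, "simulate")

  cis <- list(
    A_control = read_run_cistrome(out_dir, "A_control", "A", "control", genome),
    A_ko_c = read_run_cistrome(out_dir, "A_ko_c", "A", "ko_c", genome),
    B_control = read_run_cistrome(out_dir, "B_control", "B", "control", genome),
    B_ko_c = read_run_cistrome(out_dir, "B_ko_c", "B", "ko_c", genome),
    C_control = read_run_cistrome(out_dir, "C_control", "C", "control", genome),
    C_ko_c = read_run_cistrome(out_dir, "C_ko_c", "C", "ko_c", genome)
  )

  a_filt <- filter_peaks(cis$A_control, p$min_rpm_a, p$input_fold)
  b_filt <- filter_peaks(cis$B_control, p$min_rpm_b, p$input_fold)
  part <- overlap_cistromes(a_filt, b_filt, p$min_frac, p$min_other_rpm)

  c_filt <- filter_peaks(cis$C_control, p$min_rpm_c, p$input_fold) %>%
    filter_ko_artifacts(cis$C_ko_c, p$ko_artifact_ratio)
  triple <- triple_intersection(part, c_filt, p$min_frac)

  dep <- bind_rows(
    classify_dependency(
      a_filt, cistrome_subset(cis$A_ko_c, a_filt$peak_id),
      p$dependency_fold, p$pseudocount
    ) %>%
      mutate(factor = "A", class = part$a$class[match(.data$peak_id, part$a$peak_id)]),
    classify_dependency(
      b_filt, cistrome_subset(cis$B_ko_c, b_filt$peak_id),
      p$dependency_fold, p$pseudocount
    ) %>%
      mutate(factor = "B", class = part$b$class[match(.data$peak_id, part$b$peak_id)])
  )

  correlation <- correlate_cistromes(a_filt, b_filt)

  write_bed(part$a, file.path(out_dir, "partition_A.bed"), name_col = "class")
  write_bed(part$b, file.path(out_dir, "partition_B.bed"), name_col = "class")
  readr::write_tsv(dep, file.path(out_dir, "dependency.tsv"))
  jsonlite::write_json(
    list(
      venn = as.list(venn_counts(part)),
      convention = "co_bound counted once per A-side peak",
      triple_fractions = triple$fractions,
      triple_tests = triple$tests,
      correlation_a_b = correlation
    ),
    file.path(out_dir, "venn.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  c("partition_A.bed", "partition_B.bed", "dependency.tsv", "venn.json")
}

stage_motifs <- function(cfg, out_dir) {
  require_inputs(out_dir, c("genome.fasta", "pwms.jaspar"), "simulate")
  require_inputs(out_dir, c("partition_A.bed", "partition_B.bed"), "cistrome")
  p <- cfg$motifs
  genome_seq <- read_fasta(file.path(out_dir, "genome.fasta"), type = "DNA")
  pwms <- read_jaspar(file.path(out_dir, "pwms.jaspar"), threshold_frac = p$threshold_frac)

  part_a <- read_bed(file.path(out_dir, "partition_A.bed"))
  part_b <- read_bed(file.path(out_dir, "partition_B.bed"))
  classes <- list(
    co_bound = filter(part_a, .data$name == "co_bound"),
    a_only = filter(part_a, .data$name == "a_only"),
    b_only = filter(part_b, .data$name == "b_only")
  )
  classes <- purrr::map(classes, ~ mutate(.x, peak_id = sprintf("pk%05d", row_number())))

  freq <- purrr::map_dfr(names(classes), function(cl) {
    purrr::map_dfr(pwms, function(pw) {
      motif_frequency(classes[[cl]], genome_seq, pw, p$window_width) %>%
        mutate(class = cl, .before = 1)
    })
  })
  cmp <- purrr::map_dfr(c("a_only", "b_only"), function(other) {
    purrr::map_dfr(pwms, function(pw) {
      fa <- filter(freq, .data$class == "co_bound", .data$pwm == pw$name)
      fb <- filter(freq, .data$class == other, .data$pwm == pw$name)
      motif_count_test(fa$hits, fa$n, fb$hits, fb$n,
        pwm_name = pw$name, labels = c("co_bound", other)
      )
    })
  })
  readr::write_tsv(freq, file.path(out_dir, "motif_freq.tsv"))
  readr::write_tsv(
    select(cmp, "class_a", "class_b", "pwm", "fraction_a", "fraction_b",
      chi2 = "chi2", p = "p_value", "method"
    ),
    file.path(out_dir, "motif_compare.tsv")
  )
  c("motif_freq.tsv", "motif_compare.tsv")
}

stage_expression <- function(cfg, out_dir) {
  require_inputs(out_dir, c("counts.tsv", "samples.tsv"), "simulate")
  p <- cfg$expression
  counts <- read_counts_tsv(file.path(out_dir, "counts.tsv"))
  samples <- readr::read_tsv(file.path(out_dir, "samples.tsv"), show_col_types = FALSE)

  de_a <- de_test(counts, samples, "KO_A", "control_A", p$fold_cutoff, p$p_cutoff)
  de_b <- de_test(counts, samples, "KD_B", "control_B", p$fold_cutoff, p$p_cutoff)
  coreg <- call_coregulation(de_a, de_b)

  readr::write_tsv(as_tibble(de_a), file.path(out_dir, "de_A.tsv"))
  readr::write_tsv(as_tibble(de_b), file.path(out_dir, "de_B.tsv"))
  readr::write_tsv(
    coreg$genes %>% rename(dirA = "direction_a", dirB = "direction_b"),
    file.path(out_dir, "coregulation.tsv")
  )
  c("de_A.tsv", "de_B.tsv", "coregulation.tsv")
}

stage_integrate <- function(cfg, out_dir) {
  require_inputs(out_dir, "genes.tsv", "simulate")
  require_inputs(out_dir, "dependency.tsv", "cistrome")
  require_inputs(out_dir, c("de_A.tsv", "de_B.tsv", "coregulation.tsv"), "expression")
  p <- cfg$integration

  genes <- read_gene_models(file.path(out_dir, "genes.tsv"))
  dep <- readr::read_tsv(file.path(out_dir, "dependency.tsv"), show_col_types = FALSE)
  de_a <- readr::read_tsv(file.path(out_dir, "de_A.tsv"), show_col_types = FALSE)
  de_b <- readr::read_tsv(file.path(out_dir, "de_B.tsv"), show_col_types = FALSE)
  coreg_genes <- readr::read_tsv(file.path(out_dir, "coregulation.tsv"), show_col_types = FALSE)

  dependent_cobound <- dep %>%
    filter(.data$status == "lost", .data$class == "co_bound")
  links <- assign_gene_window(dependent_cobound, genes, p$upstream, p$downstream)
  readr::write_tsv(links, file.path(out_dir, "links.tsv"))

  universe <- build_association_universe(
    de_a, de_b, coreg_genes, links,
    include_anti_correlated = p$include_anti_correlated
  )
  assoc <- association_test(universe)
  jsonlite::write_json(
    list(
      table = as.data.frame(assoc$table),
      chi2 = assoc$statistic, df = assoc$df, p = assoc$p_value,
      n_universe = nrow(universe)
    ),
    file.path(out_dir, "association.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  c("links.tsv", "association.json")
}

#' Build the gene universe for the association test
#'
#' The universe is coregulated genes (correlated class; anti-correlated
#' optionally included) plus unchanged genes -- genes failing the
#' differential-expression gate in *both* perturbations. Genes passing in
#' only one arm are ambiguous and excluded. Each gene is flagged for
#' carrying at least one link to a dependent co-bound peak.
#'
#' @param de_a,de_b `de_results` tibbles (or data frames with `gene_id`,
#'   `passes`).
#' @param coregulation Data frame with `gene_id` and `class` (from
#'   [call_coregulation()]'s `genes`, or `coregulation.tsv`), or a
#'   `coregulation_result`.
#' @param links Peak-to-gene links of dependent co-bound peaks (column
#'   `gene_id`).
#' @param include_anti_correlated Count anti-correlated genes as
#'   coregulated (default `FALSE`).
#' @return Tibble with `gene_id`, `has_dependent_link`, `coregulated`.
#' @export
build_association_universe <- function(de_a, de_b, coregulation, links,
                                       include_anti_correlated = FALSE) {
  if (inherits(coregulation, "coregulation_result")) coregulation <- coregulation$genes
  require_columns(de_a, c("gene_id", "passes"), "de_a")
  require_columns(de_b, c("gene_id", "passes"), "de_b")
  require_columns(coregulation, c("gene_id", "class"), "coregulation")
  keep_classes <- if (include_anti_correlated) {
    c("correlated", "anti_correlated")
  } else {
    "correlated"
  }
  coreg_ids <- coregulation$gene_id[coregulation$class %in% keep_classes]
  pass_b <- de_b$passes[match(de_a$gene_id, de_b$gene_id)]
  unchanged <- de_a$gene_id[!de_a$passes & !pass_b]
  tibble(gene_id = c(coreg_ids, unchanged)) %>%
    mutate(
      coregulated = .data$gene_id %in% coreg_ids,
      has_dependent_link = .data$gene_id %in% unique(links$gene_id)
    ) %>%
    select("gene_id", "has_dependent_link", "coregulated")
}
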