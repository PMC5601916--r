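# Synthetic-data generators. Every generator is a pure function of a
# sim_config: the master seed plus a fixed per-stage offset drives all
# randomness, so identical configs give bit-identical outputs and the three
# generators can be called independently or together (simulate_all).

#' Simulate a cross-linked ChIP-MS experiment at the peptide level
#'
#' Emulates a bait-versus-control IP design: protein sequences are drawn and
#' digested in silico, peptide log2 intensities follow a protein-level
#' log-normal model with peptide and sample noise, true interactors carry a
#' linear `interactor_effect` in the bait arm, and DNA-bridged interactors
#' lose that effect in the Benzonase stratum (the nuclease destroys the DNA
#' that bridges them to the bait). Missingness is missing-not-at-random:
#' each observation is dropped with probability
#' `plogis(-steepness * (log2 intensity - midpoint))`, so low-abundance
#' peptides vanish preferentially -- the regime downshifted-Gaussian
#' imputation presumes. Each nuclease stratum (`none`, `mnase`,
#' `benzonase`) gets its own bait and control samples.
#'
#' @param config A [sim_config].
#' @return List with `peptides` (long tibble: protein_id, peptide,
#'   sample_id, condition, nuclease, intensity with `NA` = missing),
#'   `proteins` (named character vector of sequences), `samples`, and
#'   `truth` (list with `true_interactors`, `dna_bridged`).
#' @export
simulate_proteomics <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_stage_seed(config$seed, 101, {
    n <- config$n_proteins
    prot_ids <- sprintf("P%04d", seq_len(n))

    # sequences long enough to yield >= 3 observable tryptic peptides
    seqs <- character(n)
    digests <- vector("list", n)
    for (i in seq_len(n)) {
      repeat {
        s <- paste(sample(AMINO_ACIDS, sample(150:400, 1L), replace = TRUE),
          collapse = ""
        )
        d <- digest_protein(s)
        if (length(d) >= 3L) break
      }
      seqs[i] <- s
      digests[[i]] <- d
    }
    names(seqs) <- prot_ids

    true_interactors <- sort(sample(prot_ids, config$n_true_interactors))
    dna_bridged <- sort(sample(true_interactors, config$n_dna_bridged))

    strata <- c("none", "mnase", "benzonase")
    samples <- purrr::map_dfr(strata, function(nuc) {
      tibble(
        sample_id = c(
          sprintf("bait_%s_%02d", nuc, seq_len(config$n_bait_samples)),
          sprintf("ctrl_%s_%02d", nuc, seq_len(config$n_control_samples))
        ),
        condition = rep(c("bait", "control"), c(config$n_bait_samples, config$n_control_samples)),
        nuclease = nuc
      )
    })
    ns <- nrow(samples)

    n_pep <- lengths(digests)
    pep_protein <- rep(seq_len(n), n_pep)
    total_pep <- sum(n_pep)

    base_log2 <- rnorm(n, mean = 27, sd = 2) # protein abundance
    pep_offset <- rnorm(total_pep, mean = 0, sd = 1) # ionisation efficiency

    is_interactor <- prot_ids %in% true_interactors
    is_bridged <- prot_ids %in% dna_bridged
    # per protein x sample log2 effect
    effect <- matrix(0, n, ns)
    bait_col <- samples$condition == "bait"
    benzo_col <- samples$nuclease == "benzonase"
    effect[is_interactor, bait_col] <- log2(config$interactor_effect)
    effect[is_bridged, bait_col & benzo_col] <- 0 # bridge destroyed

    log2int <- base_log2[pep_protein] + pep_offset +
      effect[pep_protein, , drop = FALSE] +
      matrix(rnorm(total_pep * ns, sd = 0.5), total_pep, ns)

    p_miss <- stats::plogis(-config$missingness_steepness *
      (log2int - config$missingness_midpoint))
    missing <- matrix(runif(total_pep * ns), total_pep, ns) < p_miss
    intensity <- 2^log2int
    intensity[missing] <- NA_real_

    peptides <- tibble(
      protein_id = rep(prot_ids[pep_protein], ns),
      peptide = rep(unlist(digests), ns),
      sample_id = rep(samples$sample_id, each = total_pep),
      condition = rep(samples$condition, each = total_pep),
      nuclease = rep(samples$nuclease, each = total_pep),
      intensity = as.vector(intensity)
    )

    list(
      peptides = peptides,
      proteins = seqs,
      samples = samples,
      truth = list(true_interactors = true_interactors, dna_bridged = dna_bridged)
    )
  })
}

#' Simulate three factor cistromes on a toy genome
#'
#' Plants non-overlapping loci on the configured genome: factor-C motif loci
#' (a DR1-type direct repeat at the locus centre) all carry a C peak, and a
#' `frac_cobound` subset additionally nucleates co-bound A and B peaks
#' (jittered so pairwise overlap stays above 50%); remaining A peaks sit at
#' DR2-type motif loci, remaining B peaks at motif-free loci. In the C
#' knockout, C peaks collapse to background and the co-bound A/B peaks --
#' the dependent set -- lose signal by `dependency_effect`; all read counts
#' are Poisson around their expected signal, with matched Poisson input.
#'
#' @param config A [sim_config].
#' @param emit_sequence Generate the genome sequence with planted motifs
#'   (default `TRUE`; skip for speed when no motif scanning is needed).
#' @return List with `cistromes` (named list of [cistrome]s:
#'   `A_control`, `A_ko_c`, `B_control`, `B_ko_c`, `C_control`, `C_ko_c`),
#'   `genome_seq` (named character or `NULL`), `loci` (tibble of planted
#'   loci), and `truth` (list with `dependent_peaks`, `cobound_pairs`).
#' @export
simulate_cistromes <- function(config, emit_sequence = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  with_stage_seed(config$seed, 202, {
    w <- config$peak_width
    n_pk <- config$n_peaks_per_factor
    n_cobound <- round(config$frac_cobound * n_pk)
    n_a_only <- n_pk - n_cobound
    n_b_only <- n_pk - n_cobound
    n_loci <- n_pk + n_a_only + n_b_only

    slot_size <- max(4L * w, 1000L)
    slots <- purrr::map_dfr(names(config$genome), function(ch) {
      k <- floor(config$genome[[ch]] / slot_size)
      if (k < 1) {
        return(tibble())
      }
      tibble(chrom = ch, slot_start = (seq_len(k) - 1L) * slot_size)
    })
    if (nrow(slots) < n_loci) {
      abort(sprintf(
        "genome too small to place %d loci without overlap (room for %d).",
        n_loci, nrow(slots)
      ))
    }
    picked <- slots[sample(nrow(slots), n_loci), ]
    jitter <- sample(-(w %/% 2):(w %/% 2), n_loci, replace = TRUE)
    centers <- picked$slot_start + slot_size %/% 2L + jitter
    type <- rep(c("cobound", "c_only", "a_only", "b_only"),
      c(n_cobound, n_pk - n_cobound, n_a_only, n_b_only)
    )
    loci <- tibble(
      locus_id = sprintf("L%05d", seq_len(n_loci)),
      chrom = picked$chrom, center = centers, type = type
    )

    peak_at <- function(center, offset = 0L) {
      start <- center + offset - w %/% 2L
      tibble(start = start, end = start + w)
    }
    c_loci <- filter(loci, .data$type %in% c("cobound", "c_only"))
    cobound_loci <- filter(loci, .data$type == "cobound")
    a_only_loci <- filter(loci, .data$type == "a_only")
    b_only_loci <- filter(loci, .data$type == "b_only")
    jit <- function(k) sample(-(w %/% 5):(w %/% 5), k, replace = TRUE)

    c_peaks <- bind_cols(
      tibble(peak_id = sprintf("C_%05d", seq_len(nrow(c_loci))), chrom = c_loci$chrom),
      peak_at(c_loci$center)
    ) %>% mutate(locus_id = c_loci$locus_id)
    a_peaks <- bind_rows(
      bind_cols(
        tibble(peak_id = sprintf("A_%05d", seq_len(nrow(cobound_loci))), chrom = cobound_loci$chrom),
        peak_at(cobound_loci$center, jit(nrow(cobound_loci)))
      ) %>% mutate(locus_id = cobound_loci$locus_id, cobound = TRUE),
      bind_cols(
        tibble(
          peak_id = sprintf("A_%05d", nrow(cobound_loci) + seq_len(nrow(a_only_loci))),
          chrom = a_only_loci$chrom
        ),
        peak_at(a_only_loci$center, jit(nrow(a_only_loci)))
      ) %>% mutate(locus_id = a_only_loci$locus_id, cobound = FALSE)
    )
    b_peaks <- bind_rows(
      bind_cols(
        tibble(peak_id = sprintf("B_%05d", seq_len(nrow(cobound_loci))), chrom = cobound_loci$chrom),
        peak_at(cobound_loci$center, jit(nrow(cobound_loci)))
      ) %>% mutate(locus_id = cobound_loci$locus_id, cobound = TRUE),
      bind_cols(
        tibble(
          peak_id = sprintf("B_%05d", nrow(cobound_loci) + seq_len(nrow(b_only_loci))),
          chrom = b_only_loci$chrom
        ),
        peak_at(b_only_loci$center, jit(nrow(b_only_loci)))
      ) %>% mutate(locus_id = b_only_loci$locus_id, cobound = FALSE)
    )

    depth <- config$read_depth
    background_depth <- max(depth * 0.02, 0.5)
    dependent <- config$dependency_effect > 1
    make_cistrome <- function(peaks, factor_name, condition, expected) {
      cistrome(
        peaks %>% mutate(
          reads = rpois(n(), expected),
          input_reads = rpois(n(), depth / 10),
          strand = "."
        ),
        factor_name = factor_name, condition = condition,
        library_size = config$chip_library_size, genome = config$genome
      )
    }
    ko_depth_ab <- function(peaks) {
      if_else(peaks$cobound & dependent, depth / config$dependency_effect, depth)
    }
    cistromes <- list(
      A_control = make_cistrome(a_peaks, "A", "control", depth),
      A_ko_c = make_cistrome(a_peaks, "A", "ko_c", ko_depth_ab(a_peaks)),
      B_control = make_cistrome(b_peaks, "B", "control", depth),
      B_ko_c = make_cistrome(b_peaks, "B", "ko_c", ko_depth_ab(b_peaks)),
      C_control = make_cistrome(c_peaks, "C", "control", depth),
      C_ko_c = make_cistrome(c_peaks, "C", "ko_c", background_depth)
    )

    genome_seq <- NULL
    if (emit_sequence) {
      pwms <- builtin_pwms()
      dr1 <- pwm_consensus(pwms$hnf4_dr1)
      dr2 <- pwm_consensus(pwms$reverb_dr2)
      dr2 <- gsub("N", "A", dr2, fixed = TRUE) # fix spacer bases in the plant
      genome_seq <- purrr::imap_chr(as.list(config$genome), function(len, ch) {
        # intToUtf8 assembles multi-megabase chromosomes quickly; motifs are
        # spliced in by one segment-wise reassembly (substr<- would copy the
        # whole chromosome per plant)
        seq <- intToUtf8(utf8ToInt("ACGT")[sample.int(4L, len, replace = TRUE)])
        on_ch <- filter(loci, .data$chrom == ch) %>%
          mutate(consensus = if_else(.data$type == "a_only", dr2,
            if_else(.data$type %in% c("cobound", "c_only"), dr1, NA_character_)
          )) %>%
          filter(!is.na(.data$consensus)) %>%
          mutate(
            s = .data$center - nchar(.data$consensus) %/% 2L,
            e = .data$s + nchar(.data$consensus)
          ) %>%
          filter(.data$s >= 0, .data$e <= len) %>%
          arrange(.data$s)
        if (!nrow(on_ch)) {
          return(seq)
        }
        gaps <- substring(seq, c(0L, on_ch$e) + 1L, c(on_ch$s, len))
        pieces <- character(2L * nrow(on_ch) + 1L)
        pieces[seq(1L, length(pieces), by = 2L)] <- gaps
        pieces[seq(2L, length(pieces), by = 2L)] <- on_ch$consensus
        paste(pieces, collapse = "")
      })
      names(genome_seq) <- names(config$genome)
    }

    truth <- list(
      dependent_peaks = if (dependent) {
        sort(c(
          a_peaks$peak_id[a_peaks$cobound],
          b_peaks$peak_id[b_peaks$cobound]
        ))
      } else {
        character(0)
      },
      cobound_pairs = tibble(
        a_peak_id = a_peaks$peak_id[a_peaks$cobound],
        b_peak_id = b_peaks$peak_id[b_peaks$cobound],
        locus_id = a_peaks$locus_id[a_peaks$cobound]
      )
    )

    list(cistromes = cistromes, genome_seq = genome_seq, loci = loci, truth = truth)
  })
}

#' Simulate gene models on the toy genome
#'
#' Genes of 2--20 kb are placed uniformly (overlaps permitted, as in real
#' annotations) with random strand.
#'
#' @param config A [sim_config].
#' @return Tibble with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
simulate_gene_models <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_stage_seed(config$seed, 303, {
    lens <- sample(2000:20000, config$n_genes, replace = TRUE)
    chrom <- sample(names(config$genome), config$n_genes,
      replace = TRUE, prob = config$genome / sum(config$genome)
    )
    max_start <- config$genome[chrom] - lens
    start <- floor(runif(config$n_genes, 0, pmax(1, max_start)))
    tibble(
      gene_id = sprintf("G%04d", seq_len(config$n_genes)),
      chrom = chrom,
      start = as.integer(start),
      end = as.integer(start + lens),
      strand = sample(c("+", "-"), config$n_genes, replace = TRUE)
    ) %>% arrange(.data$chrom, .data$start)
  })
}

#' Simulate expression counts coupled to dependent co-bound sites
#'
#' Baseline counts are negative-binomial around gene-specific log-normal
#' means. Genes carrying a link to a dependent co-bound site (as computed by
#' the peak-to-gene window assignment) are planted as upregulated by
#' `de_effect` with probability `coupling_pi` -- in *both* the factor-A
#' knockout and factor-B knockdown arms, which is what makes them
#' coregulated.
#'
#' @param config A [sim_config].
#' @param gene_models Tibble from [simulate_gene_models()] (or equivalent).
#' @param dependent_site_gene_links Data frame with a `gene_id` column
#'   linking genes to dependent co-bound peaks, e.g. from
#'   [assign_gene_window()].
#' @return List with `counts` (tibble: gene_id + one column per sample),
#'   `samples` (sample_id, condition), and `truth` (list with
#'   `coregulated_genes`).
#' @export
simulate_expression <- function(config, gene_models, dependent_site_gene_links) {
  stopifnot(inherits(config, "sim_config"))
  gene_models <- check_gene_models(gene_models)
  links <- as_tibble(dependent_site_gene_links)
  if (nrow(links)) require_columns(links, "gene_id", "dependent_site_gene_links")
  if (!nrow(links) && config$coupling_pi > 0) {
    abort("empty link set with coupling_pi > 0: no gene can be planted as coregulated.")
  }
  unknown <- setdiff(links$gene_id, gene_models$gene_id)
  if (length(unknown)) {
    abort(sprintf(
      "link gene_id(s) absent from gene_models: %s.",
      paste(head(unknown, 5L), collapse = ", ")
    ))
  }

  with_stage_seed(config$seed, 404, {
    n <- nrow(gene_models)
    nrep <- config$n_samples_expression
    samples <- purrr::map_dfr(
      c("control_A", "KO_A", "control_B", "KD_B"),
      function(cond) {
        tibble(
          sample_id = sprintf("%s_%d", cond, seq_len(nrep[[cond]])),
          condition = cond
        )
      }
    )

    base_mu <- rlnorm(n, meanlog = log(200), sdlog = 1)
    linked <- gene_models$gene_id %in% unique(links$gene_id)
    planted <- linked & runif(n) < config$coupling_pi

    mu <- matrix(base_mu, n, nrow(samples))
    up_col <- samples$condition %in% c("KO_A", "KD_B")
    mu[planted, up_col] <- mu[planted, up_col] * config$de_effect

    counts <- matrix(
      rnbinom(n * nrow(samples), mu = mu, size = 1 / config$dispersion),
      n, nrow(samples),
      dimnames = list(NULL, samples$sample_id)
    )

    coregulated <- if (config$de_effect != 1) {
      sort(gene_models$gene_id[planted])
    } else {
      character(0)
    }
    list(
      counts = bind_cols(tibble(gene_id = gene_models$gene_id), as_tibble(counts)),
      samples = samples,
      truth = list(coregulated_genes = coregulated, linked_genes = sort(gene_models$gene_id[linked]))
    )
  })
}

#' Run all three generators under one configuration
#'
#' Convenience wrapper: proteomics, cistromes, gene models, the ground-truth
#' peak-to-gene links (strand-aware TSS/TES windows around genes, applied to
#' the truly dependent co-bound A peaks), and expression, with a merged
#' ground-truth list.
#'
#' @param config A [sim_config].
#' @param emit_sequence Passed to [simulate_cistromes()].
#' @return List with `proteomics`, `cistromes`, `gene_models`,
#'   `truth_links`, `expression`, and `truth` (merged).
#' @export
simulate_all <- function(config, emit_sequence = TRUE) {
  prot <- simulate_proteomics(config)
  cis <- simulate_cistromes(config, emit_sequence = emit_sequence)
  genes <- simulate_gene_models(config)
  dep_a <- cis$truth$cobound_pairs$a_peak_id
  dep_peaks <- filter(cis$cistromes$A_control, .data$peak_id %in% dep_a)
  links <- assign_gene_window(dep_peaks, genes)
  expr <- simulate_expression(config, genes, links)
  list(
    proteomics = prot,
    cistromes = cis,
    gene_models = genes,
    truth_links = links,
    expression = expr,
    truth = c(prot$truth, cis$truth, expr$truth)
  )
}
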