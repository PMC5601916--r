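#' Differential enrichment of bait over control IPs
#'
#' Per protein, within one nuclease stratum: the log2 enrichment is the
#' difference of arm means on the log2 scale, and the P-value comes from a
#' two-tailed two-sample t-test with pooled (homoscedastic) variance on the
#' imputed values. Benjamini-Hochberg adjusted P-values are reported
#' alongside the raw ones. Proteins observed (pre-imputation) in fewer than
#' half the samples of both arms are flagged `low_detection` but never
#' dropped.
#'
#' @param m A [protein_quant] at stage `"imputed"`.
#' @param nuclease Which nuclease stratum to score (`"none"`, `"mnase"`,
#'   `"benzonase"`). Each stratum is compared against its own control
#'   samples.
#' @return A tibble of class `enrichment_results` with columns `protein_id`,
#'   `n_bait`, `n_control`, `log2_enrichment`, `t_stat`, `p_value`, `adj_p`,
#'   `low_detection`.
#' @export
test_enrichment <- function(m, nuclease = "none") {
  if (!inherits(m, "protein_quant")) abort("`m` must be a protein_quant.")
  if (m$stage != "imputed") abort("`m` must be at stage 'imputed' (impute first).")
  in_stratum <- m$samples$nuclease == nuclease
  bait <- in_stratum & m$samples$condition == "bait"
  ctrl <- in_stratum & m$samples$condition == "control"
  nb <- sum(bait)
  nc <- sum(ctrl)
  if (nb < 2 || nc < 2) {
    abort(sprintf(
      "stratum '%s' needs >= 2 samples per arm (has %d bait, %d control).",
      nuclease, nb, nc
    ))
  }

  vb <- m$values[, bait, drop = FALSE]
  vc <- m$values[, ctrl, drop = FALSE]
  mb <- rowMeans(vb)
  mc <- rowMeans(vc)
  ssb <- rowSums((vb - mb)^2)
  ssc <- rowSums((vc - mc)^2)
  df <- nb + nc - 2L
  s2 <- (ssb + ssc) / df
  se <- sqrt(s2 * (1 / nb + 1 / nc))
  t_stat <- (mb - mc) / se
  t_stat[se == 0 & mb == mc] <- 0 # identical arms: define t = 0, P = 1
  p <- 2 * pt(abs(t_stat), df = df, lower.tail = FALSE)

  obs_b <- rowMeans(m$observed[, bait, drop = FALSE])
  obs_c <- rowMeans(m$observed[, ctrl, drop = FALSE])

  out <- tibble(
    protein_id = rownames(m$values),
    n_bait = nb,
    n_control = nc,
    log2_enrichment = unname(mb - mc),
    t_stat = unname(t_stat),
    p_value = unname(p),
    adj_p = unname(p.adjust(p, method = "BH")),
    low_detection = unname(obs_b < 0.5 & obs_c < 0.5)
  )
  class(out) <- c("enrichment_results", class(out))
  attr(out, "nuclease") <- nuclease
  out
}

#' Call interactors with fold-change and P-value gates
#'
#' A protein is an interactor when its linear enrichment reaches
#' `fold_cutoff` (i.e. `log2_enrichment >= log2(fold_cutoff)`) and its raw
#' t-test P-value is below `p_cutoff`. Defaults are the 10-fold / P < 0.01
#' high-stringency gate.
#'
#' @param results An `enrichment_results` tibble from [test_enrichment()].
#' @param fold_cutoff Linear fold-enrichment cutoff (> 0).
#' @param p_cutoff Raw P-value cutoff.
#' @return The input with a logical `is_interactor` column appended.
#' @export
call_interactors <- function(results, fold_cutoff = 10, p_cutoff = 0.01) {
  require_columns(results, c("protein_id", "log2_enrichment", "p_value"), "results")
  stop_if_not_scalar_number(fold_cutoff, "fold_cutoff", positive = TRUE)
  stop_if_not_proportion(p_cutoff, "p_cutoff")
  out <- results %>%
    mutate(is_interactor = .data$log2_enrichment >= log2(fold_cutoff) &
      .data$p_value < p_cutoff)
  class(out) <- unique(c("enrichment_results", class(out)))
  attr(out, "fold_cutoff") <- fold_cutoff
  attr(out, "p_cutoff") <- p_cutoff
  out
}

#' Classify interactors by nuclease sensitivity
#'
#' Interactions that survive promiscuous nuclease (Benzonase) digestion of
#' the cross-linked chromatin are taken as direct protein contacts; those
#' lost after Benzonase, while enriched untreated, are classified as bridged
#' through DNA. A protein absent from the treated stratum is `indeterminate`.
#'
#' @param untreated `enrichment_results` with `is_interactor` (from
#'   [call_interactors()]) for the untreated stratum.
#' @param benzonase `enrichment_results` for the Benzonase stratum.
#' @param mnase Optional `enrichment_results` for the MNase stratum, carried
#'   through for reporting.
#' @param retain_fold Linear enrichment a protein must retain after
#'   Benzonase to count as direct (default eightfold).
#' @param fold_cutoff Untreated enrichment backing the `dna_bridged` call
#'   (default 10-fold, matching the interactor gate).
#' @return Tibble with `protein_id`, the per-stratum log2 enrichments, and
#'   `nuclease_class` in `{"direct", "dna_bridged", "indeterminate"}` for
#'   every untreated interactor.
#' @export
classify_nuclease_sensitivity <- function(untreated, benzonase, mnase = NULL,
                                          retain_fold = 8, fold_cutoff = 10) {
  require_columns(untreated, c("protein_id", "log2_enrichment", "is_interactor"), "untreated")
  require_columns(benzonase, c("protein_id", "log2_enrichment"), "benzonase")
  stop_if_not_scalar_number(retain_fold, "retain_fold", positive = TRUE)

  out <- untreated %>%
    filter(.data$is_interactor) %>%
    select("protein_id", untreated_log2_enrichment = "log2_enrichment") %>%
    left_join(
      select(as_tibble(benzonase), "protein_id",
        benzonase_log2_enrichment = "log2_enrichment"
      ),
      by = "protein_id"
    )
  if (!is.null(mnase)) {
    require_columns(mnase, c("protein_id", "log2_enrichment"), "mnase")
    out <- left_join(
      out,
      select(as_tibble(mnase), "protein_id", mnase_log2_enrichment = "log2_enrichment"),
      by = "protein_id"
    )
  }
  out %>%
    mutate(nuclease_class = case_when(
      is.na(.data$benzonase_log2_enrichment) ~ "indeterminate",
      .data$benzonase_log2_enrichment >= log2(retain_fold) ~ "direct",
      .data$untreated_log2_enrichment >= log2(fold_cutoff) ~ "dna_bridged",
      TRUE ~ "indeterminate"
    ))
}

#' @exportS3Method generics::glance
glance.enrichment_results <- function(x, ...) {
  tibble(
    n_proteins = nrow(x),
    n_interactors = if ("is_interactor" %in% names(x)) sum(x$is_interactor) else NA_integer_,
    fold_cutoff = attr(x, "fold_cutoff") %||% NA_real_,
    p_cutoff = attr(x, "p_cutoff") %||% NA_real_,
    nuclease = attr(x, "nuclease") %||% NA_character_
  )
}

#' Volcano plot of an interactome scoring
#'
#' log2 bait/control enrichment against -log10 raw P, with the fold and P
#' gates drawn and called interactors highlighted.
#'
#' @param object An `enrichment_results` tibble with `is_interactor`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.enrichment_results <- function(object, ...) {
  fold <- attr(object, "fold_cutoff") %||% 10
  pc <- attr(object, "p_cutoff") %||% 0.01
  dat <- as_tibble(object)
  if (!"is_interactor" %in% names(dat)) dat$is_interactor <- FALSE
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$log2_enrichment,
    y = -log10(.data$p_value),
    colour = .data$is_interactor
  )) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = log2(fold), linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(pc), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey55", `TRUE` = "firebrick")) +
    ggplot2::labs(
      x = "log2 enrichment (bait / control)",
      y = "-log10 P (homoscedastic t-test)",
      colour = "interactor"
    ) +
    ggplot2::theme_minimal()
}
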