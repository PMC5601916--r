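#' Log2 counts-per-million normalisation
#'
#' `log2(count * 1e6 / library_size + 1)` with library size = column sum
#' (unless supplied). This is the deliberately simple normalisation behind
#' the package's differential-expression stand-in; the scientific content
#' downstream is the fold/P gate and the coregulation logic, not the DE
#' engine, which is swappable.
#'
#' @param counts Data frame with a `gene_id` column and one numeric column
#'   per sample (non-negative counts).
#' @param library_sizes Optional named vector of library sizes per sample;
#'   defaults to column sums.
#' @param pseudocount Added to CPM before log2 (default 1).
#' @param log Return log2 values (default `TRUE`); `FALSE` gives plain CPM.
#' @return A tibble of the same shape with normalised values.
#' @export
normalize_cpm <- function(counts, library_sizes = NULL, pseudocount = 1, log = TRUE) {
  counts <- as_tibble(counts)
  require_columns(counts, "gene_id", "counts")
  sample_cols <- setdiff(names(counts), "gene_id")
  if (!length(sample_cols)) abort("`counts` has no sample columns.")
  m <- as.matrix(counts[sample_cols])
  if (any(m < 0)) abort("counts must be non-negative.")
  ls <- library_sizes %||% colSums(m)
  if (!is.null(library_sizes)) ls <- library_sizes[sample_cols]
  if (any(is.na(ls)) || any(ls <= 0)) {
    abort("every sample needs a positive library size (empty sample?).")
  }
  cpm <- sweep(m, 2L, ls, "/") * 1e6
  if (log) cpm <- log2(cpm + pseudocount)
  bind_cols(counts["gene_id"], as_tibble(cpm))
}

#' Differential expression between two arms (Welch t on log2 CPM)
#'
#' Per gene: log2 fold change is the difference of arm means on log2-CPM,
#' the P-value comes from a two-sided Welch (unequal-variance) t-test, and
#' `passes` applies the printed gate `|log2FC| >= log2(fold_cutoff)` and
#' `P < p_cutoff` (defaults 1.7-fold, 0.05). Genes with zero variance in
#' both arms and equal means get P = 1.
#'
#' @param counts Data frame with `gene_id` plus sample columns.
#' @param samples Data frame with columns `sample_id`, `condition`.
#' @param treatment,control Condition labels of the two arms (>= 2 samples
#'   each).
#' @param fold_cutoff,p_cutoff Gate parameters.
#' @return A tibble of class `de_results`: `gene_id`, `log2_fold_change`,
#'   `t_stat`, `df`, `p_value`, `passes`, `direction` (+1/-1/0).
#' @export
de_test <- function(counts, samples, treatment, control,
                    fold_cutoff = 1.7, p_cutoff = 0.05) {
  samples <- as_tibble(samples)
  require_columns(samples, c("sample_id", "condition"), "samples")
  stop_if_not_scalar_number(fold_cutoff, "fold_cutoff", positive = TRUE)
  stop_if_not_proportion(p_cutoff, "p_cutoff")
  trt_ids <- samples$sample_id[samples$condition == treatment]
  ctl_ids <- samples$sample_id[samples$condition == control]
  if (length(trt_ids) < 2 || length(ctl_ids) < 2) {
    abort(sprintf(
      "need >= 2 samples per arm (%s: %d, %s: %d).",
      treatment, length(trt_ids), control, length(ctl_ids)
    ))
  }
  logcpm <- normalize_cpm(counts)
  missing_cols <- setdiff(c(trt_ids, ctl_ids), names(logcpm))
  if (length(missing_cols)) {
    abort(sprintf("sample column(s) absent from counts: %s.", paste(missing_cols, collapse = ", ")))
  }
  x <- as.matrix(logcpm[trt_ids])
  y <- as.matrix(logcpm[ctl_ids])
  nx <- ncol(x)
  ny <- ncol(y)
  mx <- rowMeans(x)
  my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (nx - 1)
  vy <- rowSums((y - my)^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t_stat <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * pt(abs(t_stat), df = df, lower.tail = FALSE)
  degenerate <- se2 == 0
  t_stat[degenerate & mx == my] <- 0
  p[degenerate & mx == my] <- 1 # flat gene, identical arms
  p[degenerate & mx != my] <- 0 # zero within-arm variance, different means
  lfc <- mx - my
  out <- tibble(
    gene_id = logcpm$gene_id,
    log2_fold_change = lfc,
    t_stat = t_stat,
    df = df,
    p_value = p,
    passes = abs(lfc) >= log2(fold_cutoff) & p < p_cutoff,
    direction = sign(lfc)
  )
  class(out) <- c("de_results", class(out))
  attr(out, "fold_cutoff") <- fold_cutoff
  attr(out, "p_cutoff") <- p_cutoff
  attr(out, "arms") <- c(treatment = treatment, control = control)
  out
}

#' @exportS3Method generics::glance
glance.de_results <- function(x, ...) {
  arms <- attr(x, "arms")
  tibble(
    treatment = arms[["treatment"]], control = arms[["control"]],
    n_genes = nrow(x), n_pass = sum(x$passes),
    fold_cutoff = attr(x, "fold_cutoff"), p_cutoff = attr(x, "p_cutoff")
  )
}

#' Coregulation across two independent perturbations
#'
#' Genes passing the differential-expression gate in both perturbations are
#' split by sign agreement into `correlated` (same direction) and
#' `anti_correlated` (opposite directions). Overlap significance between the
#' two pass sets is assessed with Fisher's exact test on the pass/fail by
#' perturbation table (a package choice; no canonical test exists for this
#' overlap).
#'
#' @param de_a,de_b `de_results` over the same gene universe.
#' @return An object of class `coregulation_result`: list with `genes`
#'   (tibble: gene_id, direction_a, direction_b, class), `correlated` /
#'   `anti_correlated` id vectors, and `overlap_test` (odds ratio + P).
#' @export
call_coregulation <- function(de_a, de_b) {
  require_columns(de_a, c("gene_id", "passes", "direction"), "de_a")
  require_columns(de_b, c("gene_id", "passes", "direction"), "de_b")
  if (!setequal(de_a$gene_id, de_b$gene_id)) {
    abort("`de_a` and `de_b` must share one gene universe.")
  }
  b <- de_b[match(de_a$gene_id, de_b$gene_id), ]
  both <- de_a$passes & b$passes
  genes <- tibble(
    gene_id = de_a$gene_id[both],
    direction_a = de_a$direction[both],
    direction_b = b$direction[both]
  ) %>%
    mutate(class = if_else(.data$direction_a == .data$direction_b,
      "correlated", "anti_correlated"
    ))
  tab <- table(
    factor(de_a$passes, levels = c(TRUE, FALSE)),
    factor(b$passes, levels = c(TRUE, FALSE))
  )
  ft <- fisher.test(tab)
  structure(
    list(
      genes = genes,
      correlated = genes$gene_id[genes$class == "correlated"],
      anti_correlated = genes$gene_id[genes$class == "anti_correlated"],
      overlap_test = tibble(
        n_pass_a = sum(de_a$passes), n_pass_b = sum(b$passes),
        n_pass_both = sum(both),
        odds_ratio = unname(ft$estimate), p_value = ft$p.value
      )
    ),
    class = "coregulation_result"
  )
}

#' @export
print.coregulation_result <- function(x, ...) {
  cat(sprintf(
    "<coregulation_result> %d correlated, %d anti-correlated (overlap P = %.3g)\n",
    length(x$correlated), length(x$anti_correlated), x$overlap_test$p_value
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.coregulation_result <- function(x, ...) x$genes

#' @exportS3Method generics::glance
glance.coregulation_result <- function(x, ...) {
  bind_cols(
    tibble(
      n_correlated = length(x$correlated),
      n_anti_correlated = length(x$anti_correlated)
    ),
    x$overlap_test
  )
}

#' Fold-change concordance plot across two perturbations
#'
#' @param object A `coregulation_result`.
#' @param de_a,de_b The `de_results` the call was made from (for the full
#'   background cloud).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_coregulation <- function(object, de_a, de_b, ...) {
  if (!inherits(object, "coregulation_result")) {
    abort("`object` must be a coregulation_result.")
  }
  dat <- tibble(
    gene_id = de_a$gene_id,
    lfc_a = de_a$log2_fold_change,
    lfc_b = de_b$log2_fold_change[match(de_a$gene_id, de_b$gene_id)]
  ) %>%
    left_join(object$genes[c("gene_id", "class")], by = "gene_id") %>%
    mutate(class = tidyr::replace_na(.data$class, "not coregulated"))
  ggplot2::ggplot(dat, ggplot2::aes(.data$lfc_a, .data$lfc_b, colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::scale_colour_manual(values = c(
      correlated = "firebrick", anti_correlated = "steelblue",
      `not coregulated` = "grey70"
    )) +
    ggplot2::labs(
      x = "log2 fold change (perturbation A)",
      y = "log2 fold change (perturbation B)", colour = NULL
    ) +
    ggplot2::theme_minimal()
}
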