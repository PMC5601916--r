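# Chi-squared helpers shared by the motif and association stages. Both are
# thin formatting layers over stats::chisq.test so that the distributional
# machinery is never re-implemented; tests check them against the textbook
# closed forms independently.

#' Pearson and Yates-corrected chi-squared tests on a 2x2 table
#'
#' @param tab 2x2 numeric matrix of counts.
#' @return List with `statistic`, `df`, `p_value`, `expected`.
#' @export
pearson_chi2 <- function(tab) {
  chi2_table_test(tab, correct = FALSE)
}

#' @rdname pearson_chi2
#' @export
yates_chi2 <- function(tab) {
  chi2_table_test(tab, correct = TRUE)
}

chi2_table_test <- function(tab, correct) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) abort("`tab` must be a 2x2 table.")
  if (any(tab < 0)) abort("table counts must be >= 0.")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("degenerate margin: a row or column of the table is all zero.")
  }
  res <- suppressWarnings(chisq.test(tab, correct = correct))
  list(
    statistic = unname(res$statistic),
    df = unname(res$parameter),
    p_value = res$p.value,
    expected = res$expected
  )
}

gene_tss <- function(genes) {
  if_else(genes$strand == "-", genes$end, genes$start)
}

gene_tes <- function(genes) {
  if_else(genes$strand == "-", genes$start, genes$end)
}

check_gene_models <- function(genes) {
  genes <- as_tibble(genes)
  require_columns(genes, c("gene_id", "chrom", "start", "end", "strand"), "genes")
  if (!all(genes$strand %in% c("+", "-"))) {
    abort("every gene must be strand-annotated ('+' or '-').")
  }
  if (any(genes$start < 0) || any(genes$start >= genes$end)) {
    abort("gene coordinates must satisfy 0 <= start < end.")
  }
  genes
}

#' Link each peak to its nearest gene within a distance cap
#'
#' Distances run from the peak midpoint to the gene's transcription start
#' site (strand-aware: positive values lie downstream of the TSS in the
#' gene's reading direction). Each peak links to the single gene with the
#' smallest absolute distance, provided it is within `max_dist`; ties break
#' by lexicographic `gene_id`. Peaks with no gene in range are unlinked
#' (absent from the output).
#'
#' @param peaks Data frame with `peak_id`, `chrom`, `start`, `end`.
#' @param genes Data frame with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @param max_dist Maximum |midpoint - TSS| distance in bp (default 100 kb).
#' @return Tibble with `peak_id`, `gene_id`, `distance` (signed bp),
#'   `convention = "nearest_100kb"`.
#' @export
assign_nearest_gene <- function(peaks, genes, max_dist = 100000) {
  peaks <- as_tibble(peaks)
  require_columns(peaks, c("peak_id", "chrom", "start", "end"), "peaks")
  genes <- check_gene_models(genes)
  stop_if_not_scalar_number(max_dist, "max_dist", positive = TRUE)

  mid <- (peaks$start + peaks$end) %/% 2L
  tss <- gene_tss(genes)
  purrr::map_dfr(seq_len(nrow(peaks)), function(i) {
    on_chrom <- which(genes$chrom == peaks$chrom[i])
    if (!length(on_chrom)) {
      return(tibble())
    }
    d_abs <- abs(mid[i] - tss[on_chrom])
    in_range <- d_abs <= max_dist
    if (!any(in_range)) {
      return(tibble())
    }
    cand <- on_chrom[in_range]
    ord <- order(d_abs[in_range], genes$gene_id[cand])
    g <- cand[ord[1L]]
    signed <- (mid[i] - tss[g]) * if_else(genes$strand[g] == "-", -1L, 1L)
    tibble(
      peak_id = peaks$peak_id[i], gene_id = genes$gene_id[g],
      distance = signed, convention = "nearest_100kb"
    )
  })
}

#' Link peaks to genes by a strand-aware TSS/TES window
#'
#' A peak links to every gene whose window \[TSS - upstream, TES +
#' downstream\] (coordinates reflected for minus-strand genes, closed at
#' both boundaries) contains the peak midpoint. Multi-gene links are
#' allowed.
#'
#' @inheritParams assign_nearest_gene
#' @param upstream bp upstream of the TSS (default 50 kb).
#' @param downstream bp downstream of the TES (default 2 kb).
#' @return Tibble with `peak_id`, `gene_id`, `distance` (signed
#'   strand-aware midpoint-to-TSS bp), `convention = "tss50k_tes2k"`.
#' @export
assign_gene_window <- function(peaks, genes, upstream = 50000, downstream = 2000) {
  peaks <- as_tibble(peaks)
  require_columns(peaks, c("peak_id", "chrom", "start", "end"), "peaks")
  genes <- check_gene_models(genes)
  stop_if_not_scalar_number(upstream, "upstream")
  stop_if_not_scalar_number(downstream, "downstream")

  mid <- (peaks$start + peaks$end) %/% 2L
  minus <- genes$strand == "-"
  win_lo <- if_else(minus, genes$start - downstream, genes$start - upstream)
  win_hi <- if_else(minus, genes$end + upstream, genes$end + downstream)
  tss <- gene_tss(genes)

  hits <- overlap_widths(
    peaks$chrom, mid, mid + 1L, # midpoint as a 1 bp interval
    genes$chrom, win_lo, win_hi + 1L # +1 makes the closed upper bound inclusive
  )
  if (!nrow(hits)) {
    return(tibble(
      peak_id = character(), gene_id = character(),
      distance = numeric(), convention = character()
    ))
  }
  tibble(
    peak_id = peaks$peak_id[hits$query],
    gene_id = genes$gene_id[hits$subject],
    distance = (mid[hits$query] - tss[hits$subject]) *
      if_else(minus[hits$subject], -1L, 1L),
    convention = "tss50k_tes2k"
  ) %>%
    arrange(.data$peak_id, .data$gene_id)
}

#' Association between dependent co-bound sites and coregulated genes
#'
#' Builds the 2x2 table of gene has/lacks a dependent co-bound peak link
#' against gene coregulated/unchanged, and tests it with the chi-squared
#' test with Yates continuity correction (df = 1).
#'
#' @param genes Data frame (one row per gene of the universe) with logical
#'   columns `has_dependent_link` and `coregulated`.
#' @return Object of class `association_result`: list with `table`,
#'   `statistic`, `df`, `p_value`, `expected`.
#' @export
association_test <- function(genes) {
  genes <- as_tibble(genes)
  require_columns(genes, c("has_dependent_link", "coregulated"), "genes")
  tab <- table(
    factor(genes$has_dependent_link, levels = c(TRUE, FALSE)),
    factor(genes$coregulated, levels = c(TRUE, FALSE)),
    dnn = c("has_dependent_link", "coregulated")
  )
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("degenerate margin: all genes fall in one class.")
  }
  res <- yates_chi2(tab)
  structure(
    list(
      table = tab, statistic = res$statistic, df = res$df,
      p_value = res$p_value, expected = res$expected
    ),
    class = "association_result"
  )
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf(
    "<association_result> Yates chi2 = %.3f, df = %d, P = %.3g\n",
    x$statistic, x$df, x$p_value
  ))
  print(x$table)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.association_result <- function(x, ...) {
  tibble(
    statistic = x$statistic, df = x$df, p_value = x$p_value,
    method = "chi-squared with Yates correction"
  )
}

#' @exportS3Method generics::glance
glance.association_result <- function(x, ...) tidy(x)

#' Rank-sum comparison of peak signal between two groups
#'
#' Two-sided Wilcoxon-Mann-Whitney test: exact when the combined sample size
#' is at most 20 and the data are tie-free, otherwise the normal
#' approximation with tie correction. If every value is tied across both
#' groups P = 1 by construction.
#'
#' @param x,y Numeric signal vectors (>= 3 values each).
#' @return One-row tibble with `u_statistic` (U for `x`), `p_value`,
#'   `method`.
#' @export
binding_strength_test <- function(x, y) {
  if (length(x) < 3 || length(y) < 3) abort("both groups need >= 3 values.")
  if (length(unique(c(x, y))) == 1L) {
    return(tibble(
      u_statistic = length(x) * length(y) / 2,
      p_value = 1, method = "all values tied"
    ))
  }
  exact <- (length(x) + length(y)) <= 20 && !anyDuplicated(c(x, y))
  res <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = !exact))
  tibble(
    u_statistic = unname(res$statistic),
    p_value = res$p.value,
    method = if (exact) "exact" else "normal approximation (tie-corrected)"
  )
}

#' One-tailed enrichment test for sequential-ChIP signal
#'
#' One-tailed (greater) unpaired t-test with pooled variance, as used to ask
#' whether re-precipitated signal exceeds the IgG control.
#'
#' @param signal,control Numeric replicate vectors (>= 2 each).
#' @return One-row tibble with `t_stat`, `df`, `p_value`.
#' @export
rechip_test <- function(signal, control) {
  if (length(signal) < 2 || length(control) < 2) {
    abort("both groups need >= 2 replicates.")
  }
  res <- t.test(signal, control, alternative = "greater", var.equal = TRUE)
  tibble(
    t_stat = unname(res$statistic),
    df = unname(res$parameter),
    p_value = res$p.value
  )
}
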