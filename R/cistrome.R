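#' Construct a cistrome (a factor's peak set in one condition)
#'
#' A cistrome is a tibble of called peaks carrying per-peak ChIP read counts
#' and matched input (e.g. IgG) counts, together with the library sizes
#' needed to express signal as rpm (reads per million mapped reads).
#' Coordinates are 0-based half-open throughout the package; BED files are
#' read and written natively in that convention.
#'
#' @param peaks Data frame with columns `peak_id`, `chrom`, `start`, `end`,
#'   `reads`, `input_reads`, and optionally `strand`.
#' @param factor_name,condition Labels (e.g. `"PROX1"`, `"control"`).
#' @param library_size Total mapped reads of the ChIP library (> 0).
#' @param input_library_size Total mapped reads of the input library;
#'   defaults to `library_size`.
#' @param genome Optional named numeric vector of chromosome lengths used to
#'   validate coordinates and chromosome names.
#' @return A tibble of class `cistrome` with `rpm` and `input_rpm` columns
#'   added.
#' @export
cistrome <- function(peaks, factor_name, condition, library_size,
                     input_library_size = library_size, genome = NULL) {
  peaks <- as_tibble(peaks)
  require_columns(peaks, c("peak_id", "chrom", "start", "end", "reads", "input_reads"), "peaks")
  if (!"strand" %in% names(peaks)) peaks$strand <- "."
  if (anyDuplicated(peaks$peak_id)) abort("`peak_id` values must be unique.")
  if (any(peaks$start < 0) || any(peaks$start >= peaks$end)) {
    abort("peak coordinates must satisfy 0 <= start < end (0-based half-open).")
  }
  if (any(peaks$reads < 0) || any(peaks$input_reads < 0)) abort("read counts must be >= 0.")
  stop_if_not_scalar_number(library_size, "library_size", positive = TRUE)
  stop_if_not_scalar_number(input_library_size, "input_library_size", positive = TRUE)
  if (!is.null(genome)) {
    unknown <- setdiff(unique(peaks$chrom), names(genome))
    if (length(unknown)) {
      abort(sprintf("unknown chromosome name(s): %s.", paste(unknown, collapse = ", ")))
    }
    too_far <- peaks$end > genome[peaks$chrom]
    if (any(too_far)) {
      abort(sprintf(
        "peak(s) extend beyond chromosome end: %s.",
        paste(head(peaks$peak_id[too_far], 5L), collapse = ", ")
      ))
    }
  }
  out <- peaks %>%
    mutate(
      rpm = compute_rpm(.data$reads, library_size),
      input_rpm = compute_rpm(.data$input_reads, input_library_size)
    )
  structure(out,
    class = unique(c("cistrome", class(out))),
    factor_name = factor_name, condition = condition,
    library_size = library_size, input_library_size = input_library_size,
    genome = genome
  )
}

#' Restrict a cistrome to a set of peak ids (order preserved)
#'
#' @param x A [cistrome].
#' @param ids Peak ids to keep; every id must exist in `x`.
#' @return The subset [cistrome], in the order of `ids`.
#' @export
cistrome_subset <- function(x, ids) {
  if (!inherits(x, "cistrome")) abort("`x` must be a cistrome.")
  idx <- match(ids, x$peak_id)
  if (anyNA(idx)) {
    abort(sprintf(
      "peak id(s) absent from cistrome: %s.",
      paste(head(ids[is.na(idx)], 5L), collapse = ", ")
    ))
  }
  cistrome_keep_attrs(as_tibble(x)[idx, , drop = FALSE], x)
}

cistrome_keep_attrs <- function(new, old) {
  for (a in c("factor_name", "condition", "library_size", "input_library_size", "genome")) {
    attr(new, a) <- attr(old, a)
  }
  class(new) <- unique(c("cistrome", class(new)))
  new
}

#' Reads-per-million normalisation
#'
#' `rpm = reads * 1e6 / library_size`. The browser-track scale "reads per
#' ten million" (RPTM) is `10 * rpm`; [rptm()] is provided for track output.
#'
#' @param reads Read count(s), >= 0.
#' @param library_size Total mapped reads (> 0).
#' @return Numeric vector of rpm values.
#' @export
compute_rpm <- function(reads, library_size) {
  if (any(library_size <= 0)) abort("`library_size` must be > 0.")
  if (any(reads < 0)) abort("`reads` must be >= 0.")
  reads * 1e6 / library_size
}

#' @rdname compute_rpm
#' @export
rptm <- function(reads, library_size) 10 * compute_rpm(reads, library_size)

#' Filter peaks on signal and enrichment over input
#'
#' Keeps peaks with `rpm > min_rpm` and `rpm > input_fold * input_rpm`
#' (threefold over input by default). An optional pseudocount can be added
#' to the input rpm before the fold comparison; the default of 0 applies the
#' rule exactly as stated.
#'
#' @param x A [cistrome].
#' @param min_rpm rpm cutoff (e.g. 2 for a PROX1-like factor, 1.5 for an
#'   HDAC3-like one).
#' @param input_fold Required fold over input (default 3).
#' @param input_pseudocount rpm pseudocount added to input before the fold
#'   gate (default 0).
#' @return The filtered [cistrome].
#' @export
filter_peaks <- function(x, min_rpm, input_fold = 3, input_pseudocount = 0) {
  if (!inherits(x, "cistrome")) abort("`x` must be a cistrome.")
  stop_if_not_scalar_number(min_rpm, "min_rpm")
  stop_if_not_scalar_number(input_fold, "input_fold")
  if (min_rpm < 0 || input_fold < 0 || input_pseudocount < 0) {
    abort("thresholds must be >= 0.")
  }
  keep <- x$rpm > min_rpm & x$rpm > input_fold * (x$input_rpm + input_pseudocount)
  cistrome_keep_attrs(as_tibble(x)[keep, , drop = FALSE], x)
}

overlap_widths <- function(qchrom, qstart, qend, schrom, sstart, send) {
  # all query/subject overlap pairs via IRanges; returns tibble of indices + bp
  q <- IRanges::IRanges(start = qstart + 1L, end = qend)
  s <- IRanges::IRanges(start = sstart + 1L, end = send)
  hits <- purrr::map_dfr(intersect(unique(qchrom), unique(schrom)), function(ch) {
    qi <- which(qchrom == ch)
    si <- which(schrom == ch)
    h <- IRanges::findOverlaps(q[qi], s[si])
    tibble(query = qi[S4Vectors::queryHits(h)], subject = si[S4Vectors::subjectHits(h)])
  })
  if (!nrow(hits)) {
    return(tibble(query = integer(), subject = integer(), overlap_bp = integer()))
  }
  hits$overlap_bp <- pmin(qend[hits$query], send[hits$subject]) -
    pmax(qstart[hits$query], sstart[hits$subject])
  hits
}

#' Partition two cistromes into co-bound and factor-only peaks
#'
#' A peak of cistrome `a` is co-bound when some peak of `b` overlaps it by at
#' least `min_frac` of the *query* peak's length and the other factor's
#' signal there is at least `min_other_rpm`; symmetrically for `b`. With
#' called-peak inputs the other factor's signal at a query peak is the rpm of
#' the overlapping partner peak. Each co-bound peak is paired with its
#' maximally overlapping partner (ties broken by partner `peak_id`).
#'
#' @param a,b Filtered [cistrome]s.
#' @param min_frac Minimum overlap as a fraction of the query peak length
#'   (default 0.5, evaluated from both sides).
#' @param min_other_rpm Minimum partner-factor rpm at the query peak
#'   (default 1).
#' @return An object of class `overlap_partition`: a list with tibbles `a`
#'   and `b` (each peak labelled `co_bound` / `a_only` / `b_only`), the
#'   co-bound `pairs`, and the parameters used.
#' @export
overlap_cistromes <- function(a, b, min_frac = 0.5, min_other_rpm = 1) {
  if (!inherits(a, "cistrome") || !inherits(b, "cistrome")) {
    abort("`a` and `b` must be cistromes.")
  }
  stop_if_not_proportion(min_frac, "min_frac")
  stop_if_not_scalar_number(min_other_rpm, "min_other_rpm")
  for (cis in list(a, b)) {
    genome <- attr(cis, "genome")
    if (!is.null(genome)) {
      unknown <- setdiff(unique(cis$chrom), names(genome))
      if (length(unknown)) {
        abort(sprintf("unknown chromosome name(s): %s.", paste(unknown, collapse = ", ")))
      }
    }
  }

  classify_side <- function(q, s) {
    hits <- overlap_widths(q$chrom, q$start, q$end, s$chrom, s$start, s$end)
    hits <- hits %>%
      mutate(
        frac_query = .data$overlap_bp / (q$end[.data$query] - q$start[.data$query]),
        partner_rpm = s$rpm[.data$subject]
      ) %>%
      filter(.data$frac_query >= min_frac, .data$partner_rpm >= min_other_rpm)
    best <- hits %>%
      mutate(partner_id = s$peak_id[.data$subject]) %>%
      group_by(.data$query) %>%
      arrange(dplyr::desc(.data$overlap_bp), .data$partner_id, .by_group = TRUE) %>%
      dplyr::slice(1L) %>%
      ungroup()
    list(
      co_bound = best$query,
      pairs = tibble(
        query_peak_id = q$peak_id[best$query],
        partner_peak_id = best$partner_id,
        overlap_bp = best$overlap_bp,
        frac_query = best$frac_query
      )
    )
  }

  side_a <- classify_side(a, b)
  side_b <- classify_side(b, a)

  a_out <- as_tibble(a) %>%
    mutate(class = if_else(row_number() %in% side_a$co_bound, "co_bound", "a_only"))
  b_out <- as_tibble(b) %>%
    mutate(class = if_else(row_number() %in% side_b$co_bound, "co_bound", "b_only"))

  structure(
    list(
      a = a_out, b = b_out,
      pairs = bind_rows(
        mutate(side_a$pairs, side = "a"),
        mutate(side_b$pairs, side = "b")
      ),
      factor_a = attr(a, "factor_name"), factor_b = attr(b, "factor_name"),
      min_frac = min_frac, min_other_rpm = min_other_rpm
    ),
    class = "overlap_partition"
  )
}

#' @export
print.overlap_partition <- function(x, ...) {
  v <- venn_counts(x)
  cat(sprintf(
    "<overlap_partition> %s vs %s: %d co-bound (A side), %d A-only, %d B-only\n",
    x$factor_a %||% "A", x$factor_b %||% "B", v$co_bound, v$a_only, v$b_only
  ))
  invisible(x)
}

#' Venn counts of an overlap partition
#'
#' Counts are reported in the A-side convention: `co_bound` is the number of
#' co-bound peaks of cistrome A (each co-bound region counted once from the
#' A side), `a_only` / `b_only` are the remaining peaks of each input.
#'
#' @param partition An `overlap_partition` from [overlap_cistromes()].
#' @return One-row tibble with columns `co_bound`, `a_only`, `b_only`.
#' @export
venn_counts <- function(partition) {
  if (!inherits(partition, "overlap_partition")) {
    abort("`partition` must be an overlap_partition.")
  }
  tibble(
    co_bound = sum(partition$a$class == "co_bound"),
    a_only = sum(partition$a$class == "a_only"),
    b_only = sum(partition$b$class == "b_only")
  )
}

#' Fraction of each peak class bound by a third factor
#'
#' For every class of the A/B partition (co-bound, A-only, B-only), computes
#' the fraction of peaks overlapped by a pre-filtered third cistrome `c` by
#' at least `min_frac` of the peak's length, and compares class fractions
#' with Pearson's chi-squared test.
#'
#' @param partition An `overlap_partition` from [overlap_cistromes()].
#' @param c A pre-filtered [cistrome] for the third factor (signal gate and
#'   knockout-artifact filtering applied upstream, see
#'   [filter_ko_artifacts()]).
#' @param min_frac Minimum overlap fraction of the query peak (default 0.5).
#' @return A list with `fractions` (tibble: class, n, n_bound, fraction),
#'   `triple_bound` (peak ids of co-bound A peaks also bound by C), and
#'   `tests` (pairwise chi-squared comparisons against the co-bound class).
#' @export
triple_intersection <- function(partition, c, min_frac = 0.5) {
  if (!inherits(partition, "overlap_partition")) {
    abort("`partition` must be an overlap_partition.")
  }
  if (!inherits(c, "cistrome")) abort("`c` must be a cistrome.")
  classes <- list(
    co_bound = filter(partition$a, .data$class == "co_bound"),
    a_only = filter(partition$a, .data$class == "a_only"),
    b_only = filter(partition$b, .data$class == "b_only")
  )
  if (nrow(classes$co_bound) == 0) abort("the co-bound class is empty.")

  bound_in_c <- function(q) {
    if (!nrow(q)) {
      return(logical(0))
    }
    hits <- overlap_widths(q$chrom, q$start, q$end, c$chrom, c$start, c$end)
    hits <- filter(hits, .data$overlap_bp / (q$end[.data$query] - q$start[.data$query]) >= min_frac)
    seq_len(nrow(q)) %in% hits$query
  }
  bound <- purrr::map(classes, bound_in_c)
  fractions <- tibble(
    class = names(classes),
    n = unname(vapply(bound, length, integer(1))),
    n_bound = unname(vapply(bound, sum, integer(1)))
  ) %>%
    mutate(fraction = .data$n_bound / .data$n)

  test_vs_cobound <- function(other) {
    tab <- rbind(
      c(fractions$n_bound[fractions$class == "co_bound"],
        fractions$n[fractions$class == "co_bound"] - fractions$n_bound[fractions$class == "co_bound"]),
      c(fractions$n_bound[fractions$class == other],
        fractions$n[fractions$class == other] - fractions$n_bound[fractions$class == other])
    )
    res <- pearson_chi2(tab)
    tibble(comparison = paste0("co_bound_vs_", other), chi2 = res$statistic, p_value = res$p_value)
  }
  tests <- bind_rows(lapply(
    fractions$class[fractions$class != "co_bound" & fractions$n > 0],
    test_vs_cobound
  ))

  list(
    fractions = fractions,
    triple_bound = classes$co_bound$peak_id[bound$co_bound],
    tests = tests,
    min_frac = min_frac
  )
}

#' Remove knockout-persistent peaks from a factor's cistrome
#'
#' Peaks of the deleted factor that retain signal in the knockout cannot be
#' specific binding of that factor; any peak whose knockout rpm is at least
#' `max_ko_ratio` of its control rpm is discarded.
#'
#' @param ctl,ko [cistrome]s of the same factor in control and knockout,
#'   matched by `peak_id`.
#' @param max_ko_ratio Maximum tolerated KO/control rpm ratio (default 0.5).
#' @return The control [cistrome] restricted to knockout-validated peaks.
#' @export
filter_ko_artifacts <- function(ctl, ko, max_ko_ratio = 0.5) {
  if (!inherits(ctl, "cistrome") || !inherits(ko, "cistrome")) {
    abort("`ctl` and `ko` must be cistromes.")
  }
  stop_if_not_proportion(max_ko_ratio, "max_ko_ratio")
  ko_rpm <- ko$rpm[match(ctl$peak_id, ko$peak_id)]
  if (anyNA(ko_rpm)) abort("every control peak_id must be present in the knockout cistrome.")
  keep <- ko_rpm < max_ko_ratio * ctl$rpm
  cistrome_keep_attrs(as_tibble(ctl)[keep, , drop = FALSE], ctl)
}

#' Classify peaks as knockout-dependent or unchanged
#'
#' For peaks matched by id across control and knockout conditions, the fold
#' decrease is `(ctl_rpm + pseudocount) / (ko_rpm + pseudocount)`; a peak is
#' `lost` when the decrease reaches `fold` (default twofold).
#'
#' @param ctl,ko [cistrome]s with identical `peak_id` sets.
#' @param fold Fold-decrease threshold (default 2).
#' @param pseudocount rpm pseudocount guarding against empty knockout peaks
#'   (default 0.1).
#' @return A tibble of class `dependency_calls` with columns `peak_id`,
#'   `control_rpm`, `ko_rpm`, `fold_decrease`, `status`
#'   (`"lost"`/`"unchanged"`).
#' @export
classify_dependency <- function(ctl, ko, fold = 2, pseudocount = 0.1) {
  if (!inherits(ctl, "cistrome") || !inherits(ko, "cistrome")) {
    abort("`ctl` and `ko` must be cistromes.")
  }
  stop_if_not_scalar_number(fold, "fold", positive = TRUE)
  stop_if_not_scalar_number(pseudocount, "pseudocount")
  only_ctl <- setdiff(ctl$peak_id, ko$peak_id)
  only_ko <- setdiff(ko$peak_id, ctl$peak_id)
  if (length(only_ctl) || length(only_ko)) {
    abort(sprintf(
      "peak_id(s) present in only one condition: %s.",
      paste(head(c(only_ctl, only_ko), 5L), collapse = ", ")
    ))
  }
  ko_rpm <- ko$rpm[match(ctl$peak_id, ko$peak_id)]
  out <- tibble(
    peak_id = ctl$peak_id,
    chrom = ctl$chrom, start = ctl$start, end = ctl$end,
    control_rpm = ctl$rpm,
    ko_rpm = ko_rpm,
    fold_decrease = (ctl$rpm + pseudocount) / (ko_rpm + pseudocount)
  ) %>%
    mutate(status = if_else(.data$fold_decrease >= fold, "lost", "unchanged"))
  class(out) <- c("dependency_calls", class(out))
  attr(out, "fold") <- fold
  attr(out, "pseudocount") <- pseudocount
  out
}

#' Control-versus-knockout scatter of peak intensities
#'
#' @param object A `dependency_calls` tibble from [classify_dependency()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.dependency_calls <- function(object, ...) {
  fold <- attr(object, "fold") %||% 2
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$control_rpm, y = .data$ko_rpm, colour = .data$status
  )) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_abline(slope = 1 / fold, intercept = 0, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = c(lost = "firebrick", unchanged = "grey50")) +
    ggplot2::labs(x = "control rpm", y = "knockout rpm", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Pearson correlation of two cistromes over their union peak set
#'
#' The union intervals are the merged peaks of both inputs; each cistrome's
#' signal on a union interval is the summed rpm of its peaks overlapping it.
#'
#' @param a,b [cistrome]s.
#' @return One-row tibble with `r`, `n_union`, and the factor labels.
#' @export
correlate_cistromes <- function(a, b) {
  if (!inherits(a, "cistrome") || !inherits(b, "cistrome")) {
    abort("`a` and `b` must be cistromes.")
  }
  all_chrom <- c(a$chrom, b$chrom)
  all_start <- c(a$start, b$start)
  all_end <- c(a$end, b$end)
  union <- purrr::map_dfr(unique(all_chrom), function(ch) {
    i <- which(all_chrom == ch)
    r <- IRanges::reduce(IRanges::IRanges(all_start[i] + 1L, all_end[i]))
    tibble(chrom = ch, start = IRanges::start(r) - 1L, end = IRanges::end(r))
  })
  if (nrow(union) < 3) abort("need >= 3 union peaks to correlate.")
  signal_on <- function(x) {
    hits <- overlap_widths(union$chrom, union$start, union$end, x$chrom, x$start, x$end)
    v <- numeric(nrow(union))
    if (nrow(hits)) {
      agg <- rowsum(x$rpm[hits$subject], group = hits$query)
      v[as.integer(rownames(agg))] <- agg[, 1L]
    }
    v
  }
  va <- signal_on(a)
  vb <- signal_on(b)
  if (sd(va) == 0 || sd(vb) == 0) abort("zero-variance signal vector; correlation undefined.")
  tibble(
    factor_a = attr(a, "factor_name") %||% "A",
    factor_b = attr(b, "factor_name") %||% "B",
    n_union = nrow(union),
    r = cor(va, vb)
  )
}
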