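#' Position weight matrix for motif scanning
#'
#' Stores per-position base probabilities and a background model, and scores
#' windows by log-odds (log2 of motif over background probability). The
#' default hit threshold is a fixed fraction of the matrix's maximal
#' attainable score.
#'
#' @param name Motif name.
#' @param matrix Numeric matrix of base probabilities: either 4 rows named
#'   A/C/G/T (JASPAR orientation) and L >= 4 columns, or the transpose.
#'   Counts are accepted and normalised per position.
#' @param background Length-4 base probabilities (A, C, G, T); default
#'   uniform.
#' @param threshold Log-odds hit threshold in bits; default
#'   `threshold_frac` of the maximal score.
#' @param threshold_frac Fraction of the maximal score used when `threshold`
#'   is `NULL` (default 0.8).
#' @return An object of class `pwm`.
#' @export
pwm <- function(name, matrix, background = rep(0.25, 4), threshold = NULL,
                threshold_frac = 0.8) {
  bases <- c("A", "C", "G", "T")
  m <- as.matrix(matrix)
  if (nrow(m) != 4 && ncol(m) == 4) m <- t(m)
  if (nrow(m) != 4) abort("`matrix` must have 4 rows (or columns) for A/C/G/T.")
  if (is.null(rownames(m))) rownames(m) <- bases
  m <- m[bases, , drop = FALSE]
  if (ncol(m) < 4) abort("a PWM must have length L >= 4.")
  if (any(m < 0)) abort("PWM entries must be >= 0.")
  col_tot <- colSums(m)
  if (any(col_tot <= 0)) abort("every PWM position must have positive total mass.")
  m <- sweep(m, 2L, col_tot, "/")
  colnames(m) <- NULL
  if (length(background) != 4 || abs(sum(background) - 1) > 1e-6) {
    abort("`background` must be 4 probabilities summing to 1.")
  }
  background <- setNames(as.numeric(background), bases)
  eps <- 1e-6 # floor zero probabilities so log-odds stay finite
  logodds <- log2(pmax(m, eps) / background)
  max_score <- sum(apply(logodds, 2L, max))
  structure(
    list(
      name = name, matrix = m, background = background,
      logodds = logodds, max_score = max_score,
      threshold = threshold %||% (threshold_frac * max_score)
    ),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf(
    "<pwm> %s: length %d, max score %.2f bits, threshold %.2f bits\n",
    x$name, ncol(x$matrix), x$max_score, x$threshold
  ))
  invisible(x)
}

#' Consensus sequence of a PWM (highest-probability base per position)
#' @param x A [pwm].
#' @return A character scalar.
#' @export
pwm_consensus <- function(x) {
  if (!inherits(x, "pwm")) abort("`x` must be a pwm.")
  paste(rownames(x$matrix)[apply(x$matrix, 2L, which.max)], collapse = "")
}

#' Built-in toy motifs for the synthetic genome
#'
#' Three idealised liver-factor motifs: a DR1-type direct repeat
#' (HNF4A-like), a DR2-type direct repeat (Rev-erb-like) and a palindromic
#' CCAAT-enhancer-like motif. Each position gives probability `p` to the
#' consensus base. These ship for the synthetic genome; JASPAR files of real
#' motifs are read with [read_jaspar()].
#'
#' @param p Consensus-base probability per position (default 0.85).
#' @return Named list of [pwm] objects.
#' @export
builtin_pwms <- function(p = 0.85) {
  from_consensus <- function(name, consensus) {
    bases <- c("A", "C", "G", "T")
    chars <- strsplit(consensus, "", fixed = TRUE)[[1]]
    m <- vapply(chars, function(ch) {
      if (ch == "N") {
        return(rep(0.25, 4))
      }
      v <- rep((1 - p) / 3, 4)
      v[match(ch, bases)] <- p
      v
    }, numeric(4))
    rownames(m) <- bases
    pwm(name, m)
  }
  list(
    hnf4_dr1 = from_consensus("hnf4_dr1", "AGGTCAAAGGTCA"),
    reverb_dr2 = from_consensus("reverb_dr2", "AGGTCANNAGGTCA"),
    cebp = from_consensus("cebp", "ATTGCGCAAT")
  )
}

REVCOMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp <- function(seq) {
  chars <- rev(strsplit(toupper(seq), "", fixed = TRUE)[[1]])
  paste(unname(REVCOMP[chars]), collapse = "")
}

score_offsets <- function(chars, lo) {
  # log-odds score at every offset of a character vector; N scores -Inf
  L <- ncol(lo)
  n <- length(chars) - L + 1L
  if (n < 1L) {
    return(numeric(0))
  }
  idx <- match(chars, c("A", "C", "G", "T")) # N and others -> NA
  scores <- numeric(n)
  for (k in seq_len(L)) {
    col <- idx[k:(k + n - 1L)]
    s <- unname(lo[, k][col])
    s[is.na(col)] <- -Inf
    scores <- scores + s
  }
  scores
}

#' Scan a sequence window with a PWM
#'
#' Scores every offset on both strands (the reverse complement is scanned
#' right-to-left on the same coordinates) and reports the best hit. Offsets
#' covering an `N` score `-Inf`.
#'
#' @param sequence DNA string over `{A,C,G,T,N}` at least as long as the
#'   motif.
#' @param pwm A [pwm].
#' @return One-row tibble with `pwm`, `best_score`, `position` (1-based
#'   offset of the motif's left edge on the forward strand), `strand`, and
#'   `hit` (`best_score >= threshold`). `best_score` is `-Inf` when no
#'   offset is scorable.
#' @export
scan_window <- function(sequence, pwm) {
  if (!inherits(pwm, "pwm")) abort("`pwm` must be a pwm object.")
  if (!is.character(sequence) || length(sequence) != 1L) {
    abort("`sequence` must be a single string.")
  }
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), c("A", "C", "G", "T", "N"))
  if (length(bad)) {
    abort(sprintf("sequence contains non-DNA character(s): %s.", paste(bad, collapse = ", ")))
  }
  L <- ncol(pwm$matrix)
  if (length(chars) < L) {
    abort(sprintf("window (%d bp) is shorter than the motif (%d bp).", length(chars), L))
  }
  fwd <- score_offsets(chars, pwm$logodds)
  rc <- rev(unname(REVCOMP[chars]))
  rev_scores <- score_offsets(rc, pwm$logodds)
  # offset i on the reverse complement corresponds to forward-left-edge
  # position n - L - i + 2
  n <- length(chars)
  both <- tibble(
    score = c(fwd, rev_scores),
    position = c(seq_along(fwd), n - L + 2L - seq_along(rev_scores)),
    strand = rep(c("+", "-"), c(length(fwd), length(rev_scores)))
  ) %>%
    arrange(dplyr::desc(.data$score), .data$position, .data$strand)
  best <- both[1L, ]
  pwm_name <- pwm$name
  thr <- pwm$threshold
  tibble(
    pwm = pwm_name,
    best_score = best$score,
    position = best$position,
    strand = best$strand,
    hit = is.finite(best$score) & best$score >= thr
  )
}

extract_window <- function(genome, chrom, start, end) {
  # genome: named character of chromosome sequences; 0-based half-open coords
  seq_len_chr <- nchar(genome[[chrom]])
  s <- max(0L, start)
  e <- min(seq_len_chr, end)
  substring(genome[[chrom]], s + 1L, e)
}

#' Motif hit frequency in a peak class
#'
#' Extracts a fixed window centred on each peak midpoint, scans it with the
#' PWM on both strands, and reports the fraction of peaks with a hit.
#' Windows running past a chromosome end are clipped with a warning.
#'
#' @param peaks Data frame with `peak_id`, `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param genome Named character vector of chromosome sequences (or a
#'   `Biostrings::DNAStringSet`).
#' @param pwm A [pwm].
#' @param window_width Scan window width in bp, centred on the peak midpoint
#'   (default 200).
#' @return One-row tibble with `pwm`, `n`, `hits`, `fraction`.
#' @export
motif_frequency <- function(peaks, genome, pwm, window_width = 200L) {
  peaks <- as_tibble(peaks)
  require_columns(peaks, c("peak_id", "chrom", "start", "end"), "peaks")
  if (!nrow(peaks)) abort("`peaks` must be non-empty.")
  if (methods::is(genome, "DNAStringSet")) genome <- as.character(genome)
  stop_if_not_count(window_width, "window_width")

  mid <- (peaks$start + peaks$end) %/% 2L
  w_start <- mid - window_width %/% 2L
  w_end <- w_start + window_width
  chr_len <- nchar(genome)[match(peaks$chrom, names(genome))]
  if (anyNA(chr_len)) {
    abort(sprintf(
      "peak chromosome(s) absent from genome: %s.",
      paste(unique(peaks$chrom[is.na(chr_len)]), collapse = ", ")
    ))
  }
  clipped <- w_start < 0 | w_end > chr_len
  if (any(clipped)) {
    warning(sprintf("%d window(s) clipped at chromosome bounds.", sum(clipped)))
  }
  hits <- vapply(seq_len(nrow(peaks)), function(i) {
    win <- extract_window(genome, peaks$chrom[i], w_start[i], w_end[i])
    scan_window(win, pwm)$hit
  }, logical(1))
  pwm_name <- pwm$name
  n_hits <- sum(hits)
  tibble(
    pwm = pwm_name, n = nrow(peaks), hits = n_hits,
    fraction = n_hits / nrow(peaks)
  )
}

#' Compare motif frequency between two peak classes
#'
#' Builds the 2x2 hits/non-hits by class table and applies Pearson's
#' chi-squared test (no continuity correction). When any expected cell falls
#' below 1 the test switches to Fisher's exact test with a warning.
#'
#' @param class_a,class_b Data frames of peaks (as in [motif_frequency()]).
#' @param genome Named character vector of chromosome sequences.
#' @param pwm A [pwm].
#' @param window_width Scan window in bp (default 200).
#' @param labels Length-2 class labels used in the output.
#' @return One-row tibble with both frequencies, `chi2`, `df`, `p_value`,
#'   and `method` (`"pearson_chi2"` or `"fisher_exact"`).
#' @export
compare_motif_enrichment <- function(class_a, class_b, genome, pwm,
                                     window_width = 200L,
                                     labels = c("class_a", "class_b")) {
  fa <- motif_frequency(class_a, genome, pwm, window_width)
  fb <- motif_frequency(class_b, genome, pwm, window_width)
  motif_count_test(
    hits_a = fa$hits, n_a = fa$n, hits_b = fb$hits, n_b = fb$n,
    pwm_name = pwm$name, labels = labels
  )
}

#' @rdname compare_motif_enrichment
#' @param hits_a,n_a,hits_b,n_b Hit counts and class sizes when frequencies
#'   were computed already.
#' @param pwm_name Motif label for the output.
#' @export
motif_count_test <- function(hits_a, n_a, hits_b, n_b, pwm_name = NA_character_,
                             labels = c("class_a", "class_b")) {
  if (n_a < 1 || n_b < 1) abort("both classes must be non-empty.")
  tab <- rbind(c(hits_a, n_a - hits_a), c(hits_b, n_b - hits_b))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 1)) {
    warning("expected cell < 1; using Fisher's exact test.")
    ft <- fisher.test(tab)
    stat <- NA_real_
    p <- ft$p.value
    method <- "fisher_exact"
  } else {
    res <- pearson_chi2(tab)
    stat <- res$statistic
    p <- res$p_value
    method <- "pearson_chi2"
  }
  tibble(
    pwm = pwm_name,
    class_a = labels[1], class_b = labels[2],
    n_a = n_a, hits_a = hits_a, fraction_a = hits_a / n_a,
    n_b = n_b, hits_b = hits_b, fraction_b = hits_b / n_b,
    chi2 = stat, df = 1L, p_value = p, method = method
  )
}
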