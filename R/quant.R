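#' Protein quantification matrix
#'
#' A light container for protein-by-sample quantifications as they move
#' through the scoring chain: raw iBAQ values (`stage = "raw_ibaq"`),
#' log2-transformed median-centred values (`"log2_median"`), and fully
#' imputed values (`"imputed"`). The observed/missing mask from the raw stage
#' travels with the object so detection-based flags remain available after
#' imputation.
#'
#' @param values Numeric matrix, proteins in rows (rownames = protein ids),
#'   samples in columns (colnames = sample ids); `NA` marks a missing cell.
#' @param samples Data frame with one row per column of `values`: columns
#'   `sample_id`, `condition` (`"bait"`/`"control"`) and `nuclease`
#'   (`"none"`/`"mnase"`/`"benzonase"`).
#' @param stage One of `"raw_ibaq"`, `"log2_median"`, `"imputed"`.
#' @param observed Logical matrix marking originally observed cells; defaults
#'   to `!is.na(values)`.
#' @return An object of class `protein_quant`.
#' @export
protein_quant <- function(values, samples,
                          stage = c("raw_ibaq", "log2_median", "imputed"),
                          observed = NULL) {
  stage <- match.arg(stage)
  if (!is.matrix(values) || !is.numeric(values)) abort("`values` must be a numeric matrix.")
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must have protein ids as rownames and sample ids as colnames.")
  }
  samples <- as_tibble(samples)
  require_columns(samples, c("sample_id", "condition", "nuclease"), "samples")
  if (!identical(colnames(values), samples$sample_id)) {
    abort("colnames(values) must equal samples$sample_id, in order.")
  }
  observed <- observed %||% !is.na(values)
  if (stage == "imputed" && anyNA(values)) {
    abort("an `imputed` matrix cannot contain missing values.")
  }
  structure(
    list(values = values, samples = samples, stage = stage, observed = observed),
    class = "protein_quant"
  )
}

#' @export
print.protein_quant <- function(x, ...) {
  cat(sprintf(
    "<protein_quant> %d proteins x %d samples, stage '%s' (%.1f%% observed)\n",
    nrow(x$values), ncol(x$values), x$stage, 100 * mean(x$observed)
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.protein_quant <- function(x, ...) {
  as_tibble(x$values, rownames = "protein_id") %>%
    tidyr::pivot_longer(-"protein_id", names_to = "sample_id", values_to = "value") %>%
    left_join(x$samples, by = "sample_id")
}

#' iBAQ quantification from a peptide table
#'
#' Collapses peptide-level intensities to protein-level iBAQ values: per
#' protein and sample, the sum of observed peptide intensities divided by the
#' protein's count of theoretical (tryptic, length-windowed) peptides. Cells
#' with no observed peptide are missing.
#'
#' @param peptides Data frame with columns `protein_id`, `peptide`,
#'   `sample_id`, `condition`, `nuclease`, `intensity` (`NA` or empty =
#'   missing observation).
#' @param digests Data frame with columns `protein_id`, `n_theoretical`
#'   (counts must be >= 1), e.g. from [theoretical_peptide_counts()].
#' @return A [protein_quant] at stage `"raw_ibaq"`.
#' @export
compute_ibaq <- function(peptides, digests) {
  peptides <- as_tibble(peptides)
  require_columns(
    peptides,
    c("protein_id", "peptide", "sample_id", "condition", "nuclease", "intensity"),
    "peptides"
  )
  digests <- as_tibble(digests)
  require_columns(digests, c("protein_id", "n_theoretical"), "digests")

  prot_ids <- unique(peptides$protein_id)
  denom <- digests$n_theoretical[match(prot_ids, digests$protein_id)]
  if (anyNA(denom)) {
    abort(sprintf(
      "no digest count for protein(s): %s.",
      paste(head(prot_ids[is.na(denom)], 5L), collapse = ", ")
    ))
  }
  if (any(denom < 1)) {
    abort(sprintf(
      "digest count of 0 leaves iBAQ undefined for protein(s): %s.",
      paste(head(prot_ids[denom < 1], 5L), collapse = ", ")
    ))
  }

  samples <- peptides %>%
    distinct(.data$sample_id, .data$condition, .data$nuclease) %>%
    arrange(.data$sample_id)
  if (anyDuplicated(samples$sample_id)) {
    abort("inconsistent condition/nuclease annotation within a sample_id.")
  }

  obs <- peptides %>% filter(!is.na(.data$intensity))
  if (any(obs$intensity <= 0)) abort("observed intensities must be > 0.")
  i <- match(obs$protein_id, prot_ids)
  j <- match(obs$sample_id, samples$sample_id)
  sums <- matrix(0, length(prot_ids), nrow(samples),
    dimnames = list(prot_ids, samples$sample_id)
  )
  seen <- matrix(FALSE, length(prot_ids), nrow(samples),
    dimnames = dimnames(sums)
  )
  idx <- cbind(i, j)
  agg <- rowsum(obs$intensity, group = (j - 1L) * length(prot_ids) + i)
  sums[as.integer(rownames(agg))] <- agg[, 1L]
  seen[idx] <- TRUE

  values <- sums / denom
  values[!seen] <- NA_real_
  protein_quant(values, samples, stage = "raw_ibaq")
}

#' Log2 transform and per-sample median centring
#'
#' Each observed cell becomes `log2(value) - median(log2 values observed in
#' its sample)`, so every sample's observed median is exactly zero. Missing
#' cells stay missing.
#'
#' @param m A [protein_quant] at stage `"raw_ibaq"`.
#' @return A [protein_quant] at stage `"log2_median"`.
#' @export
log2_median_normalize <- function(m) {
  if (!inherits(m, "protein_quant")) abort("`m` must be a protein_quant.")
  if (m$stage != "raw_ibaq") abort("`m` must be at stage 'raw_ibaq'.")
  v <- log2(m$values)
  n_obs <- colSums(!is.na(v))
  if (any(n_obs == 0)) {
    abort(sprintf(
      "sample(s) with zero observed values: %s.",
      paste(colnames(v)[n_obs == 0], collapse = ", ")
    ))
  }
  med <- apply(v, 2L, median, na.rm = TRUE)
  v <- sweep(v, 2L, med)
  protein_quant(v, m$samples, stage = "log2_median", observed = m$observed)
}

#' Downshifted-Gaussian imputation of missing values
#'
#' Implements the left-censored missing-value imputation idiom used for
#' affinity-purification proteomics: per sample, missing cells are drawn from
#' `Normal(mu - downshift * sigma, (width * sigma)^2)` where `mu` and `sigma`
#' are the mean and standard deviation of that sample's observed values.
#' The defaults (width 0.25, downshift 2.0) place imputed values in the low
#' tail of the intensity distribution, which is where MNAR (missing not at
#' random) observations are expected to lie.
#'
#' @param m A [protein_quant] at stage `"log2_median"`.
#' @param width Spread of the imputation distribution in units of the sample
#'   standard deviation.
#' @param downshift Location shift below the sample mean, in standard
#'   deviations.
#' @param seed Integer seed; the draw is fully reproducible.
#' @param per_sample If `TRUE` (default) `mu`/`sigma` are column-wise; if
#'   `FALSE` they are taken from the pooled observed distribution of the
#'   whole matrix.
#' @return A [protein_quant] at stage `"imputed"`.
#' @export
impute_missing <- function(m, width = 0.25, downshift = 2.0, seed = 1L,
                           per_sample = TRUE) {
  if (!inherits(m, "protein_quant")) abort("`m` must be a protein_quant.")
  if (m$stage != "log2_median") abort("`m` must be at stage 'log2_median'.")
  stop_if_not_scalar_number(width, "width")
  if (width < 0) abort("`width` must be >= 0.")
  stop_if_not_scalar_number(downshift, "downshift")

  v <- m$values
  n_obs <- colSums(!is.na(v))
  if (per_sample && any(n_obs < 2)) {
    abort(sprintf(
      "sample(s) with < 2 observed values (sigma undefined): %s.",
      paste(colnames(v)[n_obs < 2], collapse = ", ")
    ))
  }
  if (!per_sample && sum(n_obs) < 2) abort("fewer than 2 observed values in total.")

  with_stage_seed(seed, 0, {
    for (j in seq_len(ncol(v))) {
      miss <- is.na(v[, j])
      if (!any(miss)) next
      if (per_sample) {
        mu <- mean(v[, j], na.rm = TRUE)
        sigma <- sd(v[, j], na.rm = TRUE)
      } else {
        mu <- mean(v, na.rm = TRUE)
        sigma <- sd(v, na.rm = TRUE)
      }
      v[miss, j] <- rnorm(sum(miss), mean = mu - downshift * sigma, sd = width * sigma)
    }
  })
  protein_quant(v, m$samples, stage = "imputed", observed = m$observed)
}
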