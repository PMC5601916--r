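# File adapters. All tabular output is TSV with a header row; '#' lines are
# comments (used to record the seed in synthetic outputs). BED is strictly
# 0-based half-open; 1-based closed interval tables convert at the boundary
# with convert_one_based().

write_tsv_commented <- function(df, path, comments = character()) {
  if (length(comments)) {
    readr::write_lines(paste0("# ", comments), path)
    readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  } else {
    readr::write_tsv(df, path)
  }
  invisible(path)
}

#' Read and write the peptide-level intensity table
#'
#' Columns are exactly `protein_id`, `peptide`, `sample_id`, `condition`,
#' `nuclease`, `intensity`; an empty intensity field means a missing
#' observation.
#'
#' @param path File path.
#' @param peptides Tibble as produced by [simulate_proteomics()].
#' @param comments Character lines written as leading `#` comments.
#' @return `read_peptides_tsv()` returns the tibble; writers return the path
#'   invisibly.
#' @export
read_peptides_tsv <- function(path) {
  df <- readr::read_tsv(path,
    comment = "#", show_col_types = FALSE,
    col_types = readr::cols(
      protein_id = "c", peptide = "c", sample_id = "c",
      condition = "c", nuclease = "c", intensity = "d"
    )
  )
  require_columns(
    df, c("protein_id", "peptide", "sample_id", "condition", "nuclease", "intensity"),
    path
  )
  df
}

#' @rdname read_peptides_tsv
#' @export
write_peptides_tsv <- function(peptides, path, comments = character()) {
  write_tsv_commented(peptides, path, comments)
}

#' Read and write FASTA sequence files
#'
#' Thin wrappers over Biostrings returning plain named character vectors.
#'
#' @param path File path.
#' @param seqs Named character vector of sequences.
#' @param type `"AA"` or `"DNA"`.
#' @return `read_fasta()` returns a named character vector.
#' @export
read_fasta <- function(path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  set <- if (type == "AA") {
    Biostrings::readAAStringSet(path)
  } else {
    Biostrings::readDNAStringSet(path)
  }
  setNames(as.character(set), names(set))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  set <- if (type == "AA") Biostrings::AAStringSet(seqs) else Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' Read and write BED6 interval files
#'
#' BED is 0-based half-open. `read_bed()` validates every line and reports
#' the file and line number of the first malformed record.
#'
#' @param path File path.
#' @param df Data frame with `chrom`, `start`, `end`, plus columns for name,
#'   score and strand.
#' @param name_col,score_col,strand_col Columns written to BED fields 4-6
#'   (defaults: `peak_id`, a constant 0 score, `strand`).
#' @return `read_bed()` returns a tibble with columns `chrom`, `start`,
#'   `end`, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  lines <- readr::read_lines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  line_no <- which(keep)
  n_fields <- lengths(fields)
  if (any(n_fields < 3)) {
    abort(sprintf("%s:%d: BED line has fewer than 3 fields.", path, line_no[which(n_fields < 3)[1]]))
  }
  get <- function(i, default = NA_character_) {
    vapply(fields, function(f) if (length(f) >= i) f[i] else default, character(1))
  }
  start <- suppressWarnings(as.numeric(get(2)))
  end <- suppressWarnings(as.numeric(get(3)))
  bad <- is.na(start) | is.na(end) | start < 0 | start >= end
  if (any(bad)) {
    abort(sprintf(
      "%s:%d: malformed BED interval (need 0 <= start < end).",
      path, line_no[which(bad)[1]]
    ))
  }
  tibble(
    chrom = get(1), start = as.integer(start), end = as.integer(end),
    name = get(4), score = suppressWarnings(as.numeric(get(5, "0"))),
    strand = get(6, ".")
  )
}

#' @rdname read_bed
#' @export
write_bed <- function(df, path, name_col = "peak_id", score_col = NULL,
                      strand_col = "strand") {
  require_columns(df, c("chrom", "start", "end"), "df")
  name <- if (!is.null(name_col) && name_col %in% names(df)) df[[name_col]] else "."
  score <- if (!is.null(score_col) && score_col %in% names(df)) df[[score_col]] else 0
  strand <- if (!is.null(strand_col) && strand_col %in% names(df)) df[[strand_col]] else "."
  out <- tibble(
    chrom = df$chrom, start = df$start, end = df$end,
    name = name, score = score, strand = strand
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Convert 1-based closed intervals to 0-based half-open
#'
#' `[1, 100]` (1-based closed) becomes `[0, 100)`.
#'
#' @param df Data frame with `start` and `end` columns.
#' @return The data frame with `start` decremented.
#' @export
convert_one_based <- function(df) {
  require_columns(df, c("start", "end"), "df")
  df$start <- df$start - 1L
  if (any(df$start < 0) || any(df$start >= df$end)) {
    abort("intervals are not valid 1-based closed coordinates.")
  }
  df
}

#' Read and write per-peak signal tables
#'
#' Companion TSV to a peak BED: columns `peak_id`, `reads`, `library_size`,
#' `input_reads` (plus optional `input_library_size`).
#'
#' @param path File path.
#' @param cis A [cistrome].
#' @param comments Leading `#` comment lines.
#' @return `read_signal_tsv()` returns the tibble.
#' @export
read_signal_tsv <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  require_columns(df, c("peak_id", "reads", "library_size", "input_reads"), path)
  df
}

#' @rdname read_signal_tsv
#' @export
write_signal_tsv <- function(cis, path, comments = character()) {
  write_tsv_commented(
    tibble(
      peak_id = cis$peak_id, reads = cis$reads,
      library_size = attr(cis, "library_size"),
      input_reads = cis$input_reads,
      input_library_size = attr(cis, "input_library_size")
    ),
    path, comments
  )
}

#' Assemble a cistrome from a BED file and its signal table
#'
#' @param bed_path,signal_path Paths to the BED6 peak file and companion
#'   signal TSV.
#' @param factor_name,condition Labels for the cistrome.
#' @param genome Optional named chromosome lengths for validation.
#' @return A [cistrome].
#' @export
read_cistrome <- function(bed_path, signal_path, factor_name, condition,
                          genome = NULL) {
  bed <- read_bed(bed_path)
  sig <- read_signal_tsv(signal_path)
  peaks <- bed %>%
    rename(peak_id = "name") %>%
    inner_join(sig, by = "peak_id")
  if (nrow(peaks) != nrow(bed)) abort("signal table does not cover every BED peak.")
  lib <- unique(sig$library_size)
  if (length(lib) != 1) abort("library_size must be constant within one signal table.")
  input_lib <- if ("input_library_size" %in% names(sig)) unique(sig$input_library_size) else lib
  cistrome(
    select(peaks, "peak_id", "chrom", "start", "end", "strand", "reads", "input_reads"),
    factor_name = factor_name, condition = condition,
    library_size = lib, input_library_size = input_lib[1], genome = genome
  )
}

#' Read and write JASPAR-format PWM text
#'
#' The plain-text JASPAR layout: a `>name` header followed by four rows
#' `A [ ... ]`, `C [ ... ]`, `G [ ... ]`, `T [ ... ]` of per-position counts
#' or probabilities.
#'
#' @param path File path.
#' @param pwms A list of [pwm] objects.
#' @param ... Passed to [pwm()] (e.g. `threshold_frac`).
#' @return `read_jaspar()` returns a named list of [pwm] objects.
#' @export
read_jaspar <- function(path, ...) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  headers <- grep("^>", lines)
  if (!length(headers)) abort(sprintf("%s: no JASPAR '>' headers found.", path))
  out <- list()
  for (h in seq_along(headers)) {
    i <- headers[h]
    name <- sub("^>\\s*", "", lines[i])
    name <- strsplit(name, "\\s+")[[1]][1]
    block <- lines[(i + 1):min(i + 4, length(lines))]
    if (length(block) < 4) abort(sprintf("%s: motif '%s' lacks 4 base rows.", path, name))
    rows <- lapply(block, function(l) {
      nums <- regmatches(l, gregexpr("-?[0-9.]+", l))[[1]]
      as.numeric(nums)
    })
    bases <- toupper(substr(trimws(block), 1, 1))
    if (!setequal(bases, c("A", "C", "G", "T"))) {
      abort(sprintf("%s: motif '%s' rows must be labelled A/C/G/T.", path, name))
    }
    m <- do.call(rbind, rows)
    rownames(m) <- bases
    out[[name]] <- pwm(name, m[c("A", "C", "G", "T"), , drop = FALSE], ...)
  }
  out
}

#' @rdname read_jaspar
#' @export
write_jaspar <- function(pwms, path) {
  fmt <- function(x) paste(sprintf("%.6g", x), collapse = " ")
  lines <- unlist(lapply(pwms, function(p) {
    c(
      paste0(">", p$name),
      sprintf("A [ %s ]", fmt(p$matrix["A", ])),
      sprintf("C [ %s ]", fmt(p$matrix["C", ])),
      sprintf("G [ %s ]", fmt(p$matrix["G", ])),
      sprintf("T [ %s ]", fmt(p$matrix["T", ]))
    )
  }))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read and write gene model tables
#'
#' TSV with columns `chrom`, `start`, `end`, `strand`, `gene_id`
#' (0-based half-open).
#'
#' @param path File path.
#' @param genes Gene-model tibble.
#' @param comments Leading `#` comment lines.
#' @return `read_gene_models()` returns the tibble.
#' @export
read_gene_models <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  check_gene_models(df)
}

#' @rdname read_gene_models
#' @export
write_gene_models <- function(genes, path, comments = character()) {
  write_tsv_commented(
    select(check_gene_models(genes), "chrom", "start", "end", "strand", "gene_id"),
    path, comments
  )
}

#' Read and write count matrices
#'
#' TSV with a `gene_id` column and one integer column per sample.
#'
#' @param path File path.
#' @param counts Count tibble.
#' @param comments Leading `#` comment lines.
#' @return `read_counts_tsv()` returns the tibble.
#' @export
read_counts_tsv <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  require_columns(df, "gene_id", path)
  df
}

#' @rdname read_counts_tsv
#' @export
write_counts_tsv <- function(counts, path, comments = character()) {
  write_tsv_commented(counts, path, comments)
}
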