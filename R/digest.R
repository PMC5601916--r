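#' In-silico tryptic digestion of a protein sequence
#'
#' Cleaves a protein C-terminal to lysine (K) or arginine (R), except when the
#' next residue is proline (P), with zero missed cleavages -- the classic
#' trypsin rule. The number of resulting peptides inside a length window is
#' the denominator of iBAQ quantification (summed peptide intensity divided
#' by the count of theoretically observable peptides).
#'
#' @param sequence Single amino-acid string over the 20-letter alphabet.
#' @param min_len,max_len Peptide length window retained (defaults 6--30
#'   residues, the conventional observable range for bottom-up proteomics).
#' @return Character vector of theoretical peptides with
#'   `min_len <= nchar <= max_len`, in N- to C-terminal order.
#' @examples
#' digest_protein("MKWVTFISLLFLFSSAYSRGVFRRDAHK", min_len = 2, max_len = 30)
#' @export
digest_protein <- function(sequence, min_len = 6L, max_len = 30L) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence)) {
    abort("`sequence` must be a single non-empty string.")
  }
  stop_if_not_count(min_len, "min_len")
  stop_if_not_count(max_len, "max_len")
  if (min_len > max_len) abort("`min_len` must be <= `max_len`.")

  aa <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(aa), AMINO_ACIDS)
  if (length(bad)) {
    abort(sprintf(
      "`sequence` contains non-amino-acid character(s): %s.",
      paste(bad, collapse = ", ")
    ))
  }

  n <- length(aa)
  # cut after position i when aa[i] is K/R and aa[i+1] is not P
  cut_after <- which(aa %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & aa[cut_after + 1L] != "P"]
  starts <- c(1L, cut_after + 1L)
  ends <- c(cut_after, n)
  peptides <- substring(paste(aa, collapse = ""), starts, ends)
  keep <- nchar(peptides) >= min_len & nchar(peptides) <= max_len
  peptides[keep]
}

AMINO_ACIDS <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

#' Count theoretical peptides per protein
#'
#' @param proteins Named character vector of amino-acid sequences, or a data
#'   frame with columns `protein_id` and `sequence`.
#' @inheritParams digest_protein
#' @return A tibble with columns `protein_id` and `n_theoretical`.
#' @export
theoretical_peptide_counts <- function(proteins, min_len = 6L, max_len = 30L) {
  if (is.data.frame(proteins)) {
    require_columns(proteins, c("protein_id", "sequence"), "proteins")
    ids <- proteins$protein_id
    seqs <- proteins$sequence
  } else {
    if (is.null(names(proteins))) abort("`proteins` must be named by protein_id.")
    ids <- names(proteins)
    seqs <- unname(proteins)
  }
  tibble(
    protein_id = ids,
    n_theoretical = vapply(
      seqs,
      function(s) length(digest_protein(s, min_len, max_len)),
      integer(1), USE.NAMES = FALSE
    )
  )
}
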