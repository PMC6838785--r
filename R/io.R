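# Readers/writers for the external table formats. Pair tables use the
# header `Annotation,HLA,peptide[,label]`; internally columns are
# annotation/allele/peptide/label.

#' Read an HLA-peptide pair table
#'
#' @param path CSV file with header `Annotation,HLA,peptide` and optional
#'   `label`.
#' @return A tibble with columns `annotation`, `allele`, `peptide` and, if
#'   present in the file, `label`.
#' @export
read_pair_table <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("Annotation", "HLA", "peptide")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0L) {
    abort(sprintf("pair table missing column(s): %s", paste(miss, collapse = ", ")))
  }
  out <- tibble(annotation = as.character(d$Annotation),
                allele = as.character(d$HLA),
                peptide = as.character(d$peptide))
  if ("label" %in% names(d)) out$label <- as.numeric(d$label)
  out
}

#' @rdname read_pair_table
#' @param pairs Tibble with columns `annotation`, `allele`, `peptide` and
#'   optionally `label`.
#' @export
write_pair_table <- function(pairs, path) {
  out <- tibble(Annotation = pairs$annotation, HLA = pairs$allele,
                peptide = pairs$peptide)
  if ("label" %in% names(pairs)) out$label <- pairs$label
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a protein FASTA file
#'
#' @param path Multi-FASTA file of amino-acid sequences.
#' @return A named character vector, one element per protein; names are the
#'   first whitespace-delimited token of each FASTA header.
#' @export
read_proteome <- function(path) {
  rlang::check_installed("Biostrings")
  seqs <- Biostrings::readAAStringSet(path)
  out <- as.character(seqs)
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' @rdname read_proteome
#' @param proteome Named character vector of protein sequences.
#' @export
write_proteome <- function(proteome, path) {
  rlang::check_installed("Biostrings")
  x <- Biostrings::AAStringSet(proteome)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read mutation and patient-HLA tables
#'
#' The mutation CSV has columns
#' `mutation_id,patient_id,protein_id,position,ref,alt,tpm` (tpm may be
#' empty); the patient-HLA CSV has `patient_id,allele`.
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_mutations <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         position = readr::col_integer(),
                         tpm = readr::col_double(),
                         .default = readr::col_character()
                       ))
  need <- c("mutation_id", "patient_id", "protein_id", "position", "ref", "alt")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0L) {
    abort(sprintf("mutation table missing column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  if (!"tpm" %in% names(d)) d$tpm <- NA_real_
  as_tibble(d)
}

#' @rdname read_mutations
#' @export
read_patient_hla <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  miss <- setdiff(c("patient_id", "allele"), names(d))
  if (length(miss) > 0L) {
    abort(sprintf("patient-HLA table missing column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  as_tibble(d[, c("patient_id", "allele")])
}
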