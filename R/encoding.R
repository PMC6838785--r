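#' @importFrom rlang .data abort warn
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>%
NULL

# Fixed residue alphabet: the 20 standard amino acids in alphabetical order,
# with the padding symbol "X" last (index 21). Every one-hot row follows this
# ordering; changing it invalidates saved models.
AA_RESIDUES <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)
PAD_SYMBOL <- "X"
ALPHABET <- c(AA_RESIDUES, PAD_SYMBOL)

PSEUDO_LEN <- 34L  # binding-groove contact residues per allele
PEP_MAX <- 15L     # class I ligand length range handled by the encoder
PEP_MIN <- 8L
SEQ_LEN <- PSEUDO_LEN + PEP_MAX  # 49 positions per encoded pair

#' The residue alphabet used for one-hot encoding
#'
#' Returns the fixed 21-symbol alphabet: the 20 standard amino acids in
#' alphabetical order followed by the padding symbol `"X"`. Row `i` of every
#' encoded matrix is the one-hot indicator of the residue at position `i`
#' under this ordering.
#'
#' @return A character vector of length 21.
#' @export
#' @examples
#' aa_alphabet()
aa_alphabet <- function() ALPHABET

aa_index <- function(chars) {
  idx <- match(chars, ALPHABET)
  if (anyNA(idx)) {
    bad <- unique(chars[is.na(idx)])
    abort(sprintf("illegal residue(s): %s", paste(bad, collapse = ", ")))
  }
  idx
}

split_residues <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

assert_peptide <- function(peptide) {
  n <- nchar(peptide)
  if (n < PEP_MIN || n > PEP_MAX) {
    abort(sprintf("peptide '%s' has length %d; must be %d-%d",
                  peptide, n, PEP_MIN, PEP_MAX))
  }
  ch <- split_residues(peptide)
  if (!all(ch %in% AA_RESIDUES)) {
    abort(sprintf("peptide '%s' contains non-standard residues", peptide))
  }
  invisible(peptide)
}

#' Load an HLA allele to pseudo-sequence table
#'
#' Reads a two-column, headerless TSV mapping HLA allele names (e.g.
#' `HLA-A*02:01`) to their 34-residue binding-groove pseudo-sequence, the
#' fixed-length reduction that makes a single model applicable across
#' alleles (pan-allele prediction).
#'
#' @param path Path to a TSV file with columns: allele name, 34-residue
#'   amino-acid string. No header.
#' @return A tibble with columns `allele` and `pseudo`.
#' @export
load_pseudo_sequences <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) abort("pseudo-sequence table is empty")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) != 2L) {
      abort(sprintf("line %d: expected 2 tab-separated fields, got %d",
                    i, length(p)))
    }
    if (nchar(p[2]) != PSEUDO_LEN) {
      abort(sprintf("line %d: pseudo-sequence has length %d; must be %d",
                    i, nchar(p[2]), PSEUDO_LEN))
    }
    if (!all(split_residues(p[2]) %in% AA_RESIDUES)) {
      abort(sprintf("line %d: pseudo-sequence contains non-standard residues", i))
    }
  }
  tab <- tibble(
    allele = vapply(parts, `[[`, character(1), 1L),
    pseudo = vapply(parts, `[[`, character(1), 2L)
  )
  dup <- tab$allele[duplicated(tab$allele)]
  if (length(dup) > 0L) {
    abort(sprintf("duplicate allele name(s): %s",
                  paste(unique(dup), collapse = ", ")))
  }
  tab
}

pseudo_lookup <- function(allele, table) {
  i <- match(allele, table$allele)
  if (is.na(i)) abort(sprintf("unknown allele '%s'", allele))
  table$pseudo[i]
}

#' One-hot encode an HLA-peptide pair
#'
#' Concatenates the allele's 34-residue pseudo-sequence with the peptide,
#' right-pads the peptide with the pseudo-residue `"X"` to 15 positions, and
#' one-hot encodes the resulting 49 symbols over the 21-letter alphabet.
#' The pseudo-sequence always occupies rows 1-34 and the peptide rows 35
#' onward, so every pair maps to a fixed 49 x 21 binary matrix.
#'
#' @param peptide An 8-15-mer amino-acid string.
#' @param allele HLA allele name present in `table`.
#' @param table Pseudo-sequence table from [load_pseudo_sequences()].
#' @return A 49 x 21 one-hot matrix with attributes `allele` and `peptide`.
#' @seealso [decode_pair()]
#' @export
encode_pair <- function(peptide, allele, table) {
  assert_peptide(peptide)
  pseudo <- pseudo_lookup(allele, table)
  chars <- c(split_residues(pseudo), split_residues(peptide),
             rep(PAD_SYMBOL, PEP_MAX - nchar(peptide)))
  m <- matrix(0L, nrow = SEQ_LEN, ncol = length(ALPHABET),
              dimnames = list(NULL, ALPHABET))
  m[cbind(seq_len(SEQ_LEN), aa_index(chars))] <- 1L
  attr(m, "allele") <- allele
  attr(m, "peptide") <- peptide
  m
}

#' Decode a one-hot encoded pair
#'
#' Inverse of [encode_pair()]: recovers the pseudo-sequence and the peptide
#' (padding stripped) from a 49 x 21 one-hot matrix.
#'
#' @param e A 49 x 21 one-hot matrix.
#' @return A list with elements `pseudo` and `peptide`.
#' @export
decode_pair <- function(e) {
  if (!is.matrix(e) || nrow(e) != SEQ_LEN || ncol(e) != length(ALPHABET)) {
    abort(sprintf("expected a %d x %d matrix", SEQ_LEN, length(ALPHABET)))
  }
  if (!all(rowSums(e != 0) == 1L) || !all(e %in% c(0L, 1L))) {
    abort("matrix is not one-hot: every row must have exactly one 1")
  }
  chars <- ALPHABET[max.col(e)]
  pseudo <- paste(chars[seq_len(PSEUDO_LEN)], collapse = "")
  pep_chars <- chars[(PSEUDO_LEN + 1L):SEQ_LEN]
  pad <- pep_chars == PAD_SYMBOL
  if (any(pad) && any(!pad[seq(which.max(pad), length(pad))])) {
    abort("padding symbols interleaved with peptide residues")
  }
  list(pseudo = pseudo, peptide = paste(pep_chars[!pad], collapse = ""))
}

# Encode many pairs into a [n, 49, 21] array for batched network input.
encode_batch <- function(peptides, alleles, table) {
  n <- length(peptides)
  stopifnot(length(alleles) == n)
  x <- array(0, dim = c(n, SEQ_LEN, length(ALPHABET)))
  pseudo_cache <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    key <- alleles[i]
    idx_pseudo <- if (!is.null(pseudo_cache[[key]])) {
      pseudo_cache[[key]]
    } else {
      pseudo_cache[[key]] <- aa_index(split_residues(pseudo_lookup(key, table)))
    }
    assert_peptide(peptides[i])
    idx <- c(idx_pseudo,
             aa_index(split_residues(peptides[i])),
             rep(length(ALPHABET), PEP_MAX - nchar(peptides[i])))
    x[cbind(i, seq_len(SEQ_LEN), idx)] <- 1
  }
  x
}
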