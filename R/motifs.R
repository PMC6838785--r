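# Binding-motif extraction as position frequency matrices: actual motifs
# from observed binders, predicted motifs from the top-scoring fraction of
# random peptides.

#' Generate random peptides
#'
#' Peptides with i.i.d. uniform residues over the 20-letter amino-acid
#' alphabet.
#'
#' @param n Number of peptides.
#' @param length Peptide length (8-15).
#' @param seed Integer seed.
#' @return Character vector of `n` peptides.
#' @export
random_peptides <- function(n, length = 9L, seed = 1L) {
  stopifnot(n >= 0)
  if (length < PEP_MIN || length > PEP_MAX) {
    abort(sprintf("length must be %d-%d", PEP_MIN, PEP_MAX))
  }
  if (n == 0L) return(character(0))
  withr::local_seed(seed)
  m <- matrix(sample(AA_RESIDUES, n * length, replace = TRUE), nrow = n)
  apply(m, 1L, paste, collapse = "")
}

#' Position frequency matrix from equal-length peptides
#'
#' @param peptides Nonempty character vector of equal-length peptides.
#' @return An object of class `pfm`: a positions x 20 matrix of residue
#'   frequencies (rows sum to 1) with attribute `n_peptides`.
#' @export
pfm_from_peptides <- function(peptides) {
  if (length(peptides) == 0L) abort("no peptides supplied")
  lens <- unique(nchar(peptides))
  if (length(lens) != 1L) {
    abort(sprintf("peptides have mixed lengths: %s", paste(lens, collapse = ", ")))
  }
  L <- lens
  chars <- matrix(unlist(strsplit(peptides, "", fixed = TRUE)),
                  ncol = L, byrow = TRUE)
  m <- matrix(0, nrow = L, ncol = length(AA_RESIDUES),
              dimnames = list(paste0("pos", seq_len(L)), AA_RESIDUES))
  for (p in seq_len(L)) {
    tab <- table(factor(chars[, p], levels = AA_RESIDUES))
    m[p, ] <- as.numeric(tab) / length(peptides)
  }
  structure(m, n_peptides = length(peptides), class = c("pfm", "matrix"))
}

# Indices of the top ceiling(frac * n) scores; ties at the cutoff broken by
# input (generation) order. Selection depends on score ranks only.
top_fraction_idx <- function(scores, frac) {
  k <- ceiling(frac * length(scores))
  order(-scores, seq_along(scores))[seq_len(k)]
}

#' Model-predicted binding motif for an allele
#'
#' Scores `n` random 9-mers against the allele with the binding model and
#' builds a position frequency matrix from the top fraction by score
#' (default: top 1% of 100,000). Ties at the cutoff are broken by
#' generation order, so the result depends on score ranks only.
#'
#' @param model A fitted `hla_model` (binding model).
#' @param allele Allele name present in `pseudo`.
#' @param pseudo Pseudo-sequence table.
#' @param n Number of random peptides (default 100,000).
#' @param top_frac Fraction retained for the motif (default 0.01).
#' @param seed Integer seed for peptide generation.
#' @return A `pfm` of the selected peptides.
#' @export
predicted_motif <- function(model, allele, pseudo, n = 100000L,
                            top_frac = 0.01, seed = 1L) {
  peps <- random_peptides(n, length = 9L, seed = seed)
  scores <- predict_scores(peps, rep(allele, n), model, pseudo)
  pfm_from_peptides(peps[top_fraction_idx(scores, top_frac)])
}

#' Compare two position frequency matrices
#'
#' Quantitative surrogates for visual logo comparison: per-position argmax
#' agreement and mean Jensen-Shannon divergence (base-2, in [0, 1]).
#'
#' @param a,b `pfm` objects of equal length.
#' @return A tibble: `position`, `argmax_a`, `argmax_b`, `agree`, `jsd`.
#' @export
compare_pfm <- function(a, b) {
  stopifnot(nrow(a) == nrow(b))
  jsd_row <- function(p, q) {
    m <- (p + q) / 2
    kl <- function(x, y) {
      i <- x > 0
      sum(x[i] * log2(x[i] / y[i]))
    }
    (kl(p, m) + kl(q, m)) / 2
  }
  tibble(
    position = seq_len(nrow(a)),
    argmax_a = colnames(a)[max.col(unclass(a), ties.method = "first")],
    argmax_b = colnames(b)[max.col(unclass(b), ties.method = "first")],
    jsd = vapply(seq_len(nrow(a)), function(i) jsd_row(a[i, ], b[i, ]),
                 numeric(1))
  ) %>% dplyr::mutate(agree = .data$argmax_a == .data$argmax_b)
}

#' Write a PFM as TSV or a minimal MEME motif block
#'
#' The TSV has one row per position and one column per residue. The MEME
#' output is a minimal motif file (version 4 header, background, letter
#' probability matrix) consumable by MEME-suite tools and logo renderers.
#'
#' @param pfm A `pfm`.
#' @param path Output file path.
#' @param name Motif name used in the MEME header.
#' @return `path`, invisibly.
#' @export
write_pfm_tsv <- function(pfm, path) {
  df <- as.data.frame(unclass(pfm))
  df <- cbind(position = seq_len(nrow(df)), df)
  readr::write_tsv(as_tibble(df), path)
  invisible(path)
}

#' @rdname write_pfm_tsv
#' @export
write_pfm_meme <- function(pfm, path, name = "motif") {
  lines <- c(
    "MEME version 4", "",
    "ALPHABET= ACDEFGHIKLMNPQRSTVWY", "",
    "Background letter frequencies",
    paste(paste(AA_RESIDUES, "0.05000"), collapse = " "), "",
    sprintf("MOTIF %s", name),
    sprintf("letter-probability matrix: alength= 20 w= %d nsites= %d",
            nrow(pfm), attr(pfm, "n_peptides")),
    apply(unclass(pfm), 1L, function(r) paste(sprintf("%.6f", r), collapse = " "))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.pfm <- function(x, ...) {
  cat(sprintf("<pfm> %d positions, %d peptides; per-position argmax: %s\n",
              nrow(x), attr(x, "n_peptides"),
              paste(colnames(x)[max.col(unclass(x), ties.method = "first")], collapse = "")))
  invisible(x)
}

#' Plot a position frequency matrix
#'
#' Information-content scaled letter heights per position (a sequence-logo
#' style bar chart rendered with ggplot2).
#'
#' @param object A `pfm`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pfm
#' @export
autoplot.pfm <- function(object, ...) {
  m <- unclass(object)
  ic <- apply(m, 1L, function(p) {
    p <- p[p > 0]
    log2(20) + sum(p * log2(p))
  })
  df <- as.data.frame(m) %>%
    dplyr::mutate(position = seq_len(nrow(m)), ic = ic) %>%
    tidyr::pivot_longer(-c("position", "ic"), names_to = "residue",
                        values_to = "freq") %>%
    dplyr::mutate(height = .data$freq * .data$ic) %>%
    dplyr::filter(.data$height > 0.01)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$position),
                                   y = .data$height, fill = .data$residue,
                                   label = .data$residue)) +
    ggplot2::geom_col(color = "grey30", linewidth = 0.1) +
    ggplot2::geom_text(position = ggplot2::position_stack(vjust = 0.5),
                       size = 2.5) +
    ggplot2::guides(fill = "none") +
    ggplot2::labs(x = "position", y = "information content (bits)") +
    ggplot2::theme_minimal()
}
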