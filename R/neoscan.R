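# Neoantigen scanning: mutant-peptide window extraction, dual-model
# scoring, the mutation-level presentation score, and top-k ranking.

MUT_LENGTHS <- 8:11

#' Extract all mutant peptides covering a missense mutation
#'
#' Applies the amino-acid substitution to the protein and returns every 8-,
#' 9-, 10- and 11-mer window that contains the mutated position, clipped at
#' the protein termini. An internal mutation in a long protein yields
#' 8 + 9 + 10 + 11 = 38 peptides; mutations near either terminus yield
#' fewer.
#'
#' @param protein Protein sequence (string).
#' @param position 1-based position of the substituted residue.
#' @param ref Reference residue expected at `position`; a mismatch with the
#'   protein is an error.
#' @param alt Alternate residue substituted in.
#' @return A tibble: `peptide`, `length`, `start` (window start in the
#'   protein), `mut_offset` (1-based position of the mutated residue within
#'   the peptide).
#' @export
extract_mutant_peptides <- function(protein, position, ref, alt) {
  L <- nchar(protein)
  if (position < 1L || position > L) {
    abort(sprintf("position %d outside protein of length %d", position, L))
  }
  found <- substr(protein, position, position)
  if (found != ref) {
    abort(sprintf(
      "reference residue mismatch at position %d: mutation record says '%s', protein has '%s'",
      position, ref, found))
  }
  mutated <- paste0(substr(protein, 1L, position - 1L), alt,
                    substr(protein, position + 1L, L))
  out <- list()
  for (k in MUT_LENGTHS) {
    lo <- max(1L, position - k + 1L)
    hi <- min(position, L - k + 1L)
    if (hi < lo) next
    starts <- lo:hi
    out[[as.character(k)]] <- tibble(
      peptide = substring(mutated, starts, starts + k - 1L),
      length = k, start = starts, mut_offset = position - starts + 1L
    )
  }
  dplyr::bind_rows(out)
}

#' Score peptide/allele combinations with both models
#'
#' Forms the Cartesian product of the supplied peptides and the patient's
#' HLA alleles and scores every combination with the binding model and the
#' immunogenicity model.
#'
#' @param peptides Tibble from [extract_mutant_peptides()] (needs columns
#'   `peptide`, `length`) or a character vector of peptides.
#' @param alleles Character vector of the patient's HLA alleles.
#' @param binding,immuno Fitted `hla_model`s.
#' @param pseudo Pseudo-sequence table.
#' @return A tibble with one row per (peptide, allele): `peptide`,
#'   `length`, `allele`, `binding_score`, `immunogenic_score`.
#' @export
score_pairs <- function(peptides, alleles, binding, immuno, pseudo) {
  if (is.character(peptides)) {
    peptides <- tibble(peptide = peptides, length = nchar(peptides))
  }
  grid <- tidyr::crossing(peptides[, c("peptide", "length")],
                          allele = alleles)
  if (nrow(grid) == 0L) {
    return(dplyr::mutate(grid, binding_score = numeric(0),
                         immunogenic_score = numeric(0)))
  }
  grid$binding_score <- predict_scores(grid$peptide, grid$allele, binding, pseudo)
  grid$immunogenic_score <- predict_scores(grid$peptide, grid$allele, immuno, pseudo)
  grid
}

#' Drop records predicted non-immunogenic
#'
#' Removes records with immunogenic score strictly below the threshold; a
#' score exactly at the threshold is retained.
#'
#' @param records Tibble with an `immunogenic_score` column.
#' @param threshold Cutoff (default 0.5).
#' @return The retained rows.
#' @export
immunogenicity_filter <- function(records, threshold = 0.5) {
  records[records$immunogenic_score >= threshold, ]
}

#' Per-length, per-allele binder ratios from training data
#'
#' For each (peptide length, allele) cell of the training dataset, the
#' fraction of pairs labeled positive. Cells with no training records are
#' imputed with the allele-wide binder fraction (or, for alleles absent
#' altogether, the global fraction) and flagged.
#'
#' @param training Labeled pair tibble (columns `allele`, `peptide`,
#'   `label`).
#' @return An object of class `binder_ratios` holding the observed cells,
#'   per-allele fallbacks, and the global binder fraction.
#' @export
compute_binder_ratios <- function(training) {
  training <- as_tibble(training)
  cells <- training %>%
    dplyr::mutate(length = nchar(.data$peptide)) %>%
    dplyr::group_by(.data$length, .data$allele) %>%
    dplyr::summarise(ratio = mean(.data$label == 1), n = dplyr::n(),
                     .groups = "drop")
  per_allele <- training %>%
    dplyr::group_by(.data$allele) %>%
    dplyr::summarise(ratio = mean(.data$label == 1), .groups = "drop")
  structure(
    list(cells = cells, per_allele = per_allele,
         global = mean(training$label == 1)),
    class = "binder_ratios"
  )
}

#' Look up binder ratios, imputing missing cells
#'
#' @param ratios A `binder_ratios` object.
#' @param length,allele Vectors (recycled to common length).
#' @return A tibble: `length`, `allele`, `ratio`, `imputed` (TRUE where the
#'   exact cell was absent from training).
#' @export
get_binder_ratio <- function(ratios, length, allele) {
  d <- tibble(length = length, allele = allele)
  d <- dplyr::left_join(d, ratios$cells[, c("length", "allele", "ratio")],
                        by = c("length", "allele"))
  d$imputed <- is.na(d$ratio)
  fb <- ratios$per_allele$ratio[match(d$allele, ratios$per_allele$allele)]
  fb[is.na(fb)] <- ratios$global
  d$ratio[d$imputed] <- fb[d$imputed]
  d
}

#' Mutation presentation score
#'
#' Aggregates the retained records of one mutation into the presentation
#' score
#' \deqn{Pr = \sum_{i \in \{8,9,10,11\}} \frac{\sum BS_{i,h} \, r_{i,h}}{n_i}}
#' where the inner sum runs over the retained (peptide, allele) records of
#' length \eqn{i}, \eqn{BS_{i,h}} is the binding score, \eqn{r_{i,h}} the
#' training-data binder ratio for that length and allele, and \eqn{n_i} the
#' number of extracted \eqn{i}-mers for the mutation (before the
#' immunogenicity filter). Lengths with no extracted peptides contribute 0.
#'
#' @param records Retained records for one mutation: columns `length`,
#'   `allele`, `binding_score`.
#' @param ratios A `binder_ratios` object.
#' @param counts Named numeric vector of extracted window counts per
#'   length, e.g. `c("8" = 8, "9" = 9, "10" = 10, "11" = 11)`.
#' @return The presentation score, a nonnegative number.
#' @export
mutation_presentation_score <- function(records, ratios, counts) {
  records <- as_tibble(records)
  total <- 0
  for (k in MUT_LENGTHS) {
    n_k <- suppressWarnings(as.numeric(counts[as.character(k)]))
    if (length(n_k) == 0L || is.na(n_k) || n_k == 0) next
    rk <- records[records$length == k, ]
    if (nrow(rk) == 0L) next
    r <- get_binder_ratio(ratios, rk$length, rk$allele)$ratio
    total <- total + sum(rk$binding_score * r) / n_k
  }
  total
}

#' Rank mutations within a patient
#'
#' Orders mutation reports by descending presentation score within each
#' patient, breaking ties lexicographically by mutation id, and assigns
#' 1-based ranks.
#'
#' @param reports Tibble with columns `patient_id`, `mutation_id`,
#'   `presentation`.
#' @return The reports with a `rank` column, ordered by patient and rank.
#' @export
rank_mutations <- function(reports) {
  as_tibble(reports) %>%
    dplyr::group_by(.data$patient_id) %>%
    dplyr::arrange(dplyr::desc(.data$presentation), .data$mutation_id,
                   .by_group = TRUE) %>%
    dplyr::mutate(rank = dplyr::row_number()) %>%
    dplyr::ungroup()
}

#' Flag high-confidence records by binding-score rank
#'
#' Records already passed the immunogenicity filter are ranked by binding
#' score (descending, ties broken lexicographically by peptide then allele)
#' and the top `k` are flagged as high-confidence. Ranking scope is the
#' whole input by default; with `by_length = TRUE` the ranking is done
#' separately within each peptide-length class (the minimal-epitope mode).
#'
#' @param records Tibble with `binding_score`, `peptide`, `allele` and
#'   (for the length mode) `length` columns.
#' @param k Number of records to flag (default 20).
#' @param by_length Rank within peptide-length classes instead of globally.
#' @return The records with `binding_rank` and logical `high_confidence`
#'   columns.
#' @export
select_high_confidence <- function(records, k = 20L, by_length = FALSE) {
  records <- as_tibble(records)
  rank_block <- function(d) {
    ord <- order(-d$binding_score, d$peptide, d$allele)
    d$binding_rank[ord] <- seq_len(nrow(d))
    d
  }
  records$binding_rank <- NA_integer_
  if (by_length) {
    records <- records %>%
      dplyr::group_by(.data$length) %>%
      dplyr::group_modify(~rank_block(.x)) %>%
      dplyr::ungroup()
  } else {
    records <- rank_block(records)
  }
  dplyr::mutate(records, high_confidence = .data$binding_rank <= k)
}

#' Filter mutations by expression
#'
#' Keeps mutations whose expression is strictly greater than the TPM
#' threshold. Mutations with missing TPM are retained and flagged rather
#' than dropped (the filter applies only where RNA evidence exists).
#'
#' @param mutations Tibble with a `tpm` column (NA allowed).
#' @param tpm_threshold Threshold in transcripts per million (strict `>`).
#' @return The retained mutations with a logical `tpm_missing` column.
#' @export
expression_filter <- function(mutations, tpm_threshold = 2) {
  mutations <- as_tibble(mutations)
  keep <- is.na(mutations$tpm) | mutations$tpm > tpm_threshold
  dplyr::mutate(mutations[keep, ], tpm_missing = is.na(.data$tpm))
}

#' Full neoantigen scanning pipeline
#'
#' For every mutation: extract all 8-11-mer mutant windows, score every
#' (peptide, patient allele) combination with the binding and
#' immunogenicity models, drop records with immunogenic score below 0.5,
#' aggregate to the mutation presentation score, rank mutations within
#' each patient, and flag high-confidence peptide records by top-k binding
#' rank.
#'
#' @param mutations Tibble from [read_mutations()].
#' @param patient_hla Tibble with `patient_id`, `allele`.
#' @param proteome Named character vector of protein sequences.
#' @param binding,immuno Fitted `hla_model`s.
#' @param pseudo Pseudo-sequence table.
#' @param ratios `binder_ratios` from the binding training set.
#' @param tpm_threshold Optional TPM cutoff applied before scanning
#'   (strict `>`; `NULL` disables).
#' @param top_k High-confidence flag cutoff (default 20).
#' @param immuno_threshold Immunogenic-score cutoff (default 0.5).
#' @return An object of class `neoantigen_scan`: `mutations` (per-mutation
#'   tibble with `presentation` and `rank`) and `records` (per-pair tibble
#'   with scores, filter status and high-confidence flags).
#' @export
scan_neoantigens <- function(mutations, patient_hla, proteome, binding,
                             immuno, pseudo, ratios, tpm_threshold = NULL,
                             top_k = 20L, immuno_threshold = 0.5) {
  mutations <- as_tibble(mutations)
  if (!"tpm" %in% names(mutations)) mutations$tpm <- NA_real_
  if (!is.null(tpm_threshold)) {
    mutations <- expression_filter(mutations, tpm_threshold)
  }
  rec_list <- vector("list", nrow(mutations))
  rep_list <- vector("list", nrow(mutations))
  for (i in seq_len(nrow(mutations))) {
    m <- mutations[i, ]
    if (!m$protein_id %in% names(proteome)) {
      abort(sprintf("protein '%s' not in proteome", m$protein_id))
    }
    prot <- proteome[[m$protein_id]]
    peps <- extract_mutant_peptides(prot, m$position, m$ref, m$alt)
    alleles <- patient_hla$allele[patient_hla$patient_id == m$patient_id]
    counts <- table(factor(peps$length, levels = MUT_LENGTHS))
    scored <- score_pairs(peps, alleles, binding, immuno, pseudo)
    scored$retained <- scored$immunogenic_score >= immuno_threshold
    retained <- scored[scored$retained, ]
    pr <- mutation_presentation_score(retained, ratios,
                                      stats::setNames(as.numeric(counts),
                                                      names(counts)))
    rec_list[[i]] <- dplyr::mutate(scored, mutation_id = m$mutation_id,
                                   patient_id = m$patient_id)
    rep_list[[i]] <- tibble(patient_id = m$patient_id,
                            mutation_id = m$mutation_id,
                            n_peptides = nrow(peps),
                            n_retained = nrow(retained),
                            tpm = m$tpm, presentation = pr)
  }
  reports <- rank_mutations(dplyr::bind_rows(rep_list))
  records <- dplyr::bind_rows(rec_list)
  flagged <- records[records$retained, ]
  if (nrow(flagged) > 0L) {
    flagged <- flagged %>%
      dplyr::group_by(.data$patient_id) %>%
      dplyr::group_modify(~select_high_confidence(.x, k = top_k)) %>%
      dplyr::ungroup()
    records <- dplyr::left_join(
      records, flagged[, c("patient_id", "mutation_id", "peptide", "allele",
                           "binding_rank", "high_confidence")],
      by = c("patient_id", "mutation_id", "peptide", "allele"))
  } else {
    records$binding_rank <- NA_integer_
    records$high_confidence <- FALSE
  }
  structure(list(mutations = reports, records = records),
            class = "neoantigen_scan")
}

#' @export
print.neoantigen_scan <- function(x, ...) {
  cat(sprintf("<neoantigen_scan> %d mutations, %d patients, %d scored pairs (%d retained)\n",
              nrow(x$mutations), length(unique(x$mutations$patient_id)),
              nrow(x$records), sum(x$records$retained)))
  invisible(x)
}

#' Plot ranked mutation presentation scores
#'
#' @param object A `neoantigen_scan`.
#' @param ... Unused.
#' @return A ggplot of presentation score against within-patient rank.
#' @method autoplot neoantigen_scan
#' @export
autoplot.neoantigen_scan <- function(object, ...) {
  ggplot2::ggplot(object$mutations,
                  ggplot2::aes(x = .data$rank, y = .data$presentation)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~patient_id) +
    ggplot2::labs(x = "within-patient rank", y = "presentation score") +
    ggplot2::theme_minimal()
}
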