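# Training-data curation: IEDB-style record filtering, per-allele class
# balancing with model-labeled pseudo pairs, and the two-step training
# orchestration.

is_abc_allele <- function(allele) {
  stringr::str_detect(allele, "^HLA-[ABC]")
}

valid_peptide <- function(peptide) {
  nchar(peptide) >= PEP_MIN & nchar(peptide) <= PEP_MAX &
    stringr::str_detect(peptide, paste0("^[", paste(AA_RESIDUES, collapse = ""), "]+$"))
}

finish_filter <- function(kept, n_in, reasons) {
  report <- tibble(reason = names(reasons), n = unname(as.integer(reasons)))
  stopifnot(sum(report$n) == n_in - nrow(kept))
  list(records = kept, report = report)
}

#' Filter raw HLA-peptide binding records
#'
#' Applies the curation rules for binding data: keep only HLA class I
#' alleles of the A, B and C loci; keep peptide lengths 8-15 with standard
#' residues; drop every (allele, peptide) pair observed with both a
#' positive and a negative outcome (inconsistent experimental results);
#' deduplicate on (allele, peptide). Annotation text is ignored for
#' deduplication.
#'
#' @param raw A data frame with columns `allele`, `peptide`, `label`
#'   (binary) and optionally `annotation`.
#' @return A list with `records` (a tibble tagged `source = "collected"`)
#'   and `report` (a tibble of rejection reasons and counts; the counts sum
#'   to rows in minus rows out).
#' @export
filter_binding_records <- function(raw) {
  raw <- as_tibble(raw)
  if (!"annotation" %in% names(raw)) raw$annotation <- NA_character_
  n_in <- nrow(raw)
  reasons <- c(non_abc_allele = 0L, bad_peptide = 0L,
               conflicting_label = 0L, duplicate = 0L)

  keep <- is_abc_allele(raw$allele)
  reasons["non_abc_allele"] <- sum(!keep)
  d <- raw[keep, ]
  keep <- valid_peptide(d$peptide)
  reasons["bad_peptide"] <- sum(!keep)
  d <- d[keep, ]

  key <- paste(d$allele, d$peptide, sep = "\r")
  lab_per_key <- tapply(d$label, key, function(x) length(unique(x)))
  conflicted <- names(lab_per_key)[lab_per_key > 1L]
  is_conf <- key %in% conflicted
  reasons["conflicting_label"] <- sum(is_conf)
  d <- d[!is_conf, ]
  key <- key[!is_conf]

  dup <- duplicated(key)
  reasons["duplicate"] <- sum(dup)
  d <- d[!dup, ]
  d$source <- "collected"
  finish_filter(d[, c("annotation", "allele", "peptide", "label", "source")],
                n_in, reasons)
}

#' Filter raw immunogenicity records
#'
#' Curation rules for immunogenicity data differ from the binding rules in
#' one respect: a pair observed with both outcomes is retained once and
#' labeled positive (a pair that elicited T-cell activation at least once
#' is treated as immunogenic), rather than discarded. Peptide lengths 8-15
#' are kept and duplicates collapsed.
#'
#' @inheritParams filter_binding_records
#' @return As [filter_binding_records()].
#' @export
filter_immunogenicity_records <- function(raw) {
  raw <- as_tibble(raw)
  if (!"annotation" %in% names(raw)) raw$annotation <- NA_character_
  n_in <- nrow(raw)
  reasons <- c(bad_peptide = 0L, duplicate = 0L)

  keep <- valid_peptide(raw$peptide)
  reasons["bad_peptide"] <- sum(!keep)
  d <- raw[keep, ]

  key <- paste(d$allele, d$peptide, sep = "\r")
  # conflicting pairs resolve to positive: take max label within key
  max_lab <- tapply(d$label, key, max)
  dup <- duplicated(key)
  reasons["duplicate"] <- sum(dup)
  d <- d[!dup, ]
  d$label <- as.numeric(max_lab[paste(d$allele, d$peptide, sep = "\r")])
  d$source <- "collected"
  finish_filter(d[, c("annotation", "allele", "peptide", "label", "source")],
                n_in, reasons)
}

#' Per-allele positive/negative counts
#'
#' @param records A pair tibble with `allele` and `label` columns.
#' @return A tibble: `allele`, `n_pos`, `n_neg`.
#' @export
allele_stats <- function(records) {
  as_tibble(records) %>%
    dplyr::group_by(.data$allele) %>%
    dplyr::summarise(n_pos = sum(.data$label == 1),
                     n_neg = sum(.data$label == 0), .groups = "drop")
}

#' Number of candidate pseudo pairs for an allele
#'
#' The balancing procedure generates `100 * |n_pos - n_neg|` candidate
#' pseudo pairs per allele, from which high-confidence pairs are selected
#' to fill the deficient class.
#'
#' @param n_pos,n_neg Nonnegative counts of positive and negative pairs
#'   (vectorized).
#' @return Integer vector of candidate counts.
#' @export
compute_pseudo_count <- function(n_pos, n_neg) {
  stopifnot(all(n_pos >= 0), all(n_neg >= 0))
  as.integer(100 * abs(n_pos - n_neg))
}

#' Generate candidate pseudo pairs from a proteome
#'
#' Each candidate peptide is drawn by choosing a protein uniformly at
#' random and extracting a random contiguous 8-11-mer from it. Candidates
#' are unlabeled; they acquire labels only through
#' [select_confident_pseudo_pairs()].
#'
#' @param proteome Named character vector of protein sequences (see
#'   [read_proteome()]).
#' @param allele Allele name attached to every candidate.
#' @param count Number of candidates to generate.
#' @param seed Integer seed.
#' @return A tibble with columns `annotation`, `allele`, `peptide`,
#'   `source = "pseudo"`.
#' @export
generate_candidate_pseudo_pairs <- function(proteome, allele, count, seed) {
  stopifnot(count >= 0)
  lens <- nchar(proteome)
  usable <- which(lens >= PEP_MIN)
  if (length(usable) == 0L) abort("proteome has no protein of length >= 8")
  withr::local_seed(seed)
  peptides <- character(count)
  i <- 0L
  while (i < count) {
    pi <- usable[sample.int(length(usable), 1L)]
    k <- sample(8:11, 1L)
    if (lens[pi] < k) next
    start <- sample.int(lens[pi] - k + 1L, 1L)
    i <- i + 1L
    peptides[i] <- substr(proteome[pi], start, start + k - 1L)
  }
  tibble(annotation = "pseudo", allele = allele, peptide = peptides,
         source = "pseudo")
}

#' Select high-confidence pseudo pairs with a basic model
#'
#' Scores unlabeled candidates with a preliminary ("basic") binding model
#' and keeps only confident calls: score strictly below 0.1 becomes an
#' eligible negative, strictly above 0.9 an eligible positive. Up to the
#' requested number of each class is taken in scan order; a shortfall is
#' reported, never padded.
#'
#' @param candidates Tibble from [generate_candidate_pseudo_pairs()].
#' @param basic_model An `hla_model`.
#' @param pseudo Pseudo-sequence table.
#' @param need_pos,need_neg Requested counts per class.
#' @param lower,upper Confidence cutoffs (strict inequalities).
#' @return A list: `records` (labeled tibble, `source = "pseudo"`) and
#'   `shortfall` (tibble with requested/obtained counts per class).
#' @export
select_confident_pseudo_pairs <- function(candidates, basic_model, pseudo,
                                          need_pos, need_neg,
                                          lower = 0.1, upper = 0.9) {
  candidates <- as_tibble(candidates)
  scores <- if (nrow(candidates) > 0L) {
    predict_scores(candidates$peptide, candidates$allele, basic_model, pseudo)
  } else {
    numeric(0)
  }
  pos_idx <- which(scores > upper)
  neg_idx <- which(scores < lower)
  pos_take <- utils::head(pos_idx, need_pos)
  neg_take <- utils::head(neg_idx, need_neg)
  rec <- candidates[c(pos_take, neg_take), ]
  rec$label <- rep(c(1, 0), c(length(pos_take), length(neg_take)))
  rec$source <- "pseudo"
  list(
    records = rec,
    shortfall = tibble(
      class = c("positive", "negative"),
      requested = c(need_pos, need_neg),
      obtained = c(length(pos_take), length(neg_take))
    )
  )
}

#' Remove alleles with unusual class proportions
#'
#' After augmentation, any allele whose positive:negative ratio (either
#' direction) strictly exceeds 5 is dropped, including alleles with all
#' pairs in a single class.
#'
#' @param records A labeled pair tibble.
#' @param max_ratio Ratio bound (default 5; strict inequality).
#' @return A list: `records` (surviving rows) and `removed` (tibble of
#'   removed alleles with their counts).
#' @export
prune_imbalanced_alleles <- function(records, max_ratio = 5) {
  records <- as_tibble(records)
  st <- allele_stats(records)
  bad <- st$n_pos > max_ratio * st$n_neg | st$n_neg > max_ratio * st$n_pos
  removed <- st[bad, ]
  list(records = records[!records$allele %in% removed$allele, ],
       removed = removed)
}

#' Two-step training with pseudo-pair balancing
#'
#' The full curated training procedure: (1) train a basic model on the
#' collected pairs; (2) for each allele, generate `100 * |n_pos - n_neg|`
#' candidate pseudo peptides from the proteome and add the basic model's
#' high-confidence calls of the deficient class; (3) remove alleles still
#' imbalanced beyond 5:1; (4) train the final model on the augmented,
#' pruned dataset.
#'
#' @param records Filtered pair tibble (see [filter_binding_records()]).
#' @param proteome Named character vector of protein sequences.
#' @param pseudo Pseudo-sequence table covering all alleles.
#' @param config A [training_config()]; used for both training steps.
#' @return A list: `model` (final `hla_model`), `basic_model`, `records`
#'   (the augmented, pruned dataset), `report` (per-allele before/after
#'   counts with pseudo-pair shortfalls) and `removed` alleles.
#' @export
two_step_train <- function(records, proteome, pseudo,
                           config = training_config()) {
  records <- as_tibble(records)
  if (!"source" %in% names(records)) records$source <- "collected"
  basic <- hla_train(records, pseudo, config)
  st <- allele_stats(records)
  st$n_pse <- compute_pseudo_count(st$n_pos, st$n_neg)
  added <- vector("list", nrow(st))
  shortfalls <- vector("list", nrow(st))
  for (i in seq_len(nrow(st))) {
    if (st$n_pse[i] == 0L) next
    deficit <- abs(st$n_pos[i] - st$n_neg[i])
    need_pos <- if (st$n_pos[i] < st$n_neg[i]) deficit else 0L
    need_neg <- if (st$n_neg[i] < st$n_pos[i]) deficit else 0L
    cand <- generate_candidate_pseudo_pairs(
      proteome, st$allele[i], st$n_pse[i],
      seed = config$seed + i
    )
    sel <- select_confident_pseudo_pairs(cand, basic, pseudo,
                                         need_pos = need_pos,
                                         need_neg = need_neg)
    added[[i]] <- sel$records
    shortfalls[[i]] <- dplyr::mutate(sel$shortfall, allele = st$allele[i])
  }
  pseudo_rec <- dplyr::bind_rows(added)
  # pseudo records never overwrite collected ones: drop colliding keys
  if (nrow(pseudo_rec) > 0L) {
    collide <- paste(pseudo_rec$allele, pseudo_rec$peptide) %in%
      paste(records$allele, records$peptide)
    pseudo_rec <- pseudo_rec[!collide, ]
  }
  augmented <- dplyr::bind_rows(records, pseudo_rec)
  pruned <- prune_imbalanced_alleles(augmented)
  final <- hla_train(pruned$records, pseudo, config)
  before <- dplyr::rename(st, pos_before = "n_pos", neg_before = "n_neg")
  after <- dplyr::rename(allele_stats(augmented),
                         pos_after = "n_pos", neg_after = "n_neg")
  report <- dplyr::left_join(before, after, by = "allele") %>%
    dplyr::mutate(kept = !.data$allele %in% pruned$removed$allele)
  list(model = final, basic_model = basic, records = pruned$records,
       report = report, removed = pruned$removed,
       shortfalls = dplyr::bind_rows(shortfalls))
}
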