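# Brute-force window enumerator used as the oracle for peptide extraction.
brute_force_windows <- function(protein, position, alt) {
  mutated <- paste0(substr(protein, 1, position - 1), alt,
                    substr(protein, position + 1, nchar(protein)))
  out <- character(0)
  for (k in 8:11) {
    for (s in 1:(nchar(mutated) - k + 1)) {
      if (s <= position && position <= s + k - 1) {
        out <- c(out, substr(mutated, s, s + k - 1))
      }
    }
  }
  out
}

test_that("mutant peptide extraction matches brute-force enumeration", {
  withr::local_seed(17)
  # internal mutation in a long protein: 8+9+10+11 = 38 windows
  prot <- random_valid_peptide(100)
  ref <- substr(prot, 50, 50)
  alt <- setdiff(c("A", "C"), ref)[1]
  peps <- extract_mutant_peptides(prot, 50, ref, alt)
  expect_equal(nrow(peps), 38L)
  expect_equal(as.integer(table(peps$length)), c(8L, 9L, 10L, 11L))
  expect_setequal(peps$peptide, brute_force_windows(prot, 50, alt))
  # every window contains the alternate residue at the mutated offset
  expect_true(all(substr(peps$peptide, peps$mut_offset, peps$mut_offset) == alt))

  # mutation at position 1: one window per length
  ref1 <- substr(prot, 1, 1)
  alt1 <- setdiff(c("A", "C"), ref1)[1]
  p1 <- extract_mutant_peptides(prot, 1, ref1, alt1)
  expect_equal(nrow(p1), 4L)
  expect_setequal(p1$peptide, brute_force_windows(prot, 1, alt1))

  # random positions and lengths vs brute force
  for (i in 1:10) {
    L <- sample(12:60, 1)
    pr <- random_valid_peptide(L)
    pos <- sample(seq_len(L), 1)
    a <- sample(setdiff(panneo::aa_alphabet()[1:20], substr(pr, pos, pos)), 1)
    got <- extract_mutant_peptides(pr, pos, substr(pr, pos, pos), a)
    expect_setequal(got$peptide, unique(brute_force_windows(pr, pos, a)))
    for (k in 8:11) {
      expect_equal(sum(got$length == k),
                   max(0, min(k, pos, L - pos + 1, L - k + 1)))
    }
  }

  expect_error(extract_mutant_peptides(prot, 50, "B", "A"), "mismatch")
})

test_that("dual-model scoring covers the peptide x allele product", {
  tr <- fixture_trained()
  al2 <- make_alleles(2, seed = 101)
  peps <- tibble::tibble(peptide = replicate(5, random_valid_peptide(9)),
                         length = 9L)
  rec <- score_pairs(peps, al2$pseudo$allele, tr$model, tr$model, al2$pseudo)
  expect_equal(nrow(rec), 10L)
  expect_true(all(rec$binding_score > 0 & rec$binding_score < 1))
  expect_equal(rec$binding_score, rec$immunogenic_score)
  expect_equal(
    rec$binding_score,
    predict_scores(rec$peptide, rec$allele, tr$model, al2$pseudo))
  expect_equal(nrow(score_pairs(peps, character(0), tr$model, tr$model,
                                al2$pseudo)), 0L)
})

test_that("the immunogenicity filter is strict below 0.5", {
  rec <- tibble::tibble(immunogenic_score = c(0.49, 0.5, 0.51, 0.1))
  kept <- immunogenicity_filter(rec)
  expect_equal(kept$immunogenic_score, c(0.5, 0.51))
  expect_equal(nrow(immunogenicity_filter(
    tibble::tibble(immunogenic_score = c(0.1, 0.2)))), 0L)
})

test_that("binder ratios are per length/allele fractions with flagged imputation", {
  train <- tibble::tibble(
    allele = c(rep("H1", 4), rep("H2", 2)),
    peptide = c(replicate(4, random_valid_peptide(9)),
                replicate(2, random_valid_peptide(10))),
    label = c(1, 1, 1, 0, 1, 0)
  )
  ratios <- compute_binder_ratios(train)
  got <- get_binder_ratio(ratios, c(9, 10, 10), c("H1", "H2", "H1"))
  expect_equal(got$ratio[1], 0.75)
  expect_equal(got$ratio[2], 0.5)
  # missing cell (10-mers for H1) imputed with H1's overall fraction, flagged
  expect_true(got$imputed[3])
  expect_equal(got$ratio[3], 0.75)
  expect_false(any(got$imputed[1:2]))
  expect_true(all(got$ratio >= 0 & got$ratio <= 1))
})

test_that("the presentation score matches direct double summation", {
  train <- tibble::tibble(
    allele = rep(c("H1", "H2"), each = 6),
    peptide = c(replicate(6, random_valid_peptide(9)),
                replicate(6, random_valid_peptide(10))),
    label = rep(c(1, 1, 0), 4)
  )
  ratios <- compute_binder_ratios(train)

  # single retained 9-mer: BS=0.8, r known, n_9=1
  one <- tibble::tibble(length = 9L, allele = "H1", binding_score = 0.8)
  r9 <- get_binder_ratio(ratios, 9, "H1")$ratio
  expect_equal(
    mutation_presentation_score(one, ratios, c("9" = 1)),
    0.8 * r9)

  # no retained records
  expect_equal(mutation_presentation_score(one[0, ], ratios,
                                           c("8" = 8, "9" = 9)), 0)

  # 3 records across two lengths vs independent brute-force evaluation
  recs <- tibble::tibble(
    length = c(9L, 9L, 10L),
    allele = c("H1", "H2", "H2"),
    binding_score = c(0.9, 0.4, 0.7)
  )
  counts <- c("8" = 8, "9" = 9, "10" = 10, "11" = 11)
  manual <- 0
  for (i in seq_len(nrow(recs))) {
    ri <- get_binder_ratio(ratios, recs$length[i], recs$allele[i])$ratio
    manual <- manual + recs$binding_score[i] * ri / counts[[as.character(recs$length[i])]]
  }
  expect_equal(mutation_presentation_score(recs, ratios, counts), manual)

  # monotone in any single binding score
  bumped <- recs
  bumped$binding_score[2] <- bumped$binding_score[2] + 0.05
  expect_gt(mutation_presentation_score(bumped, ratios, counts),
            mutation_presentation_score(recs, ratios, counts))
})

test_that("mutation ranking is dense, 1-based, and tie-broken by id", {
  rep_tbl <- tibble::tibble(
    patient_id = "P1",
    mutation_id = c("m1", "m2", "m3"),
    presentation = c(0.9, 0.1, 0.5)
  )
  ranked <- rank_mutations(rep_tbl)
  expect_equal(ranked$rank[match(c("m1", "m2", "m3"), ranked$mutation_id)],
               c(1L, 3L, 2L))

  tied <- tibble::tibble(patient_id = "P1",
                         mutation_id = c("mB", "mA"),
                         presentation = c(0.5, 0.5))
  rt <- rank_mutations(tied)
  expect_equal(rt$mutation_id[rt$rank == 1], "mA")

  single <- rank_mutations(tibble::tibble(patient_id = "P9",
                                          mutation_id = "mX",
                                          presentation = 0))
  expect_equal(single$rank, 1L)
})

test_that("top-k flagging is rank-only and respects k", {
  withr::local_seed(23)
  rec <- tibble::tibble(
    peptide = replicate(25, random_valid_peptide(9)),
    allele = "H1",
    length = 9L,
    binding_score = runif(25)
  )
  f <- select_high_confidence(rec, k = 20)
  expect_equal(sum(f$high_confidence), 20L)
  small <- select_high_confidence(rec[1:5, ], k = 20)
  expect_equal(sum(small$high_confidence), 5L)

  # invariant under strictly monotone transform of the scores
  rec2 <- dplyr::mutate(rec, binding_score = exp(3 * binding_score) - 1)
  f2 <- select_high_confidence(rec2, k = 20)
  expect_equal(f$high_confidence[order(f$peptide)],
               f2$high_confidence[order(f2$peptide)])

  # per-length mode ranks within each length class
  recL <- dplyr::bind_rows(rec, dplyr::mutate(rec, length = 10L))
  fl <- select_high_confidence(recL, k = 3, by_length = TRUE)
  expect_equal(sum(fl$high_confidence), 6L)
})

test_that("the expression filter is strict and keeps missing TPM flagged", {
  muts <- tibble::tibble(mutation_id = paste0("m", 1:4),
                         tpm = c(2.0, 5, NA, 0.1))
  kept <- expression_filter(muts, 2)
  expect_setequal(kept$mutation_id, c("m2", "m3"))
  expect_true(kept$tpm_missing[kept$mutation_id == "m3"])
  all_pos <- tibble::tibble(mutation_id = "x", tpm = 3)
  expect_equal(nrow(expression_filter(all_pos, 0)), 1L)
})

test_that("the end-to-end scan produces coherent reports", {
  tr <- fixture_trained()
  bundle <- make_proteome_and_mutations(n_proteins = 6, protein_length = 60,
                                        n_mutations = 6, rules = tr$alleles$rules,
                                        seed = 71)
  ratios <- compute_binder_ratios(tr$pairs)
  scan <- scan_neoantigens(bundle$mutations, bundle$patient_hla,
                           bundle$proteome, tr$model, tr$model,
                           tr$alleles$pseudo, ratios)
  expect_s3_class(scan, "neoantigen_scan")
  expect_equal(nrow(scan$mutations), 6L)
  expect_true(all(scan$mutations$presentation >= 0))
  # ranks are 1..n within each patient
  by_pat <- split(scan$mutations$rank, scan$mutations$patient_id)
  for (r in by_pat) expect_equal(sort(r), seq_along(r))
  # retained records all have immunogenic score >= 0.5
  expect_true(all(scan$records$immunogenic_score[scan$records$retained] >= 0.5))
  # a mutation with zero retained records has presentation exactly 0
  zero <- scan$mutations$mutation_id[scan$mutations$n_retained == 0]
  if (length(zero) > 0) {
    expect_true(all(scan$mutations$presentation[
      scan$mutations$mutation_id %in% zero] == 0))
  }
  expect_s3_class(ggplot2::autoplot(scan), "ggplot")
})
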