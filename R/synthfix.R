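# Seeded synthetic-data generator. Planted binding rules are additive
# position weight matrices over 9 positions: simple enough for a recurrent
# model to learn and for a position frequency matrix to recover, which
# makes motif- and ranking-recovery tests meaningful. None of this emulates
# real binding energetics; it exists to exercise code paths with known
# ground truth.

PLANTED_LEN <- 9L

#' Score peptides with a planted binding rule
#'
#' The planted score of a peptide is the sum of the rule's position-weight
#' entries over positions 1..min(9, length). A peptide is a planted binder
#' when its score strictly exceeds the rule threshold.
#'
#' @param peptides Character vector (lengths 8-15).
#' @param rule A planted rule from [make_alleles()].
#' @return Numeric scores.
#' @export
planted_score <- function(peptides, rule) {
  vapply(peptides, function(p) {
    ch <- split_residues(p)
    j <- seq_len(min(PLANTED_LEN, length(ch)))
    sum(rule$weights[cbind(j, match(ch[j], AA_RESIDUES))])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Generate synthetic alleles with planted binding rules
#'
#' Produces `n` pseudo-alleles: each gets a random 34-residue
#' pseudo-sequence, and an independent planted rule — a 9 x 20 position
#' weight matrix with 2-3 strongly weighted anchor positions (distinct
#' anchor sets across alleles; collisions are resampled) and a threshold
#' calibrated so the positive rate on uniform random 9-mers matches
#' `positive_rate` within 2%.
#'
#' @param n Number of alleles (>= 1).
#' @param seed Integer seed.
#' @param positive_rate Target binder fraction among uniform 9-mers
#'   (default 0.05, the order of real presented-peptide prevalence).
#' @return A list: `pseudo` (allele/pseudo-sequence tibble usable wherever
#'   a loaded pseudo-sequence table is) and `rules` (named list of planted
#'   rules: `allele`, `anchors`, `anchor_residues`, `weights`, `threshold`,
#'   `positive_rate`, and the `central_residues` set of the planted
#'   immunogenicity rule).
#' @export
make_alleles <- function(n, seed = 1L, positive_rate = 0.05) {
  stopifnot(n >= 1)
  withr::local_seed(seed)
  alleles <- sprintf("HLA-S*%02d:01", seq_len(n))
  pseudo <- vapply(seq_len(n), function(i) {
    paste(sample(AA_RESIDUES, PSEUDO_LEN, replace = TRUE), collapse = "")
  }, character(1))
  rules <- vector("list", n)
  seen_anchor_sets <- character(0)
  calib <- matrix(sample(AA_RESIDUES, 20000L * PLANTED_LEN, replace = TRUE),
                  ncol = PLANTED_LEN)
  for (i in seq_len(n)) {
    repeat {
      n_anchor <- sample(2:3, 1L)
      anchors <- sort(sample(seq_len(PLANTED_LEN), n_anchor))
      anchor_res <- sample(AA_RESIDUES, n_anchor, replace = TRUE)
      key <- paste(anchors, anchor_res, sep = ":", collapse = ",")
      if (!key %in% seen_anchor_sets) {
        seen_anchor_sets <- c(seen_anchor_sets, key)
        break
      }
    }
    w <- matrix(stats::rnorm(PLANTED_LEN * 20L, 0, 0.3), PLANTED_LEN, 20L,
                dimnames = list(NULL, AA_RESIDUES))
    w[cbind(anchors, match(anchor_res, AA_RESIDUES))] <- 4
    # calibrate the threshold on uniform 9-mers
    sc <- w[cbind(rep(seq_len(PLANTED_LEN), each = nrow(calib)),
                  match(as.vector(calib), AA_RESIDUES))]
    sc <- rowSums(matrix(sc, nrow = nrow(calib)))
    thr <- stats::quantile(sc, 1 - positive_rate, names = FALSE)
    rules[[i]] <- list(allele = alleles[i], anchors = anchors,
                       anchor_residues = anchor_res, weights = w,
                       threshold = thr, positive_rate = positive_rate,
                       central_residues = sample(AA_RESIDUES, 8L))
  }
  names(rules) <- alleles
  list(pseudo = tibble(allele = alleles, pseudo = pseudo), rules = rules)
}

#' Sample labeled 9-mer pairs from a planted rule
#'
#' Draws uniform random 9-mers, labels each by whether its planted score
#' exceeds the rule threshold, and rejection-samples to hit the requested
#' positive fraction exactly (`round(n * positive_fraction)` positives).
#'
#' @param rule A planted rule.
#' @param n Number of pairs.
#' @param positive_fraction Target positive fraction.
#' @param seed Integer seed.
#' @param max_draws Sampling budget before declaring the fraction
#'   unattainable.
#' @return A tibble: `annotation`, `allele`, `peptide`, `label`,
#'   `source = "collected"`, in shuffled order.
#' @export
sample_labeled_pairs <- function(rule, n, positive_fraction = 0.5, seed = 1L,
                                 max_draws = 500L * n) {
  stopifnot(n >= 1)
  withr::local_seed(seed)
  need_pos <- round(n * positive_fraction)
  need_neg <- n - need_pos
  pos <- character(0)
  neg <- character(0)
  drawn <- 0L
  batch <- max(1000L, n)
  while ((length(pos) < need_pos || length(neg) < need_neg) &&
         drawn < max_draws) {
    m <- matrix(sample(AA_RESIDUES, batch * PLANTED_LEN, replace = TRUE),
                ncol = PLANTED_LEN)
    peps <- apply(m, 1L, paste, collapse = "")
    drawn <- drawn + batch
    lab <- planted_score(peps, rule) > rule$threshold
    pos <- c(pos, peps[lab])
    neg <- c(neg, peps[!lab])
  }
  if (length(pos) < need_pos || length(neg) < need_neg) {
    abort(sprintf("could not reach positive fraction %.2f within %d draws",
                  positive_fraction, max_draws))
  }
  d <- tibble(
    annotation = "synthetic",
    allele = rule$allele,
    peptide = c(pos[seq_len(need_pos)], neg[seq_len(need_neg)]),
    label = rep(c(1, 0), c(need_pos, need_neg)),
    source = "collected"
  )
  d[sample.int(n), ]
}

#' Plant immunogenicity labels on binding-labeled pairs
#'
#' A second-layer rule mirroring the binding/immunogenicity distinction: a
#' pair is immunogenic iff it is a binder AND its central residue (position
#' 5) belongs to the rule's planted `central_residues` set; non-binders are
#' never immunogenic.
#'
#' @param pairs Binding-labeled pairs from [sample_labeled_pairs()].
#' @param rule The planted rule of the pairs' allele.
#' @return The pairs with `label` replaced by the immunogenicity label; the
#'   planted central residue set is attached as attribute
#'   `central_residues`.
#' @export
make_immunogenicity_labels <- function(pairs, rule) {
  central <- rule$central_residues
  out <- dplyr::mutate(
    as_tibble(pairs),
    label = as.numeric(.data$label == 1 &
                         substr(.data$peptide, 5L, 5L) %in% central)
  )
  attr(out, "central_residues") <- central
  out
}

#' Generate a synthetic proteome with mutations and known responders
#'
#' Builds a random proteome, draws missense mutations at internal
#' positions, assigns each mutation's patient 1-2 alleles from the planted
#' rule set, and computes the ground truth: a mutation is a responder iff
#' at least one of its mutant 8-11-mer windows gains a binder call a
#' patient allele's reference window lacks AND that window satisfies the
#' allele's planted immunogenicity rule — i.e. the mutation creates a new,
#' immunogenic, presented peptide.
#'
#' @param n_proteins,protein_length Proteome dimensions
#'   (`protein_length >= 30`).
#' @param n_mutations Number of mutations.
#' @param rules Planted rules from [make_alleles()].
#' @param seed Integer seed.
#' @return A list: `proteome` (named character), `mutations` (tibble with
#'   `mutation_id`, `patient_id`, `protein_id`, `position`, `ref`, `alt`,
#'   `tpm`), `patient_hla` (tibble), `responders` (character vector of
#'   mutation ids).
#' @export
make_proteome_and_mutations <- function(n_proteins = 20L,
                                        protein_length = 120L,
                                        n_mutations = 30L, rules,
                                        seed = 1L) {
  stopifnot(protein_length >= 30)
  withr::local_seed(seed)
  proteome <- vapply(seq_len(n_proteins), function(i) {
    paste(sample(AA_RESIDUES, protein_length, replace = TRUE), collapse = "")
  }, character(1))
  names(proteome) <- sprintf("PROT%03d", seq_len(n_proteins))

  n_patients <- max(2L, ceiling(n_mutations / 10))
  patient_ids <- sprintf("PAT%02d", seq_len(n_patients))
  hla <- dplyr::bind_rows(lapply(patient_ids, function(p) {
    tibble(patient_id = p,
           allele = sample(names(rules), sample(seq_len(min(2L, length(rules))), 1L)))
  }))

  # Candidate sites are resampled until no reference window covering the
  # site is already a binder under any planted rule. Mirrors the exclusion
  # of normal-tissue-presented peptides in neoantigen benchmarks, and makes
  # the ground truth sharp: every mutant binder window is a gained one.
  ref_clean <- function(pid, pos) {
    for (k in MUT_LENGTHS) {
      starts <- max(1L, pos - k + 1L):min(pos, protein_length - k + 1L)
      wins <- substring(proteome[[pid]], starts, starts + k - 1L)
      for (r in rules) {
        if (any(planted_score(wins, r) > r$threshold)) return(FALSE)
      }
    }
    TRUE
  }
  muts <- vector("list", n_mutations)
  for (i in seq_len(n_mutations)) {
    for (attempt in 1:200) {
      pid <- sample(names(proteome), 1L)
      pos <- sample(15:(protein_length - 15L), 1L)
      if (ref_clean(pid, pos)) break
    }
    ref <- substr(proteome[[pid]], pos, pos)
    alt <- sample(setdiff(AA_RESIDUES, ref), 1L)
    muts[[i]] <- tibble(
      mutation_id = sprintf("MUT%03d", i),
      patient_id = sample(patient_ids, 1L),
      protein_id = pid, position = pos, ref = ref, alt = alt,
      tpm = round(stats::rlnorm(1L, log(10), 1), 2)
    )
  }
  mutations <- dplyr::bind_rows(muts)

  responders <- character(0)
  for (i in seq_len(n_mutations)) {
    m <- mutations[i, ]
    mut_wins <- extract_mutant_peptides(proteome[[m$protein_id]], m$position,
                                        m$ref, m$alt)
    ref_wins <- substring(proteome[[m$protein_id]], mut_wins$start,
                          mut_wins$start + mut_wins$length - 1L)
    pat_alleles <- hla$allele[hla$patient_id == m$patient_id]
    hit <- FALSE
    for (a in pat_alleles) {
      rl <- rules[[a]]
      gained <- planted_score(mut_wins$peptide, rl) > rl$threshold &
        planted_score(ref_wins, rl) <= rl$threshold
      immuno <- substr(mut_wins$peptide, 5L, 5L) %in% rl$central_residues
      if (any(gained & immuno)) {
        hit <- TRUE
        break
      }
    }
    if (hit) responders <- c(responders, m$mutation_id)
  }
  list(proteome = proteome, mutations = mutations, patient_hla = hla,
       responders = responders)
}

#' Write a complete synthetic fixture bundle to a directory
#'
#' Emits everything needed to run the pipeline from files: the
#' pseudo-sequence TSV, labeled pair CSVs (binding and immunogenicity), the
#' proteome FASTA, the mutation and patient-HLA CSVs, and a JSON ground
#' truth (planted anchors and responder ids). All outputs are plain text.
#'
#' @param dir Output directory (created if needed).
#' @param n_alleles Number of synthetic alleles.
#' @param pairs_per_allele Labeled pairs per allele.
#' @param seed Integer seed controlling the whole bundle.
#' @param ... Passed to [make_proteome_and_mutations()].
#' @return The directory path, invisibly.
#' @export
write_fixture_bundle <- function(dir, n_alleles = 3L,
                                 pairs_per_allele = 2000L, seed = 1L, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  al <- make_alleles(n_alleles, seed = seed)
  readr::write_tsv(al$pseudo, file.path(dir, "pseudo_sequences.tsv"),
                   col_names = FALSE)
  pairs <- purrr::map_dfr(seq_along(al$rules), function(i) {
    sample_labeled_pairs(al$rules[[i]], pairs_per_allele, seed = seed + i)
  })
  write_pair_table(pairs, file.path(dir, "binding_pairs.csv"))
  immuno <- purrr::map_dfr(seq_along(al$rules), function(i) {
    p <- sample_labeled_pairs(al$rules[[i]], pairs_per_allele, seed = seed + 100L + i)
    make_immunogenicity_labels(p, al$rules[[i]])
  })
  write_pair_table(immuno, file.path(dir, "immunogenicity_pairs.csv"))
  bundle <- make_proteome_and_mutations(rules = al$rules, seed = seed, ...)
  write_proteome(bundle$proteome, file.path(dir, "proteome.fasta"))
  readr::write_csv(bundle$mutations, file.path(dir, "mutations.csv"))
  readr::write_csv(bundle$patient_hla, file.path(dir, "patient_hla.csv"))
  truth <- list(
    responders = bundle$responders,
    anchors = lapply(al$rules, function(r) {
      list(anchors = r$anchors, residues = r$anchor_residues,
           threshold = r$threshold)
    })
  )
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
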