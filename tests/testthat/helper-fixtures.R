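# Shared fixtures built in code. Heavyweight objects (a trained model on
# planted-rule data) are built once per test run and memoised.

fixture_alleles <- function(n = 2, seed = 101) make_alleles(n, seed = seed)

# A tiny pseudo-sequence table with deterministic content (34-mers).
tiny_pseudo <- function() {
  tibble::tibble(
    allele = c("HLA-A*01:01", "HLA-B*07:02"),
    pseudo = c(
      strtrim(strrep("ACDEFGHIKLMNPQRSTVWY", 2), 34),
      strtrim(strrep("YWVTSRQPNMLKIHGFEDCA", 2), 34)
    )
  )
}

random_valid_peptide <- function(len) {
  paste(sample(setdiff(panneo::aa_alphabet(), "X"), len, replace = TRUE),
        collapse = "")
}

# Write a pseudo-sequence TSV and return its path.
write_pseudo_tsv <- function(tab, path = withr::local_tempfile(fileext = ".tsv",
                                                               .local_envir = parent.frame())) {
  readr::write_tsv(tab, path, col_names = FALSE)
  path
}

# Memoised small trained model on planted-rule data, reused across test
# files to keep the suite fast.
.fixture_env <- new.env(parent = emptyenv())

fixture_trained <- function() {
  if (is.null(.fixture_env$trained)) {
    al <- make_alleles(1, seed = 11)
    rule <- al$rules[[1]]
    pairs <- sample_labeled_pairs(rule, 600, positive_fraction = 0.5, seed = 12)
    cfg <- training_config(hidden = 8, layers = 3, epochs = 8,
                           batch_size = 64, dropout = 0.2, seed = 5)
    .fixture_env$trained <- list(
      alleles = al, rule = rule, pairs = pairs,
      model = hla_train(pairs, al$pseudo, cfg)
    )
  }
  .fixture_env$trained
}

# Full-scale planted-rule recovery fixture: one allele, 2,000 training
# pairs, the study-scale training configuration. Expensive (minutes); built
# once and shared by the recovery checks.
fixture_recovery <- function() {
  if (is.null(.fixture_env$recovery)) {
    al <- make_alleles(1, seed = 211)
    rule <- al$rules[[1]]
    pairs <- sample_labeled_pairs(rule, 2000, positive_fraction = 0.5,
                                  seed = 212)
    test <- sample_labeled_pairs(rule, 400, positive_fraction = 0.5,
                                 seed = 213)
    cfg <- training_config(hidden = 32, layers = 3, dropout = 0.2,
                           epochs = 35, batch_size = 16, seed = 214)
    fit <- hla_train(pairs, al$pseudo, cfg)

    raw_imm <- sample_labeled_pairs(rule, 4000, positive_fraction = 0.5,
                                    seed = 215)
    imm <- make_immunogenicity_labels(raw_imm, rule)
    pos <- imm[imm$label == 1, ]
    neg <- imm[imm$label == 0, ]
    k <- min(nrow(pos), nrow(neg), 800L)
    imm_train <- withr::with_seed(217, {
      d <- rbind(pos[seq_len(k), ], neg[sample(nrow(neg), k), ])
      d[sample.int(nrow(d)), ]
    })
    cfg_imm <- training_config(hidden = 32, layers = 3, dropout = 0.2,
                               epochs = 12, batch_size = 16, seed = 218)
    fit_imm <- hla_train(imm_train, al$pseudo, cfg_imm)
    .fixture_env$recovery <- list(alleles = al, rule = rule, pairs = pairs,
                                  test = test, model = fit,
                                  immuno_model = fit_imm)
  }
  .fixture_env$recovery
}

# A tiny deterministic network for forward-pass tests.
tiny_network <- function(hidden = 2, layers = 1, seed = 42) {
  panneo:::new_network(input_dim = 21, hidden = hidden, layers = layers,
                       seed = seed)
}
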