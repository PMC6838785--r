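---
title: "Models and methods behind panneo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind panneo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Only a small fraction of the missense mutations in a tumor yield peptides
that are (i) presented on the cell surface by the patient's HLA class I
molecules and (ii) capable of activating CD8+ T cells. panneo implements a
two-model pipeline for prioritizing such neoantigen candidates: a *binding*
classifier estimating the probability that an HLA presents a peptide, and
an *immunogenicity* classifier estimating the probability that the
presented complex activates T cells. The immunogenic score acts as a
filter (keep score >= 0.5) and the binding score drives the ranking; both
models share one architecture and one encoding.

# Encoding

Each HLA allele is represented by its 34-residue pseudo-sequence — the
binding-groove residues within contact distance of the peptide — so a
single model covers all alleles (pan-allele prediction). The
pseudo-sequence is concatenated with the peptide and one-hot encoded over
a 21-symbol alphabet (20 amino acids plus the padding symbol `X`), giving
a fixed 49 x 21 binary matrix: 34 pseudo-sequence rows followed by the
peptide right-padded to 15.

Two conventions here were genuinely open and are fixed by package
decision, not inference: the pseudo-sequence precedes the peptide, and
padding is applied on the right of the peptide segment so the
pseudo-sequence block always occupies positions 1-34. Any fixed convention
works because models are trained from scratch against this encoding; a
fixed block layout keeps each sequence region at stable positions, which
helps optimization. The alphabet is the 20 standard residues in
alphabetical order with `X` last; the ordering is embedded in saved models
and checked on load.

Pseudo-sequences are consumed as a two-column TSV. Deriving them from HLA
structures (the contact-distance computation) is out of scope; the package
ships none and tests use synthetic tables.

# The classifier

The network is three stacked bidirectional GRU layers with an attention
head. A GRU step follows the gate equations

    z_t = sigmoid(W_z x_t + U_z h_{t-1} + b_z)
    r_t = sigmoid(W_r x_t + U_r h_{t-1} + b_r)
    h_t = (1 - z_t) * h_{t-1} + z_t * tanh(W_h x_t + U_h (r_t * h_{t-1}) + b_h)

Note the update-gate convention: `z_t` multiplies the *candidate* state,
so `z_t = 0` copies the previous state. This is the mirror image of the
other common convention; the package implements the form above exactly,
and the unit tests pin it with hand-computed scalar cases.

Each bidirectional layer concatenates a left-to-right and a right-to-left
GRU pass (output width twice the per-direction hidden size). The attention
head scores each of the 49 positions with a learnable function
`e_t = tanh(w . h_t + b)`, converts scores to weights with a
max-stabilized softmax, and emits the weighted mean of the state sequence
as a context vector; an affine map and logistic sigmoid produce the final
score in (0, 1). The scoring function is a single affine map through tanh
— the simplest member of the feed-forward attention family; the published
description leaves its exact form open, so this is a package default, not
a claim of fidelity.

## Training

Training minimizes binary cross-entropy with Adam at learning rate 0.001.
Dropout at rate 0.2 is applied to each recurrent layer's output during
training only. After each epoch the model is evaluated on a stratified
10% validation split (or a caller-supplied validation set) and the
parameter snapshot with the best validation accuracy so far is kept; the
returned model carries that snapshot. Up to 100 epochs are supported;
given a seed, the whole run — initialization, split, batch order, dropout
masks — is bit-reproducible.

The forward and backward passes are hand-implemented in matrix code:
backpropagation through time with the input projections of all gates and
timesteps hoisted into single large matrix products. Correctness of every
gradient path is verified against central-difference numerical
differentiation in the test suite. Softmax is computed with
max-subtraction; predicted probabilities are clipped at 1e-12 inside the
loss only.

Defaults the published description does not fix, chosen here once: hidden
size 64 per direction per layer (configurable; the test and acceptance
runs use smaller networks, see *Problem sizes* below), batch size 128,
uniform initialization at scale 1/sqrt(fan-in). Checkpoints are saved with
`saveRDS` as a single self-describing object embedding the alphabet,
dimensions and training configuration.

# Data curation and pseudo-pair balancing

Binding records are filtered to HLA-A/B/C alleles, peptide lengths 8-15,
and consistent outcomes: a pair observed both positive and negative is
dropped entirely. Immunogenicity records keep the length rule but resolve
conflicts *to positive* — a complex that elicited T-cell activation at
least once is treated as immunogenic. Both filters deduplicate on
(allele, peptide), report per-reason rejection counts that sum to rows
removed, and are idempotent.

Per-allele class imbalance is repaired in two steps. A basic model is
trained on the collected pairs. Then, for each allele with `n_pos`
positive and `n_neg` negative pairs, `100 * |n_pos - n_neg|` candidate
peptides are drawn from a proteome (uniform protein, uniform 8-11-mer
window) and scored by the basic model; candidates scoring strictly below
0.1 become eligible negatives and strictly above 0.9 eligible positives,
and the deficient class is filled from them in scan order. Shortfalls are
reported, never padded. Alleles whose ratio still exceeds 5:1 (strictly,
in either direction, including single-class alleles) are removed, and the
final model is trained on the result. Pseudo records carry a `source`
tag end-to-end and never displace collected records on key collision.

# Neoantigen scanning and the presentation score

For each mutation the substituted protein yields every 8-, 9-, 10- and
11-mer window containing the mutated residue (8+9+10+11 = 38 windows for
an internal mutation, fewer at termini). All (window, patient-allele)
combinations are scored by both models; records with immunogenic score
strictly below 0.5 are discarded. The mutation's presentation score is

    Pr = sum over lengths i of [ sum over retained records of length i of
         BS_{i,h} * r_{i,h} ] / n_i

where `BS` is the binding score, `r_{i,h}` the fraction of length-i
training pairs for allele h labeled positive, and `n_i` the number of
*extracted* i-mers (before filtering). The printed form of this score
leaves the placement of the division ambiguous; the package places the
division inside the per-length term, making each term an average over that
length's extracted windows — the reading under which the quantity behaves
like a presentation probability. `n_i` deliberately counts extracted
windows, so discarding non-immunogenic records lowers the score rather
than renormalizing it.

Binder-ratio cells with no training data are imputed with the allele-wide
binder fraction (or the global fraction for unseen alleles) and flagged,
which avoids silently zeroing a length's contribution. Mutations are
ranked per patient by descending score; records are flagged
high-confidence when their binding-score rank is within the top k
(default 20). Ranking scope is per patient by default, with an optional
within-length-class mode for minimal-epitope comparisons. All ties break
lexicographically by identifier so output is deterministic. The
expression filter keeps mutations with TPM strictly above the threshold
and retains-but-flags mutations lacking TPM, since the filter is only
meaningful where RNA evidence exists.

# Motifs

The predicted binding motif of an allele is the position frequency matrix
of the top 1% of 100,000 random 9-mers by binding score (both counts
configurable; selection is rank-based, hence invariant to monotone
transforms of the score). The actual motif is the PFM of observed
binders. Comparison uses per-position argmax agreement and Jensen-Shannon
divergence as quantitative surrogates for visual logo similarity; they are
reported, not thresholded. PFMs serialize to TSV and minimal MEME motif
blocks; rendering is left to logo tools, with a ggplot-based `autoplot`
for quick inspection.

# Metrics

AUC is the rank-based Mann-Whitney statistic with half-credit ties;
accuracy thresholds at 0.5 with `>=` on the boundary; precision and recall
flag zero denominators as undefined rather than reporting 0. The k-fold
cross-validation splits records into random near-equal folds
(unstratified by default, matching a plain random partition; stratified
available) and averages per-fold validation results.

# The synthetic-data generator

Every recovery test runs on generated data with planted ground truth. A
planted rule is an additive 9 x 20 position weight matrix with 2-3 anchor
positions given large weights; its decision threshold is calibrated by
quantile so uniform random 9-mers are binders at a target rate. The
default rate is 0.05 — the order of magnitude of real presented-peptide
prevalence among random peptides — and deliberately low: the
mutation-level ground truth marks a mutation as a responder only when a
mutant window *gains* a binder call its reference window lacks, and that
definition only discriminates when pre-existing binder windows are rare. Labeled pairs are rejection-sampled to an exact positive fraction;
immunogenicity labels add a second planted rule (binder AND central
residue in a planted set). Proteome/mutation bundles mark a mutation as a
ground-truth responder when some mutant window gains a binder call that
its reference window lacks. The planted score itself achieves AUC 1 on its
own data — the ceiling every trained model is measured against.

Additive PWMs were chosen deliberately: they are the simplest structure a
recurrent network can learn and a PFM can visualize, so motif-recovery
tests are meaningful. What passing these tests does *not* show: real
binding chemistry is not additive per-position, real training data is not
class-balanced or i.i.d., and pseudo-sequences here are random strings
with no structural meaning. Recovery on planted rules demonstrates that
the machinery — encoding, gradients, training loop, ranking arithmetic —
is correct, not that the retrained model matches published predictive
performance on IEDB-scale data, which is out of scope.

# Problem sizes and numerical choices

The recovery suites train on 2,000 labeled pairs for a single planted
allele — enough for the planted rule to be learnable while training in
minutes on one CPU. For these runs the package uses hidden size 32 and
batch size 16: smaller batches give proportionally more Adam updates per
epoch, which matters more than capacity at this data scale; the stated
optimizer settings (Adam 0.001, dropout 0.2, BCE) are kept as-is. The
mutation-scan checks use bundles of 120 mutations across ~12 patients so
the planted-responder rank statistics rest on a handful of responders
rather than one or two.
Cross-validation examples run the same configuration at reduced epochs.

Degenerate inputs are contracts, not crashes: single-class datasets are
refused; empty record sets yield presentation score 0; unknown alleles
name the offending pair; reference-residue mismatches name both residues.
Boundary conventions follow the printed inequalities everywhere they are
stated (confidence window strictly <0.1 / >0.9; pruning strictly >5;
immunogenicity filter drops strictly <0.5; expression filter keeps
strictly >TPM threshold).

# Known limitations

- Training is CPU-bound R matrix code; it is suitable for the desk-scale
  experiments here, not for corpus-scale training.
- The attention form and hidden sizes are package defaults; no weight
  compatibility with any released checkpoint is intended.
- The immunogenicity model treats any pair ever validated as activating
  T cells as positive; patient-specific TCR repertoires are not modeled.
- Pseudo-sequence derivation, variant calling, expression quantification
  and HLA typing all happen upstream of this package.
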