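---
title: "Haplotype-block autoencoders: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-block autoencoders: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented by `haploencoder`, the
assumptions behind them, and the choices made where the design was
genuinely open. It is the reference for why the defaults are what they
are.

## The problem

Breeding panels are genotyped at tens to hundreds of thousands of
biallelic SNPs, coded here as −1 (homozygous minor), 0 (heterozygous),
+1 (homozygous major). Because recombination is locally rare, adjacent
markers form haplotype blocks: runs of markers in high mutual linkage
disequilibrium carrying only a handful of distinct variant combinations.
The package compresses each block to a single continuous feature with a
block-masked autoencoder, uses those features in standard genomic
prediction machinery, and prices individual block variants through a
supervised extension of the same network.

## Haplotype block construction

Blocks are built per chromosome by a greedy left-to-right scan in map
order. The LD measure is the squared Pearson correlation of dosage codes
(`ld_r2`); for fully homozygous lines this equals the haplotype-level r²,
and for unphased hybrids it is the composite-LD analogue — which is why
dosage correlation, not phased r², is used throughout. A marker joins the
growing block when its r² with the block's current last marker is at
least `ld_threshold` (default 0.7); up to `tolerance` (default 1)
sub-threshold joins per block are tolerated. Two decisions were open:

* **Scan semantics of the tolerance.** We read "one marker below the
  threshold" as *at most one tolerated sub-threshold adjacent join per
  block*. A block may not *end* on a tolerated join: trailing tolerated
  joins are trimmed and the trimmed marker restarts the scan. Without
  trimming, every isolated low-LD marker would be glued to the preceding
  block, which contradicts the idea that the tolerance bridges a gap
  *inside* a block.
* **Adjacent vs all-pairs LD.** Block building needs only flanking-pair
  r² (O(m)); `pairwise_ld` computes the full matrix for diagnostics but is
  never used in the scan.

Blocks of a single marker are not blocks; their markers stay unassigned.
They are excluded from the encoder input but kept in the reconstruction
target (below). An exhaustive-check oracle in the test suite verifies on
small chromosomes that every emitted block satisfies the tolerance
contract.

One consequence worth knowing: when two physically adjacent blocks sit in
moderate LD (boundary r² just below the threshold), the tolerance will
merge them pairwise. This is faithful to the scan semantics; it only
changes the granularity of the features, not the partition property.

## The block-masked autoencoder

For a block of n markers the encoder is a direct n → 1 linear stage, or,
when n ≥ `optional_layer_min_block` (default 4, "at least four markers"),
an n → ⌊n/2⌋ stage, a leaky ReLU (negative slope 0.1), and a ⌊n/2⌋ → 1
stage. Each block feeds exactly one unit of the *block layer*; encoder
weights never cross block borders. The decoder connects the block layer
densely to a hidden layer of `decoder_hidden` units (default 1000, leaky
ReLU) and on to a tanh output covering **all** filtered markers — the
unassigned markers are reconstructed purely from the decoder, so the
model can still learn their association with blocks (useful when a
marker's physical position is wrong and its true block is elsewhere).

Open points and how they were fixed:

* **Block-layer activation.** The block layer itself is linear by default
  (`block_activation = "linear"`): extracted features and the yield-head
  variant effects are then unsquashed and live on an interpretable scale.
  A leaky option is provided.
* **Initialisation.** Uniform(−1/√fan_in, +1/√fan_in) per stage — the
  conventional dense-layer default — with a mandatory integer seed;
  full-batch training makes runs bitwise reproducible.
* **Masking.** The block-diagonal encoder is implemented as per-block
  weight groups, which enforces the mask structurally;
  `encoder_weight_matrices()` materialises the equivalent dense masked
  matrices so tests can assert that every cross-block weight is exactly
  zero.
* **Batching.** Full batch is the default so the correlation term of the
  semi-supervised loss is well defined at every optimisation step. A
  minibatch mode exists; there the yield terms use the labelled samples
  present in each batch.

Training is Adam at learning rate 0.001 for 100 epochs (the defaults are
deliberately not tuned per dataset — one fixed configuration everywhere).
AE1 features are the block-layer outputs after unsupervised training.
Because neighbouring features are often highly correlated, a second step
groups features whose adjacent absolute Pearson correlation strictly
exceeds 0.7 into meta-blocks (tolerance 0; absolute correlation because
feature signs are arbitrary) and trains a fresh autoencoder of the same
architecture on them; its block layer gives the AE2 features. When no
meta-block of size ≥ 2 exists, no reduction is possible and the AE1
features are returned with a warning — the pipeline degrades gracefully
rather than inventing structure.

## Semi-supervised loss and variant effects

With phenotypes, a single linear unit with weight vector w_Z and *no
intercept* is attached to the block layer, and the loss becomes

MSE(X, X̂) − cor(y, ŷ) + MSE(y, ŷ) + λ‖w_Z‖², λ = 0.001.

The correlation term directly optimises ranking; the MSE(y, ŷ) term pins
the predictions to the trait scale (the correlation alone is scale-free);
the ridge term shrinks the yield head exactly as RR-BLUP shrinks marker
effects. Reconstruction terms run over all samples, yield terms only over
the labelled training set — the semi-supervised split. When ŷ is constant
the correlation term is set to 0 (with zero gradient) instead of
propagating NaN. Phenotypes are not centred by default because the head
has no intercept; a `center_y` switch exists for users who want deviations.

The effect of variant v in block b is (block-layer output of b evaluated
on v's raw −1/0/1 codes) × w_Z[b]. Raw codes are used because the network
was trained on raw codes. Block-locality makes the effect well defined
for variants never seen in training — the practical advantage over
dictionary-based block encodings.

## Mixed models

`grm_vanraden` implements method I: Z is the column-centred code matrix
and G = ZZ′ / 2Σpⱼ(1−pⱼ). For rescaled autoencoder features the "allele
frequency" is the formal pⱼ = (column mean + 1)/2 — a documented
convention, since features are not alleles. Note that column centring
makes G rank-deficient by one; all downstream algebra uses the
pseudo-inverse where needed.

The line model y = 1β₀ + u + e is fitted by exact REML profiled over the
variance ratio in the eigenbasis of G (a 1-D optimisation, no iteration
to diverge). The hybrid model y = 1β₀ + Z₁u₁ + Z₂u₂ + Z_s u_s + e uses
cov(u_s) = σ²_s G_s with G_s the Kronecker product G₁ ⊗ G₂ restricted to
the realised parent pairs — elementwise K₁ ∘ K₂ on the hybrid index, so
the full Kronecker matrix is never formed. Variance components come from
AI-REML with an EM fallback whenever an AI step leaves the parameter
space or decreases the restricted likelihood; EM steps are monotone,
which the tests assert on the returned trace. Convergence is a relative
log-likelihood change below 1e−8 within 200 iterations (error with trace
otherwise); variance components are clamped at a 1e−10 boundary.

Marker effects come from the GBLUP ↔ RR-BLUP equivalence,
â = Z′G⁻¹û / c, evaluated with the eigen pseudo-inverse. Back-
transformation is defined for the single-kernel model only; when block
effects are wanted for hybrids, a single-kernel additive GBLUP is fitted
on the hybrid code matrix for that purpose (the GCA/SCA decomposition has
no unique per-marker additive representation). The baseline block-variant
effect is the sum of centred variant codes times marker effects; by
linearity these sums plus the unassigned-marker contributions reconstruct
every genotype's BLUP exactly, which the tests verify.

Per-block comparisons of the two effect estimators use Pearson
correlation across variants and require at least `min_variants = 3`
distinct variants — a 2-point correlation is always ±1 and would fill the
histogram's extremes with artefacts. The parameter is exposed (set it to
2 to reproduce the two-variant regime). For display, effects are scaled
per method by the largest *absolute* effect, preserving signs and mapping
onto [−1, 1].

## Evaluation

The Mantel test compares relationship matrices on their off-diagonal
entries (the correlation is invariant to the affine similarity-to-
distance conversion); permutations (default 999, p-value resolution
1/(n_perm+1)) are delegated to `vegan::mantel`, with an independent
hand-rolled permutation loop as the cross-check oracle in the tests.
Cross-validation uses 100 seeded 80/20 splits by default; accuracy is the
test-set Pearson correlation and constant predictions are reported as NA,
never silently dropped or coerced to 0. The T0 scenario samples a parent
subset on each side (size chosen so the expected test share matches
`test_fraction`), takes hybrids with both parents sampled as the test set
and hybrids with neither as the training set; hybrids with exactly one
sampled parent are discarded for that replicate. Parent-subset sampling
was chosen over post-hoc removal from standard splits because it keeps
the test-set size controllable.

## The synthetic data generator

`simulate_genotypes` plants what the method assumes: contiguous blocks
with a limited set of variants each. Variants are built from a founder
pattern by prefix flips at spread-out cut points, so two-variant blocks
have r² = 1 at every within-block adjacent pair and each extra variant
adds one interior cut where LD dips — a crude but controllable analogue
of recombination ladders. Samples draw one variant per block; a
within-block mutation rate softens LD; filler markers between blocks are
drawn independently. Two structure mechanisms reflect real panels:
`inter_block_ld` carries a sample's latent ancestry across neighbouring
blocks (smoothly decaying LD), and `n_subpops` with `subpop_divergence`
emulates divergently selected pools (as in heterotic groups), which is
what makes per-block features correlated genome-wide and gives the
second autoencoder genuine redundancy to compress.

`simulate_trait` draws Gaussian per-marker effects and rescales the
residual noise (after orthogonalising it against the genetic values) so
the realised Var(g)/Var(y) equals h² exactly; phenotypes are standardised
to unit variance. Optional local epistasis multiplies centred codes of a
random marker pair in a fraction of blocks, scaled so that fraction f of
blocks contributes f × Var(additive). A caveat the tests document: with
complete within-block LD and few variants, any within-block interaction
lies in the span of the block's additive codes and is therefore *not*
detectable as non-additivity — blocks capture local epistasis by
construction. Only with within-block noise does the interaction escape
the additive span. `simulate_factorial` draws GCA/SCA effects from the
parental relationship matrices (u₁ ~ N(0, σ²₁G₁) etc.), so REML recovery
of the planted components is a well-posed round trip.

What the generator does **not** emulate: coalescent allele-frequency
spectra, recombination maps, genotyping error beyond the flip model,
selection, and long-range admixture gradients. Passing tests on this
generator show the machinery is correct under the model's own
assumptions; they do not certify accuracy numbers on any real panel.

## Problem sizes and numerical choices

Pipeline-level checks run at 300 samples × ~2000 markers in ~190 planted
blocks (two subpopulations, divergence 0.9, mutation 0.02, h² = 0.5),
with 20 cross-validation replicates — large enough for stable medians,
small enough to run in minutes on one CPU; the same conditions are used
by `scripts/acceptance.R`. Unit-level oracles use 20 × 50 toys. Other
numerical choices: tanh keeps reconstructions strictly inside (−1, 1);
imputation is per-marker mode with the deterministic tie order 0, +1, −1;
the data filter (samples with > 60% missing, then markers with ≥ 10%
missing or expected heterozygosity 2p(1−p) < 5%) is iterated to a fixed
point so filtering is idempotent; major-allele ties at p = 0.5 resolve to
the REF/first-listed allele.

## Limitations

* The −1/0/1 coding collapses functionally different heterozygous block
  variants of hybrids onto the same code vector (phase is lost); variant
  effects for hybrids are therefore effects of code patterns, not of
  haplotype pairs. A two-channel parental-haplotype encoding would fix
  this at twice the input width and is deliberately out of scope.
* The autoencoder is trained with one fixed architecture and schedule
  everywhere; no per-dataset tuning is attempted, so the supervised head
  can underperform a tuned predictor.
* Mode imputation is a stand-in adequate for the low missingness left
  after filtering; for heavily incomplete data an external imputer should
  be run first and its output read in.
* Blocks are univariate features: within-block dominance or phase
  information beyond the code pattern is not represented.
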