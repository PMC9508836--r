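---
title: "Calling de novo mutations in trios from pileup images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling de novo mutations in trios from pileup images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trioDNM)
```

## The problem

A de novo mutation (DNM) is a variant present in a child but inherited from
neither parent. DNMs are a major cause of severe developmental disorders, so
calling them reliably from child–father–mother ("trio") sequencing is a core
task in rare-disease genetics. The naive recipe — keep child variants absent
from both parental call sets — drowns in artifacts: sequencing errors,
mapping problems, uneven coverage, and borderline parental evidence produce
far more Mendelian-violation candidates than true DNMs (an exome typically
carries only one or two coding DNMs).

`trioDNM` implements a two-stage caller:

1. **Candidate generation.** Child variants whose normalized
   (contig, position, ref, alt) key occurs in either parent's VCF are
   discarded. This is a pure allele-aware set subtraction — the same
   operation as `bcftools isec -C` — and typically shrinks the problem
   ten-fold.
2. **Classification.** Each surviving candidate is judged *de novo* vs
   *inherited/artifact* from the aligned reads themselves, either by a
   convolutional network over an image encoding of the trio pileup, or by a
   deterministic rule-based caller on parental coverage and variant allele
   fraction (VAF).

The design replicates how a human analyst reviews candidates in a genome
browser: look at the three pileups around the site and decide whether the
child's alternate allele is real and absent from the parents.

## Image encoding

For a candidate at position $p$ we extract, per trio member, every primary,
non-duplicate, QC-pass read overlapping the 41-position window
$[p-20, p+20]$. The window becomes a $160 \times 164 \times 3$ integer
image:

* **Rows** are reads, in deterministic (leftmost position, read id) order,
  capped at 160 reads; missing rows stay zero.
* **Columns** come in 41 blocks of 4 pixels, one block per genomic
  position; within a block the pixels one-hot encode A, C, T, G. The
  variant's first base sits in block index 20 (image columns 81–84).
* **Channels** are child, father, mother.
* **Intensity** is $\mathrm{round}\!\big(255 \cdot \min(1, q_b/40) \cdot
  \min(1, q_m/60)\big)$ for base quality $q_b$ and mapping quality $q_m$ —
  monotone in both, saturating at the common Illumina maxima. The caps are
  configurable through `intensity_model()`.

Reads are rasterized in alignment-column coordinates anchored so that the
read base aligned to $p$ lands in block 20: inserted bases consume
subsequent blocks (a visible frameshift), deleted reference positions
appear as unlit blocks inside the read's span, and soft-clipped or N bases
light nothing. Reads overlapping the window but not covering $p$ are
anchored by their leftmost in-window column. These rendering rules are
config-isolated so alternative indel layouts can be swapped without
touching the classifier.

```{r encode-example, eval = FALSE}
site <- simulate_site(sim_params(), seed = 7)
img <- encode_trio(site$window)
img                       # 160 x 164 x 3, metadata attached
write_image_png(img, "site.png")   # lossless debug view
```

## The classifier

Three binary classifiers are used, one per variant type (substitutions,
insertions, deletions), because the three classes have distinct visual
signatures and very different prevalence. The architecture is deliberately
plain: nine same-padded $3\times3$ convolutions with 96 filters and ReLU;
after every third convolution, batch normalization followed by a
squeeze-and-excitation (SE) channel-attention block (reduction ratio 16 by
default — the canonical SE setting, configurable); finally concatenated
global max and global average pooling feed one sigmoid unit whose weights
carry an L1 penalty. A candidate is labelled DNM when the predicted
probability is at least 0.5 (inclusive).

The engine is implemented in the package itself (C++/Armadillo): pixel
intensities are scaled to $[0,1]$, convolutions run as nine shift-GEMMs on
zero-padded feature maps, batch-norm statistics are taken per channel over
the whole mini-batch, and the analytic gradients are verified against
finite differences in the test suite. Training uses binary cross-entropy
with Adam (substitutions) or AdamW with decoupled weight decay (indels),
mini-batches, a stepwise learning-rate decay of $0.5$ every 10 epochs
($\mathrm{lr}(e) = \mathrm{lr}_0 \cdot 0.5^{\lfloor e/10\rfloor}$, 0-based
epoch $e$), early stopping after a patience of 40 epochs without
validation improvement (default), and best-validation-epoch
checkpointing. The insertion and deletion models warm-start from the
trained substitution weights, which matters because indel training sets
are much smaller. Augmentation operates at training time only: global
brightness scaling by a factor in $[0.3, 1]$, read-order shuffling,
random coverage downsampling, and on-the-fly synthesis of adjacent
substitutions to enrich multi-nucleotide variants. MNV synthesis edits
windows rather than images so that the second substitution carries
realistic quality values.

Hyperparameters can be tuned with a seeded random search over the
documented space (filters in {32, 64, 96, 128}, batch size in {32, 64},
log-uniform L1 in $[10^{-10}, 0.1]$, learning rate in $[10^{-8}, 0.01]$,
weight decay in $[10^{-8}, 0.01]$), selecting the lowest validation
cross-entropy. A multi-bracket successive-halving scheduler would explore
the same space more efficiently at large budgets, but adds no value at the
budgets this package targets, so plain random search was chosen. The
default learning rate ($10^{-3}$), L1 ($10^{-6}$) and batch size (32) are
the package's own defaults, not tuned optima.

## The rule-based caller and hard filters

The deterministic baseline mirrors long-standing diagnostic practice. A
candidate passes when both parents have coverage $\ge 10$ and either carry
no alternate reads at all, or both have VAF $\le 15\%$ with fewer than 3
alternate reads. Around it sit two hard filters, reported alongside every
call: a population allele-frequency pre-filter (WES: AF $< 1\%$; WGS: AF
$< 0.1\%$ and upstream caller quality $> 15$; missing AF counts as novel)
and a high-quality post-filter (all three members $\ge 10$ reads, child
VAF $\ge 20\%$, population AF $< 0.01\%$). Boundary semantics are
implemented exactly as stated — inclusive/exclusive as written — and the
test suite compares the caller against a brute-force boolean oracle over
an exhaustive parental depth/alt grid. Depth counts spanning reads with
mapping quality $> 0$; alt support is CIGAR-consistent (an insertion
carrier must show the inserted bases, a deletion carrier the gapped
reference positions), mirroring pileup conventions.

## The simulator

Every other module is testable without external data because the package
ships a seeded trio read simulator. Per member it draws
$\mathrm{Poisson}(\bar d)$ reads spanning the site (default $\bar d = 30$,
80 bp reads), injects the alternate allele at the member's VAF — child at
`child_vaf` (0.5 for a germline het; lower values model mosaicism),
carrier parents at 0.5 for the inherited modes — adds base miscalls at a
$10^{-3}$ per-base rate, and samples base qualities from a truncated
normal centred at 35 (s.d. 4, capped at 40) and mapping qualities centred
at 55 (s.d. 5, capped at 60), emulating a clean modern Illumina exome.
The `artifact` mode scatters low-quality alternate bases (quality centred
at 10) across all three members at VAF 0.08, mimicking recurrent
sequencing/mapping noise. Datasets lay sites far enough apart on a
synthetic random reference that windows never overlap, and
`write_fixture()` emits the reference FASTA (indexed), one sorted and
indexed BAM per member, and bgzipped + tabix-indexed per-member VCFs that
external tools (samtools, bcftools) accept.

What the simulator does **not** model: platform-specific error spectra,
GC/coverage waves, alignment artifacts around repeats, strand bias, or
soft-clipping. Tests passing on simulated data therefore demonstrate the
correctness of the machinery (extraction, encoding, arithmetic, training
dynamics) and the separability of clean evidence classes — not real-world
error robustness, which in the original setting required tens of
thousands of manually curated training images.

## Numerical and design choices

* Internal coordinates are 0-based half-open; VCF positions are converted
  on read. Window arithmetic is asserted (`window_start + 20 ==
  variant_position`).
* Candidate matching splits multiallelics and parsimony-trims alleles
  (shared suffix then prefix). Reference-aware left-alignment is expected
  upstream (`bcftools norm`); simulated fixtures are emitted
  pre-normalized. Equivalence with `bcftools isec -C` is tested on
  randomized fixtures.
* Length-preserving multi-nucleotide changes route to the substitution
  model (the training augmentation synthesizes adjacent substitutions
  there); complex indels route by net length change, keeping the three-way
  routing total.
* Read order at inference is the deterministic sort; row overflow keeps
  the first 160 reads under that sort. Shuffling is a training-time
  augmentation only.
* Metric percentages are rounded half-up to 2 decimals (this matches
  every published benchmark cell bundled with the package); metrics with
  zero denominators are reported as `NA`, never 0.
* Brightness augmentation is applied globally rather than per channel;
  per-channel scaling would distort the relative evidence between family
  members, which is the signal of interest.
* Batch-norm uses $\epsilon = 10^{-5}$ and running-statistics momentum
  0.9; the SE bottleneck floors at one unit; BCE probabilities are clamped
  at $10^{-12}$.
* Training memory scales with (stored activations) $\approx$ layers
  $\times$ filters $\times$ 26.5k pixels $\times$ batch; the full
  96-filter architecture should be trained with small batches on
  memory-constrained machines.

## Problem sizes used in the shipped checks

The package's own tests and the reproduction script run entirely on
simulated data at desk scale, chosen to exercise the full pipeline while
remaining comfortable on a single CPU: 200-site trios for the end-to-end
rule-based check, 2,400 simulated substitution images (2,000 training /
400 held out) for the CNN check with a scaled-down network (3 conv layers,
8 filters — the SE/BN cadence, head and training schedule are identical to
the default architecture), and at most 10 training epochs. With clean
simulated classes this reaches held-out accuracy well above 95%; the
published-scale architecture and cohort sizes are neither needed nor
attempted for these checks.

## Known limitations

* The CNN is only as good as its training distribution; the shipped
  simulator produces much cleaner classes than curated real-world data.
* CRAM support follows the same reader contract as BAM but requires the
  reference FASTA.
* The candidate stage trusts the upstream caller: a DNM absent from the
  child's VCF can never be recovered.
* No genotype-likelihood modelling is attempted; the rule-based caller is
  deliberately a hard-threshold instrument.
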