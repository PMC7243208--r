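---
title: "Haplotype kernels, annotation classes and REML: the methods behind haplogp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype kernels, annotation classes and REML: the methods behind haplogp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`haplogp` predicts quantitative traits from phased genotypes with
relatedness kernels built on haplotype blocks, optionally restricted to
genomic classes taken from a genome annotation. This vignette explains the
models, the tunable parameters and their defaults, the numerical choices,
and what the bundled simulator does and does not emulate.

## The model

Everything rests on the univariate animal model

$$y = \mathbf{1}\mu + a + e,\qquad
  a \sim N(0,\sigma_a^2 K),\qquad e \sim N(0,\sigma_e^2 I),$$

where $y$ are phenotypes pre-adjusted for environmental fixed effects and
$K$ is one of nine relatedness kernels. The pipeline never changes the
model — only $K$ — so differences between prediction methods are exactly
differences in how relatedness is measured.

Phenotype adjustment is one ordinary least-squares fit of the trait on
sex, year, body weight at entry and days on feed, done once on all
phenotyped individuals before any cross-validation. Residuals are the
`y_adj` used everywhere downstream; they are mean-zero and orthogonal to
every fixed-effect column by construction.

## Quality control

Markers failing any of: call rate > 0.90, minor-allele frequency > 0.01,
Hardy–Weinberg exact-test p > 10⁻⁶ are removed first (all three assessed
on the input matrix); individuals with call rate ≤ 0.90 on the surviving
markers are removed second. All thresholds are strict inequalities. The
HWE test is the standard conditional exact test on genotype counts with no
mid-p correction. Imputation is deliberately out of scope: the reader
rejects missing or unphased genotypes, so complete phased input is a
contract, not an aspiration.

## Haploblocks and their two encodings

Within a SNP set (the markers of one annotation feature, or a whole
chromosome), a greedy left-to-right scan grows a block marker by marker
and closes it when adding the next marker would push the number of
*distinct haplotype strings observed in the population* (over all $2n$
phased haplotypes) beyond `max_alleles = 10`. Ten allele types per block
is the ceiling used throughout; the scan keeps ≤ 10 and re-starts at the
offending marker. One-marker sets and trailing singletons stay as plain
0/1/2 columns. Distinctness is counted population-wide because the
categorical model needs a finite observed allele catalog. Catalogs are
sorted lexicographically over the 0/1 strings so column order is
deterministic.

Two encodings serve different assumptions:

* **Numerical dosage** – one pseudo-marker per catalog allele holding the
  number of copies (0/1/2) the individual carries. Row sums over a block
  are 2. This assumes intra-locus additivity of haplotype allele effects.
* **Categorical** – each unordered pair of catalog alleles (a genotype
  configuration) is one state with its own potential effect; no additivity
  assumed, which lets configuration (dominance-like) effects through.

## The nine kernels

With $m$ markers, $Q_H$ whole-genome blocks and $Q_H^{GA}$ class-restricted
blocks:

| family | whole-genome SNPs | whole-genome blocks | class blocks |
|---|---|---|---|
| dosage | $G=\frac{(M-P)(M-P)'}{2\sum p_i(1-p_i)}$ | $G_H = M_H M_H'/Q_H$ | $G_H^{GA} = M_H^{GA}{M_H^{GA}}'/Q_H^{GA}$ |
| categorical (IBS) | $S$: share of markers in identical state | $S_H$ | $\tilde S$ |
| categorical epistasis | $E = \tfrac12(mS)\odot(mS+1)/m^2$ | $E_H$ (with $Q_H$) | $\tilde E$ (with $Q_H^{GA}$) |

The epistasis lift has a combinatorial identity: if two individuals share
$s$ of $c$ loci, the number of unordered locus pairs (self-pairs included)
in identical joint state is $s(s+1)/2$, hence $E = \tfrac12 (cS)(cS+1)/c^2$
with diagonal exactly $(c+1)/2c$. The test suite verifies every kernel
against independent nested-loop implementations, and that single-SNP
blocks collapse $S_H, E_H$ onto $S, E$ exactly.

$G_H$ is deliberately *uncentered* (no $P$ subtraction): the haplotype
formula is a raw cross-product of allele counts. Scale differences between
kernels do not matter for inference (next section), and exported matrices
match the formulas bit for bit — the solve-time ridge is never stored.

## REML and BLUP

Because the kernels live on very different scales ($G$ has mean diagonal
≈ 1, $G_H$ diagonals lie in $[2,4]$, $E$-family diagonals equal
$(c+1)/2c$), `reml_kernel()` first rescales $K$ to unit mean diagonal.
$\sigma_a^2$ is then genetic variance on the phenotypic scale,
$h^2=\sigma_a^2/(\sigma_a^2+\sigma_e^2)$ is comparable across kernels, and
all estimates are invariant to multiplying a kernel by a constant (the
variance ratio simply rescales) — the property that justifies the
different denominators in the kernel table. The stored `kernel_scale`
keeps BLUP consistent with the fit.

The restricted likelihood is maximised exactly: one eigendecomposition of
the (ridged) kernel turns the 2-parameter problem into a 1-D search over
$\log\lambda$, $\lambda=\sigma_a^2/\sigma_e^2$, solved by Brent's method on
$h^2\in[10^{-4}, 1-10^{-4}]$ with tolerance $10^{-10}$; $\sigma_e^2$ is
profiled analytically. Estimates pinned at the bounds are flagged
`boundary`, not errors. The standard error of $h^2$ comes from the inverse
observed information (central finite differences) via the delta method.
A diagonal ridge of $10^{-6}$ is added at solve time only. The spectral
solution is checked in the tests against a naive two-parameter optimiser
on the full restricted likelihood.

DGVs solve the mixed-model equations on the training individuals and
propagate through the kernel:
$\hat a = \sigma_a^2 K_{\cdot,t}\,V^{-1}(y_t-\hat\mu)$ with
$V=\sigma_a^2K_{tt}+\sigma_e^2I$, so masked individuals receive
predictions without contributing records, and an empty mask reproduces the
training BLUPs.

## Cross-validation, accuracy and bias

`make_cv_layouts()` assigns individuals to five near-equal folds by random
permutation, independently per replicate, deterministically per seed.
For each replicate and fold, variance components are re-estimated on the
training 80% and DGVs predicted for the fold; the five folds' validation
predictions are pooled so each replicate yields *one* accuracy,
$\mathrm{cor}(\mathrm{DGV}, y_{adj})/\sqrt{h^2}$, and one bias slope
$b(y,\mathrm{DGV})$. A slope of 1 is unbiased; > 1 means deflated
(under-dispersed) DGVs, < 1 inflated ones.

The $h^2$ in the accuracy denominator should be a property of the *trait*,
not of the kernel being evaluated: using each kernel's own estimate makes
accuracies incomparable (a kernel that inflates $\hat h^2$ is punished in
proportion). `run_cv()` defaults to the fitted kernel's full-data estimate
when used standalone, but model comparisons should pass one shared `h2` —
the all-SNP GRM estimate for real data, or the simulator's recorded
realized heritability for synthetic data (exact, and architecture-neutral:
a purely epistatic trait has near-zero GRM-visible heritability yet a
well-defined genetic variance fraction).

Bias significance deserves care. The twenty replicates reuse the same
records and are strongly correlated, so a one-sample t-test with standard
error $SD/\sqrt{20}$ wildly overstates precision and would flag slopes a
few hundredths away from 1. The flag therefore uses the replicate standard
deviation itself as the dispersion of the estimate:
$|\bar b - 1| > t_{0.975,\,r-1}\,SD$. Under this convention
well-specified dosage models come out unbiased while strongly deflated
epistasis models are flagged, which is how such CV tables are read in
practice.

## The simulator

`sim_config()` defaults describe the cohort the package is designed
around: 1331 individuals; five chromosomes × 400 markers over 1.5 Mb each
(≈ 3.8 kb spacing, a high-density chip); LD whose $r^2$ crosses 0.2 near
34 kb; 40 non-overlapping genes per chromosome of 4–20 kb (≈ one third of
the genome genic) with 1–4 exons each, every exon partitioned into CDS and
UTR with UTR caps on terminal exons; target $h^2 = 0.4$; and fixed effects
(sex, year, two covariates, each component SD 0.25 on the unit-genetic
scale) explaining ≈ 20% of phenotypic variance so the adjustment step has
real work to do.

Haplotypes come from a founder mosaic: 30 founder haplotypes per
chromosome whose alleles follow a Gaussian-copula AR(1) along the markers
(latent correlation $e^{-\rho d}$), each gamete copying a founder and
switching to a random one between markers with probability $1-e^{-\rho d}$.
The single rate $\rho$ (`ld_decay`, default $6\times10^{-6}$ per bp) was
calibrated once so realized $r^2$ crosses 0.2 at ≈ 30–35 kb; `ld_decay = 0`
degenerates to exact founder copies, very large values to free
recombination. This emulates LD decay and allele-frequency spectra, **not**
demographic history, selection, pedigree structure, or sequence-level
mutation — so passing tests say the methods behave correctly under
chip-like LD, not that any particular breed's accuracy figures transfer.

Three architectures realize the model contrasts the kernels are built for:

* `snp_additive` — i.i.d. normal effects on `n_qtl` markers (set
  `n_qtl` near the marker count for a simulation that matches the GBLUP
  prior exactly);
* `haplotype_qtl` — effects attached to the distinct haplotype alleles of
  3–5-marker windows, so the QTL is multi-allelic and no single SNP tags
  it completely (verified as an invariant);
* `epistatic` — effects attached to unordered genotype-configuration pairs
  of two-SNP windows, the exact state a haploblock-pair epistasis kernel
  measures.

Genetic values are centred and scaled so
$\mathrm{var}(g)/(\mathrm{var}(g)+\mathrm{var}(e))$ hits `h2_target`; the
realized value is recorded in the truth, never assumed. QTL placement
respects `qtl_class_bias` (fraction inside genes). Identical
configurations produce byte-identical VCF/GFF3/TSV output.

## Numerical and design choices

* Marker orientation: indicators always count the minor allele; the
  container flips columns whose indicator frequency exceeds 0.5 (ties keep
  the ALT allele), so a VCF write–read round trip reproduces dosages
  exactly.
* Overlapping same-class annotation features are merged into union
  intervals before SNP assignment, so no marker is duplicated within a
  class (duplication would silently inflate $Q_H^{GA}$);
  `merge_overlaps = FALSE` preserves per-feature duplication for
  comparison. Feature boundaries are inclusive; strand is ignored.
* Intergenic regions are the exact complement of the merged genes within
  `[1, chromosome length]`; gene and IGR therefore tile the genome and
  every QC-passed marker belongs to exactly one of the two.
* Single-SNP columns count toward $Q$ and enter the categorical kernels as
  one-locus blocks with the 0/1/2 genotype as their state.
* QC order: marker filters before the individual call-rate filter;
  applying QC twice equals applying it once on the fixtures tested.
* Degenerate inputs: monomorphic-only marker sets, singular training
  systems and confounded fixed-effect designs raise errors naming the
  offender; boundary REML estimates are flagged and returned.

## Problem sizes used in the checks

The study-scale tests use n = 800, m = 2000 (20 datasets) for
heritability recovery, and n = 500, m = 2000 with 20 CV replicates × 5
folds for the directional model comparisons (haplotype vs SNP kernels,
gene-class vs whole-genome blocks, epistasis vs plain categorical) and the
bias check. These sizes give stable means over replicates while keeping
the full suite in the minutes range on one CPU.

## Known limitations

* Single random effect only: no multi-kernel, multi-trait or Bayesian
  variants; no dominance GRM or Gaussian/RKHS kernels.
* Autosomal, biallelic, phased and complete input only; no imputation or
  phasing.
* The greedy block scan is one specific rule; LD-threshold or fixed-window
  blocks are out of scope.
* The bias flag's dispersion convention is deliberately conservative for
  correlated CV replicates; with truly independent replicates a standard
  one-sample t-test would be sharper.
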