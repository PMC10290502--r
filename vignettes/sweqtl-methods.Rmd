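---
title: "Methods: mixed-model eQTL discovery, region annotation, hotspots, PCIT and motif scanning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mixed-model eQTL discovery and annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical machinery:
the models fitted, the parameters that matter, the numerical choices made
where the design was genuinely open, and what the synthetic-data tests do
and do not demonstrate about real data.

## The association model

For each gene *h* in one tissue, the expression phenotype is the normalized
log2-cpm value and every variant *l* is tested with the mixed linear model

$$y_{hijk} = \mathrm{sex}_{hj} + \mathrm{breed}_{hk} + u_{hi} +
  s_{il}\,a_{hl} + e_{hijk},\qquad
  u_h \sim \mathrm{MVN}(0,\, \mathbf{G}\,\sigma^2_u),$$

where sex (2 levels) and breed (3 levels) are fixed effects, $s_{il}$ is
the alternative-allele dosage (0/1/2), $a_{hl}$ the allele substitution
effect, and $u$ a polygenic effect whose covariance is the genomic
relationship matrix $\mathbf{G}$ built from the autosomal markers
(VanRaden standardization: per-marker centering by $2p_l$ and scaling by
$2p_l(1-p_l)$, averaged over markers; missing dosages mean-imputed only
for this step, monomorphic markers skipped).

Estimation follows the eigendecomposition route: with
$\mathbf{G} = \mathbf{U}\mathbf{D}\mathbf{U}^\top$ restricted to the
samples with a non-missing phenotype, the rotated model has diagonal
covariance $\sigma^2_e(\lambda d_i + 1)$ with
$\lambda = \sigma^2_u/\sigma^2_e$. The restricted likelihood is profiled
over $\lambda$ on the log scale (search interval $e^{-12}$–$e^{12}$,
Brent minimization, tolerance 1e-8); a fit at the lower bound is clamped
to $\sigma^2_u = 0$. When $\mathbf{G} = \mathbf{I}$ the split
$\sigma^2_u/\sigma^2_e$ is unidentifiable — the tests therefore assert
only the identified total, which must equal the OLS residual variance.

The scan freezes $\lambda$ at its null-model value (the one-step
approximation used by fastGWA-class tools) and estimates each variant's
effect by GLS in the whitened basis. Two statistics are available:

* `wald_gls` (default) re-estimates the residual scale per variant, so
  that with $\mathbf{G} = \mathbf{I}$ and $\lambda = 0$ the test reduces
  *exactly* to OLS with covariates — this reduction is asserted to 1e-8
  in the tests;
* `score` keeps the null residual variance frozen (the classical score
  form).

Samples missing the phenotype or the genotype are dropped pairwise;
variants with missing genotypes leave the diagonal whitening and are
handled by a per-variant Cholesky solve of the frozen covariance
submatrix. Monomorphic variants within the used samples are reported with
$\beta = 0$, $p = 1$ and a flag rather than an error, so bookkeeping over
variant panels stays rectangular.

**Multiple testing.** Significance is Bonferroni-adjusted $P \le 0.05$.
The family size is genuinely ambiguous in this design (the correction can
be per gene over the variants tested, or tissue-wide over variants ×
genes); both are implemented (`family = "per_gene"` default,
`"tissue"`), and neither is asserted as the canonical choice.

## Expression processing

* **cpm filter**: threshold $T = 10 / (\min_j L_j / 10^6)$ cpm; a gene is
  kept iff its cpm reaches $T$ in at least 80% of samples. The "missing in
  more than 20% of the animals" clause is read as *below threshold* in
  more than 20% — raw count matrices have no literal missing values
  before zero-masking, so any other reading collapses the two clauses.
* **TMM / log2-cpm** are delegated to edgeR (`calcNormFactors`, `cpm`
  with `prior.count = 1`); the test suite carries an independent, naive
  transcription of the published TMM algorithm and asserts agreement to
  1e-10, so the delegation is cross-checked rather than trusted. The
  library-scaled prior means that doubling all counts and library sizes
  is invariant only up to the prior count — the tests assert the residual
  effect stays below 0.05 log2 units on typical matrices.
* **Zero masking** replaces normalized values at zero-count cells with
  `NA` *after* factor and cpm computation, so the factors see the full
  matrix; downstream tests and correlations all honor the mask.
* **Shapiro–Wilk leave-one-out screen**: for each sample $i$, $N_i$
  counts genes whose Shapiro–Wilk $p > 0.05$ with $i$ excluded. No
  flagging rule is published for this screen, so the package uses a
  robust outlier rule on $N$: flag when
  $N_i > \mathrm{median}(N) + k\,\mathrm{MAD}(N)$ with $k = 4$ (MAD with
  the usual 1.4826 consistency constant). The rule is deliberately
  conservative — removing a sample must *markedly* increase normality —
  and $k$ is exposed so users can tighten it.

## Region, cis/trans and hotspot definitions

* eQTL regions chain significant variants at gaps **strictly less than
  2 Mb** (a tie at exactly 2 Mb splits; the literal reading of "less
  than"), discard singletons (< 2 members), and extend ± 1 Mb (clipped at
  position 1). Chaining is provably equivalent to merging overlapping
  ± 1 Mb windows; the tests assert this equivalence on 1,000 random
  instances, using open-interval window intersection so the two
  formulations share the boundary convention.
* A variant is **cis** for its gene when it lies on the same chromosome
  within the annotated gene span ± 1 Mb, boundary inclusive ("within the
  expanded gene region"). The gene span is annotation start–end, not
  transcript-specific isoform ends. Signed distances are
  transcription-oriented: negative upstream of the TSS, positive
  downstream of the 3′ end, zero inside the gene.
* Region **peaks** are the top variant's position, or the arithmetic mean
  of tied top positions; ties on the smallest adjusted p-value are all
  retained as top variants, and each tied variant credits the region in
  top-hotspot counting (multi-variant top sets do occur in practice).
* **Hotspots** are variants associated with ≥ 10 distinct genes in a
  tissue; **top hotspots** additionally top ≥ 10 regions. A top hotspot
  cis to a gene *g* is a `top_of_cis_region` hotspot when it is among the
  top variants of *g*'s cis-eQTL region, else `cis_not_top`; a variant
  cis to several overlapping genes yields one classification per
  (variant, gene) pair rather than a forced unique assignment.
* Regions are strictly per (gene, tissue); a gene's regions are never
  merged across tissues.

## PCIT

For every trio $(x, y, z)$ with defined pairwise correlations the
first-order partial correlations define the tolerance
$\varepsilon = \tfrac13\!\left(\frac{r_{xy.z}}{r_{xy}} +
\frac{r_{xz.y}}{r_{xz}} + \frac{r_{yz.x}}{r_{yz}}\right)$, and the edge
$(x,y)$ is eliminated when **some** third gene explains it
($|r_{xy}| \le |\varepsilon\, r_{xz}|$ and
$|r_{xy}| \le |\varepsilon\, r_{yz}|$). The reference description admits a
stricter reading in which the edge must fail in *all* trios; both are
implemented (`quantifier = "any"` default / `"all"`). Trios containing a
correlation within 1e-12 of ±1, or a zero correlation in a tolerance
denominator, are skipped rather than propagating infinities. Correlations
are pairwise-complete Pearson on the masked matrix; cells with fewer than
3 complete pairs or a constant gene are flagged undefined and excluded
from trios. With only two genes no trio exists, so a defined edge is kept.
An exhaustive triple-loop oracle asserts exact agreement for all gene
sets of size ≤ 8.

Note that the trio rule only eliminates an indirect chain edge when the
chain is moderate: for an exact chain with link correlation $\rho$, the
edge $r_{xy} = \rho^2$ falls below the tolerance band only for
$\rho \lesssim 0.58$. The chain-recovery test therefore simulates links
near 0.45; very strong chains legitimately keep their indirect edge under
this rule.

## Motif scanning

Context sequences are the 21-mer ± 10 bp around top cis-regulatory SNPs
(the mutation at position 11), with the alternative sequence built by
substituting the center base; indels are rejected, chromosome edges are
N-padded, and a FASTA/VCF reference-allele mismatch is an error naming the
variant. PWMs come from IUPAC consensus strings (allowed bases share
$1 - 0.05\,k_\mathrm{off}$, each disallowed base gets 0.05, `N` is
background) or from MEME minimal files.

Scanning scores each window and strand with the log2 likelihood ratio
against the background. P-values are **exact**: scores are discretized to
1/1000-bit bins and the null score distribution under the iid background
is built by dynamic programming; the p-value is the tail probability at
the window's discretized score. Zero PWM probabilities are floored at
1e-4 before log-odds (configurable; with the floor disabled a zero
probability scores as the minimal bin), and N bases contribute score 0.
Enumeration over all sequences reproduces the DP p-values exactly for
widths ≤ 5. Window significance is Benjamini–Hochberg $q \le 0.1$ over
all scanned windows.

## The synthetic generator

`sim_config()` defaults encode the study design the pipeline targets:
300 animals in 3 breed strata of 100 with a balanced sex covariate;
allele frequencies drawn per LD block from Beta(1, 3) (clipped to
[0.02, 0.98]) with logit-scale breed perturbations (sd 0.3); haplotypes
copy the previous in-block allele with probability 0.9, giving
geometrically decaying LD; ~10% indels of 1–8 bp; 2% genotype
missingness. Expression runs the association model *forward*: unit latent
variance split as $h^2 = 0.3$ polygenic (drawn from the realized
genotype GRM, so heritability recovery is internally consistent) and 0.7
Gaussian noise, gene-level sex/breed effects of sd 0.5, baseline
intercepts uniform on 3–8 log2-cpm, log-normal library sizes
(median 2×10⁷, sdlog 0.3), and negative-binomial counts with dispersion
0.05. Planted effects add a per-allele dosage shift (cis/trans) or a
mediated architecture (causal variant → regulator latent → ≥ 10 targets
via centered-regulator coefficients), with the ground truth returned
alongside the data.

Desk-scale problem sizes are deliberate: the calibration and recovery
suites use 300 samples with 2,000–5,000 variants and 40–60 genes, and the
hotspot-recovery scenario uses 200-kb LD blocks so that a causal variant
has enough linked neighbors to form ≥ 2-member regions at this marker
density — a stand-in for the much denser LD of whole-genome data. What
the passing suites show is that the estimators are calibrated and recover
planted structure under the model's own assumptions; they do not show
robustness to features the generator omits: pedigree/family structure
beyond the GRM, realistic LD decay and breed divergence, batch effects,
expression outliers other than the planted kind, or non-Gaussian
expression noise beyond the NB observation layer.

## Numerical and degenerate-input conventions

* All internal coordinates are 1-based inclusive; only BED export
  converts to 0-based half-open.
* Variant ids synthesize as `chrom:pos_REF/ALT` when the VCF ID is
  missing; genotypes with any missing allele (including half-calls like
  `./1`) are missing dosages; after multiallelic splitting, a genotype
  carrying a *different* alternative allele counts 0 copies of the
  record's allele (bcftools-norm convention), which conserves summed
  alternative-allele counts per site.
* MAF filtering keeps the boundary (exactly 5% passes, "below 5%" is
  removed); missingness removes strictly above 10%. All-missing variants
  are removed and flagged without dividing by zero.
* MNPs and complex substitutions class as "other" and are excluded from
  the Ts/Tv ratio.
* Eigenvalues of the GRM are clamped at 0 before REML; aliased design
  columns are dropped with a warning; phenotypes with fewer than 30
  non-missing values are refused.

## Known limitations

* The Wald normal approximation has no small-sample df correction; at the
  suite's n = 300 this is immaterial, but at a few dozen samples the raw
  type-I error will drift.
* Bonferroni family-size ambiguity (above) means absolute significant
  counts are comparable across runs only at a fixed `family` choice.
* The X chromosome is tested but excluded from the GRM; no dosage
  compensation is modeled.
* PCIT edge retention has no permutation-based significance; it is the
  deterministic trio rule only.
* Motif scanning supports 0-order backgrounds only (uniform or estimated
  from the scanned sequences), not higher-order Markov backgrounds, and
  performs no de novo discovery — users supply consensus strings or MEME
  matrices.
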