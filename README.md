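# sweqtl

Expression GWAS (eGWAS) and eQTL annotation for multi-tissue RNA-seq
studies in livestock-scale designs: from genotype and count matrices to
mixed-model association scans, cis/trans eQTL regions, trans-regulatory
hotspots, PCIT coexpression of putative regulator genes, and motif scanning
of SNP-context sequences.

## What it does

Given biallelic genotypes (VCF), gene annotations (GFF3/GTF), raw RNA-seq
counts (TSV) and sample metadata (sex, breed), the package:

1. **Filters variants** (MAF ≥ 5%, missingness ≤ 10%) and classifies them
   (SNP / insertion / deletion, Ts/Tv ratio).
2. **Normalizes expression**: cpm filter (threshold 10 / min library size
   in millions, expressed in ≥ 80% of animals), TMM factors, log2-cpm with
   a prior count of 1, zero-count masking, and a Shapiro–Wilk leave-one-out
   outlier screen.
3. **Scans every variant against every gene** with the mixed linear model

   *y* = sex + breed + *u* + *s·a* + *e*,  *u* ~ MVN(0, **G**σ²ᵤ),

   where **G** is the VanRaden genomic relationship matrix from the
   autosomal markers, σ²ᵤ is estimated per gene by REML (eigendecomposition
   of **G**), the variance ratio is frozen for the scan (fastGWA-style
   one-step), and *a* is the allele substitution effect tested by
   GLS/Wald. Bonferroni adjustment declares associations significant at
   adjusted *P* ≤ 0.05.
4. **Clusters significant variants into eQTL regions** (single-linkage at
   gaps < 2 Mb, ≥ 2 members, ± 1 Mb extension), labels **cis** variants
   (within the gene span ± 1 Mb) and cis/trans regions, locates region
   peaks, and bins cis variants by distance to the TSS / 3′UTR.
5. **Detects hotspots** (variants associated with ≥ 10 genes), **top
   hotspots** (top variant of ≥ 10 regions), and classifies top
   cis-regulatory hotspots by whether they top their cis-eQTL region.
6. **Assesses regulator coexpression** with PCIT (partial correlation and
   information theory) and **scans PWMs** (e.g. an IUPAC consensus such as
   `GATCCNGYGTTGCYG`) over ± 10 bp SNP-context sequences with exact
   DP p-values and BH q ≤ 0.1 significance.
7. **Simulates** the whole study design (3 breed strata, sex covariate,
   LD-structured genotypes, negative-binomial counts, polygenic background,
   planted cis/trans/hotspot effects) so every stage is testable without
   external data.

## Worked example

```r
library(sweqtl)

cfg  <- sim_config(n_samples = 120, n_variants = 800, n_genes = 30,
                   chrom_length_bp = 5e6,
                   planted_effects = list(plant_cis(effect = 1.0)),
                   seed = 7)
geno <- simulate_genotypes(cfg)
expr <- simulate_expression(cfg, geno)
expr$truth$table
#>   kind           vid gene_id effect
#> 1  cis 1:2859600_A/T   G0021      1

kept <- filter_variants(geno)$kept          # 677 of 800 variants retained
norm <- normalize_expression(expr$counts)   # TMM + log2-cpm + zero mask
fit  <- egwas(norm$log2cpm["G0021", , drop = FALSE], kept, expr$meta,
              compute_grm(kept, exclude_chrom = character()))
fit
#> eGWAS: 1 genes x 677 variants; 6 significant associations
#> (p_adj <= 0.05 , per_gene family of 677 tests)
head(fit$significant[order(fit$significant$p_adj), c("vid", "beta", "p_adj")])
#>                     vid      beta        p_adj
#> 210       1:2859600_A/T 1.1431705 5.535212e-08
#> 211       1:2864400_T/A 0.9348798 9.555153e-05
#> 212 1:2868720_C/CCGTGGC 0.9902392 2.019075e-04
#> 209       1:2852820_A/G 0.7889472 3.458645e-02
#> 214       1:2890890_T/G 0.7640190 3.803140e-02
#> 213       1:2869530_G/T 0.7856727 4.143840e-02
```

The planted causal variant `1:2859600_A/T` is the top association (its
linked neighbors trail it, as expected under local LD): `beta` is the
estimated per-allele shift in log2-cpm and `p_adj` its
Bonferroni-adjusted p-value within the per-gene family. Downstream,
`cluster_regions_by_gene()`, `cis_labels()`, `find_hotspots()`,
`classify_top_cis()`, `regulator_coexpression()` and `scan_pwm()` carry the
significant associations through region, hotspot, coexpression and motif
annotation; see the methods vignette (`vignettes/sweqtl-methods.Rmd`) for
the model details and parameter choices.

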