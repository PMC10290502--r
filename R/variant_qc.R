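#' Filter variants on minor allele frequency and missingness
#'
#' A variant is retained iff its minor allele frequency (computed over
#' non-missing dosages) is at least `maf_min` AND the fraction of missing
#' genotypes is at most `max_missing`. The MAF boundary is inclusive
#' (a variant at exactly 5\% is kept); the missingness boundary removes
#' variants strictly above the threshold. Variants with all genotypes
#' missing are removed and flagged.
#'
#' @param vs [variant_set].
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param max_missing maximum missing-genotype fraction (default 0.10).
#' @return list with elements `kept` (filtered variant_set), `report`
#'   (counts removed per criterion) and `keep` (logical vector).
#' @export
filter_variants <- function(vs, maf_min = 0.05, max_missing = 0.10) {
  d <- vs$dosages
  n_miss <- rowSums(is.na(d))
  n <- ncol(d)
  miss_frac <- n_miss / n
  all_missing <- n_miss == n
  p <- rowMeans(d, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[all_missing] <- NA_real_
  fail_miss <- miss_frac > max_missing
  fail_maf <- !all_missing & maf < maf_min
  keep <- !all_missing & !fail_miss & !fail_maf
  report <- list(n_input = n, n_variants = nrow(d),
                 n_kept = sum(keep),
                 n_removed_maf = sum(fail_maf & !fail_miss),
                 n_removed_missing = sum(fail_miss & !fail_maf & !all_missing),
                 n_removed_both = sum(fail_maf & fail_miss),
                 n_all_missing = sum(all_missing),
                 maf_min = maf_min, max_missing = max_missing)
  list(kept = subset_variants(vs, keep), report = report, keep = keep,
       maf = maf, miss_frac = miss_frac)
}

#' Classify variants as SNP, insertion, deletion or other
#'
#' SNPs have single-base ref and alt; insertions have a longer alt,
#' deletions a longer ref. Equal-length multi-base alleles (MNPs) fall in
#' class "other" and are excluded from the Ts/Tv ratio.
#'
#' @param ref,alt allele strings (vectorized).
#' @return data.frame with columns `label` and `is_transition` (NA for
#'   non-SNPs). Transitions are A<->G and C<->T.
#' @export
classify_variant <- function(ref, alt) {
  lr <- nchar(ref); la <- nchar(alt)
  label <- ifelse(lr == 1L & la == 1L, "SNP",
           ifelse(la > lr, "insertion",
           ifelse(lr > la, "deletion", "other")))
  pair <- paste0(ref, alt)
  is_transition <- ifelse(label == "SNP",
                          pair %in% c("AG", "GA", "CT", "TC"), NA)
  data.frame(label = label, is_transition = is_transition,
             stringsAsFactors = FALSE)
}

#' Transition/transversion ratio over SNPs
#' @param ref,alt allele vectors.
#' @return numeric ratio (#transitions / #transversions); NaN when there are
#'   no transversions.
#' @export
tstv_ratio <- function(ref, alt) {
  cl <- classify_variant(ref, alt)
  snp <- cl$label == "SNP"
  sum(cl$is_transition[snp]) / sum(!cl$is_transition[snp])
}
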