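#' Filter lowly expressed genes
#'
#' The cpm threshold is `cpm_numerator / (minimum library size in millions)`.
#' A gene is retained iff its cpm reaches the threshold in at least
#' `min_fraction_expressed` of the samples (i.e. it is below threshold in at
#' most 20\% of the animals at the defaults).
#'
#' @param counts raw count matrix, genes x samples.
#' @param cpm_numerator numerator of the threshold rule (default 10).
#' @param min_fraction_expressed minimum fraction of samples at or above the
#'   threshold (default 0.8).
#' @return list with `keep` (logical per gene), `threshold` (cpm), and
#'   `report` (removal counts).
#' @export
filter_low_expression <- function(counts, cpm_numerator = 10,
                                  min_fraction_expressed = 0.8) {
  lib <- colSums(counts)
  if (any(lib <= 0)) {
    stop("zero library size for sample(s): ",
         paste(colnames(counts)[lib <= 0], collapse = ", "))
  }
  thr <- cpm_numerator / (min(lib) / 1e6)
  cpm <- t(t(counts) / lib) * 1e6
  frac_expr <- rowMeans(cpm >= thr)
  keep <- frac_expr >= min_fraction_expressed
  list(keep = keep, threshold = thr,
       report = list(n_genes = nrow(counts), n_kept = sum(keep),
                     n_removed = sum(!keep), threshold_cpm = thr))
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values between-sample factors (reference sample chosen
#' by the upper-quartile rule, 30\%/5\% two-sided trimming on M and A,
#' precision-weighted mean, factors rescaled to geometric mean 1), computed
#' with edgeR's implementation.
#'
#' @param counts filtered raw count matrix, genes x samples.
#' @param ref_sample optional reference column (index or name).
#' @return numeric vector of per-sample factors with geometric mean 1.
#' @export
tmm_factors <- function(counts, ref_sample = NULL) {
  refCol <- if (is.null(ref_sample)) NULL else {
    if (is.character(ref_sample)) match(ref_sample, colnames(counts)) else
      ref_sample
  }
  f <- edgeR::calcNormFactors(as.matrix(counts), method = "TMM",
                              refColumn = refCol)
  names(f) <- colnames(counts)
  f
}

#' Log2 counts-per-million with a prior count
#'
#' Uses the effective library size `L_j = lib_size_j * factor_j` and a
#' library-scaled prior: `p_j = prior * L_j / mean(L)`;
#' `value = log2((count + p_j) / (L_j + 2 p_j) * 1e6)` (edgeR's cpm
#' convention).
#'
#' @param counts raw count matrix.
#' @param norm_factors per-sample TMM factors (default 1).
#' @param prior prior count (default 1).
#' @return matrix of log2-cpm values.
#' @export
log2_cpm <- function(counts, norm_factors = rep(1, ncol(counts)), prior = 1) {
  if (any(counts < 0)) stop("negative counts")
  lib <- colSums(counts) * norm_factors
  edgeR::cpm(as.matrix(counts), lib.size = lib, log = TRUE,
             prior.count = prior)
}

#' Mask zero-count cells in a normalized matrix
#'
#' Cells whose raw count is 0 are set to `NA` in the normalized matrix so
#' that downstream tests and correlations exclude them (guarding against
#' normalization artifacts). Masking is applied after factor and cpm
#' computation, so the factors see the full count matrix.
#'
#' @param counts raw count matrix.
#' @param normalized congruent normalized matrix.
#' @return normalized matrix with masked cells set to `NA`; the logical mask
#'   is attached as attribute `"mask"`.
#' @export
mask_zero_counts <- function(counts, normalized) {
  if (!identical(dim(counts), dim(normalized)))
    stop("shape mismatch between counts and normalized matrix")
  mask <- counts == 0
  normalized[mask] <- NA_real_
  attr(normalized, "mask") <- mask
  normalized
}

#' Shapiro-Wilk leave-one-out outlier screen
#'
#' For each sample *i*, counts the genes whose expression passes a
#' Shapiro-Wilk normality test (p > `alpha`) when sample *i* is excluded.
#' A sample whose removal markedly increases the number of approximately
#' normal genes — `N_i > median(N) + k * MAD(N)` — is flagged as an outlier.
#' Genes with fewer than 3 non-missing values in a leave-one-out subset are
#' skipped from the count.
#'
#' @param mat normalized matrix, genes x samples (NA allowed).
#' @param alpha normality test level (default 0.05).
#' @param k MAD multiplier of the flagging rule (default 4).
#' @return list with `flagged` (sample names), `n_normal` (per-sample gene
#'   counts N_i), `threshold`.
#' @export
shapiro_loo_outliers <- function(mat, alpha = 0.05, k = 4) {
  ns <- ncol(mat)
  if (ns < 20L) stop("need at least 20 samples for the leave-one-out screen")
  n_normal <- vapply(seq_len(ns), function(i) {
    sub <- mat[, -i, drop = FALSE]
    sum(apply(sub, 1L, function(y) {
      y <- y[!is.na(y)]
      if (length(y) < 3L || length(unique(y)) == 1L) return(FALSE)
      stats::shapiro.test(y)$p.value > alpha
    }))
  }, numeric(1))
  names(n_normal) <- colnames(mat)
  thr <- stats::median(n_normal) + k * stats::mad(n_normal)
  flagged <- names(n_normal)[n_normal > thr]
  if (is.null(flagged)) flagged <- which(n_normal > thr)
  list(flagged = flagged, n_normal = n_normal, threshold = thr)
}

#' Full expression normalization pipeline
#'
#' Convenience wrapper: cpm filter, TMM factors, log2-cpm, zero masking.
#'
#' @param counts raw count matrix, genes x samples.
#' @param prior prior count for log2-cpm.
#' @inheritParams filter_low_expression
#' @return list with `log2cpm` (masked normalized matrix), `norm_factors`,
#'   `keep`, `filter_report`.
#' @export
normalize_expression <- function(counts, cpm_numerator = 10,
                                 min_fraction_expressed = 0.8, prior = 1) {
  fl <- filter_low_expression(counts, cpm_numerator, min_fraction_expressed)
  kept <- counts[fl$keep, , drop = FALSE]
  f <- tmm_factors(kept)
  norm <- log2_cpm(kept, f, prior = prior)
  masked <- mask_zero_counts(kept, norm)
  list(log2cpm = masked, norm_factors = f, keep = fl$keep,
       filter_report = fl$report)
}
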