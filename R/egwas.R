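#' Genomic relationship matrix
#'
#' VanRaden-style marker-standardized GRM:
#' `G_ij = (1/M) * sum_l (x_il - 2 p_l)(x_jl - 2 p_l) / (2 p_l (1 - p_l))`,
#' where `p_l` is the alternative-allele frequency and `M` the number of
#' markers used. Missing dosages are mean-imputed per variant; monomorphic
#' variants are skipped with a warning (zero denominator).
#'
#' @param dosages a [variant_set] or a variants x samples dosage matrix.
#' @param exclude_chrom chromosome names to drop before computation (used to
#'   restrict to autosomes when a variant_set is supplied); default
#'   `c("X", "Y")`.
#' @return samples x samples matrix of class `grm` with attribute
#'   `n_markers`.
#' @export
compute_grm <- function(dosages, exclude_chrom = c("X", "Y")) {
  if (inherits(dosages, "variant_set")) {
    keep <- !(dosages$info$chrom %in% exclude_chrom)
    d <- dosages$dosages[keep, , drop = FALSE]
  } else {
    d <- as.matrix(dosages)
  }
  if (anyNA(d)) {
    mu <- rowMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 1L]]
  }
  p <- rowMeans(d) / 2
  poly <- p > 0 & p < 1
  if (any(!poly)) {
    warning(sum(!poly), " monomorphic variant(s) skipped in GRM")
    d <- d[poly, , drop = FALSE]
    p <- p[poly]
  }
  M <- nrow(d)
  if (M == 0L) stop("no polymorphic variants for GRM")
  z <- (d - 2 * p) / sqrt(2 * p * (1 - p))
  g <- crossprod(z) / M
  attr(g, "n_markers") <- M
  class(g) <- c("grm", class(g))
  g
}

## REML criterion (-2 log restricted likelihood up to a constant) for the
## variance ratio lambda = sigma2_u / sigma2_e, in the eigenbasis of G.
.reml_neg2ll <- function(log_lambda, d, yt, Xt) {
  lambda <- exp(log_lambda)
  w <- lambda * d + 1
  n <- length(yt); p <- ncol(Xt)
  Xw <- Xt / sqrt(w)
  yw <- yt / sqrt(w)
  qr_x <- qr(Xw)
  res <- qr.resid(qr_x, yw)
  rss <- sum(res^2)
  s2e <- rss / (n - p)
  xtx <- crossprod(Xw)
  (n - p) * log(s2e) + sum(log(w)) + determinant(xtx)$modulus[1]
}

#' Fit the per-gene null mixed model by REML
#'
#' Fits `y = X b + u + e` with `u ~ N(0, G sigma2_u)`, `e ~ N(0, I sigma2_e)`
#' via eigendecomposition of the GRM restricted to samples with non-missing
#' phenotype, profiling the restricted likelihood over the variance ratio.
#' Boundary estimates are clamped at 0.
#'
#' @param y numeric phenotype vector (one gene's normalized expression;
#'   NA allowed).
#' @param X fixed-effect design matrix (intercept + sex + breed); aliased
#'   columns are dropped with a warning.
#' @param grm samples x samples relationship matrix.
#' @param eig optional pre-computed `eigen()` of the GRM restricted to the
#'   non-missing samples (shared across genes with identical missingness).
#' @return object of class `lmm_fit` with variance components, fixed
#'   effects, and cached rotations for [scan_gene()].
#' @export
fit_null_lmm <- function(y, X, grm, eig = NULL) {
  X <- as.matrix(X)
  used <- which(!is.na(y) & stats::complete.cases(X))
  n <- length(used)
  if (n < 30L) stop("need >= 30 non-missing phenotype values, got ", n)
  yu <- y[used]
  Xu <- X[used, , drop = FALSE]
  qx <- qr(Xu)
  if (qx$rank < ncol(Xu)) {
    drop_cols <- qx$pivot[seq.int(qx$rank + 1L, ncol(Xu))]
    warning("dropping aliased design column(s): ",
            paste(colnames(Xu)[drop_cols], collapse = ", "))
    Xu <- Xu[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
  }
  if (is.null(eig)) {
    eig <- eigen(grm[used, used], symmetric = TRUE)
  }
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  yt <- drop(crossprod(U, yu))
  Xt <- crossprod(U, Xu)
  opt <- stats::optimize(.reml_neg2ll, interval = c(-12, 12), d = d,
                         yt = yt, Xt = Xt, tol = 1e-8)
  if (!is.finite(opt$objective)) stop("non-finite restricted likelihood")
  ## boundary check: pure-residual model
  at_bound <- .reml_neg2ll(-12, d, yt, Xt) <= opt$objective + 1e-8
  lambda <- if (at_bound) 0 else exp(opt$minimum)
  w <- lambda * d + 1
  Xw <- Xt / sqrt(w); yw <- yt / sqrt(w)
  qr_x <- qr(Xw)
  beta <- qr.coef(qr_x, yw)
  rss <- sum(qr.resid(qr_x, yw)^2)
  s2e <- rss / (n - ncol(Xw))
  fit <- list(sigma2_u = lambda * s2e, sigma2_e = s2e, lambda = lambda,
              fixed_effects = beta, n_used = n, used = used,
              eig_values = d, eig_vectors = U, yt = yt, Xt = Xt,
              reml_neg2ll = opt$objective)
  class(fit) <- "lmm_fit"
  fit
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Mixed-model null fit (REML):\n")
  cat(sprintf("  sigma2_u = %.4g, sigma2_e = %.4g (lambda = %.4g)\n",
              x$sigma2_u, x$sigma2_e, x$lambda))
  cat(sprintf("  h2 = %.3f, n = %d\n",
              x$sigma2_u / (x$sigma2_u + x$sigma2_e), x$n_used))
  invisible(x)
}

#' @export
coef.lmm_fit <- function(object, ...) object$fixed_effects

#' Scan all variants against one gene's phenotype
#'
#' Tests each variant's allele-substitution effect by generalized least
#' squares under `V = sigma2_u G + sigma2_e I`, with the variance ratio
#' frozen from the null fit (one-step approximation as in fastGWA-style
#' tools). Samples missing the phenotype or the genotype are dropped
#' pairwise; `n` and the allele frequency are recorded per test. The Wald
#' test re-estimates the residual scale per variant (so with `G = I` and
#' `lambda = 0` it reduces exactly to ordinary least squares); the score
#' test keeps the null-model residual variance frozen.
#'
#' @param fit [lmm_fit] from [fit_null_lmm()].
#' @param vs [variant_set] (sample order must match the phenotype).
#' @param method `"wald_gls"` (default) or `"score"`.
#' @return data.frame of association records: vid, chrom, pos, ref, alt,
#'   beta, se, p, n, af, flag.
#' @export
scan_gene <- function(fit, vs, method = c("wald_gls", "score")) {
  method <- match.arg(method)
  used <- fit$used
  D <- vs$dosages[, used, drop = FALSE]
  m <- nrow(D)
  w <- fit$lambda * fit$eig_values + 1
  sw <- sqrt(w)
  Xw <- fit$Xt / sw
  yw <- fit$yt / sw
  qr_x <- qr(Xw)
  y_res <- qr.resid(qr_x, yw)
  s2e <- fit$sigma2_e

  beta <- se <- p <- af <- rep(NA_real_, m)
  n_used <- integer(m)
  flag <- character(m)

  k <- ncol(fit$Xt)
  n_obs <- length(used)
  complete <- !apply(D, 1L, anyNA)
  if (any(complete)) {
    S <- t(D[complete, , drop = FALSE])          # n x m_c
    St <- crossprod(fit$eig_vectors, S) / sw      # rotated + whitened
    S_res <- St - qr.fitted(qr_x, St)
    ss <- colSums(S_res^2)
    num <- colSums(S_res * y_res)
    mono <- apply(S, 2L, function(x) length(unique(x)) == 1L)
    ok <- ss > 0 & !mono
    b <- ifelse(ok, num / ss, 0)
    rss0 <- sum(y_res^2)
    s2 <- if (method == "wald_gls") {
      pmax(rss0 - num^2 / ifelse(ok, ss, 1), 0) / (n_obs - k - 1L)
    } else {
      rep(s2e, length(ss))
    }
    s <- ifelse(ok, sqrt(s2 / ss), NA_real_)
    pv <- ifelse(ok, 2 * stats::pnorm(-abs(b / s)), 1)
    idx <- which(complete)
    beta[idx] <- b; se[idx] <- s; p[idx] <- pv
    af[idx] <- colMeans(S) / 2
    n_used[idx] <- length(used)
    flag[idx] <- ifelse(mono | ss <= 0, "monomorphic", "")
  }
  incomplete <- which(!complete)
  if (length(incomplete)) {
    G_used <- tcrossprod(fit$eig_vectors * rep(fit$eig_values,
                                               each = nrow(fit$eig_vectors)),
                         fit$eig_vectors)
    V <- fit$sigma2_u * G_used + s2e * diag(length(used))
    Xu <- fit$eig_vectors %*% fit$Xt  # back-rotate design to sample space
    yu <- drop(fit$eig_vectors %*% fit$yt)
    for (i in incomplete) {
      g <- D[i, ]
      ok <- !is.na(g)
      gi <- g[ok]
      n_used[i] <- sum(ok)
      af[i] <- mean(gi) / 2
      if (length(unique(gi)) == 1L) {
        beta[i] <- 0; se[i] <- NA_real_; p[i] <- 1
        flag[i] <- "monomorphic"
        next
      }
      R <- chol(V[ok, ok])
      Z <- backsolve(R, cbind(Xu[ok, , drop = FALSE], gi, yu[ok]),
                     transpose = TRUE)
      qx <- qr(Z[, seq_len(k), drop = FALSE])
      gr <- qr.resid(qx, Z[, k + 1L])
      yr <- qr.resid(qx, Z[, k + 2L])
      ss <- sum(gr^2)
      num <- sum(gr * yr)
      beta[i] <- num / ss
      ## whitened by chol(V), so the nominal residual variance is 1;
      ## the Wald form rescales by the per-variant residual fit
      s2 <- if (method == "wald_gls") {
        max(sum(yr^2) - num^2 / ss, 0) / (sum(ok) - k - 1L)
      } else 1
      se[i] <- sqrt(s2 / ss)
      p[i] <- 2 * stats::pnorm(-abs(beta[i] / se[i]))
      flag[i] <- ""
    }
  }
  data.frame(vid = vs$info$vid, chrom = vs$info$chrom, pos = vs$info$pos,
             ref = vs$info$ref, alt = vs$info$alt,
             beta = beta, se = se, p = p, n = n_used, af = af,
             flag = flag, stringsAsFactors = FALSE)
}

#' Bonferroni adjustment with an explicit family size
#'
#' `p_adj = min(1, p * family_size)` via `stats::p.adjust(..., n = family)`;
#' associations are called significant when `p_adj <= 0.05`.
#'
#' @param p raw p-values.
#' @param family_size number of tests in the family (>= length(p)).
#' @return adjusted p-values.
#' @export
bonferroni_adjust <- function(p, family_size) {
  if (family_size < 1) stop("family_size must be >= 1")
  if (family_size < length(p)) {
    stop("family_size smaller than the number of records")
  }
  stats::p.adjust(p, method = "bonferroni", n = family_size)
}

#' Total number of association tests
#' @param n_variants number of variants tested.
#' @param genes_per_tissue vector of expressed-gene counts per tissue.
#' @return total test count (double precision; exceeds 32-bit range for
#'   genome-scale studies).
#' @export
count_tests <- function(n_variants, genes_per_tissue) {
  if (n_variants < 0 || any(genes_per_tissue < 0)) stop("negative counts")
  as.numeric(n_variants) * sum(as.numeric(genes_per_tissue))
}

#' Mixed-model expression GWAS across genes
#'
#' Runs [fit_null_lmm()] + [scan_gene()] for every gene of a normalized
#' expression matrix and applies Bonferroni adjustment. The Bonferroni
#' family defaults to the number of variants tested per gene (per-gene
#' genome-wide correction); `family = "tissue"` uses variants x genes.
#'
#' @param exprs normalized (masked) expression matrix, genes x samples.
#' @param vs [variant_set]; columns must match `colnames(exprs)`.
#' @param meta data.frame with `sample_id`, `sex`, `breed` (row order
#'   matching the expression columns).
#' @param grm genomic relationship matrix (computed from `vs` autosomes when
#'   missing).
#' @param family Bonferroni family: `"per_gene"` (default) or `"tissue"`.
#' @param alpha significance level on the adjusted p-value (default 0.05).
#' @param tissue optional tissue label stored in the records.
#' @return object of class `egwas`: list with `associations` (all tests),
#'   `significant` (subset with `p_adj <= alpha`), `null_fits` (per-gene
#'   variance components), `family`, `family_size`.
#' @export
egwas <- function(exprs, vs, meta, grm = NULL, family = c("per_gene", "tissue"),
                  alpha = 0.05, tissue = NA_character_) {
  family <- match.arg(family)
  stopifnot(ncol(exprs) == length(vs$samples))
  if (is.null(grm)) grm <- compute_grm(vs)
  X <- stats::model.matrix(~ sex + breed, data = meta)
  n_var <- nrow(vs$info)
  genes <- rownames(exprs)
  shared_eig <- NULL
  res <- vector("list", length(genes))
  nf <- vector("list", length(genes))
  for (h in seq_along(genes)) {
    y <- exprs[h, ]
    eig <- NULL
    if (!anyNA(y)) {
      if (is.null(shared_eig)) shared_eig <- eigen(grm, symmetric = TRUE)
      eig <- shared_eig
    }
    fit <- fit_null_lmm(y, X, grm, eig = eig)
    a <- scan_gene(fit, vs)
    a$gene_id <- genes[h]
    a$tissue <- tissue
    res[[h]] <- a
    nf[[h]] <- data.frame(gene_id = genes[h], sigma2_u = fit$sigma2_u,
                          sigma2_e = fit$sigma2_e, n_used = fit$n_used,
                          stringsAsFactors = FALSE)
  }
  assoc <- do.call(rbind, res)
  fam_size <- if (family == "per_gene") n_var else n_var * length(genes)
  if (family == "per_gene") {
    ## correction applied within each gene's family of n_var tests
    assoc$p_adj <- unlist(lapply(split(assoc$p, assoc$gene_id),
                                 bonferroni_adjust, fam_size),
                          use.names = FALSE)[order(order(assoc$gene_id))]
  } else {
    assoc$p_adj <- bonferroni_adjust(assoc$p, fam_size)
  }
  out <- list(associations = assoc,
              significant = assoc[assoc$p_adj <= alpha, , drop = FALSE],
              null_fits = do.call(rbind, nf),
              family = family, family_size = fam_size, alpha = alpha)
  class(out) <- "egwas"
  out
}

#' @export
print.egwas <- function(x, ...) {
  cat("eGWAS:", length(unique(x$associations$gene_id)), "genes x",
      length(unique(x$associations$vid)), "variants;",
      nrow(x$significant), "significant associations (p_adj <=",
      x$alpha, ",", x$family, "family of", x$family_size, "tests)\n")
  invisible(x)
}

#' @export
summary.egwas <- function(object, ...) {
  sig <- object$significant
  data.frame(n_tests = nrow(object$associations),
             n_significant = nrow(sig),
             n_genes_with_signal = length(unique(sig$gene_id)),
             n_variants_significant = length(unique(sig$vid)),
             family_size = object$family_size)
}
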