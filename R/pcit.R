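#' Pairwise-complete Pearson correlation matrix
#'
#' Correlations are computed on the samples where both genes are unmasked
#' (zero-count cells are NA in the normalized matrix). Cells backed by fewer
#' than 3 complete pairs, or involving a constant gene, are flagged
#' undefined (NA) and excluded from PCIT trios.
#'
#' @param expr genes x samples matrix (NA allowed).
#' @return list with `r` (correlation matrix, unit diagonal), `n_pairs`
#'   (per-cell complete-pair counts).
#' @export
pearson_matrix <- function(expr) {
  if (nrow(expr) < 3L || ncol(expr) < 3L)
    stop("need at least 3 genes and 3 samples")
  x <- t(expr)
  r <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
  ok <- !is.na(x)
  n_pairs <- crossprod(ok)
  r[n_pairs < 3L] <- NA_real_
  diag(r) <- 1
  list(r = r, n_pairs = n_pairs)
}

#' PCIT coexpression network
#'
#' Partial correlation and information theory edge elimination. For every
#' trio (x, y, z) the first-order partial correlations
#' `r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))` (and the
#' two rotations) define the trio tolerance
#' `eps = (r_xy.z/r_xy + r_xz.y/r_xz + r_yz.x/r_yz) / 3`. The edge (x, y)
#' is eliminated when some third gene z explains it:
#' `|r_xy| <= |eps r_xz|` and `|r_xy| <= |eps r_yz|`. With
#' `quantifier = "all"` the edge is eliminated only when every admissible
#' trio explains it. Trios containing a correlation of magnitude 1 (within
#' 1e-12) or a zero correlation in a tolerance denominator are skipped.
#'
#' @param r correlation matrix (e.g. from [pearson_matrix()]).
#' @param quantifier `"any"` (default, an edge is dropped if some z explains
#'   it) or `"all"`.
#' @return list with `kept` (logical adjacency matrix, upper+lower,
#'   diagonal FALSE) and `r`.
#' @export
pcit_network <- function(r, quantifier = c("any", "all")) {
  quantifier <- match.arg(quantifier)
  n <- nrow(r)
  kept <- !is.na(r)
  diag(kept) <- FALSE
  tol <- 1e-12
  for (x in seq_len(n - 1L)) {
    for (y in seq.int(x + 1L, n)) {
      rxy <- r[x, y]
      if (is.na(rxy)) { kept[x, y] <- kept[y, x] <- FALSE; next }
      z <- setdiff(seq_len(n), c(x, y))
      rxz <- r[x, z]; ryz <- r[y, z]
      valid <- !is.na(rxz) & !is.na(ryz) &
        abs(rxy) < 1 - tol & abs(rxz) < 1 - tol & abs(ryz) < 1 - tol &
        abs(rxy) > 0 & abs(rxz) > 0 & abs(ryz) > 0
      if (!any(valid)) next
      rxz <- rxz[valid]; ryz <- ryz[valid]
      pxy <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
      pxz <- (rxz - rxy * ryz) / sqrt((1 - rxy^2) * (1 - ryz^2))
      pyz <- (ryz - rxy * rxz) / sqrt((1 - rxy^2) * (1 - rxz^2))
      eps <- (pxy / rxy + pxz / rxz + pyz / ryz) / 3
      explained <- abs(rxy) <= abs(eps * rxz) & abs(rxy) <= abs(eps * ryz)
      drop_edge <- if (quantifier == "any") any(explained) else
        all(explained)
      if (drop_edge) kept[x, y] <- kept[y, x] <- FALSE
    }
  }
  list(kept = kept, r = r, quantifier = quantifier)
}

#' Regulator-to-trans-gene coexpression assessment
#'
#' Runs PCIT on the regulator plus its trans-associated genes and reports
#' which trans genes keep a direct edge to the regulator.
#'
#' @param expr normalized (masked) expression matrix, genes x samples.
#' @param regulator_gene regulator gene id (row of `expr`).
#' @param trans_genes character vector of trans-associated gene ids.
#' @param quantifier passed to [pcit_network()].
#' @return list with `coexpressed` (trans gene ids with a kept edge),
#'   `fraction`, `network`.
#' @export
regulator_coexpression <- function(expr, regulator_gene, trans_genes,
                                   quantifier = "any") {
  if (!length(trans_genes)) stop("empty trans gene list")
  genes <- c(regulator_gene, trans_genes)
  miss <- setdiff(genes, rownames(expr))
  if (length(miss)) stop("genes absent from expression matrix: ",
                         paste(miss, collapse = ", "))
  sub <- expr[genes, , drop = FALSE]
  if (length(genes) < 3L) {
    ## no third gene exists, so no trio can eliminate the edge
    r <- suppressWarnings(stats::cor(t(sub), use = "pairwise.complete.obs"))
    kept <- !is.na(r); diag(kept) <- FALSE
    net <- list(kept = kept, r = r, quantifier = quantifier)
  } else {
    pm <- pearson_matrix(sub)
    net <- pcit_network(pm$r, quantifier = quantifier)
  }
  kept_to_reg <- net$kept[regulator_gene, trans_genes]
  coexpressed <- trans_genes[kept_to_reg]
  list(coexpressed = coexpressed,
       fraction = mean(kept_to_reg), network = net)
}
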