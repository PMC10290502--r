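## Independent reference implementations used as oracles. Deliberately
## naive and kept free of any code path they check.

## --- TMM (trimmed mean of M-values), straightforward transcription -------
naive_tmm <- function(counts, ref = NULL) {
  counts <- as.matrix(counts)
  lib <- colSums(counts)
  q75 <- apply(counts, 2, function(x) stats::quantile(x, 0.75)) / lib
  if (is.null(ref)) ref <- which.min(abs(q75 - mean(q75)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    obs <- counts[, j]; refc <- counts[, ref]
    nO <- lib[j]; nR <- lib[ref]
    keep <- obs > 0 & refc > 0
    obs <- obs[keep]; refc <- refc[keep]
    logR <- log2((obs / nO) / (refc / nR))
    absE <- (log2(obs / nO) + log2(refc / nR)) / 2
    v <- (nO - obs) / nO / obs + (nR - refc) / nR / refc
    if (max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loL <- floor(n * 0.3) + 1; hiL <- n + 1 - loL
    loS <- floor(n * 0.05) + 1; hiS <- n + 1 - loS
    sel <- rank(logR) >= loL & rank(logR) <= hiL &
      rank(absE) >= loS & rank(absE) <= hiS
    f_j <- sum(logR[sel] / v[sel], na.rm = TRUE) /
      sum(1 / v[sel], na.rm = TRUE)
    if (!is.finite(f_j)) f_j <- 0
    2^f_j
  }, numeric(1))
  f / exp(mean(log(f)))
}

## --- GRM, double loop over sample pairs ----------------------------------
naive_grm <- function(d) {
  d <- as.matrix(d)
  if (anyNA(d)) {
    mu <- rowMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 1]]
  }
  p <- rowMeans(d) / 2
  keep <- p > 0 & p < 1
  d <- d[keep, , drop = FALSE]; p <- p[keep]
  M <- nrow(d); ns <- ncol(d)
  g <- matrix(0, ns, ns)
  denom <- 2 * p * (1 - p)
  for (i in seq_len(ns)) {
    for (j in i:ns) {
      g[i, j] <- g[j, i] <-
        sum((d[, i] - 2 * p) * (d[, j] - 2 * p) / denom) / M
    }
  }
  g
}

## --- region clustering via merge-of-±1Mb-windows -------------------------
## returns a list of member position vectors (>= min_members), using
## open-interval intersection so that a gap of exactly 2*pad splits
merge_windows_oracle <- function(pos, pad = 1e6, min_members = 2) {
  pos <- sort(pos)
  lo <- pos - pad; hi <- pos + pad
  groups <- list(); cur <- 1
  for (i in seq_along(pos)[-1]) {
    if (lo[i] < max(hi[cur])) cur <- c(cur, i) else {
      groups[[length(groups) + 1]] <- pos[cur]; cur <- i
    }
  }
  groups[[length(groups) + 1]] <- pos[cur]
  groups[lengths(groups) >= min_members]
}

## --- PCIT, exhaustive triple loop ----------------------------------------
brute_pcit <- function(r, quantifier = "any") {
  n <- nrow(r); tol <- 1e-12
  kept <- !is.na(r); diag(kept) <- FALSE
  pc <- function(rxy, rxz, ryz) {
    (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  }
  for (x in seq_len(n - 1)) for (y in seq.int(x + 1, n)) {
    rxy <- r[x, y]
    if (is.na(rxy)) next
    votes <- logical(0)
    for (z in seq_len(n)) {
      if (z == x || z == y) next
      rxz <- r[x, z]; ryz <- r[y, z]
      if (is.na(rxz) || is.na(ryz)) next
      if (abs(rxy) >= 1 - tol || abs(rxz) >= 1 - tol ||
          abs(ryz) >= 1 - tol) next
      if (rxy == 0 || rxz == 0 || ryz == 0) next
      eps <- (pc(rxy, rxz, ryz) / rxy + pc(rxz, rxy, ryz) / rxz +
                pc(ryz, rxy, rxz) / ryz) / 3
      votes <- c(votes,
                 abs(rxy) <= abs(eps * rxz) && abs(rxy) <= abs(eps * ryz))
    }
    drop_edge <- if (!length(votes)) FALSE else
      if (quantifier == "any") any(votes) else all(votes)
    if (drop_edge) kept[x, y] <- kept[y, x] <- FALSE
  }
  kept
}

## --- PWM p-values by sequence enumeration --------------------------------
## enumerate all 4^w sequences, discretize scores identically, and return a
## function mapping an integer score to its exact exceedance probability
enum_pwm_pvalue <- function(pwm, granularity = 1 / 1000, floor_prob = 1e-4) {
  pr <- pwm$probs
  if (floor_prob > 0) pr <- pmax(pr, floor_prob)
  lo <- log2(pr / pwm$background)
  si <- round(lo / granularity)
  w <- pwm$width
  grid <- as.matrix(expand.grid(rep(list(1:4), w)))
  scores <- apply(grid, 1, function(b) sum(si[cbind(b, 1:w)]))
  probs <- apply(grid, 1, function(b) prod(pwm$background[b]))
  function(s_int) sum(probs[scores >= s_int])
}

## --- BH step-up reference ------------------------------------------------
bh_ref <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m); out[o] <- pmin(q, 1)
  out
}

## --- small fixture builders ----------------------------------------------
write_test_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(lines, path)
  path
}

random_corr <- function(n_genes, n_samples = 20) {
  stats::cor(matrix(stats::rnorm(n_genes * n_samples), n_samples, n_genes))
}
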