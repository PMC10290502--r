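sig_df <- function(pos, p = NULL, chrom = "1") {
  data.frame(vid = sprintf("v%d", seq_along(pos)),
             chrom = rep_len(chrom, length(pos)), pos = pos,
             p_adj = if (is.null(p)) rep(0.01, length(pos)) else p,
             stringsAsFactors = FALSE)
}

test_that("chaining keeps pairs under 2 Mb, drops singletons, pads by 1 Mb", {
  r <- cluster_regions(sig_df(c(1.0e6, 2.5e6, 6.0e6)))
  expect_equal(nrow(r), 1)
  expect_equal(r$core_start, 1.0e6)
  expect_equal(r$core_end, 2.5e6)
  expect_equal(r$ext_start, 1)        # clipped at chromosome start
  expect_equal(r$ext_end, 3.5e6)
  expect_equal(r$member_vids[[1]], c("v1", "v2"))
  # gap of exactly 2 Mb splits ("less than 2 Mb" is strict)
  r2 <- cluster_regions(sig_df(c(1e6, 3e6, 3.1e6, 5.1e6)))
  expect_equal(nrow(r2), 1)  # only {3e6, 3.1e6} survives; both flanks split
  expect_equal(r2$core_start, 3e6)
  # ties on the smallest p are all recorded as top variants
  r3 <- cluster_regions(sig_df(c(1e5, 2e5, 3e5), p = c(.001, .01, .001)))
  expect_equal(r3$top_vids[[1]], c("v1", "v3"))
  # empty input
  expect_equal(nrow(cluster_regions(sig_df(numeric(0)))), 0)
})

test_that("chaining equals the merge-of-overlapping-windows formulation", {
  set.seed(101)
  for (i in 1:200) {
    pos <- sort(sample.int(3e7, sample(2:40, 1)))
    r <- cluster_regions(sig_df(pos))
    oracle <- merge_windows_oracle(pos)
    expect_equal(nrow(r), length(oracle))
    if (nrow(r)) {
      expect_equal(r$core_start, vapply(oracle, min, numeric(1)))
      expect_equal(r$core_end, vapply(oracle, max, numeric(1)))
    }
  }
})

test_that("clustering is invariant to input row order and covers non-singletons", {
  set.seed(102)
  pos <- sort(sample.int(2e7, 30))
  s <- sig_df(pos, p = runif(30))
  shuffled <- s[sample(nrow(s)), ]
  expect_equal(cluster_regions(s), cluster_regions(shuffled))
  r <- cluster_regions(s)
  members <- unlist(r$member_vids)
  singles <- setdiff(s$vid, members)
  # every dropped variant is alone: no other variant within 2 Mb
  for (v in singles) {
    p0 <- s$pos[s$vid == v]
    expect_true(all(abs(s$pos[s$vid != v] - p0) >= 2e6))
  }
})

test_that("cis classification uses an inclusive 1 Mb window around the gene", {
  gene <- data.frame(gene_id = "G1", chrom = "5", start = 3e6, end = 3.2e6,
                     strand = "+")
  inside <- classify_cis("a", "5", 3.1e6, gene)
  expect_true(inside$is_cis)
  expect_equal(inside$signed_distance, 0)
  at_edge <- classify_cis("b", "5", 3e6 - 1e6, gene)
  expect_true(at_edge$is_cis)                      # boundary inclusive
  expect_false(classify_cis("c", "5", 3e6 - 1e6 - 1, gene)$is_cis)
  expect_false(classify_cis("d", "6", 3.1e6, gene)$is_cis)  # wrong chrom
  # strand-aware sign: upstream negative, downstream positive
  expect_lt(classify_cis("e", "5", 2.9e6, gene)$signed_distance, 0)
  expect_gt(classify_cis("f", "5", 3.3e6, gene)$signed_distance, 0)
  minus <- data.frame(gene_id = "G2", chrom = "5", start = 3e6, end = 3.2e6,
                      strand = "-")
  expect_lt(classify_cis("g", "5", 3.3e6, minus)$signed_distance, 0)
  expect_gt(classify_cis("h", "5", 2.9e6, minus)$signed_distance, 0)
})

test_that("cis labels match a brute-force interval test on random pairs", {
  set.seed(103)
  for (i in 1:10) {
    gene <- data.frame(gene_id = "G", chrom = "1",
                       start = sample.int(5e7, 1), end = 0, strand = "+")
    gene$end <- gene$start + sample.int(1e5, 1)
    pos <- sample.int(6e7, 50)
    lab <- classify_cis(paste0("v", 1:50), rep("1", 50), pos, gene)
    expect_equal(lab$is_cis,
                 pos >= gene$start - 1e6 & pos <= gene$end + 1e6)
  }
})

test_that("peak position averages tied top variants", {
  pd <- peak_distances(c(10, 20, 30), c(.5, .1, .5))
  expect_equal(pd$peak, 20)
  expect_equal(pd$distances, c(-10, 0, 10))
  tie <- peak_distances(c(10, 20, 30), c(.1, .5, .1))
  expect_equal(tie$peak, 20)
  # member distances never exceed the core width
  set.seed(104)
  for (i in 1:20) {
    pos <- sort(sample.int(1e6, 8))
    pd <- peak_distances(pos, runif(8))
    expect_true(max(abs(pd$distances)) < max(pos) - min(pos) + 1)
  }
})

test_that("TSS/3'UTR bins respect transcription orientation", {
  gp <- data.frame(gene_id = "G", chrom = "1", start = 2e6, end = 2.2e6,
                   strand = "+")
  lab <- classify_cis(c("a", "b", "c"), rep("1", 3),
                      c(2e6 - 5e4, 2.2e6 + 5e4, 2.1e6), gp)
  b <- tss_utr_bins(lab)
  expect_equal(unname(b[c("up_1", "down_1", "ORF")]), c(1L, 1L, 1L))
  gm <- data.frame(gene_id = "G", chrom = "1", start = 2e6, end = 2.2e6,
                   strand = "-")
  labm <- classify_cis("a", "1", 2.2e6 + 5e4, gm)
  expect_equal(unname(tss_utr_bins(labm)["up_1"]), 1L)
})

test_that("uniform cis variants fill the distance bins uniformly", {
  set.seed(105)
  gene <- data.frame(gene_id = "G", chrom = "1", start = 5e6, end = 5.2e6,
                     strand = "+")
  n <- 5000
  pos <- round(runif(n, gene$start - 1e6, gene$end + 1e6))
  lab <- classify_cis(paste0("v", 1:n), rep("1", n), pos, gene)
  b <- tss_utr_bins(lab)
  span <- 2e6 + 2e5
  # ORF bucket proportional to gene length
  expect_equal(unname(b["ORF"]) / n, 2e5 / span, tolerance = 0.15)
  up <- b[paste0("up_", 1:10)]
  down <- b[paste0("down_", 1:10)]
  expected <- n * 1e5 / span
  expect_true(all(abs(c(up, down) - expected) < 5 * sqrt(expected)))
})

test_that("tissue summary reproduces part/whole percentages and totals", {
  counts <- data.frame(tissue = c("duodenum", "liver", "muscle"),
                       n_sig = c(3162603, 4340467, 6593010),
                       n_cis_var = c(1650766, 2436245, 3823132),
                       n_regions = c(4645, 11232, 10537),
                       n_cis_regions = c(1311, 1898, 2604))
  tab <- summarize_tissue(counts)
  expect_equal(tab$pct_cis_var, c(52.2, 56.1, 58.0, 56.1))
  expect_equal(tab$pct_cis_regions, c(28.2, 16.9, 24.7, 22.0))
  expect_equal(tab$n_sig[4], 14096080)
  expect_equal(tab$n_regions[4], 26414)
})

test_that("summary bookkeeping matches planted ground truth on a toy set", {
  sig <- data.frame(vid = c("v1", "v2", "v3", "v4"), chrom = "1",
                    pos = c(1e6, 1.2e6, 9e6, 9.1e6),
                    gene_id = c("G1", "G1", "G1", "G1"),
                    p_adj = c(.01, .02, .001, .04))
  genes <- data.frame(gene_id = "G1", chrom = "1", start = 1.5e6,
                      end = 1.6e6, strand = "+")
  lab <- cis_labels(sig, genes)
  expect_equal(sum(lab$is_cis), 2)
  reg <- cluster_regions_by_gene(sig)
  reg <- label_regions_cis(reg, lab)
  expect_equal(nrow(reg), 2)
  expect_equal(sort(reg$is_cis), c(FALSE, TRUE))
  ct <- eqtl_counts(sig, lab, reg, "toy")
  expect_equal(ct$n_sig, 4)
  expect_equal(ct$n_cis_var, 2)
  expect_equal(ct$n_regions, 2)
  expect_equal(ct$n_cis_regions, 1)
  # every cis region has a cis member; trans regions none
  cis_pairs <- paste(lab$vid[lab$is_cis], lab$gene_id[lab$is_cis])
  for (i in seq_len(nrow(reg))) {
    has_cis <- any(paste(reg$member_vids[[i]], reg$gene_id[i]) %in% cis_pairs)
    expect_equal(reg$is_cis[i], has_cis)
  }
})
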