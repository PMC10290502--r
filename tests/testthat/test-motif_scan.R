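test_that("SNP context extraction pads, substitutes, and validates", {
  ref <- c("1" = "AAAAAAAAAACAAAAAAAAAA")
  vs <- variant_set(data.frame(chrom = "1", pos = 11L, vid = "v",
                               ref = "C", alt = "G"), matrix(0, 1, 2))
  ctx <- extract_snp_context(vs, ref)
  expect_equal(ctx$ref_seq, "AAAAAAAAAACAAAAAAAAAA")
  expect_equal(ctx$alt_seq, "AAAAAAAAAAGAAAAAAAAAA")
  expect_equal(nchar(ctx$ref_seq), 21)
  # N padding near the chromosome edge
  vs_edge <- variant_set(data.frame(chrom = "1", pos = 2L, vid = "e",
                                    ref = "A", alt = "T"), matrix(0, 1, 2))
  ctx_e <- extract_snp_context(vs_edge, ref)
  expect_equal(substr(ctx_e$ref_seq, 1, 9), strrep("N", 9))
  # indels rejected; reference mismatch names the variant
  vs_i <- variant_set(data.frame(chrom = "1", pos = 11L, vid = "i",
                                 ref = "C", alt = "CT"), matrix(0, 1, 2))
  expect_error(extract_snp_context(vs_i, ref), "SNP-only")
  vs_bad <- variant_set(data.frame(chrom = "1", pos = 12L, vid = "bad",
                                   ref = "C", alt = "G"), matrix(0, 1, 2))
  expect_error(extract_snp_context(vs_bad, ref), "bad")
})

test_that("random SNP contexts agree with direct substring extraction", {
  set.seed(141)
  chrom <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE),
                 collapse = "")
  pos <- sample(100:9900, 100)
  ref <- substring(chrom, pos, pos)
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                character(1))
  vs <- variant_set(data.frame(chrom = "9", pos = pos,
                               vid = paste0("s", seq_along(pos)),
                               ref = ref, alt = alt),
                    matrix(0, length(pos), 2))
  ctx <- extract_snp_context(vs, c("9" = chrom))
  expect_equal(ctx$ref_seq, substring(chrom, pos - 10, pos + 10))
  expect_equal(substring(ctx$alt_seq, 11, 11), unname(alt))
})

test_that("IUPAC consensus expands to the documented probabilities", {
  expect_equal(unname(pwm_from_iupac("A", soft = 0)$probs[, 1]),
               c(1, 0, 0, 0))
  expect_equal(unname(pwm_from_iupac("R", soft = 0)$probs[, 1]),
               c(0.5, 0, 0.5, 0))
  p <- pwm_from_iupac("GATCCNGYGTTGCYG")
  expect_equal(p$width, 15)
  expect_equal(unname(p$probs[, 6]), rep(0.25, 4))  # N = background
  expect_equal(unname(p$probs[, 8]), c(0.05, 0.45, 0.05, 0.45))  # Y = C/T
  expect_true(all(abs(colSums(p$probs) - 1) < 1e-9))
  expect_error(pwm_from_iupac("AXG"), "invalid")
})

test_that("width-1 scan has the closed-form score and p-value", {
  p <- pwm_from_iupac("A", soft = 0)
  h <- scan_pwm(c(s = "A"), p, both_strands = FALSE, floor_prob = 0)
  expect_equal(h$score, 2)       # log2(4)
  expect_equal(h$p_value, 0.25)
})

test_that("DP p-values equal exhaustive enumeration for short motifs", {
  set.seed(142)
  for (w in c(2, 3, 5)) {
    probs <- matrix(rgamma(4 * w, 1), 4, w)
    probs <- sweep(probs, 2, colSums(probs), "/")
    rownames(probs) <- c("A", "C", "G", "T")
    pwm <- structure(list(width = w, probs = probs,
                          background = c(A = .25, C = .25, G = .25, T = .25),
                          consensus = NULL), class = "pwm")
    pfun <- enum_pwm_pvalue(pwm)
    seqs <- vapply(1:10, function(i) {
      paste(sample(c("A", "C", "G", "T"), w + 4, replace = TRUE),
            collapse = "")
    }, character(1))
    names(seqs) <- paste0("s", 1:10)
    hits <- scan_pwm(seqs, pwm, both_strands = FALSE)
    enum_p <- vapply(round(hits$score / (1 / 1000)), pfun, numeric(1))
    expect_equal(hits$p_value, enum_p, tolerance = 1e-12)
  }
})

test_that("scanning is strand-symmetric under reverse complement", {
  set.seed(143)
  pwm <- pwm_from_iupac("GATAAG")
  s <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE),
             collapse = "")
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]),
                                     collapse = ""))
  h1 <- scan_pwm(c(x = s), pwm)
  h2 <- scan_pwm(c(x = rc), pwm)
  expect_equal(sort(h1$score[h1$strand == "+"]),
               sort(h2$score[h2$strand == "-"]))
  expect_equal(sort(h1$score[h1$strand == "-"]),
               sort(h2$score[h2$strand == "+"]))
  expect_equal(max(h1$score), max(h2$score))
})

test_that("0-order background estimation counts bases and ignores N", {
  bg <- estimate_background(c("AACC", "GGNN"))
  expect_equal(unname(bg), c(2, 2, 2, 0) / 6)
  expect_equal(sum(bg), 1)
})

test_that("BH q-values match the step-up reference and the 0.1 gate", {
  h <- data.frame(seq_id = "s", offset = 1:3, strand = "+",
                  score = 0, p_value = c(0.01, 0.02, 0.03))
  q <- bh_qvalues(h)
  expect_equal(q$q_value, c(0.03, 0.03, 0.03))
  expect_true(all(q$is_significant))
  h1 <- data.frame(seq_id = "s", offset = 1:4, strand = "+",
                   score = 0, p_value = rep(1, 4))
  expect_false(any(bh_qvalues(h1)$is_significant))
  set.seed(144)
  p <- runif(200)^2
  h2 <- data.frame(seq_id = "s", offset = seq_along(p), strand = "+",
                   score = 0, p_value = p)
  expect_equal(bh_qvalues(h2)$q_value, bh_ref(p), tolerance = 1e-12)
  expect_equal(nrow(bh_qvalues(h2[0, ])), 0)
})

test_that("a planted 15-mer is recovered at q <= 0.1 with quiet controls", {
  set.seed(145)
  consensus <- "GATCCNGYGTTGCYG"
  draw_site <- function() {
    iupac <- Biostrings::IUPAC_CODE_MAP
    paste(vapply(strsplit(consensus, "")[[1]], function(ch) {
      sample(strsplit(iupac[[ch]], "")[[1]], 1)
    }, character(1)), collapse = "")
  }
  n_seq <- 50
  planted <- sample(1:7, n_seq, replace = TRUE)
  seqs <- vapply(1:n_seq, function(i) {
    s <- sample(c("A", "C", "G", "T"), 21, replace = TRUE)
    site <- strsplit(draw_site(), "")[[1]]
    s[planted[i]:(planted[i] + 14)] <- site
    paste(s, collapse = "")
  }, character(1))
  names(seqs) <- paste0("snp", 1:n_seq)
  controls <- vapply(1:50, function(i) {
    paste(sample(c("A", "C", "G", "T"), 21, replace = TRUE), collapse = "")
  }, character(1))
  names(controls) <- paste0("ctrl", 1:50)
  pwm <- pwm_from_iupac(consensus)
  hits <- bh_qvalues(scan_pwm(c(seqs, controls), pwm))
  found <- vapply(1:n_seq, function(i) {
    any(hits$is_significant & hits$seq_id == names(seqs)[i] &
          hits$offset == planted[i] & hits$strand == "+")
  }, logical(1))
  expect_gte(mean(found), 0.9)
  ctrl_sig <- hits$is_significant[grepl("^ctrl", hits$seq_id)]
  expect_lte(mean(ctrl_sig), 0.01)
})
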