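#' Simulation configuration
#'
#' Defaults emulate the study design the pipeline targets: 300 animals in 3
#' breed strata of 100 with a balanced sex covariate, LD-structured
#' biallelic genotypes with a Beta-shaped allele-frequency spectrum and
#' ~10\% short indels, negative-binomial counts with log-normal library
#' sizes, a polygenic background drawn from the realized genotype GRM
#' (h2 = 0.3), and user-specified planted cis / trans / hotspot-mediated
#' effects.
#'
#' @param n_samples total animals (default 300, split evenly over breeds).
#' @param n_breeds number of breed strata (default 3).
#' @param sex_ratio fraction of males within each breed (default 0.5).
#' @param n_chromosomes,chrom_length_bp genome layout (default 2 x 20 Mb).
#' @param n_variants total variants (default 5000).
#' @param maf_beta Beta(a, b) parameters of the allele-frequency draw
#'   (default c(1, 3)).
#' @param ld_block_length_bp LD block length (default 5e4).
#' @param copy_prob within-block probability that a haplotype copies the
#'   previous variant's allele (default 0.9).
#' @param breed_sd logit-scale sd of per-breed allele-frequency
#'   perturbations (default 0.3).
#' @param prop_indels fraction of variants simulated as 1-8 bp indels
#'   (default 0.1).
#' @param missing_rate genotype missingness rate (default 0.02).
#' @param n_genes number of genes (default 200).
#' @param gene_length_range uniform range of gene lengths in bp.
#' @param lib_meanlog,lib_sdlog log-normal library-size parameters
#'   (default log(2e7), 0.3).
#' @param dispersion negative-binomial dispersion (default 0.05; 0 gives
#'   Poisson counts).
#' @param h2_background polygenic fraction of the unit latent variance
#'   (default 0.3).
#' @param base_expr_range uniform range of baseline log2-cpm intercepts.
#' @param effect_sd sd of per-gene sex and breed fixed effects (default
#'   0.5).
#' @param planted_effects list of planted effects; see [plant_cis()] and
#'   [plant_hotspot()].
#' @param seed RNG seed; the same config yields identical output.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 300, n_breeds = 3, sex_ratio = 0.5,
                       n_chromosomes = 2, chrom_length_bp = 2e7,
                       n_variants = 5000, maf_beta = c(1, 3),
                       ld_block_length_bp = 5e4, copy_prob = 0.9,
                       breed_sd = 0.3, prop_indels = 0.1,
                       missing_rate = 0.02, n_genes = 200,
                       gene_length_range = c(5e3, 5e4),
                       lib_meanlog = log(2e7), lib_sdlog = 0.3,
                       dispersion = 0.05, h2_background = 0.3,
                       base_expr_range = c(3, 8), effect_sd = 0.5,
                       planted_effects = list(), seed = 1) {
  cfg <- as.list(environment())
  stopifnot(n_samples > 0, n_breeds > 0, n_variants > 0, n_genes > 0,
            copy_prob >= 0, copy_prob <= 1, missing_rate >= 0,
            missing_rate <= 1, h2_background >= 0, h2_background <= 1)
  class(cfg) <- "sim_config"
  cfg
}

#' Declare a planted cis (or direct trans) effect
#' @param gene_id,causal_vid explicit ids, or NULL to let the simulator pick
#'   (a variant within 1 Mb of the gene for `kind = "cis"`).
#' @param effect per-allele shift in latent log2-cpm (default 1.0).
#' @param kind `"cis"` or `"trans_direct"`.
#' @param min_maf minimum allele frequency when picking a causal variant.
#' @return planted-effect description.
#' @export
plant_cis <- function(gene_id = NULL, causal_vid = NULL, effect = 1.0,
                      kind = c("cis", "trans_direct"), min_maf = 0.2) {
  list(kind = match.arg(kind), gene_id = gene_id, causal_vid = causal_vid,
       effect = effect, min_maf = min_maf)
}

#' Declare a planted hotspot-mediated architecture
#'
#' A causal variant cis to a regulator gene shifts the regulator's latent
#' expression; each of `n_targets` downstream genes adds
#' `med_coef x (centered regulator latent)`, so the variant becomes
#' trans-associated with all targets through the regulator.
#'
#' @param regulator_gene,causal_vid explicit ids or NULL (simulator picks a
#'   regulator and a nearby variant).
#' @param n_targets number of downstream genes (default 15; the hotspot
#'   definition needs >= 10).
#' @param effect per-allele effect on the regulator (default 1.2).
#' @param med_coef mediation coefficient(s), recycled over targets
#'   (default 0.8).
#' @param min_maf minimum allele frequency for a picked causal variant.
#' @return planted-effect description.
#' @export
plant_hotspot <- function(regulator_gene = NULL, causal_vid = NULL,
                          n_targets = 15, effect = 1.2, med_coef = 0.8,
                          min_maf = 0.2) {
  if (n_targets < 10) warning("fewer than 10 targets cannot reach the ",
                              "hotspot definition")
  list(kind = "hotspot_mediated", gene_id = regulator_gene,
       causal_vid = causal_vid, n_targets = n_targets, effect = effect,
       med_coef = med_coef, min_maf = min_maf)
}

#' Simulate LD-structured genotypes
#'
#' Allele frequencies are drawn per LD block from a Beta distribution and
#' perturbed per breed on the logit scale; within a block each haplotype
#' copies the previous variant's allele with probability `copy_prob`
#' (producing decaying LD), and draws a fresh allele otherwise. About
#' `prop_indels` of the variants are 1-8 bp indels; missing genotypes are
#' sprinkled at `missing_rate`.
#'
#' @param config [sim_config()].
#' @return A [variant_set]; sample ids are `S001`, ...
#' @export
simulate_genotypes <- function(config) {
  set.seed(config$seed)
  n <- config$n_samples
  nv <- config$n_variants
  per_chrom <- diff(round(seq(0, nv, length.out = config$n_chromosomes + 1)))
  chrom <- rep(as.character(seq_len(config$n_chromosomes)), per_chrom)
  grid <- 30L  # spacing guard so indel REF strings never overlap a neighbor
  pos <- unlist(lapply(per_chrom, function(k) {
    sort(sample.int((config$chrom_length_bp - 10L) %/% grid, k)) * grid
  }))
  block <- paste0(chrom, "_", ceiling(pos / config$ld_block_length_bp))
  ublock <- unique(block)
  p_block <- pmin(pmax(stats::rbeta(length(ublock), config$maf_beta[1],
                                    config$maf_beta[2]), 0.02), 0.98)
  names(p_block) <- ublock
  breed <- rep(seq_len(config$n_breeds),
               times = rep(ceiling(n / config$n_breeds),
                           config$n_breeds))[seq_len(n)]
  ## per-(block, breed) frequencies
  p_bb <- vapply(seq_len(config$n_breeds), function(b) {
    stats::plogis(stats::qlogis(p_block) +
                    stats::rnorm(length(p_block), 0, config$breed_sd))
  }, numeric(length(ublock)))
  rownames(p_bb) <- ublock

  hap <- matrix(0L, nrow = nv, ncol = 2L * n)
  hap_breed <- rep(breed, each = 2L)
  for (l in seq_len(nv)) {
    p_l <- p_bb[block[l], hap_breed]
    fresh <- stats::rbinom(2L * n, 1L, p_l)
    if (l > 1L && block[l] == block[l - 1L]) {
      copy <- stats::runif(2L * n) < config$copy_prob
      hap[l, ] <- ifelse(copy, hap[l - 1L, ], fresh)
    } else {
      hap[l, ] <- fresh
    }
  }
  dos <- hap[, seq(1L, 2L * n, by = 2L), drop = FALSE] +
    hap[, seq(2L, 2L * n, by = 2L), drop = FALSE]
  if (config$missing_rate > 0) {
    dos[stats::runif(length(dos)) < config$missing_rate] <- NA_real_
  }

  is_indel <- stats::runif(nv) < config$prop_indels
  ref <- sample(c("A", "C", "G", "T"), nv, replace = TRUE)
  alt <- vapply(seq_len(nv), function(l) {
    if (!is_indel[l]) {
      sample(setdiff(c("A", "C", "G", "T"), ref[l]), 1L)
    } else {
      tail_seq <- paste(sample(c("A", "C", "G", "T"),
                               sample.int(8L, 1L), replace = TRUE),
                        collapse = "")
      if (stats::runif(1) < 0.5) paste0(ref[l], tail_seq) else ref[l]
    }
  }, character(1))
  del <- is_indel & nchar(alt) == 1L
  ref[del] <- vapply(which(del), function(l) {
    paste0(ref[l], paste(sample(c("A", "C", "G", "T"),
                                sample.int(8L, 1L), replace = TRUE),
                         collapse = ""))
  }, character(1))

  info <- data.frame(chrom = chrom, pos = pos,
                     vid = make_vid(chrom, pos, ref, alt),
                     ref = ref, alt = alt, stringsAsFactors = FALSE)
  variant_set(info, dos, samples = sprintf("S%03d", seq_len(n)))
}

## resolve planted-effect gene/variant choices against the simulated data
.resolve_effects <- function(config, geno, genes, used_genes = character()) {
  info <- geno$info
  af <- rowMeans(geno$dosages, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  is_snp <- nchar(info$ref) == 1L & nchar(info$alt) == 1L
  pick_variant <- function(g, min_maf) {
    cand <- which(info$chrom == g$chrom & is_snp & maf >= min_maf &
                    info$pos >= g$start - 1e6 & info$pos <= g$end + 1e6)
    if (!length(cand)) stop("no candidate cis variant for gene ", g$gene_id)
    info$vid[sample(cand, 1L)]
  }
  resolved <- list()
  for (pe in config$planted_effects) {
    if (is.null(pe$gene_id)) {
      free <- setdiff(genes$gene_id, used_genes)
      pe$gene_id <- sample(free, 1L)
    }
    used_genes <- c(used_genes, pe$gene_id)
    g <- genes[genes$gene_id == pe$gene_id, ]
    if (nrow(g) == 0L) stop("unknown gene id: ", pe$gene_id)
    if (is.null(pe$causal_vid)) {
      if (pe$kind == "trans_direct") {
        cand <- which(is_snp & maf >= pe$min_maf &
                        (info$chrom != g$chrom |
                           abs(info$pos - g$start) > 2e6))
        pe$causal_vid <- info$vid[sample(cand, 1L)]
      } else {
        pe$causal_vid <- pick_variant(g, pe$min_maf)
      }
    } else if (!pe$causal_vid %in% info$vid) {
      stop("unknown variant id: ", pe$causal_vid)
    }
    if (pe$kind == "hotspot_mediated") {
      free <- setdiff(genes$gene_id, used_genes)
      ## targets trans to the causal variant: different chromosome or > 2 Mb
      v <- info[info$vid == pe$causal_vid, ]
      gstart <- genes$start[match(free, genes$gene_id)]
      gchrom <- genes$chrom[match(free, genes$gene_id)]
      far <- free[gchrom != v$chrom | abs(gstart - v$pos) > 2e6]
      if (length(far) < pe$n_targets) stop("not enough trans target genes")
      pe$targets <- sample(far, pe$n_targets)
      used_genes <- c(used_genes, pe$targets)
      pe$med_coef <- rep_len(pe$med_coef, pe$n_targets)
    }
    resolved[[length(resolved) + 1L]] <- pe
  }
  resolved
}

#' Simulate expression counts with ground truth
#'
#' Runs the association model forward: per-gene latent log2 expression =
#' intercept + sex + breed + polygenic term (MVN with covariance
#' `G * h2_background` from the realized genotype GRM) + planted effects +
#' Gaussian noise of variance `1 - h2_background`; hotspot-mediated targets
#' add their coefficient times the centered regulator latent. Counts are
#' negative-binomial with mean `library_size * 2^latent / 1e6`.
#'
#' @param config [sim_config()].
#' @param geno [variant_set] from [simulate_genotypes()].
#' @return list: `counts` (genes x samples), `meta` (sample_id, sex,
#'   breed, tissue), `genes` (annotation data.frame), `truth` (resolved
#'   planted effects, incl. a `table` data.frame of (kind, vid, gene,
#'   effect) rows), `latent`, `grm`, `lib_sizes`.
#' @export
simulate_expression <- function(config, geno) {
  set.seed(config$seed + 1L)
  n <- config$n_samples
  breed <- factor(rep(paste0("breed", seq_len(config$n_breeds)),
                      times = rep(ceiling(n / config$n_breeds),
                                  config$n_breeds))[seq_len(n)])
  sex <- factor(unlist(lapply(table(breed), function(k) {
    rep(c("M", "F"), times = c(round(k * config$sex_ratio),
                               k - round(k * config$sex_ratio)))
  })))
  meta <- data.frame(sample_id = geno$samples, sex = sex, breed = breed,
                     tissue = "synthetic", stringsAsFactors = FALSE)

  glen <- round(stats::runif(config$n_genes, config$gene_length_range[1],
                             config$gene_length_range[2]))
  gchrom <- as.character(sample.int(config$n_chromosomes, config$n_genes,
                                    replace = TRUE))
  gstart <- round(stats::runif(config$n_genes, 1,
                               config$chrom_length_bp - max(glen)))
  genes <- data.frame(gene_id = sprintf("G%04d", seq_len(config$n_genes)),
                      chrom = gchrom, start = gstart,
                      end = gstart + glen - 1L,
                      strand = sample(c("+", "-"), config$n_genes,
                                      replace = TRUE),
                      stringsAsFactors = FALSE)

  grm <- compute_grm(geno, exclude_chrom = character())
  eg <- eigen(grm, symmetric = TRUE)
  sq <- sqrt(pmax(eg$values, 0) * config$h2_background)

  base <- stats::runif(config$n_genes, config$base_expr_range[1],
                       config$base_expr_range[2])
  sex_eff <- stats::rnorm(config$n_genes, 0, config$effect_sd)
  breed_eff <- matrix(stats::rnorm(config$n_genes * config$n_breeds, 0,
                                   config$effect_sd),
                      nrow = config$n_genes)
  latent <- matrix(0, config$n_genes, n,
                   dimnames = list(genes$gene_id, geno$samples))
  for (h in seq_len(config$n_genes)) {
    u <- drop(eg$vectors %*% (sq * stats::rnorm(n)))
    latent[h, ] <- base[h] + sex_eff[h] * (sex == "F") +
      breed_eff[h, as.integer(breed)] + u +
      stats::rnorm(n, 0, sqrt(1 - config$h2_background))
  }

  effects <- .resolve_effects(config, geno, genes)
  truth_rows <- list()
  dosage_of <- function(vid) {
    d <- geno$dosages[match(vid, geno$info$vid), ]
    ifelse(is.na(d), mean(d, na.rm = TRUE), d)
  }
  for (pe in effects) {
    d <- dosage_of(pe$causal_vid)
    latent[pe$gene_id, ] <- latent[pe$gene_id, ] + pe$effect * d
    truth_rows[[length(truth_rows) + 1L]] <-
      data.frame(kind = pe$kind, vid = pe$causal_vid, gene_id = pe$gene_id,
                 effect = pe$effect, stringsAsFactors = FALSE)
    if (pe$kind == "hotspot_mediated") {
      reg_c <- latent[pe$gene_id, ] - mean(latent[pe$gene_id, ])
      for (t in seq_along(pe$targets)) {
        latent[pe$targets[t], ] <- latent[pe$targets[t], ] +
          pe$med_coef[t] * reg_c
        truth_rows[[length(truth_rows) + 1L]] <-
          data.frame(kind = "hotspot_target", vid = pe$causal_vid,
                     gene_id = pe$targets[t],
                     effect = pe$effect * pe$med_coef[t],
                     stringsAsFactors = FALSE)
      }
    }
  }

  lib <- stats::rlnorm(n, config$lib_meanlog, config$lib_sdlog)
  mu <- t(t(2^latent) * (lib / 1e6))
  counts <- if (config$dispersion > 0) {
    matrix(stats::rnbinom(length(mu), mu = mu,
                          size = 1 / config$dispersion),
           nrow = nrow(mu), dimnames = dimnames(mu))
  } else {
    matrix(stats::rpois(length(mu), mu), nrow = nrow(mu),
           dimnames = dimnames(mu))
  }
  list(counts = counts, meta = meta, genes = genes,
       truth = list(effects = effects,
                    table = if (length(truth_rows))
                      do.call(rbind, truth_rows) else NULL),
       latent = latent, grm = grm, lib_sizes = lib)
}

## genotype string for a dosage value
.dos_to_gt <- function(d) {
  ifelse(is.na(d), "./.", c("0/0", "0/1", "1/1")[d + 1L])
}

#' Write a self-consistent fixture bundle to disk
#'
#' Writes VCF, GFF3, counts TSV, sample metadata TSV, ground-truth TSV and
#' (optionally) a reference FASTA whose bases agree with every VCF
#' reference allele. Two runs from the same simulation objects are
#' byte-identical.
#'
#' @param config [sim_config()].
#' @param geno [variant_set].
#' @param expr result of [simulate_expression()].
#' @param dir output directory (created if needed).
#' @param fasta write the reference FASTA (default TRUE; the sequence is
#'   random except at variant sites).
#' @return named character vector of file paths, invisibly.
#' @export
write_fixture_bundle <- function(config, geno, expr, dir, fasta = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "genotypes.vcf"),
             gff = file.path(dir, "genes.gff3"),
             counts = file.path(dir, "counts.tsv"),
             meta = file.path(dir, "meta.tsv"),
             truth = file.path(dir, "truth.tsv"),
             fasta = file.path(dir, "reference.fa"))

  info <- geno$info
  gt <- apply(geno$dosages, 2L, .dos_to_gt)
  header <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s,length=%d>",
                      seq_len(config$n_chromosomes),
                      config$chrom_length_bp),
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", geno$samples), collapse = "\t"))
  body <- paste(info$chrom, info$pos, info$vid, info$ref, info$alt, ".",
                "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), paths["vcf"])

  g <- expr$genes
  gff <- c("##gff-version 3",
           paste(g$chrom, "sweqtl_sim", "gene", g$start, g$end, ".",
                 g$strand, ".",
                 paste0("ID=", g$gene_id, ";gene_id=", g$gene_id),
                 sep = "\t"))
  writeLines(gff, paths["gff"])

  write_expression_tsv(expr$counts, paths["counts"])
  utils::write.table(expr$meta, paths["meta"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tt <- expr$truth$table
  if (is.null(tt)) tt <- data.frame(kind = character(), vid = character(),
                                    gene_id = character(),
                                    effect = numeric())
  utils::write.table(tt, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  if (fasta) {
    set.seed(config$seed + 2L)
    chroms <- lapply(seq_len(config$n_chromosomes), function(ch) {
      s <- sample(c("A", "C", "G", "T"), config$chrom_length_bp,
                  replace = TRUE)
      at <- info$chrom == as.character(ch)
      for (i in which(at)) {
        r <- strsplit(info$ref[i], "")[[1]]
        s[info$pos[i] + seq_along(r) - 1L] <- r
      }
      paste(s, collapse = "")
    })
    dna <- Biostrings::DNAStringSet(unlist(chroms))
    names(dna) <- as.character(seq_len(config$n_chromosomes))
    Biostrings::writeXStringSet(dna, paths["fasta"])
  } else {
    paths <- paths[names(paths) != "fasta"]
  }
  invisible(paths)
}
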