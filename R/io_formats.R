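#' Construct a variant set
#'
#' A variant set bundles the per-variant table (chromosome, 1-based position,
#' identifier, reference and alternative allele) with the variants x samples
#' dosage matrix (alternative-allele counts in 0/1/2, `NA` for missing).
#' All coordinates in the package are 1-based inclusive; only BED export
#' converts.
#'
#' @param info data.frame with columns `chrom`, `pos`, `vid`, `ref`, `alt`.
#' @param dosages numeric matrix, variants in rows, samples in columns.
#' @param samples character vector of sample ids (defaults to the dosage
#'   column names).
#' @return An object of class `variant_set`.
#' @export
variant_set <- function(info, dosages, samples = colnames(dosages)) {
  stopifnot(is.data.frame(info), nrow(info) == nrow(dosages))
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(dosages)))
  if (any(!nzchar(info$ref)) || any(!nzchar(info$alt)))
    stop("ref and alt alleles must be non-empty")
  if (any(info$ref == info$alt))
    stop("ref and alt alleles must differ")
  if (any(info$pos < 1)) stop("positions are 1-based; pos must be >= 1")
  dosages <- as.matrix(dosages)
  colnames(dosages) <- samples
  rownames(dosages) <- info$vid
  structure(list(info = info, dosages = dosages, samples = samples),
            class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat("variant_set:", nrow(x$info), "variants x", length(x$samples),
      "samples\n")
  print(utils::head(x$info, 5))
  invisible(x)
}

#' @export
dim.variant_set <- function(x) c(nrow(x$info), length(x$samples))

#' Subset a variant set by variant index
#' @param vs variant_set.
#' @param i variant indices (integer or logical).
#' @return variant_set restricted to the selected variants.
#' @export
subset_variants <- function(vs, i) {
  variant_set(vs$info[i, , drop = FALSE],
              vs$dosages[i, , drop = FALSE], vs$samples)
}

#' Synthesize a variant identifier
#'
#' Identifiers follow the "chrom:pos_REF/ALT" convention
#' (e.g. "4:96172709_C/CT").
#' @param chrom,pos,ref,alt vectors of equal length.
#' @return character vector of ids.
#' @export
make_vid <- function(chrom, pos, ref, alt) {
  paste0(chrom, ":", format(pos, scientific = FALSE, trim = TRUE),
         "_", ref, "/", alt)
}

## GT string -> count of `allele` (character index) per sample.
## "./." or any half-missing call -> NA; phased and unphased identical.
.gt_allele_count <- function(gt, allele) {
  gt[is.na(gt)] <- "./."  # upstream parsers may blank missing calls
  gt <- sub(":.*", "", gt)
  parts <- strsplit(gt, "[/|]")
  vapply(parts, function(p) {
    if (length(p) != 2L) {
      if (length(p) == 1L && p %in% c(".", "")) return(NA_real_)
      stop("non-diploid genotype: ", paste(p, collapse = "/"))
    }
    if (any(p == ".")) return(NA_real_)
    sum(p == allele)
  }, numeric(1))
}

#' Split multiallelic sites into biallelic records
#'
#' Each output record carries exactly one ALT allele; the dosage of record
#' *k* counts allele *k* only, so a genotype carrying a different alternative
#' allele contributes 0 copies (the bcftools-norm convention), conserving the
#' total alternative-allele count per site across the split records.
#'
#' @param fixed data.frame with columns `chrom`, `pos`, `id`, `ref`, `alt`
#'   (`alt` may contain comma-separated alleles; `id` may be `"."` or `NA`).
#' @param gt character matrix of GT strings (sites x samples), e.g. `"0/1"`.
#' @param samples sample ids.
#' @return A [variant_set] with one row per ALT allele.
#' @export
split_multiallelic <- function(fixed, gt, samples = colnames(gt)) {
  gt <- as.matrix(gt)
  stopifnot(nrow(fixed) == nrow(gt))
  out_info <- vector("list", nrow(fixed))
  out_dos <- vector("list", nrow(fixed))
  for (i in seq_len(nrow(fixed))) {
    alts <- strsplit(fixed$alt[i], ",", fixed = TRUE)[[1]]
    dos <- t(vapply(seq_along(alts), function(k) {
      .gt_allele_count(gt[i, ], as.character(k))
    }, numeric(ncol(gt))))
    if (length(alts) == 1L) dos <- matrix(dos, nrow = 1L)
    id <- fixed$id[i]
    vids <- if (length(alts) == 1L && !is.na(id) && id != "." && nzchar(id)) {
      id
    } else {
      make_vid(fixed$chrom[i], fixed$pos[i], fixed$ref[i], alts)
    }
    out_info[[i]] <- data.frame(chrom = fixed$chrom[i], pos = fixed$pos[i],
                                vid = vids, ref = fixed$ref[i], alt = alts,
                                stringsAsFactors = FALSE)
    out_dos[[i]] <- dos
  }
  variant_set(do.call(rbind, out_info), do.call(rbind, out_dos), samples)
}

#' Read a VCF into a biallelic variant set
#'
#' Multiallelic records are split into one row per ALT allele (see
#' [split_multiallelic()]). Missing ("./.") and half-missing genotypes map to
#' missing dosage; phased and unphased genotypes are treated identically.
#'
#' @param path VCF file (plain or bgzipped).
#' @return A [variant_set].
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop("no variant records in ", path)
  gt <- vcfR::extract.gt(v, element = "GT", return.alleles = FALSE)
  fixed <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                      id = fix$ID, ref = fix$REF, alt = fix$ALT,
                      stringsAsFactors = FALSE)
  if (anyNA(fixed$pos) || anyNA(fixed$ref) || anyNA(fixed$alt))
    stop("malformed VCF record at line with POS=",
         fix$POS[which(is.na(fixed$pos) | is.na(fixed$ref) |
                         is.na(fixed$alt))[1]])
  split_multiallelic(fixed, gt, samples = colnames(gt))
}

#' Read gene annotations from GFF3/GTF
#'
#' Keeps only features of type "gene" and returns 1-based inclusive
#' coordinates with strand.
#'
#' @param path GFF3 or GTF file.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @export
read_gff_genes <- function(path) {
  gr <- rtracklayer::import(path)
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
  if (length(gr) == 0L) {
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  ids <- if ("gene_id" %in% names(S4Vectors::mcols(gr))) {
    as.character(gr$gene_id)
  } else if ("ID" %in% names(S4Vectors::mcols(gr))) {
    as.character(gr$ID)
  } else {
    rep(NA_character_, length(gr))
  }
  if (anyNA(ids) || any(!nzchar(ids))) {
    bad <- which(is.na(ids) | !nzchar(ids))[1]
    stop("gene feature without gene_id at ",
         as.character(GenomicRanges::seqnames(gr))[bad], ":",
         GenomicRanges::start(gr)[bad])
  }
  data.frame(gene_id = ids,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Read an expression matrix from TSV
#'
#' Expects a header row of sample ids and gene ids in the first column.
#'
#' @param path TSV file.
#' @return numeric matrix, genes x samples.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(df[[1]])) {
    stop("duplicate gene ids: ",
         paste(unique(df[[1]][duplicated(df[[1]])]), collapse = ", "))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric or ragged expression values in ", path)
  rownames(m) <- df[[1]]
  m
}

#' Write an expression matrix to TSV
#' @param mat genes x samples matrix with dimnames.
#' @param path output file.
#' @return path, invisibly.
#' @export
write_expression_tsv <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write association records to TSV
#'
#' Columns follow GWAS summary-statistic convention:
#' chrom, vid, pos, ref, alt, n, af, beta, se, p, p_adj, gene_id, tissue.
#' @param assoc data.frame of association records.
#' @param path output file.
#' @return path, invisibly.
#' @export
write_association_tsv <- function(assoc, path) {
  cols <- c("chrom", "vid", "pos", "ref", "alt", "n", "af", "beta", "se",
            "p", "p_adj", "gene_id", "tissue")
  keep <- intersect(cols, names(assoc))
  utils::write.table(assoc[, keep, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read association records from TSV
#' @param path TSV written by [write_association_tsv()].
#' @return data.frame.
#' @export
read_association_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Write eQTL regions as BED
#'
#' Internal coordinates are 1-based inclusive; BED is 0-based half-open, so
#' a region (start, end) becomes (start - 1, end).
#'
#' @param regions data.frame with `chrom`, `start`, `end` and optionally
#'   `name` columns (1-based inclusive).
#' @param path output file.
#' @return path, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  name <- if ("name" %in% names(regions)) regions$name else
    paste0(regions$chrom, ":", regions$start, "-", regions$end)
  bed <- data.frame(chrom = regions$chrom,
                    start = format(regions$start - 1L, scientific = FALSE,
                                   trim = TRUE),
                    end = format(regions$end, scientific = FALSE, trim = TRUE),
                    name = name, stringsAsFactors = FALSE)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
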