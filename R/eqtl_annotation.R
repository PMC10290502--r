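#' Cluster significant variants into eQTL regions
#'
#' Single-linkage chaining per chromosome: consecutive significant variants
#' closer than `gap` (strictly less than 2 Mb by default) join one cluster;
#' clusters with fewer than `min_members` variants are discarded; the
#' retained core span is extended by `pad` on each side (clipped at 1).
#' This is equivalent to merging overlapping +-1 Mb windows around each
#' significant variant and dropping single-variant regions.
#'
#' @param sig data.frame of significant associations for ONE gene and tissue
#'   with columns `vid`, `chrom`, `pos`, `p_adj` (or `p`).
#' @param gap maximum chaining distance in bp (strict; default 2e6).
#' @param min_members minimum variants per retained region (default 2).
#' @param pad extension in bp on each side (default 1e6).
#' @return data.frame, one row per region: `chrom`, `core_start`,
#'   `core_end`, `ext_start`, `ext_end`, `n_members`, plus list-columns
#'   `member_vids` and `top_vids` (all variants tying the smallest adjusted
#'   p-value).
#' @export
cluster_regions <- function(sig, gap = 2e6, min_members = 2, pad = 1e6) {
  empty <- data.frame(chrom = character(), core_start = numeric(),
                      core_end = numeric(), ext_start = numeric(),
                      ext_end = numeric(), n_members = integer(),
                      stringsAsFactors = FALSE)
  empty$member_vids <- list(); empty$top_vids <- list()
  if (is.null(sig) || nrow(sig) == 0L) return(empty)
  pcol <- if ("p_adj" %in% names(sig)) "p_adj" else "p"
  sig <- sig[order(sig$chrom, sig$pos), , drop = FALSE]
  out <- list()
  for (ch in unique(sig$chrom)) {
    s <- sig[sig$chrom == ch, , drop = FALSE]
    cl <- cumsum(c(1, diff(s$pos) >= gap))
    for (k in unique(cl)) {
      m <- s[cl == k, , drop = FALSE]
      if (nrow(m) < min_members) next
      pmin_v <- min(m[[pcol]])
      row <- data.frame(chrom = ch, core_start = min(m$pos),
                        core_end = max(m$pos),
                        ext_start = max(1, min(m$pos) - pad),
                        ext_end = max(m$pos) + pad,
                        n_members = nrow(m), stringsAsFactors = FALSE)
      row$member_vids <- list(m$vid)
      row$top_vids <- list(m$vid[m[[pcol]] == pmin_v])
      out[[length(out) + 1L]] <- row
    }
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Classify a variant as cis or trans for a gene
#'
#' A variant is cis-regulatory for a gene when it lies on the gene's
#' chromosome within the gene span extended by `window` on each side
#' (boundary inclusive). The signed distance is 0 inside the gene body,
#' negative upstream of the TSS and positive downstream of the gene 3' end,
#' in transcription orientation.
#'
#' @param vid variant id(s).
#' @param chrom,pos variant coordinates (vectorized).
#' @param gene one-row data.frame (or list) with `gene_id`, `chrom`,
#'   `start`, `end`, `strand`.
#' @param window cis window in bp (default 1e6).
#' @return data.frame: `vid`, `gene_id`, `is_cis`, `signed_distance`.
#' @export
classify_cis <- function(vid, chrom, pos, gene, window = 1e6) {
  same <- chrom == gene$chrom
  inside <- same & pos >= gene$start & pos <= gene$end
  is_cis <- same & pos >= gene$start - window & pos <= gene$end + window
  if (gene$strand == "+") {
    d <- ifelse(pos < gene$start, pos - gene$start,
         ifelse(pos > gene$end, pos - gene$end, 0))
  } else {
    d <- ifelse(pos > gene$end, gene$end - pos,
         ifelse(pos < gene$start, gene$start - pos, 0))
  }
  d[!same] <- NA_real_
  data.frame(vid = vid, gene_id = gene$gene_id, is_cis = is_cis,
             signed_distance = d, stringsAsFactors = FALSE)
}

#' Cis labels for all significant associations
#'
#' @param sig data.frame with `vid`, `chrom`, `pos`, `gene_id`.
#' @param genes annotation data.frame from [read_gff_genes()].
#' @param window cis window in bp.
#' @return data.frame of [classify_cis()] rows, one per association.
#' @export
cis_labels <- function(sig, genes, window = 1e6) {
  rownames(genes) <- genes$gene_id
  missing_g <- setdiff(unique(sig$gene_id), genes$gene_id)
  if (length(missing_g)) {
    stop("unknown gene id(s): ", paste(missing_g, collapse = ", "))
  }
  out <- lapply(split(sig, sig$gene_id), function(s) {
    classify_cis(s$vid, s$chrom, s$pos, genes[s$gene_id[1], ], window)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Label regions as cis- or trans-eQTL regions
#'
#' A region is a cis-eQTL region iff it contains at least one member that is
#' a cis-regulatory variant of the region's gene.
#'
#' @param regions output of [cluster_regions()] (with a `gene_id` column).
#' @param labels output of [cis_labels()].
#' @return regions with an `is_cis` column added.
#' @export
label_regions_cis <- function(regions, labels) {
  cis_pairs <- paste(labels$vid[labels$is_cis], labels$gene_id[labels$is_cis])
  regions$is_cis <- vapply(seq_len(nrow(regions)), function(i) {
    any(paste(regions$member_vids[[i]], regions$gene_id[i]) %in% cis_pairs)
  }, logical(1))
  regions
}

#' Distances of region members to the region peak
#'
#' The peak is the position of the most significant member, or the
#' arithmetic mean of the tied most significant positions.
#'
#' @param pos member positions.
#' @param p member (adjusted) p-values.
#' @return list with `peak` (position) and `distances` (signed, pos - peak).
#' @export
peak_distances <- function(pos, p) {
  peak <- mean(pos[p == min(p)])
  list(peak = peak, distances = pos - peak)
}

#' Bin cis-regulatory variants by distance to TSS / 3'UTR
#'
#' Ten 100-kb bins upstream of the TSS, one ORF bucket for variants inside
#' the gene span, and ten 100-kb bins downstream of the gene 3' end, with
#' upstream/downstream defined in transcription orientation (the TSS is
#' `start` on the + strand and `end` on the - strand).
#'
#' @param labels cis labels (only rows with `is_cis` are used).
#' @param bin bin width in bp (default 1e5).
#' @param window cis window in bp (default 1e6); variants beyond it are
#'   rejected.
#' @return named integer vector of counts: `up_10` ... `up_1`, `ORF`,
#'   `down_1` ... `down_10`.
#' @export
tss_utr_bins <- function(labels, bin = 1e5, window = 1e6) {
  lab <- labels[labels$is_cis, , drop = FALSE]
  d <- lab$signed_distance
  if (any(abs(d) > window)) stop("variant beyond the cis window")
  nb <- ceiling(window / bin)
  lev <- c(paste0("up_", nb:1), "ORF", paste0("down_", 1:nb))
  b <- ifelse(d == 0, "ORF",
       ifelse(d < 0, paste0("up_", pmin(nb, ceiling(-d / bin))),
              paste0("down_", pmin(nb, ceiling(d / bin)))))
  tab <- table(factor(b, levels = lev))
  stats::setNames(as.integer(tab), names(tab))
}

#' Per-tissue eQTL summary table
#'
#' Emits, per tissue, the number of significant associations, cis-regulatory
#' variants (with percentage of the tissue total), eQTL regions and
#' cis-eQTL regions (with percentage), plus a Total row. Percentages are
#' `100 * part / whole` rounded to 1 decimal. Counts may be supplied
#' directly (e.g. from a published table) or computed from association,
#' label and region objects via [eqtl_counts()].
#'
#' @param counts data.frame with columns `tissue`, `n_sig`, `n_cis_var`,
#'   `n_regions`, `n_cis_regions`.
#' @return data.frame with percentage columns and a Total row.
#' @export
summarize_tissue <- function(counts) {
  tot <- data.frame(tissue = "Total", n_sig = sum(counts$n_sig),
                    n_cis_var = sum(counts$n_cis_var),
                    n_regions = sum(counts$n_regions),
                    n_cis_regions = sum(counts$n_cis_regions),
                    stringsAsFactors = FALSE)
  out <- rbind(counts[, names(tot)], tot)
  out$pct_cis_var <- round(100 * out$n_cis_var / out$n_sig, 1)
  out$pct_cis_regions <- round(100 * out$n_cis_regions / out$n_regions, 1)
  out
}

#' Raw counts feeding the per-tissue summary
#'
#' @param sig significant associations (rows are variant-gene tests).
#' @param labels cis labels matching `sig` row order ([cis_labels()]).
#' @param regions region table with `is_cis` ([label_regions_cis()]).
#' @param tissue tissue name.
#' @return one-row data.frame for [summarize_tissue()]. Cis-regulatory
#'   variants are counted as association rows whose variant is cis for its
#'   gene, matching the "significantly associated variants" column.
#' @export
eqtl_counts <- function(sig, labels, regions, tissue) {
  data.frame(tissue = tissue, n_sig = nrow(sig),
             n_cis_var = sum(labels$is_cis),
             n_regions = nrow(regions),
             n_cis_regions = sum(regions$is_cis),
             stringsAsFactors = FALSE)
}

#' Cluster regions for every gene of a tissue
#'
#' @param sig significant associations with `gene_id`, `vid`, `chrom`,
#'   `pos`, `p_adj`.
#' @inheritParams cluster_regions
#' @return region table with a `gene_id` column, one row per region.
#' @export
cluster_regions_by_gene <- function(sig, gap = 2e6, min_members = 2,
                                    pad = 1e6) {
  parts <- lapply(split(sig, sig$gene_id), cluster_regions, gap = gap,
                  min_members = min_members, pad = pad)
  keep <- vapply(parts, nrow, integer(1)) > 0L
  if (!any(keep)) {
    out <- cluster_regions(NULL)
    out$gene_id <- character(0)
    return(out)
  }
  parts <- parts[keep]
  out <- do.call(rbind, parts)
  out$gene_id <- rep(names(parts), vapply(parts, nrow, integer(1)))
  rownames(out) <- NULL
  out
}
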