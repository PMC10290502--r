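#' Find hotspot polymorphisms
#'
#' A hotspot is a variant significantly associated with the expression of at
#' least `min_genes` distinct genes within a tissue.
#'
#' @param sig significant associations for one tissue (`vid`, `gene_id`).
#' @param min_genes hotspot threshold (default 10).
#' @return data.frame per variant: `vid`, `n_assoc_genes`, `is_hotspot`.
#' @export
find_hotspots <- function(sig, min_genes = 10) {
  pairs <- unique(sig[, c("vid", "gene_id")])
  tab <- table(pairs$vid)
  data.frame(vid = names(tab), n_assoc_genes = as.integer(tab),
             is_hotspot = as.integer(tab) >= min_genes,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Find top-hotspot polymorphisms
#'
#' A top hotspot is a hotspot that is the most significantly associated
#' variant (smallest p-value, ties included) in at least `min_regions` eQTL
#' regions.
#'
#' @param reports output of [find_hotspots()].
#' @param regions region table carrying `top_vids` list-column.
#' @param min_regions threshold (default 10).
#' @return `reports` with `n_top_regions` and `is_top_hotspot` added.
#' @export
find_top_hotspots <- function(reports, regions, min_regions = 10) {
  top_all <- unlist(regions$top_vids)
  cnt <- table(top_all)
  reports$n_top_regions <- as.integer(cnt[reports$vid])
  reports$n_top_regions[is.na(reports$n_top_regions)] <- 0L
  reports$is_top_hotspot <- reports$is_hotspot &
    reports$n_top_regions >= min_regions
  reports
}

#' Classify top cis-regulatory hotspots
#'
#' For each top hotspot that is a cis-regulatory variant of some gene `g`:
#' class `top_of_cis_region` if it is among the top variants of `g`'s
#' cis-eQTL region, else `cis_not_top`. A top hotspot cis for no gene gets
#' class `none`. A variant cis to several genes yields one row per
#' (variant, gene) pair.
#'
#' @param reports output of [find_top_hotspots()].
#' @param regions region table with `gene_id`, `is_cis`, `member_vids`,
#'   `top_vids`.
#' @param labels cis labels ([cis_labels()]).
#' @return data.frame: `vid`, `cis_gene_id` (NA for class none),
#'   `cis_class`.
#' @export
classify_top_cis <- function(reports, regions, labels) {
  th <- reports[reports$is_top_hotspot, , drop = FALSE]
  if (nrow(th) == 0L) {
    return(data.frame(vid = character(), cis_gene_id = character(),
                      cis_class = character(), stringsAsFactors = FALSE))
  }
  cis <- unique(labels[labels$is_cis, c("vid", "gene_id")])
  out <- list()
  for (v in th$vid) {
    genes <- cis$gene_id[cis$vid == v]
    if (!length(genes)) {
      out[[length(out) + 1L]] <- data.frame(vid = v,
                                            cis_gene_id = NA_character_,
                                            cis_class = "none",
                                            stringsAsFactors = FALSE)
      next
    }
    for (g in genes) {
      rg <- regions[regions$gene_id == g & regions$is_cis, , drop = FALSE]
      member <- vapply(seq_len(nrow(rg)),
                       function(i) v %in% rg$member_vids[[i]], logical(1))
      top <- vapply(seq_len(nrow(rg)),
                    function(i) v %in% rg$top_vids[[i]], logical(1))
      cls <- if (any(member & top)) "top_of_cis_region" else "cis_not_top"
      out[[length(out) + 1L]] <- data.frame(vid = v, cis_gene_id = g,
                                            cis_class = cls,
                                            stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Cross-tissue sharing tallies
#'
#' Venn-partition counts of item sets (e.g. variant-gene association pairs,
#' cis pairs, expressed genes) across tissues: one count per non-empty
#' tissue subset, exclusive cells summing to the union size.
#'
#' @param sets named list of character vectors (one per tissue).
#' @return list with `exclusive` (named counts per exclusive Venn cell,
#'   names like "duodenum&liver"), `intersections` (counts per subset,
#'   non-exclusive), `union_size`.
#' @export
cross_tissue_shared <- function(sets) {
  if (length(sets) < 2L) stop("need at least 2 tissues")
  sets <- lapply(sets, unique)
  items <- unique(unlist(sets))
  member <- vapply(sets, function(s) items %in% s,
                   logical(length(items)))
  if (length(items) == 1L) member <- matrix(member, nrow = 1L,
                                            dimnames = list(NULL, names(sets)))
  key <- apply(member, 1L, function(r) paste(names(sets)[r], collapse = "&"))
  exclusive <- table(key)
  nm <- names(sets)
  subsets <- unlist(lapply(seq_along(nm), function(k) {
    utils::combn(nm, k, paste, collapse = "&", simplify = FALSE)
  }))
  inter <- vapply(subsets, function(s) {
    idx <- strsplit(s, "&", fixed = TRUE)[[1]]
    sum(rowSums(member[, idx, drop = FALSE]) == length(idx))
  }, numeric(1))
  names(inter) <- subsets
  list(exclusive = exclusive, intersections = inter,
       union_size = length(items))
}
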