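.BASES <- c("A", "C", "G", "T")

.revcomp <- function(s) {
  chartr("ACGTacgtN", "TGCAtgcaN",
         vapply(s, function(x) paste(rev(strsplit(x, "")[[1]]),
                                     collapse = ""), character(1)))
}

#' Extract reference/alternative context sequences around SNPs
#'
#' For each single-nucleotide variant, extracts the 21-base sequence
#' spanning `flank` bases either side of the SNP (the mutation sits at
#' position 11 for the default flank of 10) from the reference, and builds
#' the matching alternative sequence by substituting the center base.
#' Indels are rejected; positions closer than `flank` to a chromosome edge
#' are padded with N.
#'
#' @param vs [variant_set] containing SNPs only.
#' @param fasta reference: a named `Biostrings::DNAStringSet`, a named
#'   character vector of chromosome sequences, or a FASTA file path.
#' @param flank flank width in bp (default 10).
#' @return data.frame: `vid`, `ref_seq`, `alt_seq`.
#' @export
extract_snp_context <- function(vs, fasta, flank = 10) {
  if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta)) {
    fasta <- Biostrings::readDNAStringSet(fasta)
  }
  seqs <- if (inherits(fasta, "DNAStringSet")) {
    stats::setNames(as.character(fasta), names(fasta))
  } else {
    fasta
  }
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  info <- vs$info
  if (any(nchar(info$ref) != 1L | nchar(info$alt) != 1L)) {
    stop("indel variants rejected: context extraction is SNP-only")
  }
  ref_seq <- alt_seq <- character(nrow(info))
  for (i in seq_len(nrow(info))) {
    chrom <- seqs[[info$chrom[i]]]
    if (is.null(chrom)) stop("chromosome not in FASTA: ", info$chrom[i])
    L <- nchar(chrom)
    pos <- info$pos[i]
    lo <- pos - flank; hi <- pos + flank
    s <- substr(chrom, max(1L, lo), min(L, hi))
    s <- paste0(strrep("N", max(0L, 1L - lo)), s,
                strrep("N", max(0L, hi - L)))
    s <- toupper(s)
    center <- flank + 1L
    if (substr(s, center, center) != toupper(info$ref[i])) {
      stop("reference mismatch for ", info$vid[i], ": FASTA has ",
           substr(s, center, center), ", VCF says ", info$ref[i])
    }
    ref_seq[i] <- s
    substr(s, center, center) <- toupper(info$alt[i])
    alt_seq[i] <- s
  }
  data.frame(vid = info$vid, ref_seq = ref_seq, alt_seq = alt_seq,
             stringsAsFactors = FALSE)
}

#' Build a PWM from an IUPAC consensus string
#'
#' At each position, the bases allowed by the IUPAC code share
#' `1 - soft * k_off` uniformly and each disallowed base receives `soft`
#' (`k_off` = number of disallowed bases); "N" takes the background
#' distribution.
#'
#' @param consensus IUPAC string, e.g. `"GATCCNGYGTTGCYG"`.
#' @param soft probability mass per off-consensus base (default 0.05).
#' @param background named base distribution (default uniform).
#' @return object of class `pwm`: list(width, probs (4 x width matrix with
#'   rows A/C/G/T), background, consensus).
#' @export
pwm_from_iupac <- function(consensus, soft = 0.05,
                           background = c(A = .25, C = .25, G = .25,
                                          T = .25)) {
  iupac <- Biostrings::IUPAC_CODE_MAP
  chars <- strsplit(toupper(consensus), "")[[1]]
  probs <- vapply(chars, function(ch) {
    if (ch == "N") return(unname(background[.BASES]))
    if (!ch %in% names(iupac)) stop("invalid IUPAC character: ", ch)
    allowed <- strsplit(iupac[[ch]], "")[[1]]
    k_off <- 4L - length(allowed)
    p <- rep(soft, 4L)
    p[.BASES %in% allowed] <- (1 - soft * k_off) / length(allowed)
    p
  }, numeric(4))
  rownames(probs) <- .BASES
  structure(list(width = length(chars), probs = probs,
                 background = background[.BASES], consensus = consensus),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("pwm: width", x$width,
      if (!is.null(x$consensus)) paste0("(", x$consensus, ")"), "\n")
  invisible(x)
}

#' Read PWMs from a MEME minimal motif file
#'
#' Parses the `MOTIF` names and `letter-probability matrix` blocks (and the
#' background line when present); header fields beyond those are ignored.
#'
#' @param path MEME minimal format file.
#' @return named list of `pwm` objects.
#' @export
read_meme_pwm <- function(path) {
  lines <- readLines(path)
  bg <- c(A = .25, C = .25, G = .25, T = .25)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at) && bg_at[1] < length(lines)) {
    tok <- strsplit(trimws(lines[bg_at[1] + 1L]), "\\s+")[[1]]
    vals <- as.numeric(tok[c(FALSE, TRUE)])
    names(vals) <- tok[c(TRUE, FALSE)]
    if (!anyNA(vals)) bg <- vals[.BASES]
  }
  starts <- grep("^MOTIF", lines)
  out <- list()
  for (s in starts) {
    name <- strsplit(trimws(lines[s]), "\\s+")[[1]][2]
    m_at <- grep("letter-probability matrix", lines)
    m_at <- m_at[m_at > s][1]
    if (is.na(m_at)) stop("no letter-probability matrix for motif ", name)
    rows <- list()
    i <- m_at + 1L
    while (i <= length(lines) &&
           grepl("^\\s*[0-9.eE+-]+(\\s+[0-9.eE+-]+){3}\\s*$", lines[i])) {
      rows[[length(rows) + 1L]] <-
        as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]])
      i <- i + 1L
    }
    probs <- t(do.call(rbind, rows))
    rownames(probs) <- .BASES
    out[[name]] <- structure(list(width = ncol(probs), probs = probs,
                                  background = bg, consensus = NULL),
                             class = "pwm")
  }
  out
}

## discretized log-odds integer scores (4 x width) and the exact null score
## distribution under the iid background, by dynamic programming
.pwm_int_scores <- function(pwm, granularity, floor_prob) {
  pr <- pwm$probs
  if (floor_prob > 0) pr <- pmax(pr, floor_prob)
  lo <- log2(pr / pwm$background)
  si <- round(lo / granularity)
  si[!is.finite(si)] <- -1e7  # zero probability with floor disabled
  storage.mode(si) <- "double"
  si
}

.pwm_score_dist <- function(si, background) {
  dist <- 1; offset <- 0
  for (j in seq_len(ncol(si))) {
    s <- si[, j]
    mn <- min(s); mx <- max(s)
    new <- numeric(length(dist) + (mx - mn))
    for (b in 1:4) {
      sh <- s[b] - mn
      idx <- seq_along(dist) + sh
      new[idx] <- new[idx] + background[b] * dist
    }
    dist <- new
    offset <- offset + mn
  }
  ## tail[k] = P(score_int >= offset + k - 1)
  list(offset = offset, tail = rev(cumsum(rev(dist))))
}

.pwm_window_pvalue <- function(score_int, dp) {
  k <- score_int - dp$offset + 1
  ifelse(k <= 0, 1, ifelse(k > length(dp$tail), 0, dp$tail[pmax(1, k)]))
}

#' Scan sequences with a PWM, with exact p-values
#'
#' Scores every window of every sequence (both strands by default) with the
#' log2 likelihood ratio against the background and assigns each window an
#' exact p-value — the probability, under the iid background, of a score at
#' least as large — computed by dynamic programming over the discretized
#' score distribution. N bases contribute a score of 0.
#'
#' @param seqs named character vector of sequences (or `DNAStringSet`).
#' @param pwm a [pwm_from_iupac()]/[read_meme_pwm()] object.
#' @param both_strands scan the reverse strand too (default TRUE).
#' @param granularity score discretization bin in bits (default 1/1000).
#' @param floor_prob floor applied to zero/near-zero PWM probabilities
#'   before log-odds (default 1e-4; set 0 to allow -Inf scores, handled as
#'   the minimal bin).
#' @return data.frame of hits: `seq_id`, `offset` (1-based window start on
#'   the forward sequence), `strand`, `score` (bits, discretized),
#'   `p_value`.
#' @export
scan_pwm <- function(seqs, pwm, both_strands = TRUE, granularity = 1 / 1000,
                     floor_prob = 1e-4) {
  if (inherits(seqs, "DNAStringSet")) {
    seqs <- stats::setNames(as.character(seqs), names(seqs))
  }
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  si <- .pwm_int_scores(pwm, granularity, floor_prob)
  dp <- .pwm_score_dist(si, pwm$background)
  w <- pwm$width
  strands <- if (both_strands) c("+", "-") else "+"
  out <- list()
  for (id in names(seqs)) {
    s <- toupper(seqs[[id]])
    L <- nchar(s)
    if (L < w) next
    base_idx <- match(strsplit(s, "")[[1]], .BASES)  # NA for N
    for (st in strands) {
      idx <- if (st == "+") base_idx else rev(5L - base_idx)
      scores <- vapply(seq_len(L - w + 1L), function(o) {
        b <- idx[o:(o + w - 1L)]
        sum(si[cbind(b, seq_len(w))], na.rm = TRUE)  # N -> 0
      }, numeric(1))
      offs <- seq_len(L - w + 1L)
      if (st == "-") offs <- rev(offs)  # forward-strand window starts
      out[[length(out) + 1L]] <-
        data.frame(seq_id = id, offset = offs, strand = st,
                   score = scores * granularity,
                   p_value = .pwm_window_pvalue(scores, dp),
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(seq_id = character(), offset = integer(),
                      strand = character(), score = numeric(),
                      p_value = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Estimate a 0-order background from sequences
#'
#' Base frequencies over A/C/G/T (N ignored), usable as the `background`
#' of [pwm_from_iupac()] instead of the uniform default.
#'
#' @param seqs character vector of sequences (or `DNAStringSet`).
#' @return named numeric vector over A, C, G, T summing to 1.
#' @export
estimate_background <- function(seqs) {
  if (inherits(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  chars <- strsplit(toupper(paste(seqs, collapse = "")), "")[[1]]
  tab <- table(factor(chars, levels = .BASES))
  p <- as.numeric(tab) / sum(tab)
  stats::setNames(p, .BASES)
}

#' Benjamini-Hochberg q-values over scanned windows
#'
#' @param hits data.frame from [scan_pwm()].
#' @param q_max significance cutoff on the q-value (default 0.1).
#' @return `hits` with `q_value` and `is_significant` columns.
#' @export
bh_qvalues <- function(hits, q_max = 0.1) {
  if (nrow(hits) == 0L) {
    hits$q_value <- numeric(0); hits$is_significant <- logical(0)
    return(hits)
  }
  hits$q_value <- stats::p.adjust(hits$p_value, method = "BH")
  hits$is_significant <- hits$q_value <= q_max
  hits
}
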