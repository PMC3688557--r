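## PWM motif scanning and island enrichment.
##
## Motifs are position probability matrices scored as log2 odds against a
## background base composition; a window is a hit when its score reaches a
## per-motif threshold (default 80% of the maximal attainable score). Island
## enrichment contrasts presence/absence of hits between a target island set
## and the opposite day's islands as background with an exact hypergeometric
## test, and the signed dual-mark statistic combines the strongest
## acetylation and methylation associations per motif.

BASES <- c("A", "C", "G", "T")

#' Build a PWM from a count (or frequency) matrix
#'
#' @param counts 4 x L numeric matrix, rows in A, C, G, T order
#' @param name motif name
#' @param pseudocount added to every cell before column normalization
#' @param bkg background base frequencies (A, C, G, T)
#' @param threshold_frac hit threshold as a fraction of the maximal log-odds
#'   score
#' @return an object of class \code{pwm_motif}
#' @export
pwm_from_counts <- function(counts, name, pseudocount = 1,
                            bkg = rep(0.25, 4), threshold_frac = 0.8) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("PWM '", name, "': count matrix must have 4 rows (A,C,G,T)")
  if (ncol(counts) < 4L) stop("PWM '", name, "': matrix length must be >= 4")
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("PWM '", name, "': malformed count matrix")
  }
  rownames(counts) <- BASES
  prob <- sweep(counts + pseudocount, 2L, colSums(counts + pseudocount), "/")
  lo <- log2(prob / bkg)
  max_score <- sum(apply(lo, 2L, max))
  structure(list(
    name = name,
    counts = counts,
    prob = prob,
    log_odds = lo,
    pseudocount = pseudocount,
    bkg = setNames(bkg, BASES),
    threshold = threshold_frac * max_score,
    max_score = max_score
  ), class = "pwm_motif")
}

#' @export
print.pwm_motif <- function(x, ...) {
  cat(sprintf("pwm_motif '%s': length %d, consensus %s, threshold %.2f bits (max %.2f)\n",
              x$name, ncol(x$prob), pwm_consensus(x), x$threshold, x$max_score))
  invisible(x)
}

#' Consensus sequence of a PWM (highest-probability base per column)
#' @param pwm a \code{pwm_motif}
#' @return character string
#' @export
pwm_consensus <- function(pwm) {
  paste(BASES[apply(pwm$prob, 2L, which.max)], collapse = "")
}

#' Load PWMs from JASPAR-style or MEME minimal text
#'
#' JASPAR format: a \code{>name} header followed by four rows of counts
#' (optionally prefixed with the base letter and bracketed). MEME minimal
#' format is recognized by its \code{MEME version} header; its
#' letter-probability rows are used as frequencies.
#'
#' @param path motif file
#' @inheritParams pwm_from_counts
#' @return named list of \code{pwm_motif}
#' @export
load_pwms <- function(path, pseudocount = 1, bkg = rep(0.25, 4),
                      threshold_frac = 0.8) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (any(grepl("^MEME version", lines))) {
    return(parse_meme_minimal(lines, pseudocount, bkg, threshold_frac))
  }
  headers <- grep("^>", lines)
  if (!length(headers)) stop("unrecognized motif file format: ", path)
  bounds <- c(headers, length(lines) + 1L)
  pwms <- lapply(seq_along(headers), function(i) {
    name <- sub("^>\\s*", "", lines[headers[i]])
    name <- strsplit(name, "\\s+")[[1L]][1L]
    block <- lines[(headers[i] + 1L):(bounds[i + 1L] - 1L)]
    if (length(block) != 4L) {
      stop("PWM '", name, "': expected 4 matrix rows, got ", length(block))
    }
    rows <- lapply(block, function(ln) {
      nums <- regmatches(ln, gregexpr("-?[0-9]+\\.?[0-9]*", ln))[[1L]]
      as.numeric(nums)
    })
    if (length(unique(lengths(rows))) != 1L) {
      stop("PWM '", name, "': ragged count matrix")
    }
    mat <- do.call(rbind, rows)
    ## honor explicit base labels if present, else assume ACGT order
    labels <- toupper(substr(trimws(block), 1L, 1L))
    if (all(sort(labels) == BASES)) mat <- mat[match(BASES, labels), , drop = FALSE]
    pwm_from_counts(mat, name, pseudocount, bkg, threshold_frac)
  })
  setNames(pwms, vapply(pwms, `[[`, character(1), "name"))
}

parse_meme_minimal <- function(lines, pseudocount, bkg, threshold_frac) {
  starts <- grep("^MOTIF", lines)
  if (!length(starts)) stop("MEME file contains no MOTIF blocks")
  pwms <- lapply(starts, function(s) {
    name <- strsplit(trimws(lines[s]), "\\s+")[[1L]][2L]
    hdr <- s + which(grepl("^letter-probability matrix", lines[(s + 1L):length(lines)]))[1L]
    if (is.na(hdr)) stop("PWM '", name, "': missing letter-probability matrix")
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
    rows <- lines[(hdr + 1L):(hdr + w)]
    mat <- t(vapply(rows, function(ln) {
      as.numeric(strsplit(trimws(ln), "\\s+")[[1L]])
    }, numeric(4)))
    pwm_from_counts(t(mat), name, pseudocount, bkg, threshold_frac)
  })
  setNames(pwms, vapply(pwms, `[[`, character(1), "name"))
}

#' Write PWMs in JASPAR count format
#'
#' Writes the stored raw matrices, so a write/read cycle with the same
#' pseudocount reproduces the motifs exactly.
#'
#' @param pwms list of \code{pwm_motif}
#' @param path output path
#' @export
write_pwms <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(paste0(">", p$name), con)
    for (i in 1:4) {
      writeLines(sprintf("%s [ %s ]", BASES[i],
                         paste(format(p$counts[i, ], trim = TRUE, digits = 15),
                               collapse = " ")), con)
    }
  }
  invisible(path)
}

## encode sequences as integer base indices, concatenated with NA separators
## so windows can never span two sequences; returns the index vector plus the
## 0-based offset of each sequence within it
encode_sequences <- function(seqs) {
  if (methods::is(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  splits <- strsplit(seqs, "", fixed = TRUE)
  code <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  enc <- lapply(splits, function(ch) {
    v <- unname(code[ch])
    c(v, NA_integer_)
  })
  idx <- unlist(enc, use.names = FALSE)
  offsets <- cumsum(c(0L, lens + 1L))[seq_along(seqs)]
  list(idx = idx, offsets = offsets, lens = lens, n = length(seqs))
}

## per-window log-odds scores along the concatenated index vector, for one
## score matrix; windows containing N (or separators) score NA
window_scores <- function(idx, lo) {
  L <- ncol(lo)
  total <- length(idx)
  if (total < L) return(numeric(0))
  nwin <- total - L + 1L
  s <- numeric(nwin)
  for (j in seq_len(L)) {
    s <- s + lo[, j][idx[j:(nwin + j - 1L)]]
  }
  s
}

rc_log_odds <- function(lo) lo[4:1, ncol(lo):1, drop = FALSE]

#' Scan sequences with a PWM on both strands
#'
#' @param pwm a \code{pwm_motif}
#' @param seqs character vector or \code{DNAStringSet} over A,C,G,T,N;
#'   windows containing N are skipped
#' @param threshold hit threshold in bits (default: the motif's own)
#' @return data.frame with \code{seq} (index), \code{offset} (0-based on the
#'   forward strand), \code{strand}, \code{score}
#' @export
scan_sequences <- function(pwm, seqs, threshold = pwm$threshold) {
  enc <- encode_sequences(seqs)
  L <- ncol(pwm$log_odds)
  hits_one <- function(lo, strand) {
    s <- window_scores(enc$idx, lo)
    hit <- which(!is.na(s) & s >= threshold)
    if (!length(hit)) {
      return(data.frame(seq = integer(0), offset = integer(0),
                        strand = character(0), score = numeric(0)))
    }
    pos0 <- hit - 1L
    seq_i <- findInterval(pos0, enc$offsets)
    data.frame(seq = seq_i, offset = pos0 - enc$offsets[seq_i],
               strand = strand, score = s[hit], stringsAsFactors = FALSE)
  }
  out <- rbind(hits_one(pwm$log_odds, "+"),
               hits_one(rc_log_odds(pwm$log_odds), "-"))
  out <- out[out$offset + L <= enc$lens[out$seq], , drop = FALSE]
  out <- out[order(out$seq, out$offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## logical matrix: sequences x motifs, TRUE when the sequence carries >= 1 hit
pwm_hit_matrix <- function(pwms, seqs) {
  enc <- encode_sequences(seqs)
  res <- vapply(pwms, function(p) {
    hit <- logical(enc$n)
    for (lo in list(p$log_odds, rc_log_odds(p$log_odds))) {
      s <- window_scores(enc$idx, lo)
      pos <- which(!is.na(s) & s >= p$threshold) - 1L
      if (length(pos)) hit[unique(findInterval(pos, enc$offsets))] <- TRUE
    }
    hit
  }, logical(enc$n))
  if (enc$n == 1L) res <- matrix(res, nrow = 1L, dimnames = list(NULL, names(pwms)))
  res
}

## fixed-width sequence around each island midpoint, clamped at chrom bounds
island_sequences <- function(islands, genome_seq, flank = 500L) {
  if (is.character(genome_seq)) {
    if (length(genome_seq) == 1L && is.null(names(genome_seq)) &&
        file.exists(genome_seq)) {
      genome_seq <- Biostrings::readDNAStringSet(genome_seq)
      names(genome_seq) <- sub("\\s.*$", "", names(genome_seq))
    } else {
      genome_seq <- Biostrings::DNAStringSet(genome_seq)
    }
  }
  lens <- setNames(Biostrings::width(genome_seq), names(genome_seq))
  chrom <- as.character(GenomicRanges::seqnames(islands))
  if (!all(chrom %in% names(lens))) stop("island chromosome missing from genome sequence")
  s1 <- GenomicRanges::start(islands); e1 <- GenomicRanges::end(islands)
  if (any(s1 < 1L | e1 > lens[chrom])) stop("island outside genome bounds")
  mid0 <- (s1 - 1L) + (e1 - s1 + 1L) %/% 2L
  from <- pmax(mid0 - flank + 1L, 1L)
  to <- pmin(mid0 + flank, lens[chrom])
  as.character(Biostrings::subseq(genome_seq[chrom], start = from, end = to))
}

#' Per-motif enrichment of target islands against a background island set
#'
#' Counts, per motif, the islands containing at least one hit in the target
#' and background sets (each island truncated to a fixed flank around its
#' midpoint to remove length confounding) and computes the hypergeometric
#' upper-tail probability of the target hit count given the pooled totals.
#' p-values are BH-adjusted across motifs.
#'
#' @param target,background island \code{GRanges} (e.g. one day's
#'   mark-specific islands vs the opposite day's)
#' @param genome_seq genome as \code{DNAStringSet}, named character vector, or
#'   FASTA path
#' @param pwms list of \code{pwm_motif}
#' @param flank half-width in bp of the scanned region around each island
#'   midpoint
#' @param target_label optional label for the enriched condition
#' @return data.frame, one row per motif
#' @export
motif_enrichment <- function(target, background, genome_seq, pwms,
                             flank = 500L, target_label = NA_character_) {
  if (!length(target) || !length(background)) stop("island sets must be non-empty")
  seq_t <- island_sequences(target, genome_seq, flank)
  seq_b <- island_sequences(background, genome_seq, flank)
  hits_t <- pwm_hit_matrix(pwms, seq_t)
  hits_b <- pwm_hit_matrix(pwms, seq_b)
  n_t <- length(seq_t); n_b <- length(seq_b)
  k_t <- colSums(hits_t); k_b <- colSums(hits_b)
  p <- phyper(k_t - 1, k_t + k_b, n_t + n_b - k_t - k_b, n_t, lower.tail = FALSE)
  out <- data.frame(
    motif = names(pwms),
    n_target = n_t, k_target = unname(k_t),
    n_background = n_b, k_background = unname(k_b),
    p = unname(p),
    p_adj = unname(bh_adjust(p)),
    enriched_label = target_label,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Signed dual-mark motif scores
#'
#' For each motif, the stronger of the two acetylation enrichments (D0- vs
#' D8-specific islands) sets \code{x = sign * -log10(min p)} with negative
#' sign for D0 and positive for D8; \code{y} does the same for the
#' methylation mark. A motif with equal p at both days scores 0, so swapping
#' the D0 and D8 inputs flips every sign exactly. Motifs absent from any of
#' the four tables are excluded and counted.
#'
#' @param ac_d0,ac_d8,me3_d0,me3_d8 enrichment tables from
#'   \code{\link{motif_enrichment}} for the four day-specific island sets
#' @return list with \code{scores} (motif, x, y), \code{pearson},
#'   \code{spearman}, and \code{n_excluded}
#' @export
dual_mark_scores <- function(ac_d0, ac_d8, me3_d0, me3_d8) {
  tabs <- list(ac_d0, ac_d8, me3_d0, me3_d8)
  common <- Reduce(intersect, lapply(tabs, `[[`, "motif"))
  n_excluded <- length(unique(unlist(lapply(tabs, `[[`, "motif")))) - length(common)
  signed <- function(t0, t8) {
    p0 <- t0$p[match(common, t0$motif)]
    p8 <- t8$p[match(common, t8$motif)]
    sgn <- sign(p0 - p8)               # +1 when D8 stronger (smaller p)
    mag <- -log10(pmin(p0, p8))
    ifelse(sgn == 0, 0, sgn * mag)
  }
  x <- signed(ac_d0, ac_d8)
  y <- signed(me3_d0, me3_d8)
  scores <- data.frame(motif = common, x = x, y = y, stringsAsFactors = FALSE)
  ok <- length(x) >= 2L && sd(x) > 0 && sd(y) > 0
  pearson <- if (ok) cor(x, y) else NA_real_
  spearman <- if (ok) cor(x, y, method = "spearman") else NA_real_
  list(scores = scores, pearson = pearson, spearman = spearman,
       n_excluded = n_excluded)
}
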