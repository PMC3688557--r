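suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

## ---- small fixture builders -------------------------------------------

toy_meta <- function(days, donors = 1L, tech = logical(length(days))) {
  data.frame(
    sample_id = sprintf("s%02d", seq_along(days)),
    day = days,
    donor = rep_len(sprintf("donor%d", seq_len(donors)), length(days)),
    technical_replicate = tech,
    stringsAsFactors = FALSE
  )
}

toy_em <- function(values, days, probe_ids = sprintf("p%03d", seq_len(nrow(values)))) {
  expression_matrix(as.matrix(values), toy_meta(days), probe_ids)
}

toy_granges <- function(start0, end0, chrom = "chr1",
                        genome = c(chr1 = 1e6, chr2 = 1e6)) {
  GRanges(seqnames = rep_len(chrom, length(start0)),
          ranges = IRanges(start = start0 + 1L, end = end0),
          seqlengths = genome)
}

## ---- independent oracles ----------------------------------------------

## pooled-variance two-sample t
oracle_pooled_t <- function(x, y) {
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) /
    (length(x) + length(y) - 2)
  (mean(y) - mean(x)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
}

## hand step-up BH
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  pmin(adj, 1)[order(o)]
}

## brute-force island enumeration: all maximal intervals with eligible
## endpoints whose internal eligible-window gaps respect the gap rule
oracle_islands <- function(counts, lambda, p0, gap_windows, w = 600L,
                           chrom_len = length(counts) * w) {
  elig <- which(ppois(counts - 1, lambda, lower.tail = FALSE) < p0)
  empty <- data.frame(start = integer(0), end = integer(0),
                      score = numeric(0), count = integer(0))
  if (!length(elig)) return(empty)
  valid <- list()
  for (a in seq_along(elig)) {
    for (b in a:length(elig)) {
      memb <- elig[a:b]
      if (all(diff(memb) <= gap_windows + 1L)) {
        valid[[length(valid) + 1L]] <- c(i = memb[1L], j = memb[length(memb)])
      }
    }
  }
  vm <- do.call(rbind, valid)
  keep <- vapply(seq_len(nrow(vm)), function(r) {
    !any(vm[, "i"] <= vm[r, "i"] & vm[, "j"] >= vm[r, "j"] &
           (vm[, "i"] != vm[r, "i"] | vm[, "j"] != vm[r, "j"]))
  }, logical(1))
  vm <- vm[keep, , drop = FALSE]
  vm <- vm[order(vm[, "i"]), , drop = FALSE]
  data.frame(
    start = (vm[, "i"] - 1L) * w,
    end = pmin(vm[, "j"] * w, chrom_len),
    score = vapply(seq_len(nrow(vm)), function(r) {
      memb <- elig[elig >= vm[r, "i"] & elig <= vm[r, "j"]]
      sum(-dpois(counts[memb], lambda, log = TRUE))
    }, numeric(1)),
    count = vapply(seq_len(nrow(vm)), function(r) {
      sum(counts[vm[r, "i"]:vm[r, "j"]])
    }, numeric(1))
  )
}

## exhaustive hypergeometric upper tail: enumerate every possible draw of the
## second set and count overlaps at least k
oracle_hyper_upper <- function(N, n_a, n_b, k) {
  sets <- utils::combn(N, n_b)
  a <- seq_len(n_a)  # wlog the first n_a elements
  mean(apply(sets, 2L, function(s) sum(s %in% a) >= k))
}

revcomp_str <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(s, "")[[1L]]]), collapse = "")
}

## brute-force PWM scan: score every window on both strands explicitly
oracle_scan <- function(pwm, s) {
  L <- ncol(pwm$prob)
  n <- nchar(s)
  score1 <- function(win) {
    ch <- strsplit(win, "")[[1L]]
    if (any(!ch %in% c("A", "C", "G", "T"))) return(NA_real_)
    sum(vapply(seq_len(L), function(i) {
      log2(pwm$prob[ch[i], i] / pwm$bkg[ch[i]])
    }, numeric(1)))
  }
  if (n < L) {
    return(data.frame(offset = integer(0), strand = character(0),
                      score = numeric(0)))
  }
  rows <- lapply(0:(n - L), function(o) {
    win <- substr(s, o + 1L, o + L)
    rbind(data.frame(offset = o, strand = "+", score = score1(win)),
          data.frame(offset = o, strand = "-", score = score1(revcomp_str(win))))
  })
  do.call(rbind, rows)
}

## all-pairs nearest-TSS with smallest-gene-id tie-break
oracle_nearest <- function(mid0, chrom, tss) {
  vapply(seq_along(mid0), function(i) {
    t <- tss[tss$chrom == chrom[i], , drop = FALSE]
    if (!nrow(t)) return(NA_character_)
    d <- abs(t$pos - mid0[i])
    cand <- t$gene_id[d == min(d)]
    sort(cand)[1L]
  }, character(1))
}
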