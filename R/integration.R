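## Nearest-TSS annotation, 16-state chromatin-change classification, and the
## chromatin-state x expression-direction summary.
##
## Each gene gets four binary flags - a D0-specific and a D8-specific island
## of each mark annotated to it - giving 2^4 = 16 possible chromatin-change
## states. Shared (non-day-specific) islands never set a flag.

#' Read a TSS table from BED6
#'
#' The name column carries the gene id; the canonical TSS is the interval
#' start for + strand genes and the interval end for - strand genes.
#'
#' @param path BED6 file
#' @return data.frame with gene_id, chrom, pos (0-based bp), strand
#' @export
read_tss_bed <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 6L) stop("TSS table must be BED6 (strand required)")
  strand <- df[[6L]]
  pos <- ifelse(strand == "-", df[[3L]] - 1L, df[[2L]])
  tss <- data.frame(gene_id = as.character(df[[4L]]),
                    chrom = as.character(df[[1L]]),
                    pos = as.integer(pos),
                    strand = strand, stringsAsFactors = FALSE)
  if (anyDuplicated(tss$gene_id)) stop("TSS table must have one canonical TSS per gene")
  tss
}

#' Annotate islands to their nearest TSS
#'
#' Distance is measured from the island midpoint to the TSS; the nearest gene
#' wins, with exact ties broken by the lexicographically smaller gene id. The
#' signed distance is negative when the island lies upstream of the TSS
#' relative to gene strand. Islands farther than \code{max_distance} (when
#' set) or on chromosomes without any TSS are left unassigned.
#'
#' @param islands island \code{GRanges}
#' @param tss data.frame as from \code{\link{read_tss_bed}}
#' @param max_distance optional cap in bp
#' @return data.frame with chrom, start, end (0-based half-open), gene_id,
#'   distance
#' @export
annotate_nearest_tss <- function(islands, tss, max_distance = NULL) {
  if (is.null(tss) || nrow(tss) == 0L) stop("empty TSS table")
  chrom <- as.character(GenomicRanges::seqnames(islands))
  mid0 <- (GenomicRanges::start(islands) - 1L) +
    GenomicRanges::width(islands) %/% 2L
  gene <- rep(NA_character_, length(islands))
  dist_signed <- rep(NA_integer_, length(islands))
  for (chr in unique(chrom)) {
    t <- tss[tss$chrom == chr, , drop = FALSE]
    if (!nrow(t)) next
    o <- order(t$pos, t$gene_id, method = "radix")
    pos_s <- t$pos[o]; gid_s <- t$gene_id[o]; str_s <- t$strand[o]
    sel <- which(chrom == chr)
    for (ii in sel) {
      m <- mid0[ii]
      i <- findInterval(m, pos_s)
      d_left <- if (i >= 1L) m - pos_s[i] else Inf
      d_right <- if (i < length(pos_s)) pos_s[i + 1L] - m else Inf
      dmin <- min(d_left, d_right)
      if (!is.null(max_distance) && dmin > max_distance) next
      ## collect every TSS at the minimal distance (equal positions are
      ## contiguous in the sorted order)
      cand <- integer(0)
      if (d_left == dmin) {
        j <- i
        while (j >= 1L && pos_s[j] == m - dmin) { cand <- c(cand, j); j <- j - 1L }
      }
      if (d_right == dmin && dmin > 0) {
        j <- i + 1L
        while (j <= length(pos_s) && pos_s[j] == m + dmin) { cand <- c(cand, j); j <- j + 1L }
      }
      best <- cand[order(gid_s[cand])][1L]
      gene[ii] <- gid_s[best]
      dist_signed[ii] <- if (str_s[best] == "-") as.integer(pos_s[best] - m)
                         else as.integer(m - pos_s[best])
    }
  }
  out <- granges_to_bed(islands)
  out$gene_id <- gene
  out$distance <- dist_signed
  out
}

state_flag_names <- c("ac_d0", "ac_d8", "me3_d0", "me3_d8")

#' Assign each gene a 16-state chromatin-change classification
#'
#' A flag is set when at least one day-specific island of that mark/day is
#' annotated to the gene; shared islands set no flag. The state index encodes
#' the flags as \code{ac_d0 + 2*ac_d8 + 4*me3_d0 + 8*me3_d8}, so state 0 means
#' no chromatin change near the gene and state 6 (ac_d8 + me3_d0) is the
#' fully "activating" gain-acetylation / loss-methylation combination.
#'
#' @param ann_ac,ann_me3 per-mark lists with elements \code{d0_specific} and
#'   \code{d8_specific}, each an annotation data.frame from
#'   \code{\link{annotate_nearest_tss}} (or a character vector of gene ids)
#' @param universe character vector of gene ids (the expression platform)
#' @return data.frame with one row per universe gene: four logical flags and
#'   the \code{state} index; annotated genes absent from the universe are
#'   dropped and counted in attribute \code{n_outside_universe}
#' @export
assign_states <- function(ann_ac, ann_me3, universe) {
  pull_genes <- function(x) {
    g <- if (is.data.frame(x)) x$gene_id else x
    unique(g[!is.na(g)])
  }
  flags <- list(
    ac_d0 = pull_genes(ann_ac$d0_specific),
    ac_d8 = pull_genes(ann_ac$d8_specific),
    me3_d0 = pull_genes(ann_me3$d0_specific),
    me3_d8 = pull_genes(ann_me3$d8_specific)
  )
  outside <- length(unique(setdiff(unlist(flags), universe)))
  out <- data.frame(gene_id = universe, stringsAsFactors = FALSE)
  for (f in state_flag_names) out[[f]] <- out$gene_id %in% flags[[f]]
  out$state <- out$ac_d0 + 2L * out$ac_d8 + 4L * out$me3_d0 + 8L * out$me3_d8
  attr(out, "n_outside_universe") <- outside
  out
}

#' Summarize expression direction within each chromatin state
#'
#' @param states data.frame from \code{\link{assign_states}}
#' @param diffexpr gene-level differential table with \code{gene_id} and
#'   \code{direction}; genes missing from it count as not significant
#' @return list with \code{per_state} (one row per state 0..15: n_genes,
#'   n_up, n_down, n_ns, fraction_up, fraction_down) and \code{coverage}
#'   (number and fraction of significant genes carrying >= 1 mark flag)
#' @export
integration_summary <- function(states, diffexpr) {
  dir <- diffexpr$direction[match(states$gene_id, diffexpr$gene_id)]
  dir[is.na(dir)] <- "ns"
  per_state <- do.call(rbind, lapply(0:15, function(s) {
    in_s <- states$state == s
    n <- sum(in_s)
    n_up <- sum(in_s & dir == "up")
    n_down <- sum(in_s & dir == "down")
    data.frame(state = s,
               ac_d0 = bitwAnd(s, 1L) > 0, ac_d8 = bitwAnd(s, 2L) > 0,
               me3_d0 = bitwAnd(s, 4L) > 0, me3_d8 = bitwAnd(s, 8L) > 0,
               n_genes = n, n_up = n_up, n_down = n_down,
               n_ns = n - n_up - n_down,
               fraction_up = if (n > 0) n_up / n else NA_real_,
               fraction_down = if (n > 0) n_down / n else NA_real_)
  }))
  sig <- dir != "ns"
  marked <- states$state > 0L
  list(per_state = per_state,
       coverage = list(
         n_sig = sum(sig),
         n_sig_marked = sum(sig & marked),
         fraction_sig_marked = if (any(sig)) sum(sig & marked) / sum(sig) else NA_real_
       ))
}

#' Hypergeometric gene-set enrichment
#'
#' Generic over-representation test of a query gene list against named gene
#' sets within a universe; upper-tail hypergeometric p per set, BH-adjusted
#' across sets.
#'
#' @param genes query gene ids
#' @param gene_sets named list of gene-id vectors
#' @param universe gene universe; sets and query are intersected with it
#' @return data.frame with set, set_size, overlap, p, p_adj
#' @export
geneset_enrichment <- function(genes, gene_sets, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  q <- intersect(unique(genes), universe)
  rows <- lapply(names(gene_sets), function(nm) {
    s <- intersect(unique(gene_sets[[nm]]), universe)
    k <- length(intersect(q, s))
    p <- phyper(k - 1, length(s), length(universe) - length(s), length(q),
                lower.tail = FALSE)
    data.frame(set = nm, set_size = length(s), query_size = length(q),
               overlap = k, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}

#' Read gene sets from GMT
#'
#' @param path GMT file (set name, description, then member genes, tab-separated)
#' @return named list of gene-id vectors
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  setNames(lapply(parts, function(p) p[-(1:2)]),
           vapply(parts, `[[`, character(1), 1L))
}
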