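## Window/gap Poisson island calling for broad histone marks.
##
## The genome is tiled into non-overlapping w-bp windows; a window is eligible
## when its read count is improbably high under a genome-wide Poisson rate
## lambda = total_reads * w / (f * genome_size). Eligible windows separated by
## at most g bp of ineligible windows merge into islands, scored by the summed
## negative log Poisson probability of their eligible member windows. Islands
## are then tested against library-scaled input chromatin and filtered at a
## BH q-value. All coordinates are BED-convention 0-based half-open; islands
## always align to window boundaries.

#' Island caller configuration
#'
#' @param window window size w in bp (default 600)
#' @param gap maximum ineligible gap g in bp bridged when merging eligible
#'   windows (default 600); rounded up to a multiple of \code{window}
#' @param p0 Poisson upper-tail threshold for window eligibility
#' @param fdr BH q-value threshold for island significance against input
#' @param eff_frac effective (mappable) genome fraction f used in the
#'   background rate
#' @param input_flank bp of flanking sequence on each side of an island over
#'   which the local input background rate is estimated (a per-island input
#'   count over a few windows is too noisy to serve as a Poisson mean; the
#'   flank smooths it, in the spirit of local-lambda backgrounds)
#' @return list of class \code{IslandCallerConfig}
#' @export
island_config <- function(window = 600L, gap = 600L, p0 = 0.2, fdr = 0.01,
                          eff_frac = 0.8, input_flank = 5000L) {
  if (window <= 0) stop("window must be positive")
  if (p0 <= 0 || p0 >= 1) stop("p0 must be in (0, 1)")
  gap <- as.integer(ceiling(gap / window) * window)
  structure(list(window = as.integer(window), gap = gap, p0 = p0, fdr = fdr,
                 eff_frac = eff_frac, input_flank = as.integer(input_flank)),
            class = "IslandCallerConfig")
}

#' Construct a read set from intervals and a genome size table
#'
#' @param reads a \code{GRanges} or a data.frame with chrom/start/end
#'   (0-based half-open) and optional strand
#' @param genome named vector of chromosome lengths in bp
#' @return a \code{GRanges} with seqlengths set
#' @export
read_set <- function(reads, genome) {
  if (is.data.frame(reads)) reads <- bed_to_granges(reads, genome)
  else {
    missing <- setdiff(as.character(GenomeInfoDb::seqlevels(reads)), names(genome))
    if (length(missing)) {
      stop("chromosome(s) absent from genome size table: ",
           paste(missing, collapse = ", "))
    }
    GenomeInfoDb::seqlevels(reads) <- names(genome)
    GenomeInfoDb::seqlengths(reads) <- genome
  }
  validate_reads(reads)
  reads
}

validate_reads <- function(gr) {
  sl <- GenomeInfoDb::seqlengths(gr)
  if (any(is.na(sl))) stop("genome size table incomplete")
  lens <- sl[as.character(GenomicRanges::seqnames(gr))]
  bad <- GenomicRanges::start(gr) < 1L | GenomicRanges::end(gr) > lens |
    GenomicRanges::width(gr) < 1L
  if (any(bad)) stop(sum(bad), " read(s) fall outside chromosome bounds")
  invisible(gr)
}

## 0-based 5' position of each read (start for +/*, end-1 for -)
five_prime_pos0 <- function(gr) {
  neg <- as.character(GenomicRanges::strand(gr)) == "-"
  ifelse(neg, GenomicRanges::end(gr) - 1L, GenomicRanges::start(gr) - 1L)
}

## per-chrom window counts of 5' read positions
window_counts <- function(reads, genome, w) {
  pos <- five_prime_pos0(reads)
  chrom <- as.character(GenomicRanges::seqnames(reads))
  lapply(setNames(names(genome), names(genome)), function(chr) {
    nw <- as.integer(ceiling(genome[[chr]] / w))
    p <- pos[chrom == chr]
    if (!length(p)) return(integer(nw))
    tabulate(p %/% w + 1L, nbins = nw)
  })
}

#' Merge eligible windows of a single count vector into scored islands
#'
#' The elementary island-forming step, exposed for direct use on window count
#' vectors: windows with Poisson upper-tail probability below \code{p0} are
#' eligible; runs of eligible windows separated by at most \code{gap} bp of
#' ineligible windows merge into one island. Island score is the sum over
#' eligible member windows of \code{-log P(X = count | lambda)}.
#'
#' @param counts integer vector of per-window read counts
#' @param lambda expected count per window under the background model
#' @param cfg an \code{IslandCallerConfig}
#' @param chrom_len chromosome length in bp (defaults to a whole number of
#'   windows)
#' @return data.frame with 0-based half-open \code{start}, \code{end}, member
#'   window index range, \code{score} and total \code{count}
#' @export
islands_from_counts <- function(counts, lambda, cfg = island_config(),
                                chrom_len = length(counts) * cfg$window) {
  w <- cfg$window
  gap_windows <- cfg$gap %/% w
  eligible <- which(ppois(counts - 1, lambda, lower.tail = FALSE) < cfg$p0)
  if (!length(eligible)) {
    return(data.frame(start = integer(0), end = integer(0),
                      first_window = integer(0), last_window = integer(0),
                      score = numeric(0), count = integer(0)))
  }
  run <- cumsum(c(TRUE, diff(eligible) > gap_windows + 1L))
  pieces <- split(eligible, run)
  out <- lapply(pieces, function(idx) {
    first <- idx[1L]; last <- idx[length(idx)]
    span <- first:last
    data.frame(
      start = (first - 1L) * w,
      end = min(last * w, chrom_len),
      first_window = first,
      last_window = last,
      score = sum(-dpois(counts[idx], lambda, log = TRUE)),
      count = sum(counts[span])
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Call enriched islands from ChIP reads with input-chromatin background
#'
#' @param chip ChIP read set (\code{GRanges} with seqlengths, see
#'   \code{\link{read_set}})
#' @param input input-chromatin read set, or \code{NULL} to fall back (with a
#'   warning) to the genome-uniform background alone
#' @param cfg an \code{IslandCallerConfig}
#' @param mark,day optional labels stored in the result metadata
#' @return \code{GRanges} of non-overlapping, sorted islands with metadata
#'   columns \code{chip_count}, \code{input_scaled}, \code{score}, \code{p},
#'   \code{q}
#' @export
call_islands <- function(chip, input, cfg = island_config(), mark = NA_character_,
                         day = NA_character_) {
  genome <- GenomeInfoDb::seqlengths(chip)
  if (any(is.na(genome))) stop("chip read set lacks chromosome lengths")
  w <- cfg$window
  total_chip <- length(chip)
  empty <- GenomicRanges::GRanges(seqlengths = genome)
  empty$chip_count <- integer(0); empty$input_scaled <- numeric(0)
  empty$score <- numeric(0); empty$p <- numeric(0); empty$q <- numeric(0)
  if (total_chip == 0L) return(empty)

  genome_size <- sum(genome)
  lambda <- total_chip * w / (cfg$eff_frac * genome_size)
  chip_counts <- window_counts(chip, genome, w)

  uniform_bg <- is.null(input) || length(input) == 0L
  if (uniform_bg) {
    warning("empty input read set: using genome-uniform background")
    scale_factor <- NA_real_
  } else {
    scale_factor <- total_chip / length(input)
    input_counts <- window_counts(input, genome, w)
  }

  per_chrom <- lapply(names(genome), function(chr) {
    isl <- islands_from_counts(chip_counts[[chr]], lambda, cfg,
                               chrom_len = genome[[chr]])
    if (!nrow(isl)) return(NULL)
    isl$chrom <- chr
    if (uniform_bg) {
      isl$input_scaled <- 0
    } else {
      ## local input rate from the island plus flanks, rescaled to island width
      fw <- cfg$input_flank %/% w
      nw_chr <- length(input_counts[[chr]])
      isl$input_scaled <- vapply(seq_len(nrow(isl)), function(i) {
        lo <- max(1L, isl$first_window[i] - fw)
        hi <- min(nw_chr, isl$last_window[i] + fw)
        n_isl <- isl$last_window[i] - isl$first_window[i] + 1L
        sum(input_counts[[chr]][lo:hi]) * scale_factor * n_isl / (hi - lo + 1L)
      }, numeric(1))
    }
    isl
  })
  isl <- do.call(rbind, per_chrom)
  if (is.null(isl) || !nrow(isl)) return(empty)

  n_windows <- isl$last_window - isl$first_window + 1L
  ## background floor at the genome-uniform expectation keeps the Poisson
  ## mean positive where local input coverage happens to be zero
  lambda_bg <- pmax(isl$input_scaled, lambda * n_windows)
  isl$p <- ppois(isl$count - 1, lambda_bg, lower.tail = FALSE)
  isl$q <- bh_adjust(isl$p)
  isl <- isl[isl$q <= cfg$fdr, , drop = FALSE]
  if (!nrow(isl)) return(empty)

  gr <- GenomicRanges::GRanges(
    seqnames = isl$chrom,
    ranges = IRanges::IRanges(start = isl$start + 1L, end = isl$end),
    chip_count = isl$count,
    input_scaled = isl$input_scaled,
    score = isl$score,
    p = isl$p,
    q = isl$q,
    seqlengths = genome
  )
  gr <- GenomicRanges::sort(gr)
  S4Vectors::metadata(gr) <- list(mark = mark, day = day, config = cfg,
                                  lambda = lambda, total_chip = total_chip)
  gr
}

#' Classify islands of two days as shared or day-specific
#'
#' An island is shared when it overlaps any island of the other day by at
#' least 1 bp; otherwise it is specific to its day. Shared fractions are
#' reported per day (shared / islands of that day) and on the union.
#'
#' @param day0,day8 island \code{GRanges} for the two time points (same mark,
#'   same genome)
#' @return list of class \code{DifferentialOccupancy}
#' @export
differential_occupancy <- function(day0, day8) {
  g0 <- GenomeInfoDb::seqlengths(day0); g8 <- GenomeInfoDb::seqlengths(day8)
  common <- intersect(names(g0), names(g8))
  if (!identical(g0[common], g8[common])) stop("genome mismatch between island sets")
  ov <- GenomicRanges::findOverlaps(day0, day8, minoverlap = 1L)
  shared0 <- unique(S4Vectors::queryHits(ov))
  shared8 <- unique(S4Vectors::subjectHits(ov))
  res <- list(
    shared_d0 = day0[shared0],
    shared_d8 = day8[shared8],
    d0_specific = if (length(shared0)) day0[-shared0] else day0,
    d8_specific = if (length(shared8)) day8[-shared8] else day8,
    shared_fraction_d0 = if (length(day0)) length(shared0) / length(day0) else NA_real_,
    shared_fraction_d8 = if (length(day8)) length(shared8) / length(day8) else NA_real_,
    shared_fraction_union = if (length(day0) + length(day8) > 0)
      (length(shared0) + length(shared8)) / (length(day0) + length(day8)) else NA_real_
  )
  structure(res, class = "DifferentialOccupancy")
}

#' @export
print.DifferentialOccupancy <- function(x, ...) {
  cat(sprintf(
    "DifferentialOccupancy: %d D0-specific, %d D8-specific, %d/%d shared (union fraction %.2f)\n",
    length(x$d0_specific), length(x$d8_specific),
    length(x$shared_d0), length(x$shared_d8), x$shared_fraction_union))
  invisible(x)
}

#' Read-saturation analysis of island calling
#'
#' Subsamples the ChIP library without replacement at each fraction, re-calls
#' islands, and reports how many full-library islands are recovered (overlap
#' by >= 1 bp).
#'
#' @param chip,input read sets
#' @param cfg an \code{IslandCallerConfig}
#' @param fractions subsampling fractions in (0, 1]
#' @param seed RNG seed controlling the subsamples
#' @return data.frame with per-fraction island count and recovery
#' @export
saturation_curve <- function(chip, input, cfg = island_config(),
                             fractions = seq(0.1, 1, by = 0.1), seed = 1L) {
  if (any(fractions <= 0 | fractions > 1)) stop("fractions must be in (0, 1]")
  full <- call_islands(chip, input, cfg)
  set.seed(seed)
  rows <- lapply(fractions, function(f) {
    n <- round(f * length(chip))
    sub <- if (n >= length(chip)) chip else chip[sort(sample.int(length(chip), n))]
    isl <- call_islands(sub, input, cfg)
    recovered <- if (length(full)) {
      mean(GenomicRanges::countOverlaps(full, isl, minoverlap = 1L) > 0)
    } else NA_real_
    data.frame(fraction = f, n_reads = n, n_islands = length(isl),
               recovery = recovered)
  })
  do.call(rbind, rows)
}

#' Genome-wide bin counts of features
#'
#' Half-open fixed-size bins per chromosome; each feature lands in the bin
#' containing its midpoint (a midpoint exactly on a boundary belongs to the
#' higher bin, as bins are half-open).
#'
#' @param features a \code{GRanges} of intervals or loci
#' @param genome named vector of chromosome lengths; defaults to the
#'   seqlengths of \code{features}
#' @param bin_size bin width in bp (default 2 Mb)
#' @return data.frame with chrom, bin_start, bin_end, count for every bin
#' @export
bin_density <- function(features, genome = NULL, bin_size = 2e6) {
  if (is.null(genome)) genome <- GenomeInfoDb::seqlengths(features)
  if (any(is.na(genome))) stop("genome size table required")
  mid0 <- (GenomicRanges::start(features) - 1L) +
    GenomicRanges::width(features) %/% 2L
  chrom <- as.character(GenomicRanges::seqnames(features))
  out <- lapply(names(genome), function(chr) {
    nb <- as.integer(ceiling(genome[[chr]] / bin_size))
    counts <- tabulate(mid0[chrom == chr] %/% bin_size + 1L, nbins = nb)
    data.frame(chrom = chr,
               bin_start = (seq_len(nb) - 1) * bin_size,
               bin_end = pmin(seq_len(nb) * bin_size, genome[[chr]]),
               count = counts,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Correlation between two island sets
#'
#' Windows the genome at \code{w} bp, builds binary occupancy vectors for the
#' two sets, and reports their Pearson correlation together with the Jaccard
#' index of covered base pairs. The correlation is \code{NA} when either
#' vector has zero variance.
#'
#' @param set_a,set_b island \code{GRanges} on the same genome
#' @param genome named vector of chromosome lengths; defaults to seqlengths
#' @param w window size in bp
#' @return list with \code{pearson_r} and \code{jaccard}
#' @export
mark_correlation <- function(set_a, set_b, genome = NULL, w = 600L) {
  if (is.null(genome)) genome <- GenomeInfoDb::seqlengths(set_a)
  if (any(is.na(genome))) stop("genome size table required")
  occ <- function(gr) {
    unlist(lapply(names(genome), function(chr) {
      nw <- as.integer(ceiling(genome[[chr]] / w))
      v <- logical(nw)
      g <- gr[as.character(GenomicRanges::seqnames(gr)) == chr]
      if (length(g)) {
        s0 <- GenomicRanges::start(g) - 1L
        e0 <- GenomicRanges::end(g)
        for (i in seq_along(g)) {
          v[(s0[i] %/% w + 1L):((e0[i] - 1L) %/% w + 1L)] <- TRUE
        }
      }
      v
    }), use.names = FALSE)
  }
  va <- occ(set_a); vb <- occ(set_b)
  r <- if (sd(va) == 0 || sd(vb) == 0) NA_real_ else cor(va, vb)
  ra <- GenomicRanges::reduce(set_a); rb <- GenomicRanges::reduce(set_b)
  inter <- sum(GenomicRanges::width(GenomicRanges::intersect(ra, rb)))
  uni <- sum(GenomicRanges::width(GenomicRanges::union(ra, rb)))
  jac <- if (uni > 0) inter / uni else NA_real_
  list(pearson_r = r, jaccard = jac)
}
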