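#' @importFrom stats median mad var sd ppois dpois qpois phyper fisher.test
#'   p.adjust prcomp hclust cutree dist cor rnorm rpois runif rbinom rchisq
#'   pt model.matrix lm.fit setNames quantile complete.cases
#' @importFrom utils read.delim write.table head tail
#' @import methods
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a chrom.sizes table
#'
#' Two-column whitespace-delimited text: chromosome name, length in bp.
#'
#' @param path file path
#' @return named numeric vector of chromosome lengths
#' @export
read_genome_sizes <- function(path) {
  df <- read.delim(path, header = FALSE, sep = "", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("chrom.sizes file must have two columns: ", path)
  setNames(as.numeric(df[[2L]]), as.character(df[[1L]]))
}

## BED is 0-based half-open on disk; GRanges is 1-based closed in memory.
bed_to_granges <- function(df, genome = NULL) {
  colnames(df)[1:3] <- c("chrom", "start", "end")
  strand <- if (ncol(df) >= 6L) as.character(df[[6L]]) else rep("*", nrow(df))
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand
  )
  if (ncol(df) >= 4L) gr$name <- df[[4L]]
  if (!is.null(genome)) {
    missing <- setdiff(as.character(GenomeInfoDb::seqlevels(gr)), names(genome))
    if (length(missing)) {
      stop("chromosome(s) absent from genome size table: ",
           paste(missing, collapse = ", "))
    }
    GenomeInfoDb::seqlevels(gr) <- names(genome)
    ## our own bound check reports a clearer error than the S4 validity warning
    suppressWarnings(GenomeInfoDb::seqlengths(gr) <- genome)
  }
  gr
}

granges_to_bed <- function(gr, extra = NULL) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  if (!is.null(extra)) df <- cbind(df, extra)
  df
}

#' Read a BED file of genomic intervals
#'
#' @param path BED path (3+ tab-separated columns, no header)
#' @param genome optional named vector of chromosome lengths; when given,
#'   intervals are validated against it
#' @return a \code{GRanges}
#' @export
read_bed <- function(path, genome = NULL) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   comment.char = "#")
  if (ncol(df) < 3L) stop("BED file needs >= 3 columns: ", path)
  gr <- bed_to_granges(df, genome)
  if (!is.null(genome)) validate_reads(gr)
  gr
}

#' Write intervals as BED
#'
#' Islands carry their score and q-value in columns 5 and 7 respectively
#' (name and strand fill columns 4 and 6).
#'
#' @param gr a \code{GRanges}; metadata columns \code{score} and \code{q}
#'   are emitted when present
#' @param path output path
#' @export
write_bed <- function(gr, path) {
  m <- GenomicRanges::mcols(gr)
  df <- granges_to_bed(gr)
  if (!is.null(m$score)) {
    df$name <- m$name %||% paste0("island_", seq_along(gr))
    df$score <- m$score
    df$strand <- as.character(GenomicRanges::strand(gr))
    if (!is.null(m$q)) df$q <- m$q
  } else if (!is.null(m$name)) {
    df$name <- m$name
  }
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## deterministic substitute for sample() order-sensitivity in ties:
## order by numeric key then lexicographic id
order_by <- function(key, id) order(key, id, method = "radix")

stop_if_not_prob <- function(p, what = "p-values") {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop(what, " must lie in [0, 1]")
  }
  invisible(p)
}
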