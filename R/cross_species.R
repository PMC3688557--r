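## Cross-species comparison of gene-level differential expression.
##
## Human and rat arrays are reduced to a common ortholog universe keyed by a
## shared identifier namespace (Entrez in the original data); overlap of the
## two significant gene sets is then tested against the hypergeometric null.

#' Read a two-column ortholog pairing table
#'
#' @param path TSV with two columns: gene id in species A, gene id in species B
#' @return data.frame with columns \code{gene_a}, \code{gene_b}
#' @export
read_orthologs <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("ortholog table needs two columns")
  data.frame(gene_a = as.character(df[[1L]]), gene_b = as.character(df[[2L]]),
             stringsAsFactors = FALSE)
}

#' Harmonize two gene-level tables to a common ortholog universe
#'
#' Many-to-many ortholog pairs are dropped (and counted) so the retained
#' pairing is one-to-one; the result has one row per ortholog pair measured on
#' both platforms.
#'
#' @param table_a,table_b gene-level data.frames with columns \code{gene_id},
#'   \code{p_adj}, \code{direction}, \code{log2FC}
#' @param orthologs data.frame with columns \code{gene_a} (ids of table_a) and
#'   \code{gene_b} (ids of table_b)
#' @param alpha significance threshold on \code{p_adj}
#' @return data.frame with per-species significance and direction; the number
#'   of dropped many-to-many pairs is attached as attribute
#'   \code{n_dropped_multi}
#' @export
harmonize_species <- function(table_a, table_b, orthologs, alpha = 0.05) {
  keep <- !(orthologs$gene_a %in% orthologs$gene_a[duplicated(orthologs$gene_a)]) &
    !(orthologs$gene_b %in% orthologs$gene_b[duplicated(orthologs$gene_b)])
  dropped <- sum(!keep)
  orth <- orthologs[keep, , drop = FALSE]
  ia <- match(orth$gene_a, table_a$gene_id)
  ib <- match(orth$gene_b, table_b$gene_id)
  present <- !is.na(ia) & !is.na(ib)
  if (!any(present)) {
    stop("no ortholog pair measured on both platforms; incompatible identifier namespaces?")
  }
  a <- table_a[ia[present], , drop = FALSE]
  b <- table_b[ib[present], , drop = FALSE]
  out <- data.frame(
    gene_a = orth$gene_a[present],
    gene_b = orth$gene_b[present],
    sig_a = a$p_adj <= alpha,
    dir_a = a$direction,
    log2FC_a = a$log2FC,
    sig_b = b$p_adj <= alpha,
    dir_b = b$direction,
    log2FC_b = b$log2FC,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "n_dropped_multi") <- dropped
  out
}

#' Test overlap of the two species' significant gene sets
#'
#' Reports the one-sided hypergeometric upper-tail probability
#' \code{P(X >= k)} of observing at least the realized overlap given the two
#' set sizes and the common universe, the two-sided Fisher exact p of the
#' implied 2x2 table, the expected overlap \code{|A||B|/N}, and the
#' directional concordance partition of the overlapping genes.
#'
#' @param paired harmonized table from \code{\link{harmonize_species}}, or a
#'   list with elements \code{N}, \code{n_a}, \code{n_b}, \code{k} for testing
#'   printed marginals directly
#' @return an \code{OverlapResult} list
#' @export
overlap_test <- function(paired) {
  if (is.data.frame(paired)) {
    N <- nrow(paired)
    n_a <- sum(paired$sig_a)
    n_b <- sum(paired$sig_b)
    k <- sum(paired$sig_a & paired$sig_b)
    conc <- direction_concordance(paired)
  } else {
    N <- paired$N; n_a <- paired$n_a; n_b <- paired$n_b; k <- paired$k
    conc <- NULL
  }
  if (N < 1L) stop("universe must be non-empty")
  if (k > min(n_a, n_b)) stop("overlap larger than the smaller set: invalid input")
  p_hyper <- phyper(k - 1, n_a, N - n_a, n_b, lower.tail = FALSE)
  log10_p_hyper <- phyper(k - 1, n_a, N - n_a, n_b,
                          lower.tail = FALSE, log.p = TRUE) / log(10)
  tab <- matrix(c(k, n_a - k, n_b - k, N - n_a - n_b + k), nrow = 2L)
  p_fisher <- fisher.test(tab, alternative = "two.sided")$p.value
  structure(list(
    N = N, n_a = n_a, n_b = n_b, k = k,
    expected = n_a * n_b / N,
    p_hyper = p_hyper,
    log10_p_hyper = log10_p_hyper,
    p_fisher = p_fisher,
    concordance = conc,
    venn = list(A_only = n_a - k, B_only = n_b - k, both = k,
                neither = N - n_a - n_b + k)
  ), class = "OverlapResult")
}

#' @export
print.OverlapResult <- function(x, ...) {
  cat(sprintf(
    "OverlapResult: N=%d |A|=%d |B|=%d overlap=%d (expected %.1f)\n  hypergeometric upper-tail p = %.3g (log10 = %.1f); Fisher p = %.3g\n",
    x$N, x$n_a, x$n_b, x$k, x$expected, x$p_hyper, x$log10_p_hyper, x$p_fisher))
  if (!is.null(x$concordance)) {
    cat(sprintf("  concordant up %d, concordant down %d, discordant %d\n",
                x$concordance["concordant_up"], x$concordance["concordant_down"],
                x$concordance["discordant"]))
  }
  invisible(x)
}

#' Directional concordance of doubly-significant genes
#'
#' Partitions the genes significant in both species by agreement of their
#' expression direction. Genes with a missing or non-directional call are
#' excluded and counted.
#'
#' @param paired harmonized table from \code{\link{harmonize_species}}
#' @return named integer vector: concordant_up, concordant_down, discordant,
#'   excluded
#' @export
direction_concordance <- function(paired) {
  both <- paired[paired$sig_a & paired$sig_b, , drop = FALSE]
  ok <- both$dir_a %in% c("up", "down") & both$dir_b %in% c("up", "down")
  b <- both[ok, , drop = FALSE]
  c(concordant_up = sum(b$dir_a == "up" & b$dir_b == "up"),
    concordant_down = sum(b$dir_a == "down" & b$dir_b == "down"),
    discordant = sum(b$dir_a != b$dir_b),
    excluded = sum(!ok))
}

#' Write overlap results as TSV plus Venn-count JSON
#'
#' @param result an \code{OverlapResult}
#' @param tsv_path,json_path output paths (either may be NULL)
#' @export
write_overlap_result <- function(result, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path)) {
    df <- data.frame(N = result$N, n_a = result$n_a, n_b = result$n_b,
                     k = result$k, expected = result$expected,
                     p_hyper = result$p_hyper, p_fisher = result$p_fisher)
    if (!is.null(result$concordance)) {
      df <- cbind(df, as.data.frame(t(result$concordance)))
    }
    write.table(df, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(result$venn, json_path, auto_unbox = TRUE)
  }
  invisible(result)
}
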