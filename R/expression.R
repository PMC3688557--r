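## Expression preprocessing and moderated differential expression.
##
## The time-course design is five days in culture with three donors; the
## contrast of interest is last day minus first day (default D8 - D0).

#' Construct an expression matrix with sample metadata
#'
#' @param values numeric matrix, probes x samples, non-negative raw
#'   fluorescence intensities. Row names are used as probe ids when
#'   \code{probe_ids} is missing.
#' @param sample_meta data.frame with one row per column of \code{values} and
#'   columns \code{sample_id}, \code{day} (integer days in culture),
#'   \code{donor}, \code{technical_replicate} (logical).
#' @param probe_ids character vector of probe identifiers
#' @return an object of class \code{ExpressionMatrix}
#' @export
expression_matrix <- function(values, sample_meta, probe_ids = rownames(values)) {
  values <- as.matrix(values)
  if (is.null(probe_ids)) stop("probe ids are required")
  probe_ids <- as.character(probe_ids)
  if (length(probe_ids) != nrow(values)) stop("probe_ids length != nrow(values)")
  if (anyNA(probe_ids) || any(probe_ids == "")) stop("missing probe identifiers")
  if (anyDuplicated(probe_ids)) stop("duplicated probe identifiers")
  req <- c("sample_id", "day", "donor", "technical_replicate")
  if (!all(req %in% names(sample_meta))) {
    stop("sample_meta needs columns: ", paste(req, collapse = ", "))
  }
  if (nrow(sample_meta) != ncol(values)) stop("sample_meta rows != ncol(values)")
  if (anyNA(sample_meta$sample_id) || anyDuplicated(sample_meta$sample_id)) {
    stop("sample ids must be present and unique")
  }
  if (!all(is.finite(values))) stop("intensities must be finite")
  rownames(values) <- probe_ids
  colnames(values) <- sample_meta$sample_id
  structure(list(values = values, probe_ids = probe_ids,
                 sample_meta = as.data.frame(sample_meta)),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d probes x %d samples (days: %s)\n",
              nrow(x$values), ncol(x$values),
              paste(sort(unique(x$sample_meta$day)), collapse = ",")))
  invisible(x)
}

#' Generalized-log transform with affine calibration
#'
#' Applies \code{glog(x) = asinh((x - a_s) / (b_s * c)) / log(2)} per sample.
#' The transform is strictly increasing and approaches \code{log2} behaviour
#' (unit slope per doubling) for large intensities while remaining defined
#' and variance-stabilizing near background.
#'
#' @param em an \code{ExpressionMatrix}
#' @param params a list with per-sample \code{offset} and \code{scale} vectors
#'   and a global positive \code{cofactor}
#' @return an \code{ExpressionMatrix} of transformed values
#' @export
glog_transform <- function(em, params) {
  if (any(params$scale <= 0)) stop("scales must be positive")
  if (params$cofactor <= 0) stop("cofactor must be positive")
  x <- sweep(em$values, 2L, params$offset, "-")
  x <- sweep(x, 2L, params$scale * params$cofactor, "/")
  out <- em
  out$values <- asinh(x) / log(2)
  out
}

#' Estimate affine calibration parameters for the glog transform
#'
#' Per-sample offsets are the median of a dim-probe reference stratum (the
#' probes with the lowest overall mean intensity), standing in for the array
#' background. Scales are median-of-ratios factors against a pseudo-reference
#' sample (the row-wise median of offset-corrected intensities). The glog
#' cofactor defaults to the pooled median absolute deviation of the dim
#' stratum after offset correction, i.e. the background noise scale.
#'
#' @param em an \code{ExpressionMatrix} of raw non-negative intensities
#' @param dim_quantile fraction of probes forming the dim reference stratum
#' @param cofactor optional fixed glog cofactor; estimated when \code{NULL}
#' @return a params list as consumed by \code{\link{glog_transform}}
#' @export
estimate_glog_params <- function(em, dim_quantile = 0.1, cofactor = NULL) {
  x <- em$values
  if (any(x < 0)) stop("raw intensities must be non-negative")
  n_dim <- max(10L, ceiling(dim_quantile * nrow(x)))
  n_dim <- min(n_dim, nrow(x))
  dim_idx <- order_by(rowMeans(x), em$probe_ids)[seq_len(n_dim)]
  offset <- apply(x[dim_idx, , drop = FALSE], 2L, median)
  centered <- sweep(x, 2L, offset, "-")
  ref <- apply(centered, 1L, median)
  usable <- ref > 0
  if (sum(usable) < 2L) stop("too few probes above background for calibration")
  scale <- apply(centered[usable, , drop = FALSE], 2L, function(col) {
    median(col / ref[usable])
  })
  bad <- !is.finite(scale) | scale <= 0
  if (any(bad)) {
    stop("degenerate sample(s) with non-positive scale estimate: ",
         paste(colnames(x)[bad], collapse = ", "))
  }
  if (is.null(cofactor)) {
    cofactor <- median(abs(as.vector(centered[dim_idx, , drop = FALSE])))
    if (!is.finite(cofactor) || cofactor <= 0) cofactor <- 1
  }
  list(offset = offset, scale = scale, cofactor = cofactor,
       dim_probes = em$probe_ids[dim_idx])
}

#' Variance-stabilizing normalization of raw intensities
#'
#' Convenience wrapper: estimates calibration parameters and applies the glog
#' transform, yielding log2-scale values with matched per-sample medians.
#'
#' @inheritParams estimate_glog_params
#' @return list with elements \code{matrix} (transformed
#'   \code{ExpressionMatrix}) and \code{params}
#' @export
glog_normalize <- function(em, dim_quantile = 0.1, cofactor = NULL) {
  params <- estimate_glog_params(em, dim_quantile, cofactor)
  list(matrix = glog_transform(em, params), params = params)
}

## Newton inversion of trigamma, as used for moment matching the scaled-F
## distribution of residual variances (Smyth-style closed-form estimation).
trigamma_inverse <- function(x) {
  if (!is.finite(x)) return(NA_real_)
  if (x <= 0) return(Inf)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (-dif / y < 1e-10) break
  }
  y
}

#' Moment-matched prior for per-probe residual variances
#'
#' Models observed residual variances as draws from a scaled F distribution,
#' \code{s_g^2 ~ s0^2 * F(d_g, d0)}, and recovers the prior variance
#' \code{s0^2} and prior degrees of freedom \code{d0} by matching moments of
#' \code{log(s_g^2)}.
#'
#' @param s2 numeric vector of residual variances (positive)
#' @param df residual degrees of freedom (scalar)
#' @return list with \code{s0_2} and \code{d0}
#' @export
estimate_variance_prior <- function(s2, df) {
  ## variances at floating-point noise level are effectively zero
  tol <- 1e-9 * max(s2, 0)
  keep <- is.finite(s2) & s2 > tol
  if (!any(keep)) stop("all residual variances are zero: degenerate input")
  if (sum(keep) < length(s2)) {
    warning(sum(!keep), " non-positive residual variances excluded from prior estimation")
  }
  z <- log(s2[keep]) - digamma(df / 2) + log(df / 2)
  evar <- var(z) - trigamma(df / 2)
  d0 <- 2 * trigamma_inverse(evar)
  if (!is.finite(d0)) {
    warning("prior degrees of freedom not estimable; falling back to d0 = 0 (no moderation)")
    return(list(s0_2 = exp(mean(z)), d0 = 0))
  }
  s0_2 <- exp(mean(z) + digamma(d0 / 2) - log(d0 / 2))
  list(s0_2 = s0_2, d0 = d0)
}

#' Empirical-Bayes moderated t-test between two time points
#'
#' Fits an ordinary least-squares group-means model over the whole time course
#' (day as a factor), then contrasts \code{day_alt - day_ref}. Per-probe
#' residual variances are shrunk toward a moment-matched prior,
#' \code{s2_tilde = (d0*s0^2 + d_g*s_g^2) / (d0 + d_g)}, and the moderated t
#' is referred to a t distribution on \code{d0 + d_g} degrees of freedom.
#'
#' @param em a normalized \code{ExpressionMatrix} (log2-scale values)
#' @param day_ref,day_alt the contrasted days (defaults 0 and 8)
#' @param exclude_technical drop samples flagged as technical replicates
#'   before fitting (default TRUE)
#' @param alpha BH-adjusted significance threshold for the direction call
#' @param d0 optional override of the prior degrees of freedom; \code{0}
#'   reproduces the ordinary t-test, large values approach a common-variance
#'   z-like statistic
#' @return list with \code{table} (data.frame: probe_id, log2FC, t_mod, p_raw,
#'   p_adj, direction) and \code{params} (s0_2, d0, d_g, contrast variance)
#' @export
fit_moderated_ttest <- function(em, day_ref = 0, day_alt = 8,
                                exclude_technical = TRUE, alpha = 0.05,
                                d0 = NULL) {
  meta <- em$sample_meta
  keep <- if (exclude_technical) !meta$technical_replicate else rep(TRUE, nrow(meta))
  meta <- meta[keep, , drop = FALSE]
  y <- em$values[, keep, drop = FALSE]
  for (d in c(day_ref, day_alt)) {
    if (sum(meta$day == d) < 2L) {
      stop("need >= 2 biological samples at day ", d)
    }
  }
  day <- factor(meta$day)
  design <- model.matrix(~ 0 + day)
  colnames(design) <- levels(day)
  fit <- lm.fit(design, t(y))
  coefs <- t(fit$coefficients)
  d_g <- nrow(meta) - ncol(design)
  if (d_g < 1L) stop("no residual degrees of freedom")
  s2 <- colSums(as.matrix(fit$residuals)^2) / d_g
  if (all(s2 <= 0)) stop("all residual variances are zero: degenerate input")
  log2fc <- coefs[, as.character(day_alt)] - coefs[, as.character(day_ref)]
  v <- 1 / sum(meta$day == day_ref) + 1 / sum(meta$day == day_alt)

  if (is.null(d0)) {
    prior <- estimate_variance_prior(s2, d_g)
  } else {
    prior <- list(s0_2 = if (d0 > 0) estimate_variance_prior(s2, d_g)$s0_2 else NA_real_,
                  d0 = d0)
  }
  s2_post <- if (prior$d0 == 0) {
    s2
  } else if (!is.finite(prior$d0)) {
    rep(prior$s0_2, length(s2))
  } else {
    (prior$d0 * prior$s0_2 + d_g * s2) / (prior$d0 + d_g)
  }
  se <- sqrt(s2_post * v)
  t_mod <- ifelse(se > 0, log2fc / se, ifelse(log2fc == 0, 0, sign(log2fc) * Inf))
  df_total <- min(prior$d0 + d_g, .Machine$double.xmax)
  p_raw <- 2 * pt(-abs(t_mod), df = df_total)
  p_adj <- bh_adjust(p_raw)
  direction <- ifelse(p_adj <= alpha, ifelse(log2fc > 0, "up", "down"), "ns")
  table <- data.frame(
    probe_id = em$probe_ids,
    log2FC = unname(log2fc),
    t_mod = unname(t_mod),
    p_raw = unname(p_raw),
    p_adj = unname(p_adj),
    direction = direction,
    stringsAsFactors = FALSE
  )
  rownames(table) <- NULL
  list(table = table,
       params = list(s0_2 = prior$s0_2, d0 = prior$d0, d_g = d_g, v = v,
                     s2 = unname(s2)))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validating wrapper around \code{stats::p.adjust(method = "BH")}.
#'
#' @param p numeric vector of p-values in [0, 1]
#' @return adjusted p-values, clipped at 1
#' @export
bh_adjust <- function(p) {
  stop_if_not_prob(p)
  p.adjust(p, method = "BH")
}

#' Collapse probe-level results to gene level
#'
#' A gene is significant if at least one of its probes is significant at the
#' BH-adjusted threshold; the gene inherits the statistics of its most
#' significant probe. Genes whose significant probes disagree in direction are
#' flagged bidirectional (expression arrays routinely carry a few such genes,
#' with probes in different parts of the gene moving in opposite directions).
#'
#' @param table probe-level data.frame from \code{\link{fit_moderated_ttest}}
#' @param probe_map data.frame with columns \code{probe_id}, \code{gene_id}
#' @param alpha significance threshold on \code{p_adj}
#' @return gene-level data.frame with \code{n_probes} and \code{bidirectional}
#'   columns; unmapped probes are excluded and their count attached as
#'   attribute \code{n_unmapped}
#' @export
collapse_probes_to_genes <- function(table, probe_map, alpha = 0.05) {
  m <- match(table$probe_id, probe_map$probe_id)
  unmapped <- sum(is.na(m))
  if (unmapped > 0) {
    message(unmapped, " probes without gene mapping excluded")
  }
  tab <- table[!is.na(m), , drop = FALSE]
  tab$gene_id <- probe_map$gene_id[m[!is.na(m)]]
  ## most-significant-probe rule; deterministic tie-breaks
  ord <- order(tab$gene_id, tab$p_adj, tab$p_raw, -abs(tab$log2FC),
               tab$probe_id, method = "radix")
  tab <- tab[ord, , drop = FALSE]
  first <- !duplicated(tab$gene_id)
  best <- tab[first, , drop = FALSE]
  sig <- tab$p_adj <= alpha
  sig_dir <- tapply(ifelse(sig, ifelse(tab$log2FC > 0, 1L, -1L), NA_integer_),
                    tab$gene_id, function(d) {
                      d <- d[!is.na(d)]
                      length(unique(d)) > 1L
                    })
  n_probes <- tapply(tab$probe_id, tab$gene_id, length)
  out <- data.frame(
    gene_id = best$gene_id,
    log2FC = best$log2FC,
    t_mod = best$t_mod,
    p_raw = best$p_raw,
    p_adj = best$p_adj,
    direction = ifelse(best$p_adj <= alpha,
                       ifelse(best$log2FC > 0, "up", "down"), "ns"),
    n_probes = as.integer(n_probes[best$gene_id]),
    bidirectional = as.logical(sig_dir[best$gene_id]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "n_unmapped") <- unmapped
  out
}

#' Select the most variant probes
#'
#' Probes ranked by across-sample variance (descending); ties broken
#' lexicographically by probe id.
#'
#' @param em an \code{ExpressionMatrix}
#' @param fraction proportion of probes to keep, in (0, 1]
#' @return character vector of probe ids, \code{ceiling(fraction * n)} long
#' @export
select_top_variant <- function(em, fraction = 0.05) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  x <- em$values
  n <- ncol(x)
  v <- rowSums((x - rowMeans(x))^2) / (n - 1)
  k <- ceiling(fraction * nrow(x))
  em$probe_ids[order_by(-v, em$probe_ids)][seq_len(k)]
}

#' Hierarchical clustering of samples with silhouette QC
#'
#' Agglomerates samples by Ward's method on Euclidean distances over the
#' supplied probe subset, cuts the tree at \code{k} clusters, and reports
#' per-sample silhouette widths.
#'
#' @param em a normalized \code{ExpressionMatrix}
#' @param probes probe subset to use (default: all)
#' @param k number of clusters for the cut (optional)
#' @return list with \code{hclust}, \code{labels} (NULL when k missing) and
#'   \code{silhouette} data.frame
#' @export
cluster_samples <- function(em, probes = NULL, k = NULL) {
  x <- em$values
  if (!is.null(probes)) x <- x[probes, , drop = FALSE]
  if (ncol(x) < 2L) stop("need >= 2 samples")
  d <- dist(t(x))
  hc <- hclust(d, method = "ward.D2")
  labels <- NULL
  sil <- NULL
  if (!is.null(k)) {
    if (k > ncol(x)) stop("more clusters requested than samples")
    labels <- cutree(hc, k = k)
    if (k >= 2L && k < ncol(x)) {
      s <- cluster::silhouette(labels, d)
      sil <- data.frame(sample_id = colnames(x),
                        cluster = s[, "cluster"],
                        sil_width = s[, "sil_width"],
                        stringsAsFactors = FALSE)
    }
  }
  list(hclust = hc, labels = labels, silhouette = sil)
}

#' Principal component analysis of samples
#'
#' Centered (unscaled) PCA of samples over a probe subset. The sign of each
#' component is fixed by forcing its largest-magnitude loading positive so
#' results are reproducible across platforms.
#'
#' @param em a normalized \code{ExpressionMatrix}
#' @param probes probe subset (default: all)
#' @return list with \code{scores} (samples x components),
#'   \code{variance_fraction}, and \code{loadings}
#' @export
pca_samples <- function(em, probes = NULL) {
  x <- em$values
  if (!is.null(probes)) x <- x[probes, , drop = FALSE]
  if (ncol(x) < 2L) stop("need >= 2 samples")
  p <- prcomp(t(x), center = TRUE, scale. = FALSE)
  for (i in seq_len(ncol(p$rotation))) {
    j <- which.max(abs(p$rotation[, i]))
    if (p$rotation[j, i] < 0) {
      p$rotation[, i] <- -p$rotation[, i]
      p$x[, i] <- -p$x[, i]
    }
  }
  vf <- p$sdev^2 / sum(p$sdev^2)
  list(scores = p$x, variance_fraction = vf, loadings = p$rotation)
}

#' Write a differential-expression table as TSV
#'
#' @param table probe- or gene-level data.frame
#' @param path output path
#' @export
write_diffexpr_tsv <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix and sample sheet from delimited text
#'
#' @param values_path tab-delimited matrix; first column probe id, header row
#'   of sample ids
#' @param sample_sheet_path TSV with columns sample_id, day, donor,
#'   technical_replicate
#' @return an \code{ExpressionMatrix}
#' @export
read_expression_tsv <- function(values_path, sample_sheet_path) {
  df <- read.delim(values_path, check.names = FALSE, stringsAsFactors = FALSE)
  probe_ids <- as.character(df[[1L]])
  values <- as.matrix(df[, -1L, drop = FALSE])
  meta <- read.delim(sample_sheet_path, stringsAsFactors = FALSE)
  meta$technical_replicate <- as.logical(meta$technical_replicate)
  meta <- meta[match(colnames(values), meta$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id)) stop("sample sheet does not cover all matrix columns")
  expression_matrix(values, meta, probe_ids)
}
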