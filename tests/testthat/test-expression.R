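test_that("glog calibration aligns affinely related samples and preserves order", {
  set.seed(11)
  x1 <- rexp(500, rate = 1 / 200) + 20
  em <- toy_em(cbind(x1, 2 * x1), days = c(0, 8))
  res <- glog_normalize(em)
  v <- res$matrix$values
  expect_equal(v[, 1], v[, 2], tolerance = 1e-6)
  ## strictly monotone per sample
  o <- order(x1)
  expect_true(all(diff(v[o, 1]) >= 0))
  expect_equal(order(v[, 1]), order(em$values[, 1]))
  ## matched medians by construction on the affine pair
  expect_equal(median(v[, 1]), median(v[, 2]), tolerance = 1e-6)
})

test_that("glog transform is asinh-based: zero maps to zero and slope approaches log2", {
  em <- toy_em(matrix(c(0, 1e8, 2e8), ncol = 1), days = 0,
               probe_ids = c("a", "b", "c"))
  tr <- glog_transform(em, list(offset = 0, scale = 1, cofactor = 1))
  expect_identical(tr$values[1, 1], 0)
  ## one doubling adds one log2 unit in the asymptotic regime
  slope <- tr$values[3, 1] - tr$values[2, 1]
  expect_equal(slope, 1, tolerance = 0.01)
})

test_that("degenerate all-constant samples are rejected by calibration", {
  em <- toy_em(cbind(c(1, 2, 3, 4), rep(5, 4)), days = c(0, 8))
  expect_error(glog_normalize(em), "degenerate")
})

test_that("moderated t with d0 = 0 equals the ordinary pooled t", {
  em <- toy_em(rbind(c(1, 2, 3, 4, 5, 6),
                     c(10, 12, 11, 30, 31, 29)),
               days = c(0, 0, 0, 8, 8, 8))
  fit <- fit_moderated_ttest(em, d0 = 0)
  expect_equal(fit$table$t_mod[1], oracle_pooled_t(c(1, 2, 3), c(4, 5, 6)),
               tolerance = 1e-12)
  expect_equal(fit$table$t_mod[2],
               oracle_pooled_t(c(10, 12, 11), c(30, 31, 29)),
               tolerance = 1e-12)
  tt <- t.test(c(4, 5, 6), c(1, 2, 3), var.equal = TRUE)
  expect_equal(fit$table$t_mod[1], unname(tt$statistic), tolerance = 1e-12)
  expect_equal(fit$table$p_raw[1], tt$p.value, tolerance = 1e-12)
})

test_that("a constant probe yields zero effect, zero t and p = 1", {
  em <- toy_em(rbind(rep(7, 6), c(1, 2, 3, 9, 10, 11)),
               days = c(0, 0, 0, 8, 8, 8))
  ## the zero-variance probe is excluded from prior estimation with a warning
  w <- capture_warnings(fit <- fit_moderated_ttest(em))
  expect_true(any(grepl("excluded", w)))
  expect_equal(fit$table$log2FC[1], 0)
  expect_equal(fit$table$t_mod[1], 0)
  expect_equal(fit$table$p_raw[1], 1)
})

test_that("variance prior recovery: moment matching is accurate at 5000 probes", {
  set.seed(42)
  s0_2 <- 0.04; d0 <- 4; d_g <- 4
  sigma2 <- d0 * s0_2 / rchisq(5000, df = d0)
  s2 <- sigma2 * rchisq(5000, df = d_g) / d_g
  est <- estimate_variance_prior(s2, d_g)
  expect_lt(abs(est$s0_2 - s0_2) / s0_2, 0.15)
  expect_lt(abs(est$d0 - d0) / d0, 0.15)
})

test_that("estimated prior agrees with limma's squeezeVar hyperparameters", {
  set.seed(7)
  s2 <- 0.05 * rchisq(2000, df = 4) / 4 * (4 / rchisq(2000, df = 6) * 1.5)
  est <- estimate_variance_prior(s2, 4)
  sq <- limma::squeezeVar(s2, df = 4)
  expect_equal(est$d0, sq$df.prior, tolerance = 1e-6)
  expect_equal(est$s0_2, sq$var.prior, tolerance = 1e-6)
})

test_that("technical replicates are excluded from the fit when requested", {
  vals <- rbind(c(1, 2, 3, 4, 5, 6, 100))
  meta <- toy_meta(days = c(0, 0, 0, 8, 8, 8, 0),
                   tech = c(rep(FALSE, 6), TRUE))
  em <- expression_matrix(vals, meta, "p1")
  fit <- fit_moderated_ttest(em, d0 = 0)
  expect_equal(fit$table$t_mod[1], oracle_pooled_t(c(1, 2, 3), c(4, 5, 6)),
               tolerance = 1e-12)
})

test_that("bh_adjust matches the hand step-up oracle and p.adjust", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03, 0.02)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(1)
  p <- runif(200)^2
  expect_equal(bh_adjust(p), oracle_bh(p))
  ## invariant under permutation of input order
  perm <- sample(200)
  expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm])
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  expect_error(bh_adjust(c(0.5, -0.1)), "0, 1")
})

test_that("probe-to-gene collapse follows the most-significant-probe rule", {
  tab <- data.frame(
    probe_id = c("p1", "p2", "p3", "p4", "p5"),
    log2FC = c(1.2, -0.8, 0.5, -0.2, 2.0),
    t_mod = c(5, -4, 1, -0.5, 6),
    p_raw = c(0.001, 0.01, 0.15, 0.6, 0.0001),
    p_adj = c(0.01, 0.04, 0.2, 0.3, 0.001),
    direction = c("up", "down", "ns", "ns", "up"),
    stringsAsFactors = FALSE
  )
  map <- data.frame(probe_id = c("p1", "p2", "p3", "p4", "p5"),
                    gene_id = c("gA", "gA", "gB", "gB", "gC"))
  out <- collapse_probes_to_genes(tab, map, alpha = 0.05)
  gA <- out[out$gene_id == "gA", ]
  ## up probe p_adj 0.01 and down probe 0.04: significant, up, bidirectional
  expect_equal(gA$direction, "up")
  expect_true(gA$bidirectional)
  gB <- out[out$gene_id == "gB", ]
  expect_equal(gB$direction, "ns")
  expect_false(gB$bidirectional)
  expect_equal(out$n_probes, c(2L, 2L, 1L))
})

test_that("gene counts satisfy the up/down/bidirectional partition identity", {
  set.seed(23)
  n <- 400
  tab <- data.frame(
    probe_id = sprintf("p%03d", 1:n),
    log2FC = rnorm(n),
    t_mod = rnorm(n),
    p_raw = runif(n)^3,
    stringsAsFactors = FALSE
  )
  tab$p_adj <- bh_adjust(tab$p_raw)
  tab$direction <- ifelse(tab$p_adj <= 0.05,
                          ifelse(tab$log2FC > 0, "up", "down"), "ns")
  map <- data.frame(probe_id = tab$probe_id,
                    gene_id = sprintf("g%03d", sample(150, n, replace = TRUE)))
  out <- collapse_probes_to_genes(tab, map, alpha = 0.05)
  sig <- out$p_adj <= 0.05
  n_any_up <- sum(sig & (out$direction == "up" | out$bidirectional))
  n_any_down <- sum(sig & (out$direction == "down" | out$bidirectional))
  expect_equal(n_any_up + n_any_down - sum(sig & out$bidirectional), sum(sig))
  ## unmapped probes are excluded and counted
  map2 <- map[-(1:10), ]
  expect_message(out2 <- collapse_probes_to_genes(tab, map2), "10 probes")
  expect_equal(attr(out2, "n_unmapped"), 10L)
})

test_that("top-variance probe selection matches exhaustive sorting", {
  set.seed(5)
  x <- matrix(rnorm(10 * 4, sd = rep(runif(10, 0.1, 3), 4)), nrow = 10)
  x[3, ] <- 2  # constant probe
  em <- toy_em(x, days = c(0, 2, 4, 8))
  v <- apply(x, 1, var)
  expect_equal(sort(select_top_variant(em, 0.2)),
               sort(em$probe_ids[order(-v)][1:2]))
  expect_equal(sort(select_top_variant(em, 1)), sort(em$probe_ids))
  ## the constant probe ranks last
  expect_false(em$probe_ids[3] %in% select_top_variant(em, 0.9))
  expect_error(select_top_variant(em, 0), "fraction")
})

test_that("Ward clustering recovers the obvious 1-D partition and handles duplicates", {
  em <- toy_em(matrix(c(0, 1, 10), nrow = 1), days = c(0, 0, 8),
               probe_ids = "p1")
  res <- cluster_samples(em, k = 2)
  lab <- unname(res$labels)
  expect_equal(lab[1], lab[2])
  expect_false(lab[1] == lab[3])
  ## two identical samples merge at height zero
  em2 <- toy_em(matrix(c(1, 1, 5), nrow = 1), days = c(0, 0, 8),
                probe_ids = "p1")
  expect_equal(min(cluster_samples(em2)$hclust$height), 0)
  expect_error(cluster_samples(em, k = 5), "more clusters")
})

test_that("silhouette widths approach 1 for well-separated tight clusters", {
  em <- toy_em(matrix(c(0, 0.01, 100, 100.01), nrow = 1),
               days = c(0, 0, 8, 8), probe_ids = "p1")
  res <- cluster_samples(em, k = 2)
  expect_true(all(res$silhouette$sil_width > 0.99))
})

test_that("PCA variance fractions match the covariance eigen-decomposition", {
  set.seed(9)
  x <- matrix(rnorm(9), nrow = 3,
              dimnames = list(NULL, NULL))
  em <- toy_em(x, days = c(0, 4, 8))
  res <- pca_samples(em)
  expect_equal(sum(res$variance_fraction), 1, tolerance = 1e-9)
  ev <- eigen(cov(t(x)), symmetric = TRUE)$values
  expect_equal(res$variance_fraction, ev / sum(ev), tolerance = 1e-8)
  ## two samples: single informative component
  em2 <- toy_em(matrix(rnorm(6), nrow = 3), days = c(0, 8))
  expect_equal(pca_samples(em2)$variance_fraction[1], 1, tolerance = 1e-9)
  ## sign convention: largest-magnitude loading positive
  for (i in seq_len(ncol(res$loadings))) {
    expect_gte(res$loadings[which.max(abs(res$loadings[, i])), i], 0)
  }
})

test_that("moderated t interpolates between ordinary t and the common-variance limit", {
  set.seed(31)
  n <- 300
  vals <- 2^matrix(rnorm(n * 6, mean = 6, sd = 0.4), nrow = n)
  em <- toy_em(log2(vals), days = c(0, 0, 0, 8, 8, 8))
  fit0 <- fit_moderated_ttest(em, d0 = 0)
  ## the common-variance data set makes the prior df estimate non-finite,
  ## which warns; only s0^2 is needed here
  fit_inf <- suppressWarnings(fit_moderated_ttest(em, d0 = 1e6))
  ## ordinary-t limit, independently recomputed
  g0 <- em$values[, 1:3]; g8 <- em$values[, 4:6]
  t_ord <- vapply(seq_len(n), function(i) oracle_pooled_t(g0[i, ], g8[i, ]),
                  numeric(1))
  expect_equal(fit0$table$t_mod, t_ord, tolerance = 1e-10)
  ## common-variance limit
  t_common <- fit_inf$table$log2FC / sqrt(fit_inf$params$s0_2 * (1 / 3 + 1 / 3))
  expect_lt(max(abs(fit_inf$table$t_mod - t_common) / abs(t_common)), 1e-3)
})
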