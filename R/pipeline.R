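## End-to-end driver: simulate -> expression -> islands -> motifs ->
## integration -> cross-species, with a machine-readable report, plus format
## diagnostics for user-supplied input files.

#' Pipeline configuration
#'
#' @param seed integer seed; all pipeline randomness derives from it
#' @param outdir optional output directory for the report and per-stage TSVs
#' @param sim overrides forwarded to \code{\link{sim_config}} (expression,
#'   chip, coupling lists)
#' @param islands overrides forwarded to \code{\link{island_config}}
#' @param motifs list with \code{pwm_path} (defaults to the shipped synthetic
#'   JASPAR-format library) and \code{flank}
#' @param integration list with \code{max_distance} (NULL = no cap) and
#'   \code{alpha}
#' @param expression list with \code{alpha}, \code{top_variant_fraction},
#'   \code{k_clusters}
#' @return nested list of class \code{PipelineConfig}; unknown keys are
#'   rejected
#' @export
pipeline_config <- function(seed = 1L, outdir = NULL, sim = list(),
                            islands = list(), motifs = list(),
                            integration = list(), expression = list()) {
  motifs_def <- list(
    pwm_path = system.file("extdata", "motifs_synthetic_jaspar.txt",
                           package = "chromintegrate"),
    flank = 500L)
  integ_def <- list(max_distance = NULL, alpha = 0.05)
  expr_def <- list(alpha = 0.05, top_variant_fraction = 0.05, k_clusters = 3L)
  isl_def <- list(window = 600L, gap = 600L, p0 = 0.2, fdr = 0.01,
                  eff_frac = 0.8)
  check <- function(def, ov, what) {
    unknown <- setdiff(names(ov), names(def))
    if (length(unknown)) stop("unknown ", what, " config key(s): ",
                              paste(unknown, collapse = ", "))
    modifyList(def, ov, keep.null = TRUE)
  }
  sim_ok <- setdiff(names(sim), c("expression", "chip", "coupling"))
  if (length(sim_ok)) stop("unknown sim config key(s): ",
                           paste(sim_ok, collapse = ", "))
  structure(list(
    seed = as.integer(seed),
    outdir = outdir,
    sim = sim,
    islands = check(isl_def, islands, "islands"),
    motifs = check(motifs_def, motifs, "motifs"),
    integration = check(integ_def, integration, "integration"),
    expression = check(expr_def, expression, "expression")
  ), class = "PipelineConfig")
}

#' Load a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of \code{\link{pipeline_config}};
#' unknown keys are rejected.
#'
#' @param path YAML file
#' @param seed optional seed override (e.g. from a command-line flag)
#' @return a \code{PipelineConfig}
#' @export
read_pipeline_config <- function(path, seed = NULL) {
  if (!requireNamespace("yaml", quietly = TRUE)) stop("yaml package required")
  cfg <- yaml::read_yaml(path)
  allowed <- c("seed", "outdir", "sim", "islands", "motifs", "integration",
               "expression")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  if (!is.null(seed)) cfg$seed <- seed
  do.call(pipeline_config, cfg)
}

run_stage <- function(name, expr) {
  t0 <- Sys.time()
  res <- tryCatch(force(expr), error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  message(sprintf("[%s] done in %.1fs", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

#' Run the full synthetic pipeline
#'
#' Executes, in dependency order: expression simulation, glog normalization
#' and moderated differential expression; ChIP simulation, island calling for
#' both marks at both days, and differential occupancy; nearest-TSS
#' annotation; motif enrichment of the day-specific islands with the opposite
#' day as background and the signed dual-mark statistic; 16-state integration
#' with expression direction; and a cross-species style overlap test against
#' a second simulated expression data set sharing half of the planted genes.
#'
#' @param config a \code{PipelineConfig}
#' @return report list with per-stage counts and parameters; written as JSON
#'   (plus TSV tables) under \code{config$outdir} when set
#' @export
run_pipeline <- function(config) {
  scfg <- do.call(sim_config, c(list(seed = config$seed), config$sim))
  icfg <- do.call(island_config, config$islands)

  expr <- run_stage("simulate_expression", simulate_expression(scfg))
  de <- run_stage("diffexpr", {
    norm <- glog_normalize(expr$matrix)
    fit <- fit_moderated_ttest(norm$matrix, alpha = config$expression$alpha)
    genes <- collapse_probes_to_genes(fit$table, expr$probe_map,
                                      alpha = config$expression$alpha)
    top <- select_top_variant(norm$matrix, config$expression$top_variant_fraction)
    clus <- cluster_samples(norm$matrix, top, k = config$expression$k_clusters)
    pca <- pca_samples(norm$matrix, top)
    list(fit = fit, genes = genes, clusters = clus, pca = pca, norm = norm)
  })

  chip <- run_stage("simulate_chip", simulate_chip(scfg))
  isl <- run_stage("call_islands", {
    tracks <- c("ac_d0", "ac_d8", "me3_d0", "me3_d8")
    sets <- lapply(setNames(tracks, tracks), function(tr) {
      parts <- strsplit(tr, "_")[[1L]]
      call_islands(chip$reads[[tr]], chip$reads$input, icfg,
                   mark = parts[1L], day = parts[2L])
    })
    occ <- list(ac = differential_occupancy(sets$ac_d0, sets$ac_d8),
                me3 = differential_occupancy(sets$me3_d0, sets$me3_d8))
    list(sets = sets, occ = occ)
  })

  ann <- run_stage("annotate", {
    lapply(isl$occ, function(o) list(
      d0_specific = annotate_nearest_tss(o$d0_specific, chip$tss,
                                         config$integration$max_distance),
      d8_specific = annotate_nearest_tss(o$d8_specific, chip$tss,
                                         config$integration$max_distance)))
  })

  mot <- run_stage("motifs", {
    if (is.null(chip$genome_seq)) return(NULL)
    pwms <- load_pwms(config$motifs$pwm_path)
    enr <- function(target, background, label) {
      if (!length(target) || !length(background)) return(NULL)
      motif_enrichment(target, background, chip$genome_seq, pwms,
                       flank = config$motifs$flank, target_label = label)
    }
    tabs <- list(
      ac_d0 = enr(isl$occ$ac$d0_specific, isl$occ$ac$d8_specific, "ac_d0"),
      ac_d8 = enr(isl$occ$ac$d8_specific, isl$occ$ac$d0_specific, "ac_d8"),
      me3_d0 = enr(isl$occ$me3$d0_specific, isl$occ$me3$d8_specific, "me3_d0"),
      me3_d8 = enr(isl$occ$me3$d8_specific, isl$occ$me3$d0_specific, "me3_d8"))
    dual <- if (!any(vapply(tabs, is.null, logical(1)))) {
      dual_mark_scores(tabs$ac_d0, tabs$ac_d8, tabs$me3_d0, tabs$me3_d8)
    } else NULL
    list(tables = tabs, dual = dual)
  })

  integ <- run_stage("integrate", {
    universe <- intersect(chip$tss$gene_id, de$genes$gene_id)
    states <- assign_states(ann$ac, ann$me3, universe)
    summary <- integration_summary(states, de$genes)
    list(states = states, summary = summary)
  })

  xsp <- run_stage("overlap", {
    ## second "species": same gene universe, sharing half of the planted set
    set.seed(config$seed + 11L)
    de_a <- expr$truth$de_genes
    n_half <- floor(nrow(de_a) / 2)
    shared <- de_a[sample.int(nrow(de_a), n_half), , drop = FALSE]
    all_genes <- sprintf("g%05d", seq_len(scfg$expression$n_genes))
    fresh_pool <- setdiff(all_genes, de_a$gene_id)
    fresh <- data.frame(
      gene_id = sample(fresh_pool, nrow(de_a) - n_half),
      sign = sample(c(-1, 1), nrow(de_a) - n_half, replace = TRUE),
      stringsAsFactors = FALSE)
    scfg_b <- sim_config(seed = config$seed + 10L,
                         expression = modifyList(
                           scfg$expression,
                           list(de_genes = rbind(shared, fresh))),
                         chip = list(with_sequence = FALSE))
    expr_b <- simulate_expression(scfg_b)
    norm_b <- glog_normalize(expr_b$matrix)
    fit_b <- fit_moderated_ttest(norm_b$matrix, alpha = config$expression$alpha)
    genes_b <- collapse_probes_to_genes(fit_b$table, expr_b$probe_map,
                                        alpha = config$expression$alpha)
    orth <- data.frame(gene_a = de$genes$gene_id, gene_b = de$genes$gene_id,
                       stringsAsFactors = FALSE)
    paired <- harmonize_species(de$genes, genes_b, orth,
                                alpha = config$expression$alpha)
    overlap_test(paired)
  })

  hist16 <- integ$summary$per_state$n_genes
  names(hist16) <- as.character(0:15)
  report <- list(
    seed = config$seed,
    parameters = list(islands = unclass(icfg),
                      alpha = config$expression$alpha,
                      motif_flank = config$motifs$flank,
                      max_distance = config$integration$max_distance),
    expression = list(
      n_probes = nrow(de$fit$table),
      n_significant_probes = sum(de$fit$table$p_adj <= config$expression$alpha),
      n_genes = nrow(de$genes),
      n_significant_genes = sum(de$genes$direction != "ns"),
      n_up = sum(de$genes$direction == "up"),
      n_down = sum(de$genes$direction == "down"),
      n_bidirectional = sum(de$genes$bidirectional, na.rm = TRUE),
      pc1_variance_fraction = de$pca$variance_fraction[1L],
      d0 = de$fit$params$d0, s0_2 = de$fit$params$s0_2),
    islands = lapply(isl$sets, length),
    shared_fraction = lapply(isl$occ, function(o)
      list(d0 = o$shared_fraction_d0, d8 = o$shared_fraction_d8,
           union = o$shared_fraction_union)),
    top_motifs = if (!is.null(mot)) lapply(mot$tables, function(t)
      if (is.null(t)) NULL else t$motif[order(t$p)][1:3]) else NULL,
    dual_mark = if (!is.null(mot) && !is.null(mot$dual))
      list(pearson = mot$dual$pearson, spearman = mot$dual$spearman) else NULL,
    state_histogram = as.list(hist16),
    universe_size = nrow(integ$states),
    coverage = integ$summary$coverage,
    overlap = list(N = xsp$N, n_a = xsp$n_a, n_b = xsp$n_b, k = xsp$k,
                   expected = xsp$expected, p_hyper = xsp$p_hyper,
                   p_fisher = xsp$p_fisher)
  )

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
    write_diffexpr_tsv(de$fit$table, file.path(config$outdir, "diffexpr_probes.tsv"))
    write_diffexpr_tsv(de$genes, file.path(config$outdir, "diffexpr_genes.tsv"))
    for (tr in names(isl$sets)) {
      write_bed(isl$sets[[tr]], file.path(config$outdir, paste0("islands_", tr, ".bed")))
    }
    write.table(integ$states, file.path(config$outdir, "states.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(integ$summary$per_state,
                file.path(config$outdir, "state_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(as.list(hist16),
                         file.path(config$outdir, "state_histogram.json"),
                         auto_unbox = TRUE)
  }
  invisible(structure(list(report = report, diffexpr = de, islands = isl,
                           annotation = ann, motifs = mot,
                           integration = integ, overlap = xsp),
                      class = "PipelineResult"))
}

#' Validate the structure of a pipeline report
#'
#' @param report report list from \code{\link{run_pipeline}} (or parsed JSON)
#' @return TRUE when all required sections and invariants are present
#' @export
validate_report <- function(report) {
  need <- c("seed", "parameters", "expression", "islands", "shared_fraction",
            "state_histogram", "universe_size", "coverage", "overlap")
  if (!all(need %in% names(report))) return(FALSE)
  hist <- unlist(report$state_histogram)
  length(hist) == 16L && sum(hist) == report$universe_size
}

#' Diagnose common format problems in input files
#'
#' Runs per-file sanity checks (never errors): BED column counts, coordinate
#' sanity and sortedness; FASTA structure (header first, no empty records);
#' TSV header presence and rectangular shape; chrom.sizes two-column numeric.
#'
#' @param paths character vector of file paths
#' @param formats matching vector of formats: "bed", "fasta", "tsv", or
#'   "chrom_sizes"
#' @return data.frame of violations (file, line, check, message); zero rows
#'   when everything is well-formed
#' @export
validate_inputs <- function(paths, formats) {
  stopifnot(length(paths) == length(formats))
  bad <- list()
  note <- function(file, line, check, msg) {
    bad[[length(bad) + 1L]] <<- data.frame(file = file, line = line,
                                           check = check, message = msg,
                                           stringsAsFactors = FALSE)
  }
  for (i in seq_along(paths)) {
    path <- paths[i]
    if (!file.exists(path)) { note(path, NA, "exists", "file not found"); next }
    lines <- readLines(path, warn = FALSE)
    fmt <- formats[i]
    if (fmt == "bed") {
      prev <- list()
      for (ln in seq_along(lines)) {
        if (grepl("^#", lines[ln]) || !nzchar(lines[ln])) next
        f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
        if (length(f) < 3L) { note(path, ln, "bed_columns", "fewer than 3 columns"); next }
        s <- suppressWarnings(as.numeric(f[2L])); e <- suppressWarnings(as.numeric(f[3L]))
        if (is.na(s) || is.na(e)) { note(path, ln, "bed_numeric", "non-numeric coordinates"); next }
        if (s >= e) note(path, ln, "bed_interval", sprintf("start (%s) >= end (%s)", f[2L], f[3L]))
        if (s < 0) note(path, ln, "bed_interval", "negative start")
        p <- prev[[f[1L]]]
        if (!is.null(p) && s < p) note(path, ln, "bed_sorted", "intervals not sorted by start within chromosome")
        prev[[f[1L]]] <- s
      }
    } else if (fmt == "fasta") {
      if (!length(lines) || !grepl("^>", lines[1L])) {
        note(path, 1L, "fasta_header", "file does not start with a header line")
      }
      headers <- grep("^>", lines)
      bounds <- c(headers, length(lines) + 1L)
      for (h in seq_along(headers)) {
        body <- lines[setdiff(seq(headers[h] + 1L, bounds[h + 1L] - 1L),
                              integer(0))]
        if (headers[h] + 1L > bounds[h + 1L] - 1L ||
            !any(nzchar(gsub("\\s", "", body)))) {
          note(path, headers[h], "fasta_truncated",
               sprintf("record '%s' has no sequence", sub("^>", "", lines[headers[h]])))
        } else if (any(grepl("[^ACGTNacgtn ]", body))) {
          note(path, headers[h], "fasta_alphabet", "non-ACGTN characters in sequence")
        }
      }
    } else if (fmt == "tsv") {
      if (!length(lines)) { note(path, 1L, "tsv_header", "empty file"); next }
      ncol0 <- length(strsplit(lines[1L], "\t", fixed = TRUE)[[1L]])
      if (ncol0 < 2L) note(path, 1L, "tsv_header", "header has fewer than 2 columns")
      for (ln in seq_along(lines)[-1L]) {
        if (!nzchar(lines[ln])) next
        if (length(strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]) != ncol0) {
          note(path, ln, "tsv_rectangular", "row width differs from header")
        }
      }
    } else if (fmt == "chrom_sizes") {
      for (ln in seq_along(lines)) {
        f <- strsplit(lines[ln], "\\s+")[[1L]]
        if (length(f) < 2L || is.na(suppressWarnings(as.numeric(f[2L])))) {
          note(path, ln, "chrom_sizes", "expected 'chrom<TAB>length'")
        }
      }
    } else {
      note(path, NA, "format", paste0("unknown format '", fmt, "'"))
    }
  }
  if (!length(bad)) {
    return(data.frame(file = character(0), line = integer(0),
                      check = character(0), message = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, bad)
  rownames(out) <- NULL
  out
}
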