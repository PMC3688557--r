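## Synthetic-data generators with recorded ground truth.
##
## The generators emulate the structure of the study's data: a five-timepoint
## (D0..D8), three-donor bead-array expression matrix with technical
## duplicates at D0 and D4; two histone marks sequenced at D0 and D8 plus
## matched input chromatin over a small multi-chromosome genome; motif
## instances planted inside day-specific islands; and a configurable coupling
## between chromatin-change state and expression direction. Every generator
## is a pure function of its configuration (which includes the seed).

#' Simulation configuration
#'
#' Defaults encode the study conditions: 2000 probes over ~1670 genes (some
#' genes carry two probes), days 0/2/4/6/8 with 3 donors and technical
#' duplicates of D0 and D4, variance prior s0^2 = 0.04 with d0 = 4, planted
#' log2 effects of 1.5 reached at the last day; a 10 Mb genome in 4
#' chromosomes, 600 bp windows at background rate lambda = 0.25 reads/window,
#' 10-fold enrichment in planted islands of 3-8 windows, 36 bp reads; and a
#' baseline P(up) of 0.3 rising to 0.8 for the gain-acetylation /
#' loss-methylation state.
#'
#' @param seed integer seed; all generator randomness derives from it
#' @param expression,chip,coupling named lists overriding individual defaults
#' @return nested configuration list of class \code{SimConfig}
#' @export
sim_config <- function(seed = 1L, expression = list(), chip = list(),
                       coupling = list()) {
  expr_def <- list(
    n_probes = 2000L, n_genes = 1667L,
    days = c(0L, 2L, 4L, 6L, 8L), donors = 3L,
    technical_dup_days = c(0L, 4L),
    de_fraction = 0.15, effect_log2 = 1.5,
    s0_2 = 0.04, d0 = 4,
    donor_sd = 0.15, base_mean = 7, base_sd = 1.5,
    bkg_mean = 30, bkg_sd = 5,
    de_genes = NULL  # optional data.frame(gene_id, sign) forcing the planted set
  )
  chip_def <- list(
    chroms = c(chr1 = 3e6, chr2 = 3e6, chr3 = 2e6, chr4 = 2e6),
    window = 600L, lambda = 0.25, fold = 10, read_len = 36L,
    n_shared = 30L, n_d0_specific = 40L, n_d8_specific = 40L,
    width_windows = 3:8, n_genes = 400L,
    with_sequence = TRUE, plantings = list(), retry_cap = 1000L
  )
  p_up_def <- setNames(rep(0.3, 16L), as.character(0:15))
  p_up_def["6"] <- 0.8  # gain-Ac / loss-me3 genes skew upward
  coup_def <- list(
    genes_per_state = setNames(rep(100L, 16L), as.character(0:15)),
    p_up = p_up_def, baseline_up = 0.3, p_sig = 1.0
  )
  check_override <- function(def, ov, what) {
    unknown <- setdiff(names(ov), names(def))
    if (length(unknown)) stop("unknown ", what, " config field(s): ",
                              paste(unknown, collapse = ", "))
    for (nm in names(ov)) def[[nm]] <- ov[[nm]]
    def
  }
  structure(list(
    seed = as.integer(seed),
    expression = check_override(expr_def, expression, "expression"),
    chip = check_override(chip_def, chip, "chip"),
    coupling = check_override(coup_def, coupling, "coupling")
  ), class = "SimConfig")
}

#' Simulate a raw expression matrix with planted differential genes
#'
#' Per-probe variances are drawn from a scaled inverse-chi-square prior;
#' planted genes shift linearly over the time course, reaching the full log2
#' effect at the last day. Donor offsets add probe-level donor structure, and
#' values are exponentiated with additive background noise so the glog
#' calibration has real work to do.
#'
#' @param cfg a \code{SimConfig}
#' @return list with \code{matrix} (\code{ExpressionMatrix} of raw
#'   intensities), \code{probe_map}, and \code{truth} (planted DE genes with
#'   signs, per-probe variances, config echo)
#' @export
simulate_expression <- function(cfg) {
  e <- cfg$expression
  set.seed(cfg$seed)
  gene_ids <- sprintf("g%05d", seq_len(e$n_genes))
  probe_ids <- sprintf("p%05d", seq_len(e$n_probes))
  gene_of <- c(seq_len(min(e$n_genes, e$n_probes)),
               sample.int(e$n_genes, max(0L, e$n_probes - e$n_genes), replace = TRUE))
  probe_map <- data.frame(probe_id = probe_ids, gene_id = gene_ids[gene_of],
                          stringsAsFactors = FALSE)

  if (!is.null(e$de_genes)) {
    de_idx <- match(e$de_genes$gene_id, gene_ids)
    if (anyNA(de_idx)) stop("forced DE gene(s) outside the simulated universe")
    de_sign <- e$de_genes$sign
  } else {
    n_de <- round(e$de_fraction * e$n_genes)
    de_idx <- if (n_de > 0) sort(sample.int(e$n_genes, n_de)) else integer(0)
    de_sign <- if (n_de > 0) sample(c(-1, 1), n_de, replace = TRUE) else numeric(0)
  }
  delta_gene <- numeric(e$n_genes)
  delta_gene[de_idx] <- de_sign * e$effect_log2

  meta <- expand.grid(donor = sprintf("donor%d", seq_len(e$donors)),
                      day = e$days, stringsAsFactors = FALSE)
  meta$technical_replicate <- FALSE
  for (d in e$technical_dup_days) {
    meta <- rbind(meta, data.frame(donor = "donor1", day = d,
                                   technical_replicate = TRUE))
  }
  meta$sample_id <- sprintf("D%d_%s%s", meta$day, meta$donor,
                            ifelse(meta$technical_replicate, "_tech", ""))
  n_s <- nrow(meta)

  sigma2 <- e$d0 * e$s0_2 / rchisq(e$n_probes, df = e$d0)
  base <- rnorm(e$n_probes, e$base_mean, e$base_sd)
  donor_eff <- matrix(rnorm(e$n_probes * e$donors, 0, e$donor_sd),
                      nrow = e$n_probes)
  colnames(donor_eff) <- sprintf("donor%d", seq_len(e$donors))
  max_day <- max(e$days)
  delta_probe <- delta_gene[gene_of]

  mu <- matrix(0, e$n_probes, n_s)
  for (s in seq_len(n_s)) {
    mu[, s] <- base + donor_eff[, meta$donor[s]] +
      delta_probe * meta$day[s] / max_day +
      rnorm(e$n_probes, 0, sqrt(sigma2))
  }
  values <- pmax(e$bkg_mean + 2^mu + matrix(rnorm(e$n_probes * n_s, 0, e$bkg_sd),
                                            e$n_probes), 0)
  em <- expression_matrix(values, meta[, c("sample_id", "day", "donor",
                                           "technical_replicate")], probe_ids)
  truth <- list(
    de_genes = data.frame(gene_id = gene_ids[de_idx], sign = de_sign,
                          stringsAsFactors = FALSE),
    sigma2 = sigma2,
    seed = cfg$seed,
    config = e
  )
  list(matrix = em, probe_map = probe_map, truth = truth)
}

## global window bookkeeping for the simulated genome
genome_windows <- function(chroms, w) {
  nw <- as.integer(ceiling(chroms / w))
  data.frame(chrom = rep(names(chroms), nw),
             local = unlist(lapply(nw, seq_len)),
             stringsAsFactors = FALSE)
}

#' Simulate histone-mark ChIP reads, matched input, genome and TSS table
#'
#' Background reads fall uniformly at rate lambda per window in every track;
#' planted islands receive additional fold-enriched reads in the ChIP track(s)
#' they belong to. Islands are drawn per mark as shared (present both days) or
#' day-specific, placed without overlap (with a two-window buffer; re-drawn up
#' to a retry cap). When sequences are generated, motif instances are written
#' into day-specific island sequences according to the planting rules.
#'
#' @param cfg a \code{SimConfig}
#' @return list with \code{genome} (chrom sizes), \code{genome_seq}
#'   (\code{DNAStringSet} or NULL), \code{reads} (list ac_d0, ac_d8, me3_d0,
#'   me3_d8, input), \code{tss}, and \code{truth} (planted islands with mark
#'   and day_class, motif plantings, config echo)
#' @export
simulate_chip <- function(cfg) {
  ch <- cfg$chip
  set.seed(cfg$seed + 1L)
  w <- ch$window
  chroms <- ch$chroms
  wins <- genome_windows(chroms, w)
  W <- nrow(wins)
  if (min(ch$width_windows) * w < w) stop("island width must be >= window size")

  ## --- island placement on the window grid, disjoint with 2-window buffer
  marks <- c("ac", "me3")
  classes <- c("shared", "d0_specific", "d8_specific")
  n_per <- c(shared = ch$n_shared, d0_specific = ch$n_d0_specific,
             d8_specific = ch$n_d8_specific)
  occupied <- logical(W)
  ok_span <- function(s, width_w) {
    span_end <- s + width_w - 1L
    if (wins$chrom[s] != wins$chrom[span_end]) return(FALSE)
    !any(occupied[max(1L, s - 2L):min(W, span_end + 2L)])
  }
  plan <- list()
  for (mk in marks) {
    for (cl in classes) {
      for (i in seq_len(n_per[[cl]])) {
        width_w <- ch$width_windows[sample.int(length(ch$width_windows), 1L)]
        placed <- FALSE
        ## cheap rejection first; exact feasibility sampling when dense
        for (try in seq_len(min(ch$retry_cap, 50L))) {
          s <- sample.int(W - width_w + 1L, 1L)
          if (ok_span(s, width_w)) { placed <- TRUE; break }
        }
        if (!placed) {
          occ_cum <- cumsum(c(0L, occupied))
          starts <- seq_len(W - width_w + 1L)
          free <- occ_cum[pmin(W, starts + width_w + 1L) + 1L] -
            occ_cum[pmax(1L, starts - 2L)] == 0L
          same_chr <- wins$chrom[starts] == wins$chrom[starts + width_w - 1L]
          feasible <- starts[free & same_chr]
          if (!length(feasible)) {
            stop("could not place island without overlap after ",
                 ch$retry_cap, " retries: genome too dense for the island plan")
          }
          s <- feasible[sample.int(length(feasible), 1L)]
          placed <- TRUE
        }
        occupied[s:(s + width_w - 1L)] <- TRUE
        plan[[length(plan) + 1L]] <- data.frame(
          mark = mk, day_class = cl, gstart = s, width_w = width_w,
          stringsAsFactors = FALSE)
      }
    }
  }
  plan <- do.call(rbind, plan)
  chrom_of <- wins$chrom[plan$gstart]
  local0 <- (wins$local[plan$gstart] - 1L) * w
  islands <- GenomicRanges::GRanges(
    seqnames = chrom_of,
    ranges = IRanges::IRanges(
      start = local0 + 1L,
      end = pmin(local0 + plan$width_w * w, chroms[chrom_of])),
    mark = plan$mark, day_class = plan$day_class,
    seqlengths = chroms
  )
  islands$island_id <- sprintf("isl_%03d", seq_along(islands))

  ## --- reads: window counts then 5'-position placement
  win_start0 <- (wins$local - 1L) * w
  win_len <- pmin(chroms[wins$chrom] - win_start0, w)  # last window may be short
  make_track <- function(extra_idx_list) {
    counts <- rpois(W, ch$lambda)
    for (span in extra_idx_list) {
      counts[span] <- counts[span] + rpois(length(span), (ch$fold - 1) * ch$lambda)
    }
    tot <- sum(counts)
    if (tot == 0L) {
      return(GenomicRanges::GRanges(seqlengths = chroms))
    }
    widx <- rep.int(seq_len(W), counts)
    p0 <- win_start0[widx] + floor(runif(tot) * win_len[widx])
    chrom <- wins$chrom[widx]
    neg <- runif(tot) < 0.5
    len <- ch$read_len
    ## 5' position is p0 on either strand: '-' reads extend leftward
    start0 <- ifelse(neg, p0 - len + 1L, p0)
    flip <- neg & start0 < 0L
    neg[flip] <- FALSE
    start0[flip] <- p0[flip]
    end0 <- pmin(start0 + len, chroms[chrom])
    o <- order(chrom, start0, method = "radix")
    gr <- GenomicRanges::GRanges(
      seqnames = chrom[o],
      ranges = IRanges::IRanges(start = start0[o] + 1L, end = end0[o]),
      strand = ifelse(neg[o], "-", "+"),
      seqlengths = chroms)
    gr
  }
  spans_for <- function(mk, day) {
    cls <- c("shared", paste0(day, "_specific"))
    sel <- which(plan$mark == mk & plan$day_class %in% cls)
    lapply(sel, function(i) plan$gstart[i]:(plan$gstart[i] + plan$width_w[i] - 1L))
  }
  reads <- list(
    ac_d0 = make_track(spans_for("ac", "d0")),
    ac_d8 = make_track(spans_for("ac", "d8")),
    me3_d0 = make_track(spans_for("me3", "d0")),
    me3_d8 = make_track(spans_for("me3", "d8")),
    input = make_track(list())
  )

  ## --- TSS table
  tss <- data.frame(
    gene_id = sprintf("g%05d", seq_len(ch$n_genes)),
    chrom = sample(names(chroms), ch$n_genes, replace = TRUE,
                   prob = chroms / sum(chroms)),
    strand = sample(c("+", "-"), ch$n_genes, replace = TRUE),
    stringsAsFactors = FALSE
  )
  tss$pos <- floor(runif(ch$n_genes) * (chroms[tss$chrom] - 1))
  tss <- tss[order(tss$gene_id), c("gene_id", "chrom", "pos", "strand")]
  rownames(tss) <- NULL

  ## --- genome sequence with planted motif instances
  genome_seq <- NULL
  plantings <- data.frame(motif = character(0), island_id = character(0),
                          chrom = character(0), pos = integer(0),
                          strand = character(0), stringsAsFactors = FALSE)
  if (isTRUE(ch$with_sequence)) {
    genome_seq <- Biostrings::DNAStringSet(vapply(names(chroms), function(chr) {
      paste(sample(BASES, chroms[[chr]], replace = TRUE), collapse = "")
    }, character(1)))
    names(genome_seq) <- names(chroms)
    isl_class <- paste(plan$mark, sub("_specific", "", plan$day_class), sep = "_")
    for (rule in ch$plantings) {
      motif_seq <- if (is.character(rule$motif)) rule$motif else pwm_consensus(rule$motif)
      motif_name <- if (is.character(rule$motif)) rule$motif else rule$motif$name
      L <- nchar(motif_seq)
      targets <- which(isl_class %in% rule$classes & plan$day_class != "shared")
      for (i in targets) {
        if (runif(1) >= rule$prob) next
        chr <- chrom_of[i]
        mid0 <- local0[i] + (plan$width_w[i] * w) %/% 2L
        lo <- max(0L, mid0 - 400L)
        hi <- min(chroms[[chr]] - L, mid0 + 400L - L)
        if (hi < lo) next
        pos0 <- lo + floor(runif(1) * (hi - lo + 1))
        strand <- sample(c("+", "-"), 1L)
        inst <- if (strand == "+") motif_seq else
          as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif_seq)))
        genome_seq[[chr]] <- Biostrings::replaceAt(
          genome_seq[[chr]], IRanges::IRanges(pos0 + 1L, pos0 + L), inst)
        plantings <- rbind(plantings, data.frame(
          motif = motif_name, island_id = islands$island_id[i], chrom = chr,
          pos = as.integer(pos0), strand = strand, stringsAsFactors = FALSE))
      }
    }
  }

  list(
    genome = chroms,
    genome_seq = genome_seq,
    reads = reads,
    tss = tss,
    truth = list(islands = islands, plantings = plantings, tss = tss,
                 seed = cfg$seed, config = ch)
  )
}

state_from_flags <- function(ac_d0, ac_d8, me3_d0, me3_d8) {
  as.integer(ac_d0) + 2L * as.integer(ac_d8) +
    4L * as.integer(me3_d0) + 8L * as.integer(me3_d8)
}

#' Simulate a coupling between chromatin state and expression direction
#'
#' Draws per-gene expression directions with \code{P(up | state)} taken from
#' the coupling table (states not listed fall back to the baseline, with a
#' warning if the table is non-empty but misses a populated state). When a
#' ChIP truth object is supplied, gene states are derived from its planted
#' day-specific islands by nearest-TSS annotation; otherwise states are drawn
#' directly with \code{genes_per_state} genes each.
#'
#' @param cfg a \code{SimConfig}
#' @param chip_truth optional result of \code{\link{simulate_chip}}
#' @return list with \code{states} (gene_id, flags, state),
#'   \code{diffexpr} (gene-level table with direction), and \code{truth}
#' @export
simulate_coupling <- function(cfg, chip_truth = NULL) {
  co <- cfg$coupling
  set.seed(cfg$seed + 2L)
  if (is.null(chip_truth)) {
    gps <- co$genes_per_state
    state <- rep(as.integer(names(gps)), gps)
    gene_id <- sprintf("g%05d", seq_along(state))
    states <- data.frame(gene_id = gene_id,
                         ac_d0 = bitwAnd(state, 1L) > 0,
                         ac_d8 = bitwAnd(state, 2L) > 0,
                         me3_d0 = bitwAnd(state, 4L) > 0,
                         me3_d8 = bitwAnd(state, 8L) > 0,
                         state = state, stringsAsFactors = FALSE)
  } else {
    tr <- chip_truth$truth
    isl <- tr$islands
    by_class <- function(mk, cl) {
      sub <- isl[isl$mark == mk & isl$day_class == cl]
      if (!length(sub)) return(character(0))
      ann <- annotate_nearest_tss(sub, tr$tss)
      ann$gene_id
    }
    states <- assign_states(
      ann_ac = list(d0_specific = by_class("ac", "d0_specific"),
                    d8_specific = by_class("ac", "d8_specific")),
      ann_me3 = list(d0_specific = by_class("me3", "d0_specific"),
                     d8_specific = by_class("me3", "d8_specific")),
      universe = tr$tss$gene_id
    )
  }
  present <- unique(states$state[states$state > 0L])
  missing <- setdiff(as.character(present), names(co$p_up))
  if (length(co$p_up) && length(missing)) {
    warning("coupling table missing state(s) ", paste(missing, collapse = ","),
            "; using baseline probability")
  }
  p_up <- co$baseline_up + numeric(nrow(states))
  hit <- match(as.character(states$state), names(co$p_up))
  p_up[!is.na(hit)] <- co$p_up[hit[!is.na(hit)]]
  sig <- runif(nrow(states)) < co$p_sig
  up <- runif(nrow(states)) < p_up
  direction <- ifelse(!sig, "ns", ifelse(up, "up", "down"))
  diffexpr <- data.frame(
    gene_id = states$gene_id,
    log2FC = ifelse(direction == "up", 1.5, ifelse(direction == "down", -1.5, 0)),
    p_adj = ifelse(sig, 0.001, 1),
    direction = direction,
    stringsAsFactors = FALSE
  )
  list(states = states, diffexpr = diffexpr,
       truth = list(p_up_table = co$p_up, baseline_up = co$baseline_up,
                    p_sig = co$p_sig, seed = cfg$seed))
}

#' Write simulation ground truth as JSON
#'
#' @param truth truth list from a generator
#' @param path output path
#' @export
write_truth_json <- function(truth, path) {
  ser <- truth
  if (!is.null(ser$islands) && methods::is(ser$islands, "GRanges")) {
    ser$islands <- cbind(granges_to_bed(ser$islands),
                         as.data.frame(GenomicRanges::mcols(ser$islands)))
  }
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' Read simulation ground truth back from JSON
#'
#' @param path JSON path written by \code{\link{write_truth_json}}
#' @param genome optional chrom sizes to restore islands as \code{GRanges}
#' @return truth list
#' @export
read_truth_json <- function(path, genome = NULL) {
  tr <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(tr$islands) && !is.null(genome)) {
    df <- as.data.frame(tr$islands, stringsAsFactors = FALSE)
    gr <- bed_to_granges(df[, c("chrom", "start", "end")], genome)
    for (col in setdiff(names(df), c("chrom", "start", "end"))) {
      GenomicRanges::mcols(gr)[[col]] <- df[[col]]
    }
    tr$islands <- gr
  }
  tr
}
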