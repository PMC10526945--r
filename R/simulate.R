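#' Build and validate a synthetic cohort configuration
#'
#' Encodes the study design the analysis assumes: a herd scored for
#' aggression, extreme CAS groups selected for sequencing, windowed read
#' depth proportional to copy number, background CNVRs of all three
#' types, and one causal gain CNVR whose copy number is differentiated
#' between the eventual groups (to a target V_ST) and drives one gene's
#' expression through a linear dosage effect.
#'
#' @param n_individuals Herd size scored for CAS (default 48).
#' @param n_select `c(map, lap)` group sizes sequenced from the CAS
#'   extremes (default 12 + 12); `NULL` sequences the whole herd with no
#'   grouping.
#' @param chromosome_lengths Named bp vector (default four chromosomes
#'   of 120/100/80/60 kb); each must be at least 10 windows long.
#' @param window_size Window width in bp (default 800).
#' @param n_cnvrs_per_type Named counts of background CNVRs,
#'   `c(loss=, gain=, both=)`.
#' @param cnvr_windows Range of background CNVR lengths in windows.
#' @param carrier_freq_range Range of background carrier frequencies.
#' @param causal_cnvr `NULL`, or a list with `target_vst` (in `[0,1]`),
#'   `dosage_slope` (expression units per copy), `within_sd`
#'   (within-group copy-number SD; must be 0 iff `target_vst` is 1),
#'   and optionally `affected_gene`.
#' @param cas_model List: `baseline_rate` (expected CAS at copy number
#'   2), `copy_number_effect` (CAS units per copy), `residual_sd`.
#' @param depth_range Per-individual mean depth range (default 10-16x).
#' @param depth_noise_sd Window depth noise SD as a fraction of the
#'   individual's mean depth (default 0.05).
#' @param n_genes Genes simulated for the expression matrix.
#' @param expression_model List: `base_mean`, `residual_sd` (log2-scale
#'   expression units).
#' @param qpcr_model List: `ct_reference`, `ct_noise_sd`.
#' @param seed Master integer seed; documented sub-seeds drive each
#'   component.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(
    n_individuals = 48,
    n_select = c(map = 12, lap = 12),
    chromosome_lengths = c(chr1 = 120000, chr2 = 100000, chr3 = 80000,
                           chr4 = 60000),
    window_size = 800,
    n_cnvrs_per_type = c(loss = 10, gain = 6, both = 4),
    cnvr_windows = c(2, 6),
    carrier_freq_range = c(0.15, 0.85),
    causal_cnvr = list(target_vst = 0.6, dosage_slope = 0.8,
                       within_sd = 0.4, affected_gene = "gene_causal"),
    cas_model = list(baseline_rate = 10, copy_number_effect = 3,
                     residual_sd = 2),
    depth_range = c(10, 16),
    depth_noise_sd = 0.05,
    n_genes = 40,
    expression_model = list(base_mean = 8, residual_sd = 0.5),
    qpcr_model = list(ct_reference = 22, ct_noise_sd = 0.1),
    seed = 1) {
  if (window_size <= 0) stop_bad("window_size must be > 0")
  if (is.null(names(chromosome_lengths)))
    names(chromosome_lengths) <- sprintf("chr%d", seq_along(chromosome_lengths))
  if (any(chromosome_lengths < 10 * window_size))
    stop_bad("chromosome_lengths must all be >= 10 * window_size")
  if (!is.null(n_select)) {
    if (sum(n_select) > n_individuals)
      stop_bad("n_select sums to %d > n_individuals (%d)",
               sum(n_select), n_individuals)
    if (length(n_select) != 2) stop_bad("n_select must be c(map, lap)")
    names(n_select) <- c("map", "lap")
  }
  nt <- setNames(rep(0L, 3), c("loss", "gain", "both"))
  nt[names(n_cnvrs_per_type)] <- n_cnvrs_per_type
  if (!is.null(causal_cnvr)) {
    t <- causal_cnvr$target_vst
    s <- causal_cnvr$within_sd %||% 0.4
    if (is.null(t) || t < 0 || t > 1)
      stop_bad("causal_cnvr$target_vst must lie in [0, 1]")
    if (t == 1 && s > 0)
      stop_bad("target_vst = 1 is unreachable with within_sd > 0: zero within-group variance is required")
    if (s == 0 && t > 0 && t < 1)
      stop_bad("target_vst = %g is unreachable with within_sd = 0: constant groups force V_ST = 1", t)
    causal_cnvr$within_sd <- s
    causal_cnvr$affected_gene <- causal_cnvr$affected_gene %||% "gene_causal"
  }
  structure(list(
    n_individuals = n_individuals, n_select = n_select,
    chromosome_lengths = chromosome_lengths, window_size = window_size,
    n_cnvrs_per_type = nt, cnvr_windows = cnvr_windows,
    carrier_freq_range = carrier_freq_range, causal_cnvr = causal_cnvr,
    cas_model = cas_model, depth_range = depth_range,
    depth_noise_sd = depth_noise_sd, n_genes = n_genes,
    expression_model = expression_model, qpcr_model = qpcr_model,
    seed = as.integer(seed)), class = "simulation_config")
}

#' Simulate a complete synthetic cohort
#'
#' Generates, from one master seed: true window copy numbers with
#' background and causal CNVRs; per-pig attack records whose expected
#' CAS increases with causal copy number; MAP/LAP selection from the CAS
#' extremes; raw window read depth for the sequenced pigs (mean
#' proportional to copy number / 2 times the pig's mean depth, Gaussian
#' noise truncated at 0); gene models; an expression matrix with the
#' causal dosage effect; and a qPCR plate consistent with the causal
#' copy numbers.
#'
#' The causal CNVR assigns the herd to two balanced latent dosage
#' clusters: copy number N(2, s) vs N(2 + d, s) with
#' `d = 2 s sqrt(t / (1 - t))` for target V_ST `t` (and d = 2, s = 0 for
#' t = 1), so that after CAS-based extreme selection the realized V_ST
#' between MAP and LAP is close to the target.
#'
#' @param config A [simulation_config()].
#' @return List of class `synthetic_cohort`: `config`, `windows`,
#'   `depth` (a `depth_matrix` for the sequenced pigs), `truth`
#'   (`window_cn`, `cnvrs`, `cnvr_cn`), `phenotypes` (herd-wide, with
#'   `group`), `sequenced` (ids), `gene_models`, `gene_positions`,
#'   `expression`, `qpcr`, `causal` (name, affected gene, true copy
#'   numbers).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  ids <- sprintf("pig%02d", seq_len(cfg$n_individuals))

  ## 0. causal-separation calibration (own RNG stream) ------------------
  causal_d <- if (!is.null(cfg$causal_cnvr))
    calibrate_causal_separation(cfg) else 0

  ## 1. genome + truth CNVRs --------------------------------------------
  set.seed(sub_seed(cfg$seed, 1L))
  windows <- make_windows(cfg$chromosome_lengths, cfg$window_size)
  n_win <- nrow(windows)
  truth_cn <- matrix(2, n_win, cfg$n_individuals,
                     dimnames = list(NULL, ids))

  runs <- place_cnvr_runs(windows, cfg)
  for (k in seq_along(runs)) {
    r <- runs[[k]]
    if (r$causal) {
      cn_vals <- causal_copy_numbers(cfg, causal_d)
      causal_cn_vec <- cn_vals
    } else {
      cn_vals <- background_copy_numbers(r$type, cfg)
    }
    truth_cn[r$win_idx, ] <- matrix(cn_vals, length(r$win_idx),
                                    cfg$n_individuals, byrow = TRUE)
  }
  causal_cn <- setNames(
    if (exists("causal_cn_vec", inherits = FALSE)) causal_cn_vec
    else rep(2, cfg$n_individuals), ids)

  ## 2. behavior + selection --------------------------------------------
  set.seed(sub_seed(cfg$seed, 2L))
  phen <- simulate_phenotypes(causal_cn, ids, cfg)
  if (!is.null(cfg$n_select)) {
    phen <- select_extreme_groups(phen, cfg$n_select[["map"]],
                                  cfg$n_select[["lap"]])
    sequenced <- phen$pig_id[phen$group != "unselected"]
  } else {
    phen$group <- factor(rep("unselected", nrow(phen)),
                         levels = c("MAP", "LAP", "unselected"))
    sequenced <- ids
  }
  sequenced <- sort(sequenced)

  ## 2b. truth CNVR table for the sequenced cohort ----------------------
  # a CNVR is defined within the studied population: regions whose
  # carriers were all left unsequenced are not truth CNVRs, and the
  # loss/gain/both type reflects the sequenced pigs' values
  cnvr_rows <- lapply(runs, function(r) {
    vals <- truth_cn[r$win_idx[1], sequenced]
    has_loss <- any(vals <= 1.5); has_gain <- any(vals >= 2.5)
    if (!has_loss && !has_gain) return(NULL)
    data.frame(
      chrom = windows$chrom[r$win_idx[1]],
      start = windows$start[r$win_idx[1]],
      end = windows$end[r$win_idx[length(r$win_idx)]],
      type = if (has_loss && has_gain) "both"
             else if (has_loss) "loss" else "gain",
      is_causal = r$causal, stringsAsFactors = FALSE)
  })
  keep <- !vapply(cnvr_rows, is.null, logical(1))
  runs_kept <- runs[keep]
  if (any(keep)) {
    truth_cnvrs <- do.call(rbind, cnvr_rows[keep])
    ord <- order(truth_cnvrs$chrom, truth_cnvrs$start)
    truth_cnvrs <- truth_cnvrs[ord, , drop = FALSE]
    runs_kept <- runs_kept[ord]
    truth_cnvrs <- data.frame(
      name = sprintf("truth-%d", seq_len(nrow(truth_cnvrs))), truth_cnvrs,
      stringsAsFactors = FALSE)
    rownames(truth_cnvrs) <- NULL
  } else {
    truth_cnvrs <- data.frame(name = character(), chrom = character(),
                              start = integer(), end = integer(),
                              type = character(), is_causal = logical(),
                              stringsAsFactors = FALSE)
  }
  causal_row <- which(truth_cnvrs$is_causal)

  ## 3. read depth for sequenced pigs -----------------------------------
  set.seed(sub_seed(cfg$seed, 3L))
  ns <- length(sequenced)
  mean_depth <- setNames(runif(ns, cfg$depth_range[1], cfg$depth_range[2]),
                         sequenced)
  cn_seq <- truth_cn[, sequenced, drop = FALSE]
  mu <- sweep(cn_seq / 2, 2, mean_depth, "*")
  noise <- matrix(rnorm(length(mu), 0, 1), nrow(mu), ncol(mu))
  depth <- pmax(mu + noise * rep(mean_depth * cfg$depth_noise_sd,
                                 each = nrow(mu)), 0)
  dimnames(depth) <- list(NULL, sequenced)

  ## 4. gene models ------------------------------------------------------
  set.seed(sub_seed(cfg$seed, 4L))
  gm <- simulate_gene_models(windows, truth_cnvrs, causal_row, cfg)

  ## 5-6. expression + qPCR ---------------------------------------------
  cohort <- structure(list(
    config = cfg, windows = windows,
    depth = structure(list(windows = windows, depth = depth,
                           mean_depth = mean_depth),
                      class = "depth_matrix"),
    truth = list(window_cn = cn_seq, cnvrs = truth_cnvrs,
                 cnvr_cn = truth_cnvr_cn(truth_cnvrs, runs_kept, truth_cn,
                                         sequenced)),
    phenotypes = phen, sequenced = sequenced,
    gene_models = gm$models, gene_positions = gm$positions,
    causal = list(
      name = if (length(causal_row)) truth_cnvrs$name[causal_row] else NULL,
      affected_gene = if (!is.null(cfg$causal_cnvr))
        cfg$causal_cnvr$affected_gene else NULL,
      true_cn = causal_cn[sequenced])
  ), class = "synthetic_cohort")

  if (!is.null(cfg$causal_cnvr)) {
    cohort$expression <- simulate_expression(
      cohort, dosage_slope = cfg$causal_cnvr$dosage_slope,
      residual_sd = cfg$expression_model$residual_sd,
      seed = sub_seed(cfg$seed, 5L))
  } else {
    cohort$expression <- simulate_expression(
      cohort, dosage_slope = 0,
      residual_sd = cfg$expression_model$residual_sd,
      seed = sub_seed(cfg$seed, 5L))
  }
  cohort$qpcr <- simulate_qpcr(
    cohort$causal$true_cn,
    ct_noise_sd = cfg$qpcr_model$ct_noise_sd,
    ct_reference = cfg$qpcr_model$ct_reference,
    seed = sub_seed(cfg$seed, 6L))
  cohort
}

#' @noRd
make_windows <- function(chromosome_lengths, window_size) {
  out <- lapply(names(chromosome_lengths), function(ch) {
    n <- floor(chromosome_lengths[[ch]] / window_size)
    data.frame(chrom = ch,
               start = as.integer(window_size * (seq_len(n) - 1)),
               end = as.integer(window_size * seq_len(n)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# choose non-overlapping window runs for background CNVRs plus the causal
# region (middle of the first chromosome), with a one-window buffer
#' @noRd
place_cnvr_runs <- function(windows, cfg) {
  runs <- list()
  occupied <- rep(FALSE, nrow(windows))
  reserve <- function(idx) {
    lo <- max(1L, idx[1] - 1L); hi <- min(nrow(windows), idx[length(idx)] + 1L)
    occupied[seq.int(lo, hi)] <<- TRUE
  }
  chr1 <- windows$chrom == windows$chrom[1]
  if (!is.null(cfg$causal_cnvr)) {
    w <- which(chr1)
    mid <- w[floor(length(w) / 2)]
    idx <- seq.int(mid, mid + 3L) # 4 windows = 3.2 kb at the default width
    runs[[length(runs) + 1L]] <- list(win_idx = idx, type = "gain",
                                      causal = TRUE)
    reserve(idx)
  }
  types <- rep(names(cfg$n_cnvrs_per_type), cfg$n_cnvrs_per_type)
  for (ty in types) {
    len <- sample(seq.int(cfg$cnvr_windows[1], cfg$cnvr_windows[2]), 1)
    ok <- FALSE
    for (try in 1:200) {
      # keep runs inside one chromosome
      st <- sample.int(nrow(windows) - len + 1L, 1)
      idx <- seq.int(st, st + len - 1L)
      if (length(unique(windows$chrom[idx])) > 1L) next
      if (any(occupied[idx])) next
      ok <- TRUE
      break
    }
    if (!ok) stop_bad("could not place %d CNVRs in this genome; enlarge chromosomes",
                      length(types))
    runs[[length(runs) + 1L]] <- list(win_idx = idx, type = ty,
                                      causal = FALSE)
    reserve(idx)
  }
  runs
}

#' @noRd
background_copy_numbers <- function(type, cfg) {
  n <- cfg$n_individuals
  f <- runif(1, cfg$carrier_freq_range[1], cfg$carrier_freq_range[2])
  carrier <- rbinom(n, 1, f) == 1
  if (!any(carrier)) carrier[sample.int(n, 1)] <- TRUE
  cn <- rep(2, n)
  pick <- function(m, vals, prob) sample(vals, m, replace = TRUE, prob = prob)
  m <- sum(carrier)
  cn[carrier] <- switch(
    type,
    loss = pick(m, c(0, 1), c(0.25, 0.75)),
    gain = pick(m, c(3, 4), c(0.7, 0.3)),
    both = ifelse(runif(m) < 0.5, pick(m, c(0, 1), c(0.25, 0.75)),
                  pick(m, c(3, 4), c(0.7, 0.3))))
  cn
}

# two balanced latent clusters; the separation d is pre-calibrated by
# calibrate_causal_separation() so the realized post-selection V_ST
# matches the target
#' @noRd
causal_copy_numbers <- function(cfg, d) {
  n <- cfg$n_individuals
  s <- cfg$causal_cnvr$within_sd
  high <- sample(rep(c(TRUE, FALSE), length.out = n))
  cn <- ifelse(high, 2 + d, 2)
  if (s > 0) cn <- pmax(cn + rnorm(n, 0, s), 0.2)
  cn
}

# Selecting CAS extremes both mixes the latent clusters (lowering the
# between-group difference) and selects on copy number within clusters
# (raising it), so the naive closed form d = 2 s sqrt(t/(1-t)) is biased.
# Calibrate d by bisection against a Monte-Carlo estimate of the realized
# post-selection V_ST, using a vectorized mirror of simulate_phenotypes()
# (kept in sync with it) with common random numbers across d, so the
# estimate is fast, deterministic and monotone in d.
.calibration_cache <- new.env(parent = emptyenv())

#' @noRd
calibrate_causal_separation <- function(cfg, reps = 200L) {
  t <- cfg$causal_cnvr$target_vst
  s <- cfg$causal_cnvr$within_sd
  if (s == 0) return(if (t == 1) 2 else 0)
  if (is.null(cfg$n_select)) return(2 * s * sqrt(t / (1 - t)))
  if (t == 0) return(0)
  n <- cfg$n_individuals
  n_map <- cfg$n_select[["map"]]; n_lap <- cfg$n_select[["lap"]]
  cm <- cfg$cas_model
  # d is a design-time constant of the configuration, not part of the
  # cohort's randomness: fixed internal RNG stream + cache by parameters
  key <- paste(t, s, n, n_map, n_lap, cm$baseline_rate,
               cm$copy_number_effect, cm$residual_sd, reps, sep = "|")
  if (!is.null(.calibration_cache[[key]]))
    return(.calibration_cache[[key]])
  old_rng <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  sex_eff <- 0.5 * (seq_len(n) %% 2 == 1)          # male, female, ...
  batch_eff <- 1.0 * (seq_len(n) > ceiling(n / 2)) # batch2 second half
  set.seed(sub_seed(777L, 9L)) # common random numbers across d
  high <- t(vapply(seq_len(reps),
                   function(i) sample(rep(c(TRUE, FALSE), length.out = n)),
                   logical(n)))
  z_cn <- matrix(rnorm(reps * n), reps, n)
  z_cas <- matrix(rnorm(reps * n), reps, n)
  u_pois <- matrix(runif(reps * n), reps, n)
  realized <- function(d) {
    cn <- pmax(2 + d * high + s * z_cn, 0.2)
    target <- pmax(cm$baseline_rate + cm$copy_number_effect * (cn - 2) +
                     rep(sex_eff + batch_eff, each = reps) +
                     cm$residual_sd * z_cas, 0)
    count <- qpois(u_pois, 0.6 * target)
    cas <- pmax(target, count)
    cas[count == 0] <- 0
    v <- vapply(seq_len(reps), function(i) {
      ord <- order(-cas[i, ], seq_len(n))
      r <- vst(cn[i, ord[seq_len(n_map)]],
               cn[i, ord[seq.int(n - n_lap + 1L, n)]])$vst
      if (is.na(r)) 0 else r
    }, numeric(1))
    mean(v)
  }
  lo <- 0
  hi <- max(4 * s * sqrt(t / (1 - t)), 2 * s)
  while (realized(hi) < t && hi < 50 * s) hi <- hi * 2
  base <- realized(lo)
  if (base >= t) {
    warning(sprintf(
      "target_vst %.2f is below the V_ST induced by CAS selection alone (%.2f) at these group sizes; using zero cluster separation",
      t, base))
    d <- lo
  } else {
    for (i in 1:20) {
      mid <- (lo + hi) / 2
      if (realized(mid) < t) lo <- mid else hi <- mid
    }
    d <- (lo + hi) / 2
  }
  if (!is.null(old_rng)) assign(".Random.seed", old_rng, .GlobalEnv)
  .calibration_cache[[key]] <- d
  d
}

#' @noRd
simulate_phenotypes <- function(causal_cn, ids, cfg) {
  n <- length(ids)
  sex <- rep(c("male", "female"), length.out = n)
  batch <- rep(c("batch1", "batch2"), each = ceiling(n / 2))[seq_len(n)]
  pen <- sprintf("pen%d", ((seq_len(n) - 1) %/% 6) + 1)
  cm <- cfg$cas_model
  target <- cm$baseline_rate +
    cm$copy_number_effect * (causal_cn - 2) +
    0.5 * (sex == "male") + 1.0 * (batch == "batch2") +
    rnorm(n, 0, cm$residual_sd)
  target <- pmax(target, 0)
  count <- rpois(n, 0.6 * target)
  count[target == 0] <- 0L
  dur <- pmax(0, (target - count)) / 0.07
  dur[count == 0] <- 0
  cas <- composite_aggressive_score(count, dur)
  data.frame(pig_id = ids, attack_count = count, attack_duration_s = dur,
             sex = sex, batch = batch, pen = pen, cas = cas,
             stringsAsFactors = FALSE)
}

#' @noRd
truth_cnvr_cn <- function(truth_cnvrs, runs, truth_cn, sequenced) {
  if (!nrow(truth_cnvrs))
    return(matrix(numeric(), 0, length(sequenced),
                  dimnames = list(NULL, sequenced)))
  m <- do.call(rbind, lapply(runs, function(r)
    colMeans(truth_cn[r$win_idx, sequenced, drop = FALSE])))
  rownames(m) <- truth_cnvrs$name
  m
}

# genes tile the genome away from the causal region; one gene is pinned
# over the causal CNVR so a cis dosage effect exists
#' @noRd
simulate_gene_models <- function(windows, truth_cnvrs, causal_row, cfg) {
  glen <- 6000
  genome <- tapply(windows$end, windows$chrom, max)
  chroms <- names(genome)
  n <- cfg$n_genes
  pos <- data.frame(
    gene_id = sprintf("gene%03d", seq_len(n)),
    chrom = sample(chroms, n, replace = TRUE),
    start = NA_real_, end = NA_real_,
    strand = sample(c("+", "-"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  pos$start <- floor(runif(n, 0, unname(genome[pos$chrom]) - glen))
  pos$end <- pos$start + glen
  if (length(causal_row)) {
    cz <- truth_cnvrs[causal_row, ]
    pos$gene_id[1] <- cfg$causal_cnvr$affected_gene
    pos$chrom[1] <- cz$chrom
    pos$start[1] <- max(0, cz$start - 1000)
    pos$end[1] <- pos$start[1] + glen
    pos$strand[1] <- "+"
  }
  exon_len <- 800
  exons <- rbind(
    data.frame(gene_id = pos$gene_id, chrom = pos$chrom,
               start = pos$start, end = pos$start + exon_len,
               stringsAsFactors = FALSE),
    data.frame(gene_id = pos$gene_id, chrom = pos$chrom,
               start = pos$end - exon_len, end = pos$end,
               stringsAsFactors = FALSE))
  plus <- pos$strand == "+"
  utr5 <- data.frame(gene_id = pos$gene_id, chrom = pos$chrom,
                     start = ifelse(plus, pos$start, pos$end - 200),
                     end = ifelse(plus, pos$start + 200, pos$end),
                     stringsAsFactors = FALSE)
  utr3 <- data.frame(gene_id = pos$gene_id, chrom = pos$chrom,
                     start = ifelse(plus, pos$end - 200, pos$start),
                     end = ifelse(plus, pos$end, pos$start + 200),
                     stringsAsFactors = FALSE)
  list(models = gene_model_set(pos, exons, utr5, utr3),
       positions = pos[, c("gene_id", "chrom", "start", "end")])
}

#' Simulate an expression matrix with a dosage effect
#'
#' The affected gene's expression is `base_mean + dosage_slope *
#' copy_number + N(0, residual_sd)` per sequenced pig; every other gene
#' is `base_mean + N(0, residual_sd)`, independent of copy number.
#' Values are on a normalized log2-like scale.
#'
#' @param cohort A `synthetic_cohort` (needs `causal$true_cn`,
#'   `gene_positions`, `sequenced`).
#' @param dosage_slope Expression units per copy for the affected gene.
#' @param residual_sd Residual SD.
#' @param seed Integer seed.
#' @return List: `values` (genes x samples matrix), `gene_positions`.
#' @export
simulate_expression <- function(cohort, dosage_slope, residual_sd,
                                seed = 1L) {
  stopifnot(inherits(cohort, "synthetic_cohort") ||
              (is.list(cohort) && !is.null(cohort$gene_positions)))
  set.seed(as.integer(seed))
  genes <- cohort$gene_positions$gene_id
  samples <- cohort$sequenced
  base <- cohort$config$expression_model$base_mean %||% 8
  vals <- matrix(rnorm(length(genes) * length(samples), base, residual_sd),
                 length(genes), length(samples),
                 dimnames = list(genes, samples))
  ag <- cohort$causal$affected_gene
  if (!is.null(ag) && dosage_slope != 0) {
    if (!ag %in% genes)
      stop_bad("affected gene '%s' not in the simulated gene list", ag)
    cn <- cohort$causal$true_cn[samples]
    vals[ag, ] <- base + dosage_slope * cn +
      rnorm(length(samples), 0, residual_sd)
  }
  list(values = vals, gene_positions = cohort$gene_positions)
}

#' Simulate a qPCR plate from true copy numbers
#'
#' dCt is `-log2(copy_number / 2)` plus Gaussian cycle noise; the
#' reference gene Ct is fixed per sample, and the target Ct is
#' `reference + dCt`, so `2 * 2^(-dCt)` recovers the copy number
#' (unbiased on the log scale).
#'
#' @param true_copy_numbers Named positive copy numbers (names = sample
#'   ids).
#' @param ct_noise_sd Ct noise SD in cycles.
#' @param ct_reference Reference gene Ct (constant per sample).
#' @param seed Integer seed.
#' @return data.frame: sample_id, ct_target, ct_reference.
#' @export
simulate_qpcr <- function(true_copy_numbers, ct_noise_sd = 0.1,
                          ct_reference = 22, seed = 1L) {
  if (any(true_copy_numbers <= 0))
    stop_bad("true copy numbers must be positive for qPCR simulation")
  set.seed(as.integer(seed))
  n <- length(true_copy_numbers)
  dct <- -log2(true_copy_numbers / 2) + rnorm(n, 0, ct_noise_sd)
  data.frame(
    sample_id = names(true_copy_numbers) %||% as.character(seq_len(n)),
    ct_target = ct_reference + dct,
    ct_reference = rep(ct_reference, n),
    stringsAsFactors = FALSE)
}
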