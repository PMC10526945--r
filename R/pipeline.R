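#' Default pipeline configuration
#'
#' Nested per-stage parameter blocks for [run_pipeline()]. Any subset can
#' be overridden via a YAML file or an R list; unknown fields are
#' rejected by validation.
#'
#' @param seed Master seed recorded in every stage report.
#' @return Named list of stage blocks.
#' @export
default_run_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    stages = list(simulate = TRUE, score = TRUE, call_cnvr = TRUE,
                  summarize = TRUE, vst = TRUE, gwas = TRUE, eqtl = TRUE,
                  qpcr_roc = TRUE),
    simulate = list(),           # overrides for simulation_config()
    score = list(n_top = NULL, n_bottom = NULL), # default: from simulate
    call_cnvr = list(min_carriers = 1, max_gap_windows = 0,
                     min_length = 1500),
    summarize = list(promoter_up = 2000, promoter_down = 500),
    vst = list(top_fraction = 0.01),
    gwas = list(covariates = c("sex", "batch")),
    eqtl = list(cis_window = 1e6, log_transform = FALSE),
    qpcr_roc = list()
  )
}

#' Run the CNVR association pipeline end to end
#'
#' Executes the enabled stages in dependency order — simulate, score,
#' call_cnvr, summarize, vst, gwas, eqtl, qpcr_roc — writing each
#' stage's tabular outputs plus a JSON provenance block (parameters,
#' seed, input checksums) under `out_dir`. A failed stage halts its
#' dependents with a named error. Outputs are pure functions of
#' (config, seed): re-running reproduces them byte for byte.
#'
#' @param config A config list from [default_run_config()], or a path to
#'   a YAML file with the same structure.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional override of `config$seed`.
#' @param only Optional character vector restricting which stages run
#'   (their upstream dependencies must already have run into `out_dir`,
#'   or be included).
#' @return Invisible list: per-stage results plus `provenance`.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir,
                         seed = NULL, only = NULL) {
  if (is.character(config) && length(config) == 1)
    config <- modifyList(default_run_config(), yaml::read_yaml(config))
  else
    config <- modifyList(default_run_config(), config)
  stage_names <- c("simulate", "score", "call_cnvr", "summarize", "vst",
                   "gwas", "eqtl", "qpcr_roc")
  bad <- setdiff(names(config$stages), stage_names)
  if (length(bad)) stop_bad("unknown stages in config: %s",
                            paste(bad, collapse = ", "))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  enabled <- vapply(stage_names,
                    function(s) isTRUE(config$stages[[s]]), logical(1))
  if (!is.null(only)) enabled <- enabled & stage_names %in% only
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  state <- new.env(parent = emptyenv())
  report <- list()
  need <- function(what, stage) {
    if (is.null(state[[what]]))
      stop_bad("stage '%s' needs output '%s' from an upstream stage that did not run",
               stage, what)
    state[[what]]
  }

  if (enabled[["simulate"]]) {
    sim_args <- config$simulate
    sim_args$seed <- config$seed
    cfg <- do.call(simulation_config, sim_args)
    cohort <- simulate_cohort(cfg)
    state$cohort <- cohort
    write_depth_matrix(cohort$depth, file.path(out_dir, "depth.tsv"))
    write_cnvr_bed(cohort$truth$cnvrs, file.path(out_dir, "truth_cnvrs.bed"))
    write.table(
      data.frame(name = rownames(cohort$truth$cnvr_cn),
                 cohort$truth$cnvr_cn, check.names = FALSE),
      file.path(out_dir, "truth_cnvr_cn.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.csv(cohort$phenotypes,
                     file.path(out_dir, "phenotypes.csv"), row.names = FALSE)
    write_expression_matrix(cohort$expression,
                            file.path(out_dir, "expression.tsv"))
    utils::write.csv(cohort$qpcr, file.path(out_dir, "qpcr.csv"),
                     row.names = FALSE)
    yaml::write_yaml(config, file.path(out_dir, "config_echo.yaml"))
    report$simulate <- list(
      n_sequenced = length(cohort$sequenced),
      n_truth_cnvrs = nrow(cohort$truth$cnvrs),
      causal = cohort$causal$name)
  }

  if (enabled[["score"]]) {
    cohort <- need("cohort", "score")
    ph <- cohort$phenotypes
    ph$cas <- composite_aggressive_score(ph$attack_count,
                                         ph$attack_duration_s)
    n_top <- config$score$n_top %||%
      (cohort$config$n_select %||% c(map = ceiling(nrow(ph) / 2)))[[1]]
    n_bottom <- config$score$n_bottom %||%
      (cohort$config$n_select %||% c(0, lap = floor(nrow(ph) / 2)))[[2]]
    cas <- select_extreme_groups(ph, n_top, n_bottom)
    state$cas <- cas
    utils::write.csv(cas, file.path(out_dir, "cas.csv"), row.names = FALSE)
    report$score <- list(n_map = sum(cas$group == "MAP"),
                         n_lap = sum(cas$group == "LAP"))
  }

  if (enabled[["call_cnvr"]]) {
    cohort <- need("cohort", "call_cnvr")
    cnmat <- normalize_depth(cohort$depth)
    calls <- do.call(call_cnvrs, c(list(cnmat), config$call_cnvr))
    state$calls <- calls
    state$cnmat <- cnmat
    write_cnvr_bed(calls$cnvrs, file.path(out_dir, "cnvr.bed"))
    write.table(data.frame(name = rownames(calls$cn), calls$cn,
                           check.names = FALSE),
                file.path(out_dir, "cnvr_cn.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    report$call_cnvr <- list(n_cnvrs = nrow(calls$cnvrs),
                             by_type = as.list(table(calls$cnvrs$type)))
  }

  if (enabled[["summarize"]]) {
    cohort <- need("cohort", "summarize")
    calls <- need("calls", "summarize")
    lens <- cohort$config$chromosome_lengths
    summ <- summarize_landscape(calls$cnvrs, lens)
    regr <- chromosome_regressions(
      calls$cnvrs, lens,
      per_individual = data.frame(
        individual = colnames(calls$cn),
        mean_depth = cohort$depth$mean_depth[colnames(calls$cn)],
        n_cnvrs = if (nrow(calls$cn))
          colSums(calls$cn <= 1.5 | calls$cn >= 2.5) else 0))
    anno <- annotate_position(calls$cnvrs, cohort$gene_models,
                              config$summarize$promoter_up,
                              config$summarize$promoter_down)
    state$landscape <- list(summary = summ, regressions = regr,
                            annotation = anno)
    jsonlite::write_json(list(
      n_cnvrs = summ$n_cnvrs,
      counts_by_type = as.list(summ$counts_by_type),
      total_span_bp = summ$total_span_bp,
      genome_fraction_pct = summ$genome_fraction_pct,
      length_bins = summ$length_bins,
      freq_bins = summ$freq_bins,
      annotation = as.list(table(anno))),
      file.path(out_dir, "landscape.json"), auto_unbox = TRUE, digits = NA)
    write.table(regr, file.path(out_dir, "chromosome_regressions.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    report$summarize <- list(genome_fraction_pct = summ$genome_fraction_pct)
  }

  if (enabled[["vst"]]) {
    calls <- need("calls", "vst")
    cas <- need("cas", "vst")
    groups <- setNames(as.character(cas$group), cas$pig_id)
    vres <- vst_scan(calls$cn, groups[colnames(calls$cn)],
                     top_fraction = config$vst$top_fraction)
    state$vst <- vres
    write.table(vres, file.path(out_dir, "vst.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    report$vst <- list(top = vres$name[1])
  }

  if (enabled[["gwas"]]) {
    calls <- need("calls", "gwas")
    cas <- need("cas", "gwas")
    seqd <- colnames(calls$cn)
    ph <- cas[match(seqd, cas$pig_id), ]
    K <- kinship_matrix(calls$cn)
    covs <- config$gwas$covariates
    fe <- if (length(covs)) ph[, covs, drop = FALSE] else NULL
    gres <- mlm_gwas(setNames(ph$cas, seqd), calls$cn, K,
                     fixed_effects = fe)
    state$gwas <- gres
    write.table(gres, file.path(out_dir, "gwas.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    report$gwas <- list(
      top = gres$name[which.min(gres$p)],
      varcomp = as.list(attr(gres, "varcomp")))
  }

  if (enabled[["eqtl"]]) {
    cohort <- need("cohort", "eqtl")
    calls <- need("calls", "eqtl")
    eres <- eqtl_scan(calls$cn, calls$cnvrs,
                      cohort$expression$values,
                      cohort$expression$gene_positions,
                      cis_window = config$eqtl$cis_window,
                      log_transform = config$eqtl$log_transform)
    state$eqtl <- eres
    write.table(eres, file.path(out_dir, "eqtl.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    report$eqtl <- list(n_pairs = nrow(eres),
                        n_cis = sum(eres$relation == "cis"))
  }

  if (enabled[["qpcr_roc"]]) {
    cohort <- need("cohort", "qpcr_roc")
    cas <- need("cas", "qpcr_roc")
    q <- qpcr_relative_cn(cohort$qpcr$ct_target, cohort$qpcr$ct_reference,
                          cohort$qpcr$sample_id)
    ph <- cas[match(q$sample_id, cas$pig_id), ]
    val <- two_step_validation(q$calibrated_cn, ph$cas,
                               pig_id = q$sample_id)
    sel <- ph$group %in% c("MAP", "LAP")
    roc <- roc_auc(q$calibrated_cn[sel], ph$group[sel] == "MAP")
    state$validation <- list(qpcr = q, two_step = val, roc = roc)
    utils::write.csv(q, file.path(out_dir, "qpcr_cn.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(
      two_step = val, auc = roc$auc,
      map_mean_cn = mean(q$calibrated_cn[ph$group == "MAP"]),
      lap_mean_cn = mean(q$calibrated_cn[ph$group == "LAP"])),
      file.path(out_dir, "validation.json"), auto_unbox = TRUE,
      digits = NA)
    report$qpcr_roc <- list(auc = roc$auc)
  }

  prov <- list(seed = config$seed,
               stages_run = stage_names[enabled],
               parameters = config[setdiff(names(config), "stages")],
               outputs = file_checksums(out_dir))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  report$provenance <- prov
  invisible(c(as.list(state), list(report = report)))
}

#' @noRd
file_checksums <- function(dir) {
  fs <- setdiff(list.files(dir, full.names = TRUE),
                file.path(dir, "provenance.json"))
  fs <- fs[!file.info(fs)$isdir]
  as.list(tools::md5sum(fs))
}
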