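#' Dosage eQTL scan: CNVR copy number vs gene expression
#'
#' For every (CNVR, gene) pair fits `expression ~ copy_number +
#' covariates` by least squares and reports the dosage slope with a
#' two-sided t-test. Pairs are labelled `cis` when the gap between the
#' CNVR and the gene's transcript span is at most `cis_window` bp (0 for
#' overlap), `trans` otherwise, and Benjamini-Hochberg adjusted p-values
#' are computed within each relation class. Expression is log2(x+1)
#' transformed by default.
#'
#' @param cn CNVRs x samples copy-number matrix.
#' @param cnvr_positions data.frame (name, chrom, start, end) for the
#'   rows of `cn`.
#' @param expression Genes x samples expression matrix (same sample
#'   columns as `cn`).
#' @param gene_positions data.frame (gene_id, chrom, start, end) for the
#'   rows of `expression`.
#' @param covariates Optional data.frame of per-sample covariates.
#' @param cis_window Max CNVR-to-gene distance (bp) called cis; default
#'   1 Mb.
#' @param log_transform log2(x+1)-transform expression first (default
#'   TRUE).
#' @return data.frame: cnvr, gene, effect, t, p, p_adj, relation,
#'   distance. Zero-variance CNVRs or genes are skipped (NA effect, with
#'   `skipped` reason).
#' @export
eqtl_scan <- function(cn, cnvr_positions, expression, gene_positions,
                      covariates = NULL, cis_window = 1e6,
                      log_transform = TRUE) {
  stopifnot(is.matrix(cn), is.matrix(expression))
  if (cis_window <= 0) stop_bad("cis_window must be positive")
  shared <- intersect(colnames(cn), colnames(expression))
  if (length(shared) < 3)
    stop_bad("need >= 3 shared samples between CN and expression; got %d",
             length(shared))
  cn <- cn[, shared, drop = FALSE]
  expr <- expression[, shared, drop = FALSE]
  if (log_transform) {
    if (any(expr < 0))
      stop_bad("expression has negative values; use log_transform = FALSE for data already on a log-like scale")
    expr <- log2(expr + 1)
  }
  n <- length(shared)

  C <- matrix(1, n, 1)
  if (!is.null(covariates)) {
    stopifnot(nrow(covariates) == n)
    C <- stats::model.matrix(~ ., data = covariates)
  }
  k <- ncol(C)
  # residualize both sides on covariates (Frisch-Waugh), then per-pair OLS
  P <- diag(n) - C %*% solve(crossprod(C), t(C))
  Gr <- cn %*% P
  Er <- expr %*% P
  gss <- rowSums(Gr * Gr)
  ess <- rowSums(Er * Er)
  dfree <- n - k - 1L

  cross <- Er %*% t(Gr)                      # genes x cnvrs
  b <- sweep(cross, 2, gss, "/")
  rss <- outer(ess, rep(1, nrow(cn))) - b * cross
  rss[rss < 0] <- 0
  se <- sqrt(sweep(rss / dfree, 2, gss, "/"))
  tstat <- b / se
  pval <- 2 * pt(-abs(tstat), dfree)

  dist <- pair_distances(cnvr_positions, gene_positions)
  relation <- ifelse(dist <= cis_window, "cis", "trans")

  cnvr_names <- cnvr_positions$name %||% rownames(cn)
  gene_names <- gene_positions$gene_id %||% rownames(expression)
  # rows cnvr-major, gene-minor: column-major vec of the genes x cnvrs
  # matrices aligns; distance/relation are cnvrs x genes, so transpose
  out <- data.frame(
    cnvr = rep(cnvr_names, each = nrow(expr)),
    gene = rep(gene_names, times = nrow(cn)),
    effect = as.vector(b), t = as.vector(tstat), p = as.vector(pval),
    relation = as.vector(t(relation)),
    distance = as.vector(t(dist)),
    stringsAsFactors = FALSE)
  skip <- rep(gss < 1e-12, each = nrow(expr)) |
    rep(ess < 1e-12, times = nrow(cn))
  out$effect[skip] <- NA_real_
  out$t[skip] <- NA_real_
  out$p[skip] <- NA_real_
  out$skipped <- ifelse(skip, "zero variance", "")
  out$p_adj <- NA_real_
  for (rel in c("cis", "trans")) {
    i <- out$relation == rel & !skip
    out$p_adj[i] <- p.adjust(out$p[i], method = "BH")
  }
  out
}

# gap in bp between CNVR i and gene j spans (0 when overlapping),
# Inf across chromosomes; returns cnvrs x genes matrix
#' @noRd
pair_distances <- function(cnvr_positions, gene_positions) {
  check_intervals(cnvr_positions, "cnvr_positions")
  check_intervals(gene_positions, "gene_positions")
  nc <- nrow(cnvr_positions); ng <- nrow(gene_positions)
  d <- matrix(Inf, nc, ng)
  same <- outer(as.character(cnvr_positions$chrom),
                as.character(gene_positions$chrom), "==")
  gap1 <- outer(cnvr_positions$start, gene_positions$end, "-") # cnvr right of gene
  gap2 <- outer(-cnvr_positions$end, gene_positions$start, "+") # gene right of cnvr
  g <- pmax(gap1, gap2, 0)
  d[same] <- g[same]
  d
}

#' qPCR relative copy number by the 2^(-dCt) method
#'
#' dCt = Ct(target) - Ct(reference); each unit corresponds to a two-fold
#' quantity change, so the relative quantity is `2^(-dCt)` (1 when target
#' and single-copy reference amplify identically). `calibrated_cn = 2 *
#' relative_quantity` converts to an absolute diploid-scaled copy number
#' under the assumption that the reference gene is present in two copies.
#'
#' @param ct_target,ct_reference Finite Ct values (cycles), recycled.
#' @param sample_id Optional sample identifiers.
#' @return data.frame: sample_id, ct_target, ct_reference, delta_ct,
#'   relative_quantity, calibrated_cn.
#' @examples
#' qpcr_relative_cn(21, 22)$relative_quantity # 2
#' @export
qpcr_relative_cn <- function(ct_target, ct_reference, sample_id = NULL) {
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_reference)))
    stop_bad("Ct values must be finite")
  d <- ct_target - ct_reference
  rq <- 2^(-d)
  data.frame(
    sample_id = sample_id %||% seq_along(d),
    ct_target = ct_target, ct_reference = ct_reference,
    delta_ct = d, relative_quantity = rq, calibrated_cn = 2 * rq,
    stringsAsFactors = FALSE)
}

#' qPCR standard curve and amplification efficiency
#'
#' Regresses Ct on log10 input amount over a dilution series; the
#' amplification efficiency is `10^(-1/slope) - 1` (100% at the perfect
#' doubling slope of -3.3219 cycles per decade).
#'
#' @param dilution_log10 log10 relative input amounts (>= 3 points).
#' @param ct Observed Ct values.
#' @return List: slope, intercept, r2, efficiency, valid (FALSE when the
#'   slope is non-negative, which no real dilution series should give).
#' @export
standard_curve <- function(dilution_log10, ct) {
  if (length(dilution_log10) < 3)
    stop_bad("need at least 3 dilution points")
  fit <- lm(ct ~ dilution_log10)
  slope <- coef(fit)[[2]]
  valid <- slope < 0
  if (!valid) warning("non-negative standard-curve slope; efficiency undefined")
  list(slope = slope, intercept = coef(fit)[[1]],
       r2 = summary(fit)$r.squared,
       efficiency = if (valid) 10^(-1 / slope) - 1 else NA_real_,
       valid = valid)
}

#' Two-group comparison by Student's t-test
#'
#' Two-sided pooled-variance t-test by default (`var_equal = FALSE` for
#' Welch). Zero pooled variance yields NA statistics rather than an
#' error.
#'
#' @param values Numeric vector.
#' @param group_labels Two-level labels along `values`.
#' @param var_equal Pooled-variance test (default TRUE).
#' @return List: t, p, df, means (named by group), n (named by group).
#' @export
group_compare <- function(values, group_labels, var_equal = TRUE) {
  g <- factor(group_labels)
  if (nlevels(g) != 2) stop_bad("need exactly two groups, got %d", nlevels(g))
  if (min(table(g)) < 2) stop_bad("each group needs >= 2 values")
  means <- tapply(values, g, mean)
  ns <- as.integer(table(g))
  tt <- tryCatch(t.test(values ~ g, var.equal = var_equal),
                 error = function(e) NULL)
  if (is.null(tt))
    return(list(t = NA_real_, p = NA_real_, df = NA_real_,
                means = means, n = setNames(ns, levels(g))))
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), means = means,
       n = setNames(ns, levels(g)))
}

#' ROC curve and AUC for a quantitative marker
#'
#' AUC is the Mann-Whitney rank statistic — the probability that a random
#' positive outranks a random negative, ties counted 1/2 — which equals
#' the trapezoidal area under the empirical ROC curve. The full
#' sensitivity/specificity curve over all observed thresholds is
#' returned.
#'
#' @param marker_values Numeric marker (higher = more positive-like).
#' @param binary_labels Logical or 0/1 labels; both classes must occur.
#' @return List of class `roc_report`: auc, n_pos, n_neg, and `curve`
#'   (data.frame threshold, sensitivity, specificity).
#' @export
roc_auc <- function(marker_values, binary_labels) {
  lab <- as.logical(binary_labels)
  if (any(is.na(lab)) || length(unique(lab)) < 2)
    stop_bad("binary_labels must contain both classes")
  n1 <- sum(lab); n0 <- sum(!lab)
  r <- rank(marker_values)
  auc <- (sum(r[lab]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(marker_values), decreasing = TRUE))
  sens <- vapply(thr, function(t) mean(marker_values[lab] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(marker_values[!lab] < t), numeric(1))
  structure(list(auc = auc, n_pos = n1, n_neg = n0,
                 curve = data.frame(threshold = thr, sensitivity = sens,
                                    specificity = spec)),
            class = "roc_report")
}

#' @export
print.roc_report <- function(x, ...) {
  cat(sprintf("ROC report: AUC = %.3f (%d positives, %d negatives)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Two-step validation of a copy-number / CAS association
#'
#' Runs the three grouped comparisons used to validate a candidate
#' marker region:
#' mode A — CAS extremes (MAP vs LAP by `n_top`/`n_bottom`) compared on
#' copy number; mode B — median split by copy number, compared on CAS;
#' mode C — median split by CAS, compared on copy number (the variant
#' used for a qPCR population). With odd n the larger half is the "top"
#' half. All three modes are reported.
#'
#' @param cn_values Per-pig copy numbers.
#' @param cas_values Per-pig CAS, same order.
#' @param pig_id Optional ids (used in deterministic tie-breaking).
#' @param n_top,n_bottom Extreme-group sizes for mode A (defaults: a
#'   median split).
#' @return data.frame with one row per mode: mode, compared, n_high,
#'   n_low, mean_high, mean_low, t, p.
#' @export
two_step_validation <- function(cn_values, cas_values, pig_id = NULL,
                                n_top = NULL, n_bottom = NULL) {
  n <- length(cn_values)
  stopifnot(length(cas_values) == n)
  id <- as.character(pig_id %||% seq_len(n))
  n_top <- n_top %||% ceiling(n / 2)
  n_bottom <- n_bottom %||% floor(n / 2)

  split_by <- function(v, k_top, k_bottom = n - k_top) {
    ord <- order(-v, id)
    half <- rep(NA_character_, n)
    half[ord[seq_len(k_top)]] <- "high"
    half[ord[seq.int(n - k_bottom + 1L, n)]] <- "low"
    factor(half, levels = c("high", "low"))
  }
  run <- function(mode, split_values, compare_values, compared,
                  k_top, k_bottom) {
    g <- split_by(split_values, k_top, k_bottom)
    keep <- !is.na(g)
    res <- group_compare(compare_values[keep], g[keep])
    data.frame(mode = mode, compared = compared,
               n_high = res$n[["high"]], n_low = res$n[["low"]],
               mean_high = unname(res$means["high"]),
               mean_low = unname(res$means["low"]),
               t = res$t, p = res$p, stringsAsFactors = FALSE)
  }
  out <- rbind(
    run("A_extremes_by_cas", cas_values, cn_values, "copy_number",
        n_top, n_bottom),
    run("B_median_split_by_cn", cn_values, cas_values, "cas",
        ceiling(n / 2), floor(n / 2)),
    run("C_median_split_by_cas", cas_values, cn_values, "copy_number",
        ceiling(n / 2), floor(n / 2)))
  rownames(out) <- NULL
  out
}
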