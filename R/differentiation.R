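#' V_ST copy-number differentiation between two groups
#'
#' V_ST contrasts the pooled copy-number variance with the size-weighted
#' within-group variances:
#' \deqn{V_{ST} = \frac{V_{total} - (V_m N_m + V_l N_l)/N_{total}}{V_{total}}}
#' where \eqn{V_{total}} is the variance of the pooled values and
#' \eqn{V_m, V_l} the within-group variances. With population
#' (divide-by-N) variances — the default — two internally constant groups
#' with different means give exactly 1, and identical groups give 0.
#' Slightly negative finite-sample values are preserved, not clipped.
#'
#' @param values_m,values_l Copy numbers of the two groups (each length
#'   >= 2).
#' @param estimator "population" (divide by N, default) or "sample"
#'   (divide by N-1).
#' @return List: `vst`, `v_total`, `v_m`, `v_l`, `n_m`, `n_l`, `n_total`.
#'   `vst` is NA when the pooled variance is zero (undefined, reported
#'   missing rather than 0).
#' @examples
#' vst(c(2, 2, 2, 4), c(2, 2, 2, 2))$vst # 1/7
#' @export
vst <- function(values_m, values_l,
                estimator = c("population", "sample")) {
  estimator <- match.arg(estimator)
  n_m <- length(values_m); n_l <- length(values_l)
  if (n_m < 2 || n_l < 2) stop_bad("each group needs at least 2 values")
  vfun <- if (estimator == "population") pop_var else var
  v_m <- vfun(values_m)
  v_l <- vfun(values_l)
  v_total <- vfun(c(values_m, values_l))
  n_total <- n_m + n_l
  v <- if (v_total > 0)
    (v_total - (v_m * n_m + v_l * n_l) / n_total) / v_total
  else NA_real_
  list(vst = v, v_total = v_total, v_m = v_m, v_l = v_l,
       n_m = n_m, n_l = n_l, n_total = n_total)
}

#' V_ST scan over a CNVR copy-number matrix
#'
#' Computes V_ST for every CNVR, ranks regions by descending V_ST (ties
#' broken by region name), and flags the top 1%. The flagged count is
#' `max(1, floor(0.01 * n_ranked))` over regions with a defined V_ST —
#' e.g. 68 of 6869. Regions with zero pooled variance get NA and are
#' excluded from ranking.
#'
#' @param cn CNVRs x individuals copy-number matrix (rownames = CNVR
#'   names).
#' @param groups Group labels ("MAP"/"LAP" or any two levels) along the
#'   columns of `cn`, or named by individual.
#' @param top_fraction Fraction flagged (default 0.01).
#' @param estimator Passed to [vst()].
#' @return data.frame: name, vst, v_total, v_m, v_l, rank, top_1pct,
#'   sorted by rank (NA V_ST last).
#' @export
vst_scan <- function(cn, groups, top_fraction = 0.01,
                     estimator = c("population", "sample")) {
  estimator <- match.arg(estimator)
  stopifnot(is.matrix(cn))
  groups <- align_labels(groups, colnames(cn))
  lev <- unique(groups[!is.na(groups) & groups != "unselected"])
  if (length(lev) != 2)
    stop_bad("groups must have exactly two levels, got: %s",
             paste(lev, collapse = ", "))
  im <- which(groups == lev[1]); il <- which(groups == lev[2])
  if (length(im) < 2 || length(il) < 2)
    stop_bad("each group needs at least 2 individuals")
  vfun <- if (estimator == "population") row_pop_var else
    function(m) apply(m, 1, var)
  v_m <- vfun(cn[, im, drop = FALSE])
  v_l <- vfun(cn[, il, drop = FALSE])
  v_tot <- vfun(cn[, c(im, il), drop = FALSE])
  n_m <- length(im); n_l <- length(il); n_t <- n_m + n_l
  v <- ifelse(v_tot > 0,
              (v_tot - (v_m * n_m + v_l * n_l) / n_t) / v_tot, NA_real_)
  nm <- rownames(cn) %||% sprintf("CNVR-%d", seq_len(nrow(cn)))
  df <- data.frame(name = nm, vst = v, v_total = v_tot, v_m = v_m,
                   v_l = v_l, stringsAsFactors = FALSE)
  ord <- order(-df$vst, df$name, na.last = TRUE)
  df <- df[ord, , drop = FALSE]
  n_ranked <- sum(!is.na(df$vst))
  df$rank <- NA_integer_
  df$rank[seq_len(n_ranked)] <- seq_len(n_ranked)
  n_top <- if (n_ranked > 0) max(1L, floor(top_fraction * n_ranked)) else 0L
  df$top_1pct <- !is.na(df$rank) & df$rank <= n_top
  rownames(df) <- NULL
  df
}

#' @noRd
align_labels <- function(groups, ids) {
  groups <- as.character(groups)
  if (!is.null(names(groups)) && !is.null(ids)) {
    if (!all(ids %in% names(groups)))
      stop_bad("group labels missing for: %s",
               paste(setdiff(ids, names(groups)), collapse = ", "))
    groups <- groups[ids]
  }
  groups
}

#' Genomic relationship (kinship) matrix from copy-number dosages
#'
#' Standardized-dosage GRM: each CNVR's copy numbers are centered and
#' scaled to unit (population) variance, and K = Z Z' / m over the m
#' informative CNVRs. The mean of the diagonal is exactly 1 by
#' construction; zero-variance CNVRs are dropped.
#'
#' @param cn CNVRs x individuals copy-number matrix.
#' @return n x n symmetric positive semi-definite matrix with individual
#'   dimnames.
#' @export
kinship_matrix <- function(cn) {
  stopifnot(is.matrix(cn))
  v <- row_pop_var(cn)
  keep <- v > 0
  if (!any(keep)) stop_bad("all CNVRs have constant copy number")
  z <- (cn[keep, , drop = FALSE] - rowMeans(cn[keep, , drop = FALSE])) /
    sqrt(v[keep])
  m <- nrow(z)
  K <- crossprod(z) / m
  dimnames(K) <- list(colnames(cn), colnames(cn))
  K
}

#' Mixed linear model association scan over CNVRs
#'
#' Fits, for each CNVR, the single-marker mixed model
#' `y = X a + w b + g + e` with `g ~ N(0, sg^2 K)` and `e ~ N(0, se^2 I)`,
#' where `y` is the phenotype (e.g. CAS), `X` holds the intercept and
#' fixed covariates (batch, sex), and `w` is the CNVR copy-number dosage.
#' The variance ratio `delta = se^2/sg^2` is estimated once by exact
#' REML on the null model via the eigendecomposition of K (the
#' EMMA/EMMAX strategy), then each CNVR is tested by generalized least
#' squares with a Wald t-test on `b`. With `K = I` the model collapses
#' exactly to ordinary least squares.
#'
#' @param phenotype Numeric phenotype vector (optionally named by
#'   individual).
#' @param cn CNVRs x individuals copy-number matrix.
#' @param K Kinship matrix from [kinship_matrix()] (or identity).
#' @param fixed_effects Optional data.frame of covariates (factors or
#'   numeric), rows along individuals.
#' @param coding How copy numbers enter the marker column: "dosage"
#'   (continuous copy number, default) or "absdev" (absolute deviation
#'   from the diploid 2, an alternative for mixed loss/gain regions
#'   where the direction of change differs between carriers).
#' @return data.frame: name, beta, se, t, p (one row per CNVR; constant
#'   CNVRs get NA), with the variance components in
#'   `attr(, "varcomp")`: sigma_g2, sigma_e2, delta.
#' @export
mlm_gwas <- function(phenotype, cn, K, fixed_effects = NULL,
                     coding = c("dosage", "absdev")) {
  coding <- match.arg(coding)
  stopifnot(is.matrix(cn), is.matrix(K))
  if (coding == "absdev") cn <- abs(cn - 2)
  n <- length(phenotype)
  if (ncol(cn) != n || nrow(K) != n || ncol(K) != n)
    stop_bad("dimension mismatch: phenotype %d, cn columns %d, K %dx%d",
             n, ncol(cn), nrow(K), ncol(K))
  if (!is.null(fixed_effects)) {
    stopifnot(nrow(fixed_effects) == n)
    X <- stats::model.matrix(~ ., data = fixed_effects)
  } else {
    X <- matrix(1, n, 1)
  }
  p0 <- ncol(X)
  if (n < p0 + 2) stop_bad("n (%d) too small for %d fixed effects", n, p0)

  eg <- eigen(K, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  Ut <- t(eg$vectors)
  yt <- drop(Ut %*% phenotype)
  Xt <- Ut %*% X

  reml_ll <- function(log_delta) {
    w <- 1 / (lam + exp(log_delta))
    XtWX <- crossprod(Xt * w, Xt)
    beta <- solve(XtWX, crossprod(Xt * w, yt))
    r <- yt - drop(Xt %*% beta)
    rss <- sum(w * r * r)
    np <- n - p0
    -0.5 * (np * log(rss / np) + sum(log(lam + exp(log_delta))) +
              determinant(XtWX, logarithm = TRUE)$modulus[1])
  }
  opt <- optimize(reml_ll, c(log(1e-5), log(1e5)), maximum = TRUE)
  delta <- exp(opt$maximum)
  w <- 1 / (lam + delta)
  np <- n - p0
  XtWX <- crossprod(Xt * w, Xt)
  beta0 <- solve(XtWX, crossprod(Xt * w, yt))
  rss0 <- sum(w * (yt - drop(Xt %*% beta0))^2)
  sigma_g2 <- rss0 / np
  sigma_e2 <- sigma_g2 * delta

  dfree <- n - p0 - 1L
  res <- matrix(NA_real_, nrow(cn), 4,
                dimnames = list(NULL, c("beta", "se", "t", "p")))
  sw <- sqrt(w)
  Xs <- Xt * sw
  ys <- yt * sw
  for (j in seq_len(nrow(cn))) {
    if (pop_var(cn[j, ]) == 0) next
    wt <- drop(Ut %*% cn[j, ]) * sw
    M <- cbind(Xs, wt)
    f <- .lm.fit(M, ys)
    rss <- sum(f$residuals^2)
    XtX_inv_last <- tryCatch(
      chol2inv(chol(crossprod(M)))[p0 + 1L, p0 + 1L],
      error = function(e) NA_real_)
    if (is.na(XtX_inv_last)) next
    b <- f$coefficients[p0 + 1L]
    s2 <- rss / dfree
    se <- sqrt(s2 * XtX_inv_last)
    tval <- b / se
    res[j, ] <- c(b, se, tval, 2 * pt(-abs(tval), dfree))
  }
  out <- data.frame(name = rownames(cn) %||%
                      sprintf("CNVR-%d", seq_len(nrow(cn))),
                    res, stringsAsFactors = FALSE)
  attr(out, "varcomp") <- c(sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
                            delta = delta)
  rownames(out) <- NULL
  out
}
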