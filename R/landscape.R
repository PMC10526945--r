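#' Descriptive statistics of a CNVR set
#'
#' Summarizes a CNVR map the way CNV surveys report it: counts by type,
#' total span and genome fraction, a length histogram, mean length per
#' type, and a carrier-frequency histogram.
#'
#' @param cnvrs data.frame with chrom, start, end (0-based half-open),
#'   type, carrier_count.
#' @param chromosome_lengths Named numeric vector (bp per chromosome) or a
#'   data.frame with columns chrom, length. Every chromosome appearing in
#'   `cnvrs` must be present.
#' @param length_breaks_kb Interior breakpoints (kb) of the length bins;
#'   default `c(5, 10, 100)` gives <5 Kb, 5-10 Kb, 10-100 Kb, >100 Kb
#'   (half-open on the left bin edge).
#' @param freq_breaks Upper edges of the carrier-count bins; default
#'   `c(4, 10, 15, 20)` gives 1-4, 5-10, 11-15, 16-20, >20 pigs.
#' @return A list of class `landscape_summary`: `n_cnvrs`,
#'   `counts_by_type`, `total_span_bp`, `genome_fraction_pct`,
#'   `length_bins`, `mean_length_by_type`, `freq_bins`.
#' @export
summarize_landscape <- function(cnvrs, chromosome_lengths,
                                length_breaks_kb = c(5, 10, 100),
                                freq_breaks = c(4, 10, 15, 20)) {
  check_intervals(cnvrs, "cnvrs")
  lens <- chrom_length_vector(chromosome_lengths)
  missing <- setdiff(unique(cnvrs$chrom), names(lens))
  if (length(missing))
    stop_bad("chromosomes in CNVRs absent from lengths table: %s",
             paste(missing, collapse = ", "))
  len <- cnvrs$end - cnvrs$start
  total_span <- sum(len)
  genome <- sum(lens)

  lb <- c(0, length_breaks_kb * 1000, Inf)
  lab <- c(sprintf("<%g Kb", length_breaks_kb[1]),
           sprintf("%g-%g Kb", head(length_breaks_kb, -1),
                   length_breaks_kb[-1]),
           sprintf(">%g Kb", length_breaks_kb[length(length_breaks_kb)]))
  lbin <- cut(len, breaks = lb, labels = lab, right = FALSE)
  length_bins <- data.frame(bin = lab, count = as.integer(table(lbin)[lab]),
                            stringsAsFactors = FALSE)
  length_bins$pct <- if (nrow(cnvrs)) 100 * length_bins$count / nrow(cnvrs) else NA_real_

  fb <- c(0, freq_breaks, Inf)
  flab <- c(sprintf("%d-%d", c(1, head(freq_breaks, -1) + 1), freq_breaks),
            sprintf(">%d", freq_breaks[length(freq_breaks)]))
  fbin <- cut(cnvrs$carrier_count, breaks = fb, labels = flab, right = TRUE)
  freq_bins <- data.frame(bin = flab, count = as.integer(table(fbin)[flab]),
                          stringsAsFactors = FALSE)
  freq_bins$pct <- if (nrow(cnvrs)) 100 * freq_bins$count / nrow(cnvrs) else NA_real_

  structure(list(
    n_cnvrs = nrow(cnvrs),
    counts_by_type = table(factor(cnvrs$type, levels = c("loss", "gain", "both"))),
    total_span_bp = total_span,
    genome_fraction_pct = 100 * total_span / genome,
    length_bins = length_bins,
    mean_length_by_type = tapply(len, factor(cnvrs$type,
                                 levels = c("loss", "gain", "both")), mean),
    freq_bins = freq_bins
  ), class = "landscape_summary")
}

#' @noRd
chrom_length_vector <- function(chromosome_lengths) {
  if (is.data.frame(chromosome_lengths)) {
    stopifnot(all(c("chrom", "length") %in% names(chromosome_lengths)))
    return(setNames(chromosome_lengths$length,
                    as.character(chromosome_lengths$chrom)))
  }
  if (is.null(names(chromosome_lengths)))
    stop_bad("chromosome_lengths must be named or a chrom/length data.frame")
  chromosome_lengths
}

#' Chromosome-level regressions of CNVR burden
#'
#' Fits the four simple least-squares regressions used to describe how
#' CNVRs distribute over a genome: CNVR count on chromosome length, total
#' CNVR span per chromosome on CNVR count, mean CNVR length on chromosome
#' length, and (if `per_individual` is given) per-individual CNVR count on
#' mean sequencing depth.
#'
#' @param cnvrs CNVR table (chrom, start, end).
#' @param chromosome_lengths Named vector or chrom/length data.frame;
#'   chromosomes without CNVRs contribute zero counts.
#' @param per_individual Optional data.frame with columns `individual`,
#'   `mean_depth`, `n_cnvrs` for the depth regression.
#' @return data.frame with one row per model: model, n, slope, intercept,
#'   r, p. A zero-variance predictor is flagged by `degenerate = TRUE` and
#'   NA slope/r/p.
#' @export
chromosome_regressions <- function(cnvrs, chromosome_lengths,
                                   per_individual = NULL) {
  check_intervals(cnvrs, "cnvrs")
  lens <- chrom_length_vector(chromosome_lengths)
  if (length(lens) < 3) stop_bad("need at least 3 chromosomes")
  chroms <- names(lens)
  cnt <- as.numeric(table(factor(cnvrs$chrom, levels = chroms)))
  span <- vapply(chroms, function(ch) {
    i <- cnvrs$chrom == ch
    sum(cnvrs$end[i] - cnvrs$start[i])
  }, numeric(1))
  mlen <- ifelse(cnt > 0, span / cnt, NA_real_)

  fits <- list(
    count_vs_chrom_length = list(y = cnt, x = as.numeric(lens)),
    span_vs_count = list(y = as.numeric(span), x = cnt),
    mean_length_vs_chrom_length = list(y = mlen, x = as.numeric(lens))
  )
  if (!is.null(per_individual)) {
    stopifnot(all(c("mean_depth", "n_cnvrs") %in% names(per_individual)))
    fits$count_vs_depth <- list(y = per_individual$n_cnvrs,
                                x = per_individual$mean_depth)
  }
  out <- lapply(names(fits), function(nm) {
    x <- fits[[nm]]$x; y <- fits[[nm]]$y
    keep <- complete.cases(x, y)
    x <- x[keep]; y <- y[keep]
    if (length(x) < 3 || var(x) == 0) {
      return(data.frame(model = nm, n = length(x), slope = NA_real_,
                        intercept = NA_real_, r = NA_real_, p = NA_real_,
                        degenerate = TRUE, stringsAsFactors = FALSE))
    }
    fit <- lm(y ~ x)
    sm <- summary(fit)
    data.frame(model = nm, n = length(x), slope = coef(fit)[[2]],
               intercept = coef(fit)[[1]],
               r = sign(coef(fit)[[2]]) * sqrt(sm$r.squared),
               p = sm$coefficients[2, 4],
               degenerate = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Count members of one interval set overlapped by another
#'
#' Two regions overlap when they share at least one base pair; with
#' 0-based half-open coordinates, abutting regions (`end == start`) do
#' not. The percentage is relative to `set_a`, matching the convention of
#' cross-study CNVR comparisons.
#'
#' @param set_a,set_b data.frames with chrom, start, end (0-based
#'   half-open).
#' @return List: `n_a`, `n_a_overlapped`, `percent_of_a`, and the logical
#'   vector `overlapped` along `set_a` rows.
#' @export
overlap_sets <- function(set_a, set_b) {
  check_intervals(set_a, "set_a")
  check_intervals(set_b, "set_b")
  if (nrow(set_a) == 0)
    return(list(n_a = 0L, n_a_overlapped = 0L, percent_of_a = NA_real_,
                overlapped = logical()))
  hit <- if (nrow(set_b)) {
    # disjoint chromosome universes are expected when comparing maps
    suppressWarnings(
      IRanges::overlapsAny(as_granges0(set_a), as_granges0(set_b),
                           minoverlap = 1L))
  } else rep(FALSE, nrow(set_a))
  list(n_a = nrow(set_a), n_a_overlapped = sum(hit),
       percent_of_a = 100 * sum(hit) / nrow(set_a), overlapped = hit)
}
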