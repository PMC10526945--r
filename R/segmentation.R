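#' Normalize a window read-depth matrix to diploid-scaled copy numbers
#'
#' Each individual's window depths are divided by that individual's median
#' window depth and doubled, so an individual's genome-wide median copy
#' number is 2 by construction. This is the usual read-depth assumption:
#' depth proportional to copy number, most of the genome diploid.
#'
#' @param depth A `depth_matrix` as returned by [read_depth_matrix()] /
#'   [simulate_cohort()]: list with `windows` (chrom, start, end) and
#'   `depth` (windows x individuals numeric matrix).
#' @return A `copy_number_matrix`: list with the same `windows` and a `cn`
#'   matrix of diploid-scaled copy numbers.
#' @export
normalize_depth <- function(depth) {
  stopifnot(is.list(depth), !is.null(depth$windows), !is.null(depth$depth))
  d <- depth$depth
  med <- apply(d, 2, median)
  bad <- colnames(d)[!is.finite(med) | med <= 0]
  if (length(bad))
    stop_bad("individuals with non-positive median depth: %s",
             paste(bad, collapse = ", "))
  cn <- 2 * sweep(d, 2, med, "/")
  structure(list(windows = depth$windows, cn = cn),
            class = "copy_number_matrix")
}

#' Classify a diploid-scaled copy number as loss / normal / gain
#'
#' Copy number at or below 1.5 is a loss, at or above 2.5 a gain,
#' strictly between is normal. The boundary values go to loss/gain, since
#' those thresholds are stated inclusively.
#'
#' @param cn Non-negative numeric vector of copy numbers.
#' @return Character vector in {"loss", "normal", "gain"}.
#' @examples
#' classify_copy_number(c(1.5, 2, 2.5)) # loss normal gain
#' @export
classify_copy_number <- function(cn) {
  if (any(is.na(cn)) || any(cn < 0))
    stop_bad("copy numbers must be non-negative and non-missing")
  ifelse(cn <= 1.5, "loss", ifelse(cn >= 2.5, "gain", "normal"))
}

#' Assemble typed CNV regions from a copy-number matrix
#'
#' A window is variant when at least `min_carriers` individuals are
#' non-normal there ([classify_copy_number()]). Maximal runs of variant
#' windows on a chromosome — allowing up to `max_gap_windows` intervening
#' non-variant windows — become candidate regions; regions shorter than
#' `min_length` bp are dropped. A region is typed `loss` if only losses
#' are observed over its member windows, `gain` if only gains, and `both`
#' when both occur. The per-region carrier count is the number of
#' individuals whose mean copy number over the region is non-normal, and
#' regions are named CNVR-1, CNVR-2, ... in chromosome-position order.
#'
#' @param cnmat A `copy_number_matrix` from [normalize_depth()].
#' @param min_carriers Minimum non-normal individuals for a window to be
#'   variant (default 1).
#' @param max_gap_windows Non-variant windows tolerated inside a run
#'   (default 0).
#' @param min_length Minimum region length in bp (default 1500, i.e. at
#'   least two 800-bp windows).
#' @return A list with `cnvrs` (data.frame: name, chrom, start, end, type,
#'   carrier_count) and `cn` (regions x individuals matrix of mean copy
#'   number over member windows, rownames = region names).
#' @export
call_cnvrs <- function(cnmat, min_carriers = 1L, max_gap_windows = 0L,
                       min_length = 1500L) {
  stopifnot(is.list(cnmat), !is.null(cnmat$windows), !is.null(cnmat$cn))
  if (min_carriers < 1L) stop_bad("min_carriers must be >= 1")
  win <- cnmat$windows
  cn <- cnmat$cn
  n_nonnormal <- rowSums(cn <= 1.5 | cn >= 2.5)
  variant <- n_nonnormal >= min_carriers

  regions <- list()
  for (chr in unique(win$chrom)) {
    idx <- which(win$chrom == chr)
    for (r in variant_runs(variant[idx], max_gap_windows)) {
      wi <- idx[r]
      start <- win$start[wi[1L]]
      end <- win$end[wi[length(wi)]]
      if (end - start < min_length) next
      sub <- cn[wi, , drop = FALSE]
      any_loss <- any(sub <= 1.5)
      any_gain <- any(sub >= 2.5)
      type <- if (any_loss && any_gain) "both" else if (any_loss) "loss" else "gain"
      mean_cn <- colMeans(sub)
      carrier_count <- sum(mean_cn <= 1.5 | mean_cn >= 2.5)
      regions[[length(regions) + 1L]] <- list(
        chrom = chr, start = start, end = end, type = type,
        carrier_count = carrier_count, mean_cn = mean_cn)
    }
  }
  if (!length(regions)) {
    return(list(
      cnvrs = data.frame(name = character(), chrom = character(),
                         start = integer(), end = integer(),
                         type = character(), carrier_count = integer(),
                         stringsAsFactors = FALSE),
      cn = matrix(numeric(), 0, ncol(cn), dimnames = list(NULL, colnames(cn)))))
  }
  df <- data.frame(
    chrom = vapply(regions, `[[`, character(1), "chrom"),
    start = vapply(regions, `[[`, numeric(1), "start"),
    end = vapply(regions, `[[`, numeric(1), "end"),
    type = vapply(regions, `[[`, character(1), "type"),
    carrier_count = vapply(regions, `[[`, numeric(1), "carrier_count"),
    stringsAsFactors = FALSE)
  ord <- order(df$chrom, df$start)
  cnr <- do.call(rbind, lapply(regions[ord], `[[`, "mean_cn"))
  df <- df[ord, , drop = FALSE]
  df <- data.frame(name = sprintf("CNVR-%d", seq_len(nrow(df))), df,
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  rownames(cnr) <- df$name
  list(cnvrs = df, cn = cnr)
}

# Group indices of TRUE windows into runs, merging runs separated by at
# most `gap` FALSE windows. Runs start and end on a TRUE window.
#' @noRd
variant_runs <- function(v, gap = 0L) {
  iv <- which(v)
  if (!length(iv)) return(list())
  brk <- c(0L, which(diff(iv) > gap + 1L), length(iv))
  lapply(seq_len(length(brk) - 1L),
         function(k) seq.int(iv[brk[k] + 1L], iv[brk[k + 1L]]))
}
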