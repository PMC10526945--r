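`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_bad <- function(...) stop(sprintf(...), call. = FALSE)

#' Population (divide-by-N) variance
#' @noRd
pop_var <- function(x) {
  n <- length(x)
  if (n == 0L) return(NA_real_)
  sum((x - mean(x))^2) / n
}

#' Row-wise population variance of a matrix
#' @noRd
row_pop_var <- function(m) {
  mu <- rowMeans(m)
  rowMeans(m * m) - mu * mu
}

#' Validate a CNVR interval table (chrom/start/end, 0-based half-open)
#' @noRd
check_intervals <- function(x, what = "intervals") {
  need <- c("chrom", "start", "end")
  if (!is.data.frame(x) || !all(need %in% names(x)))
    stop_bad("%s must be a data.frame with columns chrom, start, end", what)
  if (nrow(x) && any(x$end - x$start <= 0))
    stop_bad("%s contain non-positive widths; expected 0-based half-open coordinates",
             what)
  invisible(x)
}

#' GRanges from a 0-based half-open interval table
#' @noRd
as_granges0 <- function(x) {
  GenomicRanges::GRanges(
    seqnames = as.character(x$chrom),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

#' Derive a component sub-seed from a master seed, kept inside 32-bit range
#' @noRd
sub_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + offset
}
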