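#' Read a windowed depth (or copy-number) matrix TSV
#'
#' First column `window` holds `chrom:start-end` in 0-based half-open
#' coordinates; remaining columns are individuals.
#'
#' @param path TSV file.
#' @return A `depth_matrix` list: `windows` (chrom, start, end) and
#'   `depth` (windows x individuals matrix).
#' @export
read_depth_matrix <- function(path) {
  x <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(x)[1] != "window")
    stop_bad("first column of %s must be 'window' (chrom:start-end)", path)
  m <- regmatches(x$window, regexec("^(.+):([0-9]+)-([0-9]+)$", x$window))
  if (any(lengths(m) != 4)) stop_bad("malformed window ids in %s", path)
  windows <- data.frame(
    chrom = vapply(m, `[`, character(1), 2),
    start = as.integer(vapply(m, `[`, character(1), 3)),
    end = as.integer(vapply(m, `[`, character(1), 4)),
    stringsAsFactors = FALSE)
  depth <- as.matrix(x[, -1, drop = FALSE])
  structure(list(windows = windows, depth = depth), class = "depth_matrix")
}

#' Write a depth or copy-number matrix TSV
#' @param x A `depth_matrix` or `copy_number_matrix`.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_depth_matrix <- function(x, path) {
  m <- x$depth %||% x$cn
  df <- data.frame(window = sprintf("%s:%d-%d", x$windows$chrom,
                                    x$windows$start, x$windows$end),
                   m, check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write CNVRs as a BED6+1 file
#'
#' Columns: chrom, start, end, name, score (carrier count), strand "."
#' and type; 0-based half-open, matching BED.
#'
#' @param cnvrs CNVR table from [call_cnvrs()].
#' @param path Output BED.
#' @return `path`, invisibly.
#' @export
write_cnvr_bed <- function(cnvrs, path) {
  check_intervals(cnvrs, "cnvrs")
  bed <- data.frame(cnvrs$chrom, cnvrs$start, cnvrs$end, cnvrs$name,
                    cnvrs$carrier_count %||% 0L, ".",
                    cnvrs$type %||% ".", stringsAsFactors = FALSE)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a CNVR BED6+1 file written by [write_cnvr_bed()]
#' @param path BED file.
#' @return data.frame: name, chrom, start, end, type, carrier_count.
#' @export
read_cnvr_bed <- function(path) {
  x <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(x) < 4) stop_bad("%s does not look like a CNVR BED file", path)
  data.frame(name = x[[4]], chrom = as.character(x[[1]]), start = x[[2]],
             end = x[[3]],
             type = if (ncol(x) >= 7) x[[7]] else NA_character_,
             carrier_count = if (ncol(x) >= 5) x[[5]] else NA_integer_,
             stringsAsFactors = FALSE)
}

#' Read a chromosome-length table
#'
#' Two-column TSV (chrom, length). The package ships the Sscrofa 11.1
#' chromosome lengths (autosomes 1-18 plus X) at
#' `system.file("extdata", "sscrofa11_chrom_lengths.tsv", package =
#' "cnvrscan")`.
#'
#' @param path TSV file with columns chrom, length.
#' @return Named numeric vector of lengths.
#' @export
read_chrom_lengths <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "length") %in% names(x)))
  setNames(as.numeric(x$length), as.character(x$chrom))
}

#' Read an attack-record CSV (pig_id, attack_count, attack_duration_s, ...)
#' @param path CSV file.
#' @return data.frame of attack records.
#' @export
read_attack_records <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("pig_id", "attack_count", "attack_duration_s")
  if (!all(need %in% names(x)))
    stop_bad("attack records need columns: %s", paste(need, collapse = ", "))
  if (any(x$attack_count == 0 & x$attack_duration_s > 0))
    stop_bad("attack_duration_s must be 0 whenever attack_count is 0")
  x
}

#' Read a genes x samples expression TSV
#'
#' Columns gene_id, chrom, start, end then one column per sample.
#' @param path TSV file.
#' @return List: `values` (matrix), `gene_positions` (data.frame).
#' @export
read_expression_matrix <- function(path) {
  x <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "start", "end")
  if (!all(need %in% names(x)))
    stop_bad("expression TSV needs leading columns: %s",
             paste(need, collapse = ", "))
  vals <- as.matrix(x[, setdiff(names(x), need), drop = FALSE])
  rownames(vals) <- x$gene_id
  list(values = vals, gene_positions = x[, need])
}

#' Write a genes x samples expression TSV
#' @param expression List with `values` and `gene_positions` as from
#'   [simulate_expression()].
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expression, path) {
  df <- cbind(expression$gene_positions,
              as.data.frame(expression$values, check.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a qPCR Ct CSV (sample_id, ct_target, ct_reference)
#' @param path CSV file.
#' @return data.frame.
#' @export
read_qpcr_plate <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "ct_target", "ct_reference")
  if (!all(need %in% names(x)))
    stop_bad("qPCR CSV needs columns: %s", paste(need, collapse = ", "))
  x
}
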