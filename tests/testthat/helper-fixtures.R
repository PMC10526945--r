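# shared fixture builders (everything generated in code; no files)

# tiny copy-number matrix with named rows/columns
toy_cn_matrix <- function(n_cnvrs = 5, n_ind = 8, seed = 1, sd = 0.3) {
  set.seed(seed)
  m <- matrix(2 + rnorm(n_cnvrs * n_ind, 0, sd), n_cnvrs, n_ind,
              dimnames = list(sprintf("CNVR-%d", seq_len(n_cnvrs)),
                              sprintf("ind%02d", seq_len(n_ind))))
  m
}

# a depth matrix with a given true copy-number profile and noise
toy_depth <- function(true_cn, mean_depth = 13, noise_sd = 0,
                      window = 800, chrom = "chr1", seed = 1) {
  set.seed(seed)
  n_win <- nrow(true_cn)
  windows <- data.frame(chrom = chrom,
                        start = window * (seq_len(n_win) - 1),
                        end = window * seq_len(n_win))
  mu <- true_cn / 2 * mean_depth
  d <- pmax(mu + matrix(rnorm(length(mu), 0, noise_sd * mean_depth),
                        nrow(mu)), 0)
  colnames(d) <- colnames(true_cn) %||%
    sprintf("ind%02d", seq_len(ncol(true_cn)))
  structure(list(windows = windows, depth = d), class = "depth_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a two-gene model set on one small chromosome for annotation tests
toy_gene_models <- function() {
  genes <- data.frame(
    gene_id = c("gA", "gB"), chrom = c("chr1", "chr1"),
    start = c(10000, 50000), end = c(20000, 60000),
    strand = c("+", "-"), stringsAsFactors = FALSE)
  exons <- data.frame(
    gene_id = c("gA", "gA", "gB"), chrom = "chr1",
    start = c(10000, 18000, 59000), end = c(11000, 20000, 60000),
    stringsAsFactors = FALSE)
  utr5 <- data.frame(gene_id = "gA", chrom = "chr1",
                     start = 10000, end = 10200, stringsAsFactors = FALSE)
  utr3 <- data.frame(gene_id = "gA", chrom = "chr1",
                     start = 19800, end = 20000, stringsAsFactors = FALSE)
  gene_model_set(genes, exons, utr5, utr3)
}

# small cohort config used across tests (fast: cached calibration)
small_config <- function(seed = 1, ...) {
  simulation_config(seed = seed, ...)
}
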