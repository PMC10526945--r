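#' Construct a gene model set
#'
#' Container for the gene features used by positional annotation: gene
#' (transcript) spans, exons, and 5'/3' UTRs, all in 0-based half-open
#' coordinates with strand. The TSS is the `start` of a `+` gene and the
#' `end - 1` position of a `-` gene.
#'
#' @param genes data.frame: gene_id, chrom, start, end, strand ("+"/"-").
#' @param exons data.frame: gene_id, chrom, start, end. Must lie within
#'   their gene span.
#' @param utr5,utr3 Optional data.frames like `exons` for untranslated
#'   regions.
#' @return A list of class `gene_model_set`.
#' @export
gene_model_set <- function(genes, exons = NULL,
                           utr5 = NULL, utr3 = NULL) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand") %in% names(genes)))
  check_intervals(genes, "genes")
  empty <- data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  exons <- exons %||% empty
  utr5 <- utr5 %||% empty
  utr3 <- utr3 %||% empty
  for (nm in c("exons", "utr5", "utr3")) {
    x <- get(nm)
    if (nrow(x)) check_intervals(x, nm)
  }
  if (nrow(exons)) {
    span <- genes[match(exons$gene_id, genes$gene_id), ]
    if (any(is.na(span$gene_id)) ||
        any(exons$start < span$start | exons$end > span$end))
      stop_bad("exons must lie within their gene span")
  }
  structure(list(genes = genes, exons = exons, utr5 = utr5, utr3 = utr3),
            class = "gene_model_set")
}

#' Read gene models from a GFF3 file
#'
#' Extracts gene spans, exons and UTRs from a GFF3 annotation (1-based
#' inclusive on disk, converted to the package's 0-based half-open
#' convention). Features are tied to genes via the `Parent`/`ID`
#' attribute chain collapsed to the enclosing gene where possible, else
#' by coordinate containment.
#'
#' @param path GFF3 file.
#' @return A [gene_model_set()].
#' @export
read_gff3_genes <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop_bad("reading GFF3 requires the rtracklayer package")
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  to0 <- function(d, id) data.frame(
    gene_id = id, chrom = as.character(d$seqnames),
    start = d$start - 1L, end = d$end, stringsAsFactors = FALSE)
  g <- df[df$type == "gene", ]
  if (!nrow(g)) stop_bad("no gene features in %s", path)
  gid <- if (!is.null(g$ID)) as.character(g$ID) else as.character(g$Name)
  genes <- data.frame(gene_id = gid, chrom = as.character(g$seqnames),
                      start = g$start - 1L, end = g$end,
                      strand = as.character(g$strand),
                      stringsAsFactors = FALSE)
  genes$strand[!genes$strand %in% c("+", "-")] <- "+"
  # assign sub-features to genes by containment (robust to transcript nesting)
  assign_gene <- function(d) {
    if (!nrow(d)) return(NULL)
    ov <- suppressWarnings(GenomicRanges::findOverlaps(
      as_granges0(data.frame(chrom = as.character(d$seqnames),
                             start = d$start - 1L, end = d$end)),
      as_granges0(genes), type = "within", select = "first"))
    keep <- !is.na(ov)
    to0(d[keep, , drop = FALSE], genes$gene_id[ov[keep]])
  }
  gene_model_set(
    genes,
    exons = assign_gene(df[df$type == "exon", ]),
    utr5 = assign_gene(df[df$type %in% c("five_prime_UTR", "5UTR"), ]),
    utr3 = assign_gene(df[df$type %in% c("three_prime_UTR", "3UTR"), ])
  )
}

#' Assign each CNVR a single positional category
#'
#' Tests overlap of each region against promoters (a strand-aware window
#' around the TSS), 5' and 3' UTRs, exons and gene bodies, and resolves
#' multiple hits by the fixed priority Promoter > 5' UTR > 3' UTR > Exon
#' > Intron > Distal Intergenic. A region inside a gene span that touches
#' no exon/UTR/promoter is intronic; a region touching no gene feature at
#' all is distal intergenic, so the categories partition the set.
#'
#' @param cnvrs CNVR table (chrom, start, end).
#' @param gene_models A [gene_model_set()].
#' @param promoter_up,promoter_down Promoter window in bp upstream /
#'   downstream of the TSS (defaults 2000 / 500).
#' @param split_utr If `FALSE`, report one joint "3' and 5' UTR" category
#'   instead of separate UTR labels.
#' @return Character vector of categories along `cnvrs` rows.
#' @export
annotate_position <- function(cnvrs, gene_models,
                              promoter_up = 2000, promoter_down = 500,
                              split_utr = TRUE) {
  check_intervals(cnvrs, "cnvrs")
  stopifnot(inherits(gene_models, "gene_model_set"))
  q <- as_granges0(cnvrs)
  g <- gene_models$genes
  hits <- function(tbl) {
    if (is.null(tbl) || !nrow(tbl)) return(rep(FALSE, nrow(cnvrs)))
    suppressWarnings(
      IRanges::overlapsAny(q, as_granges0(tbl), minoverlap = 1L))
  }
  # promoter: [TSS - up, TSS + down) on +, mirrored on -
  prom <- if (nrow(g)) {
    plus <- g$strand != "-"
    data.frame(
      chrom = g$chrom,
      start = pmax(0, ifelse(plus, g$start - promoter_up,
                             g$end - promoter_down)),
      end = ifelse(plus, g$start + promoter_down, g$end + promoter_up),
      stringsAsFactors = FALSE)
  } else NULL
  in_prom <- hits(prom)
  in_u5 <- hits(gene_models$utr5)
  in_u3 <- hits(gene_models$utr3)
  in_exon <- hits(gene_models$exons)
  in_gene <- hits(g)

  cat <- rep("Distal Intergenic", nrow(cnvrs))
  cat[in_gene] <- "Intron"
  cat[in_exon] <- "Exon"
  cat[in_u3] <- if (split_utr) "3' UTR" else "3' and 5' UTR"
  cat[in_u5] <- if (split_utr) "5' UTR" else "3' and 5' UTR"
  cat[in_prom] <- "Promoter"
  cat
}
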