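#' Longest interval spanning k consecutive transposon gaps
#'
#' Given sorted insertion positions inside a gene, finds the longest
#' interval from transposon n to transposon n + k. With boundary padding
#' (default), virtual transposons at -1 and at the gene length are appended
#' so that insertion-free regions at the gene termini — the dominant case
#' for essential domains at 5' or 3' ends — can be spanned. With fewer than
#' k + 1 (augmented) positions the full span is returned.
#'
#' @param positions sorted numeric vector of in-gene positions (0-based bp,
#'   unique coordinates).
#' @param gene_len gene length in bp.
#' @param k number of gaps spanned (default 5).
#' @param pad_boundaries add virtual positions -1 and `gene_len`
#'   (default TRUE).
#' @return list with `start`, `end`, `length` (bp) of the winning interval.
#' @export
longest_k_gap <- function(positions, gene_len, k = 5, pad_boundaries = TRUE) {
  if (k < 1) stop("k must be >= 1")
  p <- sort(unique(as.numeric(positions)))
  if (length(p) && (p[1] < 0 || p[length(p)] >= gene_len))
    stop("positions must lie in [0, gene_len)")
  if (pad_boundaries) p <- c(-1, p, gene_len)
  n <- length(p)
  if (n < k + 1) {
    lo <- if (n) p[1] else 0
    hi <- if (n) p[n] else gene_len
    return(list(start = lo, end = hi, length = hi - lo))
  }
  i <- seq_len(n - k)
  span <- p[i + k] - p[i]
  w <- which.max(span)
  list(start = p[w], end = p[w + k], length = span[w])
}

#' Essential-protein-domain likelihood score for one gene
#'
#' Scores a gene's likelihood of containing a transposon-intolerant
#' (essential) domain: the length of the longest interval between
#' transposon n and transposon n + k, multiplied by the total number of
#' transposons mapping to the gene, divided by the gene length to the power
#' 1.5. A score of 0 is assigned when fewer than `min_tn` transposons map
#' to the gene, when the longest interval is shorter than `min_interval_bp`,
#' or when it covers more than 90% or less than 10% of the gene length; the
#' conditions are checked in that order and the first failure is recorded.
#'
#' Positions entering the gap computation are unique coordinates; two
#' insertions at the same base on opposite strands count as two transposons
#' for `n_tn` but one position geometrically.
#'
#' @param gene_id identifier carried into the result.
#' @param positions in-gene insertion coordinates (0-based bp, strand
#'   ignored).
#' @param gene_len gene length in bp (> 0).
#' @param n_tn total transposons in the gene; defaults to
#'   `length(positions)` and should be supplied when opposite-strand
#'   insertions share coordinates.
#' @param k,pad_boundaries see [longest_k_gap()].
#' @param min_tn,min_interval_bp,fraction_band zero-condition thresholds
#'   (defaults 20 transposons, 300 bp, (0.10, 0.90)).
#' @return one-row data.frame: `gene_id`, `score`, `n_tn`,
#'   `interval_start`, `interval_end`, `interval_length`, `fraction`,
#'   `zero_reason` (one of `none`, `too_few_tn`, `interval_too_short`,
#'   `fraction_out_of_band`).
#' @export
domain_score <- function(gene_id, positions, gene_len, n_tn = NULL,
                         k = 5, pad_boundaries = TRUE,
                         min_tn = 20, min_interval_bp = 300,
                         fraction_band = c(0.10, 0.90)) {
  if (gene_len <= 0) stop("gene length must be > 0")
  if (is.null(n_tn)) n_tn <- length(positions)
  gap <- longest_k_gap(positions, gene_len, k = k, pad_boundaries = pad_boundaries)
  fraction <- gap$length / gene_len
  zero_reason <- "none"
  if (n_tn < min_tn) {
    zero_reason <- "too_few_tn"
  } else if (gap$length < min_interval_bp) {
    zero_reason <- "interval_too_short"
  } else if (fraction <= fraction_band[1] || fraction >= fraction_band[2]) {
    zero_reason <- "fraction_out_of_band"
  }
  score <- if (zero_reason == "none") gap$length * n_tn / gene_len^1.5 else 0
  data.frame(gene_id = gene_id, score = score, n_tn = n_tn,
             interval_start = gap$start, interval_end = gap$end,
             interval_length = gap$length, fraction = fraction,
             zero_reason = zero_reason, stringsAsFactors = FALSE)
}

#' Score every gene of a library for essential domains
#'
#' @param library an [insertion_library()].
#' @param genes gene table from [load_annotation()].
#' @param ... passed to [domain_score()] (k, thresholds, padding).
#' @return data.frame with one [domain_score()] row per gene.
#' @export
score_domains <- function(library, genes, ...) {
  ins <- library$insertions
  gene_gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1, genes$end))
  ins_gr <- GenomicRanges::GRanges(
    ins$chrom, IRanges::IRanges(ins$position + 1, ins$position + 1))
  hits <- GenomicRanges::findOverlaps(ins_gr, gene_gr, ignore.strand = TRUE)
  by_gene <- split(S4Vectors::queryHits(hits), S4Vectors::subjectHits(hits))
  res <- lapply(seq_len(nrow(genes)), function(i) {
    idx <- by_gene[[as.character(i)]]
    pos <- if (is.null(idx)) numeric(0) else ins$position[idx] - genes$start[i]
    domain_score(genes$gene_id[i], unique(pos), genes$end[i] - genes$start[i],
                 n_tn = length(idx), ...)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Rank genes by domain likelihood score
#'
#' Descending score; ties and zero scores fall back to gene id order, so
#' zero-score genes come last in annotation order.
#'
#' @param results data.frame from [score_domains()].
#' @return the same rows reordered.
#' @export
rank_genes <- function(results) {
  out <- results[order(-results$score, results$gene_id), ]
  rownames(out) <- NULL
  out
}

#' Write domain scores as TSV
#'
#' @param results table from [score_domains()].
#' @param path output file.
#' @export
write_domain_scores <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
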