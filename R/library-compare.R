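#' Per-gene counts of two libraries, side by side
#'
#' The per-gene table behind pairwise library scatters. With
#' `metric = "transposons"` it compares insertion-site counts (negative
#' selection: genes required in one condition lose transposons); with
#' `metric = "reads"` it compares sequencing-read counts (positive
#' selection: resistant insertion mutants outgrow the culture and dominate
#' reads).
#'
#' @param lib_a,lib_b two [insertion_library()] objects.
#' @param genes gene table from [load_annotation()].
#' @param metric `"transposons"` or `"reads"`.
#' @return data.frame with `gene_id`, raw `count_a`, `count_b`, and
#'   library-size-normalized `norm_a`, `norm_b`, plus `ratio_b_over_a`
#'   computed on normalized counts (NA where `norm_a` is 0).
#' @export
pairwise_scatter_table <- function(lib_a, lib_b, genes,
                                   metric = c("transposons", "reads")) {
  metric <- match.arg(metric)
  sa <- count_per_gene(lib_a, genes)
  sb <- count_per_gene(lib_b, genes)
  if (!identical(sa$gene_id, sb$gene_id))
    stop("annotation mismatch between libraries")
  col <- if (metric == "transposons") "tn" else "reads"
  ncol_ <- if (metric == "transposons") "norm_tn" else "norm_reads"
  out <- data.frame(gene_id = sa$gene_id,
                    count_a = sa[[col]], count_b = sb[[col]],
                    norm_a = sa[[ncol_]], norm_b = sb[[ncol_]],
                    stringsAsFactors = FALSE)
  out$ratio_b_over_a <- ifelse(out$norm_a > 0, out$norm_b / out$norm_a, NA_real_)
  out
}

#' Volcano comparison of library sets
#'
#' For each gene, transposon counts are normalized per library to the
#' library's total mapped transposons (with a pseudocount so that
#' insertion-free genes — precisely the interesting ones — keep finite fold
#' changes). The fold change is the mean normalized count in the
#' experimental set divided by that in the reference set; the p-value is a
#' two-sided two-sample Student's t-test on the normalized values (pooled
#' variance by default, Welch behind `welch = TRUE`). Groups where both
#' sides have zero variance get an NA p-value rather than a fabricated 0.
#'
#' @param exp_libs,ref_libs lists of [insertion_library()] objects
#'   (at least one each; p-values require at least two per set).
#' @param genes gene table from [load_annotation()].
#' @param pseudocount transposons added to every gene's count before
#'   normalization; `"auto"` (default) uses 0.5.
#' @param metric `"transposons"` (default, negative selection) or
#'   `"density"` (counts divided by gene length before normalization).
#' @param welch use the Welch unequal-variance t-test instead of pooled.
#' @param p_adjust apply Benjamini-Hochberg correction in an extra column
#'   `p_adj` (off by default; raw p-values are what volcano plots show).
#' @return data.frame sorted by p-value: `gene_id`, `mean_norm_exp`,
#'   `mean_norm_ref`, `fold_change`, `log2_fc`, `t_statistic`, `df`,
#'   `p_value`, `n_exp`, `n_ref`.
#' @export
volcano <- function(exp_libs, ref_libs, genes, pseudocount = "auto",
                    metric = c("transposons", "density"),
                    welch = FALSE, p_adjust = FALSE) {
  metric <- match.arg(metric)
  if (!length(exp_libs) || !length(ref_libs))
    stop("each set needs at least one library")
  if (identical(pseudocount, "auto")) pseudocount <- 0.5
  norm_mat <- function(libs) {
    vapply(libs, function(l) {
      s <- count_per_gene(l, genes)
      cnt <- s$tn + pseudocount
      if (metric == "density") cnt <- cnt / s$length
      cnt / l$total_transposons
    }, numeric(nrow(genes)))
  }
  X <- norm_mat(exp_libs)  # genes x n_exp
  Y <- norm_mat(ref_libs)
  n1 <- ncol(X); n2 <- ncol(Y)
  m1 <- rowMeans(X); m2 <- rowMeans(Y)
  fc <- m1 / m2
  t_stat <- df <- p <- rep(NA_real_, nrow(genes))
  if (n1 >= 2 && n2 >= 2) {
    v1 <- rowSums((X - m1)^2) / (n1 - 1)
    v2 <- rowSums((Y - m2)^2) / (n2 - 1)
    if (welch) {
      se2 <- v1 / n1 + v2 / n2
      df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
      t_stat <- (m1 - m2) / sqrt(se2)
    } else {
      sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
      df <- rep(n1 + n2 - 2, nrow(genes))
      t_stat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    }
    zero_var <- v1 + v2 == 0
    t_stat[zero_var] <- NA_real_
    p <- 2 * stats::pt(-abs(t_stat), df)
  }
  out <- data.frame(gene_id = genes$gene_id,
                    mean_norm_exp = m1, mean_norm_ref = m2,
                    fold_change = fc, log2_fc = log2(fc),
                    t_statistic = t_stat, df = df, p_value = p,
                    n_exp = n1, n_ref = n2, stringsAsFactors = FALSE)
  if (p_adjust) out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$gene_id), ]
  rownames(out) <- NULL
  out
}

#' Flag volcano hits
#'
#' @param rows table from [volcano()].
#' @param fc_cut fold-change cutoff (>= 1); synthetic-sick genes have
#'   `fold_change < 1/fc_cut`, suppressed/enriched genes
#'   `fold_change > fc_cut`.
#' @param p_cut p-value cutoff.
#' @return the table with an added `hit` column:
#'   `"synthetic_sick"`, `"enriched"` or `"none"`.
#' @export
annotate_hits <- function(rows, fc_cut = 2, p_cut = 0.05) {
  sig <- !is.na(rows$p_value) & rows$p_value < p_cut
  rows$hit <- "none"
  rows$hit[sig & rows$fold_change < 1 / fc_cut] <- "synthetic_sick"
  rows$hit[sig & rows$fold_change > fc_cut] <- "enriched"
  rows
}
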