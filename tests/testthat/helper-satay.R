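# fixtures and independent oracles used across the suite

tiny_index <- function(lengths = c(chrI = 10000, chrII = 8000),
                       centromeres = NULL) {
  genome_index(data.frame(name = names(lengths), length = unname(lengths)),
               centromeres = centromeres)
}

make_genes <- function(gene_id, chrom, start, end, strand = "+",
                       essential = NA) {
  data.frame(gene_id = gene_id, name = gene_id, chrom = chrom,
             start = start, end = end, strand = strand,
             essential = essential, stringsAsFactors = FALSE)
}

make_lib <- function(chrom, position, strand = "+", reads = 1, id = "lib") {
  insertion_library(data.frame(chrom = chrom, position = position,
                               strand = strand, reads = reads),
                    library_id = id)
}

# brute-force union-find over the pairwise relation
# |pos_i - pos_j| <= tol & same strand & same chrom; returns one row per
# component: chrom, strand, modal position (ties -> smallest), group size
oracle_merge <- function(reads, tol = 2) {
  n <- nrow(reads)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j &&
        reads$chrom[i] == reads$chrom[j] &&
        reads$strand[i] == reads$strand[j] &&
        abs(reads$position[i] - reads$position[j]) <= tol) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  comps <- split(seq_len(n), root)
  out <- do.call(rbind, lapply(comps, function(idx) {
    p <- reads$position[idx]
    tab <- table(p)
    data.frame(chrom = reads$chrom[idx[1]],
               position = as.numeric(names(tab)[which.max(tab)]),
               strand = reads$strand[idx[1]],
               reads = length(idx), stringsAsFactors = FALSE)
  }))
  out <- out[order(out$chrom, out$position, out$strand), ]
  rownames(out) <- NULL
  out
}

random_reads <- function(n, n_chrom = 2, span = 500) {
  data.frame(chrom = paste0("chr", sample.int(n_chrom, n, replace = TRUE)),
             position = sample.int(span, n, replace = TRUE),
             strand = sample(c("+", "-"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# exhaustive scan for the longest interval spanning k gaps
oracle_kgap <- function(positions, gene_len, k = 5, pad = TRUE) {
  p <- sort(unique(positions))
  if (pad) p <- c(-1, p, gene_len)
  n <- length(p)
  if (n < k + 1) {
    lo <- if (n) p[1] else 0; hi <- if (n) p[n] else gene_len
    return(list(start = lo, end = hi, length = hi - lo))
  }
  best <- -Inf; bi <- NA
  for (i in seq_len(n - k)) {
    if (p[i + k] - p[i] > best) { best <- p[i + k] - p[i]; bi <- i }
  }
  list(start = p[bi], end = p[bi + k], length = best)
}

write_mini_gff <- function(path = tempfile(fileext = ".gff3")) {
  writeLines(c(
    "##gff-version 3",
    "chrI\tsgd\tgene\t11\t40\t.\t+\t.\tID=gene:GA;Name=GA",
    "chrI\tsgd\tCDS\t11\t20\t.\t+\t0\tParent=gene:GA",
    "chrI\tsgd\tCDS\t31\t40\t.\t+\t0\tParent=gene:GA",
    "chrI\tsgd\tgene\t101\t200\t.\t-\t.\tID=gene:GB;Name=GB",
    "chrI\tsgd\tCDS\t101\t200\t.\t-\t0\tParent=gene:GB",
    "chrII\tsgd\tgene\t501\t700\t.\t+\t.\tID=gene:GC;Name=GC",
    "chrII\tsgd\tCDS\t501\t700\t.\t+\t0\tParent=gene:GC"), path)
  path
}
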