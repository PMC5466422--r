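#' Genome skeleton: chromosome sizes, centromeres, optional sequences
#'
#' A `genome_index` is the coordinate authority for every other function in
#' the package. All internal coordinates are 0-based, half-open; GFF3 I/O
#' converts from/to the 1-based inclusive convention, BED I/O is native.
#'
#' @param chromosomes data.frame with columns `name` (character) and
#'   `length` (positive integer base pairs), one row per chromosome.
#' @param centromeres optional named numeric vector of centromere midpoints
#'   (0-based bp), names = chromosome names. May be empty; operations that
#'   need centromeres refuse to run on an index without them.
#' @param sequences optional [Biostrings::DNAStringSet] named by chromosome.
#' @return An object of class `genome_index`.
#' @export
genome_index <- function(chromosomes, centromeres = NULL, sequences = NULL) {
  stopifnot(is.data.frame(chromosomes), all(c("name", "length") %in% names(chromosomes)))
  chromosomes$name <- as.character(chromosomes$name)
  chromosomes$length <- as.numeric(chromosomes$length)
  if (anyDuplicated(chromosomes$name))
    stop("duplicate chromosome name(s): ",
         paste(unique(chromosomes$name[duplicated(chromosomes$name)]), collapse = ", "))
  if (any(chromosomes$length <= 0))
    stop("chromosome lengths must be > 0")
  if (is.null(centromeres)) centromeres <- stats::setNames(numeric(0), character(0))
  centromeres <- unlist(centromeres)
  if (length(centromeres)) {
    unknown <- setdiff(names(centromeres), chromosomes$name)
    if (length(unknown))
      stop("centromere on unknown chromosome(s): ", paste(unknown, collapse = ", "))
    len <- chromosomes$length[match(names(centromeres), chromosomes$name)]
    bad <- centromeres < 0 | centromeres >= len
    if (any(bad))
      stop("centromere midpoint outside [0, length) on: ",
           paste(names(centromeres)[bad], collapse = ", "))
  }
  if (!is.null(sequences)) {
    stopifnot(methods::is(sequences, "DNAStringSet"))
    if (!all(chromosomes$name %in% names(sequences)))
      stop("sequences missing for some chromosomes")
  }
  structure(
    list(chromosomes = chromosomes[, c("name", "length")],
         centromeres = centromeres,
         sequences = sequences),
    class = "genome_index"
  )
}

#' @export
print.genome_index <- function(x, ...) {
  cat("genome_index:", nrow(x$chromosomes), "chromosome(s),",
      sum(x$chromosomes$length), "bp total,",
      length(x$centromeres), "centromere(s),",
      if (is.null(x$sequences)) "no sequences" else "with sequences", "\n")
  invisible(x)
}

chrom_length <- function(index, chrom) {
  i <- match(chrom, index$chromosomes$name)
  if (anyNA(i))
    stop("unknown chromosome(s): ", paste(unique(chrom[is.na(i)]), collapse = ", "))
  index$chromosomes$length[i]
}

#' Load a genome index from chromosome-size and centromere tables
#'
#' @param chrom_sizes_file TSV with two columns: chromosome name, length (bp).
#' @param centromere_file optional TSV with two columns: chromosome name,
#'   centromere midpoint (1-based bp, as distributed by genome databases).
#'   Converted internally to 0-based.
#' @param aliases optional named character vector mapping foreign chromosome
#'   names to the canonical names in `chrom_sizes_file` (e.g.
#'   `c(I = "chrI")`). Applied to the centromere table and available to
#'   other loaders; no name guessing is ever done.
#' @return A [genome_index()].
#' @export
load_genome_index <- function(chrom_sizes_file, centromere_file = NULL, aliases = NULL) {
  sizes <- utils::read.table(chrom_sizes_file, sep = "\t", header = FALSE,
                             col.names = c("name", "length"),
                             colClasses = c("character", "numeric"))
  cen <- NULL
  if (!is.null(centromere_file) && file.exists(centromere_file) &&
      file.size(centromere_file) > 0) {
    ct <- utils::read.table(centromere_file, sep = "\t", header = FALSE,
                            col.names = c("name", "midpoint"),
                            colClasses = c("character", "numeric"))
    ct$name <- apply_aliases(ct$name, aliases)
    cen <- stats::setNames(ct$midpoint - 1, ct$name)  # 1-based -> 0-based
  }
  genome_index(sizes, centromeres = cen)
}

apply_aliases <- function(x, aliases) {
  if (is.null(aliases)) return(x)
  hit <- x %in% names(aliases)
  x[hit] <- unname(aliases[x[hit]])
  x
}

#' Load gene records from a GFF3 annotation
#'
#' Reads features of one kind (default `"CDS"`, falling back to `"gene"`
#' when no CDS is present) and collapses multi-part CDS features of the same
#' gene to their genomic span (min start .. max end, introns included).
#' GFF3 1-based inclusive coordinates are converted to internal 0-based
#' half-open.
#'
#' @param gff3_file path to a GFF3 file.
#' @param feature_kind feature type to extract (GFF3 column 3).
#' @param index optional [genome_index()]; when given, gene coordinates are
#'   validated against it and genes on unknown chromosomes are an error.
#' @param aliases optional chromosome alias map, see [load_genome_index()].
#' @return data.frame with columns `gene_id`, `name`, `chrom`, `start`,
#'   `end` (0-based half-open), `strand`, `essential` (NA until flagged).
#' @export
load_annotation <- function(gff3_file, feature_kind = c("CDS", "gene"),
                            index = NULL, aliases = NULL) {
  validate_gff3_lines(gff3_file)
  gr <- rtracklayer::import(gff3_file, format = "gff3")
  kinds <- as.character(gr$type)
  feature_kind <- feature_kind[feature_kind %in% kinds]
  if (!length(feature_kind))
    stop("no features of the requested kind in ", gff3_file)
  gr <- gr[kinds == feature_kind[1]]
  ids <- feature_gene_ids(gr)
  df <- data.frame(
    gene_id = ids,
    chrom = apply_aliases(as.character(GenomicRanges::seqnames(gr)), aliases),
    start1 = GenomicRanges::start(gr),
    end1 = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  nm <- if (!is.null(gr$Name)) as.character(gr$Name) else ids
  nm[is.na(nm)] <- ids[is.na(nm)]
  df$name <- nm
  # collapse multi-part features (e.g. CDS exons) to the genomic span
  sp <- split(df, df$gene_id)
  genes <- do.call(rbind, lapply(sp, function(d) {
    data.frame(gene_id = d$gene_id[1], name = d$name[1], chrom = d$chrom[1],
               start = min(d$start1) - 1, end = max(d$end1),
               strand = d$strand[1], stringsAsFactors = FALSE)
  }))
  genes <- genes[order(genes$chrom, genes$start, genes$gene_id), ]
  rownames(genes) <- NULL
  genes$essential <- NA
  if (!is.null(index)) validate_genes(genes, index)
  genes
}

feature_gene_ids <- function(gr) {
  # Prefer the Parent gene for CDS parts, else ID, else Name
  ids <- rep(NA_character_, length(gr))
  if (!is.null(gr$Parent)) {
    p <- as.character(S4Vectors::unstrsplit(gr$Parent, ","))
    ids[nzchar(p) & !is.na(p)] <- p[nzchar(p) & !is.na(p)]
  }
  if (!is.null(gr$ID)) {
    id <- as.character(gr$ID)
    ids[is.na(ids)] <- id[is.na(ids)]
  }
  if (!is.null(gr$Name)) {
    nm <- as.character(gr$Name)
    ids[is.na(ids)] <- nm[is.na(ids)]
  }
  if (anyNA(ids)) stop("GFF3 features without ID/Parent/Name attribute")
  sub("^gene:", "", ids)
}

validate_gff3_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  bad <- which(body)[nfield != 9]
  if (length(bad))
    stop("malformed GFF3 line ", bad[1], " in ", path,
         " (expected 9 tab-separated fields, got ", nfield[match(bad[1], which(body))], ")")
  invisible(TRUE)
}

validate_genes <- function(genes, index) {
  unknown <- setdiff(genes$chrom, index$chromosomes$name)
  if (length(unknown))
    stop("gene(s) on unknown chromosome(s): ", paste(unknown, collapse = ", "))
  len <- chrom_length(index, genes$chrom)
  bad <- genes$start < 0 | genes$start >= genes$end | genes$end > len
  if (any(bad))
    stop("gene coordinates out of bounds: ",
         paste(genes$gene_id[bad], collapse = ", "))
  invisible(TRUE)
}

#' Load a list of known-essential gene identifiers
#'
#' @param tsv_file file with one gene identifier per row (first column used).
#' @param genes optional gene table from [load_annotation()]; identifiers
#'   absent from it trigger a warning but stay in the returned set.
#' @return character vector of unique gene identifiers.
#' @export
load_essential_list <- function(tsv_file, genes = NULL) {
  if (!file.exists(tsv_file)) stop("no such file: ", tsv_file)
  if (file.size(tsv_file) == 0) return(character(0))
  tab <- utils::read.table(tsv_file, sep = "\t", header = FALSE,
                           colClasses = "character")
  ids <- unique(tab[[1]])
  if (!is.null(genes)) {
    missing <- setdiff(ids, genes$gene_id)
    if (length(missing))
      warning(length(missing), " essential identifier(s) absent from annotation: ",
              paste(utils::head(missing, 5), collapse = ", "))
  }
  ids
}

#' Flag genes as essential according to an identifier set
#'
#' @param genes gene table from [load_annotation()].
#' @param essential_ids character vector of essential gene identifiers.
#' @return the gene table with logical column `essential` filled in.
#' @export
flag_essentials <- function(genes, essential_ids) {
  genes$essential <- genes$gene_id %in% essential_ids
  genes
}

#' Export gene records back to GFF3
#'
#' Inverse of [load_annotation()] for span-collapsed genes: internal 0-based
#' half-open coordinates are re-expressed as GFF3 1-based inclusive.
#'
#' @param genes gene table.
#' @param path output file.
#' @param feature_kind GFF3 feature type to write.
#' @export
write_annotation <- function(genes, path, feature_kind = "gene") {
  lines <- sprintf("%s\tsatay\t%s\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
                   genes$chrom, feature_kind,
                   as.integer(genes$start) + 1L, as.integer(genes$end),
                   genes$strand, genes$gene_id, genes$name)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}
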