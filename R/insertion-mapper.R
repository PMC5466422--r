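#' Construct an insertion library
#'
#' An `insertion_library` holds one collapsed transposon insertion per row:
#' chromosome, representative 0-based position, orientation and supporting
#' read count, sorted by (chrom, position, strand) with no duplicates.
#'
#' @param insertions data.frame with columns `chrom`, `position`, `strand`,
#'   `reads`.
#' @param library_id identifier string.
#' @param metadata free-form named list (genotype, condition, ...).
#' @return object of class `insertion_library` with fields `insertions`,
#'   `total_transposons`, `total_reads`.
#' @export
insertion_library <- function(insertions, library_id = "library", metadata = list()) {
  stopifnot(is.data.frame(insertions),
            all(c("chrom", "position", "strand", "reads") %in% names(insertions)))
  ins <- insertions[, c("chrom", "position", "strand", "reads")]
  ins$chrom <- as.character(ins$chrom)
  ins$position <- as.numeric(ins$position)
  ins$strand <- as.character(ins$strand)
  ins$reads <- as.numeric(ins$reads)
  if (nrow(ins)) {
    if (!all(ins$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
    if (any(ins$reads < 1)) stop("read_count must be >= 1")
    ins <- ins[order(ins$chrom, ins$position, ins$strand), ]
    key <- (2 * match(ins$chrom, unique(ins$chrom)) + (ins$strand == "-")) *
      (max(ins$position) + 2) + ins$position
    if (anyDuplicated(key))
      stop("duplicate insertion at identical (chrom, position, strand)")
  }
  rownames(ins) <- NULL
  structure(
    list(library_id = library_id, metadata = metadata, insertions = ins,
         total_transposons = nrow(ins), total_reads = sum(ins$reads)),
    class = "insertion_library"
  )
}

#' @export
print.insertion_library <- function(x, ...) {
  cat("insertion_library '", x$library_id, "': ",
      x$total_transposons, " transposons, ", x$total_reads, " reads",
      if (x$total_transposons)
        paste0(" (median ", stats::median(x$insertions$reads), "/tn)"), "\n", sep = "")
  invisible(x)
}

#' Extract transposon-junction coordinates from aligned reads
#'
#' Each kept primary alignment yields one junction read whose coordinate is
#' the 5'-most aligned base in read orientation: the leftmost reference base
#' for `+` alignments, the rightmost for `-` alignments (the sequencing
#' protocol reads outward from the transposon terminus, so the read start is
#' the transposon-genome junction). Unmapped, secondary and supplementary
#' alignments are dropped, as are reads under `min_mapq` and, by default,
#' multimappers (MAPQ 0), mirroring the discard of reads mapping to
#' repetitive DNA.
#'
#' @param alignment_file coordinate-sorted SAM or BAM file.
#' @param min_mapq minimum mapping quality kept (default 1).
#' @param drop_multimappers drop MAPQ-0 / non-unique alignments (default TRUE).
#' @return data.frame with columns `chrom`, `position` (0-based), `strand`,
#'   `mapq`; attribute `drop_counts` records how many alignments each filter
#'   removed.
#' @export
extract_junctions <- function(alignment_file, min_mapq = 1, drop_multimappers = TRUE) {
  # check the sort order on the *input* header: asBam re-sorts silently
  so <- alignment_sort_order(alignment_file)
  if (!is.na(so) && so != "coordinate")
    stop("alignment file is not coordinate-sorted (SO:", so,
         "); sort it first, e.g. with 'samtools sort'")
  bam <- as_bam(alignment_file)
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]
  if (!length(hdr$targets)) stop("missing SAM/BAM header in ", alignment_file)
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  ga <- GenomicAlignments::readGAlignments(
    bam, param = Rsamtools::ScanBamParam(flag = flags, what = "mapq"))
  n_primary <- length(ga)
  mapq <- S4Vectors::mcols(ga)$mapq
  mapq[is.na(mapq)] <- 255L
  low <- mapq < min_mapq
  multi <- drop_multimappers & mapq == 0L
  keep <- !(low | multi)
  ga <- ga[keep]
  minus <- as.character(GenomicAlignments::strand(ga)) == "-"
  pos0 <- ifelse(minus,
                 GenomicAlignments::end(ga) - 1,    # rightmost base, 0-based
                 GenomicAlignments::start(ga) - 1)  # leftmost base, 0-based
  out <- data.frame(chrom = as.character(GenomicAlignments::seqnames(ga)),
                    position = pos0,
                    strand = ifelse(minus, "-", "+"),
                    mapq = mapq[keep],
                    stringsAsFactors = FALSE)
  attr(out, "drop_counts") <- c(low_mapq = sum(low & !multi),
                                multimapper = sum(multi),
                                kept = sum(keep),
                                primary = n_primary)
  out
}

alignment_sort_order <- function(path) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    hd <- unlist(Rsamtools::scanBamHeader(path)[[1]]$text["@HD"])
  } else {
    lines <- readLines(path, n = 100, warn = FALSE)
    hd_line <- grep("^@HD", lines, value = TRUE)
    if (!length(hd_line)) return(NA_character_)
    hd <- strsplit(hd_line[1], "\t")[[1]]
  }
  so <- grep("^SO:", hd, value = TRUE)
  if (!length(so)) return(NA_character_)
  sub("^SO:", "", so[1])
}

as_bam <- function(path) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    if (!file.exists(paste0(path, ".bai"))) Rsamtools::indexBam(path)
    return(path)
  }
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = TRUE)
  bam
}

#' Collapse junction reads into transposon insertions
#'
#' Reads on the same chromosome and orientation whose positions differ by at
#' most `tolerance_bp` are considered to originate from the same transposon
#' (sequencing is imperfectly accurate near the junction). Grouping is
#' transitive along the sorted positions (single-linkage), which is the only
#' order-independent closure of the pairwise rule. Each group becomes one
#' insertion with `reads` = group size and `position` = the group's modal
#' read position (ties broken toward the smallest coordinate).
#'
#' @param junctions data.frame from [extract_junctions()] (columns `chrom`,
#'   `position`, `strand`; one row per read).
#' @param tolerance_bp maximum distance merged (default 2).
#' @param library_id,metadata passed to [insertion_library()].
#' @return an [insertion_library()]; total reads are conserved.
#' @export
merge_junctions <- function(junctions, tolerance_bp = 2,
                            library_id = "library", metadata = list()) {
  if (tolerance_bp < 0) stop("tolerance_bp must be >= 0")
  if (!nrow(junctions))
    return(insertion_library(
      data.frame(chrom = character(), position = numeric(),
                 strand = character(), reads = numeric()),
      library_id, metadata))
  o <- order(junctions$chrom, junctions$strand, junctions$position)
  ch <- junctions$chrom[o]; st <- junctions$strand[o]; po <- junctions$position[o]
  n <- length(po)
  newgrp <- c(TRUE, ch[-1] != ch[-n] | st[-1] != st[-n] |
                    (po[-1] - po[-n]) > tolerance_bp)
  grp <- cumsum(newgrp)
  rep_pos <- vapply(split(po, grp), modal_position, numeric(1))
  ins <- data.frame(chrom = ch[newgrp], position = unname(rep_pos),
                    strand = st[newgrp],
                    reads = as.numeric(tabulate(grp)),
                    stringsAsFactors = FALSE)
  # merging can map two groups of opposite strand onto one coordinate; that
  # is fine (distinct strand), but identical (chrom,pos,strand) cannot arise
  # since same-strand groups are separated by > tolerance_bp >= 0
  insertion_library(ins, library_id, metadata)
}

modal_position <- function(p) {
  tab <- table(p)
  as.numeric(names(tab)[which.max(tab)])  # which.max takes first = smallest
}

#' Write an insertion library as a BED6 track
#'
#' One row per insertion: 0-based half-open single-base interval, name ".",
#' score = read count, strand column set. Suitable for genome-browser upload.
#'
#' @param library an [insertion_library()].
#' @param path output file.
#' @param index optional [genome_index()]; when supplied, positions outside
#'   chromosome bounds are an error.
#' @param track_line write a `track` header line (default TRUE).
#' @export
write_bed <- function(library, path, index = NULL, track_line = TRUE) {
  ins <- library$insertions
  if (!is.null(index) && nrow(ins)) {
    len <- chrom_length(index, ins$chrom)
    if (any(ins$position < 0 | ins$position >= len))
      stop("insertion position(s) outside chromosome bounds")
  }
  header <- sprintf("track name=%s type=bed", library$library_id)
  rows <- sprintf("%s\t%d\t%d\t.\t%d\t%s",
                  ins$chrom, as.integer(ins$position),
                  as.integer(ins$position) + 1L,
                  as.integer(ins$reads), ins$strand)
  writeLines(c(if (track_line) header, rows), path)
  invisible(path)
}

#' Read an insertion library from a BED6 or TSV insertion table
#'
#' Inverts [write_bed()] bit-exactly. TSV tables (written by
#' [write_insertion_table()]) carry columns chrom, pos, strand, reads.
#'
#' @param path BED or TSV file.
#' @param library_id identifier for the returned library (defaults to the
#'   BED track name when present).
#' @return an [insertion_library()].
#' @export
read_insertions <- function(path, library_id = NULL) {
  lines <- readLines(path, warn = FALSE)
  is_track <- startsWith(lines, "track")
  if (any(is_track) && is.null(library_id)) {
    m <- regmatches(lines[is_track][1],
                    regexec("name=([^ \t]+)", lines[is_track][1]))[[1]]
    if (length(m) == 2) library_id <- m[2]
  }
  if (is.null(library_id)) library_id <- "library"
  body <- lines[!is_track & nzchar(lines)]
  if (length(body) && startsWith(body[1], "chrom\t")) {        # TSV table
    tab <- utils::read.table(text = body, sep = "\t", header = TRUE,
                             colClasses = c("character", "numeric",
                                            "character", "numeric"))
    ins <- data.frame(chrom = tab$chrom, position = tab$pos,
                      strand = tab$strand, reads = tab$reads)
  } else if (length(body)) {                                    # BED6
    tab <- utils::read.table(text = body, sep = "\t", header = FALSE)
    if (ncol(tab) < 6) stop("expected BED6 (6 columns) in ", path)
    ins <- data.frame(chrom = as.character(tab[[1]]), position = tab[[2]],
                      strand = as.character(tab[[6]]), reads = tab[[5]])
  } else {
    ins <- data.frame(chrom = character(), position = numeric(),
                      strand = character(), reads = numeric())
  }
  insertion_library(ins, library_id)
}

#' Write an insertion library as a TSV insertion table
#'
#' @param library an [insertion_library()].
#' @param path output file.
#' @export
write_insertion_table <- function(library, path) {
  ins <- library$insertions
  writeLines(c("chrom\tpos\tstrand\treads",
               sprintf("%s\t%d\t%s\t%d", ins$chrom, as.integer(ins$position),
                       ins$strand, as.integer(ins$reads))), path)
  invisible(path)
}

#' Write per-position read counts as a variableStep WIG track
#'
#' Opposite-strand insertions at the same base are summed (WIG carries one
#' value per position).
#'
#' @param library an [insertion_library()].
#' @param path output file.
#' @export
write_wig <- function(library, path) {
  ins <- library$insertions
  out <- sprintf("track type=wiggle_0 name=%s", library$library_id)
  for (ch in unique(ins$chrom)) {
    d <- ins[ins$chrom == ch, ]
    reads <- tapply(d$reads, d$position, sum)
    pos <- as.numeric(names(reads))
    o <- order(pos)
    out <- c(out, sprintf("variableStep chrom=%s", ch),
             sprintf("%d\t%d", as.integer(pos[o]) + 1L, as.integer(reads[o])))
  }
  writeLines(out, path)
  invisible(path)
}
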