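#' Configuration for synthetic saturated-mutagenesis libraries
#'
#' Defaults emulate a wild-type yeast library launched from a centromeric
#' plasmid: a 16-chromosome, ~12 Mb genome; insertion intensity modulated
#' with the ~160 bp nucleosome phase; ~20% of insertions contributed by
#' pericentromeric bumps (the transposon excises from a centromeric plasmid
#' and centromeres cluster); a read-count law with median 22 reads per
#' transposon; essential genes and essential domains insertion-free.
#'
#' @param seed integer master seed; everything downstream is deterministic
#'   given it.
#' @param n_chromosomes,chrom_length_bp genome skeleton; centromeres sit at
#'   `centromere_frac` of each chromosome.
#' @param n_genes,gene_length_range non-overlapping genes placed uniformly.
#' @param essential_fraction fraction of genes flagged essential
#'   (insertion-free), ~0.2 in yeast.
#' @param domain_fraction fraction of the non-essential genes given an
#'   essential sub-domain (insertion-free interval inside an otherwise
#'   tolerant gene).
#' @param domain_start_frac,domain_len_frac uniform ranges (as fractions of
#'   gene length) for the domain start and length.
#' @param n_insertions transposons per library.
#' @param nucleosome_period_bp,modulation_amplitude sinusoidal insertion-
#'   intensity modulation `1 + a sin(2 pi x / P)`; amplitude in [0, 1).
#' @param centromere_excess_fraction expected fraction of insertions drawn
#'   from the pericentromeric component (exponential bumps at every
#'   centromere, decay `centromere_decay_bp`).
#' @param read_median target median reads per transposon (shifted-geometric
#'   law: 1 + Geom(p), heavy right tail like PCR amplification).
#' @param gc genome GC content for simulated sequences.
#' @param with_sequences generate per-chromosome sequences (off for large
#'   genomes where only coordinates matter).
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1,
                              n_chromosomes = 16,
                              chrom_length_bp = 750e3,
                              n_genes = 1000,
                              gene_length_range = c(300, 3000),
                              essential_fraction = 0.2,
                              domain_fraction = 0,
                              domain_start_frac = c(0.1, 0.5),
                              domain_len_frac = c(0.2, 0.4),
                              centromere_frac = 0.5,
                              n_insertions = 1e5,
                              nucleosome_period_bp = 160,
                              modulation_amplitude = 0.5,
                              centromere_excess_fraction = 0.20,
                              centromere_decay_bp = 10e3,
                              read_median = 22,
                              gc = 0.38,
                              with_sequences = FALSE) {
  cfg <- as.list(environment())
  stopifnot(modulation_amplitude >= 0, modulation_amplitude < 1,
            centromere_excess_fraction >= 0, centromere_excess_fraction < 1,
            essential_fraction >= 0, essential_fraction < 1,
            domain_fraction >= 0, domain_fraction <= 1,
            chrom_length_bp > 0, n_insertions > 0, read_median >= 1)
  structure(cfg, class = "simulation_config")
}

#' Simulate a genome skeleton, gene annotation and truth table
#'
#' Chromosome sequences (when requested) are i.i.d. bases at the configured
#' GC content; genes are placed uniformly without overlap; essential flags
#' and essential-domain intervals are drawn per the configuration and
#' recorded in the truth table.
#'
#' @param config a [simulation_config()].
#' @return list with `index` ([genome_index()]), `genes` (gene table as in
#'   [load_annotation()]), `truth` (data.frame gene_id, essential,
#'   domain_start, domain_end in gene-relative bp, fitness).
#' @export
simulate_genome <- function(config) {
  withr::with_seed(config$seed, {
    chroms <- data.frame(
      name = sprintf("chr%02d", seq_len(config$n_chromosomes)),
      length = rep(config$chrom_length_bp, config$n_chromosomes))
    cen <- stats::setNames(floor(chroms$length * config$centromere_frac),
                           chroms$name)
    seqs <- NULL
    if (config$with_sequences) {
      pr <- c(A = (1 - config$gc) / 2, C = config$gc / 2,
              G = config$gc / 2, T = (1 - config$gc) / 2)
      seqs <- Biostrings::DNAStringSet(vapply(chroms$length, function(L)
        paste(sample(names(pr), L, replace = TRUE, prob = pr), collapse = ""),
        character(1)))
      names(seqs) <- chroms$name
    }
    index <- genome_index(chroms, centromeres = cen, sequences = seqs)

    glen <- round(stats::runif(config$n_genes,
                               config$gene_length_range[1],
                               config$gene_length_range[2]))
    gchrom <- sort(sample.int(config$n_chromosomes, config$n_genes,
                              replace = TRUE))
    starts <- numeric(config$n_genes)
    for (ci in unique(gchrom)) {
      sel <- which(gchrom == ci)
      total <- sum(glen[sel])
      L <- chroms$length[ci]
      if (total > L) stop("genes don't fit on chromosome ", chroms$name[ci])
      slack <- sort(stats::runif(length(sel), 0, L - total))
      starts[sel] <- floor(slack + cumsum(c(0, glen[sel][-length(sel)])))
    }
    genes <- data.frame(
      gene_id = sprintf("G%04d", seq_len(config$n_genes)),
      name = sprintf("G%04d", seq_len(config$n_genes)),
      chrom = chroms$name[gchrom],
      start = starts, end = starts + glen,
      strand = sample(c("+", "-"), config$n_genes, replace = TRUE),
      stringsAsFactors = FALSE)
    essential <- stats::runif(config$n_genes) < config$essential_fraction
    genes$essential <- essential

    dom_start <- dom_end <- rep(NA_real_, config$n_genes)
    candidates <- which(!essential)
    n_dom <- round(config$domain_fraction * length(candidates))
    if (n_dom > 0) {
      dom_genes <- sample(candidates, n_dom)
      lf <- stats::runif(n_dom, config$domain_len_frac[1],
                         config$domain_len_frac[2])
      sf <- stats::runif(n_dom, config$domain_start_frac[1],
                         config$domain_start_frac[2])
      sf <- pmin(sf, 1 - lf)  # keep the domain inside the gene
      dom_start[dom_genes] <- floor(sf * glen[dom_genes])
      dom_end[dom_genes] <- floor((sf + lf) * glen[dom_genes])
    }
    truth <- data.frame(gene_id = genes$gene_id, essential = essential,
                        domain_start = dom_start, domain_end = dom_end,
                        fitness = rep(1, config$n_genes),
                        stringsAsFactors = FALSE)
    list(index = index, genes = genes, truth = truth)
  })
}

# 0-based half-open forbidden intervals per chromosome: essential gene spans
# plus essential-domain intervals
forbidden_intervals <- function(genes, truth) {
  ess <- genes[genes$essential %in% TRUE, c("chrom", "start", "end")]
  hasdom <- !is.na(truth$domain_start)
  if (any(hasdom)) {
    g <- genes[match(truth$gene_id[hasdom], genes$gene_id), ]
    dom <- data.frame(chrom = g$chrom,
                      start = g$start + truth$domain_start[hasdom],
                      end = g$start + truth$domain_end[hasdom])
    ess <- rbind(ess, dom)
  }
  ess
}

in_intervals <- function(chrom, pos, ivals) {
  if (!nrow(ivals)) return(rep(FALSE, length(pos)))
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1, pos + 1))
  iv <- GenomicRanges::GRanges(ivals$chrom,
                               IRanges::IRanges(ivals$start + 1, ivals$end))
  GenomicRanges::countOverlaps(gr, iv) > 0
}

# shifted geometric read-count law: 1 + Geom(p) with median = read_median
read_law_p <- function(read_median) 1 - 2^(-1 / (read_median - 0.5))

#' Simulate an insertion library over a simulated genome
#'
#' Insertion positions are drawn from a mixture: with probability
#' `1 - centromere_excess_fraction` from the genome-wide intensity
#' `1 + a sin(2 pi x / P)` (zero inside essential genes and essential
#' domains), otherwise from per-centromere exponential bumps. Strands are
#' Bernoulli(1/2); read counts are i.i.d. shifted-geometric with the
#' configured median. Exactly `n_insertions` distinct
#' (chrom, position, strand) sites are produced.
#'
#' @param genome output of [simulate_genome()].
#' @param config a [simulation_config()].
#' @param seed RNG seed for this library (defaults to `config$seed + 1`, so
#'   several libraries over one genome get distinct seeds).
#' @param library_id identifier of the emitted library.
#' @return an [insertion_library()]; metadata carries the per-insertion
#'   origin class (`background` / `centromeric`) aligned with the sorted
#'   insertion table.
#' @export
simulate_library <- function(genome, config, seed = config$seed + 1,
                             library_id = "sim") {
  index <- genome$index
  ivals <- forbidden_intervals(genome$genes, genome$truth)
  if (sum(pmax(ivals$end - ivals$start, 0)) >= sum(index$chromosomes$length))
    stop("no insertion support: essential regions cover the genome")
  a <- config$modulation_amplitude
  P <- config$nucleosome_period_bp
  fcen <- config$centromere_excess_fraction
  if (fcen > 0 && !length(index$centromeres))
    stop("centromeric excess requested but the genome has no centromeres")
  chrom_names <- index$chromosomes$name
  chrom_len <- index$chromosomes$length
  cen_names <- names(index$centromeres)

  withr::with_seed(seed, {
    # the mixture weight is an expected fraction of *emitted* insertions, so
    # the component split is drawn once and each component filled to quota
    # (rejection rates differ between components and must not distort it)
    n_cen <- stats::rbinom(1, config$n_insertions, fcen)
    n_bg <- config$n_insertions - n_cen
    seen <- numeric(0)
    M <- max(chrom_len) + 5

    accept <- function(ch, pos, strand) {
      ok <- pos >= 0 & pos < chrom_len[match(ch, chrom_names)] &
        !in_intervals(ch, pos, ivals)
      ch <- ch[ok]; pos <- pos[ok]; strand <- strand[ok]
      n0 <- length(ch)
      if (!n0) return(NULL)
      # collapsed insertion maps never hold two same-orientation sites
      # within the 2 bp merging tolerance; emitted maps keep that property.
      # The spacing filter runs on a sorted view, but candidates are kept
      # in their original random draw order so the truncation to the
      # component quota stays unbiased.
      o2 <- order(ch, strand, pos)
      sc <- ch[o2]; sp <- pos[o2]; ss <- strand[o2]
      prev_close <- c(FALSE, sc[-1] == sc[-n0] & ss[-1] == ss[-n0] &
                               sp[-1] - sp[-n0] <= 2)
      # integer site keys (chrom x strand folded above the position) make
      # the conflict lookup a plain hash match
      key <- (2 * match(sc, chrom_names) + (ss == "-")) * M + sp
      conflict <- Reduce(`|`, lapply(-2:2, function(d) (key + d) %in% seen))
      keep_sorted <- !prev_close & !conflict
      new <- logical(n0)
      new[o2] <- keep_sorted
      seen <<- c(seen, key[keep_sorted])
      data.frame(chrom = ch[new], position = pos[new], strand = strand[new],
                 stringsAsFactors = FALSE)
    }

    fill <- function(need, draw) {
      parts <- list(); got <- 0
      while (got < need) {
        m <- max(2 * (need - got), 1000)
        cand <- draw(m)
        kept <- accept(cand$chrom, cand$position, cand$strand)
        if (!is.null(kept)) {
          if (nrow(kept) > need - got) {
            drop_key <- (2 * match(kept$chrom, chrom_names) +
                           (kept$strand == "-")) * M + kept$position
            kept <- kept[seq_len(need - got), ]
            # release blocked keys for rows beyond the quota
            seen <<- setdiff(seen, drop_key[-seq_len(nrow(kept))])
          }
          parts[[length(parts) + 1]] <- kept
          got <- got + nrow(kept)
        }
      }
      do.call(rbind, parts)
    }

    draw_bg <- function(m) {
      ci <- sample.int(length(chrom_names), m, replace = TRUE,
                       prob = chrom_len)
      p <- floor(stats::runif(m, 0, chrom_len[ci]))
      keep <- stats::runif(m) < (1 + a * sin(2 * pi * p / P)) / (1 + a)
      data.frame(chrom = chrom_names[ci][keep], position = p[keep],
                 strand = sample(c("+", "-"), sum(keep), replace = TRUE),
                 stringsAsFactors = FALSE)
    }
    draw_cen <- function(m) {
      cn <- sample(cen_names, m, replace = TRUE)
      d <- stats::rexp(m, rate = 1 / config$centromere_decay_bp)
      side <- sample(c(-1, 1), m, replace = TRUE)
      data.frame(chrom = cn,
                 position = floor(index$centromeres[cn] + side * d),
                 strand = sample(c("+", "-"), m, replace = TRUE),
                 stringsAsFactors = FALSE)
    }

    bg <- if (n_bg) cbind(fill(n_bg, draw_bg), origin = "background") else NULL
    cen <- if (n_cen) cbind(fill(n_cen, draw_cen), origin = "centromeric") else NULL
    acc <- rbind(bg, cen)
    acc$reads <- 1 + stats::rgeom(config$n_insertions,
                                  read_law_p(config$read_median))
    o <- order(acc$chrom, acc$position, acc$strand)
    acc <- acc[o, ]
    insertion_library(acc[, c("chrom", "position", "strand", "reads")],
                      library_id = library_id,
                      metadata = list(origin = acc$origin,
                                      seed = seed, config = config))
  })
}

#' Apply a per-gene fitness map to a base library
#'
#' Models growth selection in a condition: insertions in gene g are thinned
#' with probability `1 - min(fitness, 1)` (fitness 0 = disruption lethal in
#' the condition, gene ends up insertion-free) and read counts are
#' multiplied by `max(fitness, 1)` (positive selection: resistant mutants
#' outgrow the culture and dominate sequencing reads).
#'
#' @param base_library an [insertion_library()] (e.g. from
#'   [simulate_library()]).
#' @param genes gene table the fitness map refers to.
#' @param fitness named numeric vector (gene_id -> fitness in [0, Inf));
#'   genes absent from the map keep fitness 1.
#' @param seed RNG seed for the thinning draws.
#' @param library_id identifier of the emitted library.
#' @return an [insertion_library()].
#' @export
simulate_condition <- function(base_library, genes, fitness, seed = 1,
                               library_id = "condition") {
  ins <- base_library$insertions
  fit <- rep(1, nrow(ins))
  for (g in names(fitness)) {
    i <- match(g, genes$gene_id)
    if (is.na(i)) stop("fitness for unknown gene: ", g)
    hit <- ins$chrom == genes$chrom[i] &
      ins$position >= genes$start[i] & ins$position < genes$end[i]
    fit[hit] <- fitness[[g]]
  }
  if (any(fit < 0)) stop("fitness must be >= 0")
  withr::with_seed(seed, {
    keep <- stats::runif(nrow(ins)) < pmin(fit, 1)
    out <- ins[keep, ]
    out$reads <- out$reads * pmax(fit[keep], 1)
    insertion_library(out, library_id = library_id,
                      metadata = base_library$metadata)
  })
}

#' Cells representing each clone after library regrowth
#'
#' Representation arithmetic for planning library regrowth: reseeding a
#' library of `n_clones` in `culture_volume_ml` at `cell_density_per_ml`,
#' of which `transposed_fraction` carry a transposon, represents each clone
#' by `density x volume x fraction / n_clones` cells. Reseeding a 2e6-clone
#' library in 2 L at 2.5e6 cells/ml with 80% transposed cells gives 2000
#' cells per clone.
#'
#' @param n_clones,culture_volume_ml,cell_density_per_ml positive numbers.
#' @param transposed_fraction fraction of cells carrying a transposon,
#'   in (0, 1].
#' @return cells per clone (numeric).
#' @export
clone_representation <- function(n_clones, culture_volume_ml,
                                 cell_density_per_ml, transposed_fraction) {
  if (any(c(n_clones, culture_volume_ml, cell_density_per_ml,
            transposed_fraction) <= 0) || transposed_fraction > 1)
    stop("all inputs must be > 0 and transposed_fraction in (0, 1]")
  cell_density_per_ml * culture_volume_ml * transposed_fraction / n_clones
}

#' Emit a library as coordinate-sorted single-end SAM alignments
#'
#' Each insertion becomes `reads` identical perfect alignments whose 5' end
#' (in read orientation) sits at the insertion position, so that junction
#' extraction and merging round-trip the library exactly. Reads near a
#' chromosome edge are shortened to fit.
#'
#' @param library an [insertion_library()].
#' @param index a [genome_index()].
#' @param path output SAM file.
#' @param read_len alignment length in bp (default 50).
#' @export
write_sam <- function(library, index, path, read_len = 50) {
  ins <- library$insertions
  len <- chrom_length(index, ins$chrom)
  plus <- ins$strand == "+"
  w <- ifelse(plus, pmin(read_len, len - ins$position),
              pmin(read_len, ins$position + 1))
  left0 <- ifelse(plus, ins$position, ins$position - w + 1)
  flag <- ifelse(plus, 0L, 16L)
  reps <- as.integer(ins$reads)
  i <- rep(seq_len(nrow(ins)), reps)
  rows <- sprintf("r%07d\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t*\t*",
                  seq_along(i), flag[i], ins$chrom[i],
                  as.integer(left0[i]) + 1L, as.integer(w[i]))
  ord <- order(match(ins$chrom[i], index$chromosomes$name), left0[i])
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", index$chromosomes$name,
                      as.integer(index$chromosomes$length)))
  writeLines(c(header, rows[ord]), path)
  invisible(path)
}

#' Write simulated chromosome sequences as FASTA
#'
#' @param index a [genome_index()] carrying sequences.
#' @param path output FASTA file.
#' @export
write_genome_fasta <- function(index, path) {
  if (is.null(index$sequences)) stop("genome index has no sequences")
  Biostrings::writeXStringSet(index$sequences, path)
  invisible(path)
}
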