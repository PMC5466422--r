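#' Moving-average insertion-density track
#'
#' Per-base insertion indicator (1 where one or more transposons map,
#' counting opposite-strand insertions at the same base separately)
#' smoothed with a centered boxcar. At chromosome edges the window is
#' truncated to the available bases, so values stay on the
#' transposons-per-bp scale everywhere.
#'
#' @param library an [insertion_library()].
#' @param index a [genome_index()] providing chromosome lengths.
#' @param window_bp moving-average width in bp (default 40).
#' @return named list of numeric vectors (one per chromosome, length =
#'   chromosome length), class `density_track`.
#' @export
density_track <- function(library, index, window_bp = 40) {
  if (window_bp < 1) stop("window_bp must be >= 1")
  ins <- library$insertions
  tracks <- lapply(seq_len(nrow(index$chromosomes)), function(i) {
    ch <- index$chromosomes$name[i]
    L <- index$chromosomes$length[i]
    if (window_bp > L) stop("window larger than chromosome ", ch)
    x <- numeric(L)
    p <- ins$position[ins$chrom == ch]
    if (length(p)) {
      cnt <- table(p)
      x[as.numeric(names(cnt)) + 1] <- as.numeric(cnt)
    }
    boxcar_mean(x, window_bp)
  })
  structure(stats::setNames(tracks, index$chromosomes$name),
            window_bp = window_bp, class = "density_track")
}

# centered boxcar mean with truncated edges, O(L) via cumulative sums
boxcar_mean <- function(x, w) {
  L <- length(x)
  left <- floor((w - 1) / 2); right <- floor(w / 2)
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(L) - left, 1)
  hi <- pmin(seq_len(L) + right, L)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Autocorrelation periodicity of a density track
#'
#' Autocorrelation of the insertion-density signal at integer-bp lags; the
#' estimated period is the lag of the highest local maximum (with
#' prominence above a floor) inside a search band. Insertion frequency
#' modulated by nucleosome phasing shows up as a ~160 bp periodicity.
#'
#' @param track numeric vector (one chromosome of a [density_track()]), or
#'   a `density_track`, in which case chromosomes are concatenated
#'   correlation-weighted by length.
#' @param max_lag_bp largest lag computed (default 500).
#' @param band lag window searched for the period (default c(50, 500) bp).
#' @param prominence_floor minimum peak prominence; `NULL` (default) uses
#'   `max(0.01, 9 / sqrt(track length))`, which scales with the sampling
#'   noise of the correlogram so that white-noise tracks report no period.
#' @return list of class `periodicity_result`: `lags`, `acf` (values in
#'   [-1, 1]), `estimated_period` (bp; NA when no prominent peak),
#'   `peak_prominence`.
#' @export
autocorrelate <- function(track, max_lag_bp = 500, band = c(50, 500),
                          prominence_floor = NULL) {
  if (inherits(track, "density_track")) {
    acs <- lapply(track, autocorrelate, max_lag_bp = max_lag_bp,
                  band = band, prominence_floor = prominence_floor)
    wts <- vapply(track, length, numeric(1))
    ok <- !vapply(acs, function(a) all(is.na(a$acf)), logical(1))
    if (!any(ok)) stop("autocorrelation undefined: all chromosomes constant")
    acfm <- Reduce(`+`, Map(function(a, w) a$acf * w, acs[ok], wts[ok])) /
      sum(wts[ok])
    if (is.null(prominence_floor))
      prominence_floor <- max(0.01, 9 / sqrt(sum(wts[ok])))
    return(pick_period(0:max_lag_bp, acfm, band, prominence_floor))
  }
  if (length(track) <= 2 * max_lag_bp)
    stop("track must be longer than 2 x max_lag_bp")
  if (is.null(prominence_floor))
    prominence_floor <- max(0.01, 9 / sqrt(length(track)))
  if (stats::sd(track) == 0)
    return(structure(list(lags = 0:max_lag_bp,
                          acf = rep(NA_real_, max_lag_bp + 1),
                          estimated_period = NA_real_,
                          peak_prominence = NA_real_),
                     class = "periodicity_result"))
  ac <- stats::acf(track, lag.max = max_lag_bp, plot = FALSE,
                   demean = TRUE)$acf[, 1, 1]
  pick_period(0:max_lag_bp, ac, band, prominence_floor)
}

# topographic prominence: height above the higher of the two key saddles
# (deepest valley on the way to the nearest higher ground on each side)
peak_prominences <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    left <- x[seq_len(p - 1)]
    hi_l <- which(left > h)
    vL <- min(if (length(hi_l)) left[(max(hi_l) + 1):(p - 1)] else left, h)
    right <- x[seq(p + 1, length(x))]
    hi_r <- which(right > h)
    vR <- min(if (length(hi_r)) right[seq_len(min(hi_r) - 1)] else right, h)
    h - max(vL, vR)
  }, numeric(1))
}

pick_period <- function(lags, ac, band, prominence_floor) {
  period <- NA_real_; prom_best <- NA_real_
  pk <- pracma::findpeaks(ac)
  if (!is.null(pk))
    pk <- pk[pk[, 2] > 1 & pk[, 2] < length(ac), , drop = FALSE]
  if (!is.null(pk) && nrow(pk)) {
    prom <- peak_prominences(ac, pk[, 2])
    peak_lags <- lags[pk[, 2]]
    keep <- peak_lags >= band[1] & peak_lags <= band[2] &
      prom >= prominence_floor
    if (any(keep)) {
      h <- pk[keep, 1]; pl <- peak_lags[keep]; pr <- prom[keep]
      # a periodic signal repeats its correlogram peak at every multiple of
      # the period with near-equal height, so the strongest peak may be a
      # harmonic; descend to the fundamental: the smallest comparable-height
      # peak sitting near an integer fraction of the strongest peak's lag
      best <- which.max(h)
      L0 <- pl[best]; h0 <- h[best]
      for (k in 2:4) {
        tgt <- L0 / k
        j <- which(abs(pl - tgt) <= 0.12 * tgt & h >= 0.5 * h0)
        if (length(j)) best <- j[which.min(abs(pl[j] - tgt))]
      }
      period <- pl[best]
      prom_best <- pr[best]
    }
  }
  structure(list(lags = lags, acf = ac, estimated_period = period,
                 peak_prominence = prom_best),
            class = "periodicity_result")
}

#' @export
print.periodicity_result <- function(x, ...) {
  cat("periodicity_result: estimated period",
      if (is.na(x$estimated_period)) "absent (no prominent peak)"
      else paste0(x$estimated_period, " bp"), "\n")
  invisible(x)
}

#' Cross-correlation of an insertion track with another per-bp track
#'
#' Pearson correlation between the two tracks at a series of relative
#' offsets (positive offset shifts `other_track` rightward). For insertion
#' densities against nucleosome occupancy the correlation is most negative
#' at offset 0: transposons prefer inter-nucleosomal DNA.
#'
#' @param track,other_track numeric vectors on the same coordinates.
#' @param offsets integer offsets in bp (default -400..400).
#' @return data.frame `offset`, `correlation`, with attributes
#'   `argmax`/`argmin` (offsets of the extreme correlations).
#' @export
cross_correlate <- function(track, other_track, offsets = -400:400) {
  if (length(track) != length(other_track))
    stop("tracks differ in length")
  L <- length(track)
  cc <- vapply(offsets, function(o) {
    if (o >= 0) stats::cor(track[seq_len(L - o)], other_track[seq_len(L - o) + o])
    else stats::cor(track[seq_len(L + o) - o], other_track[seq_len(L + o)])
  }, numeric(1))
  out <- data.frame(offset = offsets, correlation = cc)
  attr(out, "argmax") <- offsets[which.max(cc)]
  attr(out, "argmin") <- offsets[which.min(cc)]
  out
}

#' Pericentromeric-enrichment estimator
#'
#' For each chromosome the cumulative number of insertions C(d) within
#' distance d of the centromere is computed. Away from the centromere C(d)
#' grows linearly (uniform background accumulating on both arms); the
#' pericentromeric excess shows up as the intercept of an ordinary
#' least-squares fit of C(d) on d over the linear part. Summing the
#' intercepts over chromosomes estimates the total number of transposons
#' enriched at pericentromeric regions; divided by the library total it
#' gives the enriched fraction (~20% in plasmid-launched wild-type
#' libraries).
#'
#' @param library an [insertion_library()].
#' @param index a [genome_index()] with centromeres.
#' @param fit_range numeric c(d_min, d_max) in bp delimiting the linear
#'   part (default 50-300 kb).
#' @param step_bp spacing of the distance grid (default 1 kb).
#' @return list of class `centromere_enrichment`: `per_chromosome`
#'   (data.frame chrom, slope tn/bp, intercept tn), `total_excess`,
#'   `fraction` (= total_excess / total transposons), `fit_range`,
#'   `excluded` (chromosomes without centromere or too short).
#' @export
centromere_enrichment <- function(library, index,
                                  fit_range = c(50e3, 300e3), step_bp = 1e3) {
  if (!length(index$centromeres))
    stop("genome index has no centromeres; cannot estimate enrichment")
  if (fit_range[1] >= fit_range[2]) stop("d_min must be < d_max")
  ins <- library$insertions
  grid <- seq(fit_range[1], fit_range[2], by = step_bp)
  rows <- list(); excluded <- character(0)
  for (ch in index$chromosomes$name) {
    cen <- index$centromeres[ch]
    if (is.na(cen) || !ch %in% names(index$centromeres)) {
      excluded <- c(excluded, ch); next
    }
    L <- chrom_length(index, ch)
    if (L < fit_range[1]) {
      warning("chromosome ", ch, " shorter than d_min; excluded")
      excluded <- c(excluded, ch); next
    }
    d <- abs(ins$position[ins$chrom == ch] - cen)
    C <- vapply(grid, function(g) sum(d <= g), numeric(1))
    fit <- stats::lm(C ~ grid)
    rows[[ch]] <- data.frame(chrom = ch,
                             slope = unname(stats::coef(fit)[2]),
                             intercept = unname(stats::coef(fit)[1]))
  }
  if (!length(rows)) stop("no chromosome usable for the centromere fit")
  per_chrom <- do.call(rbind, rows)
  rownames(per_chrom) <- NULL
  total_excess <- sum(per_chrom$intercept)
  structure(list(per_chromosome = per_chrom,
                 total_excess = total_excess,
                 fraction = total_excess / library$total_transposons,
                 fit_range = fit_range, excluded = excluded),
            class = "centromere_enrichment")
}

#' @export
print.centromere_enrichment <- function(x, ...) {
  cat("centromere_enrichment:", round(x$total_excess), "excess transposons (",
      sprintf("%.1f%%", 100 * x$fraction), "of library ) over",
      nrow(x$per_chromosome), "chromosome(s)\n")
  invisible(x)
}

#' Nucleotide composition around insertion sites
#'
#' Base frequencies at each position in a window around a seeded random
#' sample of insertion sites, oriented by the transposon insertion (minus-
#' strand sites are reverse-complemented). An unbiased integrase shows the
#' genome's background composition (38% GC in yeast) at every offset.
#'
#' @param library an [insertion_library()].
#' @param index a [genome_index()] carrying sequences.
#' @param flank_bp half-window in bp (default 15).
#' @param sample_n number of sites sampled (default 50000, capped at the
#'   library size).
#' @param seed RNG seed for the sample.
#' @return matrix 4 x (2*flank_bp+1), rows A/C/G/T, columns offsets
#'   -flank..+flank, each column summing to 1; attribute `n_skipped`
#'   counts sites whose window ran off a chromosome end.
#' @export
sequence_context <- function(library, index, flank_bp = 15,
                             sample_n = 50000, seed = 1) {
  if (is.null(index$sequences)) stop("genome index has no sequences")
  ins <- library$insertions
  n <- min(sample_n, nrow(ins))
  idx <- withr::with_seed(seed, sample.int(nrow(ins), n))
  d <- ins[idx, ]
  len <- chrom_length(index, d$chrom)
  ok <- d$position - flank_bp >= 0 & d$position + flank_bp < len
  n_skipped <- sum(!ok)
  d <- d[ok, ]
  views <- Biostrings::DNAStringSet(lapply(seq_len(nrow(d)), function(i) {
    s <- Biostrings::subseq(index$sequences[[d$chrom[i]]],
                            start = d$position[i] - flank_bp + 1,
                            end = d$position[i] + flank_bp + 1)
    if (d$strand[i] == "-") Biostrings::reverseComplement(s) else s
  }))
  cm <- Biostrings::consensusMatrix(views, as.prob = TRUE,
                                    baseOnly = TRUE)[c("A", "C", "G", "T"), ]
  cm <- sweep(cm, 2, colSums(cm), "/")   # drop the 'other' row, renormalize
  colnames(cm) <- as.character(-flank_bp:flank_bp)
  attr(cm, "n_skipped") <- n_skipped
  cm
}
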