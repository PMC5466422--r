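test_that("density track is a truncated boxcar of the insertion indicator", {
  idx <- tiny_index(c(chrI = 2000))
  lib <- make_lib("chrI", 1000)
  tr <- density_track(lib, idx, 40)[["chrI"]]
  expect_equal(sum(tr > 0), 40)                    # plateau spans 40 bp
  expect_equal(unique(round(tr[tr > 0], 10)), 1 / 40)

  # two insertions 10 bp apart: overlap region reaches 2/40
  lib2 <- make_lib(c("chrI", "chrI"), c(1000, 1010))
  tr2 <- density_track(lib2, idx, 40)[["chrI"]]
  expect_equal(max(tr2), 2 / 40)
  # direct convolution oracle
  x <- numeric(2000); x[c(1001, 1011)] <- 1
  conv <- sapply(1:2000, function(i) {
    lo <- max(1, i - 19); hi <- min(2000, i + 20)
    mean(x[lo:hi])
  })
  expect_equal(tr2, conv)

  # empty chromosome stays all-zero; integral matches insertion count
  lib3 <- make_lib("chrI", c(3, 500, 1999))
  trs <- density_track(lib3, tiny_index(c(chrI = 2000, chrII = 500)), 40)
  expect_true(all(trs[["chrII"]] == 0))
  expect_error(density_track(lib3, tiny_index(c(chrI = 30)), 40), "window")
})

test_that("autocorrelation finds planted periods and refuses degenerate tracks", {
  x <- sin(2 * pi * (1:4000) / 160)
  pr <- autocorrelate(x, 500)
  expect_equal(pr$estimated_period, 160)
  expect_equal(pr$acf[1], 1)   # lag 0

  # white noise: no prominent peak in almost all draws
  nas <- vapply(1:20, function(s) {
    withr::with_seed(s, is.na(autocorrelate(rnorm(5000), 500)$estimated_period))
  }, logical(1))
  expect_gte(mean(nas), 0.9)

  # constant track: correlation undefined, reported absent
  pr0 <- autocorrelate(rep(2, 3000), 500)
  expect_true(is.na(pr0$estimated_period))
  expect_error(autocorrelate(rnorm(100), 500), "longer")
})

test_that("nucleosome-phase modulation is recovered from simulated libraries", {
  cfg <- simulation_config(seed = 1, n_chromosomes = 1,
                           chrom_length_bp = 200e3, n_genes = 0,
                           essential_fraction = 0,
                           centromere_excess_fraction = 0,
                           modulation_amplitude = 0.5,
                           nucleosome_period_bp = 160,
                           n_insertions = 5000)
  g <- simulate_genome(cfg)
  lib <- simulate_library(g, cfg)
  pr <- autocorrelate(density_track(lib, g$index, 40))
  expect_true(abs(pr$estimated_period - 160) <= 10)
})

test_that("cross-correlation locates the anti-phase at offset zero", {
  x <- sin(2 * pi * (1:3000) / 160) + rnorm(3000, sd = 0.1)
  cc <- cross_correlate(x, x, offsets = -50:50)
  expect_equal(attr(cc, "argmax"), 0)
  expect_equal(max(cc$correlation), 1)

  cc2 <- cross_correlate(x, -x, offsets = -50:50)
  expect_equal(attr(cc2, "argmin"), 0)
  expect_equal(min(cc2$correlation), -1)

  # insertions anti-phased to a nucleosome sinusoid dip at offset 0
  cfg <- simulation_config(seed = 8, n_chromosomes = 1,
                           chrom_length_bp = 100e3, n_genes = 0,
                           centromere_excess_fraction = 0,
                           modulation_amplitude = 0.8,
                           n_insertions = 8000)
  g <- simulate_genome(cfg)
  lib <- simulate_library(g, cfg)
  tr <- density_track(lib, g$index, 40)[["chr01"]]
  nuc <- -sin(2 * pi * (seq_along(tr) - 1) / 160)  # occupancy anti-phased
  cc3 <- cross_correlate(tr, nuc, offsets = -200:200)
  expect_lt(cc3$correlation[cc3$offset == 0], -0.3)
  # the global minimum sits at offset 0 up to the 160 bp period ambiguity
  # (offsets +-160 are equivalent phases of the sinusoid)
  m <- attr(cc3, "argmin")
  expect_lte(abs(((m + 80) %% 160) - 80), 10)
  expect_lt(cc3$correlation[cc3$offset == 0] - min(cc3$correlation), 0.02)
  expect_error(cross_correlate(x, x[-1]), "length")
})

test_that("centromere enrichment estimates the planted excess fraction", {
  cfg <- simulation_config(seed = 7, n_genes = 0,
                           centromere_excess_fraction = 0.2,
                           modulation_amplitude = 0,
                           n_insertions = 4e4)
  g <- simulate_genome(cfg)
  lib <- simulate_library(g, cfg)
  ce <- centromere_enrichment(lib, g$index)
  expect_true(ce$fraction > 0.15 && ce$fraction < 0.25)
  expect_equal(nrow(ce$per_chromosome), 16)

  # uniform insertions: estimated excess is near zero
  cfg0 <- simulation_config(seed = 7, n_genes = 0,
                            centromere_excess_fraction = 0,
                            modulation_amplitude = 0, n_insertions = 4e4)
  g0 <- simulate_genome(cfg0)
  ce0 <- centromere_enrichment(simulate_library(g0, cfg0), g0$index)
  expect_lt(abs(ce0$fraction), 0.03)

  expect_error(centromere_enrichment(lib, g$index, fit_range = c(3e5, 5e4)),
               "d_min")
})

test_that("sequence context recovers genome composition around sites", {
  cfg <- simulation_config(seed = 12, n_chromosomes = 1,
                           chrom_length_bp = 50e3, n_genes = 0,
                           centromere_excess_fraction = 0,
                           modulation_amplitude = 0, n_insertions = 3000,
                           gc = 0.38, with_sequences = TRUE)
  g <- simulate_genome(cfg)
  lib <- simulate_library(g, cfg)
  cm <- sequence_context(lib, g$index, flank_bp = 10, sample_n = 2000, seed = 3)
  expect_equal(dim(cm), c(4, 21))
  expect_equal(colSums(cm), rep(1, 21), ignore_attr = TRUE)
  gc_obs <- mean(cm["G", ] + cm["C", ])
  expect_equal(gc_obs, 0.38, tolerance = 0.03)
  expect_error(sequence_context(lib, tiny_index()), "sequences")
})
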