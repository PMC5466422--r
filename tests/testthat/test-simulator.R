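test_that("simulated genomes honour the configuration and are seeded", {
  cfg <- simulation_config(seed = 4, n_chromosomes = 16,
                           chrom_length_bp = 50e3, n_genes = 300,
                           essential_fraction = 0.2, n_insertions = 1000)
  g <- simulate_genome(cfg)
  expect_equal(nrow(g$index$chromosomes), 16)
  expect_length(g$index$centromeres, 16)
  expect_equal(nrow(g$genes), 300)
  # genes do not overlap within a chromosome
  by_chrom <- split(g$genes, g$genes$chrom)
  for (d in by_chrom) {
    d <- d[order(d$start), ]
    if (nrow(d) > 1) expect_true(all(d$start[-1] >= d$end[-nrow(d)]))
  }
  # essential fraction within binomial range
  expect_equal(mean(g$genes$essential), 0.2, tolerance = 0.08)
  # deterministic given the seed
  expect_identical(g$genes, simulate_genome(cfg)$genes)

  # sequences hit the configured GC content
  cfgs <- simulation_config(seed = 4, n_chromosomes = 1,
                            chrom_length_bp = 200e3, n_genes = 0,
                            gc = 0.38, with_sequences = TRUE)
  gs <- simulate_genome(cfgs)
  freq <- Biostrings::letterFrequency(gs$index$sequences[[1]], "GC",
                                      as.prob = TRUE)
  expect_equal(unname(freq), 0.38, tolerance = 0.01)

  # genes that cannot fit are an error
  expect_error(simulate_genome(
    simulation_config(seed = 1, n_chromosomes = 1, chrom_length_bp = 5e3,
                      n_genes = 50, gene_length_range = c(400, 500))),
    "fit")
})

test_that("simulated libraries obey the configured laws", {
  cfg <- simulation_config(seed = 9, n_chromosomes = 2,
                           chrom_length_bp = 100e3, n_genes = 50,
                           essential_fraction = 0.2,
                           centromere_excess_fraction = 0,
                           modulation_amplitude = 0, n_insertions = 10e3)
  g <- simulate_genome(cfg)
  lib <- simulate_library(g, cfg)
  expect_equal(lib$total_transposons, 10e3)
  expect_identical(lib$insertions,
                   simulate_library(g, cfg)$insertions)  # deterministic

  # read law: median 22 at scale
  expect_equal(stats::median(lib$insertions$reads), 22)

  # essential spans contain zero insertions by construction
  ess <- g$genes[g$genes$essential, ]
  st <- count_per_gene(lib, ess)
  expect_true(all(st$tn == 0))

  # no modulation, no centromere component: positions pass a KS test
  # against uniform on the non-essential support (checked per chromosome
  # after dropping essential spans from consideration)
  pos <- lib$insertions$position[lib$insertions$chrom == "chr01"]
  ess1 <- ess[ess$chrom == "chr01", ]
  keep <- !vapply(pos, function(p)
    any(p >= ess1$start & p < ess1$end), logical(1))
  # map to the cumulative non-essential coordinate to make the null uniform
  breaks <- sort(c(0, ess1$start, ess1$end, 100e3))
  widths <- diff(breaks)
  open <- rep(c(TRUE, FALSE), length.out = length(widths))
  cum_open <- cumsum(c(0, widths * open))
  u_bp <- vapply(pos[keep], function(p) {
    i <- findInterval(p, breaks, rightmost.closed = TRUE)
    cum_open[i] + if (open[i]) p - breaks[i] else 0
  }, numeric(1))
  # sub-bp jitter removes integer ties without changing the distribution
  u <- (u_bp + stats::runif(length(u_bp))) / sum(widths * open)
  expect_gt(stats::ks.test(u, "punif")$p.value, 0.01)

  # strand balance
  expect_equal(mean(lib$insertions$strand == "+"), 0.5, tolerance = 0.02)

  # same-orientation sites always separated by more than the 2 bp tolerance
  ins <- lib$insertions
  o <- order(ins$chrom, ins$strand, ins$position)
  d <- diff(ins$position[o])
  same <- ins$chrom[o][-1] == ins$chrom[o][-nrow(ins)] &
    ins$strand[o][-1] == ins$strand[o][-nrow(ins)]
  expect_true(all(d[same] > 2))

  # essential genes tiling the whole genome leave no insertion support
  cfg_all <- simulation_config(seed = 2, n_chromosomes = 1,
                               chrom_length_bp = 1e3, n_genes = 2,
                               gene_length_range = c(500, 500),
                               essential_fraction = 0.999, n_insertions = 10)
  g_all <- simulate_genome(cfg_all)
  g_all$genes$essential <- TRUE
  g_all$truth$essential <- TRUE
  expect_error(simulate_library(g_all, cfg_all), "support")
})

test_that("condition libraries thin lethal genes and boost resistant reads", {
  cfg <- simulation_config(seed = 21, n_chromosomes = 2,
                           chrom_length_bp = 80e3, n_genes = 60,
                           essential_fraction = 0, centromere_excess_fraction = 0,
                           n_insertions = 5e3)
  g <- simulate_genome(cfg)
  base <- simulate_library(g, cfg)
  dead <- g$genes$gene_id[1:3]
  cond <- simulate_condition(base, g$genes,
                             stats::setNames(rep(0, 3), dead), seed = 2)
  st <- count_per_gene(cond, g$genes)
  expect_true(all(st$tn[st$gene_id %in% dead] == 0))

  # fitness 1 everywhere leaves the library untouched
  neutral <- simulate_condition(base, g$genes,
                                stats::setNames(1, g$genes$gene_id[4]),
                                seed = 3)
  expect_identical(neutral$insertions, base$insertions)

  # positive selection multiplies reads
  up <- simulate_condition(base, g$genes,
                           stats::setNames(50, g$genes$gene_id[5]), seed = 4)
  g5 <- g$genes[5, ]
  hit <- up$insertions$position >= g5$start & up$insertions$position < g5$end &
    up$insertions$chrom == g5$chrom
  base_hit <- base$insertions$position >= g5$start &
    base$insertions$position < g5$end & base$insertions$chrom == g5$chrom
  expect_equal(sum(up$insertions$reads[hit]),
               50 * sum(base$insertions$reads[base_hit]))

  expect_error(simulate_condition(base, g$genes, c(NOPE = 0.5)), "unknown")
})

test_that("clone representation arithmetic matches the worked example", {
  expect_equal(clone_representation(2e6, 2000, 2.5e6, 0.8), 2000)
  # identity: n clones at exactly n cells, all transposed
  expect_equal(clone_representation(5e6, 2000, 2.5e3, 1), 1)
  # linear in the transposed fraction
  expect_equal(clone_representation(2e6, 2000, 2.5e6, 0.4), 1000)
  expect_error(clone_representation(0, 1, 1, 1), "> 0")
  expect_error(clone_representation(1, 1, 1, 1.5), "> 0")
})

test_that("emitted SAM round-trips through the mapper exactly", {
  cfg <- simulation_config(seed = 6, n_chromosomes = 2,
                           chrom_length_bp = 60e3, n_genes = 40,
                           n_insertions = 3e3)
  g <- simulate_genome(cfg)
  lib <- simulate_library(g, cfg)
  sam <- tempfile(fileext = ".sam")
  write_sam(lib, g$index, sam)
  back <- merge_junctions(extract_junctions(sam), library_id = lib$library_id)
  expect_identical(back$insertions, lib$insertions)
  expect_equal(back$total_reads, lib$total_reads)
})
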