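test_that("the simulator is fully deterministic per seed", {
  cfg <- sim_config(seed = 7L)
  a <- simulate_genome_annotation(cfg)
  b <- simulate_genome_annotation(cfg)
  expect_identical(a$genome, b$genome)
  expect_identical(a$annotation$raw, b$annotation$raw)
  ta <- plant_sites(cfg, a)
  tb <- plant_sites(cfg, b)
  expect_identical(ta$signal, tb$signal)
  expect_identical(ta$background, tb$background)
  la <- suppressWarnings(simulate_library(cfg, ta, "rbp", "rbp1"))
  lb <- suppressWarnings(simulate_library(cfg, tb, "rbp", "rbp1"))
  expect_identical(la$seq, lb$seq)
  expect_identical(la$mm, lb$mm)
})

test_that("annotation layout matches the configured counts", {
  sim <- sim_default()
  raw <- sim$annotation$raw
  cfg <- sim$config
  expect_equal(sum(raw$feature == "transcript"),
               cfg$n_transcripts + cfg$n_lincrna)
  expect_equal(sum(raw$feature == "lincRNA"), cfg$n_lincrna)
  expect_equal(sum(raw$feature == "repeat"), cfg$n_repeats)
  expect_equal(sum(raw$feature == "3utr"), cfg$n_transcripts)
  # transcripts do not overlap each other
  tx <- raw[raw$feature == "transcript", ]
  expect_equal(nrow(union_sites(
    data.frame(tx[, c("chrom", "start", "end", "strand")], site_id = "x",
               read_count = 1L, conv_locs = ".",
               max_depth = NA_integer_), stranded = FALSE)), nrow(tx))
})

test_that("genome GC content is within 3 SE of the configured value", {
  cfg <- sim_config(seed = 8L)
  g <- simulate_genome_annotation(cfg)$genome
  s <- paste(g, collapse = "")
  n <- nchar(s)
  gc <- sum(strsplit(s, "")[[1]] %in% c("G", "C")) / n
  se <- sqrt(cfg$gc * (1 - cfg$gc) / n)
  expect_lt(abs(gc - cfg$gc), 3 * se)
})

test_that("every planted signal site carries the motif", {
  sim <- sim_default()
  seqs <- site_sequences(sim$truth$signal, sim$genome)
  hits <- vapply(seqs, function(s)
    length(scan_iupac(sim$config$signal_motif, s)) > 0, TRUE)
  expect_true(all(hits))
})

test_that("background sharing fraction controls site identity", {
  sim1 <- plant_sites(sim_config(seed = 9L, background_sharing = 1),
                      simulate_genome_annotation(sim_config(seed = 9L)))
  expect_true(all(sim1$background$shared))
  sim0 <- plant_sites(sim_config(seed = 9L, background_sharing = 0),
                      simulate_genome_annotation(sim_config(seed = 9L)))
  expect_true(all(!sim0$background$shared))
  # per-library unique sites are pairwise disjoint
  key <- paste(sim0$background$chrom, sim0$background$start)
  expect_equal(anyDuplicated(key), 0L)
})

test_that("conversion regimes are honored, including the zero regime", {
  cfg0 <- sim_config(seed = 10L, p_conv_crosslinked = 0,
                     p_conv_background_reads = 0)
  sim <- simulate_genome_annotation(cfg0)
  tr <- plant_sites(cfg0, sim)
  lib <- suppressWarnings(simulate_library(cfg0, tr, "rbp", "rbp1"))
  u <- filter_utilized(lib[, 1:9])$utilized
  expect_equal(conversion_fraction(u), 0)
})

test_that("background site composition is G-dominant on the site strand", {
  sim <- sim_default()
  seqs <- site_sequences(sim$truth$background, sim$genome)
  base_freq <- table(strsplit(paste(seqs, collapse = ""), "")[[1]])
  expect_true(base_freq["G"] > max(base_freq[c("A", "C")]))
  expect_true(base_freq["A"] > base_freq["C"])
})

test_that("call evaluation reports precision and recall", {
  truth <- rbind(mk_site("c1", 0, 10, id = "t1"),
                 mk_site("c1", 100, 110, id = "t2"))
  expect_equal(evaluate_calls(truth, truth),
               list(precision = 1, recall = 1, n_called = 2L,
                    n_truth = 2L))
  r <- evaluate_calls(parclipbg:::empty_sites(), truth)
  expect_equal(r$recall, 0)
  expect_true(is.na(r$precision))
})

test_that("written datasets round-trip and include ground truth", {
  od <- file.path(tempdir(), "simout")
  unlink(od, recursive = TRUE)
  sim <- suppressWarnings(simulate_parclip(sim_config(seed = 12L,
                                                      total_reads = 200L),
                                           outdir = od))
  expect_true(file.exists(file.path(od, "genome.fa")))
  reads <- read_alignments(file.path(od, "reads", "bg1.tsv"), "tabular")
  expect_equal(nrow(reads), nrow(sim$libraries$bg1))
  tr <- read_sites_bed(file.path(od, "truth", "signal_sites.bed"))
  expect_equal(nrow(tr), nrow(sim$truth$signal))
  cfg <- yaml::read_yaml(file.path(od, "config.yaml"))
  expect_equal(cfg$seed, 12L)
})
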