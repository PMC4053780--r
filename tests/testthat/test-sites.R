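utilized_from <- function(reads) filter_utilized(reads)$utilized

test_that("overlapping reads merge into one maximal group", {
  u <- utilized_from(mk_reads(
    mk_read("a", start = 100, end = 120, mm = "105:T>C"),
    mk_read("b", start = 115, end = 135, mm = "117:T>C")))
  g <- call_groups(u)
  expect_equal(nrow(g), 1L)
  expect_equal(g$start, 100L)
  expect_equal(g$end, 135L)
  expect_equal(g$read_count, 2L)
  expect_equal(g$conv_locs, "105;117")
  expect_equal(g$max_depth, 2L)  # depth 2 on [115,120)
})

test_that("opposite strands never merge; adjacency never merges", {
  u <- utilized_from(mk_reads(
    mk_read("a", start = 100, end = 120),
    mk_read("b", start = 100, end = 120, strand = "-"),
    mk_read("c", start = 120, end = 140)))
  g <- call_groups(u)
  expect_equal(nrow(g), 3L)
  expect_equal(nrow(call_groups(u, stranded = FALSE)), 2L)
})

test_that("groups match the pairwise-merge oracle and conserve reads", {
  set.seed(11)
  for (n in c(50, 200)) {
    start <- sample.int(800, n, replace = TRUE)
    reads <- mk_read(sprintf("r%03d", 1:n), chrom = "c1", start = 0,
                     end = 20)
    reads$chrom <- sample(c("c1", "c2"), n, replace = TRUE)
    reads$start <- start
    reads$end <- start + sample(15:30, n, replace = TRUE)
    reads$seq <- vapply(reads$end - reads$start, function(w)
      paste(rep("A", w), collapse = ""), "")
    reads$strand <- sample(c("+", "-"), n, replace = TRUE)
    u <- utilized_from(reads)
    g <- call_groups(u)
    oracle <- brute_merge(u)
    expect_equal(g[, c("chrom", "start", "end", "strand")], oracle)
    expect_equal(sum(g$read_count), nrow(u))
  }
})

test_that("cluster thresholds are applied exactly at their boundaries", {
  mkg <- function(count, conv) {
    g <- mk_site("c1", 100, 140, "+", "G1", count, conv)
    g$read_ids <- "x"
    g
  }
  expect_equal(nrow(call_clusters(mkg(5L, "105;117"))), 1L)
  expect_equal(nrow(call_clusters(mkg(6L, "105"))), 0L)
  expect_equal(nrow(call_clusters(mkg(4L, "105;110;115"))), 0L)
  expect_error(call_clusters(mkg(5L, "105;117"), min_reads = 0),
               "positive")
})

test_that("raising cluster thresholds never increases cluster count", {
  sim <- sim_default()
  g <- call_groups(filter_utilized(sim$libraries$bg1)$utilized)
  n_prev <- Inf
  for (t in c(1, 5, 25)) {
    n <- nrow(call_clusters(g, min_reads = t, min_conv_locs = 1))
    expect_lte(n, n_prev)
    n_prev <- n
  }
  expect_lte(nrow(call_clusters(g, 5, 3)), nrow(call_clusters(g, 5, 2)))
  expect_true(all(call_clusters(g)$site_id %in% g$site_id))
})

test_that("site sequences are transcript-oriented", {
  genome <- Biostrings::DNAStringSet(c(c1 = "ACGT", c2 = "AAAC"))
  expect_equal(site_sequences(mk_site("c1", 0, 4, "+"), genome), "ACGT")
  expect_equal(site_sequences(mk_site("c1", 0, 4, "-"), genome), "ACGT")
  expect_equal(site_sequences(mk_site("c2", 0, 3, "-"), genome), "TTT")
  expect_error(site_sequences(mk_site("c1", 0, 5, "+"), genome), "bounds")
  # independent reverse-complement oracle on simulated sites
  sim <- sim_default()
  sites <- sim$truth$background[1:20, ]
  got <- site_sequences(sites, sim$genome)
  for (i in seq_len(20)) {
    fwd <- as.character(Biostrings::subseq(sim$genome[[sites$chrom[i]]],
                                           sites$start[i] + 1L,
                                           sites$end[i]))
    want <- if (sites$strand[i] == "-")
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
    else fwd
    expect_equal(got[i], want)
  }
})
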