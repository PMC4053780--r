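test_that("overlap is >= 1 bp with half-open adjacency excluded", {
  a <- mk_site("c1", 100, 110)
  expect_true(site_overlaps(a, mk_site("c1", 109, 115))[1, 1])
  expect_false(site_overlaps(a, mk_site("c1", 110, 120))[1, 1])
  expect_false(site_overlaps(a, mk_site("c2", 100, 110))[1, 1])
  expect_false(site_overlaps(a, mk_site("c1", 100, 110, "-"))[1, 1])
  expect_true(site_overlaps(a, mk_site("c1", 100, 110, "-"),
                            stranded = FALSE)[1, 1])
})

test_that("union merges overlapping intervals and sums read counts", {
  u <- union_sites(list(mk_site("c1", 100, 110, count = 3),
                        mk_site("c1", 105, 120, count = 4, conv = "107")))
  expect_equal(nrow(u), 1L)
  expect_equal(u$start, 100L)
  expect_equal(u$end, 120L)
  expect_equal(u$read_count, 7L)
  expect_equal(u$conv_locs, "107")
  disjoint <- rbind(mk_site("c1", 0, 10, id = "a"),
                    mk_site("c1", 50, 60, id = "b"))
  expect_equal(union_sites(disjoint)[, c("start", "end")],
               disjoint[, c("start", "end")])
})

test_that("union matches the pairwise-merge oracle on random instances", {
  set.seed(5)
  for (rep in 1:20) {
    s <- rand_sites(80)
    u <- union_sites(s)
    expect_equal(u[, c("chrom", "start", "end", "strand")],
                 brute_merge(s))
  }
})

test_that("background subtraction removes whole sites and partitions", {
  sites <- rbind(mk_site("c1", 100, 135, id = "a"),
                 mk_site("c1", 300, 320, id = "b"))
  bg <- mk_site("c1", 130, 200, id = "bg")
  r <- subtract_background(sites, bg)
  expect_equal(r$removed$site_id, "a")   # 5 bp overlap -> whole site gone
  expect_equal(r$kept$site_id, "b")
  # empty background is the identity
  r0 <- subtract_background(sites, parclipbg:::empty_sites())
  expect_equal(nrow(r0$kept), 2L)
  expect_equal(nrow(r0$removed), 0L)
  # idempotent, disjoint partition
  r2 <- subtract_background(r$kept, bg)
  expect_equal(r2$kept, r$kept)
  expect_equal(nrow(r2$removed), 0L)
  set.seed(6)
  s <- rand_sites(300)
  b <- rand_sites(100)
  r3 <- subtract_background(s, b)
  expect_equal(nrow(r3$kept) + nrow(r3$removed), 300L)
  expect_equal(length(intersect(r3$kept$site_id, r3$removed$site_id)), 0L)
  hit <- brute_hits_any(s, b)
  expect_setequal(r3$removed$site_id, s$site_id[hit])
})

test_that("three-way overlap report handles identity and disjoint cases", {
  A <- rbind(mk_site("c1", 0, 10, id = "x", count = 5),
             mk_site("c1", 50, 60, id = "y", count = 5))
  r <- venn3(A, A, A, min_reads = 5)
  expect_equal(unname(r$pct_in_both_others), rep(100, 3))
  expect_equal(unname(r$pct_in_at_least_one), rep(100, 3))
  expect_equal(unname(r$venn["A&B&C"]), 2L)
  B <- mk_site("c1", 100, 110, count = 9)
  C <- mk_site("c1", 200, 210, count = 9)
  r2 <- venn3(A, B, C)
  expect_equal(unname(r2$pct_in_at_least_one), rep(0, 3))
  expect_equal(sum(r2$venn), 4L)
  # venn regions partition each library's loci
  expect_equal(unname(r2$locus_counts),
               c(2L, 1L, 1L))
  expect_error(venn3(A, B, C, min_reads = 0), "min_reads")
})

test_that("depth filtering in the overlap report is monotone", {
  sim <- sim_default()
  g <- lapply(c("bg1", "bg2", "bg3"), function(l)
    call_groups(filter_utilized(sim$libraries[[l]])$utilized))
  counts <- vapply(c(1, 5, 25), function(t)
    venn3(g[[1]], g[[2]], g[[3]], min_reads = t)$site_counts,
    numeric(3))
  expect_true(all(diff(t(counts)) <= 0))
})

test_that("membership binning saturates and zeroes correctly", {
  a <- mk_site("c1", 0, 10, count = 2)
  b <- mk_site("c1", 5, 15, count = 3)
  r <- bin_by_membership(list(a, b), union_sites(list(a, b)))
  expect_equal(r$n_loci, c(0L, 1L))
  expect_equal(r$pct_background[2], 100)
  a2 <- mk_site("c1", 0, 10)
  b2 <- mk_site("c1", 100, 110)
  r2 <- bin_by_membership(list(a2, b2), parclipbg:::empty_sites())
  expect_equal(r2$n_loci, c(2L, 0L))
  expect_equal(r2$pct_background[1], 0)
})

test_that("depth correlation is 1 on identity, ~0 on independence", {
  set.seed(7)
  A <- rand_sites(60, span = 5000, width_max = 20)
  A <- A[!duplicated(paste(A$chrom, A$start)), ]
  expect_equal(depth_correlation(A, A)$r_squared, 1)
  # scaling read counts leaves the log-scale fit essentially perfect
  B <- A
  B$read_count <- 2L * A$read_count
  expect_gt(depth_correlation(A, B)$r_squared, 0.99)
  # independent counts: R^2 near zero
  C <- A
  C$read_count <- sample(A$read_count)
  expect_lt(depth_correlation(A, C)$r_squared, 0.2)
  expect_error(depth_correlation(A[1, ], A[1, ]), "3 matched loci")
})
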