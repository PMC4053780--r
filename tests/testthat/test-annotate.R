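mk_index <- function() {
  build_annotation_index(data.frame(
    chrom = "c1",
    feature = c("transcript", "5utr", "cds", "3utr", "transcript",
                "lincRNA", "repeat"),
    start = c(1000L, 1000L, 1100L, 1700L, 3000L, 3000L, 5000L),
    end = c(2000L, 1100L, 1700L, 2000L, 3500L, 3500L, 5200L),
    strand = c("+", "+", "+", "+", "-", "-", "+"),
    transcript_id = c("t1", "t1", "t1", "t1", "l1", "l1", "rp1")))
}

test_that("category assignment follows the fixed priority", {
  idx <- mk_index()
  expect_equal(assign_category(mk_site("c1", 1200, 1230), idx), "cds")
  # a site straddling cds and 3utr takes the higher-priority 3utr
  expect_equal(assign_category(mk_site("c1", 1690, 1720), idx), "3utr")
  expect_equal(assign_category(mk_site("c1", 9000, 9030), idx),
               "intergenic")
  expect_equal(assign_category(mk_site("c1", 5050, 5080), idx), "repeat")
  # priority is configurable
  expect_equal(assign_category(mk_site("c1", 1690, 1720), idx,
                               priority = c("cds", "5utr", "3utr",
                                            "intron", "lincRNA",
                                            "repeat")), "cds")
})

test_that("category composition sums to 100 and tracks transcript shares", {
  idx <- mk_index()
  comp <- category_composition(rbind(mk_site("c1", 1200, 1230),
                                     mk_site("c1", 1210, 1240)), idx)
  expect_equal(unname(comp["cds"]), 100)
  expect_equal(sum(comp), 100)
  expect_error(category_composition(parclipbg:::empty_sites(), idx),
               "empty")
  # a simulated total-RNA library lands in transcripts at their
  # nucleotide shares: cds+utr+intron categories dominate intergenic
  sim <- sim_default()
  comp2 <- category_composition(sim$libraries$total, sim$annotation)
  expect_equal(sum(comp2), 100, tolerance = 1e-9)
  expect_lt(comp2["intergenic"], 20)
  expect_gt(comp2["cds"], comp2["5utr"])  # cds is the widest feature
})

test_that("TSS window density follows the stated normalization", {
  idx <- mk_index()
  # all 25 site nucleotides inside the [25,50) window of the + transcript;
  # the window union spans both transcripts (50 bp = 0.050 kb), so
  # density = (25/25) / 0.050 = 20 per kb
  site <- mk_site("c1", 1025, 1050)
  d <- tss_window_density(site, idx, windows = list(c(25, 50)))
  # two transcripts (t1 at 1000+, l1 TSS at 3500-) -> 50 bp of window
  expect_equal(d$window_kb, 0.050)
  expect_equal(d$density, (25 / 25) / 0.050)
  # no items in window -> 0
  d0 <- tss_window_density(mk_site("c1", 1900, 1920), idx,
                           windows = list(c(25, 50)))
  expect_equal(d0$density, 0)
  # library-size invariance: duplicating every item changes nothing
  dup <- rbind(site, site)
  expect_equal(tss_window_density(dup, idx,
                                  windows = list(c(25, 50)))$density,
               d$density)
  # minus-strand windows run downstream, i.e. to lower coordinates
  dm <- tss_window_density(mk_site("c1", 3450, 3475, "-"), idx,
                           windows = list(c(25, 50)))
  expect_equal(dm$nt_in, 25L)
})

test_that("terminus enrichment is capped at Inf and ~1 under uniformity", {
  one_tx <- build_annotation_index(data.frame(
    chrom = "c1", feature = "transcript", start = 1000L, end = 2000L,
    strand = "+", transcript_id = "t1"))
  at_term <- mk_site("c1", 1960, 2000)
  r <- terminus_enrichment(at_term, one_tx)
  expect_true(r$capped)
  expect_equal(r$ratio, Inf)
  # sites tiling the transcript uniformly -> ratio near 1
  tile <- do.call(rbind, lapply(seq(1000, 1975, by = 25), function(s)
    mk_site("c1", s, s + 25)))
  ru <- terminus_enrichment(tile, one_tx)
  expect_equal(ru$ratio, 1, tolerance = 0.05)
  # transcripts shorter than the window are skipped with a warning
  with_tiny <- build_annotation_index(data.frame(
    chrom = "c1", feature = c("transcript", "transcript"),
    start = c(1000L, 0L), end = c(2000L, 30L), strand = "+",
    transcript_id = c("t1", "tiny")))
  expect_warning(r2 <- terminus_enrichment(at_term, with_tiny), "shorter")
  expect_equal(r2$ratio, r$ratio)
})
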