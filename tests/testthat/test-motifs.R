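test_that("k-mer counting handles overlap, N windows and rank order", {
  t1 <- count_kmers("GGGG", 2)
  expect_equal(unname(t1$counts["GG"]), 3L)
  expect_equal(sum(count_kmers("ACGNA", 2)$counts), 2L)  # GN, NA skipped
  t2 <- count_kmers(c("AAAC", "AAAC"), 3)
  expect_equal(names(t2$counts), c("AAA", "AAC"))  # count then lex order
  expect_equal(t2$total_nt, 8L)
  expect_warning(count_kmers("AC", 5), "empty")
})

test_that("k-mer counts agree with brute-force substring enumeration", {
  set.seed(21)
  for (k in c(2, 4, 7)) {
    seqs <- replicate(15, rand_seq(sample(8:40, 1)))
    tab <- count_kmers(seqs, k)$counts
    brute <- table(unlist(lapply(seqs, function(s) {
      n <- nchar(s)
      if (n < k) character(0) else substring(s, 1:(n - k + 1), k:n)
    })))
    expect_equal(sum(tab), sum(brute))
    expect_equal(unname(tab[names(brute)]), unname(as.integer(brute)))
    # total windows conserved
    expect_equal(sum(tab), sum(pmax(0, nchar(seqs) - k + 1)))
    # order invariance
    expect_equal(count_kmers(rev(seqs), k)$counts, tab)
  }
})

test_that("dinucleotide shuffle preserves the dinucleotide multiset", {
  expect_equal(dinucleotide_shuffle("AAAA"), "AAAA")
  set.seed(31)
  seqs <- replicate(300, rand_seq(sample(5:50, 1),
                                  prob = c(.4, .1, .2, .3)))
  sh <- dinucleotide_shuffle(seqs, seed = 1)
  for (i in seq_along(seqs))
    expect_equal(dinuc_multiset(sh[i]), dinuc_multiset(seqs[i]))
  # deterministic under a seed, seed-free draws vary
  expect_equal(dinucleotide_shuffle(seqs, seed = 1), sh)
  # N splits the sequence into independently shuffled segments
  shn <- dinucleotide_shuffle("ACGTNNACGTA", seed = 4)
  expect_equal(substr(shn, 5, 6), "NN")
  expect_equal(dinuc_multiset(substr(shn, 1, 4)), dinuc_multiset("ACGT"))
})

test_that("IUPAC scanning matches a regex-expansion oracle", {
  expect_equal(scan_iupac("UGUAHAUA", "TGTACATA"), 0L)  # H accepts C
  expect_equal(scan_iupac("UGUAHAUA", "TGTAGATA"), integer(0))
  expect_error(scan_iupac("UGZA", "TGTA"), "invalid IUPAC")
  set.seed(41)
  codes <- c("A", "C", "G", "T", "R", "Y", "H", "N", "W")
  for (i in 1:50) {
    pat <- paste(sample(codes, sample(3:6, 1), replace = TRUE),
                 collapse = "")
    s <- rand_seq(60)
    expect_equal(scan_iupac(pat, s), regex_scan(pat, s), info = pat)
  }
})

test_that("enrichment test p-values are bounded away from zero", {
  set.seed(51)
  seqs <- replicate(10, rand_seq(30, prob = c(.4, .3, .2, .1)))
  r <- kmer_enrichment_test(seqs, "GGGGGGGG", n_shuffles = 19, seed = 2)
  expect_equal(r$p_empirical, 1)  # absent everywhere
  expect_gt(r$p_empirical, 0)
  r2 <- kmer_enrichment_test(seqs, "AC", n_shuffles = 19, seed = 2)
  expect_gte(r2$p_empirical, 1 / 20)  # +1 correction floor
  expect_error(kmer_enrichment_test("ACG", "ACGT", n_shuffles = 19),
               "longer")
  expect_error(kmer_enrichment_test(seqs, "AC", n_shuffles = 5), "19")
})

test_that("logo matrices are count-weighted per-position frequencies", {
  t1 <- count_kmers("GGGGGGGG", 8)
  m <- top_kmer_logo(t1, 1)
  expect_equal(unname(m["G", ]), rep(1, 8))
  expect_equal(unname(colSums(m)), rep(1, 8))
  t2 <- count_kmers(c("AAAA", "CCCC"), 4)
  expect_warning(m2 <- top_kmer_logo(t2, 25), "using all")
  expect_equal(unname(m2["A", ]), rep(0.5, 4))
  expect_equal(unname(m2["C", ]), rep(0.5, 4))
})

test_that("motif percentages and enrichment change follow the arithmetic", {
  seqs <- c("TTTGTATT", "AAAAAAAA")
  expect_equal(percent_sites_with_motif(seqs, "UGUA"), 50)
  expect_equal(percent_sites_with_motif(seqs, "CCC"), 0)
  expect_error(percent_sites_with_motif(character(0), "UGUA"), "no seq")
  before <- c(rep("TGTAAAAA", 4), rep("CCCCCCCC", 6))
  after <- c(rep("TGTAAAAA", 12), rep("CCCCCCCC", 13))
  r <- motif_enrichment_change(before, after, "UGUA")
  expect_equal(r$pct_before, 40)
  expect_equal(r$pct_after, 48)
  expect_equal(r$percent_change, 20)
  expect_equal(r$fold, 1.2)
  r0 <- motif_enrichment_change(before, before, "UGUA")
  expect_equal(r0$percent_change, 0)
  rna <- motif_enrichment_change("AAAA", "TGTA", "UGUA")
  expect_true(rna$undefined)
})

test_that("matched pairs is zero on identity and antisymmetric", {
  set.seed(61)
  seqs_a <- replicate(20, rand_seq(30))
  seqs_b <- replicate(20, rand_seq(30, prob = c(.4, .2, .2, .2)))
  ta <- count_kmers(seqs_a, 7)
  tb <- count_kmers(seqs_b, 7)
  same <- matched_pairs(ta, ta)
  expect_true(all(same$log_ratio == 0))
  ab <- matched_pairs(ta, tb)
  ba <- matched_pairs(tb, ta)
  ab <- ab[order(ab$kmer), ]
  ba <- ba[order(ba$kmer), ]
  expect_equal(ab$log_ratio, -ba$log_ratio)
  # a k-mer present only after has a positive log-ratio
  only_after <- setdiff(names(tb$counts), names(ta$counts))
  if (length(only_after))
    expect_true(all(ab$log_ratio[ab$kmer %in% only_after] > 0))
  expect_error(matched_pairs(ta, count_kmers(seqs_b, 6)), "different k")
})
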