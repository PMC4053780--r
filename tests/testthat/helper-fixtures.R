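# Shared fixtures and independent brute-force oracles.

# one default simulation, generated once per test run
.fixture_cache <- new.env()

sim_default <- function() {
  if (is.null(.fixture_cache$sim))
    .fixture_cache$sim <- suppressWarnings(simulate_parclip(sim_config()))
  .fixture_cache$sim
}

# compact read-row constructor
mk_read <- function(id, chrom = "c1", start, end, strand = "+",
                    seq = NULL, mm = ".", nmap = 1L, lib = "test") {
  if (is.null(seq)) seq <- paste(rep("A", end - start), collapse = "")
  data.frame(read_id = id, chrom = chrom, start = as.integer(start),
             end = as.integer(end), strand = strand, seq = seq, mm = mm,
             nmap = as.integer(nmap), library_id = lib)
}

mk_reads <- function(...) do.call(rbind, list(...))

# compact site-row constructor
mk_site <- function(chrom = "c1", start, end, strand = "+", id = "S1",
                    count = 1L, conv = ".") {
  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(end), strand = strand, site_id = id,
             read_count = as.integer(count), conv_locs = conv,
             max_depth = NA_integer_)
}

rand_sites <- function(n, span = 1000L, width_max = 30L, chroms = c("c1", "c2")) {
  start <- sample.int(span, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE), start = start,
             end = start + sample.int(width_max, n, replace = TRUE),
             strand = sample(c("+", "-"), n, replace = TRUE),
             site_id = sprintf("R%04d", seq_len(n)),
             read_count = sample.int(40, n, replace = TRUE),
             conv_locs = ".", max_depth = NA_integer_)
}

# arithmetic overlap oracle
brute_overlap <- function(a, b, stranded = TRUE) {
  a$chrom == b$chrom & max(a$start, b$start) < min(a$end, b$end) &
    (!stranded | a$strand == b$strand)
}

# O(n^2) pairwise-merge oracle for interval union (plain vectors for
# speed; the algorithm stays the naive repeated pairwise merge)
brute_merge <- function(sites, stranded = TRUE) {
  chrom <- sites$chrom
  start <- sites$start
  end <- sites$end
  strand <- if (stranded) sites$strand else rep("+", length(chrom))
  repeat {
    merged <- FALSE
    i <- 1
    while (i < length(start)) {
      j <- i + 1
      while (j <= length(start)) {
        if (chrom[i] == chrom[j] && strand[i] == strand[j] &&
              max(start[i], start[j]) < min(end[i], end[j])) {
          start[i] <- min(start[i], start[j])
          end[i] <- max(end[i], end[j])
          chrom <- chrom[-j]; start <- start[-j]; end <- end[-j]
          strand <- strand[-j]
          merged <- TRUE
        } else j <- j + 1
      }
      i <- i + 1
    }
    if (!merged) break
  }
  out <- data.frame(chrom = chrom, start = start, end = end,
                    strand = strand)
  out <- out[order(out$chrom, out$start, out$end, out$strand), ]
  rownames(out) <- NULL
  out
}

# arithmetic any-overlap oracle: does site i of s hit anything in bg
brute_hits_any <- function(s, bg, stranded = TRUE) {
  vapply(seq_len(nrow(s)), function(i)
    any(s$chrom[i] == bg$chrom &
          pmax(s$start[i], bg$start) < pmin(s$end[i], bg$end) &
          (!stranded | s$strand[i] == bg$strand)), TRUE)
}

# vectorized arithmetic overlap oracle over paired rows
brute_overlap_pairs <- function(a, b, stranded = TRUE) {
  a$chrom == b$chrom & pmax(a$start, b$start) < pmin(a$end, b$end) &
    (!stranded | a$strand == b$strand)
}

# sorted dinucleotide multiset of a sequence
dinuc_multiset <- function(s) {
  n <- nchar(s)
  if (n < 2) return(character(0))
  sort(substring(s, 1:(n - 1), 2:n))
}

# regex-expansion oracle for IUPAC scanning (0-based offsets)
regex_scan <- function(pattern, sequence) {
  codes <- Biostrings::IUPAC_CODE_MAP
  pattern <- gsub("U", "T", toupper(pattern))
  rx <- paste0("(?=", paste(vapply(strsplit(pattern, "")[[1]], function(ch)
    paste0("[", codes[[ch]], "]"), ""), collapse = ""), ")")
  m <- gregexpr(rx, sequence, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m) - 1L
}

# all distinct rearrangements of a short sequence preserving the
# dinucleotide multiset, by exhaustive permutation
enumerate_shuffles <- function(s) {
  ch <- strsplit(s, "")[[1]]
  perm <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perm(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  ps <- unique(vapply(perm(ch), paste, "", collapse = ""))
  ref <- dinuc_multiset(s)
  ps[vapply(ps, function(p) identical(dinuc_multiset(p), ref), TRUE)]
}

rand_seq <- function(len, prob = c(.25, .25, .25, .25)) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = prob),
        collapse = "")
}
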