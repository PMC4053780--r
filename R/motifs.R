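# Background-aware k-mer motif analysis: counting, dinucleotide-preserving
# shuffle null, top-k-mer logos, IUPAC scanning, and matched-pairs
# comparison of k-mer frequencies before/after background correction.

.norm_dna <- function(x) {
  x <- toupper(x)
  gsub("U", "T", x, fixed = TRUE)
}

#' Count all k-mers over a sequence collection
#'
#' Counts every overlapping window of length `k`; windows containing a
#' non-ACGT character are skipped. U is accepted as a synonym for T.
#'
#' @param sequences character vector of nucleotide sequences.
#' @param k oligomer length (>= 1).
#' @param source label recording what was counted (`"sites"` or `"reads"`).
#' @return object of class `kmer_table`: list with `k`, `counts` (named
#'   integer vector, sorted by decreasing count with lexicographic
#'   tie-break, zero-count k-mers dropped), `total_nt` (total nucleotides in
#'   the collection), `source`.
#' @export
count_kmers <- function(sequences, k, source = "sites") {
  stopifnot(k >= 1)
  sequences <- .norm_dna(sequences)
  total_nt <- sum(nchar(sequences))
  if (!length(sequences) || all(nchar(sequences) < k)) {
    warning("no sequence of length >= k; empty k-mer table")
    counts <- setNames(integer(0), character(0))
  } else {
    counts <- Biostrings::oligonucleotideFrequency(
      Biostrings::DNAStringSet(sequences), width = k,
      simplify.as = "collapsed")
    counts <- counts[counts > 0]
    counts <- counts[order(-counts, names(counts))]
  }
  structure(list(k = as.integer(k), counts = counts,
                 total_nt = total_nt, source = source),
            class = "kmer_table")
}

# --- dinucleotide-preserving shuffle (Altschul-Erickson) ------------------

# Shuffle one N-free character vector, preserving mono- and dinucleotide
# multisets: build the order-1 de Bruijn multigraph, draw a uniform random
# Eulerian path with the original start/end vertices (random last-edge
# arborescence + rejection, then uniform permutation of remaining edges).
.shuffle_segment <- function(ch) {
  L <- length(ch)
  if (L < 3L) return(ch)
  verts <- unique(ch)
  if (length(verts) == 1L) return(ch)
  from <- ch[-L]
  to <- ch[-1L]
  adj <- split(to, factor(from, levels = verts))
  s_last <- ch[L]
  nonterm <- setdiff(names(adj)[lengths(adj) > 0], s_last)
  for (attempt in 1:10000) {
    last_edge <- vapply(nonterm, function(v) {
      tg <- adj[[v]]
      tg[sample.int(length(tg), 1L)]
    }, character(1))
    # accept iff following chosen last edges from every non-terminal vertex
    # reaches the terminal vertex (spanning arborescence toward s_last)
    ok <- all(vapply(nonterm, function(v) {
      seen <- character(0)
      while (v != s_last) {
        if (v %in% seen || !(v %in% names(last_edge))) return(FALSE)
        seen <- c(seen, v)
        v <- last_edge[[v]]
      }
      TRUE
    }, logical(1)))
    if (ok) break
    if (attempt == 10000L) stop("dinucleotide shuffle failed to converge")
  }
  ordered <- lapply(setNames(names(adj), names(adj)), function(v) {
    tg <- adj[[v]]
    if (v %in% nonterm) {
      drop <- match(last_edge[[v]], tg)
      rest <- tg[-drop]
      c(if (length(rest)) rest[sample.int(length(rest))], last_edge[[v]])
    } else {
      if (length(tg)) tg[sample.int(length(tg))] else tg
    }
  })
  ptr <- setNames(rep(1L, length(ordered)), names(ordered))
  out <- character(L)
  out[1L] <- ch[1L]
  v <- ch[1L]
  for (i in 2:L) {
    nxt <- ordered[[v]][ptr[[v]]]
    ptr[[v]] <- ptr[[v]] + 1L
    out[i] <- nxt
    v <- nxt
  }
  out
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Produces a random rearrangement of each sequence with exactly the same
#' mononucleotide and dinucleotide multisets, by sampling a uniform random
#' Eulerian path through the order-1 de Bruijn multigraph with the original
#' first and last bases fixed. This is the null model for k-mer enrichment:
#' it preserves local composition biases that a simple permutation would
#' destroy. Runs of non-ACGT characters (for example N) stay in place and
#' the ACGT segments between them are shuffled independently.
#'
#' @param sequences character vector (U accepted for T; returned as T).
#' @param seed optional integer seed; the global RNG state is restored
#'   afterwards.
#' @return character vector of shuffled sequences.
#' @export
dinucleotide_shuffle <- function(sequences, seed = NULL) {
  if (!is.null(seed))
    return(withr::with_seed(seed, dinucleotide_shuffle(sequences)))
  vapply(.norm_dna(sequences), function(s) {
    ch <- strsplit(s, "")[[1]]
    is_acgt <- ch %in% c("A", "C", "G", "T")
    if (all(is_acgt)) return(paste(.shuffle_segment(ch), collapse = ""))
    r <- rle(is_acgt)
    stops <- cumsum(r$lengths)
    starts <- stops - r$lengths + 1L
    for (i in seq_along(r$values)) {
      if (r$values[i] && r$lengths[i] >= 2L) {
        idx <- starts[i]:stops[i]
        ch[idx] <- .shuffle_segment(ch[idx])
      }
    }
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

.check_iupac <- function(pattern) {
  pattern <- .norm_dna(pattern)
  if (!nzchar(pattern)) stop("empty motif pattern")
  bad <- setdiff(strsplit(pattern, "")[[1]], names(Biostrings::IUPAC_CODE_MAP))
  if (length(bad)) stop("invalid IUPAC code in pattern: ", bad[1])
  pattern
}

#' Scan a sequence for an IUPAC degenerate motif
#'
#' Reports every (possibly overlapping) offset where each pattern symbol's
#' base set contains the sequence base. U is a synonym for T; H = A/C/T.
#' Ambiguity codes are interpreted in the pattern only, so an N in the
#' sequence matches nothing but a pattern N.
#'
#' @param pattern IUPAC pattern string (e.g. `"UGUAHAUA"`).
#' @param sequence a single nucleotide sequence.
#' @return integer vector of 0-based match offsets.
#' @export
scan_iupac <- function(pattern, sequence) {
  pattern <- .check_iupac(pattern)
  sequence <- .norm_dna(sequence)
  if (nchar(sequence) < nchar(pattern)) return(integer(0))
  m <- Biostrings::matchPattern(Biostrings::DNAString(pattern),
                                Biostrings::DNAString(sequence),
                                fixed = "subject")
  GenomicRanges::start(m) - 1L
}

.count_motif <- function(pattern, sequences) {
  # per-sequence match counts for an IUPAC pattern
  pattern <- .check_iupac(pattern)
  sequences <- .norm_dna(sequences)
  Biostrings::vcountPattern(Biostrings::DNAString(pattern),
                            Biostrings::DNAStringSet(sequences),
                            fixed = "subject")
}

#' Empirical k-mer/motif enrichment test against a shuffle null
#'
#' Measures the frequency of `query` (an exact k-mer or IUPAC pattern) in
#' `sequences` as matches per scanning window, then recomputes it on
#' `n_shuffles` dinucleotide-preserving shuffles of the sequences. The
#' empirical p-value is `(1 + #{null >= observed}) / (1 + n_shuffles)`,
#' never zero by construction; a normal-approximation p-value from the null
#' mean and sd is also reported for tail probabilities beyond Monte-Carlo
#' resolution.
#'
#' @param sequences character vector of sequences.
#' @param query k-mer or IUPAC pattern.
#' @param n_shuffles number of shuffle replicates (>= 19).
#' @param seed optional seed for the shuffles.
#' @param shuffle_unit shuffle each sequence independently
#'   (`"per_sequence"`, default) or the whole concatenated library
#'   (`"whole_library"`).
#' @return list: `observed`, `null_mean`, `null_sd`, `p_empirical`,
#'   `p_normal`, `n_shuffles`.
#' @export
kmer_enrichment_test <- function(sequences, query, n_shuffles = 99L,
                                 seed = NULL,
                                 shuffle_unit = c("per_sequence",
                                                  "whole_library")) {
  shuffle_unit <- match.arg(shuffle_unit)
  stopifnot(n_shuffles >= 19L)
  sequences <- .norm_dna(sequences)
  qlen <- nchar(.check_iupac(query))
  windows <- sum(pmax(0L, nchar(sequences) - qlen + 1L))
  if (windows == 0L) stop("query longer than every sequence")
  if (!is.null(seed))
    return(withr::with_seed(seed, kmer_enrichment_test(
      sequences, query, n_shuffles, seed = NULL,
      shuffle_unit = shuffle_unit)))
  freq_of <- function(seqs) sum(.count_motif(query, seqs)) / windows
  observed <- freq_of(sequences)
  lens <- nchar(sequences)
  null_freq <- vapply(seq_len(n_shuffles), function(i) {
    if (shuffle_unit == "per_sequence") {
      freq_of(dinucleotide_shuffle(sequences))
    } else {
      cat_seq <- paste(sequences, collapse = "")
      sh <- dinucleotide_shuffle(cat_seq)
      ends <- cumsum(lens)
      freq_of(substring(sh, ends - lens + 1L, ends))
    }
  }, numeric(1))
  nsd <- stats::sd(null_freq)
  p_norm <- if (is.na(nsd) || nsd == 0) {
    if (observed > mean(null_freq)) 0 else 1
  } else stats::pnorm(observed, mean(null_freq), nsd, lower.tail = FALSE)
  list(observed = observed, null_mean = mean(null_freq), null_sd = nsd,
       p_empirical = (1 + sum(null_freq >= observed)) / (1 + n_shuffles),
       p_normal = p_norm, n_shuffles = n_shuffles)
}

#' Position frequency matrix from the top k-mers
#'
#' Stacks the `n_top` most abundant k-mers without alignment offsets, each
#' weighted by its count, and returns per-position base frequencies — the
#' frequency matrix behind a motif logo.
#'
#' @param table a `kmer_table`.
#' @param n_top number of top k-mers (default 25).
#' @return 4 x k matrix (rows A, C, G, T), each column summing to 1.
#' @export
top_kmer_logo <- function(table, n_top = 25L) {
  stopifnot(inherits(table, "kmer_table"))
  counts <- table$counts
  if (length(counts) < n_top) {
    warning(sprintf("only %d k-mers available; using all", length(counts)))
    n_top <- length(counts)
  }
  if (!n_top) stop("empty k-mer table")
  top <- counts[seq_len(n_top)]
  chars <- do.call(rbind, strsplit(names(top), ""))
  bases <- c("A", "C", "G", "T")
  mat <- vapply(seq_len(table$k), function(j) {
    w <- vapply(bases, function(b) sum(top[chars[, j] == b]), numeric(1))
    w / sum(top)
  }, numeric(4))
  rownames(mat) <- bases
  mat
}

#' Percent of site sequences containing a motif
#'
#' @param sequences character vector of site sequences.
#' @param pattern IUPAC pattern.
#' @return percent in `[0, 100]` of sequences with >= 1 match.
#' @export
percent_sites_with_motif <- function(sequences, pattern) {
  if (!length(sequences)) stop("no sequences")
  100 * mean(.count_motif(pattern, sequences) > 0)
}

#' Motif enrichment change after background correction
#'
#' @param before_seqs,after_seqs site sequences before and after
#'   correction.
#' @param pattern IUPAC pattern.
#' @return list: `pct_before`, `pct_after`, `percent_change`
#'   (`100 * (after - before) / before`), `fold` (`after / before`), and
#'   `undefined` (TRUE when `pct_before == 0`).
#' @export
motif_enrichment_change <- function(before_seqs, after_seqs, pattern) {
  pb <- percent_sites_with_motif(before_seqs, pattern)
  pa <- percent_sites_with_motif(after_seqs, pattern)
  if (pb == 0)
    return(list(pct_before = 0, pct_after = pa, percent_change = NA_real_,
                fold = NA_real_, undefined = TRUE))
  list(pct_before = pb, pct_after = pa,
       percent_change = 100 * (pa - pb) / pb, fold = pa / pb,
       undefined = FALSE)
}

#' Matched-pairs comparison of k-mer tables before/after correction
#'
#' Normalizes each k-mer count (plus a pseudocount) by the library's total
#' nucleotides and reports, for every k-mer observed in either table, the
#' mean of the two normalized frequencies (abundance axis) and
#' `log2(after / before)` of the normalized frequencies. Swapping the
#' tables negates every log-ratio.
#'
#' @param before,after `kmer_table`s of the same k.
#' @param pseudocount added to each count before normalization (default 1).
#' @return data frame `kmer, mean_abundance, log_ratio`, sorted by
#'   decreasing mean abundance.
#' @export
matched_pairs <- function(before, after, pseudocount = 1) {
  stopifnot(inherits(before, "kmer_table"), inherits(after, "kmer_table"))
  if (before$k != after$k) stop("k-mer tables have different k")
  kmers <- sort(union(names(before$counts), names(after$counts)))
  cb <- setNames(rep(0, length(kmers)), kmers)
  cb[names(before$counts)] <- before$counts
  ca <- setNames(rep(0, length(kmers)), kmers)
  ca[names(after$counts)] <- after$counts
  fb <- (cb + pseudocount) / before$total_nt
  fa <- (ca + pseudocount) / after$total_nt
  out <- data.frame(kmer = kmers, mean_abundance = (fa + fb) / 2,
                    log_ratio = log2(fa / fb))
  out <- out[order(-out$mean_abundance, out$kmer), ]
  rownames(out) <- NULL
  out
}
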