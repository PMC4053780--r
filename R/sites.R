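# Binding-site (group) and cluster calling.
#
# A group is a maximal strand-specific genomic interval covered by >= 1
# utilized read; a cluster is a group with >= 5 reads and >= 2 distinct
# T-to-C conversion locations. No sub-peak splitting is performed: one
# group is one site.

#' Call groups (binding sites with any read evidence)
#'
#' Merges overlapping utilized reads of the same chromosome (and strand,
#' unless `stranded = FALSE`) into maximal intervals. Each group records its
#' member reads, total read count, the union of member conversion locations,
#' and the maximum per-nucleotide read depth. Output is deterministically
#' sorted by (chrom, start, end, strand).
#'
#' @param utilized utilized-read data frame ([filter_utilized()]).
#' @param stranded merge only reads on the same strand (default TRUE).
#' @param id_prefix prefix for generated site ids.
#' @return sites data frame with columns `chrom, start, end, strand,
#'   site_id, read_count, conv_locs, max_depth, read_ids`.
#' @export
call_groups <- function(utilized, stranded = TRUE, id_prefix = "S") {
  if (!nrow(utilized)) {
    out <- empty_sites()
    out$read_ids <- character(0)
    return(out)
  }
  gr <- sites_to_granges(utilized, stranded = stranded)
  # min.gapwidth = 0: adjacent half-open reads ([a,b) vs [b,c)) never merge
  red <- GenomicRanges::reduce(gr, with.revmap = TRUE, min.gapwidth = 0L,
                               ignore.strand = !stranded)
  revmap <- S4Vectors::mcols(red)$revmap
  tc <- parse_pos_set(utilized$tc_pos)
  n <- length(red)
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red) - 1L,
    end = GenomicRanges::end(red),
    strand = if (stranded) as.character(GenomicRanges::strand(red)) else
      rep("+", n),
    site_id = NA_character_, read_count = NA_integer_,
    conv_locs = NA_character_, max_depth = NA_integer_,
    read_ids = NA_character_)
  for (i in seq_len(n)) {
    mem <- revmap[[i]]
    out$read_count[i] <- length(mem)
    out$conv_locs[i] <- format_pos_set(unlist(tc[mem]))
    depth <- integer(out$end[i] - out$start[i])
    for (j in mem) {
      a <- utilized$start[j] - out$start[i] + 1L
      b <- utilized$end[j] - out$start[i]
      depth[a:b] <- depth[a:b] + 1L
    }
    out$max_depth[i] <- max(depth)
    out$read_ids[i] <- paste(utilized$read_id[mem], collapse = ";")
  }
  out <- sort_sites(out)
  out$site_id <- sprintf("%s%06d", id_prefix, seq_len(n))
  rownames(out) <- NULL
  out
}

#' Call clusters from groups
#'
#' A cluster is a group with at least `min_reads` overlapping reads and at
#' least `min_conv_locs` distinct T-to-C conversion locations (a conversion
#' location is a genomic coordinate with >= 1 converting read, however many
#' reads convert there).
#'
#' @param groups sites data frame from [call_groups()].
#' @param min_reads minimum read count (default 5).
#' @param min_conv_locs minimum number of distinct conversion locations
#'   (default 2).
#' @return subset of `groups`.
#' @export
call_clusters <- function(groups, min_reads = 5L, min_conv_locs = 2L) {
  if (min_reads < 1L || min_conv_locs < 1L)
    stop("cluster thresholds must be positive")
  keep <- groups$read_count >= min_reads &
    n_pos_set(groups$conv_locs) >= min_conv_locs
  out <- groups[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract site sequences in transcript orientation
#'
#' Returns the genomic sequence of each site, reverse-complemented for
#' minus-strand sites so that all sequences read 5' to 3' along the
#' transcript.
#'
#' @param sites sites data frame.
#' @param genome named `DNAStringSet` ([read_genome()]).
#' @return character vector of sequences, one per site.
#' @export
site_sequences <- function(sites, genome) {
  if (!nrow(sites)) return(character(0))
  if (!all(sites$chrom %in% names(genome)))
    stop("site on a chromosome absent from the genome")
  lens <- setNames(Biostrings::width(genome), names(genome))
  if (any(sites$start < 0L | sites$end > lens[sites$chrom]))
    stop("site outside genome bounds")
  out <- character(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    s <- as.character(Biostrings::subseq(genome[[sites$chrom[i]]],
                                         sites$start[i] + 1L, sites$end[i]))
    out[i] <- if (sites$strand[i] == "-") revcomp_chr(s) else s
  }
  out
}
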