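# Utilized-read filtering and conversion/mismatch statistics.
#
# The unit of all downstream analysis is the "utilized" read: uniquely
# mapping, >= min_len bases, carrying 0, 1 or 2 T-to-C conversions (read in
# transcript orientation) and no other mismatch type. On a minus-strand read
# a T-to-C conversion appears as A-to-G in forward-reference records.

.mm_labels <- {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(alt = b, ref = b, stringsAsFactors = FALSE)
  g <- g[g$ref != g$alt, ]
  sort(paste0(g$ref, ">", g$alt))
}

#' Classify a mismatch in transcript orientation
#'
#' Mismatch records are stored in forward-reference coordinates with
#' forward-reference bases. For reads on the minus strand the transcript
#' orientation is the reverse complement, so a forward-reference `A>G`
#' record on a minus-strand read classifies as `T>C`.
#'
#' @param strand `"+"` or `"-"` per mismatch (recycled).
#' @param ref,alt forward-reference and read base of each mismatch.
#' @return character vector of labels such as `"T>C"`.
#' @export
classify_conversion <- function(strand, ref, alt) {
  n <- max(length(strand), length(ref), length(alt))
  strand <- rep_len(strand, n); ref <- rep_len(ref, n)
  alt <- rep_len(alt, n)
  if (!all(c(ref, alt) %in% c("A", "C", "G", "T")))
    stop("non-ACGT base in mismatch record")
  minus <- strand == "-"
  ref[minus] <- .complement_base[ref[minus]]
  alt[minus] <- .complement_base[alt[minus]]
  paste0(ref, ">", alt)
}

#' Filter aligned reads to utilized reads
#'
#' Keeps a read iff it maps uniquely (`nmap == 1`), is at least `min_len`
#' bases long, every mismatch classifies as T-to-C in transcript orientation
#' (unless `allow_other_mismatches`), and it carries at most `max_tc` T-to-C
#' conversions. Mismatch records involving N are ignored and do not
#' disqualify a read. Each rejected read is tallied once under the first
#' failing reason (multimapper, too_short, other_mismatch, too_many_tc).
#'
#' @param reads aligned-read data frame ([read_alignments()]).
#' @param max_tc maximum number of T-to-C conversions (default 2).
#' @param min_len minimum read length in bases (default 10).
#' @param allow_other_mismatches keep reads whose non-T-to-C mismatches
#'   would otherwise disqualify them (the T-to-C cap still applies).
#' @return list with `utilized` (the kept reads plus a `tc_pos` column of
#'   `;`-joined forward-reference conversion coordinates) and `tally`
#'   (named integer vector: kept plus the four rejection reasons).
#' @export
filter_utilized <- function(reads, max_tc = 2L, min_len = 10L,
                            allow_other_mismatches = FALSE) {
  tally <- c(kept = 0L, multimapper = 0L, too_short = 0L,
             other_mismatch = 0L, too_many_tc = 0L)
  if (!nrow(reads)) {
    out <- reads
    out$tc_pos <- character(0)
    return(list(utilized = out, tally = tally))
  }
  mml <- parse_mm(reads$mm)
  n_tc <- integer(nrow(reads))
  n_other <- integer(nrow(reads))
  tc_pos <- character(nrow(reads))
  for (i in seq_len(nrow(reads))) {
    m <- mml[[i]]
    keep <- m$ref %in% c("A", "C", "G", "T") &
      m$alt %in% c("A", "C", "G", "T")
    m <- m[keep, , drop = FALSE]
    if (!nrow(m)) { tc_pos[i] <- "."; next }
    lab <- classify_conversion(reads$strand[i], m$ref, m$alt)
    is_tc <- lab == "T>C"
    n_tc[i] <- sum(is_tc)
    n_other[i] <- sum(!is_tc)
    tc_pos[i] <- format_pos_set(m$pos[is_tc])
  }
  len <- reads$end - reads$start
  reason <- rep("kept", nrow(reads))
  reason[n_tc > max_tc] <- "too_many_tc"
  if (!allow_other_mismatches) reason[n_other > 0] <- "other_mismatch"
  reason[len < min_len] <- "too_short"
  reason[reads$nmap != 1L] <- "multimapper"
  tab <- table(factor(reason, levels = names(tally)))
  tally[] <- as.integer(tab)
  utilized <- reads[reason == "kept", , drop = FALSE]
  utilized$tc_pos <- tc_pos[reason == "kept"]
  rownames(utilized) <- NULL
  list(utilized = utilized, tally = tally)
}

#' Fraction of utilized reads carrying a T-to-C conversion
#'
#' Crosslinked 4SU reads out as a T-to-C conversion during reverse
#' transcription, so this fraction separates crosslinked material (roughly
#' 50-80% of reads converted) from non-crosslinked carry-over (10-20%).
#'
#' @param utilized utilized-read data frame (needs the `tc_pos` column).
#' @return fraction in `[0, 1]`.
#' @export
conversion_fraction <- function(utilized) {
  if (!nrow(utilized)) stop("conversion_fraction undefined for empty input")
  mean(n_pos_set(utilized$tc_pos) > 0)
}

#' Mismatch-type profile in transcript orientation
#'
#' Tallies every mismatch record of every read over the 12 ordered
#' (ref, alt) base pairs after strand resolution. In PAR-CLIP data T>C
#' dominates all other cells. Mismatches involving N are skipped.
#'
#' @param reads aligned-read data frame.
#' @return named integer vector over the 12 mismatch types.
#' @export
mismatch_profile <- function(reads) {
  prof <- setNames(integer(length(.mm_labels)), .mm_labels)
  if (!nrow(reads)) return(prof)
  mml <- parse_mm(reads$mm)
  nmm <- vapply(mml, nrow, integer(1))
  if (!sum(nmm)) return(prof)
  m <- do.call(rbind, mml)
  strand <- rep(reads$strand, nmm)
  ok <- m$ref %in% c("A", "C", "G", "T") & m$alt %in% c("A", "C", "G", "T")
  lab <- classify_conversion(strand[ok], m$ref[ok], m$alt[ok])
  tab <- table(factor(lab, levels = .mm_labels))
  prof[] <- as.integer(tab)
  prof
}
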