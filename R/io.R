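# Readers and writers for every on-disk representation the pipeline touches.
#
# Coordinate contract: all tabular/BED interfaces are 0-based half-open.
# SAM input (1-based) is converted on read. Minus-strand reads report their
# sequence in read orientation; mismatch records stay in forward-reference
# coordinates with forward-reference bases.

.read_cols <- c("read_id", "chrom", "start", "end", "strand", "seq", "mm",
                "nmap", "library_id")

validate_reads <- function(reads, context = "reads") {
  stopifnot(all(.read_cols %in% names(reads)))
  if (!nrow(reads)) return(invisible(reads))
  bad <- which(reads$end <= reads$start |
                 (reads$end - reads$start) != nchar(reads$seq))
  if (length(bad))
    stop(sprintf("%s: record %d violates start < end == start + length(seq)",
                 context, bad[1]))
  mml <- parse_mm(reads$mm)
  for (i in seq_len(nrow(reads))) {
    m <- mml[[i]]
    if (!nrow(m)) next
    if (any(m$pos < reads$start[i] | m$pos >= reads$end[i]))
      stop(sprintf("%s: record %d has a mismatch outside the read span",
                   context, i))
    if (any(m$ref == m$alt))
      stop(sprintf("%s: record %d has ref == alt in a mismatch", context, i))
  }
  invisible(reads)
}

#' Read aligned PAR-CLIP reads
#'
#' Reads single-end aligned reads from the package's tabular dialect or from
#' SAM. The tabular dialect is a TSV with a `#`-prefixed header and columns
#' `read_id, chrom, start, end, strand, seq, mm, nmap` (optionally
#' `library_id`): coordinates 0-based half-open, `seq` in read orientation,
#' `mm` a `;`-joined list of `pos:ref>alt` mismatch records in
#' forward-reference coordinates (`.` if none), `nmap` the number of genomic
#' loci the read maps to. SAM input must be indel-free: reads whose CIGAR
#' contains I/D/N/S operations are dropped and counted in the
#' `n_rejected_cigar` attribute; mismatches are recovered from the `MD` tag
#' and `nmap` from the `NH` tag (1 if absent).
#'
#' @param path input file.
#' @param dialect `"tabular"` or `"sam"`.
#' @param library_id library label attached to every read; defaults to the
#'   file's basename (tabular files carrying their own `library_id` column
#'   keep it).
#' @return data frame of aligned reads, one row per read.
#' @export
read_alignments <- function(path, dialect = c("tabular", "sam"),
                            library_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(library_id))
    library_id <- sub("\\.[^.]*$", "", basename(path))
  reads <- switch(dialect,
                  tabular = .read_tabular(path, library_id),
                  sam = .read_sam(path, library_id))
  validate_reads(reads, path)
  reads
}

.read_tabular <- function(path, library_id) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  if (!any(keep)) {
    out <- data.frame(read_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), seq = character(0),
                      mm = character(0), nmap = integer(0),
                      library_id = character(0))
    return(out)
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 8)) {
    bad <- which(keep)[which(nf < 8)[1]]
    stop(sprintf("%s: malformed line %d (expected >= 8 tab-separated fields)",
                 path, bad))
  }
  col <- function(i) vapply(fields, `[`, "", i)
  start <- suppressWarnings(as.integer(col(3)))
  end <- suppressWarnings(as.integer(col(4)))
  nmap <- suppressWarnings(as.integer(col(8)))
  bad <- which(is.na(start) | is.na(end) | is.na(nmap) |
                 !(col(5) %in% c("+", "-")))
  if (length(bad))
    stop(sprintf("%s: malformed line %d", path, which(keep)[bad[1]]))
  lib <- if (any(nf >= 9)) ifelse(nf >= 9, col(9), library_id) else
    rep(library_id, length(fields))
  data.frame(read_id = col(1), chrom = col(2), start = start, end = end,
             strand = col(5), seq = toupper(col(6)), mm = col(7),
             nmap = nmap, library_id = lib)
}

#' Write aligned reads in the tabular dialect
#'
#' @param reads data frame as returned by [read_alignments()].
#' @param path output file.
#' @export
write_reads_tsv <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cols <- intersect(c(.read_cols, "tc_pos"), names(reads))
  writeLines(paste0("#", paste(cols, collapse = "\t")), con)
  if (nrow(reads))
    write.table(reads[, cols], con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.parse_md <- function(md, seq_fwd, start) {
  # MD tag over a match-only alignment: alternating match lengths and
  # reference bases at mismatch positions
  tokens <- regmatches(md, gregexpr("[0-9]+|[A-Z]|\\^[A-Z]+", md))[[1]]
  pos <- start
  out <- list(pos = integer(0), ref = character(0), alt = character(0))
  for (tk in tokens) {
    if (grepl("^[0-9]+$", tk)) {
      pos <- pos + as.integer(tk)
    } else if (startsWith(tk, "^")) {
      stop("deletion in MD tag of an M-only alignment")
    } else {
      out$pos <- c(out$pos, pos)
      out$ref <- c(out$ref, tk)
      out$alt <- c(out$alt, substr(seq_fwd, pos - start + 1L,
                                   pos - start + 1L))
      pos <- pos + 1L
    }
  }
  out
}

.read_sam <- function(path, library_id) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  recs <- vector("list", length(lines))
  n_cigar <- 0L
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11) stop(sprintf("%s: malformed SAM line %d", path, i))
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) > 0L) next                     # unmapped
    if (grepl("[IDNSHP]", f[6])) { n_cigar <- n_cigar + 1L; next }
    seq_fwd <- toupper(f[10])
    start <- as.integer(f[4]) - 1L                       # to 0-based
    end <- start + nchar(seq_fwd)
    minus <- bitwAnd(flag, 16L) > 0L
    tags <- f[-(1:11)]
    md <- sub("^MD:Z:", "", grep("^MD:Z:", tags, value = TRUE))
    nh <- sub("^NH:i:", "", grep("^NH:i:", tags, value = TRUE))
    mm <- if (length(md)) {
      m <- .parse_md(md[1], seq_fwd, start)
      format_mm(m$pos, m$ref, m$alt)
    } else "."
    recs[[i]] <- data.frame(
      read_id = f[1], chrom = f[3], start = start, end = end,
      strand = if (minus) "-" else "+",
      seq = if (minus) revcomp_chr(seq_fwd) else seq_fwd,
      mm = mm, nmap = if (length(nh)) as.integer(nh[1]) else 1L,
      library_id = library_id)
  }
  recs <- recs[!vapply(recs, is.null, TRUE)]
  out <- if (length(recs)) do.call(rbind, recs) else
    .read_tabular(tempfile_empty(), library_id)
  if (n_cigar)
    message(sprintf("%s: %d reads with indel/clip CIGAR operations rejected",
                    path, n_cigar))
  attr(out, "n_rejected_cigar") <- n_cigar
  out
}

tempfile_empty <- function() {
  tf <- tempfile()
  writeLines("#read_id\tchrom\tstart\tend\tstrand\tseq\tmm\tnmap", tf)
  tf
}

#' Write sites as BED6
#'
#' One line per site: chrom, start, end, name = `site_id`,
#' score = `read_count`, strand; sorted by (chrom, start, end, strand).
#'
#' @param sites sites data frame (see [call_groups()]).
#' @param path output file.
#' @export
write_sites_bed <- function(sites, path) {
  check_sites(sites)
  sites <- sort_sites(sites)
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(sites)) {
    writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%s", sites$chrom, sites$start,
                       sites$end, sites$site_id, sites$read_count,
                       sites$strand), con)
  }
  invisible(path)
}

#' Read a BED6 site file
#'
#' @param path BED6 file written by [write_sites_bed()] or any BED6 source.
#' @return sites data frame (`conv_locs` and `max_depth` are `NA` because
#'   BED6 does not carry them).
#' @export
read_sites_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (!length(lines)) return(empty_sites())
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 6))
    stop(path, ": BED6 requires 6 fields per line")
  col <- function(i) vapply(f, `[`, "", i)
  out <- data.frame(chrom = col(1), start = as.integer(col(2)),
                    end = as.integer(col(3)), strand = col(6),
                    site_id = col(4), read_count = as.integer(col(5)),
                    conv_locs = NA_character_, max_depth = NA_integer_)
  check_sites(out)
  out
}

#' Read a genome FASTA
#'
#' @param path FASTA file.
#' @return a [Biostrings::DNAStringSet] with uppercase sequences.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  if (anyDuplicated(names(g)))
    stop(path, ": duplicate FASTA header")
  Biostrings::DNAStringSet(toupper(g))
}

#' Write a genome FASTA
#'
#' @param genome named `DNAStringSet` or named character vector.
#' @param path output file.
#' @export
write_genome <- function(genome, path) {
  if (!methods::is(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read a GTF-lite transcript annotation
#'
#' Nine tab-separated GTF columns with features restricted to
#' `transcript, 5utr, cds, 3utr, intron, lincRNA, repeat` and a
#' `transcript_id "..."` attribute. 1-based closed GTF coordinates are
#' converted to 0-based half-open on read. Every non-transcript feature
#' attached to a transcript must lie within that transcript's span.
#' Transcription start sites and 3' ends are resolved by strand: a
#' plus-strand transcript `[s, e)` has TSS `s` and 3' end `e`; a minus-strand
#' one has TSS `e` and 3' end `s`.
#'
#' @param path GTF-lite file.
#' @return an `annotation_index` (see [build_annotation_index()]).
#' @export
read_annotation <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 9))
    stop(path, ": GTF requires 9 fields per line")
  col <- function(i) vapply(f, `[`, "", i)
  tid <- sub('.*transcript_id "([^"]+)".*', "\\1", col(9))
  feats <- data.frame(chrom = col(1), feature = col(3),
                      start = as.integer(col(4)) - 1L,
                      end = as.integer(col(5)),
                      strand = col(7), transcript_id = tid)
  known <- c("transcript", "5utr", "cds", "3utr", "intron", "lincRNA",
             "repeat")
  if (!all(feats$feature %in% known))
    stop(path, ": unknown feature type ",
         setdiff(feats$feature, known)[1])
  build_annotation_index(feats)
}

#' Write a GTF-lite annotation
#'
#' @param index an `annotation_index`, or a feature data frame with columns
#'   `chrom, feature, start, end, strand, transcript_id` (0-based half-open).
#' @param path output file.
#' @param source value for the GTF source column.
#' @export
write_annotation_gtf <- function(index, path, source = "parclipbg") {
  feats <- if (inherits(index, "annotation_index")) index$raw else index
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf('%s\t%s\t%s\t%d\t%d\t.\t%s\t.\ttranscript_id "%s";',
                     feats$chrom, source, feats$feature, feats$start + 1L,
                     feats$end, feats$strand, feats$transcript_id), con)
  invisible(path)
}
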