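# Internal helpers: coordinate conversion, mismatch-string codecs, strand ops.

# sites/reads data frames use 0-based half-open [start, end); GRanges is
# 1-based closed, so [s, e) maps to IRanges(s + 1, e). Under this mapping
# half-open adjacency ([a,b) vs [b,c)) never overlaps in IRanges either.
sites_to_granges <- function(x, stranded = TRUE) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = if (stranded) x$strand else "*"
  )
}

.complement_base <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp_chr <- function(x) {
  vapply(x, function(s) {
    ch <- strsplit(chartr("ACGTUacgtu", "TGCAAtgcaa", s), "")[[1]]
    paste(rev(ch), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# mm field codec: ";"-joined "pos:ref>alt" in forward-reference coordinates,
# "." when the read has no mismatches.
parse_mm <- function(mm) {
  lapply(mm, function(s) {
    if (is.na(s) || s == "." || s == "") {
      return(data.frame(pos = integer(0), ref = character(0),
                        alt = character(0)))
    }
    parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "[:>]")
    data.frame(
      pos = as.integer(vapply(parts, `[`, "", 1L)),
      ref = vapply(parts, `[`, "", 2L),
      alt = vapply(parts, `[`, "", 3L)
    )
  })
}

format_mm <- function(pos, ref, alt) {
  if (length(pos) == 0L) return(".")
  paste(sprintf("%d:%s>%s", pos, ref, alt), collapse = ";")
}

# integer-set codec used for tc_pos and conv_locs columns
parse_pos_set <- function(s) {
  lapply(s, function(x) {
    if (is.na(x) || x == "." || x == "") integer(0)
    else as.integer(strsplit(x, ";", fixed = TRUE)[[1]])
  })
}

format_pos_set <- function(pos) {
  if (length(pos) == 0L) return(".")
  paste(sort(unique(as.integer(pos))), collapse = ";")
}

n_pos_set <- function(s) {
  vapply(parse_pos_set(s), length, integer(1))
}

empty_sites <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             strand = character(0), site_id = character(0),
             read_count = integer(0), conv_locs = character(0),
             max_depth = integer(0))
}

check_sites <- function(sites) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "start", "end", "strand") %in% names(sites)))
  if (nrow(sites) && any(sites$end <= sites$start))
    stop("invalid site interval: end <= start")
  invisible(sites)
}

sort_sites <- function(sites) {
  sites[order(sites$chrom, sites$start, sites$end, sites$strand), ,
        drop = FALSE]
}

# derive independent sub-seeds from one user seed, all < 2^31
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
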