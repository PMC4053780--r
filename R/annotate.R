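# Genomic category assignment and positional analyses: category
# composition, TSS-downstream window density, transcript 3'-terminus
# enrichment.

.categories <- c("5utr", "cds", "3utr", "intron", "lincRNA", "repeat")
.default_priority <- c("3utr", "5utr", "cds", "intron", "lincRNA", "repeat")

#' Build an annotation index from a feature table
#'
#' @param features data frame with columns `chrom, feature, start, end,
#'   strand, transcript_id` in 0-based half-open coordinates. Rows with
#'   `feature == "transcript"` define transcript spans (each gets one TSS
#'   and one 3' end, resolved by strand); other rows are category
#'   intervals and must lie within their transcript's span when one is
#'   defined.
#' @return object of class `annotation_index`: list with `features`
#'   (non-transcript rows), `transcripts` (with `tss` and `end3` columns)
#'   and `raw` (the input table).
#' @export
build_annotation_index <- function(features) {
  stopifnot(all(c("chrom", "feature", "start", "end", "strand",
                  "transcript_id") %in% names(features)))
  if (any(features$end <= features$start))
    stop("invalid feature interval: end <= start")
  tx <- features[features$feature == "transcript", , drop = FALSE]
  fe <- features[features$feature != "transcript", , drop = FALSE]
  if (anyDuplicated(tx$transcript_id))
    stop("duplicate transcript_id among transcript rows")
  if (nrow(tx)) {
    tx$tss <- ifelse(tx$strand == "+", tx$start, tx$end)
    tx$end3 <- ifelse(tx$strand == "+", tx$end, tx$start)
    span <- match(fe$transcript_id, tx$transcript_id)
    has_tx <- !is.na(span)
    if (any(has_tx & (fe$start < tx$start[span] | fe$end > tx$end[span])))
      stop("feature outside its transcript span")
  } else {
    tx$tss <- integer(0)
    tx$end3 <- integer(0)
  }
  structure(list(features = fe, transcripts = tx, raw = features),
            class = "annotation_index")
}

.feature_granges <- function(index, category = NULL) {
  fe <- index$features
  if (!is.null(category)) fe <- fe[fe$feature == category, , drop = FALSE]
  GenomicRanges::GRanges(fe$chrom,
                         IRanges::IRanges(fe$start + 1L, fe$end),
                         strand = fe$strand)
}

#' Assign each site to a genomic category
#'
#' Overlap (>= 1 bp) against the annotation's category intervals, resolved
#' by a fixed priority (default `3utr > 5utr > cds > intron > lincRNA >
#' repeat`); sites overlapping nothing are `intergenic`. Overlap ignores
#' strand by default, matching location-based read attribution.
#'
#' @param sites sites (or reads) data frame with `chrom, start, end,
#'   strand`.
#' @param index an `annotation_index`.
#' @param priority category precedence, highest first.
#' @param stranded require matching strands (default FALSE).
#' @return character vector of category labels, one per site.
#' @export
assign_category <- function(sites, index, priority = .default_priority,
                            stranded = FALSE) {
  stopifnot(inherits(index, "annotation_index"),
            setequal(priority, .categories))
  if (!nrow(sites)) return(character(0))
  out <- rep("intergenic", nrow(sites))
  gr <- sites_to_granges(sites, stranded = stranded)
  fe_gr <- .feature_granges(index)
  hits <- GenomicRanges::findOverlaps(gr, fe_gr, ignore.strand = !stranded)
  if (length(hits)) {
    cat_hit <- index$features$feature[S4Vectors::subjectHits(hits)]
    rank_hit <- match(cat_hit, priority)
    best <- tapply(rank_hit, S4Vectors::queryHits(hits), min)
    out[as.integer(names(best))] <- priority[best]
  }
  out
}

#' Genomic category composition of a site or read set
#'
#' @inheritParams assign_category
#' @return named numeric vector of percents over
#'   `5utr, cds, 3utr, intron, lincRNA, repeat, intergenic`, summing to
#'   100.
#' @export
category_composition <- function(sites, index,
                                 priority = .default_priority,
                                 stranded = FALSE) {
  if (!nrow(sites)) stop("category_composition undefined for empty input")
  lab <- assign_category(sites, index, priority, stranded)
  lev <- c(.categories, "intergenic")
  counts <- table(factor(lab, levels = lev))
  setNames(100 * as.vector(counts) / length(lab), lev)
}

.window_granges <- function(tx, offset_lo, offset_hi, chrom_lens = NULL) {
  # genomic interval [offset_lo, offset_hi) bases downstream of each TSS,
  # following transcript strand
  plus <- tx$strand == "+"
  start0 <- ifelse(plus, tx$tss + offset_lo, tx$tss - offset_hi)
  end0 <- ifelse(plus, tx$tss + offset_hi, tx$tss - offset_lo)
  start0 <- pmax(start0, 0L)
  keep <- end0 > start0
  GenomicRanges::GRanges(tx$chrom[keep],
                         IRanges::IRanges(start0[keep] + 1L, end0[keep]),
                         strand = tx$strand[keep])
}

.density_in <- function(items, window_gr, stranded) {
  # (item nucleotides inside the window union / total item nucleotides)
  # per kb of window union
  w <- GenomicRanges::reduce(window_gr, ignore.strand = !stranded)
  len_kb <- sum(GenomicRanges::width(w)) / 1000
  total_nt <- sum(items$end - items$start)
  if (len_kb == 0 || total_nt == 0)
    return(list(density = 0, nt_in = 0L, window_kb = len_kb))
  it <- sites_to_granges(items, stranded = stranded)
  # per-item overlap nucleotides (items may overlap one another, so the
  # set-level intersect would undercount; windows in w are disjoint)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(it, w, ignore.strand = !stranded))
  qi <- it[S4Vectors::queryHits(hits)]
  si <- w[S4Vectors::subjectHits(hits)]
  nt_in <- sum(pmin(GenomicRanges::end(qi), GenomicRanges::end(si)) -
                 pmax(GenomicRanges::start(qi),
                      GenomicRanges::start(si)) + 1L)
  list(density = (nt_in / total_nt) / len_kb, nt_in = nt_in,
       window_kb = len_kb)
}

#' Item density in windows downstream of transcription start sites
#'
#' For each window `[a, b)` bases downstream of a TSS (strand-respecting),
#' computes the fraction of the library's nucleotides falling in the union
#' of that window over all transcripts, normalized per kb of window length
#' ("fraction of nucleotides per library per kb"). The normalization makes
#' the density invariant to library size.
#'
#' @param items sites or reads data frame.
#' @param index an `annotation_index` with transcript TSSs.
#' @param windows list of `c(lo, hi)` offsets in bp downstream of the TSS;
#'   defaults to `[25, 50)` and `[50, 100)`.
#' @param stranded require item strand to match transcript strand
#'   (default FALSE).
#' @return data frame `window, density, nt_in, window_kb`.
#' @export
tss_window_density <- function(items, index,
                               windows = list(c(25L, 50L), c(50L, 100L)),
                               stranded = FALSE) {
  stopifnot(inherits(index, "annotation_index"))
  tx <- index$transcripts
  if (!nrow(tx)) stop("annotation has no transcripts")
  rows <- lapply(windows, function(w) {
    wg <- .window_granges(tx, w[1], w[2])
    d <- .density_in(items, wg, stranded)
    data.frame(window = sprintf("[%d,%d)", w[1], w[2]),
               density = d$density, nt_in = d$nt_in,
               window_kb = d$window_kb)
  })
  do.call(rbind, rows)
}

#' Site enrichment at transcript 3' termini
#'
#' Compares item density in the last `window_nt` bases of each transcript
#' (the window `[-window_nt, 0)` upstream of the 3' end) against density
#' over the remainder of transcript bodies. Ratios above 1 indicate
#' 3'-terminal enrichment. Transcripts shorter than `window_nt` are
#' skipped with a warning.
#'
#' @param sites sites data frame.
#' @param index an `annotation_index`.
#' @param window_nt terminal window size in bases (default 50).
#' @param stranded strand-aware density (default FALSE).
#' @return list: `ratio`, `density_terminus`, `density_rest`, `capped`
#'   (TRUE when the rest-density is 0 and the ratio is reported as Inf).
#' @export
terminus_enrichment <- function(sites, index, window_nt = 50L,
                                stranded = FALSE) {
  stopifnot(inherits(index, "annotation_index"))
  tx <- index$transcripts
  short <- (tx$end - tx$start) < window_nt
  if (any(short)) {
    warning(sprintf("%d transcripts shorter than %d nt skipped",
                    sum(short), window_nt))
    tx <- tx[!short, , drop = FALSE]
  }
  if (!nrow(tx)) stop("no transcript long enough for the terminal window")
  plus <- tx$strand == "+"
  term <- GenomicRanges::GRanges(
    tx$chrom,
    IRanges::IRanges(ifelse(plus, tx$end - window_nt, tx$start) + 1L,
                     ifelse(plus, tx$end, tx$start + window_nt)),
    strand = tx$strand)
  body <- GenomicRanges::GRanges(tx$chrom,
                                 IRanges::IRanges(tx$start + 1L, tx$end),
                                 strand = tx$strand)
  rest <- GenomicRanges::setdiff(body, term, ignore.strand = !stranded)
  d_term <- .density_in(sites, term, stranded)
  d_rest <- .density_in(sites, rest, stranded)
  capped <- d_rest$density == 0 && d_term$density > 0
  ratio <- if (capped) Inf else if (d_rest$density == 0) NA_real_ else
    d_term$density / d_rest$density
  list(ratio = ratio, density_terminus = d_term$density,
       density_rest = d_rest$density, capped = capped)
}
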