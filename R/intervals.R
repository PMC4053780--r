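# Overlap algebra on sites: background subtraction, depth-thresholded
# replicate overlap, membership binning, and depth correlation.
#
# Overlap means >= 1 shared base pair: same chrom, max(starts) < min(ends),
# and equal strand when stranded. Half-open adjacency is never an overlap.

#' Pairwise site overlap
#'
#' @param a,b sites data frames.
#' @param stranded require equal strands (default TRUE).
#' @return logical matrix, `nrow(a)` by `nrow(b)`, TRUE where the pair
#'   shares at least one base pair.
#' @export
site_overlaps <- function(a, b, stranded = TRUE) {
  check_sites(a); check_sites(b)
  out <- matrix(FALSE, nrow(a), nrow(b))
  if (!nrow(a) || !nrow(b)) return(out)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(sites_to_granges(a, stranded),
                                sites_to_granges(b, stranded),
                                ignore.strand = !stranded))
  out[cbind(S4Vectors::queryHits(hits), S4Vectors::subjectHits(hits))] <- TRUE
  out
}

.overlaps_any <- function(a, b, stranded = TRUE) {
  if (!nrow(a)) return(logical(0))
  if (!nrow(b)) return(rep(FALSE, nrow(a)))
  suppressWarnings(
    GenomicRanges::countOverlaps(sites_to_granges(a, stranded),
                                 sites_to_granges(b, stranded),
                                 ignore.strand = !stranded)) > 0
}

#' Merge site lists into maximal union intervals
#'
#' Concatenates one or more site lists and merges all overlapping intervals
#' (per strand unless `stranded = FALSE`) into maximal loci. Read counts are
#' summed and conversion locations unioned over the merged members. Used to
#' build the background union from multiple control libraries and to define
#' the distinct loci underlying membership binning.
#'
#' @param site_lists a single sites data frame or a list of them.
#' @param stranded merge per strand (default TRUE).
#' @param id_prefix prefix for generated locus ids.
#' @return sites data frame of merged loci.
#' @export
union_sites <- function(site_lists, stranded = TRUE, id_prefix = "U") {
  if (is.data.frame(site_lists)) site_lists <- list(site_lists)
  stopifnot(length(site_lists) >= 1)
  all_sites <- do.call(rbind, lapply(site_lists, function(s) {
    check_sites(s)
    s[, c("chrom", "start", "end", "strand", "read_count", "conv_locs")]
  }))
  if (!nrow(all_sites)) return(empty_sites())
  gr <- sites_to_granges(all_sites, stranded)
  # min.gapwidth = 0: adjacency never counts as overlap
  red <- GenomicRanges::reduce(gr, with.revmap = TRUE, min.gapwidth = 0L,
                               ignore.strand = !stranded)
  revmap <- S4Vectors::mcols(red)$revmap
  convs <- parse_pos_set(all_sites$conv_locs)
  n <- length(red)
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red) - 1L,
    end = GenomicRanges::end(red),
    strand = if (stranded) as.character(GenomicRanges::strand(red)) else
      rep("+", n),
    site_id = NA_character_,
    read_count = vapply(revmap, function(m)
      sum(all_sites$read_count[m]), integer(1)),
    conv_locs = vapply(revmap, function(m)
      format_pos_set(unlist(convs[m])), character(1)),
    max_depth = NA_integer_)
  out <- sort_sites(out)
  out$site_id <- sprintf("%s%06d", id_prefix, seq_len(n))
  rownames(out) <- NULL
  out
}

#' Background correction: whole-site removal against a background union
#'
#' A site is removed in full if it overlaps any background interval by one
#' or more base pairs; there is no partial trimming. `kept` and `removed`
#' partition the input.
#'
#' @param sites sites data frame to correct.
#' @param background_union merged background sites ([union_sites()]).
#' @param stranded require equal strands for an overlap (default TRUE).
#' @return list with `kept` and `removed` sites data frames.
#' @export
subtract_background <- function(sites, background_union, stranded = TRUE) {
  check_sites(sites)
  hit <- .overlaps_any(sites, background_union, stranded)
  list(kept = `rownames<-`(sites[!hit, , drop = FALSE], NULL),
       removed = `rownames<-`(sites[hit, , drop = FALSE], NULL))
}

#' Three-library overlap report at a read-depth threshold
#'
#' Filters each library to sites with `read_count >= min_reads`, merges the
#' survivors into distinct loci, and reports the seven Venn region counts
#' over locus membership plus, per library, the percent of its loci found
#' in at least one other library and in both other libraries. With
#' `per_site = TRUE` the percentages are instead computed over each
#' library's raw thresholded sites (does this site overlap >= 1 site of
#' another library), without merging.
#'
#' @param A,B,C sites data frames with read counts.
#' @param min_reads depth threshold (>= 1).
#' @param stranded strand-aware overlap (default TRUE).
#' @param per_site compute percentages per raw site instead of per merged
#'   locus.
#' @param names library names for the report.
#' @return list of class `overlap_report`: `min_reads`, `site_counts`
#'   (thresholded raw site counts), `locus_counts`, `venn` (named region
#'   counts), `pct_in_at_least_one`, `pct_in_both_others`.
#' @export
venn3 <- function(A, B, C, min_reads = 1L, stranded = TRUE,
                  per_site = FALSE, names = c("A", "B", "C")) {
  if (min_reads < 1L) stop("min_reads must be >= 1")
  libs <- list(A, B, C)
  libs <- lapply(libs, function(s) {
    check_sites(s)
    s[s$read_count >= min_reads, , drop = FALSE]
  })
  names(libs) <- names
  loci <- union_sites(libs, stranded = stranded)
  member <- vapply(libs, function(s) .overlaps_any(loci, s, stranded),
                   logical(nrow(loci)))
  if (nrow(loci) == 1L) member <- matrix(member, nrow = 1)
  pattern <- apply(member, 1, function(m)
    paste(names[m], collapse = "&"))
  regions <- c(names, paste(names[1], names[2], sep = "&"),
               paste(names[1], names[3], sep = "&"),
               paste(names[2], names[3], sep = "&"),
               paste(names, collapse = "&"))
  venn <- setNames(integer(length(regions)), regions)
  tab <- table(pattern)
  venn[names(tab)] <- as.integer(tab)
  pct1 <- pct2 <- setNames(numeric(3), names)
  for (i in 1:3) {
    if (per_site) {
      others <- do.call(rbind, lapply(libs[-i], function(s)
        s[, c("chrom", "start", "end", "strand", "site_id", "read_count",
              "conv_locs", "max_depth")]))
      in_other <- .overlaps_any(libs[[i]], others, stranded)
      both <- .overlaps_any(libs[[i]], libs[setdiff(1:3, i)][[1]],
                            stranded) &
        .overlaps_any(libs[[i]], libs[setdiff(1:3, i)][[2]], stranded)
      n_i <- nrow(libs[[i]])
      pct1[i] <- if (n_i) 100 * mean(in_other) else NA_real_
      pct2[i] <- if (n_i) 100 * mean(both) else NA_real_
    } else {
      mine <- member[, i]
      n_i <- sum(mine)
      pct1[i] <- if (n_i) 100 * mean(rowSums(member[mine, , drop = FALSE])
                                     >= 2) else NA_real_
      pct2[i] <- if (n_i) 100 * mean(rowSums(member[mine, , drop = FALSE])
                                     == 3) else NA_real_
    }
  }
  structure(list(min_reads = min_reads,
                 site_counts = setNames(vapply(libs, nrow, integer(1)),
                                        names),
                 locus_counts = setNames(colSums(member), names),
                 venn = venn,
                 pct_in_at_least_one = pct1,
                 pct_in_both_others = pct2),
            class = "overlap_report")
}

#' Bin merged loci by library membership and score background overlap
#'
#' Merges all sites across `n >= 2` libraries into distinct loci, counts for
#' each locus the number of libraries with at least one overlapping site,
#' and reports per membership bin `m = 1..n` the number of loci and the
#' percent of them overlapping the background union.
#'
#' @param site_lists list of >= 2 sites data frames.
#' @param background_union merged background sites.
#' @param stranded strand-aware overlap (default TRUE).
#' @return data frame with columns `m, n_loci, pct_background`.
#' @export
bin_by_membership <- function(site_lists, background_union,
                              stranded = TRUE) {
  stopifnot(is.list(site_lists), length(site_lists) >= 2)
  n <- length(site_lists)
  loci <- union_sites(site_lists, stranded = stranded)
  member <- vapply(site_lists, function(s)
    .overlaps_any(loci, s, stranded), logical(nrow(loci)))
  if (nrow(loci) == 1L) member <- matrix(member, nrow = 1)
  m <- rowSums(member)
  in_bg <- .overlaps_any(loci, background_union, stranded)
  out <- data.frame(m = seq_len(n), n_loci = 0L,
                    pct_background = NA_real_)
  for (k in seq_len(n)) {
    sel <- m == k
    out$n_loci[k] <- sum(sel)
    if (any(sel)) out$pct_background[k] <- 100 * mean(in_bg[sel])
  }
  out
}

#' Between-library read-depth correlation over matched loci
#'
#' Merges the two libraries' sites into loci, assigns each locus the summed
#' read count of the overlapping sites from each library (0 if absent), and
#' returns the R-squared of the least-squares fit of one library on the
#' other, on log2(count + pseudocount) by default.
#'
#' @param A,B sites data frames.
#' @param log_scale fit on log2 counts (default TRUE).
#' @param pseudocount added before the log (default 1).
#' @param stranded strand-aware overlap (default TRUE).
#' @return list with `r_squared`, `n_loci`, and the per-locus count matrix.
#' @export
depth_correlation <- function(A, B, log_scale = TRUE, pseudocount = 1,
                              stranded = TRUE) {
  if (!nrow(A) || !nrow(B)) stop("both libraries must be non-empty")
  loci <- union_sites(list(A, B), stranded = stranded)
  if (nrow(loci) < 3) stop("fewer than 3 matched loci")
  count_in <- function(lib) {
    ov <- site_overlaps(loci, lib, stranded)
    as.integer(ov %*% lib$read_count)
  }
  x <- count_in(A); y <- count_in(B)
  if (log_scale) { x <- log2(x + pseudocount); y <- log2(y + pseudocount) }
  r2 <- if (stats::var(x) == 0 || stats::var(y) == 0) NA_real_ else
    suppressWarnings(summary(stats::lm(y ~ x))$r.squared)
  list(r_squared = r2, n_loci = nrow(loci),
       counts = data.frame(locus = loci$site_id, A = count_in(A),
                           B = count_in(B)))
}
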