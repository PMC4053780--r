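# Sequencing-saturation analysis: subsample reads at fixed fractions with
# replicates, re-run the site caller, and report the fraction of full-set
# sites and clusters recovered.

#' Subsample reads without replacement
#'
#' @param reads read data frame.
#' @param fraction sampling fraction in `(0, 1]`; `round(fraction * n)`
#'   reads are drawn.
#' @param seed optional integer seed (RNG state restored afterwards).
#' @return row subset of `reads`, in original row order.
#' @export
subsample_reads <- function(reads, fraction, seed = NULL) {
  if (fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]")
  if (!is.null(seed))
    return(withr::with_seed(seed, subsample_reads(reads, fraction)))
  n <- nrow(reads)
  take <- sort(sample.int(n, round(fraction * n)))
  out <- reads[take, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Saturation curve of site and cluster discovery
#'
#' For each sampling fraction and replicate: subsample the raw reads,
#' re-run utilized-read filtering and group/cluster calling, and report
#' the fraction of the full library's groups (and clusters) recovered. A
#' full-set site counts as recovered when a subsample site of the same
#' kind overlaps it by >= 1 bp (`match = "overlap"`, the default, because
#' site boundaries shift under subsampling) or exactly reproduces its
#' coordinates (`match = "exact"`).
#'
#' @param reads raw aligned reads of one library.
#' @param fractions sampling fractions (default `0.1, 0.3, 0.5, 0.7, 0.9`).
#' @param reps replicates per fraction (default 5).
#' @param seed seed from which per-replicate subsampling seeds are derived.
#' @param min_reads,min_conv_locs cluster thresholds ([call_clusters()]).
#' @param max_tc,min_len utilized-read thresholds ([filter_utilized()]).
#' @param match `"overlap"` or `"exact"` recovery matching.
#' @param stranded strand-aware calling and matching (default TRUE).
#' @return data frame of class `saturation_curve`: columns `fraction, rep,
#'   site_recovery, cluster_recovery`, with the full-set site and cluster
#'   counts in attributes `n_sites` and `n_clusters`.
#' @export
saturation_curve <- function(reads, fractions = c(0.1, 0.3, 0.5, 0.7, 0.9),
                             reps = 5L, seed = 1L, min_reads = 5L,
                             min_conv_locs = 2L, max_tc = 2L,
                             min_len = 10L, match = c("overlap", "exact"),
                             stranded = TRUE) {
  match <- match.arg(match)
  full_u <- filter_utilized(reads, max_tc, min_len)$utilized
  full_g <- call_groups(full_u, stranded = stranded)
  full_c <- call_clusters(full_g, min_reads, min_conv_locs)
  if (!nrow(full_g)) stop("no sites in the full read set")
  recovered <- function(full, called) {
    if (!nrow(full)) return(NA_real_)
    if (!nrow(called)) return(0)
    if (match == "overlap") {
      mean(.overlaps_any(full, called, stranded))
    } else {
      key <- function(s) paste(s$chrom, s$start, s$end, s$strand)
      mean(key(full) %in% key(called))
    }
  }
  grid <- expand.grid(rep = seq_len(reps), fraction = fractions)
  seeds <- derive_seeds(seed, nrow(grid))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    sub <- subsample_reads(reads, grid$fraction[i], seeds[i])
    u <- filter_utilized(sub, max_tc, min_len)$utilized
    g <- call_groups(u, stranded = stranded)
    cl <- call_clusters(g, min_reads, min_conv_locs)
    data.frame(fraction = grid$fraction[i], rep = grid$rep[i],
               site_recovery = recovered(full_g, g),
               cluster_recovery = recovered(full_c, cl))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$fraction, out$rep), ]
  rownames(out) <- NULL
  attr(out, "n_sites") <- nrow(full_g)
  attr(out, "n_clusters") <- nrow(full_c)
  class(out) <- c("saturation_curve", "data.frame")
  out
}
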