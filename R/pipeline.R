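# End-to-end workflow: filter -> call sites -> background union ->
# subtract -> overlap / motif / annotation / saturation reporting.

#' Pipeline parameter set
#'
#' Central container for the workflow's numeric parameters. Defaults:
#' utilized reads carry at most 2 T-to-C conversions and are >= 10 nt;
#' clusters need >= 5 reads and >= 2 conversion locations; replicate
#' overlap is reported at read-depth thresholds 1/5/25; matched-pairs
#' k-mer length 7; logos from the top 25 8-mers; saturation at fractions
#' 0.1-0.9 with 5 replicates.
#'
#' @param min_reads,min_conv_locs cluster thresholds.
#' @param max_tc,min_len utilized-read thresholds.
#' @param depth_thresholds read-depth thresholds for overlap reports.
#' @param k_motif matched-pairs k-mer length.
#' @param k_logo,top_n logo k-mer length and number of top k-mers.
#' @param n_shuffles shuffle replicates for enrichment tests.
#' @param fractions,reps saturation grid.
#' @param stranded strand-aware interval operations throughout.
#' @param seed seed for stochastic stages.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_reads = 5L, min_conv_locs = 2L,
                            max_tc = 2L, min_len = 10L,
                            depth_thresholds = c(1L, 5L, 25L),
                            k_motif = 7L, k_logo = 8L, top_n = 25L,
                            n_shuffles = 99L,
                            fractions = c(0.1, 0.3, 0.5, 0.7, 0.9),
                            reps = 5L, stranded = TRUE, seed = 1L) {
  cfg <- as.list(environment())
  if (any(c(min_reads, min_conv_locs, max_tc + 1L, min_len, k_motif,
            k_logo, top_n, reps) < 1L))
    stop("pipeline thresholds must be positive")
  structure(cfg, class = "pipeline_config")
}

#' Run the background-correction pipeline
#'
#' Filters every library to utilized reads, calls groups and clusters,
#' merges the background libraries' groups into the background union,
#' removes every RBP site overlapping that union by >= 1 bp, and collects
#' the companion statistics: per-library conversion fractions and
#' filtering tallies, depth-thresholded overlap among the first three
#' background libraries, membership binning of all libraries against the
#' background union, and (per RBP library) motif percentages before/after
#' correction, matched-pairs k-mer shifts, genomic category composition
#' and TSS-window densities.
#'
#' @param libraries named list of aligned-read data frames.
#' @param genome named `DNAStringSet` (or character) genome.
#' @param annotation an `annotation_index`, or NULL to skip positional
#'   analyses.
#' @param background_libs,rbp_libs names of the background and RBP
#'   libraries in `libraries`.
#' @param motif optional IUPAC motif for enrichment-change reporting.
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result` with elements `config`,
#'   `libraries` (per-library tallies, conversion fraction, site/cluster
#'   counts), `sites` (per-library groups and clusters), `background_union`,
#'   `correction` (per RBP library: kept/removed sites and counts),
#'   `overlap` (per depth threshold), `membership`, `motifs`, `annotation`.
#' @export
run_pipeline <- function(libraries, genome, annotation = NULL,
                         background_libs, rbp_libs, motif = NULL,
                         config = pipeline_config()) {
  stopifnot(all(c(background_libs, rbp_libs) %in% names(libraries)))
  if (!methods::is(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(unlist(genome))
  lib_stats <- list()
  groups <- list()
  clusters <- list()
  for (l in names(libraries)) {
    f <- filter_utilized(libraries[[l]], config$max_tc, config$min_len)
    g <- call_groups(f$utilized, stranded = config$stranded,
                     id_prefix = paste0(l, "_S"))
    cl <- call_clusters(g, config$min_reads, config$min_conv_locs)
    groups[[l]] <- g
    clusters[[l]] <- cl
    lib_stats[[l]] <- list(
      n_reads_in = nrow(libraries[[l]]), tally = as.list(f$tally),
      conversion_fraction = if (nrow(f$utilized))
        conversion_fraction(f$utilized) else NA_real_,
      n_groups = nrow(g), n_clusters = nrow(cl))
  }
  bg_union <- union_sites(groups[background_libs],
                          stranded = config$stranded, id_prefix = "BG")
  correction <- list()
  motifs_out <- list()
  annot_out <- list()
  for (l in rbp_libs) {
    corr <- subtract_background(groups[[l]], bg_union,
                                stranded = config$stranded)
    correction[[l]] <- list(kept = corr$kept, removed = corr$removed,
                            n_kept = nrow(corr$kept),
                            n_removed = nrow(corr$removed),
                            pct_removed = 100 * nrow(corr$removed) /
                              max(1L, nrow(groups[[l]])))
    seq_before <- site_sequences(groups[[l]], genome)
    seq_after <- site_sequences(corr$kept, genome)
    m <- list(matched_pairs = matched_pairs(
      count_kmers(seq_before, config$k_motif, "sites"),
      count_kmers(seq_after, config$k_motif, "sites")))
    if (!is.null(motif) && length(seq_after))
      m$enrichment_change <- motif_enrichment_change(seq_before, seq_after,
                                                     motif)
    motifs_out[[l]] <- m
    if (!is.null(annotation)) {
      annot_out[[l]] <- list(
        composition_before = as.list(category_composition(groups[[l]],
                                                          annotation)),
        composition_after = if (nrow(corr$kept))
          as.list(category_composition(corr$kept, annotation)) else NULL,
        tss_before = tss_window_density(groups[[l]], annotation),
        tss_after = tss_window_density(corr$kept, annotation))
    }
  }
  overlap <- NULL
  if (length(background_libs) >= 3) {
    b3 <- groups[background_libs[1:3]]
    overlap <- lapply(config$depth_thresholds, function(t)
      venn3(b3[[1]], b3[[2]], b3[[3]], min_reads = t,
            stranded = config$stranded, names = background_libs[1:3]))
    names(overlap) <- paste0("min_reads_", config$depth_thresholds)
  }
  membership <- if (length(c(rbp_libs, background_libs)) >= 2)
    bin_by_membership(groups[c(rbp_libs, background_libs)], bg_union,
                      stranded = config$stranded) else NULL
  bg_logo <- {
    bg_seqs <- site_sequences(bg_union, genome)
    tab <- count_kmers(bg_seqs, config$k_logo, "sites")
    if (length(tab$counts)) top_kmer_logo(tab, min(config$top_n,
                                                   length(tab$counts)))
    else NULL
  }
  structure(list(config = config, libraries = lib_stats,
                 sites = list(groups = groups, clusters = clusters),
                 background_union = bg_union, correction = correction,
                 overlap = overlap, membership = membership,
                 motifs = motifs_out, background_logo = bg_logo,
                 annotation = annot_out),
            class = "pipeline_result")
}

#' Serializable summary of a pipeline result
#'
#' Reduces a `pipeline_result` to plain lists/vectors suitable for
#' `jsonlite::write_json`.
#'
#' @param result a `pipeline_result`.
#' @return nested list.
#' @export
pipeline_summary <- function(result) {
  ov <- lapply(result$overlap, function(o)
    list(min_reads = o$min_reads, site_counts = as.list(o$site_counts),
         venn = as.list(o$venn),
         pct_in_at_least_one = as.list(o$pct_in_at_least_one),
         pct_in_both_others = as.list(o$pct_in_both_others)))
  corr <- lapply(result$correction, function(x)
    x[c("n_kept", "n_removed", "pct_removed")])
  mot <- lapply(result$motifs, function(m) {
    out <- list()
    if (!is.null(m$enrichment_change)) out$enrichment_change <-
        m$enrichment_change
    out$top_shifted <- utils::head(
      m$matched_pairs[order(-abs(m$matched_pairs$log_ratio)), ], 10)
    out
  })
  list(parameters = unclass(result$config),
       libraries = result$libraries, correction = corr, overlap = ov,
       membership = result$membership, motifs = mot,
       annotation = result$annotation)
}
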