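# Synthetic PAR-CLIP simulator with ground truth.
#
# Emulates the statistical structure the correction method assumes:
# several libraries share a reproducible, G-rich crosslinked background
# site set whose abundant sites are abundant in every library; RBP
# libraries add signal sites carrying a planted motif; reads carry T-to-C
# conversions at crosslinked rates (signal/background) or non-crosslinked
# rates (total RNA), plus configurable multimapper and non-T>C error
# contamination. Site abundance is drawn once per site and per-library
# depths are Poisson around it, so read-depth thresholds (1/5/25) stratify
# sites consistently across libraries.

#' Simulation configuration
#'
#' Defaults define the study conditions: a 200 kb two-chromosome genome at
#' GC 0.45 with 30 protein-coding transcripts (5'UTR/CDS/optional
#' intron/3'UTR), lincRNAs and labeled repeats; 60 signal sites carrying an
#' A-rich 7-mer motif (containing the canonical poly(A) signal) placed in
#' 3'UTR/CDS; 80 background sites per library with G > A > C > T
#' composition, 60% of them shared identically across all libraries and a
#' quarter placed 25-100 bp downstream of TSSs; long-tailed (log-normal)
#' site abundance with a depth boost for shared background sites; per-read
#' conversion probabilities of 0.65 for crosslinked material and 0.15 for
#' the non-crosslinked total-RNA control; 5% multimappers and a 3% non-T>C
#' error rate.
#'
#' @param seed master seed; fully determines all output.
#' @param genome_length,gc genome size (split over two chromosomes) and GC
#'   content.
#' @param n_transcripts,intron_prob,n_lincrna,n_repeats annotation layout.
#' @param n_signal_sites,signal_motif planted signal sites and their motif
#'   (IUPAC allowed in scanning; the planted instance uses A/C/G/T with U
#'   treated as T).
#' @param n_background_sites,bg_weights,background_sharing,tss_bg_fraction
#'   background sites per library, their base composition, the fraction
#'   shared across all libraries, and the fraction placed just downstream
#'   of TSSs.
#' @param depth_meanlog,depth_sdlog,signal_depth_meanlog,shared_depth_boost
#'   log-normal site-abundance parameters (shared background sites get
#'   `depth_meanlog + shared_depth_boost`).
#' @param p_conv_crosslinked,p_conv_background_reads,p_conv_noncrosslinked
#'   per-read probability of carrying >= 1 T-to-C conversion for signal
#'   reads, background-site reads, and total-RNA reads.
#' @param read_length read length in bases.
#' @param multimap_fraction fraction of reads emitted with `nmap > 1`.
#' @param other_mismatch_rate fraction of reads carrying one random
#'   non-T>C mismatch.
#' @param n_rbp_libs,n_background_libs,total_reads library layout.
#' @param site_width_range planted site widths (uniform).
#' @param distinct_signal_per_rbp give each RBP library its own disjoint
#'   signal-site set (a different-RBPs design) instead of one shared set
#'   (replicate design, the default); background sharing is unaffected.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 42L,
                       genome_length = 200000L, gc = 0.45,
                       n_transcripts = 30L, intron_prob = 0.5,
                       n_lincrna = 5L, n_repeats = 10L,
                       n_signal_sites = 60L, signal_motif = "AAATAAA",
                       n_background_sites = 80L,
                       bg_weights = c(A = 0.25, C = 0.13, G = 0.52,
                                      T = 0.10),
                       background_sharing = 0.6, tss_bg_fraction = 0.25,
                       depth_meanlog = 1.0, depth_sdlog = 1.1,
                       signal_depth_meanlog = 1.8,
                       shared_depth_boost = 1.2,
                       p_conv_crosslinked = 0.65,
                       p_conv_background_reads = 0.65,
                       p_conv_noncrosslinked = 0.15,
                       read_length = 30L, multimap_fraction = 0.05,
                       other_mismatch_rate = 0.03,
                       n_rbp_libs = 2L, n_background_libs = 3L,
                       total_reads = 3000L,
                       site_width_range = c(25L, 40L),
                       distinct_signal_per_rbp = FALSE) {
  cfg <- as.list(environment())
  probs <- c(gc, background_sharing, tss_bg_fraction, p_conv_crosslinked,
             p_conv_background_reads, p_conv_noncrosslinked,
             multimap_fraction, other_mismatch_rate, intron_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  stopifnot(abs(sum(bg_weights) - 1) < 1e-6, read_length >= 10)
  structure(cfg, class = "sim_config")
}

.rand_dna <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

#' Simulate a genome and transcript annotation
#'
#' Generates a random genome at the configured GC content and lays out
#' non-overlapping transcripts (5'UTR, CDS with optional intron, 3'UTR),
#' lincRNAs and labeled repeat intervals along it. Deterministic per seed.
#'
#' @param config a `sim_config`.
#' @return list with `genome` (character vector of chromosome sequences;
#'   convert with `Biostrings::DNAStringSet` as needed) and `annotation`
#'   (an `annotation_index`).
#' @export
simulate_genome_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(derive_seeds(config$seed, 10)[1], {
    chroms <- c("chr1", "chr2")
    clen <- rep(config$genome_length %/% 2L, 2)
    genome <- setNames(vapply(clen, function(n)
      paste(.rand_dna(n, config$gc), collapse = ""), character(1)), chroms)
    feats <- list()
    cursor <- setNames(rep(200L, 2), chroms)
    add <- function(chrom, feature, start, end, strand, tid)
      feats[[length(feats) + 1L]] <<- data.frame(
        chrom = chrom, feature = feature, start = start, end = end,
        strand = strand, transcript_id = tid)
    for (t in seq_len(config$n_transcripts)) {
      chrom <- chroms[(t %% 2L) + 1L]
      tid <- sprintf("tx%03d", t)
      strand <- sample(c("+", "-"), 1)
      u5 <- sample(60:150, 1); u3 <- sample(200:400, 1)
      cds <- sample(300:900, 1)
      has_intron <- stats::runif(1) < config$intron_prob
      intr <- if (has_intron) sample(150:300, 1) else 0L
      span <- u5 + cds + intr + u3
      s <- cursor[chrom] + sample(200:600, 1)
      if (s + span > clen[match(chrom, chroms)] - 200L)
        stop("layout infeasible for genome length")
      # genomic left-to-right feature order depends on strand
      parts_tx <- list(c("5utr", u5))
      if (has_intron) {
        c1 <- cds %/% 2L
        parts_tx <- c(parts_tx, list(c("cds", c1), c("intron", intr),
                                     c("cds", cds - c1)))
      } else parts_tx <- c(parts_tx, list(c("cds", cds)))
      parts_tx <- c(parts_tx, list(c("3utr", u3)))
      parts <- if (strand == "+") parts_tx else rev(parts_tx)
      pos <- s
      for (p in parts) {
        w <- as.integer(p[2])
        add(chrom, p[1], pos, pos + w, strand, tid)
        pos <- pos + w
      }
      add(chrom, "transcript", s, s + span, strand, tid)
      cursor[chrom] <- s + span
    }
    for (i in seq_len(config$n_lincrna)) {
      chrom <- chroms[(i %% 2L) + 1L]
      tid <- sprintf("linc%02d", i)
      w <- sample(400:700, 1)
      s <- cursor[chrom] + sample(200:600, 1)
      if (s + w > clen[match(chrom, chroms)] - 200L)
        stop("layout infeasible for genome length")
      strand <- sample(c("+", "-"), 1)
      add(chrom, "lincRNA", s, s + w, strand, tid)
      add(chrom, "transcript", s, s + w, strand, tid)
      cursor[chrom] <- s + w
    }
    for (i in seq_len(config$n_repeats)) {
      chrom <- chroms[(i %% 2L) + 1L]
      w <- sample(200:400, 1)
      s <- cursor[chrom] + sample(200:600, 1)
      if (s + w > clen[match(chrom, chroms)] - 200L)
        stop("layout infeasible for genome length")
      add(chrom, "repeat", s, s + w, sample(c("+", "-"), 1),
          sprintf("rep%02d", i))
      cursor[chrom] <- s + w
    }
    features <- do.call(rbind, feats)
    list(genome = genome, annotation = build_annotation_index(features))
  })
}

.write_segment <- function(genome, chrom, start, strand, seq_strand) {
  # write a strand-oriented sequence into the forward genome at [start, ...)
  fwd <- if (strand == "-") revcomp_chr(seq_strand) else seq_strand
  s <- genome[[chrom]]
  substr(s, start + 1L, start + nchar(fwd)) <- fwd
  genome[[chrom]] <- s
  genome
}

.truth_site_row <- function(chrom, start, end, strand, site_id, class,
                            library, abundance) {
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             site_id = site_id, read_count = 0L, conv_locs = ".",
             max_depth = NA_integer_, class = class, library = library,
             abundance = abundance)
}

#' Plant signal and background sites into a simulated genome
#'
#' Signal sites are placed inside 3'UTR (70%) or CDS (30%) features with
#' the signal motif written into the genome at the site center (in
#' transcript orientation). Background sites are rewritten with G-rich
#' composition (at least 3 T positions are retained on the site strand so
#' conversions remain possible); a configured fraction is shared
#' identically across all libraries and a configured fraction sits 25-100
#' bp downstream of a TSS. No planted sites overlap; sites are separated
#' by a 50 bp buffer so called groups stay distinct.
#'
#' @param config a `sim_config`.
#' @param sim output of [simulate_genome_annotation()].
#' @return list of class `sim_truth`: `genome` (with motifs/backgrounds
#'   written in), `signal` and `background` site tables (the latter with
#'   `shared` and `library` columns; `library == "all"` for shared sites),
#'   and `lib_ids` (RBP, background and total library names).
#' @export
plant_sites <- function(config, sim) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(derive_seeds(config$seed, 10)[2], {
    genome <- as.list(sim$genome)
    ann <- sim$annotation
    chrom_len <- vapply(genome, nchar, integer(1))
    occupied <- data.frame(chrom = character(0), start = integer(0),
                           end = integer(0))
    buffer <- 50L
    is_free <- function(chrom, start, end) {
      o <- occupied[occupied$chrom == chrom, , drop = FALSE]
      !any(pmax(o$start, start - buffer) < pmin(o$end, end + buffer))
    }
    claim <- function(chrom, start, end)
      occupied <<- rbind(occupied,
                         data.frame(chrom = chrom, start = start, end = end))
    widths <- function(n) sample(config$site_width_range[1]:
                                   config$site_width_range[2], n,
                                 replace = TRUE)
    fe <- ann$features
    tx <- ann$transcripts
    place_in_feature <- function(w, cats) {
      cand <- fe[fe$feature %in% cats & (fe$end - fe$start) > w + 2L, ]
      for (a in 1:200) {
        row <- cand[sample.int(nrow(cand), 1), ]
        s <- row$start + sample.int(row$end - row$start - w, 1)
        if (is_free(row$chrom, s, s + w)) {
          claim(row$chrom, s, s + w)
          return(list(chrom = row$chrom, start = s, strand = row$strand))
        }
      }
      stop("insufficient space to place a site")
    }
    place_tss <- function(w) {
      for (a in 1:200) {
        row <- tx[sample.int(nrow(tx), 1), ]
        off <- sample(25:(100 - w), 1)
        s <- if (row$strand == "+") row$tss + off else row$tss - off - w
        if (s >= 0 && s + w <= chrom_len[row$chrom] &&
              is_free(row$chrom, s, s + w)) {
          claim(row$chrom, s, s + w)
          return(list(chrom = row$chrom, start = s, strand = row$strand))
        }
      }
      stop("insufficient space to place a TSS-proximal site")
    }
    place_uniform <- function(w) {
      for (a in 1:500) {
        chrom <- sample(names(genome), 1)
        s <- sample.int(chrom_len[chrom] - w, 1) - 1L
        if (is_free(chrom, s, s + w)) {
          claim(chrom, s, s + w)
          return(list(chrom = chrom, start = s,
                      strand = sample(c("+", "-"), 1)))
        }
      }
      stop("insufficient space to place a site")
    }
    # --- signal sites ---
    # one signal set shared by all RBP libraries (replicate design) or,
    # with distinct_signal_per_rbp, a disjoint set per RBP library (a
    # different-RBPs design, where inter-library sharing happens only at
    # the planted background)
    motif <- .norm_dna(config$signal_motif)
    lib_rbp <- sprintf("rbp%d", seq_len(config$n_rbp_libs))
    sig_owners <- if (config$distinct_signal_per_rbp) lib_rbp else "rbp"
    sig <- list()
    for (owner in sig_owners) {
      sig_w <- widths(config$n_signal_sites)
      for (i in seq_len(config$n_signal_sites)) {
        cats <- if (stats::runif(1) < 0.7) "3utr" else "cds"
        loc <- place_in_feature(sig_w[i], cats)
        a <- stats::rlnorm(1, config$signal_depth_meanlog,
                           config$depth_sdlog)
        sig[[length(sig) + 1L]] <- .truth_site_row(
          loc$chrom, loc$start, loc$start + sig_w[i], loc$strand,
          sprintf("sig_%s_%03d", owner, i), "signal", owner, a)
        # write the motif at the site center, transcript orientation
        off <- (sig_w[i] - nchar(motif)) %/% 2L
        mstart <- if (loc$strand == "+") loc$start + off else
          loc$start + sig_w[i] - off - nchar(motif)
        genome <- .write_segment(genome, loc$chrom, mstart, loc$strand,
                                 motif)
      }
    }
    signal <- do.call(rbind, sig)
    # --- background sites ---
    bg_seq <- function(w) {
      s <- sample(names(config$bg_weights), w, replace = TRUE,
                  prob = config$bg_weights)
      n_t <- sum(s == "T")
      if (n_t < 3L) s[sample(which(s != "T"), 3L - n_t)] <- "T"
      paste(s, collapse = "")
    }
    lib_bg <- sprintf("bg%d", seq_len(config$n_background_libs))
    n_shared <- round(config$background_sharing * config$n_background_sites)
    n_unique <- config$n_background_sites - n_shared
    # only shared sites are eligible for TSS-proximal placement: they are
    # the ones carried into RBP libraries, where the positional artifact
    # must be demonstrable and removable
    place_bg <- function(site_id, library, shared) {
      w <- widths(1)
      loc <- if (shared && stats::runif(1) < config$tss_bg_fraction)
        place_tss(w) else place_uniform(w)
      genome <<- .write_segment(genome, loc$chrom, loc$start, loc$strand,
                                bg_seq(w))
      a <- stats::rlnorm(1, config$depth_meanlog +
                           if (shared) config$shared_depth_boost else 0,
                         config$depth_sdlog)
      row <- .truth_site_row(loc$chrom, loc$start, loc$start + w,
                             loc$strand, site_id, "background", library, a)
      row$shared <- shared
      row
    }
    bg <- list()
    for (i in seq_len(n_shared))
      bg[[length(bg) + 1L]] <- place_bg(sprintf("bgS%03d", i), "all", TRUE)
    for (lib in lib_bg)
      for (i in seq_len(n_unique))
        bg[[length(bg) + 1L]] <- place_bg(sprintf("bgU_%s_%03d", lib, i),
                                          lib, FALSE)
    background <- do.call(rbind, bg)
    structure(list(genome = genome, signal = signal,
                   background = background,
                   lib_ids = list(rbp = lib_rbp, background = lib_bg,
                                  total = "total")),
              class = "sim_truth")
  })
}

.sim_reads_from_sites <- function(config, genome, sites, p_conv,
                                  library_id, counter_env) {
  chrom_len <- vapply(genome, nchar, integer(1))
  rl <- config$read_length
  rows <- list()
  for (i in seq_len(nrow(sites))) {
    st <- sites[i, ]
    depth <- max(1L, stats::rpois(1, st$abundance))
    lo <- max(0L, st$start - 4L)
    hi <- min(chrom_len[st$chrom] - rl, st$end + 4L - rl)
    if (hi < lo) hi <- lo
    for (r in seq_len(depth)) {
      s <- lo + sample.int(hi - lo + 1L, 1) - 1L
      rows[[length(rows) + 1L]] <- .make_read(
        config, genome, st$chrom, s, st$strand, p_conv, st$site_id,
        library_id, counter_env)
    }
  }
  rows
}

.make_read <- function(config, genome, chrom, start, strand, p_conv,
                       origin, library_id, counter_env) {
  rl <- config$read_length
  end <- start + rl
  fwd <- substr(genome[[chrom]], start + 1L, end)
  tch <- strsplit(if (strand == "-") revcomp_chr(fwd) else fwd, "")[[1]]
  orig <- tch
  crosslinked <- FALSE
  if (stats::runif(1) < p_conv) {
    t_idx <- which(tch == "T")
    if (!length(t_idx)) {
      counter_env$n_no_t <- counter_env$n_no_t + 1L
    } else {
      n_conv <- min(sample(1:2, 1, prob = c(0.75, 0.25)), length(t_idx))
      conv <- sample(t_idx, n_conv)
      tch[conv] <- "C"
      crosslinked <- TRUE
    }
  }
  if (stats::runif(1) < config$other_mismatch_rate) {
    i <- sample.int(rl, 1)
    if (tch[i] == orig[i]) {
      tch[i] <- sample(setdiff(c("A", "C", "G", "T"), orig[i]), 1)
      # avoid fabricating an extra T>C in transcript orientation
      if (orig[i] == "T" && tch[i] == "C") tch[i] <- "G"
    }
  }
  diff <- which(tch != orig)
  if (length(diff)) {
    if (strand == "+") {
      pos <- start + diff - 1L
      ref <- orig[diff]; alt <- tch[diff]
    } else {
      pos <- end - diff
      ref <- .complement_base[orig[diff]]
      alt <- .complement_base[tch[diff]]
    }
    o <- order(pos)
    mm <- format_mm(pos[o], ref[o], alt[o])
  } else mm <- "."
  nmap <- if (stats::runif(1) < config$multimap_fraction)
    sample(2:10, 1) else 1L
  list(chrom = chrom, start = start, end = end, strand = strand,
       seq = paste(tch, collapse = ""), mm = mm, nmap = nmap,
       library_id = library_id, origin_site = origin,
       crosslinked = crosslinked)
}

.bind_reads <- function(rows) {
  data.frame(read_id = NA_character_,
             chrom = vapply(rows, `[[`, "", "chrom"),
             start = vapply(rows, `[[`, 0L, "start"),
             end = vapply(rows, `[[`, 0L, "end"),
             strand = vapply(rows, `[[`, "", "strand"),
             seq = vapply(rows, `[[`, "", "seq"),
             mm = vapply(rows, `[[`, "", "mm"),
             nmap = vapply(rows, `[[`, 0L, "nmap"),
             library_id = vapply(rows, `[[`, "", "library_id"),
             origin_site = vapply(rows, `[[`, "", "origin_site"),
             crosslinked = vapply(rows, `[[`, NA, "crosslinked"))
}

#' Simulate one sequencing library
#'
#' RBP libraries draw reads from the signal sites and the shared
#' background sites; background libraries draw from the shared background
#' plus their own unique background sites; the total-RNA library draws
#' reads uniformly from transcript nucleotides (annotation-proportional
#' sampling) with the non-crosslinked conversion rate. Reads from a site
#' lacking any T on its strand are emitted unconverted and counted in the
#' `n_no_t` attribute.
#'
#' @param config a `sim_config`.
#' @param truth a `sim_truth` from [plant_sites()].
#' @param kind `"rbp"`, `"background"` or `"total"`.
#' @param library_id library label (e.g. `"rbp1"`, `"bg2"`, `"total"`).
#' @param annotation `annotation_index` (required for `kind = "total"`).
#' @param seed optional seed (defaults to one derived from the config
#'   seed and the library id).
#' @return aligned-read data frame with truth columns `origin_site` and
#'   `crosslinked`; strip them with `[, 1:9]` for pipeline input.
#' @export
simulate_library <- function(config, truth, kind = c("rbp", "background",
                                                     "total"),
                             library_id, annotation = NULL, seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(truth, "sim_truth"))
  if (is.null(seed)) {
    all_libs <- unlist(truth$lib_ids)
    seed <- derive_seeds(config$seed, 10L + length(all_libs))[
      10L + match(library_id, all_libs)]
  }
  withr::with_seed(seed, {
    counter <- new.env()
    counter$n_no_t <- 0L
    genome <- truth$genome
    rows <- switch(kind,
      rbp = {
        shared <- truth$background[truth$background$shared, , drop = FALSE]
        mine_sig <- truth$signal[truth$signal$library %in%
                                   c("rbp", library_id), , drop = FALSE]
        c(.sim_reads_from_sites(config, genome, mine_sig,
                                config$p_conv_crosslinked, library_id,
                                counter),
          .sim_reads_from_sites(config, genome, shared,
                                config$p_conv_background_reads, library_id,
                                counter))
      },
      background = {
        mine <- truth$background[truth$background$shared |
                                   truth$background$library == library_id, ,
                                 drop = FALSE]
        .sim_reads_from_sites(config, genome, mine,
                              config$p_conv_background_reads, library_id,
                              counter)
      },
      total = {
        if (is.null(annotation))
          stop("total library needs the annotation")
        tx <- annotation$transcripts
        w <- tx$end - tx$start - config$read_length
        tx <- tx[w > 0, , drop = FALSE]
        w <- w[w > 0]
        idx <- sample.int(nrow(tx), config$total_reads, replace = TRUE,
                          prob = w)
        lapply(idx, function(i) {
          s <- tx$start[i] + sample.int(w[i], 1) - 1L
          .make_read(config, genome, tx$chrom[i], s, tx$strand[i],
                     config$p_conv_noncrosslinked, NA_character_,
                     library_id, counter)
        })
      })
    out <- .bind_reads(rows)
    out$read_id <- sprintf("%s_r%06d", library_id, seq_len(nrow(out)))
    if (counter$n_no_t > 0L)
      warning(sprintf("%s: %d reads from T-less spans emitted unconverted",
                      library_id, counter$n_no_t))
    attr(out, "n_no_t") <- counter$n_no_t
    out
  })
}

#' Run the full simulator
#'
#' Generates genome + annotation, plants sites, and simulates every
#' library (`n_rbp_libs` RBP, `n_background_libs` background, one total).
#' Fully deterministic per `config$seed`. With `outdir` the dataset is
#' also written to disk (`genome.fa`, `annotation.gtf`,
#' `reads/<lib>.tsv`, `truth/*.bed`, `config.yaml`).
#'
#' @param config a `sim_config`.
#' @param outdir optional output directory.
#' @return list: `config`, `genome` (`DNAStringSet`, post-planting),
#'   `annotation`, `truth`, `libraries` (named list of read data frames,
#'   truth columns included).
#' @export
simulate_parclip <- function(config = sim_config(), outdir = NULL) {
  sim <- simulate_genome_annotation(config)
  truth <- plant_sites(config, sim)
  libs <- c(
    setNames(lapply(truth$lib_ids$rbp, function(l)
      simulate_library(config, truth, "rbp", l)), truth$lib_ids$rbp),
    setNames(lapply(truth$lib_ids$background, function(l)
      simulate_library(config, truth, "background", l)),
      truth$lib_ids$background),
    setNames(list(simulate_library(config, truth, "total", "total",
                                   annotation = sim$annotation)), "total"))
  genome <- Biostrings::DNAStringSet(unlist(truth$genome))
  out <- list(config = config, genome = genome,
              annotation = sim$annotation, truth = truth,
              libraries = libs)
  if (!is.null(outdir)) {
    dir.create(file.path(outdir, "reads"), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(outdir, "truth"), showWarnings = FALSE)
    write_genome(genome, file.path(outdir, "genome.fa"))
    write_annotation_gtf(sim$annotation, file.path(outdir,
                                                   "annotation.gtf"))
    for (l in names(libs))
      write_reads_tsv(libs[[l]][, .read_cols],
                      file.path(outdir, "reads", paste0(l, ".tsv")))
    write_sites_bed(truth$signal,
                    file.path(outdir, "truth", "signal_sites.bed"))
    write_sites_bed(truth$background,
                    file.path(outdir, "truth", "background_sites.bed"))
    cfg <- unclass(config)
    cfg$bg_weights <- as.list(cfg$bg_weights)
    yaml::write_yaml(cfg, file.path(outdir, "config.yaml"))
  }
  out
}

#' Precision/recall of called sites against planted truth
#'
#' Matching is >= 1 bp overlap. Precision is the fraction of called sites
#' overlapping any truth site; recall the fraction of truth sites
#' recovered.
#'
#' @param called called sites data frame.
#' @param truth_sites planted sites data frame.
#' @param stranded strand-aware matching (default TRUE).
#' @return list: `precision`, `recall`, `n_called`, `n_truth`.
#' @export
evaluate_calls <- function(called, truth_sites, stranded = TRUE) {
  precision <- if (nrow(called))
    mean(.overlaps_any(called, truth_sites, stranded)) else NA_real_
  recall <- if (nrow(truth_sites))
    mean(.overlaps_any(truth_sites, called, stranded)) else NA_real_
  list(precision = precision, recall = recall, n_called = nrow(called),
       n_truth = nrow(truth_sites))
}
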