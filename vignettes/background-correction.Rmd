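---
title: "Quantifying and correcting crosslinked background in PAR-CLIP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and correcting crosslinked background in PAR-CLIP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parclipbg)
```

## The problem

PAR-CLIP identifies the binding sites of an RNA-binding protein (RBP) by
feeding cells 4-thiouridine (4SU), crosslinking protein to RNA with
UV 365 nm, immunoprecipitating the RBP, and sequencing the protected RNA
fragments. Crosslinked 4SU reads out as a diagnostic T-to-C conversion
during reverse transcription, which is commonly taken as proof of a
direct interaction. The difficulty this package addresses is that
control immunoprecipitations — a non-RBP tag, or no tag at all — also
yield large numbers of uniquely mapping reads *with* T-to-C conversions:
covalently crosslinked background that is reproducible across control
samples, G-rich in composition, and concentrated at loci that recur
across many unrelated PAR-CLIP experiments. Conversion-based filters
cannot remove it, because it is genuinely crosslinked.

The remedy is empirical, borrowed from the RIP-chip tradition: sequence
background libraries alongside the RBP library, process them
identically, and subtract.

## The method

1. **Utilized reads.** A read is *utilized* if it maps uniquely
   (`nmap == 1`), is at least 10 nt long, and carries 0, 1 or 2 T-to-C
   conversions in transcript orientation and no other mismatch type. On
   a minus-strand read, a T-to-C conversion appears as A-to-G in
   forward-reference records; `classify_conversion()` resolves this.
2. **Groups and clusters.** A *group* is a maximal strand-specific
   interval covered by at least one utilized read (`call_groups()`); a
   *cluster* is a group with at least 5 reads and at least 2 distinct
   conversion locations (`call_clusters()`). A conversion location is a
   genomic coordinate with at least one converting read, regardless of
   how many reads convert there. No kernel-density sub-splitting is
   performed: one group is one site.
3. **Background union and subtraction.** The background libraries'
   groups are merged into maximal loci (`union_sites()`), and any RBP
   site overlapping that union by **one or more base pairs is removed in
   full** (`subtract_background()`); no partial trimming.
4. **Companion statistics.** Conversion fractions and mismatch profiles
   (`conversion_fraction()`, `mismatch_profile()`); depth-thresholded
   three-way overlap (`venn3()`); membership binning against the
   background union (`bin_by_membership()`); between-library depth
   correlation (`depth_correlation()`); k-mer tables, logos and the
   dinucleotide-preserving shuffle null (`count_kmers()`,
   `top_kmer_logo()`, `dinucleotide_shuffle()`,
   `kmer_enrichment_test()`); IUPAC motif scanning and matched-pairs
   k-mer comparison (`scan_iupac()`, `percent_sites_with_motif()`,
   `matched_pairs()`); genomic category and positional profiles
   (`assign_category()`, `tss_window_density()`,
   `terminus_enrichment()`); and saturation by subsampling
   (`saturation_curve()`).

All intervals are 0-based half-open everywhere — in data frames, BED
output, and internally. Adjacent intervals (`[a,b)` vs `[b,c)`) never
count as overlapping; the GenomicRanges-backed merging passes
`min.gapwidth = 0` for exactly this reason.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `max_tc` | 2 | conversions/read | utilized-read definition |
| `min_len` | 10 | nt | post-alignment length guard |
| `min_reads` | 5 | reads | cluster depth threshold |
| `min_conv_locs` | 2 | distinct coordinates | cluster conversion threshold |
| `depth_thresholds` | 1, 5, 25 | reads | overlap-report strata |
| `k_motif` | 7 | nt | matched-pairs k-mer length |
| `k_logo`, `top_n` | 8, 25 | nt, k-mers | logo construction |
| `n_shuffles` | 99 | replicates | shuffle-null resolution (min 19) |
| `fractions`, `reps` | 0.1–0.9, 5 | — | saturation grid |

Reads with any non-T-to-C mismatch are excluded from utilized reads by
default (the strictest reading of the utilized definition);
`allow_other_mismatches = TRUE` relaxes this. Mismatch records involving
N are ignored and never disqualify a read.

Interval operations are strand-aware by default — conversions are
strand-resolved, so merging opposite strands would conflate antisense
signal — and every entry point takes `stranded = FALSE` for comparison.

Category assignment uses the fixed priority
`3utr > 5utr > cds > intron > lincRNA > repeat > intergenic`, with 3'UTR
first because UTR binding is the biological signal of interest for the
canonical test RBPs; the priority vector is an argument.

## The simulator

`simulate_parclip()` generates, deterministically per seed: a two-
chromosome genome at configurable GC; non-overlapping transcripts with
5'UTR/CDS/optional-intron/3'UTR structure plus lincRNAs and labeled
repeats; planted **signal sites** in 3'UTR/CDS carrying an A-rich 7-mer
motif (default `AAATAAA`, which contains the canonical poly(A) signal);
and planted **background sites** rewritten with G > A > C > T
composition, a configurable fraction shared identically across all
libraries and a configurable fraction of the shared ones placed 25–100
bp downstream of a TSS. RBP libraries draw reads from signal plus shared
background; background libraries from shared plus their own unique
background; the total-RNA control draws annotation-proportionally from
transcript bodies. Per-read conversion probabilities default to 0.65
for crosslinked material (signal and background sites — crosslinked
background is the phenomenon of interest) and 0.15 for the
non-crosslinked total-RNA regime; 5% of reads are multimappers and 3%
carry one random non-T-to-C error.

Two modeling decisions deserve emphasis:

* **Depth.** Each site's abundance is drawn once (log-normal; shared
  background sites receive a mean-log boost of 1.2), and each library's
  read depth at the site is Poisson around that abundance. This makes
  abundant sites abundant in *every* library, which is what produces the
  empirical signature that overlap between background replicates rises
  with the read-depth threshold. Independent per-library depth draws
  destroy that signature.
* **Replicates vs different RBPs.** By default all RBP libraries share
  one signal-site set (a replicate design). With
  `distinct_signal_per_rbp = TRUE` each RBP library gets its own
  disjoint signal set, so that the only loci shared between RBP
  libraries are the planted background — the configuration in which
  membership binning must climb to 100% background overlap at maximal
  membership. Under the default sharing mechanism (a site is either
  shared by all libraries or unique to one) intermediate membership
  bins are essentially empty; a smooth gradient across bins, as seen in
  real multi-study compilations, would require per-site sharing
  probabilities, which this simulator deliberately does not model.

What the simulator does **not** emulate: RNase T1 cut-site and ligation
biases, fragment-length distributions, PCR duplication, sequencing
quality, expression-level variation across transcripts, and
higher-order (beyond first-order) background sequence structure.
Passing tests on this synthetic data therefore demonstrate algorithmic
correctness and the qualitative phenomena of crosslinked background —
not performance on any real library.

One consequence of the first-order background model is worth knowing:
because background site sequences are i.i.d. draws from a base-weight
distribution, their k-mer content is fully explained by their
dinucleotide composition, and the dinucleotide-preserving shuffle null
finds the top background 8-mer *not* significantly enriched. Real
G-rich background has longer-range structure (G-runs) that the shuffle
does not preserve, which is why the same test is informative on real
data. The acceptance script therefore demonstrates the enrichment test
on the planted signal motif in corrected sites, where the null is
exceeded at the empirical floor.

## Numerical choices

* **Empirical p-values** are `(1 + #{null >= observed}) / (1 + n)` —
  never zero; a normal-approximation tail p from the null mean/sd is
  reported alongside for values beyond Monte-Carlo resolution.
* **Calibration.** The p-value uniformity check in the test suite uses
  the degenerate query `ANT` rather than a literal k-mer: at desk-scale
  sequence collections a literal k-mer's integer count ties frequently
  across 19 shuffle replicates, and ties make the empirical rank
  conservative (a property of any discrete permutation p-value, not an
  implementation flaw). A query with one degenerate position raises the
  expected count enough that the tie mass is negligible.
* **Shuffle.** `dinucleotide_shuffle()` is the Eulerian-path shuffle:
  build the order-1 de Bruijn multigraph, sample a random last-edge
  arborescence toward the terminal base (rejection step), permute the
  remaining edge lists uniformly, and walk. First and last bases are
  fixed; mono- and dinucleotide multisets are conserved exactly; runs of
  non-ACGT characters stay in place and the segments between them are
  shuffled independently. Shuffling is per sequence by default; a
  whole-library mode concatenates first.
* **Matched pairs** add a pseudocount of 1 to each count before
  normalizing by the library's total nucleotides, so k-mers absent on
  one side have finite log-ratios; swapping the tables negates every
  log-ratio exactly.
* **Depth correlation** is computed on `log2(count + 1)` because read
  counts span orders of magnitude; `log_scale = FALSE` gives the linear
  fit.
* **Ties in k-mer rank order** are broken lexicographically.
* **Degenerate inputs**: empty read sets produce empty site lists;
  empty backgrounds make subtraction the identity; terminal-window
  enrichment with an empty remainder density reports `Inf` with a
  `capped` flag; transcripts shorter than the terminal window are
  skipped with a warning.
* **venn3 semantics.** Percent-overlap is computed on merged loci
  (a locus present in two libraries counts once), matching "sites
  appearing in exactly the indicated number of libraries";
  `per_site = TRUE` switches to raw per-site percentages.
* **Saturation matching** is overlap-based (>= 1 bp against the
  full-set sites) because site boundaries shift under subsampling;
  `match = "exact"` requires identical coordinates.

## Problem sizes

The bundled study conditions are a 200 kb genome, 30 transcripts plus 5
lincRNAs and 10 repeats, 60 signal sites, 80 background sites per
library (60% shared), 2 RBP + 3 background libraries and a 3000-read
total-RNA control — roughly 1–2 thousand utilized reads and ~100 sites
per library. Brute-force oracle comparisons run at 10^4 random
instances for pairwise overlap and up to 500 reads for group calling;
shuffle conservation is checked on 10^4 random sequences and
calibration on 200 replicates of 20x50-nt collections.

## Limitations

* One background mechanism (shared crosslinked sites) — the likely
  reality of multiple distinct background sources is collapsed into it.
* No per-nucleotide crosslink scoring or sub-group peak resolution.
* Whole-site removal is aggressive by construction: a true site that
  merely touches background is discarded (that is the method, not a
  bug).
* Desk-scale depth correlation between background replicates (~0.2–0.3
  R²) is far below real-data values, because union loci are dominated
  by depth-1 library-unique sites at this scale.
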