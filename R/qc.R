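## Assembly QC: telomere-motif scanning, genetic/physical map concordance,
## basic assembly statistics.

#' Scan for telomeric repeat arrays
#'
#' Counts exact occurrences of the motif and its reverse complement in
#' non-overlapping windows tiling each chromosome (step-1 counting; the
#' plant telomere motif `TTTAGGG` cannot overlap itself, so the
#' distinction is moot for the default). A chromosome end is positive
#' when the copies within its `terminal_windows` outermost windows reach
#' `min_copies`.
#'
#' @param genome a `haplotype_genome`.
#' @param motif telomere motif (plus strand).
#' @param window window size in bp.
#' @param terminal_windows windows per end considered terminal.
#' @param min_copies copy threshold for a positive end.
#' @return a list per chromosome: data frame of window counts and the two
#'   terminal flags.
#' @export
telomere_scan <- function(genome, motif = "TTTAGGG", window = 10000L,
                          terminal_windows = 2L, min_copies = 10L) {
  if (!nzchar(motif)) stop("motif must be non-empty")
  m <- Biostrings::DNAString(motif)
  mrc <- Biostrings::reverseComplement(m)
  out <- list()
  for (cid in names(genome$seqs)) {
    seq <- genome$seqs[[cid]]
    L <- length(seq)
    nw <- max(ceiling(L / window), 1L)
    starts <- c(Biostrings::start(Biostrings::matchPattern(m, seq)),
                Biostrings::start(Biostrings::matchPattern(mrc, seq)))
    cnt <- tabulate(findInterval(starts - 1L, (seq_len(nw) - 1L) * window),
                    nbins = nw)
    wdf <- data.frame(chrom = cid,
                      start = (seq_len(nw) - 1L) * window,
                      end = pmin(seq_len(nw) * window, L),
                      count = cnt, stringsAsFactors = FALSE)
    tw <- min(terminal_windows, nw)
    out[[cid]] <- list(
      windows = wdf,
      left_terminal_positive = sum(cnt[seq_len(tw)]) >= min_copies,
      right_terminal_positive = sum(cnt[nw - seq_len(tw) + 1L]) >=
        min_copies)
  }
  out
}

#' Genetic-map / physical-map concordance
#'
#' Per chromosome with at least three markers: Spearman rank correlation
#' between genetic (cM) and physical (bp) position (midranks on ties),
#' the orientation-corrected |rho| (stored maps may run in either
#' direction), the marker count and the largest rank discordance.
#'
#' @param markers a genetic-map data frame (`marker_id`, `chrom`, `cM`,
#'   `bp`).
#' @return a data frame with one row per chromosome.
#' @export
map_concordance <- function(markers) {
  out <- lapply(split(markers, markers$chrom), function(d) {
    n <- nrow(d)
    if (n < 3L)
      return(data.frame(chrom = d$chrom[1], n_markers = n,
                        rho = NA_real_, abs_rho = NA_real_,
                        max_rank_discordance = NA_real_,
                        stringsAsFactors = FALSE))
    rho <- stats::cor(d$cM, d$bp, method = "spearman")
    data.frame(chrom = d$chrom[1], n_markers = n, rho = rho,
               abs_rho = abs(rho),
               max_rank_discordance = max(abs(rank(d$cM) - rank(d$bp))),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Basic assembly statistics
#'
#' @param genome a `haplotype_genome`.
#' @return a list with `total_length`, `n_chromosomes`, a per-chromosome
#'   data frame of lengths and N-gap run counts, and
#'   `gapless_chromosomes`.
#' @export
assembly_stats <- function(genome) {
  per <- lapply(names(genome$seqs), function(cid) {
    seq <- genome$seqs[[cid]]
    runs <- Biostrings::matchPattern("N", seq)
    nrun <- if (length(runs) == 0L) 0L else
      sum(diff(c(-2L, Biostrings::start(runs))) > 1L)
    data.frame(chrom = cid, length = length(seq), n_gap_runs = nrun,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  list(total_length = sum(per$length),
       n_chromosomes = nrow(per),
       chromosomes = per,
       gapless_chromosomes = sum(per$n_gap_runs == 0L))
}
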