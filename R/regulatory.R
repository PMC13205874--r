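## Promoter extraction, variant burden counting, and the DE vs non-DE
## burden comparison.

#' Extract strand-aware promoter windows
#'
#' The promoter of a plus-strand gene is the `window` bp immediately
#' upstream of its start; for a minus-strand gene, immediately downstream
#' of its end. Windows are clipped at chromosome bounds; a fully clipped
#' window is kept with zero length and flagged `empty`.
#'
#' @param genes a `gene_models` data frame.
#' @param genome the matching `haplotype_genome`.
#' @param window promoter size in bp.
#' @return a data frame `gene_id`, `haplotype`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`, `empty`.
#' @export
extract_promoters <- function(genes, genome, window = 3000L) {
  if (!all(genes$chrom %in% names(genome$seqs)))
    stop("gene on unknown chromosome: ",
         genes$chrom[!genes$chrom %in% names(genome$seqs)][1])
  len <- chrom_lengths(genome)
  plus <- genes$strand == "+"
  start <- ifelse(plus, pmax(genes$start - window, 0L), genes$end)
  end <- ifelse(plus, genes$start,
                pmin(genes$end + window, len[genes$chrom]))
  data.frame(gene_id = genes$gene_id, haplotype = genes$haplotype,
             chrom = genes$chrom, start = as.integer(start),
             end = as.integer(end), strand = genes$strand,
             empty = end <= start, stringsAsFactors = FALSE)
}

#' Count variants in promoter windows
#'
#' SNP calls are counted by position; SV calls (INS, DEL, INV, TRANS,
#' HDR) are counted once per call overlapping the window by at least one
#' base -- a zero-length breakpoint (e.g. the reference side of an
#' insertion) counts when the breakpoint lies inside the window. Counts
#' are taken on the promoter's own haplotype side of each call.
#'
#' @param promoters output of [extract_promoters()].
#' @param region_calls the `region_calls` partition (hap-1 as reference).
#' @return a data frame `gene_id`, `haplotype`, `snp_count`, `sv_count`,
#'   `total`.
#' @export
count_promoter_variants <- function(promoters, region_calls) {
  known <- unique(c(region_calls$ref_chrom, region_calls$qry_chrom))
  known <- known[!is.na(known)]
  if (!all(promoters$chrom %in% known))
    stop("promoter on chromosome absent from calls: ",
         promoters$chrom[!promoters$chrom %in% known][1])
  sv_types <- c("INS", "DEL", "INV", "TRANS", "HDR")
  count_one <- function(p) {
    if (p$haplotype == "hap1") {
      cc <- region_calls$ref_chrom
      cs <- region_calls$ref_start; ce <- region_calls$ref_end
    } else {
      cc <- region_calls$qry_chrom
      cs <- region_calls$qry_start; ce <- region_calls$qry_end
    }
    on <- !is.na(cc) & cc == p$chrom
    hit <- on & (pmax(cs, p$start) < pmin(ce, p$end) |
                   (cs == ce & cs >= p$start & cs < p$end))
    c(snp = sum(hit & region_calls$type == "SNP"),
      sv = sum(hit & region_calls$type %in% sv_types))
  }
  m <- t(vapply(seq_len(nrow(promoters)), function(i)
    count_one(promoters[i, ]), c(snp = 0, sv = 0)))
  data.frame(gene_id = promoters$gene_id,
             haplotype = promoters$haplotype,
             snp_count = as.integer(m[, "snp"]),
             sv_count = as.integer(m[, "sv"]),
             total = as.integer(m[, "snp"] + m[, "sv"]),
             stringsAsFactors = FALSE)
}

#' Compare promoter variant burden between DE and non-DE pairs
#'
#' A pair's burden is the maximum of its two haplotypes' promoter totals
#' (symmetric in the haplotypes, since neither side is a privileged
#' reference). Groups are compared with a rank-based two-sample test; a
#' group with fewer than two pairs skips the test with a notice.
#'
#' @param burdens output of [count_promoter_variants()] covering both
#'   haplotypes' promoters.
#' @param de_pairs,nonde_pairs pair data frames (`gene_id_h1`,
#'   `gene_id_h2`).
#' @return a list with per-group medians and sizes, the p-value,
#'   `direction`, a `note`, and the per-pair burdens.
#' @export
compare_de_burden <- function(burdens, de_pairs, nonde_pairs) {
  b <- stats::setNames(burdens$total, burdens$gene_id)
  pair_burden <- function(pairs) {
    if (nrow(pairs) == 0L) return(numeric(0))
    pmax(b[pairs$gene_id_h1], b[pairs$gene_id_h2], na.rm = TRUE)
  }
  x <- pair_burden(de_pairs)
  y <- pair_burden(nonde_pairs)
  p <- NA_real_; note <- ""
  if (length(x) >= 2L && length(y) >= 2L) {
    p <- suppressWarnings(stats::wilcox.test(x, y)$p.value)
  } else note <- "test skipped: group with < 2 pairs"
  md <- stats::median(x) - stats::median(y)
  list(n_de = length(x), n_nonde = length(y),
       median_de = stats::median(x), median_nonde = stats::median(y),
       p_value = p,
       direction = if (!length(x) || !length(y) || is.na(md) || md == 0)
         "none" else if (md > 0) "DE higher" else "non-DE higher",
       note = note,
       de_burdens = unname(x), nonde_burdens = unname(y))
}
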