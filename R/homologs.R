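## One-to-one homolog pairing and the identical-pair set used for the
## cis-regulatory analysis.

#' Pair one-to-one homologous genes across haplotypes
#'
#' Candidate partners are collected inside the syntenic projection window
#' of each gene; pairs are reciprocal best hits by global CDS identity.
#' Genes with no candidate, or with several equally best candidates, stay
#' unpaired. A pair is `identical` iff the two coding sequences are
#' byte-equal (which implies equal length) -- "100% identity" means exact
#' equality, not a rounded alignment score.
#'
#' @param genes_h1,genes_h2 `gene_models` with CDS sequences.
#' @param region_calls the `region_calls` partition (hap-1 as reference).
#' @param search_window bp added around the projected locus.
#' @param genome_wide if `TRUE`, genes with no syntenic candidate fall
#'   back to a genome-wide best-identity search (off by default so that
#'   translocated paralogs cannot enter the identical-pair control set).
#' @return a `homolog_pairs` data frame: `gene_id_h1`, `gene_id_h2`,
#'   `cds_identity`, `identical`, `syntenic`.
#' @export
pair_homologs <- function(genes_h1, genes_h2, region_calls,
                          search_window = 5000L, genome_wide = FALSE) {
  proj12 <- make_projection(region_calls, "ref")
  n1 <- nrow(genes_h1); n2 <- nrow(genes_h2)
  best_of <- function(ident) {
    # index of the unique maximum, NA when tied or empty
    if (length(ident) == 0L || all(is.na(ident))) return(NA_integer_)
    m <- max(ident, na.rm = TRUE)
    w <- which(ident == m)
    if (length(w) != 1L) NA_integer_ else w
  }
  # candidate sets and identities, hap-1 -> hap-2
  cand_list <- vector("list", n1)
  ident_list <- vector("list", n1)
  syn_flag <- logical(n1)
  och <- genes_h2$chrom; os <- genes_h2$start; oe <- genes_h2$end
  for (i in seq_len(n1)) {
    p1 <- proj12(genes_h1$chrom[i], genes_h1$start[i])
    p2 <- proj12(genes_h1$chrom[i], genes_h1$end[i])
    cand <- integer(0)
    if (!is.na(p1$chrom)) {
      lo <- min(p1$pos, p2$pos) - search_window
      hi <- max(p1$pos, p2$pos) + search_window
      cand <- which(och == p1$chrom & os < hi & oe > lo)
    }
    syn_flag[i] <- length(cand) > 0L
    if (!syn_flag[i] && genome_wide) cand <- seq_len(n2)
    cand_list[[i]] <- cand
    ident_list[[i]] <- vapply(cand, function(j)
      cds_identity(genes_h1$cds_seq[i], genes_h2$cds_seq[j]), numeric(1))
  }
  # forward best
  fwd <- vapply(seq_len(n1), function(i) {
    b <- best_of(ident_list[[i]])
    if (is.na(b)) NA_integer_ else cand_list[[i]][b]
  }, integer(1))
  # reverse best among the hap-1 genes that proposed each hap-2 gene
  rev_best <- rep(NA_integer_, n2)
  for (j in seq_len(n2)) {
    props <- which(fwd == j | vapply(cand_list, function(cc)
      j %in% cc, logical(1)))
    if (length(props) == 0L) next
    ident <- vapply(props, function(i)
      ident_list[[i]][match(j, cand_list[[i]])], numeric(1))
    b <- best_of(ident)
    if (!is.na(b)) rev_best[j] <- props[b]
  }
  keep <- which(!is.na(fwd) & rev_best[fwd] == seq_len(n1))
  pairs <- data.frame(
    gene_id_h1 = genes_h1$gene_id[keep],
    gene_id_h2 = genes_h2$gene_id[fwd[keep]],
    cds_identity = vapply(keep, function(i)
      ident_list[[i]][match(fwd[i], cand_list[[i]])], numeric(1)),
    syntenic = syn_flag[keep],
    stringsAsFactors = FALSE)
  pairs$identical <- genes_h1$cds_seq[keep] == genes_h2$cds_seq[fwd[keep]]
  stopifnot(all(!pairs$identical | pairs$cds_identity == 1))
  class(pairs) <- c("homolog_pairs", "data.frame")
  pairs
}

#' Keep only identical homolog pairs
#'
#' The identical pairs (byte-equal CDS) are the universe for the
#' inter-haplotype differential-expression test; pairs never flagged DE
#' there form the non-DE control set for the promoter-burden comparison.
#'
#' @param pairs output of [pair_homologs()].
#' @return the subset with `identical == TRUE`.
#' @export
filter_identical <- function(pairs) {
  out <- pairs[pairs$identical, , drop = FALSE]
  rownames(out) <- NULL
  out
}
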