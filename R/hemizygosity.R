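## Hemizygous (haplotype-specific) gene detection and categorization.

#' Call hemizygous genes
#'
#' A gene is homozygous iff some gene on the other haplotype lies within
#' the syntenic projection of its locus and has global CDS identity at or
#' above `cds_identity_threshold`; otherwise it is hemizygous. The search
#' is restricted to the projected window (no genome-wide best hit), so
#' paralogs elsewhere cannot rescue a truly hemizygous gene.
#'
#' @param genes_h1,genes_h2 `gene_models` for the two haplotypes (with CDS
#'   sequences populated).
#' @param region_calls the `region_calls` partition of the two haplotypes
#'   (hap-1 as reference).
#' @param cds_identity_threshold minimum CDS identity for homozygosity.
#' @param search_window bp added on each side of the projected locus when
#'   collecting candidate partners.
#' @return a data frame with one row per gene on both haplotypes:
#'   `gene_id`, `haplotype`, `status` (`homozygous`/`hemizygous`),
#'   `category` (`NA` until [categorize_hemizygous()]),
#'   `overlap_fraction`, `partner_id`, `partner_identity`.
#' @export
call_hemizygous <- function(genes_h1, genes_h2, region_calls,
                            cds_identity_threshold = 0.9,
                            search_window = 5000L) {
  proj12 <- make_projection(region_calls, "ref")
  proj21 <- make_projection(region_calls, "qry")
  one_side <- function(genes, others, proj) {
    if (nrow(genes) > 0 && !all(genes$chrom %in% unique(
      c(region_calls$ref_chrom, region_calls$qry_chrom, genes$chrom))))
      stop("gene on unknown chromosome")
    out <- data.frame(gene_id = genes$gene_id,
                      haplotype = genes$haplotype,
                      status = "hemizygous",
                      category = NA_character_,
                      overlap_fraction = NA_real_,
                      partner_id = NA_character_,
                      partner_identity = NA_real_,
                      stringsAsFactors = FALSE)
    if (nrow(genes) == 0L) return(out)
    och <- others$chrom; os <- others$start; oe <- others$end
    for (i in seq_len(nrow(genes))) {
      p1 <- proj(genes$chrom[i], genes$start[i])
      p2 <- proj(genes$chrom[i], genes$end[i])
      if (is.na(p1$chrom)) next
      lo <- min(p1$pos, p2$pos) - search_window
      hi <- max(p1$pos, p2$pos) + search_window
      cand <- which(och == p1$chrom & os < hi & oe > lo)
      if (length(cand) == 0L) next
      ident <- vapply(cand, function(j)
        cds_identity(genes$cds_seq[i], others$cds_seq[j]), numeric(1))
      best <- which.max(ident)
      out$partner_id[i] <- others$gene_id[cand[best]]
      out$partner_identity[i] <- ident[best]
      if (!is.na(ident[best]) && ident[best] >= cds_identity_threshold)
        out$status[i] <- "homozygous"
    }
    out
  }
  rbind(one_side(genes_h1, genes_h2, proj12),
        one_side(genes_h2, genes_h1, proj21))
}

# Per-haplotype views of the region classes hemizygous genes live in.
# "Insertion" means sequence present in that haplotype and absent from the
# other: the reference side of DEL calls for hap-1, the query side of INS
# calls for hap-2.
hemizygosity_region_views <- function(calls, haplotype) {
  side <- function(types, use_ref) {
    x <- calls[calls$type %in% types, , drop = FALSE]
    if (use_ref)
      data.frame(chrom = x$ref_chrom, start = x$ref_start,
                 end = x$ref_end, stringsAsFactors = FALSE)
    else
      data.frame(chrom = x$qry_chrom, start = x$qry_start,
                 end = x$qry_end, stringsAsFactors = FALSE)
  }
  use_ref <- haplotype == "hap1"
  v <- list(
    insertion = side(if (use_ref) "DEL" else "INS", use_ref),
    HDR = side("HDR", use_ref),
    unique = side("NOTAL", use_ref))
  lapply(v, function(d) d[!is.na(d$chrom) & d$end > d$start, , drop = FALSE])
}

#' Categorize hemizygous genes by hosting region class
#'
#' Each hemizygous gene is assigned the region class -- insertion (in its
#' own haplotype), HDR, or haplotype-unique -- with which its span overlaps
#' most, provided that the overlap fraction reaches `min_overlap`; ties
#' resolve in the priority order insertion > HDR > unique. Genes
#' overlapping no qualifying region are `unassigned`.
#'
#' @param records output of [call_hemizygous()].
#' @param genes_h1,genes_h2 the gene models (for spans).
#' @param region_calls the region partition.
#' @param min_overlap minimum qualifying overlap fraction.
#' @return `records` with `category` and `overlap_fraction` filled in for
#'   hemizygous genes.
#' @export
categorize_hemizygous <- function(records, genes_h1, genes_h2,
                                  region_calls, min_overlap = 0.5) {
  genes <- rbind(genes_h1[c("gene_id", "haplotype", "chrom", "start", "end")],
                 genes_h2[c("gene_id", "haplotype", "chrom", "start", "end")])
  gidx <- match(records$gene_id, genes$gene_id)
  views <- list(hap1 = hemizygosity_region_views(region_calls, "hap1"),
                hap2 = hemizygosity_region_views(region_calls, "hap2"))
  ov_fraction <- function(chrom, s, e, regions) {
    idx <- regions$chrom == chrom & regions$start < e & regions$end > s
    if (!any(idx)) return(0)
    sum(pmin(regions$end[idx], e) - pmax(regions$start[idx], s)) / (e - s)
  }
  cats <- c("insertion", "HDR", "unique")
  for (i in which(records$status == "hemizygous")) {
    g <- gidx[i]
    v <- views[[records$haplotype[i]]]
    fr <- vapply(cats, function(cl)
      ov_fraction(genes$chrom[g], genes$start[g], genes$end[g], v[[cl]]),
      numeric(1))
    best <- which(fr == max(fr))[1]  # vector order encodes tie priority
    if (fr[best] >= min_overlap) {
      records$category[i] <- cats[best]
      records$overlap_fraction[i] <- fr[best]
    } else {
      records$category[i] <- "unassigned"
      records$overlap_fraction[i] <- fr[best]
    }
  }
  records
}

#' Summarize hemizygous gene categories
#'
#' Per haplotype: total gene count, hemizygous count, hemizygous
#' percentage of all genes (rounded to the nearest integer), and
#' per-category counts with percentages of the hemizygous total (rounded
#' to one decimal).
#'
#' @param records categorized hemizygosity records.
#' @return a data frame with one row per haplotype x category plus one
#'   `all` row per haplotype; empty input gives an empty summary.
#' @export
summarize_categories <- function(records) {
  out <- list()
  for (h in unique(records$haplotype)) {
    r <- records[records$haplotype == h, , drop = FALSE]
    total <- nrow(r)
    hemi <- sum(r$status == "hemizygous")
    out[[length(out) + 1L]] <- data.frame(
      haplotype = h, category = "all", count = hemi,
      percent = if (total > 0) round(100 * hemi / total) else 0,
      stringsAsFactors = FALSE)
    for (cl in c("insertion", "HDR", "unique", "unassigned")) {
      n <- sum(r$status == "hemizygous" & !is.na(r$category) &
                 r$category == cl)
      out[[length(out) + 1L]] <- data.frame(
        haplotype = h, category = cl, count = n,
        percent = if (hemi > 0) round(100 * n / hemi, 1) else 0,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(haplotype = character(), category = character(),
                      count = integer(), percent = numeric()))
  do.call(rbind, out)
}
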