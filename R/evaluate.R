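## Evaluation of a region-call set against the simulator's planted truth.

#' Structural-variant recovery against planted truth
#'
#' A planted SV is recovered when a call of the same type has both
#' breakpoints within `tol` bp of the truth breakpoints, on the interval
#' of the haplotype that carries the event (reference side for DEL, INV
#' and TRANS; query side for INS).
#'
#' @param calls `region_calls` produced by [classify_regions()].
#' @param truth_regions the simulator's truth `region_calls`.
#' @param tol breakpoint tolerance in bp (defaults to the anchor k).
#' @param min_len only truth events of at least this length are scored.
#' @param types truth event types scored.
#' @return a data frame with one row per scored truth event
#'   (`type`, `length`, `recovered`) plus a `rate` attribute.
#' @export
sv_recovery <- function(calls, truth_regions, tol = 31L, min_len = 0L,
                        types = c("INS", "DEL", "INV", "TRANS")) {
  side <- function(df, type) {
    if (type == "INS")
      data.frame(chrom = df$qry_chrom, start = df$qry_start,
                 end = df$qry_end, stringsAsFactors = FALSE)
    else
      data.frame(chrom = df$ref_chrom, start = df$ref_start,
                 end = df$ref_end, stringsAsFactors = FALSE)
  }
  rows <- list()
  for (ty in types) {
    tr <- side(truth_regions[truth_regions$type == ty, , drop = FALSE], ty)
    cl <- side(calls[calls$type == ty, , drop = FALSE], ty)
    len <- tr$end - tr$start
    keep <- len >= min_len
    tr <- tr[keep, , drop = FALSE]; len <- len[keep]
    if (nrow(tr) == 0L) next
    rec <- vapply(seq_len(nrow(tr)), function(i)
      any(cl$chrom == tr$chrom[i] &
            abs(cl$start - tr$start[i]) <= tol &
            abs(cl$end - tr$end[i]) <= tol), logical(1))
    rows[[ty]] <- data.frame(type = ty, length = len, recovered = rec,
                             stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(type = character(), length = integer(),
               recovered = logical())
  rownames(out) <- NULL
  attr(out, "rate") <- if (nrow(out)) mean(out$recovered) else NA_real_
  out
}

#' SNP recall and false positives against planted truth
#'
#' A truth SNP is recalled when a called SNP sits at the same reference
#' position with the same two alleles; any called SNP without a truth
#' counterpart is a false positive.
#'
#' @param calls,truth_regions as in [sv_recovery()].
#' @return a list with `recall`, `n_truth`, `n_called`,
#'   `false_positives` (all unmatched calls) and
#'   `false_positives_clean` (unmatched calls outside truth HDR and
#'   unique regions, i.e. on identical flanks, where a false SNP would
#'   be a genuine artefact rather than diverged-interior ambiguity).
#' @export
snp_recall <- function(calls, truth_regions) {
  key <- function(df) {
    s <- df[df$type == "SNP", , drop = FALSE]
    paste(s$ref_chrom, s$ref_start, s$ref_base, s$qry_base)
  }
  tk <- key(truth_regions); ck <- key(calls)
  snps <- calls[calls$type == "SNP", , drop = FALSE]
  fp <- !ck %in% tk
  div <- truth_regions[truth_regions$type %in% c("HDR", "NOTAL") &
                         !is.na(truth_regions$ref_chrom), , drop = FALSE]
  in_div <- vapply(seq_len(nrow(snps)), function(i)
    any(div$ref_chrom == snps$ref_chrom[i] &
          div$ref_start <= snps$ref_start[i] &
          div$ref_end > snps$ref_start[i]), logical(1))
  list(recall = if (length(tk)) mean(tk %in% ck) else NA_real_,
       n_truth = length(tk), n_called = length(ck),
       false_positives = sum(fp),
       false_positives_clean = sum(fp & !in_div))
}

#' Hemizygosity detection performance against planted truth
#'
#' @param records categorized records from [categorize_hemizygous()].
#' @param truth the simulator's hemizygosity truth table.
#' @return a list with `precision`, `recall`, `category_accuracy`
#'   (fraction of true hemizygous genes assigned their true category),
#'   and the category confusion table.
#' @export
hemizygosity_performance <- function(records, truth) {
  m <- merge(records, truth, by = "gene_id", suffixes = c("", ".truth"))
  tp <- sum(m$status == "hemizygous" & m$status.truth == "hemizygous")
  fp <- sum(m$status == "hemizygous" & m$status.truth == "homozygous")
  fn <- sum(m$status == "homozygous" & m$status.truth == "hemizygous")
  both <- m[m$status == "hemizygous" & m$status.truth == "hemizygous", ]
  list(precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       category_accuracy = if (nrow(both) > 0)
         mean(both$category == both$category.truth) else NA_real_,
       confusion = table(called = both$category,
                         truth = both$category.truth))
}
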