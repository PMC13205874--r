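## TPM computation, hemizygous-vs-homozygous expression comparison, and
## inter-haplotype differential expression over identical homolog pairs.

#' Compute transcripts per million
#'
#' Per sample, each gene's count is divided by its effective length in kb
#' and the rates are scaled so the column sums to one million. All-zero
#' samples yield all-zero columns and are flagged in the `zero_columns`
#' attribute rather than producing NaN.
#'
#' @param mat an [expression_matrix()].
#' @return a numeric matrix of TPM values (genes x samples) with
#'   attributes `tissue`, `replicate` and `zero_columns`.
#' @export
compute_tpm <- function(mat) {
  stopifnot(inherits(mat, "expression_matrix"))
  if (any(mat$lengths <= 0)) stop("zero-length gene: ",
                                  names(mat$lengths)[mat$lengths <= 0][1])
  rate <- mat$counts / (mat$lengths / 1000)
  cs <- colSums(rate)
  zero <- cs == 0
  cs[zero] <- 1
  tpm <- sweep(rate, 2, cs, "/") * 1e6
  attr(tpm, "tissue") <- mat$tissue
  attr(tpm, "replicate") <- mat$replicate
  attr(tpm, "zero_columns") <- unname(which(zero))
  tpm
}

#' Compare hemizygous vs homozygous expression
#'
#' For each tissue, genes are summarized by their mean TPM across that
#' tissue's replicates; the hemizygous and homozygous groups are compared
#' on log2(TPM + 1) with a rank-based two-sample (Wilcoxon) test. Groups
#' with fewer than two genes skip the test with a notice.
#'
#' @param tpm TPM matrix from [compute_tpm()] for one haplotype.
#' @param records hemizygosity records ([call_hemizygous()]) -- only rows
#'   for genes present in `tpm` are used.
#' @param tissues tissues to compare (default: all in the matrix).
#' @return a data frame with per-tissue group medians, quartiles, p-value,
#'   and `direction` (`hemizygous higher` / `homozygous higher` / `none`).
#' @export
compare_hemi_vs_homo <- function(tpm, records,
                                 tissues = unique(attr(tpm, "tissue"))) {
  tis <- attr(tpm, "tissue")
  st <- records$status[match(rownames(tpm), records$gene_id)]
  out <- list()
  for (tt in tissues) {
    mu <- rowMeans(tpm[, tis == tt, drop = FALSE])
    x <- log2(mu[which(st == "hemizygous")] + 1)
    y <- log2(mu[which(st == "homozygous")] + 1)
    p <- NA_real_; note <- ""
    if (length(x) >= 2L && length(y) >= 2L) {
      p <- suppressWarnings(stats::wilcox.test(x, y)$p.value)
    } else note <- "test skipped: group with < 2 genes"
    md <- stats::median(x) - stats::median(y)
    out[[tt]] <- data.frame(
      tissue = tt,
      n_hemizygous = length(x), n_homozygous = length(y),
      median_hemi = stats::median(x), median_homo = stats::median(y),
      q1_hemi = unname(stats::quantile(x, 0.25, na.rm = TRUE)),
      q3_hemi = unname(stats::quantile(x, 0.75, na.rm = TRUE)),
      q1_homo = unname(stats::quantile(y, 0.25, na.rm = TRUE)),
      q3_homo = unname(stats::quantile(y, 0.75, na.rm = TRUE)),
      p_value = p,
      direction = if (is.na(md) || md == 0) "none"
      else if (md > 0) "hemizygous higher" else "homozygous higher",
      note = note, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# Welch two-sample t-test p-value with explicit handling of the
# zero-variance degeneracy (discrete counts can tie exactly).
welch_p <- function(x, y) {
  if (stats::var(x) == 0 && stats::var(y) == 0)
    return(if (mean(x) == mean(y)) 1 else 0)
  stats::t.test(x, y)$p.value
}

#' Inter-haplotype differential expression over identical pairs
#'
#' For each identical homolog pair and tissue, log2(TPM + 1) of the two
#' haplotypes' replicates is compared with a moderated two-sample t-test
#' (limma's `lmFit`/`eBayes`, fitted per tissue across all pairs):
#' with typical replicate numbers of two or three, per-pair variance
#' estimates are unstable, and limma's empirical-Bayes pooling across
#' pairs is the standard remedy in expression analysis.
#' Benjamini-Hochberg correction is applied across the entire
#' pair x tissue family jointly, and a pair is flagged DE iff any tissue
#' reaches `q < alpha`. Since the paired coding sequences are
#' byte-identical, any reproducible difference is attributable to
#' regulation, not to the transcripts themselves. With fewer than three
#' pairs there is nothing to pool, and a plain Welch test is used
#' instead.
#'
#' @param tpm_h1,tpm_h2 TPM matrices from [compute_tpm()].
#' @param pairs identical pairs from [filter_identical()].
#' @param alpha FDR threshold for the DE flag.
#' @return a data frame with one row per pair x tissue: `log2fc`
#'   (hap-1 over hap-2), `p_value`, `q_value`, and the pair-level
#'   `de_flag` repeated on each row.
#' @export
de_between_haplotypes <- function(tpm_h1, tpm_h2, pairs, alpha = 0.05) {
  t1 <- attr(tpm_h1, "tissue"); t2 <- attr(tpm_h2, "tissue")
  missing1 <- setdiff(pairs$gene_id_h1, rownames(tpm_h1))
  missing2 <- setdiff(pairs$gene_id_h2, rownames(tpm_h2))
  if (length(missing1) || length(missing2))
    stop("pair gene missing from expression matrix: ",
         c(missing1, missing2)[1])
  tissues <- intersect(unique(t1), unique(t2))
  rows <- list()
  for (tt in tissues) {
    x <- log2(tpm_h1[pairs$gene_id_h1, t1 == tt, drop = FALSE] + 1)
    y <- log2(tpm_h2[pairs$gene_id_h2, t2 == tt, drop = FALSE] + 1)
    lfc <- rowMeans(x) - rowMeans(y)
    if (nrow(pairs) >= 3L) {
      mat <- cbind(x, y)
      design <- cbind(Intercept = 1,
                      hap2 = rep(c(0, 1), c(ncol(x), ncol(y))))
      fit <- limma::eBayes(limma::lmFit(mat, design))
      pv <- fit$p.value[, "hap2"]
    } else {
      pv <- vapply(seq_len(nrow(pairs)), function(i)
        welch_p(x[i, ], y[i, ]), numeric(1))
    }
    rows[[tt]] <- data.frame(
      gene_id_h1 = pairs$gene_id_h1, gene_id_h2 = pairs$gene_id_h2,
      tissue = tt, log2fc = unname(lfc), p_value = unname(pv),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  flag <- tapply(res$q_value < alpha, res$gene_id_h1, any)
  res$de_flag <- as.logical(flag[res$gene_id_h1])
  res
}

#' Pair-level DE summary
#' @param res output of [de_between_haplotypes()].
#' @return one row per pair with `de_flag` and the minimum q-value.
#' @export
de_pair_summary <- function(res) {
  out <- do.call(rbind, lapply(split(res, res$gene_id_h1), function(d)
    data.frame(gene_id_h1 = d$gene_id_h1[1], gene_id_h2 = d$gene_id_h2[1],
               min_q = min(d$q_value), de_flag = d$de_flag[1],
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}
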