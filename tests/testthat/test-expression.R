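em_of <- function(counts, lengths, tissue = rep("leaf", ncol(counts)),
                  replicate = seq_len(ncol(counts))) {
  expression_matrix(counts, tissue, replicate, lengths, "hap1")
}

test_that("TPM normalization: single gene, hand arithmetic, zeros", {
  one <- em_of(matrix(7L, 1, 1, dimnames = list("g1", NULL)),
               c(g1 = 500))
  expect_equal(as.numeric(compute_tpm(one)), 1e6)

  two <- em_of(matrix(c(10L, 10L), 2, 1,
                      dimnames = list(c("a", "b"), NULL)),
               c(a = 1000, b = 2000))
  tpm <- compute_tpm(two)
  expect_equal(as.numeric(tpm), c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)

  z <- em_of(matrix(c(5L, 3L, 0L, 0L), 2, 2,
                    dimnames = list(c("a", "b"), NULL)),
             c(a = 1000, b = 2000))
  tz <- compute_tpm(z)
  expect_equal(unname(tz[, 2]), c(0, 0))
  expect_equal(attr(tz, "zero_columns"), 2L)
  expect_error(compute_tpm(em_of(matrix(1L, 1, 1,
                                        dimnames = list("g", NULL)),
                                 c(g = 0))), "zero-length")
})

test_that("TPM columns sum to one million", {
  sim <- small_sim()
  for (tpm in list(compute_tpm(sim$expr_h1), compute_tpm(sim$expr_h2)))
    expect_true(all(abs(colSums(tpm) - 1e6) < 1e-6 * 1e6))
})

test_that("hemizygous-vs-homozygous comparison reports direction", {
  sim <- small_sim()
  rec <- sim$truth$hemizygosity[sim$truth$hemizygosity$haplotype == "hap1", ]
  names(rec)[names(rec) == "status"] <- "status"
  tpm <- compute_tpm(sim$expr_h1)
  rep_ <- compare_hemi_vs_homo(tpm, rec)
  # simulator boosts hemizygous means 2x: direction holds in all tissues
  expect_true(all(rep_$direction == "hemizygous higher"))
  expect_true(all(rep_$p_value < 0.05))
  # identical distributions: no direction
  fake <- rec
  tpm_const <- tpm; tpm_const[] <- 5
  attr(tpm_const, "tissue") <- attr(tpm, "tissue")
  rep0 <- compare_hemi_vs_homo(tpm_const, fake)
  expect_true(all(rep0$direction == "none"))
  # tiny group: test skipped with notice, no crash
  rec1 <- rec
  rec1$status[rec1$status == "hemizygous"][-1] <- "homozygous"
  rep1 <- compare_hemi_vs_homo(tpm, rec1)
  expect_true(all(grepl("skipped", rep1$note)))
  expect_true(all(is.na(rep1$p_value)))
})

test_that("DE over identical haplotype matrices finds nothing", {
  sim <- small_sim()
  tpm1 <- compute_tpm(sim$expr_h1)
  idp <- data.frame(
    gene_id_h1 = rownames(tpm1)[1:10], gene_id_h2 = rownames(tpm1)[1:10],
    identical = TRUE, stringsAsFactors = FALSE)
  res <- de_between_haplotypes(tpm1, tpm1, idp)
  expect_true(all(!res$de_flag))
  expect_true(all(res$log2fc == 0))
  # degenerate alpha
  res0 <- de_between_haplotypes(tpm1, tpm1,
                                data.frame(gene_id_h1 = rownames(tpm1)[1:2],
                                           gene_id_h2 = rownames(tpm1)[1:2]),
                                alpha = 0)
  expect_true(all(!res0$de_flag))
  expect_error(
    de_between_haplotypes(tpm1, tpm1,
                          data.frame(gene_id_h1 = "nope",
                                     gene_id_h2 = rownames(tpm1)[1])),
    "nope")
})

test_that("planted cis effects are recalled with no false positives", {
  run <- default_run(1)
  sim <- run$sim
  pairs <- pair_homologs(sim$genes_h1, sim$genes_h2, run$calls)
  idp <- filter_identical(pairs)
  res <- de_between_haplotypes(compute_tpm(sim$expr_h1),
                               compute_tpm(sim$expr_h2), idp)
  sm <- de_pair_summary(res)
  called <- sm$gene_id_h1[sm$de_flag]
  truth <- sim$truth$de$gene_id_h1
  expect_gte(sum(truth %in% called), 10)
  expect_lte(sum(!called %in% truth), 1)
  # BH q-values are monotone in p within the family
  o <- order(res$p_value)
  expect_true(all(diff(res$q_value[o]) >= -1e-12))
})

test_that("DE recall rises monotonically with the cis effect size", {
  folds <- c(1, 2, 4, 8)
  recall <- vapply(folds, function(f) {
    cfg <- small_config(seed = 17, cis_effect_fold = f)
    sim <- simulate_diploid(cfg)
    truth <- sim$truth$homolog_pairs
    idp <- truth[truth$identical, c("gene_id_h1", "gene_id_h2")]
    res <- de_between_haplotypes(compute_tpm(sim$expr_h1),
                                 compute_tpm(sim$expr_h2), idp)
    sm <- de_pair_summary(res)
    de_truth <- sim$truth$de$gene_id_h1
    if (length(de_truth) == 0) return(0)
    mean(de_truth %in% sm$gene_id_h1[sm$de_flag])
  }, numeric(1))
  expect_true(all(diff(recall) >= 0))
  expect_gt(recall[4], recall[1])
})
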