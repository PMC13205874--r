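test_that("promoter windows are strand-aware and clipped", {
  g <- haplotype_genome(c(chr1 = random_seq(6000, 3)), "hap1")
  genes <- toy_genes(g, c(4999L, 999L))   # 1-based starts 5000 and 1000
  pm <- extract_promoters(genes, g, window = 3000L)
  # plus-strand gene starting at 1-based 5000: promoter 2000..4999
  expect_equal(pm$start[1], 1999L)
  expect_equal(pm$end[1], 4999L)
  # gene starting at 1-based 1000: clipped to length 999
  expect_equal(pm$start[2], 0L)
  expect_equal(pm$end[2] - pm$start[2], 999L)
  # minus-strand gene ending at the chromosome end: empty, flagged
  gm <- toy_genes(g, 5400L, strand = "-")
  gm$end <- 6000L
  gm$cds[[1]] <- matrix(as.integer(c(5400, 5800, 5600, 6000)), 2)
  gm <- gene_models(as.data.frame(gm), g)
  pm2 <- extract_promoters(gm, g)
  expect_true(pm2$empty)
  expect_equal(pm2$end - pm2$start, 0L)
  # promoters never overlap their own gene body
  sim <- small_sim()
  pms <- extract_promoters(sim$genes_h1, sim$hap1)
  ov <- pms$start < sim$genes_h1$end & pms$end > sim$genes_h1$start
  expect_true(all(!ov))
})

test_that("variant counting: SNPs by position, SVs once per call", {
  calls <- region_calls(
    ref_chrom = c("c1", "c1", "c1", "c1", "c1"),
    ref_start = c(100L, 200L, 300L, 450L, 0L),
    ref_end   = c(101L, 201L, 301L, 450L, 5000L),
    qry_chrom = c("c1", "c1", "c1", "c1", "c1"),
    qry_start = c(100L, 200L, 300L, 400L, 0L),
    qry_end   = c(101L, 201L, 301L, 480L, 5000L),
    type = c("SNP", "SNP", "SNP", "INS", "SYN"),
    ref_base = c("A", "C", "G", NA, NA),
    qry_base = c("T", "T", "T", NA, NA))
  pm <- data.frame(gene_id = "g", haplotype = "hap1", chrom = "c1",
                   start = 0L, end = 1000L, strand = "+", empty = FALSE,
                   stringsAsFactors = FALSE)
  b <- count_promoter_variants(pm, calls)
  expect_equal(b$snp_count, 3L)   # 3 SNPs in window
  expect_equal(b$sv_count, 1L)    # 1 insertion breakpoint; SYN not counted
  expect_equal(b$total, 4L)

  # an SV spanning the whole promoter counts once, not per base
  big <- region_calls("c1", 0L, 5000L, "c1", 0L, 0L, "DEL")
  expect_equal(count_promoter_variants(pm, big)$sv_count, 1L)
  # empty window, and burden invariant under call shuffling
  none <- count_promoter_variants(
    data.frame(gene_id = "g", haplotype = "hap1", chrom = "c1",
               start = 600L, end = 900L, strand = "+", empty = FALSE),
    calls)
  expect_equal(none$total, 0L)
  set.seed(2)
  shuf <- calls[sample(nrow(calls)), ]
  expect_equal(count_promoter_variants(pm, shuf), b)
  expect_error(count_promoter_variants(
    data.frame(gene_id = "g", haplotype = "hap1", chrom = "nope",
               start = 0L, end = 10L, strand = "+", empty = FALSE), calls),
    "nope")
})

test_that("burden comparison reports direction and degenerate notices", {
  burdens <- data.frame(
    gene_id = c("a1", "a2", "b1", "b2", "c1", "c2", "d1", "d2"),
    haplotype = rep(c("hap1", "hap2"), 4),
    snp_count = 0L, sv_count = 0L,
    total = c(9L, 7L, 8L, 8L, 1L, 2L, 2L, 1L), stringsAsFactors = FALSE)
  de <- data.frame(gene_id_h1 = c("a1", "b1"), gene_id_h2 = c("a2", "b2"))
  nd <- data.frame(gene_id_h1 = c("c1", "d1"), gene_id_h2 = c("c2", "d2"))
  r <- compare_de_burden(burdens, de, nd)
  expect_equal(r$de_burdens, c(9, 8))    # pair burden = max of the two sides
  expect_equal(r$nonde_burdens, c(2, 2))
  expect_equal(r$direction, "DE higher")
  # equal burdens in both groups
  r0 <- compare_de_burden(burdens, nd, nd)
  expect_equal(r0$direction, "none")
  # single DE pair: medians still reported, test skipped
  r1 <- compare_de_burden(burdens, de[1, ], nd)
  expect_true(grepl("skipped", r1$note))
  expect_true(is.na(r1$p_value))
  expect_equal(r1$median_de, 9)
})

test_that("planted promoter variants separate DE from non-DE pairs", {
  run <- default_run(1)
  sim <- run$sim
  pm <- rbind(extract_promoters(sim$genes_h1, sim$hap1),
              extract_promoters(sim$genes_h2, sim$hap2))
  burden <- count_promoter_variants(pm, run$calls)
  truth <- sim$truth$homolog_pairs
  de <- sim$truth$de[, c("gene_id_h1", "gene_id_h2")]
  nd <- truth[truth$identical & !truth$gene_id_h1 %in% de$gene_id_h1,
              c("gene_id_h1", "gene_id_h2")]
  r <- compare_de_burden(burden, de, nd)
  expect_equal(r$direction, "DE higher")
  expect_lt(r$p_value, 0.05)
  # called burdens track the planted truth counts
  tr <- sim$truth$promoter_variants
  m <- merge(burden, tr, by = c("gene_id", "haplotype"))
  expect_gt(stats::cor(m$total.x, m$total.y), 0.95)
})
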