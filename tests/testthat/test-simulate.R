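no_edit_config <- function(seed = 3) {
  simulation_config(seed = seed, chromosome_length = 60000L,
                    snp_rate = 0, n_insertions = 0L, n_deletions = 0L,
                    n_inversions = 0L, n_translocations = 0L, n_hdrs = 0L,
                    n_unique_segments = 0L, genes_per_chromosome = 10L,
                    hemizygous_fraction = 0, n_identical_pairs = 5L,
                    n_de_pairs = 0L, n_map_markers = 5L)
}

test_that("a config with no events yields identical haplotypes", {
  sim <- simulate_diploid(no_edit_config())
  expect_identical(as.character(sim$hap1$seqs),
                   as.character(sim$hap2$seqs))
  expect_identical(sim$genes_h1$cds_seq, sim$genes_h2$cds_seq)
})

test_that("simulation is byte-deterministic under a fixed seed", {
  a <- simulate_diploid(small_config())
  b <- simulate_diploid(small_config())
  expect_identical(as.character(a$hap1$seqs), as.character(b$hap1$seqs))
  expect_identical(as.character(a$hap2$seqs), as.character(b$hap2$seqs))
  expect_identical(a$expr_h1$counts, b$expr_h1$counts)
  expect_identical(a$truth$edit_script, b$truth$edit_script)
  expect_identical(a$markers, b$markers)
})

test_that("length bookkeeping: one 100-bp insertion shifts hap-2 by 100", {
  cfg <- simulation_config(
    seed = 5, chromosome_length = 60000L, snp_rate = 0,
    n_insertions = 1L, n_deletions = 0L, indel_len_range = c(100L, 100L),
    n_inversions = 0L, n_translocations = 0L, n_hdrs = 0L,
    n_unique_segments = 0L, genes_per_chromosome = 5L,
    hemizygous_fraction = 0, n_identical_pairs = 3L, n_de_pairs = 0L,
    n_map_markers = 5L)
  sim <- simulate_diploid(cfg)
  expect_equal(sum(chrom_lengths(sim$hap2)) - sum(chrom_lengths(sim$hap1)),
               100L)
})

test_that("apply_edit_script: identity, SNP, inversion oracle", {
  g <- haplotype_genome(c(chr1 = random_seq(5000, 11)), "hap1")
  empty <- data.frame(type = character(), chrom = character(),
                      start = integer(), end = integer(), seq = character(),
                      ref = character(), alt = character(),
                      dst_chrom = character(), dst_pos = integer(),
                      stringsAsFactors = FALSE)
  expect_identical(as.character(apply_edit_script(g, empty)$seqs),
                   as.character(g$seqs))

  refb <- substr(as.character(g$seqs[["chr1"]]), 101, 101)
  altb <- setdiff(c("A", "C", "G", "T"), refb)[1]
  snp <- data.frame(type = "snp", chrom = "chr1", start = 100L, end = 101L,
                    seq = NA, ref = refb, alt = altb, dst_chrom = NA,
                    dst_pos = NA, stringsAsFactors = FALSE)
  out <- apply_edit_script(g, snp)
  d <- which(charToRaw(as.character(out$seqs[[1]])) !=
               charToRaw(as.character(g$seqs[[1]])))
  expect_equal(d, 101L)  # exactly one mismatching position
  # wrong ref base is rejected
  snp$ref <- altb
  expect_error(apply_edit_script(g, snp), "mismatch")

  inv <- data.frame(type = "inv", chrom = "chr1", start = 1000L,
                    end = 2000L, seq = NA, ref = NA, alt = NA,
                    dst_chrom = NA, dst_pos = NA, stringsAsFactors = FALSE)
  out <- apply_edit_script(g, inv)
  seg <- substr(as.character(out$seqs[[1]]), 1001, 2000)
  expect_equal(seg,
               revcomp_str(substr(as.character(g$seqs[[1]]), 1001, 2000)))
})

test_that("edit-script consistency and truth-partition invariants hold", {
  sim <- small_sim()
  # applying the script to hap-1 reproduces hap-2 byte-for-byte
  re2 <- apply_edit_script(sim$hap1, sim$truth$edit_script)
  expect_identical(as.character(re2$seqs), as.character(sim$hap2$seqs))
  # truth regions cover each haplotype's non-telomeric length exactly once
  tel <- nchar(strrep("TTTAGGG", sim$truth$config$telomere_array_copies))
  check_side <- function(genome, chrom, start, end) {
    for (cid in names(genome$seqs)) {
      idx <- !is.na(chrom) & chrom == cid & end > start
      ir <- IRanges::IRanges(start[idx] + 1L, end[idx])
      cov <- IRanges::coverage(ir, width = length(genome$seqs[[cid]]))
      v <- as.integer(cov)
      L <- length(v)
      expect_true(all(v[(tel + 1):(L - tel)] == 1L))
      expect_true(all(v[c(seq_len(tel), (L - tel + 1):L)] == 0L))
    }
  }
  tr <- sim$truth$regions
  check_side(sim$hap1, tr$ref_chrom, tr$ref_start, tr$ref_end)
  check_side(sim$hap2, tr$qry_chrom, tr$qry_start, tr$qry_end)
  # every planted hemizygous gene lies wholly inside its truth region class
  hem <- sim$truth$hemizygosity
  hem <- hem[hem$status == "hemizygous", ]
  genes <- rbind(sim$genes_h1[c("gene_id", "chrom", "start", "end")],
                 sim$genes_h2[c("gene_id", "chrom", "start", "end")])
  expect_true(all(hem$gene_id %in% genes$gene_id))
})

test_that("simulated counts match configured means (stochastic 5%)", {
  cfg <- simulation_config(
    seed = 13, chromosome_length = 80000L, genes_per_chromosome = 8L,
    n_insertions = 4L, n_deletions = 4L, n_inversions = 0L,
    n_translocations = 0L, n_hdrs = 1L, n_unique_segments = 1L,
    n_identical_pairs = 6L, n_de_pairs = 2L,
    replicates_per_tissue = 50L, n_map_markers = 5L)
  sim <- simulate_diploid(cfg)
  means <- sim$truth$expression_means$h1
  tis <- sim$expr_h1$tissue
  # 200 replicate draws per gene across the four tissues
  rel_err <- vapply(rownames(means), function(g) {
    obs <- vapply(colnames(means), function(tt)
      mean(sim$expr_h1$counts[g, tis == tt]), numeric(1))
    mean(abs(obs - means[g, ]) / means[g, ])
  }, numeric(1))
  expect_lt(median(rel_err), 0.05)
  expect_gt(mean(rel_err < 0.10), 0.9)
})

test_that("infeasible packing is reported as a configuration error", {
  cfg <- simulation_config(seed = 1, chromosome_length = 40000L,
                           n_hdrs = 30L, hdr_len_range = c(15000L, 20000L))
  expect_error(simulate_diploid(cfg), "infeasible packing")
})
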