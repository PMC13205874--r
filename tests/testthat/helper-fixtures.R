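# Shared fixtures. Heavy simulated datasets are memoized so that several
# test files can share one default-scale run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

revcomp_str <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a compact configuration for module-level tests
small_config <- function(seed = 7, ...) {
  simulation_config(
    seed = seed, chromosome_length = 150000L,
    n_insertions = 12L, n_deletions = 12L,
    indel_len_range = c(50L, 2500L),
    n_inversions = 1L, inversion_len_range = c(5000L, 12000L),
    n_translocations = 1L, translocation_len_range = c(5000L, 8000L),
    n_hdrs = 3L, hdr_len_range = c(2000L, 8000L),
    n_unique_segments = 1L, unique_len_range = c(3000L, 6000L),
    genes_per_chromosome = 40L, n_identical_pairs = 24L, n_de_pairs = 6L,
    n_map_markers = 12L, ...)
}

small_sim <- function() memo("small_sim", simulate_diploid(small_config()))

small_calls <- function() memo("small_calls", {
  sim <- small_sim()
  classify_regions(chain_anchors(find_anchors(sim$hap1, sim$hap2)),
                   sim$hap1, sim$hap2)
})

# the default-scale study-condition run shared by the acceptance tests
default_run <- function(seed = 1) memo(paste0("default_run_", seed), {
  sim <- simulate_diploid(simulation_config(seed = seed))
  gc()
  calls <- classify_regions(chain_anchors(find_anchors(sim$hap1, sim$hap2)),
                            sim$hap1, sim$hap2)
  gc()
  list(sim = sim, calls = calls)
})

# two identical single-chromosome genomes with simple two-exon genes, for
# degenerate-case tests
toy_pair <- function(n = 20000, seed = 42) {
  s <- random_seq(n, seed)
  g1 <- haplotype_genome(c(chr1 = s), "hap1")
  g2 <- haplotype_genome(c(chr1 = s), "hap2")
  list(h1 = g1, h2 = g2)
}

toy_genes <- function(genome, starts, span = 600L, strand = "+") {
  hap <- genome$label
  df <- data.frame(
    gene_id = sprintf("%s_g%02d", hap, seq_along(starts)),
    haplotype = hap, chrom = "chr1", strand = strand,
    start = as.integer(starts), end = as.integer(starts + span),
    stringsAsFactors = FALSE)
  df$cds <- lapply(starts, function(s) {
    e1 <- 240L
    m <- cbind(c(s, s + e1 + 100L), c(s + e1, s + span))
    storage.mode(m) <- "integer"
    m
  })
  gene_models(df, genome)
}

# swap the two haplotype roles of a call set (INS <-> DEL, sides and
# alleles transposed); used for symmetry checks
swap_calls <- function(calls) {
  out <- calls
  out$ref_chrom <- calls$qry_chrom; out$ref_start <- calls$qry_start
  out$ref_end <- calls$qry_end
  out$qry_chrom <- calls$ref_chrom; out$qry_start <- calls$ref_start
  out$qry_end <- calls$ref_end
  out$ref_base <- calls$qry_base; out$qry_base <- calls$ref_base
  out$type[calls$type == "INS"] <- "DEL"
  out$type[calls$type == "DEL"] <- "INS"
  hapcompare:::validate_region_calls(as.data.frame(out))
}
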