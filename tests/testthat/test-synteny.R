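# Brute-force anchor oracle: enumerate every k-mer of both genomes in R,
# count canonically (k-mer and reverse complement identified), and keep
# those occurring exactly once in each genome.
brute_anchors <- function(ref, qry, k) {
  enumerate <- function(s) {
    n <- nchar(s)
    kmers <- substring(s, 1:(n - k + 1), k:n)
    rcs <- vapply(kmers, revcomp_str, character(1))
    canon <- ifelse(kmers <= rcs, kmers, rcs)
    data.frame(canon = canon, pos = 0:(n - k), fwd = kmers <= rcs,
               stringsAsFactors = FALSE)
  }
  a <- enumerate(ref); b <- enumerate(qry)
  ua <- a[a$canon %in% names(which(table(a$canon) == 1)), ]
  ub <- b[b$canon %in% names(which(table(b$canon) == 1)), ]
  m <- merge(ua, ub, by = "canon")
  data.frame(ref_start = m$pos.x, qry_start = m$pos.y,
             forward = m$fwd.x == m$fwd.y)
}

test_that("find_anchors equals the brute-force all-substring oracle", {
  s <- random_seq(200, 21)
  g1 <- haplotype_genome(c(chr1 = s), "hap1")
  g2 <- haplotype_genome(c(chr1 = s), "hap2")
  a <- find_anchors(g1, g2, 31)
  oracle <- brute_anchors(s, s, 31)
  expect_equal(nrow(a), 170L)
  expect_true(all(a$forward))
  expect_equal(sort(a$ref_start), sort(oracle$ref_start))
  expect_equal(a$ref_start, a$qry_start)

  # oracle equality on a diverged pair too
  s2 <- random_seq(200, 22)
  q <- paste0(substr(s, 1, 90), substr(s2, 1, 40), substr(s, 121, 200))
  g3 <- haplotype_genome(c(chr1 = q), "hap2")
  a2 <- find_anchors(g1, g3, 31)
  o2 <- brute_anchors(s, q, 31)
  expect_equal(a2[order(a2$ref_start), c("ref_start", "qry_start", "forward")],
               o2[order(o2$ref_start), ], ignore_attr = TRUE)
})

test_that("anchor orientation flips on a reverse-complemented genome", {
  s <- random_seq(300, 31)
  g1 <- haplotype_genome(c(chr1 = s), "hap1")
  g2 <- haplotype_genome(c(chr1 = revcomp_str(s)), "hap2")
  a <- find_anchors(g1, g2, 31)
  expect_equal(nrow(a), 270L)
  expect_true(all(!a$forward))
})

test_that("degenerate repeats yield no anchors; k is validated", {
  g1 <- haplotype_genome(c(chr1 = strrep("A", 200)), "hap1")
  g2 <- haplotype_genome(c(chr1 = strrep("A", 200)), "hap2")
  expect_equal(nrow(find_anchors(g1, g2, 31)), 0L)
  expect_error(find_anchors(g1, g2, 30), "odd")
  expect_error(find_anchors(g1, g2, 9), "odd|\\[11")
  # N-containing k-mers are never anchors
  s <- random_seq(100, 5)
  gN <- haplotype_genome(c(chr1 = paste0(substr(s, 1, 50), "N",
                                         substr(s, 52, 100))), "hap1")
  aN <- find_anchors(gN, haplotype_genome(c(chr1 = s), "hap2"), 31)
  expect_false(any(aN$ref_start > 50 - 31 & aN$ref_start < 51))
})

test_that("chaining: identity gives one chain, inversions break it", {
  s <- random_seq(30000, 33)
  g1 <- haplotype_genome(c(chr1 = s), "hap1")
  g2 <- haplotype_genome(c(chr1 = s), "hap2")
  cs <- chain_anchors(find_anchors(g1, g2))
  expect_equal(nrow(cs$chains), 1L)
  expect_equal(cs$chains$n_anchors, nrow(cs$anchors))

  inv <- paste0(substr(s, 1, 10000),
                revcomp_str(substr(s, 10001, 20000)),
                substr(s, 20001, 30000))
  g3 <- haplotype_genome(c(chr1 = inv), "hap2")
  cs2 <- chain_anchors(find_anchors(g1, g3))
  expect_gte(nrow(cs2$chains), 3L)
  expect_equal(cs2$chains$forward[order(cs2$chains$ref_start)][1:3],
               c(TRUE, FALSE, TRUE))

  # anchors alternating between chromosomes chain to singletons: discarded
  fake <- data.frame(
    ref_chrom = "chr1", ref_start = seq(0, 900, by = 100),
    qry_chrom = rep(c("chrA", "chrB"), 5),
    qry_start = seq(0, 900, by = 100), forward = TRUE,
    stringsAsFactors = FALSE)
  attr(fake, "k") <- 31L
  expect_equal(nrow(chain_anchors(fake)$chains), 0L)
})

test_that("identical genomes classify as one SYN block and no SNPs", {
  s <- random_seq(40000, 44)
  g1 <- haplotype_genome(c(chr1 = s), "hap1")
  g2 <- haplotype_genome(c(chr1 = s), "hap2")
  calls <- classify_regions(chain_anchors(find_anchors(g1, g2)), g1, g2)
  expect_equal(sum(calls$type == "SNP"), 0L)
  expect_equal(sum(calls$type == "SYN"), 1L)
  expect_true(region_partition_check(calls, g1, g2)$ok)
})

test_that("a single substituted base is called as exactly one SNP", {
  s <- random_seq(40000, 45)
  pos <- 20000L  # 0-based
  refb <- substr(s, pos + 1, pos + 1)
  altb <- setdiff(c("A", "C", "G", "T"), refb)[1]
  q <- paste0(substr(s, 1, pos), altb, substr(s, pos + 2, nchar(s)))
  g1 <- haplotype_genome(c(chr1 = s), "hap1")
  g2 <- haplotype_genome(c(chr1 = q), "hap2")
  calls <- classify_regions(chain_anchors(find_anchors(g1, g2)), g1, g2)
  snp <- calls[calls$type == "SNP", ]
  expect_equal(nrow(snp), 1L)
  expect_equal(snp$ref_start, pos)
  expect_equal(snp$ref_base, refb)
  expect_equal(snp$qry_base, altb)
  expect_true(region_partition_check(calls, g1, g2)$ok)
})

test_that("swapping haplotype roles exchanges INS and DEL, keeps SNPs", {
  sim <- small_sim()
  fwd <- small_calls()
  rev <- classify_regions(
    chain_anchors(find_anchors(sim$hap2, sim$hap1)), sim$hap2, sim$hap1)
  expect_equal(sum(rev$type == "SNP"), sum(fwd$type == "SNP"))
  expect_equal(sum(rev$type == "INS"), sum(fwd$type == "DEL"))
  expect_equal(sum(rev$type == "DEL"), sum(fwd$type == "INS"))
  expect_equal(sum(rev$type == "INV"), sum(fwd$type == "INV"))
})

test_that("partition check flags removed and duplicated calls", {
  sim <- small_sim()
  calls <- small_calls()
  expect_true(region_partition_check(calls, sim$hap1, sim$hap2)$ok)
  # drop one sizeable two-sided call: its interval becomes uncovered
  drop <- which(calls$type == "SYN" &
                  calls$ref_end - calls$ref_start > 100)[1]
  broken <- calls[-drop, ]
  chk <- region_partition_check(broken, sim$hap1, sim$hap2)
  expect_false(chk$ok)
  expect_true(any(chk$ref_uncovered$start <= calls$ref_start[drop] &
                    chk$ref_uncovered$end >= calls$ref_start[drop] + 1))
  # duplicate a call: overlap reported
  dup <- rbind(calls, calls[drop, ])
  chk2 <- region_partition_check(dup, sim$hap1, sim$hap2)
  expect_false(chk2$ok)
  expect_gt(nrow(chk2$ref_overlapped), 0L)
})

test_that("planted SVs are recovered with correct type and breakpoints", {
  sim <- small_sim()
  calls <- small_calls()
  rec <- sv_recovery(calls, sim$truth$regions, tol = 31L, min_len = 62L)
  expect_gte(attr(rec, "rate"), 0.95)
  sn <- snp_recall(calls, sim$truth$regions)
  expect_gte(sn$recall, 0.99)
  expect_equal(sn$false_positives_clean, 0L)
})
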