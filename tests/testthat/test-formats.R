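test_that("coordinate conversion handles the boundary cases", {
  # first base, last base of a 10-bp chromosome, and a length-1 interval
  expect_equal(coords_to_1based(0L, 1L), list(start = 1L, end = 1L))
  expect_equal(coords_to_1based(9L, 10L), list(start = 10L, end = 10L))
  expect_equal(coords_from_1based(1L, 1L), list(start = 0L, end = 1L))
  expect_equal(coords_from_1based(10L, 10L), list(start = 9L, end = 10L))
  # anchored empty interval round-trips through the (p+1, p) encoding
  io <- coords_to_1based(5L, 5L)
  expect_equal(io, list(start = 6L, end = 5L))
  expect_equal(coords_from_1based(io$start, io$end),
               list(start = 5L, end = 5L))
})

test_that("FASTA reading normalizes case, maps U to T, rejects junk", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1 some description", "acgtn", ">chr2", "ACGU"), f)
  g <- read_genome(f, "hap1")
  expect_equal(as.character(g$seqs[["chr1"]]), "ACGTN")
  expect_equal(as.character(g$seqs[["chr2"]]), "ACGT")

  writeLines(c(">c1", "ACGT", ">c1", "AA"), f)
  expect_error(read_genome(f), "duplicate")

  writeLines(c(">c1", "ACXGT"), f)
  expect_error(read_genome(f), "invalid character 'X' in record 'c1' at offset 3")

  g2 <- haplotype_genome(c(chrA = "ACGTACGT"), "hap2")
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_genome(g2, f2)
  back <- read_genome(f2, "hap2")
  expect_equal(as.character(back$seqs), as.character(g2$seqs))
  expect_error(haplotype_genome(c(chrA = ""), "hap1"), "empty")
})

test_that("GFF3 gene models: CDS extraction, strand, longest-mRNA rule", {
  g <- haplotype_genome(c(chr1 = "ATGAAACCCGGGTTTACGTACGTACG"), "hap1")
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\t.\tgene\t1\t6\t.\t+\t.\tID=gplus",
    "chr1\t.\tmRNA\t1\t6\t.\t+\t.\tID=gplus.m;Parent=gplus",
    "chr1\t.\tCDS\t1\t3\t.\t+\t0\tID=c1;Parent=gplus.m",
    "chr1\t.\tgene\t1\t6\t.\t-\t.\tID=gminus",
    "chr1\t.\tmRNA\t1\t6\t.\t-\t.\tID=gminus.m;Parent=gminus",
    "chr1\t.\tCDS\t1\t3\t.\t-\t0\tID=c2;Parent=gminus.m",
    # two isoforms: 12-bp CDS chain must win over the 3-bp one
    "chr1\t.\tgene\t7\t26\t.\t+\t.\tID=giso",
    "chr1\t.\tmRNA\t7\t26\t.\t+\t.\tID=giso.m1;Parent=giso",
    "chr1\t.\tCDS\t7\t12\t.\t+\t0\tID=c3;Parent=giso.m1",
    "chr1\t.\tCDS\t16\t21\t.\t+\t0\tID=c4;Parent=giso.m1",
    "chr1\t.\tmRNA\t7\t26\t.\t+\t.\tID=giso.m2;Parent=giso",
    "chr1\t.\tCDS\t7\t9\t.\t+\t0\tID=c5;Parent=giso.m2",
    # a gene with no CDS is skipped, with a count
    "chr1\t.\tgene\t22\t26\t.\t+\t.\tID=gnone",
    "chr1\t.\tmRNA\t22\t26\t.\t+\t.\tID=gnone.m;Parent=gnone"), f)
  gm <- read_annotation(f, g)
  expect_equal(attr(gm, "skipped"), 1L)
  expect_setequal(gm$gene_id, c("gplus", "gminus", "giso"))
  expect_equal(gm$cds_seq[gm$gene_id == "gplus"], "ATG")
  expect_equal(gm$cds_seq[gm$gene_id == "gminus"], "CAT")
  expect_equal(gm$cds_len[gm$gene_id == "giso"], 12)

  # writer round trip
  f2 <- withr::local_tempfile(fileext = ".gff3")
  write_annotation(gm, f2)
  gm2 <- read_annotation(f2, g)
  expect_equal(gm2$cds_seq[order(gm2$gene_id)],
               gm$cds_seq[order(gm$gene_id)])
})

test_that("region-call TSV round-trips, rejects unknown types", {
  calls <- region_calls(
    ref_chrom = c("c1", "c1", NA),
    ref_start = c(0L, 150L, NA), ref_end = c(100L, 150L, NA),
    qry_chrom = c("c1", "c1", "c2"),
    qry_start = c(0L, 200L, 0L), qry_end = c(100L, 260L, 500L),
    type = c("SYN", "INS", "NOTAL"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_region_calls(calls, f)
  back <- read_region_calls(f)
  expect_equal(as.data.frame(back), as.data.frame(calls))

  writeLines("c1\t1\t100\tc1\t1\t100\tDUP", f)
  expect_error(read_region_calls(f), "DUP.*line 1")

  writeLines("c1\t1\t100\tc1\t1\t100\tSYN", f)
  one <- read_region_calls(f)
  expect_equal(nrow(one), 1L)
  expect_equal(one$type, "SYN")
  expect_equal(one$ref_start, 0L)
  expect_equal(one$ref_end, 100L)

  # SNP rows keep their alleles through the trailing columns
  snp <- region_calls("c1", 4L, 5L, "c1", 4L, 5L, "SNP", "A", "G")
  write_region_calls(snp, f)
  expect_equal(as.data.frame(read_region_calls(f)), as.data.frame(snp))
})

test_that("VCF writing follows POS/anchor conventions and round-trips", {
  # sequence engineered so every base is readable by eye
  refseq <- "ACGTAGGGCCTTA"
  qryseq <- "ACGTGGCCTTA"
  ref <- haplotype_genome(c(c1 = refseq), "hap1")
  qry <- haplotype_genome(c(c1 = qryseq), "hap2")
  # SNP at 1-based position 5 (A->G); deletion of ref 6..8 (1-based)
  calls <- region_calls(
    ref_chrom = c("c1", "c1"), ref_start = c(4L, 5L), ref_end = c(5L, 8L),
    qry_chrom = c("c1", "c1"), qry_start = c(4L, 5L), qry_end = c(5L, 5L),
    type = c("SNP", "DEL"), ref_base = c("A", NA), qry_base = c("G", NA))
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(calls, ref, qry, f)
  lines <- grep("^[^#]", readLines(f), value = TRUE)
  snp <- strsplit(lines[1], "\t")[[1]]
  del <- strsplit(lines[2], "\t")[[1]]
  expect_equal(as.integer(snp[2]), 5L)
  expect_equal(snp[4], "A"); expect_equal(snp[5], "G")
  # anchor-base oracle: REF = slice 5..8 of the sequence, ALT = base 5
  expect_equal(as.integer(del[2]), 5L)
  expect_equal(del[4], substr(refseq, 5, 8))
  expect_equal(nchar(del[4]), 4L)
  expect_equal(del[5], substr(refseq, 5, 5))

  back <- read_vcf(f)
  expect_equal(as.data.frame(back), as.data.frame(calls))
})

test_that("BED, counts and genetic-map files round-trip", {
  bed <- data.frame(chrom = c("c1", "c2"), start = c(0L, 10L),
                    end = c(5L, 20L), name = c("a", "b"),
                    stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed(bed, f)
  expect_equal(read_bed(f), bed)

  cnt <- matrix(c(3L, 0L, 7L, 2L), 2,
                dimnames = list(c("g1", "g2"), NULL))
  em <- expression_matrix(cnt, tissue = c("leaf", "root"),
                          replicate = c(1L, 1L),
                          lengths = c(g1 = 300, g2 = 600), label = "hap1")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_counts(em, f2)
  back <- read_counts(f2, lengths = c(g1 = 300, g2 = 600), label = "hap1")
  expect_equal(back$counts, em$counts)
  expect_equal(back$tissue, em$tissue)
  expect_equal(back$lengths, em$lengths)

  mk <- data.frame(marker_id = c("m1", "m2"), chrom = "c1",
                   cM = c(0.5, 1.7), bp = c(10L, 99L),
                   stringsAsFactors = FALSE)
  f3 <- withr::local_tempfile(fileext = ".tsv")
  write_genetic_map(mk, f3)
  expect_equal(read_genetic_map(f3), mk)
  g <- haplotype_genome(c(c1 = "ACGT"), "hap1")
  expect_error(read_genetic_map(f3, g), "outside")
})
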