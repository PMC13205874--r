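#' @useDynLib hapcompare, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

REGION_TYPES <- c("SYN", "INV", "TRANS", "INS", "DEL", "HDR", "NOTAL", "SNP")
TISSUES <- c("leaf", "stolon", "rhizome", "root")

## ---- haplotype genomes ----------------------------------------------------

#' Haplotype genome container
#'
#' A named set of chromosome sequences for one haplotype of a phased
#' diploid assembly. Sequences are uppercase over the alphabet
#' \{A, C, G, T, N\}; N marks assembly gaps.
#'
#' @param seqs a named [Biostrings::DNAStringSet] or named character vector
#'   of chromosome sequences.
#' @param label haplotype label, `"hap1"` or `"hap2"`.
#' @return an object of class `haplotype_genome`: a list with elements
#'   `label` and `seqs` (a `DNAStringSet`).
#' @export
haplotype_genome <- function(seqs, label = c("hap1", "hap2")) {
  label <- match.arg(label)
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  nm <- names(seqs)
  if (is.null(nm) || anyNA(nm) || any(nm == ""))
    stop("all chromosomes must be named")
  if (anyDuplicated(nm))
    stop("duplicate chromosome id: ", nm[duplicated(nm)][1])
  if (any(Biostrings::width(seqs) == 0L))
    stop("empty chromosome sequence: ", nm[Biostrings::width(seqs) == 0L][1])
  bad <- Biostrings::letterFrequency(seqs, "ACGTN") != Biostrings::width(seqs)
  if (any(bad))
    stop("sequence contains characters outside {A,C,G,T,N}: ", nm[bad][1])
  structure(list(label = label, seqs = seqs), class = "haplotype_genome")
}

#' @export
print.haplotype_genome <- function(x, ...) {
  cat(sprintf("<haplotype_genome> %s: %d chromosome(s), %s bp total\n",
              x$label, length(x$seqs),
              format(sum(Biostrings::width(x$seqs)), big.mark = ",")))
  invisible(x)
}

#' Chromosome lengths of a haplotype genome
#' @param genome a `haplotype_genome`.
#' @return named integer vector of chromosome lengths.
#' @export
chrom_lengths <- function(genome) {
  stats::setNames(Biostrings::width(genome$seqs), names(genome$seqs))
}

#' Read a haplotype genome from FASTA
#'
#' Sequences are uppercased and `U` is mapped to `T`. Any character outside
#' \{A, C, G, T, N\} is rejected with the offending record and offset named.
#'
#' @param path path to a FASTA file.
#' @param label haplotype label to attach (`"hap1"` or `"hap2"`).
#' @return a [haplotype_genome()].
#' @export
read_genome <- function(path, label = c("hap1", "hap2")) {
  label <- match.arg(label)
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- Biostrings::readBStringSet(path)
  nm <- names(raw)
  # FASTA headers may carry descriptions; the id is the first word
  nm <- sub("\\s.*$", "", nm)
  if (anyDuplicated(nm))
    stop("duplicate record id in ", path, ": ", nm[duplicated(nm)][1])
  ch <- toupper(as.character(raw))
  ch <- gsub("U", "T", ch, fixed = TRUE)
  bad <- regexpr("[^ACGTN]", ch)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1]
    stop(sprintf("invalid character '%s' in record '%s' at offset %d",
                 substr(ch[i], bad[i], bad[i]), nm[i], bad[i]))
  }
  if (any(nchar(ch) == 0L))
    stop("empty record in ", path, ": ", nm[nchar(ch) == 0L][1])
  names(ch) <- nm
  haplotype_genome(ch, label)
}

#' Write a haplotype genome to FASTA
#' @param genome a `haplotype_genome`.
#' @param path output path.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome$seqs, path, width = 80L)
  invisible(path)
}

## ---- gene models ----------------------------------------------------------

#' Gene model table
#'
#' Gene models are stored as a data frame with one row per gene:
#' `gene_id`, `haplotype`, `chrom`, `strand`, `start`, `end` (0-based
#' half-open span), `cds` (list column of two-column integer matrices of
#' 0-based half-open CDS intervals, sorted, non-overlapping), `cds_seq`
#' (spliced, strand-corrected coding sequence) and `cds_len`.
#'
#' @param df a data frame with the columns above (`cds_seq`/`cds_len` are
#'   filled in when a genome is supplied).
#' @param genome optional `haplotype_genome` used to (re)extract CDS
#'   sequences.
#' @return a validated `gene_models` data frame.
#' @export
gene_models <- function(df, genome = NULL) {
  need <- c("gene_id", "haplotype", "chrom", "strand", "start", "end", "cds")
  if (!all(need %in% names(df)))
    stop("missing gene model columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id: ", df$gene_id[duplicated(df$gene_id)][1])
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  for (i in seq_len(nrow(df))) {
    m <- df$cds[[i]]
    if (!is.matrix(m) || ncol(m) != 2L || nrow(m) < 1L)
      stop("gene ", df$gene_id[i], ": cds must be a two-column matrix")
    if (is.unsorted(m[, 1], strictly = TRUE) && nrow(m) > 1L)
      stop("gene ", df$gene_id[i], ": CDS intervals not sorted")
    if (any(m[, 2] <= m[, 1]))
      stop("gene ", df$gene_id[i], ": empty CDS interval")
    if (nrow(m) > 1L && any(m[-1, 1] < m[-nrow(m), 2]))
      stop("gene ", df$gene_id[i], ": overlapping CDS intervals")
    if (m[1, 1] < df$start[i] || m[nrow(m), 2] > df$end[i])
      stop("gene ", df$gene_id[i], ": CDS outside gene span")
  }
  if (!is.null(genome)) {
    if (!all(df$chrom %in% names(genome$seqs)))
      stop("gene on unknown chromosome: ",
           df$chrom[!df$chrom %in% names(genome$seqs)][1])
    df$cds_seq <- vapply(seq_len(nrow(df)), function(i) {
      extract_cds(genome, df$chrom[i], df$strand[i], df$cds[[i]])
    }, character(1))
  }
  if (is.null(df$cds_seq)) df$cds_seq <- NA_character_
  df$cds_len <- vapply(df$cds, function(m) sum(m[, 2] - m[, 1]), numeric(1))
  ok <- is.na(df$cds_seq) | nchar(df$cds_seq) == df$cds_len
  if (!all(ok)) stop("cds_seq length mismatch for ", df$gene_id[!ok][1])
  class(df) <- c("gene_models", "data.frame")
  df
}

#' Extract a spliced, strand-corrected CDS sequence
#'
#' CDS intervals are concatenated in increasing coordinate order; for a
#' minus-strand gene the concatenation is reverse-complemented, which
#' equals taking the intervals in decreasing order and reverse-complementing
#' each.
#'
#' @param genome a `haplotype_genome`.
#' @param chrom chromosome id.
#' @param strand `"+"` or `"-"`.
#' @param cds two-column matrix of 0-based half-open intervals.
#' @return a character scalar.
#' @export
extract_cds <- function(genome, chrom, strand, cds) {
  seq <- genome$seqs[[chrom]]
  if (max(cds[, 2]) > length(seq))
    stop("CDS outside chromosome bounds on ", chrom)
  parts <- vapply(seq_len(nrow(cds)), function(j)
    as.character(Biostrings::subseq(seq, cds[j, 1] + 1L, cds[j, 2])),
    character(1))
  s <- paste(parts, collapse = "")
  if (strand == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

#' Read gene models from GFF3
#'
#' Expects `gene`, `mRNA` and `CDS` features linked by `ID`/`Parent`.
#' For multi-isoform genes the mRNA with the longest summed CDS is kept,
#' so each gene contributes exactly one coding sequence. Genes without any
#' CDS are skipped; their number is returned in the `skipped` attribute.
#'
#' @param path path to a GFF3 file.
#' @param genome the matching `haplotype_genome` (for CDS extraction and
#'   bounds checks).
#' @return a `gene_models` data frame with attribute `skipped`.
#' @export
read_annotation <- function(path, genome) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gr$type)
  genes <- gr[typ == "gene"]
  mrnas <- gr[typ == "mRNA"]
  cdss <- gr[typ == "CDS"]
  mrna_parent <- vapply(mrnas$Parent, function(p) p[1], character(1))
  cds_parent <- vapply(cdss$Parent, function(p) p[1], character(1))
  cds_by_mrna <- split(seq_along(cdss), cds_parent)
  skipped <- 0L
  rows <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    gid <- genes$ID[i]
    mi <- which(mrna_parent == gid)
    best <- NULL; best_len <- -1L
    for (m in mi) {
      ci <- cds_by_mrna[[mrnas$ID[m]]]
      if (is.null(ci)) next
      len <- sum(GenomicRanges::width(cdss[ci]))
      if (len > best_len) { best_len <- len; best <- ci }
    }
    if (is.null(best)) { skipped <- skipped + 1L; next }
    cd <- cdss[best]
    o <- order(GenomicRanges::start(cd))
    cv <- coords_from_1based(GenomicRanges::start(cd)[o],
                             GenomicRanges::end(cd)[o])
    rows[[i]] <- data.frame(
      gene_id = gid,
      chrom = as.character(GenomicRanges::seqnames(genes)[i]),
      strand = as.character(GenomicRanges::strand(genes)[i]),
      start = coords_from_1based(GenomicRanges::start(genes)[i],
                                 GenomicRanges::end(genes)[i])$start,
      end = GenomicRanges::end(genes)[i],
      stringsAsFactors = FALSE)
    rows[[i]]$cds <- list(cbind(cv$start, cv$end))
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    df <- data.frame(gene_id = character(), haplotype = character(),
                     chrom = character(), strand = character(),
                     start = integer(), end = integer())
    df$cds <- list()
    out <- gene_models(df, genome)
  } else {
    df <- do.call(rbind, rows)
    df$haplotype <- genome$label
    out <- gene_models(df, genome)
  }
  attr(out, "skipped") <- skipped
  out
}

#' Write gene models to GFF3
#' @param genes a `gene_models` data frame.
#' @param path output path.
#' @export
write_annotation <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    io <- coords_to_1based(g$start, g$end)
    writeLines(sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$chrom, "hapcompare", io$start, io$end, g$strand,
                       g$gene_id), con)
    mid <- paste0(g$gene_id, ".m1")
    writeLines(sprintf("%s\t%s\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                       g$chrom, "hapcompare", io$start, io$end, g$strand,
                       mid, g$gene_id), con)
    m <- genes$cds[[i]]
    for (j in seq_len(nrow(m))) {
      cio <- coords_to_1based(m[j, 1], m[j, 2])
      writeLines(sprintf(
        "%s\t%s\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.c%d;Parent=%s",
        g$chrom, "hapcompare", cio$start, cio$end, g$strand, mid, j, mid),
        con)
    }
  }
  invisible(path)
}

## ---- region calls ---------------------------------------------------------

#' Region call table
#'
#' One row per classified interval pair (or single-haplotype interval).
#' Coordinates are internal 0-based half-open. An *anchored empty* side
#' (e.g. the reference side of an insertion) has `start == end` at the
#' breakpoint; a wholly absent side has `NA` chromosome and coordinates.
#' SNP rows carry the two alleles in `ref_base`/`qry_base`.
#'
#' @param ref_chrom,ref_start,ref_end reference-side interval.
#' @param qry_chrom,qry_start,qry_end query-side interval.
#' @param type region type, one of `SYN INV TRANS INS DEL HDR NOTAL SNP`.
#' @param ref_base,qry_base SNP alleles (`NA` otherwise).
#' @return a `region_calls` data frame sorted by reference chromosome and
#'   start.
#' @export
region_calls <- function(ref_chrom, ref_start, ref_end,
                         qry_chrom, qry_start, qry_end, type,
                         ref_base = NA_character_,
                         qry_base = NA_character_) {
  df <- data.frame(ref_chrom = as.character(ref_chrom),
                   ref_start = as.integer(ref_start),
                   ref_end = as.integer(ref_end),
                   qry_chrom = as.character(qry_chrom),
                   qry_start = as.integer(qry_start),
                   qry_end = as.integer(qry_end),
                   type = as.character(type),
                   ref_base = as.character(ref_base),
                   qry_base = as.character(qry_base),
                   stringsAsFactors = FALSE)
  validate_region_calls(df)
}

validate_region_calls <- function(df) {
  bad <- !df$type %in% REGION_TYPES
  if (any(bad))
    stop("unknown region type '", df$type[bad][1], "' at row ",
         which(bad)[1])
  rlen <- df$ref_end - df$ref_start
  qlen <- df$qry_end - df$qry_start
  rhas <- !is.na(df$ref_chrom) & !is.na(rlen) & rlen > 0L
  qhas <- !is.na(df$qry_chrom) & !is.na(qlen) & qlen > 0L
  two <- df$type %in% c("SYN", "INV", "TRANS", "HDR")
  if (any(two & !(rhas & qhas)))
    stop("two-sided region with an empty side at row ",
         which(two & !(rhas & qhas))[1])
  if (any(df$type == "INS" & (rhas | !qhas)))
    stop("INS must have empty ref side and non-empty qry side")
  if (any(df$type == "DEL" & (qhas | !rhas)))
    stop("DEL must have empty qry side and non-empty ref side")
  if (any(df$type == "NOTAL" & (rhas == qhas)))
    stop("NOTAL must have exactly one side")
  snp <- df$type == "SNP"
  if (any(snp & (rlen != 1L | qlen != 1L)))
    stop("SNP intervals must have length 1")
  if (any(snp & (is.na(df$ref_base) | is.na(df$qry_base))))
    stop("SNP rows need ref_base and qry_base")
  o <- order(is.na(df$ref_chrom), df$ref_chrom, df$ref_start,
             df$qry_chrom, df$qry_start)
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("region_calls", "data.frame")
  df
}

#' Read SyRI-style region calls from TSV
#'
#' Tab-separated columns: ref-chrom, ref-start, ref-end, qry-chrom,
#' qry-start, qry-end, type (1-based inclusive; `-` for a wholly absent
#' side; an anchored empty side is encoded as start = end + 1). Two
#' optional trailing columns carry SNP alleles.
#'
#' @param path path to the TSV.
#' @return a `region_calls` data frame.
#' @export
read_region_calls <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          colClasses = "character", fill = TRUE)
  if (!ncol(df) %in% c(7L, 9L))
    stop("expected 7 or 9 tab-separated columns in ", path)
  bad <- !df[[7]] %in% REGION_TYPES
  if (any(bad))
    stop("unknown region type '", df[[7]][bad][1], "' at line ",
         which(bad)[1], " of ", path)
  parse_side <- function(chrom, s, e) {
    absent <- chrom == "-"
    chrom[absent] <- NA_character_
    s[absent] <- NA; e[absent] <- NA
    cv <- coords_from_1based(as.integer(s), as.integer(e))
    list(chrom = chrom, start = cv$start, end = cv$end)
  }
  r <- parse_side(df[[1]], df[[2]], df[[3]])
  q <- parse_side(df[[4]], df[[5]], df[[6]])
  rb <- if (ncol(df) == 9L) ifelse(df[[8]] == "-", NA, df[[8]]) else NA
  qb <- if (ncol(df) == 9L) ifelse(df[[9]] == "-", NA, df[[9]]) else NA
  region_calls(r$chrom, r$start, r$end, q$chrom, q$start, q$end,
               df[[7]], rb, qb)
}

#' Write region calls to TSV
#' @param calls a `region_calls` data frame.
#' @param path output path.
#' @export
write_region_calls <- function(calls, path) {
  side <- function(chrom, s, e) {
    out <- matrix("-", nrow = length(chrom), ncol = 3)
    has <- !is.na(chrom)
    io <- coords_to_1based(s[has], e[has])
    out[has, 1] <- chrom[has]
    out[has, 2] <- as.character(io$start)
    out[has, 3] <- as.character(io$end)
    out
  }
  m <- cbind(side(calls$ref_chrom, calls$ref_start, calls$ref_end),
             side(calls$qry_chrom, calls$qry_start, calls$qry_end),
             calls$type,
             ifelse(is.na(calls$ref_base), "-", calls$ref_base),
             ifelse(is.na(calls$qry_base), "-", calls$qry_base))
  ok <- tryCatch({
    utils::write.table(m, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    TRUE
  }, error = function(e) stop("cannot write ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}

## ---- VCF ------------------------------------------------------------------

#' Write SNPs and small indels to VCF 4.2
#'
#' SNP rows are written with 1-based `POS` and the two alleles. INS/DEL
#' rows up to `max_len` are written with the standard anchor-base
#' convention (the base immediately left of the event is prepended to both
#' alleles). Query-side coordinates are preserved in the `INFO` field
#' (`QC`, `QS`, `QE`, 1-based inclusive) so the file round-trips.
#' Indels whose event starts at the first base of a chromosome have no
#' left anchor and are skipped with a warning.
#'
#' @param calls a `region_calls` data frame.
#' @param ref,qry the two `haplotype_genome`s (for anchor and allele
#'   sequence).
#' @param path output path.
#' @param max_len maximum indel length written (larger events are regional,
#'   not VCF material).
#' @export
write_vcf <- function(calls, ref, qry, path, max_len = 10000L) {
  keep <- calls$type %in% c("SNP", "INS", "DEL")
  x <- calls[keep, , drop = FALSE]
  lines <- c("##fileformat=VCFv4.2",
             "##INFO=<ID=QC,Number=1,Type=String,Description=\"Query chromosome\">",
             "##INFO=<ID=QS,Number=1,Type=Integer,Description=\"Query start (1-based)\">",
             "##INFO=<ID=QE,Number=1,Type=Integer,Description=\"Query end (1-based)\">",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  skipped <- 0L
  for (i in seq_len(nrow(x))) {
    r <- x[i, ]
    qinfo <- sprintf("QC=%s;QS=%d;QE=%d", r$qry_chrom,
                     r$qry_start + 1L, r$qry_end)
    if (r$type == "SNP") {
      lines <- c(lines, sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                                r$ref_chrom, r$ref_start + 1L,
                                r$ref_base, r$qry_base, qinfo))
    } else if (r$type == "DEL") {
      if (r$ref_end - r$ref_start > max_len) next
      if (r$ref_start == 0L) { skipped <- skipped + 1L; next }
      anchor <- as.character(Biostrings::subseq(
        ref$seqs[[r$ref_chrom]], r$ref_start, r$ref_start))
      del <- as.character(Biostrings::subseq(
        ref$seqs[[r$ref_chrom]], r$ref_start + 1L, r$ref_end))
      lines <- c(lines, sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                                r$ref_chrom, r$ref_start,
                                paste0(anchor, del), anchor, qinfo))
    } else { # INS
      if (r$qry_end - r$qry_start > max_len) next
      if (r$ref_start == 0L) { skipped <- skipped + 1L; next }
      anchor <- as.character(Biostrings::subseq(
        ref$seqs[[r$ref_chrom]], r$ref_start, r$ref_start))
      ins <- as.character(Biostrings::subseq(
        qry$seqs[[r$qry_chrom]], r$qry_start + 1L, r$qry_end))
      lines <- c(lines, sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                                r$ref_chrom, r$ref_start,
                                anchor, paste0(anchor, ins), qinfo))
    }
  }
  if (skipped > 0L)
    warning(skipped, " indel(s) at a chromosome start skipped (no anchor base)")
  writeLines(lines, path)
  invisible(path)
}

#' Read a VCF written by [write_vcf()] back into region calls
#' @param path path to the VCF.
#' @return a `region_calls` data frame of SNP/INS/DEL rows.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fx) == 0L)
    return(region_calls(character(), integer(), integer(), character(),
                        integer(), integer(), character()))
  info <- function(key) {
    m <- regmatches(fx$INFO, regexpr(paste0(key, "=[^;]+"), fx$INFO))
    sub(paste0(key, "="), "", m)
  }
  qc <- info("QC"); qs <- as.integer(info("QS")); qe <- as.integer(info("QE"))
  pos <- as.integer(fx$POS)
  nr <- nchar(fx$REF); na_ <- nchar(fx$ALT)
  typ <- ifelse(nr == 1L & na_ == 1L, "SNP", ifelse(nr > na_, "DEL", "INS"))
  rs <- ifelse(typ == "SNP", pos - 1L, pos)        # drop anchor base
  re <- ifelse(typ == "SNP", pos, ifelse(typ == "DEL", pos + nr - 1L, pos))
  qcv <- coords_from_1based(qs, qe)
  region_calls(fx$CHROM, rs, re, qc, qcv$start, qcv$end, typ,
               ifelse(typ == "SNP", fx$REF, NA),
               ifelse(typ == "SNP", fx$ALT, NA))
}

## ---- BED ------------------------------------------------------------------

#' Write/read BED intervals
#'
#' BED is 0-based half-open, i.e. the package's internal convention; the
#' conversion at this boundary is the identity but still passes through
#' [coords_to_1based()]'s inverse pair for symmetry of audit.
#'
#' @param df data frame with columns `chrom`, `start`, `end` and optional
#'   `name`.
#' @param path file path.
#' @return `read_bed` returns a data frame with `chrom`, `start`, `end`,
#'   `name`.
#' @export
write_bed <- function(df, path) {
  nm <- if (!is.null(df$name)) df$name else "."
  utils::write.table(
    data.frame(df$chrom, format(df$start, scientific = FALSE, trim = TRUE),
               format(df$end, scientific = FALSE, trim = TRUE), nm),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  out <- data.frame(chrom = as.character(df[[1]]),
                    start = as.integer(df[[2]]),
                    end = as.integer(df[[3]]),
                    stringsAsFactors = FALSE)
  out$name <- if (ncol(df) >= 4L) as.character(df[[4]]) else "."
  out
}

## ---- expression matrices --------------------------------------------------

#' Expression count matrix for one haplotype
#'
#' @param counts integer matrix, genes x samples; rownames are gene ids.
#' @param tissue,replicate per-column sample descriptors; tissues are
#'   `leaf`, `stolon`, `rhizome`, `root`.
#' @param lengths effective gene lengths in bp (named or in row order).
#' @param label haplotype label.
#' @return an `expression_matrix` object.
#' @export
expression_matrix <- function(counts, tissue, replicate, lengths,
                              label = c("hap1", "hap2")) {
  label <- match.arg(label)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have gene ids as rownames")
  if (length(tissue) != ncol(counts) || length(replicate) != ncol(counts))
    stop("tissue/replicate length must match column count")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  if (!is.null(names(lengths))) lengths <- lengths[rownames(counts)]
  if (length(lengths) != nrow(counts) || anyNA(lengths))
    stop("one effective length per gene is required")
  colnames(counts) <- paste0(tissue, ":", replicate)
  structure(list(label = label, counts = counts,
                 tissue = as.character(tissue),
                 replicate = as.integer(replicate),
                 lengths = stats::setNames(as.numeric(lengths),
                                           rownames(counts))),
            class = "expression_matrix")
}

#' Write/read an expression count matrix as TSV
#'
#' Column header is `gene_id` followed by one `tissue:replicate` column per
#' sample. Effective lengths are not stored in the TSV; supply them (or the
#' gene models that carry them) when reading.
#'
#' @param mat an `expression_matrix`.
#' @param path file path.
#' @param lengths effective lengths, or a `gene_models` data frame whose
#'   `cds_len` is used.
#' @param label haplotype label for the object read back.
#' @export
write_counts <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat$counts), mat$counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path, lengths, label = c("hap1", "hap2")) {
  label <- match.arg(label)
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df$gene_id
  parts <- strsplit(colnames(counts), ":", fixed = TRUE)
  if (inherits(lengths, "gene_models"))
    lengths <- stats::setNames(lengths$cds_len, lengths$gene_id)
  expression_matrix(counts,
                    tissue = vapply(parts, `[`, "", 1),
                    replicate = as.integer(vapply(parts, `[`, "", 2)),
                    lengths = lengths, label = label)
}

## ---- genetic map ----------------------------------------------------------

#' Read/write genetic-map markers
#'
#' TSV columns: `marker_id`, `chrom`, `cM`, `bp` (physical position,
#' 1-based). Genetic positions must be non-negative; when a genome is
#' supplied, physical positions are checked against chromosome lengths.
#'
#' @param path file path.
#' @param genome optional `haplotype_genome` for bounds checking.
#' @param markers data frame with the four columns above.
#' @export
read_genetic_map <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("marker_id", "chrom", "cM", "bp")
  if (!all(need %in% names(df)))
    stop("genetic map needs columns: ", paste(need, collapse = ", "))
  if (any(df$cM < 0)) stop("negative cM position")
  if (!is.null(genome)) {
    len <- chrom_lengths(genome)
    if (!all(df$chrom %in% names(len)))
      stop("marker on unknown chromosome: ",
           df$chrom[!df$chrom %in% names(len)][1])
    if (any(df$bp < 1L | df$bp > len[df$chrom]))
      stop("marker physical position outside chromosome")
  }
  df[, need]
}

#' @rdname read_genetic_map
#' @export
write_genetic_map <- function(markers, path) {
  utils::write.table(markers[, c("marker_id", "chrom", "cM", "bp")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
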