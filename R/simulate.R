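## Phased-diploid simulator with planted truth.
##
## hap-1 is built first; hap-2 is *only ever* produced by applying the edit
## script, so the truth set is exact by construction. Every stage draws from
## its own seed substream derived from the master seed, so adding a stage
## never perturbs earlier ones.

#' Simulation configuration
#'
#' Defaults describe a desk-scale phased diploid: two 500-kb chromosome
#' pairs related by SNPs (5 per kb), 40 insertions and 40 deletions
#' (log-uniform 50-5000 bp), 2 inversions (5-50 kb), 1 inter-chromosomal
#' translocation (5-20 kb), 6 highly diverged regions (2-20 kb at 60-80%
#' identity, substitutions only), 2 haplotype-unique terminal segments per
#' haplotype (3-10 kb), 120 genes per chromosome of which 12% are
#' hemizygous (hosted in insertions : HDRs : unique segments at roughly
#' 44 : 52 : 4), telomeric `TTTAGGG` arrays at every chromosome end,
#' genetic-map markers, and negative-binomial expression counts for four
#' tissues. A designated set of homozygous gene pairs has its CDS shielded
#' from SNPs (identical pairs); a subset of those receives a cis effect
#' (fold change on one haplotype) plus planted variants in its 3-kb
#' upstream promoter.
#'
#' @param seed master RNG seed (integer).
#' @param n_chromosomes,chromosome_length genome shape (body length in bp,
#'   telomere arrays are appended on top).
#' @param snp_rate SNPs per bp of SNP-eligible sequence.
#' @param n_insertions,n_deletions,indel_len_range indel events; lengths
#'   drawn log-uniformly.
#' @param n_inversions,inversion_len_range inversions.
#' @param n_translocations,translocation_len_range cut-and-paste
#'   translocations to a different chromosome (requires >= 2 chromosomes).
#' @param n_hdrs,hdr_len_range,hdr_identity_range highly diverged regions;
#'   identity is the fraction of bases left untouched (no indels inside).
#' @param n_unique_segments,unique_len_range haplotype-unique terminal
#'   segments per haplotype, placed between chromosome body and telomere.
#' @param genes_per_chromosome,gene_span_range genes per chromosome and
#'   their span in bp (two CDS exons split by a short intron).
#' @param hemizygous_fraction fraction of each haplotype's genes that are
#'   hemizygous.
#' @param hemizygous_category_weights relative insertion : HDR : unique
#'   hosting weights for hemizygous genes.
#' @param n_identical_pairs homozygous pairs whose CDS is shielded from
#'   SNPs, guaranteeing byte-identical coding sequence.
#' @param n_de_pairs identical pairs receiving a cis expression effect and
#'   planted promoter variants.
#' @param cis_effect_fold expression fold change on the up-regulated
#'   haplotype of a DE pair (all tissues).
#' @param hemizygous_expression_fold mean expression multiplier of
#'   hemizygous genes relative to homozygous baseline.
#' @param replicates_per_tissue RNA-seq replicates per tissue (tissues are
#'   fixed: leaf, stolon, rhizome, root).
#' @param nb_dispersion negative-binomial dispersion (size = 1/dispersion).
#' @param promoter_extra_snps,promoter_extra_sv planted variants in the
#'   3-kb upstream window of each DE gene (extra SNPs, plus one small
#'   insertion when `promoter_extra_sv`).
#' @param promoter_window promoter window in bp.
#' @param telomere_array_copies copies of `TTTAGGG` appended at each
#'   chromosome end.
#' @param n_map_markers genetic-map markers per chromosome.
#' @param gc_content GC fraction of the simulated background sequence.
#' @return a validated `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_chromosomes = 2L,
                              chromosome_length = 500000L,
                              snp_rate = 0.005,
                              n_insertions = 40L,
                              n_deletions = 40L,
                              indel_len_range = c(50L, 5000L),
                              n_inversions = 2L,
                              inversion_len_range = c(5000L, 50000L),
                              n_translocations = 1L,
                              translocation_len_range = c(5000L, 20000L),
                              n_hdrs = 6L,
                              hdr_len_range = c(2000L, 20000L),
                              hdr_identity_range = c(0.6, 0.8),
                              n_unique_segments = 2L,
                              unique_len_range = c(3000L, 10000L),
                              genes_per_chromosome = 120L,
                              gene_span_range = c(600L, 1200L),
                              hemizygous_fraction = 0.12,
                              hemizygous_category_weights =
                                c(insertion = 44.3, HDR = 52.2, unique = 3.4),
                              n_identical_pairs = 60L,
                              n_de_pairs = 12L,
                              cis_effect_fold = 4,
                              hemizygous_expression_fold = 2,
                              replicates_per_tissue = 3L,
                              nb_dispersion = 0.1,
                              promoter_extra_snps = 25L,
                              promoter_extra_sv = TRUE,
                              promoter_window = 3000L,
                              telomere_array_copies = 30L,
                              n_map_markers = 30L,
                              gc_content = 0.44) {
  cfg <- as.list(environment())
  counts <- c(cfg$n_chromosomes, cfg$chromosome_length, cfg$n_insertions,
              cfg$n_deletions, cfg$n_inversions, cfg$n_translocations,
              cfg$n_hdrs, cfg$n_unique_segments, cfg$genes_per_chromosome,
              cfg$n_identical_pairs, cfg$n_de_pairs,
              cfg$replicates_per_tissue, cfg$promoter_extra_snps,
              cfg$telomere_array_copies, cfg$n_map_markers)
  if (any(counts < 0)) stop("all counts must be >= 0")
  if (cfg$hemizygous_fraction < 0 || cfg$hemizygous_fraction > 1)
    stop("hemizygous_fraction must be in [0, 1]")
  if (cfg$snp_rate < 0 || cfg$snp_rate > 1)
    stop("snp_rate must be in [0, 1]")
  if (cfg$n_translocations > 0 && cfg$n_chromosomes < 2)
    stop("translocations need at least 2 chromosomes")
  if (cfg$n_identical_pairs > cfg$genes_per_chromosome * cfg$n_chromosomes)
    stop("more identical pairs than genes")
  if (cfg$n_de_pairs > cfg$n_identical_pairs)
    stop("n_de_pairs cannot exceed n_identical_pairs")
  structure(cfg, class = "simulation_config")
}

TELOMERE_MOTIF <- "TTTAGGG"

stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 48271 + stage * 9973) %% 2147483647)
}

random_dna <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

rlogunif_int <- function(n, lo, hi) {
  as.integer(round(exp(stats::runif(n, log(lo), log(hi)))))
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

## interval bookkeeping for event packing -----------------------------------

new_occupancy <- function(chrom_ids) {
  e <- new.env(parent = emptyenv())
  for (id in chrom_ids) assign(id, matrix(numeric(0), ncol = 2), envir = e)
  e
}

occ_conflicts <- function(occ, chrom, start, end, pad = 0) {
  m <- get(chrom, envir = occ)
  nrow(m) > 0 && any(m[, 1] < end + pad & m[, 2] > start - pad)
}

occ_claim <- function(occ, chrom, start, end) {
  m <- get(chrom, envir = occ)
  assign(chrom, rbind(m, c(start, end)), envir = occ)
}

# Place an interval of length len on a random chromosome, keeping `pad` bp
# clear of every previously claimed interval and `margin` bp off each end.
place_interval <- function(occ, lens, len, pad = 500, margin = 15000,
                           chrom = NULL, max_try = 2000) {
  for (i in seq_len(max_try)) {
    cid <- if (is.null(chrom))
      sample(names(lens), 1, prob = as.numeric(lens)) else chrom
    lo <- margin
    hi <- lens[[cid]] - margin - len
    if (hi <= lo) next
    s <- lo + floor(stats::runif(1) * (hi - lo))
    if (!occ_conflicts(occ, cid, s, s + len, pad)) {
      occ_claim(occ, cid, s, s + len)
      return(list(chrom = cid, start = s, end = s + len))
    }
  }
  stop("infeasible packing: could not place an interval of ", len,
       " bp; reduce event counts or lengths in the configuration")
}

## gene structure ------------------------------------------------------------

# Two-exon gene within a span: CDS length is a multiple of 3.
make_gene_structure <- function(span) {
  intron <- 100L
  cds_total <- span - intron
  cds_total <- cds_total - cds_total %% 3L
  e1 <- as.integer(floor(cds_total / 2))
  e2 <- cds_total - e1
  list(span = e1 + intron + e2,
       cds = rbind(c(0L, e1), c(e1 + intron, e1 + intron + e2)))
}

## the simulator -------------------------------------------------------------

#' Simulate a phased diploid genome with planted truth
#'
#' Builds haplotype 1, plants an edit script (SNPs, insertions, deletions,
#' inversions, translocations, HDR resequencing, unique terminal
#' segments), derives haplotype 2 exclusively through
#' [apply_edit_script()], annotates genes on both haplotypes (with a
#' controlled hemizygous subset hosted inside insertion / HDR / unique
#' regions), simulates negative-binomial expression counts for four
#' tissues, and returns the complete truth set.
#'
#' @param config a [simulation_config()].
#' @return a list of class `diploid_simulation` with elements `hap1`,
#'   `hap2` (genomes), `genes_h1`, `genes_h2`, `expr_h1`, `expr_h2`,
#'   `markers`, and `truth` (edit script, truth region calls, hemizygosity
#'   truth, homolog/identical-pair truth, DE truth, promoter-variant
#'   truth).
#' @export
simulate_diploid <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  tel <- strrep(TELOMERE_MOTIF, cfg$telomere_array_copies)
  tel_rc <- revcomp_chr(tel)
  tel_len <- nchar(tel)
  chrom_ids <- paste0("chr", seq_len(cfg$n_chromosomes))

  ## stage 1: background bodies
  set.seed(stage_seed(cfg$seed, 1L))
  bodies <- stats::setNames(
    vapply(chrom_ids, function(i)
      random_dna(cfg$chromosome_length, cfg$gc_content), character(1)),
    chrom_ids)
  body_len <- stats::setNames(rep(cfg$chromosome_length, cfg$n_chromosomes),
                              chrom_ids)

  ## stage 2: structural events on body coordinates
  set.seed(stage_seed(cfg$seed, 2L))
  occ <- new_occupancy(chrom_ids)
  ev <- list()
  add_ev <- function(type, chrom, start, end, seq = NA, ref = NA, alt = NA,
                     dst_chrom = NA, dst_pos = NA) {
    ev[[length(ev) + 1L]] <<- data.frame(
      type = type, chrom = chrom, start = start, end = end, seq = seq,
      ref = ref, alt = alt, dst_chrom = dst_chrom, dst_pos = dst_pos,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(cfg$n_inversions)) {
    len <- rlogunif_int(1, cfg$inversion_len_range[1],
                        cfg$inversion_len_range[2])
    p <- place_interval(occ, body_len, len)
    add_ev("inv", p$chrom, p$start, p$end)
  }
  for (i in seq_len(cfg$n_translocations)) {
    len <- rlogunif_int(1, cfg$translocation_len_range[1],
                        cfg$translocation_len_range[2])
    p <- place_interval(occ, body_len, len)
    dst <- place_interval(occ, body_len, 1L,
                          chrom = sample(setdiff(chrom_ids, p$chrom), 1))
    add_ev("trans", p$chrom, p$start, p$end,
           dst_chrom = dst$chrom, dst_pos = dst$start)
  }
  hdr_meta <- list()
  for (i in seq_len(cfg$n_hdrs)) {
    len <- rlogunif_int(1, cfg$hdr_len_range[1], cfg$hdr_len_range[2])
    p <- place_interval(occ, body_len, len)
    ident <- stats::runif(1, cfg$hdr_identity_range[1],
                          cfg$hdr_identity_range[2])
    hdr_meta[[i]] <- list(chrom = p$chrom, start = p$start, end = p$end,
                          identity = ident)
    add_ev("hdr", p$chrom, p$start, p$end)  # replacement seq filled later
  }
  del_meta <- list()
  for (i in seq_len(cfg$n_deletions)) {
    len <- rlogunif_int(1, cfg$indel_len_range[1], cfg$indel_len_range[2])
    p <- place_interval(occ, body_len, len)
    del_meta[[i]] <- p
    add_ev("del", p$chrom, p$start, p$end)
  }
  ins_meta <- list()
  for (i in seq_len(cfg$n_insertions)) {
    len <- rlogunif_int(1, cfg$indel_len_range[1], cfg$indel_len_range[2])
    p <- place_interval(occ, body_len, 1L)
    ins_meta[[i]] <- list(chrom = p$chrom, pos = p$start, len = len)
    add_ev("ins", p$chrom, p$start, p$start)  # seq filled after gene hosting
  }
  # haplotype-unique terminal segments: one chromosome end each, hap-1 ends
  # disjoint from hap-2 ends
  ends <- expand.grid(chrom = chrom_ids, side = c("L", "R"),
                      stringsAsFactors = FALSE)
  if (2L * cfg$n_unique_segments > nrow(ends))
    stop("not enough chromosome ends for the requested unique segments")
  pick <- sample(nrow(ends), 2L * cfg$n_unique_segments)
  u1_ends <- ends[pick[seq_len(cfg$n_unique_segments)], , drop = FALSE]
  u2_ends <- ends[pick[cfg$n_unique_segments + seq_len(cfg$n_unique_segments)],
                  , drop = FALSE]
  u1_meta <- lapply(seq_len(nrow(u1_ends)), function(i) list(
    chrom = u1_ends$chrom[i], side = u1_ends$side[i],
    len = rlogunif_int(1, cfg$unique_len_range[1], cfg$unique_len_range[2])))
  u2_meta <- lapply(seq_len(nrow(u2_ends)), function(i) list(
    chrom = u2_ends$chrom[i], side = u2_ends$side[i],
    len = rlogunif_int(1, cfg$unique_len_range[1], cfg$unique_len_range[2])))

  ## stage 3: genes
  set.seed(stage_seed(cfg$seed, 3L))
  n_genes <- cfg$genes_per_chromosome * cfg$n_chromosomes
  n_hemi <- round(cfg$hemizygous_fraction * n_genes)
  w <- cfg$hemizygous_category_weights / sum(cfg$hemizygous_category_weights)
  n_hemi_ins <- round(n_hemi * w[["insertion"]])
  n_hemi_hdr <- round(n_hemi * w[["HDR"]])
  n_hemi_unique <- max(n_hemi - n_hemi_ins - n_hemi_hdr, 0L)
  n_hom <- n_genes - n_hemi

  gene_rows_h1 <- list()  # body-coordinate gene descriptors for hap-1
  gene_rows_h2 <- list()  # descriptors resolved to hap-2 later
  add_gene_h1 <- function(chrom, start, struct, strand, origin) {
    gene_rows_h1[[length(gene_rows_h1) + 1L]] <<- list(
      chrom = chrom, start = start, span = struct$span, cds = struct$cds,
      strand = strand, origin = origin)
  }

  # homozygous genes on the shared background
  for (i in seq_len(n_hom)) {
    struct <- make_gene_structure(
      sample(cfg$gene_span_range[1]:cfg$gene_span_range[2], 1))
    p <- place_interval(occ, body_len, struct$span, pad = 200,
                        margin = 16000)
    add_gene_h1(p$chrom, p$start, struct,
                sample(c("+", "-"), 1), origin = "homozygous")
  }

  # hemizygous genes hosted inside planted regions, one list per haplotype;
  # hosting into an interval keeps 100 bp off each host edge
  host_gene <- function(host_free, span) {
    # host_free: remaining [start, end) inside the host
    if (host_free[2] - host_free[1] < span) return(NULL)
    s <- host_free[1] +
      floor(stats::runif(1) * (host_free[2] - host_free[1] - span + 1))
    s
  }
  place_in_hosts <- function(hosts, n_target, add_fun) {
    # hosts: list of list(len = usable length, meta = ...); round-robin
    placed <- 0L
    free <- lapply(hosts, function(h) c(100L, h$len - 100L))
    while (placed < n_target) {
      progressed <- FALSE
      for (hi in seq_along(hosts)) {
        if (placed >= n_target) break
        struct <- make_gene_structure(
          sample(cfg$gene_span_range[1]:cfg$gene_span_range[2], 1))
        s <- host_gene(free[[hi]], struct$span)
        if (is.null(s)) next
        add_fun(hosts[[hi]]$meta, s, struct, sample(c("+", "-"), 1))
        free[[hi]][1] <- s + struct$span + 200L
        placed <- placed + 1L
        progressed <- TRUE
      }
      if (!progressed) break
    }
    placed
  }

  # hap-1 hemizygous in deletion intervals (hap-1-specific sequence)
  del_hosts <- lapply(del_meta, function(p)
    list(len = p$end - p$start, meta = p))
  del_hosts <- del_hosts[vapply(del_hosts, function(h)
    h$len >= cfg$gene_span_range[1] + 200L, logical(1))]
  place_in_hosts(del_hosts, n_hemi_ins, function(meta, s, struct, strand)
    add_gene_h1(meta$chrom, meta$start + s, struct, strand, "hemi_insertion"))
  # hap-1 hemizygous in HDR intervals (hap-1 side)
  hdr_hosts <- lapply(hdr_meta, function(p)
    list(len = p$end - p$start, meta = p))
  place_in_hosts(hdr_hosts, n_hemi_hdr, function(meta, s, struct, strand)
    add_gene_h1(meta$chrom, meta$start + s, struct, strand, "hemi_HDR"))
  # hap-1 hemizygous in hap-1-unique terminal segments (segment-local coords)
  u1_hosts <- lapply(seq_along(u1_meta), function(i)
    list(len = u1_meta[[i]]$len, meta = i))
  place_in_hosts(u1_hosts, n_hemi_unique, function(meta, s, struct, strand) {
    u1_meta[[meta]]$genes[[length(u1_meta[[meta]]$genes) + 1L]] <<-
      list(offset = s, cds = struct$cds, span = struct$span, strand = strand)
  })

  # hap-2 hemizygous: in insertion sequences, HDR (hap-2 side), unique
  add_gene_h2 <- function(kind, meta, s, struct, strand) {
    gene_rows_h2[[length(gene_rows_h2) + 1L]] <<- list(
      kind = kind, meta = meta, offset = s, span = struct$span,
      cds = struct$cds, strand = strand)
  }
  ins_hosts <- lapply(seq_along(ins_meta), function(i)
    list(len = ins_meta[[i]]$len, meta = i))
  ins_hosts <- ins_hosts[vapply(ins_hosts, function(h)
    h$len >= cfg$gene_span_range[1] + 200L, logical(1))]
  place_in_hosts(ins_hosts, n_hemi_ins, function(meta, s, struct, strand)
    add_gene_h2("insertion", meta, s, struct, strand))
  place_in_hosts(hdr_hosts, n_hemi_hdr, function(meta, s, struct, strand)
    add_gene_h2("HDR", meta, s, struct, strand))
  u2_hosts <- lapply(seq_along(u2_meta), function(i)
    list(len = u2_meta[[i]]$len, meta = i))
  place_in_hosts(u2_hosts, n_hemi_unique, function(meta, s, struct, strand)
    add_gene_h2("unique", meta, s, struct, strand))

  # identical-pair designation among homozygous genes
  hom_idx <- which(vapply(gene_rows_h1, function(g)
    g$origin == "homozygous", logical(1)))
  n_ident <- min(cfg$n_identical_pairs, length(hom_idx))
  ident_idx <- sort(sample(hom_idx, n_ident))

  # DE designation: identical pairs whose promoter window is on-chromosome
  promoter_body_window <- function(g) {
    if (g$strand == "+")
      c(g$start - cfg$promoter_window, g$start)
    else
      c(g$start + g$span, g$start + g$span + cfg$promoter_window)
  }
  de_candidates <- ident_idx[vapply(ident_idx, function(i) {
    wnd <- promoter_body_window(gene_rows_h1[[i]])
    wnd[1] >= 0 && wnd[2] <= body_len[[gene_rows_h1[[i]]$chrom]]
  }, logical(1))]
  n_de <- min(cfg$n_de_pairs, length(de_candidates))
  de_idx <- sort(sample(de_candidates, n_de))

  # planted promoter variants for DE genes: extra SNPs (and one small
  # insertion) in the 3-kb upstream window, kept off claimed intervals
  prom_snp <- list()   # list of (chrom, pos)
  for (i in de_idx) {
    g <- gene_rows_h1[[i]]
    wnd <- promoter_body_window(g)
    # one small insertion near the window edge farthest from the gene
    if (cfg$promoter_extra_sv) {
      len <- sample(80:150, 1)
      at <- if (g$strand == "+") wnd[1] + 150L else wnd[2] - 150L
      if (!occ_conflicts(occ, g$chrom, at, at + 1L, pad = 120)) {
        occ_claim(occ, g$chrom, at - 120L, at + 120L)
        ins_meta[[length(ins_meta) + 1L]] <-
          list(chrom = g$chrom, pos = at, len = len)
        add_ev("ins", g$chrom, at, at)
      }
    }
    lo <- wnd[1] + 400L; hi <- wnd[2] - 50L
    cand <- sample(lo:hi, min(cfg$promoter_extra_snps * 3L, hi - lo))
    ok <- !vapply(cand, function(p)
      occ_conflicts(occ, g$chrom, p, p + 1L, pad = 100), logical(1))
    take <- utils::head(cand[ok], cfg$promoter_extra_snps)
    for (p in take)
      prom_snp[[length(prom_snp) + 1L]] <- list(chrom = g$chrom, pos = p)
  }

  ## stage 4: background SNPs
  set.seed(stage_seed(cfg$seed, 4L))
  protected <- lapply(stats::setNames(chrom_ids, chrom_ids),
                      function(x) matrix(numeric(0), ncol = 2))
  for (i in ident_idx) {
    g <- gene_rows_h1[[i]]
    abs_cds <- g$cds + g$start
    protected[[g$chrom]] <- rbind(protected[[g$chrom]], abs_cds)
  }
  snp_rows <- list()
  for (cid in chrom_ids) {
    # eligible = body minus structural events (padded) minus shielded CDS
    occm <- get(cid, envir = occ)
    # only structural events need padding; gene claims need no SNP shield,
    # so rebuild the exclusion set from event metadata
    excl <- matrix(numeric(0), ncol = 2)
    for (e in ev) if (e$chrom == cid && e$type != "snp")
      excl <- rbind(excl, c(e$start - 100, e$end + 100))
    for (e in ev) if (!is.na(e$dst_chrom) && e$dst_chrom == cid)
      excl <- rbind(excl, c(e$dst_pos - 100, e$dst_pos + 100))
    excl <- rbind(excl, protected[[cid]])
    excl_ir <- IRanges::reduce(IRanges::IRanges(
      pmax(excl[, 1], 0) + 1, pmin(excl[, 2], body_len[[cid]])))
    allowed <- IRanges::setdiff(
      IRanges::IRanges(1, body_len[[cid]]), excl_ir)
    pos_pool <- unlist(lapply(seq_along(allowed), function(j)
      IRanges::start(allowed)[j]:IRanges::end(allowed)[j])) - 1L
    n_snp <- round(cfg$snp_rate * length(pos_pool))
    if (n_snp > 0) {
      pos <- sort(sample(pos_pool, n_snp))
      snp_rows[[cid]] <- data.frame(chrom = cid, pos = pos,
                                    stringsAsFactors = FALSE)
    }
  }
  if (length(prom_snp) > 0) {
    ps <- do.call(rbind, lapply(prom_snp, function(x)
      data.frame(chrom = x$chrom, pos = x$pos, stringsAsFactors = FALSE)))
    snp_rows[["promoter"]] <- ps
  }
  snps <- if (length(snp_rows) > 0) do.call(rbind, snp_rows) else
    data.frame(chrom = character(), pos = integer())
  snps <- snps[!duplicated(snps[c("chrom", "pos")]), , drop = FALSE]

  ## assemble hap-1, resolve sequences, shift coordinates ---------------
  set.seed(stage_seed(cfg$seed, 5L))
  # left-end insert offsets per chromosome (telomere + optional unique seg)
  u1_by_end <- function(cid, side) {
    hit <- vapply(u1_meta, function(u)
      u$chrom == cid && u$side == side, logical(1))
    if (any(hit)) u1_meta[[which(hit)[1]]] else NULL
  }
  u2_by_end <- function(cid, side) {
    hit <- vapply(u2_meta, function(u)
      u$chrom == cid && u$side == side, logical(1))
    if (any(hit)) u2_meta[[which(hit)[1]]] else NULL
  }
  # generate the unique segment / insertion sequences (genes embedded are
  # simply part of the random sequence; coordinates recorded)
  for (i in seq_along(u1_meta))
    u1_meta[[i]]$seq <- random_dna(u1_meta[[i]]$len, cfg$gc_content)
  for (i in seq_along(u2_meta))
    u2_meta[[i]]$seq <- random_dna(u2_meta[[i]]$len, cfg$gc_content)
  for (i in seq_along(ins_meta))
    ins_meta[[i]]$seq <- random_dna(ins_meta[[i]]$len, cfg$gc_content)
  # HDR replacement sequences: substitute (1 - identity) of bases
  hdr_seqs <- lapply(hdr_meta, function(h) {
    seg <- substr(bodies[[h$chrom]], h$start + 1L, h$end)
    v <- strsplit(seg, "", fixed = TRUE)[[1]]
    n_sub <- round((1 - h$identity) * length(v))
    at <- sample(length(v), n_sub)
    v[at] <- vapply(v[at], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    paste(v, collapse = "")
  })

  hap1_seqs <- character(0)
  left_off <- stats::setNames(integer(cfg$n_chromosomes), chrom_ids)
  for (cid in chrom_ids) {
    uL <- u1_by_end(cid, "L"); uR <- u1_by_end(cid, "R")
    left_off[[cid]] <- tel_len + (if (is.null(uL)) 0L else uL$len)
    hap1_seqs[[cid]] <- paste0(
      tel_rc, if (is.null(uL)) "" else uL$seq, bodies[[cid]],
      if (is.null(uR)) "" else uR$seq, tel)
  }
  hap1 <- haplotype_genome(hap1_seqs, "hap1")
  hap1_len <- chrom_lengths(hap1)

  ## edit script on final hap-1 coordinates ------------------------------
  sh <- function(cid, pos) pos + left_off[[cid]]   # body -> hap-1 coords
  script <- list()
  add_op <- function(type, chrom, start, end, seq = NA_character_,
                     ref = NA_character_, alt = NA_character_,
                     dst_chrom = NA_character_, dst_pos = NA_integer_) {
    script[[length(script) + 1L]] <<- data.frame(
      type = type, chrom = chrom, start = as.integer(start),
      end = as.integer(end), seq = seq, ref = ref, alt = alt,
      dst_chrom = dst_chrom, dst_pos = as.integer(dst_pos),
      stringsAsFactors = FALSE)
  }
  hdr_i <- 0L
  for (e in ev) {
    if (e$type == "inv") add_op("inv", e$chrom, sh(e$chrom, e$start),
                                sh(e$chrom, e$end))
    else if (e$type == "del") add_op("del", e$chrom, sh(e$chrom, e$start),
                                     sh(e$chrom, e$end))
    else if (e$type == "hdr") {
      hdr_i <- hdr_i + 1L
      add_op("hdr", e$chrom, sh(e$chrom, e$start), sh(e$chrom, e$end),
             seq = hdr_seqs[[hdr_i]])
    } else if (e$type == "trans")
      add_op("trans", e$chrom, sh(e$chrom, e$start), sh(e$chrom, e$end),
             dst_chrom = e$dst_chrom, dst_pos = sh(e$dst_chrom, e$dst_pos))
  }
  for (m in ins_meta)
    add_op("ins", m$chrom, sh(m$chrom, m$pos), sh(m$chrom, m$pos),
           seq = m$seq)
  for (u in u1_meta) {
    s <- if (u$side == "L") tel_len else hap1_len[[u$chrom]] - tel_len - u$len
    add_op("udel", u$chrom, s, s + u$len)
  }
  for (u in u2_meta) {
    p <- if (u$side == "L") {
      uL <- u1_by_end(u$chrom, "L")
      tel_len + (if (is.null(uL)) 0L else uL$len)  # just inside hap-1 left end
    } else hap1_len[[u$chrom]] - tel_len
    add_op("uins", u$chrom, p, p, seq = u$seq)
  }
  # SNPs: alt base differs from ref
  if (nrow(snps) > 0) {
    bases <- c("A", "C", "G", "T")
    for (cid in unique(snps$chrom)) {
      sub <- snps[snps$chrom == cid, , drop = FALSE]
      pos1 <- sh(cid, sub$pos)
      refb <- substring(hap1_seqs[[cid]], pos1 + 1L, pos1 + 1L)
      # alt = ref shifted by a uniform 1..3 step around the base cycle
      shift <- sample.int(3L, length(refb), replace = TRUE)
      altb <- bases[(match(refb, bases) - 1L + shift) %% 4L + 1L]
      script[[length(script) + 1L]] <- data.frame(
        type = "snp", chrom = cid, start = as.integer(pos1),
        end = as.integer(pos1 + 1L), seq = NA_character_, ref = refb,
        alt = altb, dst_chrom = NA_character_, dst_pos = NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  script <- if (length(script)) do.call(rbind, script) else
    data.frame(type = character(), chrom = character(), start = integer(),
               end = integer(), seq = character(), ref = character(),
               alt = character(), dst_chrom = character(),
               dst_pos = integer(), stringsAsFactors = FALSE)
  script <- script[order(script$chrom, script$start,
                         script$type != "uins"), ]
  rownames(script) <- NULL

  ## hap-2 via the edit script (single source of truth)
  hap2 <- apply_edit_script(hap1, script)
  hap2_len <- chrom_lengths(hap2)

  ## coordinate mapper hap-1 -> hap-2 ------------------------------------
  mapper <- make_pos_mapper(script)

  ## gene tables ----------------------------------------------------------
  g1 <- list(); g2 <- list()
  pair_of <- integer(0)  # for homozygous genes: index linking g1/g2 rows
  for (i in seq_along(gene_rows_h1)) {
    g <- gene_rows_h1[[i]]
    s1 <- sh(g$chrom, g$start)
    g1[[length(g1) + 1L]] <- list(
      chrom = g$chrom, start = s1, end = s1 + g$span, cds = g$cds + s1,
      strand = g$strand, origin = g$origin, sim_idx = i)
    if (g$origin == "homozygous") {
      s2 <- mapper(g$chrom, s1)
      g2[[length(g2) + 1L]] <- list(
        chrom = g$chrom, start = s2, end = s2 + g$span, cds = g$cds + s2,
        strand = g$strand, origin = "homozygous", sim_idx = i)
    }
  }
  # hap-1-unique hosted genes
  for (u in u1_meta) {
    if (is.null(u$genes)) next
    base <- if (u$side == "L") tel_len else
      hap1_len[[u$chrom]] - tel_len - u$len
    for (gg in u$genes) {
      s1 <- base + gg$offset
      g1[[length(g1) + 1L]] <- list(
        chrom = u$chrom, start = s1, end = s1 + gg$span, cds = gg$cds + s1,
        strand = gg$strand, origin = "hemi_unique", sim_idx = NA)
    }
  }
  # hap-2 hosted genes
  ins_q_start <- function(m) mapper(m$chrom, sh(m$chrom, m$pos),
                                    before_insert = TRUE)
  for (h in gene_rows_h2) {
    if (h$kind == "insertion") {
      m <- ins_meta[[h$meta]]
      s2 <- ins_q_start(m) + h$offset
      cid <- m$chrom
    } else if (h$kind == "HDR") {
      m <- h$meta  # hdr placement record (body coords)
      s2 <- mapper(m$chrom, sh(m$chrom, m$start)) + h$offset
      cid <- m$chrom
    } else { # unique
      u <- u2_meta[[h$meta]]
      p <- if (u$side == "L") {
        uL <- u1_by_end(u$chrom, "L")
        tel_len + (if (is.null(uL)) 0L else uL$len)
      } else hap1_len[[u$chrom]] - tel_len
      s2 <- mapper(u$chrom, p, before_insert = TRUE) + h$offset
      cid <- u$chrom
    }
    g2[[length(g2) + 1L]] <- list(
      chrom = cid, start = s2, end = s2 + h$span, cds = h$cds + s2,
      strand = h$strand, origin = paste0("hemi_", h$kind), sim_idx = NA)
  }

  build_gene_df <- function(gl, hap, genome) {
    o <- order(vapply(gl, `[[`, "", "chrom"),
               vapply(gl, function(x) x$start, numeric(1)))
    gl <- gl[o]
    df <- data.frame(
      gene_id = sprintf("%sg%04d", sub("hap", "h", hap), seq_along(gl)),
      haplotype = hap,
      chrom = vapply(gl, `[[`, "", "chrom"),
      strand = vapply(gl, `[[`, "", "strand"),
      start = vapply(gl, function(x) as.integer(x$start), integer(1)),
      end = vapply(gl, function(x) as.integer(x$end), integer(1)),
      stringsAsFactors = FALSE)
    df$cds <- lapply(gl, function(x) {
      m <- x$cds; storage.mode(m) <- "integer"; m
    })
    df$origin <- vapply(gl, `[[`, "", "origin")
    df$sim_idx <- vapply(gl, function(x)
      if (is.na(x$sim_idx[1])) NA_integer_ else as.integer(x$sim_idx),
      integer(1))
    gene_models(df, genome)
  }
  genes_h1 <- build_gene_df(g1, "hap1", hap1)
  genes_h2 <- build_gene_df(g2, "hap2", hap2)

  ## truth tables ----------------------------------------------------------
  hom1 <- genes_h1[genes_h1$origin == "homozygous", ]
  hom2 <- genes_h2[genes_h2$origin == "homozygous", ]
  hom2_id <- stats::setNames(hom2$gene_id, hom2$sim_idx)
  homolog_truth <- data.frame(
    gene_id_h1 = hom1$gene_id,
    gene_id_h2 = as.character(hom2_id[as.character(hom1$sim_idx)]),
    stringsAsFactors = FALSE)
  cds1 <- stats::setNames(hom1$cds_seq, hom1$gene_id)
  cds2 <- stats::setNames(hom2$cds_seq, hom2$gene_id)
  homolog_truth$identical <-
    cds1[homolog_truth$gene_id_h1] == cds2[homolog_truth$gene_id_h2]
  homolog_truth$designated <- hom1$sim_idx %in% ident_idx

  hemi_cat <- function(origin) c(
    homozygous = NA, hemi_insertion = "insertion", hemi_HDR = "HDR",
    hemi_unique = "unique")[origin]
  hemizygosity_truth <- rbind(
    data.frame(gene_id = genes_h1$gene_id, haplotype = "hap1",
               status = ifelse(genes_h1$origin == "homozygous",
                               "homozygous", "hemizygous"),
               category = unname(hemi_cat(genes_h1$origin)),
               stringsAsFactors = FALSE),
    data.frame(gene_id = genes_h2$gene_id, haplotype = "hap2",
               status = ifelse(genes_h2$origin == "homozygous",
                               "homozygous", "hemizygous"),
               category = unname(hemi_cat(genes_h2$origin)),
               stringsAsFactors = FALSE))

  de_truth <- data.frame(
    gene_id_h1 = hom1$gene_id[hom1$sim_idx %in% de_idx],
    gene_id_h2 = as.character(hom2_id[as.character(
      hom1$sim_idx[hom1$sim_idx %in% de_idx])]),
    stringsAsFactors = FALSE)
  de_truth$up_haplotype <- sample(c("hap1", "hap2"), nrow(de_truth),
                                  replace = TRUE)
  de_truth$fold <- rep(cfg$cis_effect_fold, nrow(de_truth))

  ## truth region calls ----------------------------------------------------
  truth_regions <- build_truth_regions(script, hap1_len, hap2_len, tel_len,
                                       mapper)

  ## promoter-variant truth -------------------------------------------------
  promoter_truth <- promoter_variant_truth(script, genes_h1, genes_h2,
                                           mapper, cfg$promoter_window,
                                           hap1_len, hap2_len)

  ## stage 6: expression ----------------------------------------------------
  set.seed(stage_seed(cfg$seed, 6L))
  expr <- simulate_expression(cfg, genes_h1, genes_h2, homolog_truth,
                              de_truth)

  ## stage 7: genetic map ---------------------------------------------------
  set.seed(stage_seed(cfg$seed, 7L))
  markers <- do.call(rbind, lapply(chrom_ids, function(cid) {
    bp <- sort(sample(hap1_len[[cid]], cfg$n_map_markers))
    data.frame(marker_id = sprintf("%s_m%03d", cid,
                                   seq_len(cfg$n_map_markers)),
               chrom = cid,
               cM = round(cumsum(stats::runif(cfg$n_map_markers, 0.5, 1.5)),
                          3),
               bp = bp, stringsAsFactors = FALSE)
  }))

  truth <- list(edit_script = script, regions = truth_regions,
                hemizygosity = hemizygosity_truth,
                homolog_pairs = homolog_truth, de = de_truth,
                promoter_variants = promoter_truth,
                expression_means = expr$means, config = cfg)
  structure(list(hap1 = hap1, hap2 = hap2, genes_h1 = genes_h1,
                 genes_h2 = genes_h2, expr_h1 = expr$h1, expr_h2 = expr$h2,
                 markers = markers, truth = truth),
            class = "diploid_simulation")
}
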