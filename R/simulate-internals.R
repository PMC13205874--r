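## Edit-script machinery shared by the simulator and its verification hook.

#' Apply an edit script to a haplotype genome
#'
#' Transforms haplotype 1 into haplotype 2 by applying, per chromosome:
#' SNP substitutions (`snp`), HDR resequencing (`hdr`, same-length
#' replacement), then structural edits -- insertions (`ins`), deletions
#' (`del`), inversions (`inv`), cut-and-paste translocations (`trans`),
#' and haplotype-unique terminal segments (`udel` removes hap-1-only
#' sequence, `uins` adds hap-2-only sequence). The simulator only ever
#' produces hap-2 through this function, so the planted truth is exact by
#' construction; calling it independently verifies that invariant.
#'
#' @param genome a `haplotype_genome` (haplotype 1).
#' @param script an edit-script data frame as produced by
#'   [simulate_diploid()] (`truth$edit_script`).
#' @return the derived `haplotype_genome` labelled `hap2`.
#' @export
apply_edit_script <- function(genome, script) {
  chrom_ids <- names(genome$seqs)
  if (!all(script$chrom %in% chrom_ids))
    stop("edit script references unknown chromosome")
  # overlap validation over structural footprints (per chromosome)
  for (cid in chrom_ids) {
    s <- script[script$chrom == cid & script$type != "snp", , drop = FALSE]
    d <- script[!is.na(script$dst_chrom) & script$dst_chrom == cid, ,
                drop = FALSE]
    iv <- rbind(
      if (nrow(s)) cbind(s$start, pmax(s$end, s$start + 1L)),
      if (nrow(d)) cbind(d$dst_pos, d$dst_pos + 1L))
    if (!is.null(iv) && nrow(iv) > 1L) {
      iv <- iv[order(iv[, 1]), , drop = FALSE]
      if (any(iv[-1, 1] < iv[-nrow(iv), 2]))
        stop("overlapping edits on ", cid)
    }
  }

  vecs <- lapply(chrom_ids, function(cid)
    strsplit(as.character(genome$seqs[[cid]]), "", fixed = TRUE)[[1]])
  names(vecs) <- chrom_ids

  # point substitutions
  snps <- script[script$type == "snp", , drop = FALSE]
  for (cid in unique(snps$chrom)) {
    sub <- snps[snps$chrom == cid, ]
    have <- vecs[[cid]][sub$start + 1L]
    if (!all(have == sub$ref))
      stop("SNP ref mismatch on ", cid, " at offset ",
           sub$start[which(have != sub$ref)[1]])
    vecs[[cid]][sub$start + 1L] <- sub$alt
  }
  # HDR resequencing (same length)
  hdrs <- script[script$type == "hdr", , drop = FALSE]
  for (i in seq_len(nrow(hdrs))) {
    h <- hdrs[i, ]
    repl <- strsplit(h$seq, "", fixed = TRUE)[[1]]
    if (length(repl) != h$end - h$start)
      stop("HDR replacement length mismatch")
    vecs[[h$chrom]][(h$start + 1L):h$end] <- repl
  }

  # structural pass: extract translocated segments first (post-substitution)
  trans <- script[script$type == "trans", , drop = FALSE]
  trans_seg <- lapply(seq_len(nrow(trans)), function(i)
    paste(vecs[[trans$chrom[i]]][(trans$start[i] + 1L):trans$end[i]],
          collapse = ""))

  out <- character(0)
  for (cid in chrom_ids) {
    ops <- script[script$chrom == cid &
                    script$type %in% c("ins", "uins", "del", "udel",
                                       "inv", "trans"), , drop = FALSE]
    # synthesized insertions for translocations landing on this chromosome
    land <- which(!is.na(trans$dst_chrom) & trans$dst_chrom == cid)
    if (length(land)) {
      ops <- rbind(ops, data.frame(
        type = "ins", chrom = cid, start = trans$dst_pos[land],
        end = trans$dst_pos[land], seq = unlist(trans_seg[land]),
        ref = NA, alt = NA, dst_chrom = NA, dst_pos = NA,
        stringsAsFactors = FALSE))
    }
    ops <- ops[order(ops$start, ops$start != ops$end), , drop = FALSE]
    v <- vecs[[cid]]
    pieces <- character(0)
    cur <- 0L
    for (i in seq_len(nrow(ops))) {
      o <- ops[i, ]
      if (o$start > cur)
        pieces <- c(pieces, paste(v[(cur + 1L):o$start], collapse = ""))
      if (o$type %in% c("ins", "uins")) {
        pieces <- c(pieces, o$seq)
        cur <- o$start
      } else if (o$type %in% c("del", "udel", "trans")) {
        cur <- o$end
      } else if (o$type == "inv") {
        pieces <- c(pieces, revcomp_chr(
          paste(v[(o$start + 1L):o$end], collapse = "")))
        cur <- o$end
      }
    }
    if (cur < length(v))
      pieces <- c(pieces, paste(v[(cur + 1L):length(v)], collapse = ""))
    out[[cid]] <- paste(pieces, collapse = "")
  }
  haplotype_genome(out, "hap2")
}

# Build a hap-1 -> hap-2 coordinate mapper from the edit script.
# mapper(chrom, pos) maps a hap-1 position lying outside removed segments;
# `before_insert = TRUE` excludes length gained by edits at exactly `pos`
# (giving the hap-2 start of an insertion at that point).
make_pos_mapper <- function(script) {
  tabs <- list()
  add <- function(cid, eff, delta) {
    tabs[[cid]] <<- rbind(tabs[[cid]], c(eff, delta))
  }
  for (i in seq_len(nrow(script))) {
    o <- script[i, ]
    if (o$type %in% c("ins", "uins")) add(o$chrom, o$start, nchar(o$seq))
    else if (o$type %in% c("del", "udel"))
      add(o$chrom, o$end, -(o$end - o$start))
    else if (o$type == "trans") {
      add(o$chrom, o$end, -(o$end - o$start))
      add(o$dst_chrom, o$dst_pos, o$end - o$start)
    }
  }
  tabs <- lapply(tabs, function(m) m[order(m[, 1]), , drop = FALSE])
  function(chrom, pos, before_insert = FALSE) {
    m <- tabs[[chrom]]
    if (is.null(m)) return(pos)
    keep <- if (before_insert) m[, 1] < pos else m[, 1] <= pos
    pos + sum(m[keep, 2])
  }
}

# Emit the truth region partition implied by an edit script: SYN between
# events, one call per planted event, telomeres excluded.
build_truth_regions <- function(script, hap1_len, hap2_len, tel_len,
                                mapper) {
  cap <- 2L * nrow(script) + 4L * length(hap1_len) + 8L
  RC <- character(cap); RS <- integer(cap); RE <- integer(cap)
  QC <- character(cap); QS <- integer(cap); QE <- integer(cap)
  TY <- character(cap); RB <- character(cap); QB <- character(cap)
  k <- 0L
  emit <- function(type, rc, rs, re, qc, qs, qe, rb = NA, qb = NA) {
    k <<- k + 1L
    RC[k] <<- rc; RS[k] <<- rs; RE[k] <<- re
    QC[k] <<- qc; QS[k] <<- qs; QE[k] <<- qe
    TY[k] <<- type; RB[k] <<- rb; QB[k] <<- qb
  }
  trans <- script[script$type == "trans", , drop = FALSE]
  for (cid in names(hap1_len)) {
    ops <- script[script$chrom == cid, , drop = FALSE]
    land <- which(!is.na(trans$dst_chrom) & trans$dst_chrom == cid)
    if (length(land)) {
      ops <- rbind(ops, data.frame(
        type = "transdst", chrom = cid, start = trans$dst_pos[land],
        end = trans$dst_pos[land],
        seq = NA, ref = NA, alt = NA, dst_chrom = NA,
        dst_pos = trans$end[land] - trans$start[land],  # reuse: length
        stringsAsFactors = FALSE))
    }
    ops <- ops[order(ops$start, ops$start != ops$end), , drop = FALSE]
    typ <- ops$type; ost <- ops$start; oen <- ops$end
    osq <- ops$seq; orf <- ops$ref; oal <- ops$alt
    odc <- ops$dst_chrom; odp <- ops$dst_pos
    r_cur <- tel_len
    q_cur <- tel_len
    for (i in seq_along(typ)) {
      if (ost[i] > r_cur) {
        emit("SYN", cid, r_cur, ost[i], cid, q_cur,
             q_cur + (ost[i] - r_cur))
        q_cur <- q_cur + (ost[i] - r_cur)
        r_cur <- ost[i]
      }
      t <- typ[i]
      if (t == "snp") {
        emit("SNP", cid, ost[i], ost[i] + 1L, cid, q_cur, q_cur + 1L,
             orf[i], oal[i])
        r_cur <- r_cur + 1L; q_cur <- q_cur + 1L
      } else if (t == "ins") {
        L <- nchar(osq[i])
        emit("INS", cid, ost[i], ost[i], cid, q_cur, q_cur + L)
        q_cur <- q_cur + L
      } else if (t == "uins") {
        L <- nchar(osq[i])
        emit("NOTAL", NA, NA, NA, cid, q_cur, q_cur + L)
        q_cur <- q_cur + L
      } else if (t == "del") {
        emit("DEL", cid, ost[i], oen[i], cid, q_cur, q_cur)
        r_cur <- oen[i]
      } else if (t == "udel") {
        emit("NOTAL", cid, ost[i], oen[i], NA, NA, NA)
        r_cur <- oen[i]
      } else if (t == "inv") {
        emit("INV", cid, ost[i], oen[i], cid, q_cur,
             q_cur + (oen[i] - ost[i]))
        r_cur <- oen[i]; q_cur <- q_cur + (oen[i] - ost[i])
      } else if (t == "hdr") {
        emit("HDR", cid, ost[i], oen[i], cid, q_cur,
             q_cur + (oen[i] - ost[i]))
        r_cur <- oen[i]; q_cur <- q_cur + (oen[i] - ost[i])
      } else if (t == "trans") {
        dq <- mapper(odc[i], odp[i], before_insert = TRUE)
        emit("TRANS", cid, ost[i], oen[i], odc[i], dq,
             dq + (oen[i] - ost[i]))
        r_cur <- oen[i]
      } else if (t == "transdst") {
        q_cur <- q_cur + odp[i]  # dst_pos column reused as length
      }
    }
    r_end <- hap1_len[[cid]] - tel_len
    q_end <- hap2_len[[cid]] - tel_len
    if (r_end > r_cur)
      emit("SYN", cid, r_cur, r_end, cid, q_cur, q_cur + (r_end - r_cur))
    if (q_cur + (r_end - r_cur) != q_end)
      stop("internal truth bookkeeping error on ", cid)
  }
  idx <- seq_len(k)
  validate_region_calls(data.frame(
    ref_chrom = RC[idx], ref_start = RS[idx], ref_end = RE[idx],
    qry_chrom = QC[idx], qry_start = QS[idx], qry_end = QE[idx],
    type = TY[idx], ref_base = RB[idx], qry_base = QB[idx],
    stringsAsFactors = FALSE))
}

# Per-gene planted-variant counts within the (strand-aware) promoter
# window, on each gene's own haplotype coordinates.
promoter_variant_truth <- function(script, genes_h1, genes_h2, mapper,
                                   window, hap1_len, hap2_len) {
  # hap-1 and hap-2 footprints of every op
  n <- nrow(script)
  f1c <- script$chrom
  f1s <- script$start
  f1e <- ifelse(script$type %in% c("ins", "uins"), script$start, script$end)
  f2c <- ifelse(script$type == "trans", script$dst_chrom, script$chrom)
  f2s <- integer(n); f2e <- integer(n)
  typ <- script$type; ch <- script$chrom; st <- script$start
  en <- script$end; sq <- script$seq
  for (i in seq_len(n)) {
    if (typ[i] %in% c("ins", "uins")) {
      q <- mapper(ch[i], st[i], before_insert = TRUE)
      f2s[i] <- q; f2e[i] <- q + nchar(sq[i])
    } else if (typ[i] %in% c("del", "udel")) {
      q <- mapper(ch[i], en[i])
      f2s[i] <- q; f2e[i] <- q
    } else if (typ[i] == "trans") {
      q <- mapper(script$dst_chrom[i], script$dst_pos[i],
                  before_insert = TRUE)
      f2s[i] <- q; f2e[i] <- q + (en[i] - st[i])
    } else {
      q <- mapper(ch[i], st[i])
      f2s[i] <- q; f2e[i] <- q + (en[i] - st[i])
    }
  }
  is_snp <- script$type == "snp"
  count_side <- function(genes, fc, fs, fe, lens) {
    out <- data.frame(gene_id = genes$gene_id,
                      haplotype = genes$haplotype,
                      snp_count = 0L, sv_count = 0L,
                      stringsAsFactors = FALSE)
    gch <- genes$chrom; gst <- genes$start; gen <- genes$end
    gstr <- genes$strand
    for (i in seq_len(nrow(genes))) {
      if (gstr[i] == "+") {
        ps <- max(gst[i] - window, 0L); pe <- gst[i]
      } else {
        ps <- gen[i]; pe <- min(gen[i] + window, lens[[gch[i]]])
      }
      on_chrom <- fc == gch[i]
      ov <- on_chrom & (pmax(fs, ps) < pmin(fe, pe) |
                          (fs == fe & fs >= ps & fs < pe))
      out$snp_count[i] <- sum(ov & is_snp)
      out$sv_count[i] <- sum(ov & !is_snp)
    }
    out$total <- out$snp_count + out$sv_count
    out
  }
  rbind(count_side(genes_h1, f1c, f1s, f1e, hap1_len),
        count_side(genes_h2, f2c, f2s, f2e, hap2_len))
}

# Negative-binomial expression counts with planted cis effects.
simulate_expression <- function(cfg, genes_h1, genes_h2, homolog_truth,
                                de_truth) {
  n1 <- nrow(genes_h1); n2 <- nrow(genes_h2)
  tiss <- rep(TISSUES, each = cfg$replicates_per_tissue)
  reps <- rep(seq_len(cfg$replicates_per_tissue), length(TISSUES))
  # per-gene baselines on hap-1, shared with the hap-2 partner
  base1 <- stats::rlnorm(n1, log(150), 1)
  tf1 <- matrix(stats::rlnorm(n1 * length(TISSUES), 0, 0.3), n1,
                dimnames = list(genes_h1$gene_id, TISSUES))
  mean1 <- base1 * tf1
  hemi1 <- genes_h1$origin != "homozygous"
  mean1[hemi1, ] <- mean1[hemi1, ] * cfg$hemizygous_expression_fold

  mean2 <- matrix(NA_real_, n2, length(TISSUES),
                  dimnames = list(genes_h2$gene_id, TISSUES))
  mean2[homolog_truth$gene_id_h2, ] <- mean1[homolog_truth$gene_id_h1, ]
  hemi2 <- is.na(mean2[, 1])
  base2 <- stats::rlnorm(sum(hemi2), log(150), 1)
  tf2 <- matrix(stats::rlnorm(sum(hemi2) * length(TISSUES), 0, 0.3),
                sum(hemi2))
  mean2[hemi2, ] <- base2 * tf2 * cfg$hemizygous_expression_fold

  for (i in seq_len(nrow(de_truth))) {
    if (de_truth$up_haplotype[i] == "hap1")
      mean1[de_truth$gene_id_h1[i], ] <-
        mean1[de_truth$gene_id_h1[i], ] * de_truth$fold[i]
    else
      mean2[de_truth$gene_id_h2[i], ] <-
        mean2[de_truth$gene_id_h2[i], ] * de_truth$fold[i]
  }

  draw <- function(means) {
    counts <- matrix(0L, nrow(means), length(tiss),
                     dimnames = list(rownames(means), NULL))
    for (j in seq_along(tiss))
      counts[, j] <- stats::rnbinom(nrow(means), mu = means[, tiss[j]],
                                    size = 1 / cfg$nb_dispersion)
    counts
  }
  c1 <- draw(mean1); c2 <- draw(mean2)
  list(
    h1 = expression_matrix(c1, tiss, reps,
                           stats::setNames(genes_h1$cds_len,
                                           genes_h1$gene_id), "hap1"),
    h2 = expression_matrix(c2, tiss, reps,
                           stats::setNames(genes_h2$cds_len,
                                           genes_h2$gene_id), "hap2"),
    means = list(h1 = mean1, h2 = mean2))
}
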