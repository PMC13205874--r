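## Anchor-based haplotype comparison producing the SyRI-style region
## partition (SYN / INV / TRANS / INS / DEL / HDR / NOTAL / SNP).

#' Find unique k-mer anchors between two genomes
#'
#' Anchors are k-mers occurring exactly once in each genome under
#' strand-canonical counting (a k-mer and its reverse complement are the
#' same object; k must be odd so no k-mer is its own reverse complement).
#' k-mers containing N are never anchors. Each anchor records the
#' forward-strand start of the k-mer in both genomes and whether the match
#' is direct (`forward`) or reverse-complemented.
#'
#' @param ref,qry `haplotype_genome` objects.
#' @param k odd k-mer size, 11 <= k <= 63.
#' @return a data frame of anchors (`ref_chrom`, `ref_start`, `qry_chrom`,
#'   `qry_start`, `forward`, `k`), sorted by reference position.
#' @export
find_anchors <- function(ref, qry, k = 31L) {
  if (k %% 2L != 1L || k < 11L || k > 63L)
    stop("k must be odd and in [11, 63]")
  rs <- lapply(as.character(ref$seqs), identity)
  qs <- lapply(as.character(qry$seqs), identity)
  df <- kmer_anchors_cpp(rs, qs, as.integer(k))
  out <- data.frame(
    ref_chrom = names(ref$seqs)[df$ref_chrom_i],
    ref_start = df$ref_pos,
    qry_chrom = names(qry$seqs)[df$qry_chrom_i],
    qry_start = df$qry_pos,
    forward = df$forward,
    stringsAsFactors = FALSE)
  out <- out[order(out$ref_chrom, out$ref_start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "k") <- as.integer(k)
  out
}

#' Chain co-linear anchors
#'
#' Greedy chaining in reference order: a chain breaks when the reference
#' or query chromosome changes, the orientation flips, query monotonicity
#' (increasing for forward chains, decreasing for reverse) is violated, or
#' the gap between consecutive anchors exceeds `max_gap` on either genome.
#' Chains with fewer than `min_chain_anchors` anchors are discarded.
#'
#' @param anchors an anchor data frame from [find_anchors()].
#' @param max_gap maximum inter-anchor gap in bp on either genome.
#' @param min_chain_anchors minimum anchors per retained chain.
#' @return a `chain_set`: list with `chains` (one row per chain: spans,
#'   orientation, anchor count) and `anchors` (retained anchors with their
#'   chain id), plus the k in use.
#' @export
chain_anchors <- function(anchors, max_gap = 20000L,
                          min_chain_anchors = 3L) {
  k <- attr(anchors, "k")
  if (is.null(k)) stop("anchors must come from find_anchors()")
  n <- nrow(anchors)
  if (n == 0L) {
    return(structure(list(
      chains = data.frame(chain_id = integer(), ref_chrom = character(),
                          qry_chrom = character(), forward = logical(),
                          n_anchors = integer(), ref_start = integer(),
                          ref_end = integer(), qry_start = integer(),
                          qry_end = integer()),
      anchors = cbind(anchors, chain_id = integer(0)), k = k),
      class = "chain_set"))
  }
  a <- anchors[order(anchors$ref_chrom, anchors$ref_start), , drop = FALSE]
  rc <- a$ref_chrom; qc <- a$qry_chrom; fw <- a$forward
  rp <- a$ref_start; qp <- a$qry_start
  i <- seq_len(n - 1L); j <- i + 1L
  brk <- rc[j] != rc[i] | qc[j] != qc[i] | fw[j] != fw[i] |
    (rp[j] - rp[i] - k) > max_gap |
    ifelse(fw[i],
           qp[j] <= qp[i] | (qp[j] - qp[i] - k) > max_gap,
           qp[j] >= qp[i] | (qp[i] - qp[j] - k) > max_gap)
  id <- cumsum(c(TRUE, brk))
  cnt <- tabulate(id)
  keep <- cnt[id] >= min_chain_anchors
  a <- a[keep, , drop = FALSE]
  id <- id[keep]
  if (length(id) == 0L) {
    empty <- structure(list(
      chains = data.frame(chain_id = integer(), ref_chrom = character(),
                          qry_chrom = character(), forward = logical(),
                          n_anchors = integer(), ref_start = integer(),
                          ref_end = integer(), qry_start = integer(),
                          qry_end = integer()),
      anchors = cbind(a, chain_id = integer(0)), k = k),
      class = "chain_set")
    return(empty)
  }
  id <- match(id, unique(id))
  a$chain_id <- id
  ch <- data.frame(
    chain_id = seq_len(max(id)),
    ref_chrom = rc[keep][!duplicated(id)],
    qry_chrom = qc[keep][!duplicated(id)],
    forward = fw[keep][!duplicated(id)],
    n_anchors = tabulate(id),
    ref_start = as.integer(tapply(a$ref_start, id, min)),
    ref_end = as.integer(tapply(a$ref_start, id, max)) + k,
    qry_start = as.integer(tapply(a$qry_start, id, min)),
    qry_end = as.integer(tapply(a$qry_start, id, max)) + k,
    stringsAsFactors = FALSE)
  rownames(a) <- NULL
  structure(list(chains = ch, anchors = a, k = k), class = "chain_set")
}

# Max-weight strictly increasing subsequence (O(n^2)); returns indices.
weighted_lis <- function(pos, weight) {
  n <- length(pos)
  if (n == 0L) return(integer(0))
  best <- weight
  prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (pos[j] < pos[i] && best[j] + weight[i] > best[i]) {
        best[i] <- best[j] + weight[i]
        prev[i] <- j
      }
    }
  }
  i <- which.max(best)
  out <- integer(0)
  while (!is.na(i)) { out <- c(i, out); i <- prev[i] }
  out
}

## region call accumulator ---------------------------------------------------

new_call_sink <- function(cap = 4096L) {
  e <- new.env(parent = emptyenv())
  e$k <- 0L
  e$rc <- character(cap); e$rs <- integer(cap); e$re <- integer(cap)
  e$qc <- character(cap); e$qs <- integer(cap); e$qe <- integer(cap)
  e$ty <- character(cap); e$rb <- character(cap); e$qb <- character(cap)
  e
}

sink_emit <- function(e, type, rc, rs, re, qc, qs, qe,
                      rb = NA_character_, qb = NA_character_) {
  if (e$k == length(e$ty)) {  # grow
    for (f in c("rc", "rs", "re", "qc", "qs", "qe", "ty", "rb", "qb"))
      e[[f]] <- c(e[[f]], e[[f]])
  }
  k <- e$k + 1L
  e$rc[k] <- rc; e$rs[k] <- rs; e$re[k] <- re
  e$qc[k] <- qc; e$qs[k] <- qs; e$qe[k] <- qe
  e$ty[k] <- type; e$rb[k] <- rb; e$qb[k] <- qb
  e$k <- k
}

sink_collect <- function(e) {
  idx <- seq_len(e$k)
  validate_region_calls(data.frame(
    ref_chrom = e$rc[idx], ref_start = e$rs[idx], ref_end = e$re[idx],
    qry_chrom = e$qc[idx], qry_start = e$qs[idx], qry_end = e$qe[idx],
    type = e$ty[idx], ref_base = e$rb[idx], qry_base = e$qb[idx],
    stringsAsFactors = FALSE))
}

#' Classify the two haplotypes into a SyRI-style region partition
#'
#' The largest consistent set of co-directional, co-chromosomal forward
#' chains forms the syntenic backbone of each chromosome pair. Reverse
#' chains inside the backbone become INV; chains mapping to another
#' chromosome (or displaced beyond `trans_displacement`) become TRANS.
#' Between consecutive backbone anchors the two gap sequences are
#' end-trimmed and compared: equal single differing bases are SNPs, a
#' one-sided residual is an INS (extra sequence in the query haplotype) or
#' DEL, large two-sided residuals with banded-alignment identity below
#' `hdr_max_identity` are HDRs (at or above the threshold they are
#' absorbed into synteny, with interior SNPs re-called when the sides have
#' equal length), and small unequal residuals are emitted as paired small
#' DEL + INS. Sequence outside the backbone and its gap logic --
#' chromosome ends beyond the outermost anchors -- is NOTAL
#' (haplotype-unique). Before gap analysis, backbone anchor runs
#' (separated by gaps larger than `prune_gap`) are pruned when sparse:
#' in clean sequence anchors step by one, so a genuine run spans close
#' to its anchor count even across SNP interruptions, whereas chance
#' intact k-mers inside a diverged region spread a few anchors over a
#' wide span. Residual dense-mismatch blocks (at least 25% mismatching
#' positions, far beyond any realistic SNP clustering) are emitted as
#' HDR fragments rather than SNP runs, so stray anchors cannot shatter
#' one diverged region into spurious SNPs.
#'
#' @param chains a `chain_set` from [chain_anchors()].
#' @param ref,qry the two `haplotype_genome`s.
#' @param min_sv_len minimum one-sided residual for a "structural" INS/DEL
#'   (shorter residuals are still emitted, as small indels).
#' @param hdr_min_len minimum two-sided residual length for HDR testing.
#' @param hdr_max_identity identity threshold below which a two-sided
#'   residual is an HDR; ties resolve toward synteny.
#' @param trans_displacement query-side displacement (bp) beyond which a
#'   co-chromosomal forward chain outside the backbone is a translocation.
#' @param prune_gap,min_run_anchors backbone-run pruning parameters.
#' @return a `region_calls` data frame forming an exact single-coverage
#'   partition of both genomes (verifiable with
#'   [region_partition_check()]).
#' @export
classify_regions <- function(chains, ref, qry, min_sv_len = 50L,
                             hdr_min_len = 500L, hdr_max_identity = 0.9,
                             trans_displacement = 100000L,
                             prune_gap = 200L, min_run_anchors = 5L) {
  stopifnot(inherits(chains, "chain_set"))
  k <- chains$k
  ch <- chains$chains
  anc <- chains$anchors
  ref_len <- chrom_lengths(ref)
  qry_len <- chrom_lengths(qry)
  sink <- new_call_sink()

  ## partner assignment and chain classification
  fwd <- ch[ch$forward, , drop = FALSE]
  partner <- if (nrow(fwd) > 0)
    tapply(fwd$n_anchors, list(fwd$ref_chrom, fwd$qry_chrom), sum)
  else NULL
  partner_of <- function(rc) {
    if (is.null(partner) || !rc %in% rownames(partner))
      return(NA_character_)
    row <- partner[rc, ]
    colnames(partner)[which.max(ifelse(is.na(row), 0, row))]
  }
  partners <- stats::setNames(
    vapply(names(ref_len), partner_of, character(1)), names(ref_len))

  islands <- list()  # classified non-backbone chains
  backbone_anchor_idx <- integer(0)
  for (rc in names(ref_len)) {
    p <- partners[[rc]]
    sub <- ch[ch$ref_chrom == rc, , drop = FALSE]
    if (nrow(sub) == 0L) next
    cand <- sub[sub$forward & sub$qry_chrom %in% p, , drop = FALSE]
    cand <- cand[order(cand$ref_start), , drop = FALSE]
    bb <- cand$chain_id[weighted_lis(cand$qry_start, cand$n_anchors)]
    backbone_anchor_idx <- c(backbone_anchor_idx,
                             which(anc$chain_id %in% bb &
                                     anc$ref_chrom == rc))
    for (i in seq_len(nrow(sub))) {
      cid <- sub$chain_id[i]
      if (cid %in% bb) next
      type <- if (!sub$forward[i] && sub$qry_chrom[i] %in% p) "INV"
      else if (!identical(sub$qry_chrom[i], p)) "TRANS"
      else {
        # forward, co-chromosomal, not in backbone: displaced?
        disp <- abs((sub$qry_start[i] - sub$ref_start[i]))
        if (disp > trans_displacement) "TRANS" else NA_character_
      }
      if (is.na(type)) next  # dropped; its span falls to gap logic
      isl <- new.env(parent = emptyenv())
      isl$type <- type; isl$ref_chrom <- rc
      isl$rs <- sub$ref_start[i]; isl$re <- sub$ref_end[i]
      isl$qry_chrom <- sub$qry_chrom[i]
      isl$qs <- sub$qry_start[i]; isl$qe <- sub$qry_end[i]
      isl$ref_done <- FALSE; isl$qry_done <- FALSE
      islands[[length(islands) + 1L]] <- isl
    }
  }

  ## per-chromosome backbone walks
  for (rc in names(ref_len)) {
    p <- partners[[rc]]
    ai <- backbone_anchor_idx[anc$ref_chrom[backbone_anchor_idx] == rc]
    if (length(ai) == 0L || is.na(p)) {
      sink_emit(sink, "NOTAL", rc, 0L, ref_len[[rc]],
                NA_character_, NA_integer_, NA_integer_)
      next
    }
    ar <- anc$ref_start[ai]; aq <- anc$qry_start[ai]
    o <- order(ar); ar <- ar[o]; aq <- aq[o]
    # prune sparse runs (stray intact k-mers inside diverged regions):
    # in clean sequence anchors step by one, so a genuine run's span stays
    # close to its anchor count even across SNP interruptions, while
    # chance survivors inside an HDR are spread thin
    if (length(ar) > 1L) {
      gap_r <- diff(ar) - k; gap_q <- diff(aq) - k
      run <- cumsum(c(TRUE, gap_r > prune_gap | gap_q > prune_gap))
      sz <- tabulate(run)
      span_r <- tapply(ar, run, max) - tapply(ar, run, min)
      span_q <- tapply(aq, run, max) - tapply(aq, run, min)
      ok <- span_r <= 8 * pmax(sz, min_run_anchors) &
        span_q <= 8 * pmax(sz, min_run_anchors)
      keep <- ok[run]
      ar <- ar[keep]; aq <- aq[keep]
    }
    if (length(ar) == 0L) {
      sink_emit(sink, "NOTAL", rc, 0L, ref_len[[rc]],
                NA_character_, NA_integer_, NA_integer_)
      next
    }
    walk_backbone(sink, rc, p, ar, aq, k, ref, qry, islands,
                  min_sv_len, hdr_min_len, hdr_max_identity,
                  ref_len[[rc]], qry_len[[p]])
  }

  ## island calls, with breakpoints clipped by the walks that claimed them
  for (isl in islands) {
    if (isl$re <= isl$rs || isl$qe <= isl$qs) {
      warning("degenerate ", isl$type, " span dropped on ", isl$ref_chrom)
      next
    }
    sink_emit(sink, isl$type, isl$ref_chrom, isl$rs, isl$re,
              isl$qry_chrom, isl$qs, isl$qe)
  }

  ## query chromosomes never used as a partner are wholly unaligned
  for (qc in setdiff(names(qry_len), partners[!is.na(partners)]))
    sink_emit(sink, "NOTAL", NA_character_, NA_integer_, NA_integer_,
              qc, 0L, qry_len[[qc]])

  sink_collect(sink)
}

# Walk one chromosome pair's backbone anchors, classifying inter-anchor
# gaps with island (INV/TRANS) awareness and emitting merged SYN runs.
walk_backbone <- function(sink, rc, p, ar, aq, k, ref, qry, islands,
                          min_sv_len, hdr_min_len, hdr_max_identity,
                          rlen, qlen) {
  refseq <- as.character(ref$seqs[[rc]])
  qryseq <- as.character(qry$seqs[[p]])
  st <- new.env(parent = emptyenv())
  st$syn_r <- ar[1]; st$syn_q <- aq[1]
  close_syn <- function(r, q) {
    if (r > st$syn_r && q > st$syn_q) {
      sink_emit(sink, "SYN", rc, st$syn_r, r, p, st$syn_q, q)
    } else if (r > st$syn_r) {
      sink_emit(sink, "NOTAL", rc, st$syn_r, r,
                NA_character_, NA_integer_, NA_integer_)
    } else if (q > st$syn_q) {
      sink_emit(sink, "NOTAL", NA_character_, NA_integer_, NA_integer_,
                p, st$syn_q, q)
    }
    st$syn_r <- r; st$syn_q <- q
  }
  reset_syn <- function(r, q) { st$syn_r <- r; st$syn_q <- q }

  # islands relevant to this chromosome pair
  isl_ref <- Filter(function(x) x$ref_chrom == rc, islands)
  isl_qry <- Filter(function(x) x$qry_chrom == p, islands)

  process_gap <- function(r0, r1, q0, q1) {
    if (r1 < r0) r0 <- r1
    if (q1 < q0) q0 <- q1
    if (r1 == r0 && q1 == q0) return(invisible())
    # islands whose (unclaimed) side midpoint falls inside this gap;
    # chain ends may overhang neighbouring anchors by up to a k-mer and
    # are clipped to the claiming gap
    in_ref <- Filter(function(x)
      !x$ref_done && (x$rs + x$re) / 2 >= r0 && (x$rs + x$re) / 2 < r1,
      isl_ref)
    in_qry <- Filter(function(x)
      !x$qry_done && (x$qs + x$qe) / 2 >= q0 && (x$qs + x$qe) / 2 < q1,
      isl_qry)
    if (length(in_ref) + length(in_qry) > 0L) {
      # pick the leftmost island by (virtual) ref position
      virt <- c(vapply(in_ref, function(x) as.numeric(x$rs), numeric(1)),
                vapply(in_qry, function(x)
                  as.numeric(r0 + (x$qs - q0)), numeric(1)))
      pickq <- which.min(virt) > length(in_ref)
      isl <- if (pickq) in_qry[[which.min(virt) - length(in_ref)]]
      else in_ref[[which.min(virt)]]
      on_ref <- any(vapply(in_ref, identical, logical(1), y = isl))
      on_qry <- any(vapply(in_qry, identical, logical(1), y = isl))
      if (on_ref) {
        isl$rs <- max(isl$rs, r0); isl$re <- min(isl$re, r1)
        isl$ref_done <- TRUE
      }
      if (on_qry) {
        isl$qs <- max(isl$qs, q0); isl$qe <- min(isl$qe, q1)
        isl$qry_done <- TRUE
      }
      if (on_ref && on_qry) {
        process_gap(r0, isl$rs, q0, isl$qs)
        close_syn(isl$rs, isl$qs)
        reset_syn(isl$re, isl$qe)
        process_gap(isl$re, r1, isl$qe, q1)
      } else if (on_ref) {   # e.g. translocation source
        qmid <- min(q0 + (isl$rs - r0), q1)
        process_gap(r0, isl$rs, q0, qmid)
        close_syn(isl$rs, qmid)
        reset_syn(isl$re, qmid)
        process_gap(isl$re, r1, qmid, q1)
      } else {               # e.g. translocation destination
        rmid <- min(r0 + (isl$qs - q0), r1)
        process_gap(r0, rmid, q0, isl$qs)
        close_syn(rmid, isl$qs)
        reset_syn(rmid, isl$qe)
        process_gap(rmid, r1, isl$qe, q1)
      }
      return(invisible())
    }
    base_gap(r0, r1, q0, q1)
  }

  base_gap <- function(r0, r1, q0, q1) {
    a0 <- r1 - r0; b0 <- q1 - q0
    R <- charToRaw(substr(refseq, r0 + 1L, r1))
    Q <- charToRaw(substr(qryseq, q0 + 1L, q1))
    m <- min(a0, b0)
    pfx <- 0L
    if (m > 0L) {
      neq <- which(R[seq_len(m)] != Q[seq_len(m)])
      pfx <- if (length(neq)) neq[1] - 1L else m
    }
    sfx <- 0L
    m2 <- m - pfx
    if (m2 > 0L) {
      rrev <- R[a0 - seq_len(m2) + 1L]; qrev <- Q[b0 - seq_len(m2) + 1L]
      neq <- which(rrev != qrev)
      sfx <- if (length(neq)) neq[1] - 1L else m2
    }
    a <- a0 - pfx - sfx; b <- b0 - pfx - sfx
    rs <- r0 + pfx; qs <- q0 + pfx
    if (a == 0L && b == 0L) return(invisible())
    if (a == 0L) {
      close_syn(rs, qs)
      sink_emit(sink, "INS", rc, rs, rs, p, qs, qs + b)
      reset_syn(rs, qs + b)
    } else if (b == 0L) {
      close_syn(rs, qs)
      sink_emit(sink, "DEL", rc, rs, rs + a, p, qs, qs)
      reset_syn(rs + a, qs)
    } else if (a == b) {
      is_hdr <- FALSE
      if (a >= hdr_min_len) {
        d <- banded_edit_distance_cpp(
          rawToChar(R[(pfx + 1L):(pfx + a)]),
          rawToChar(Q[(pfx + 1L):(pfx + b)]), 50L)
        is_hdr <- (1 - d / a) < hdr_max_identity
      }
      mm <- which(R[(pfx + 1L):(pfx + a)] != Q[(pfx + 1L):(pfx + b)])
      # dense equal-length mismatch blocks are HDR interior fragments
      # (stray anchors can split one diverged region): no SNP cluster at
      # realistic rates comes near 25% mismatch density
      if (!is_hdr && a >= 30L && length(mm) / a >= 0.25) is_hdr <- TRUE
      if (is_hdr) {
        close_syn(rs, qs)
        sink_emit(sink, "HDR", rc, rs, rs + a, p, qs, qs + b)
        reset_syn(rs + a, qs + b)
      } else {
        for (i in mm) {
          close_syn(rs + i - 1L, qs + i - 1L)
          sink_emit(sink, "SNP", rc, rs + i - 1L, rs + i, p,
                    qs + i - 1L, qs + i,
                    rawToChar(R[pfx + i]), rawToChar(Q[pfx + i]))
          reset_syn(rs + i, qs + i)
        }
      }
    } else {
      if (min(a, b) >= hdr_min_len) {
        d <- banded_edit_distance_cpp(
          rawToChar(R[(pfx + 1L):(pfx + a)]),
          rawToChar(Q[(pfx + 1L):(pfx + b)]),
          2L * abs(a - b) + 50L)
        if ((1 - d / max(a, b)) < hdr_max_identity) {
          close_syn(rs, qs)
          sink_emit(sink, "HDR", rc, rs, rs + a, p, qs, qs + b)
          reset_syn(rs + a, qs + b)
        }
        # identity >= threshold: absorbed into the running SYN block
      } else {
        close_syn(rs, qs)
        sink_emit(sink, "DEL", rc, rs, rs + a, p, qs, qs)
        sink_emit(sink, "INS", rc, rs + a, rs + a, p, qs, qs + b)
        reset_syn(rs + a, qs + b)
      }
    }
    invisible()
  }

  ## terminal NOTAL before the first anchor
  if (ar[1] > 0L)
    sink_emit(sink, "NOTAL", rc, 0L, ar[1],
              NA_character_, NA_integer_, NA_integer_)
  if (aq[1] > 0L)
    sink_emit(sink, "NOTAL", NA_character_, NA_integer_, NA_integer_,
              p, 0L, aq[1])
  n <- length(ar)
  if (n > 1L) {
    gr <- ar[-1] - (ar[-n] + k)
    gq <- aq[-1] - (aq[-n] + k)
    for (i in which(gr > 0L | gq > 0L)) {
      process_gap(ar[i + 1L] - max(gr[i], 0L), ar[i + 1L],
                  aq[i + 1L] - max(gq[i], 0L), aq[i + 1L])
    }
  }
  close_syn(ar[n] + k, aq[n] + k)
  if (ar[n] + k < rlen)
    sink_emit(sink, "NOTAL", rc, ar[n] + k, rlen,
              NA_character_, NA_integer_, NA_integer_)
  if (aq[n] + k < qlen)
    sink_emit(sink, "NOTAL", NA_character_, NA_integer_, NA_integer_,
              p, aq[n] + k, qlen)
  invisible()
}

#' Verify the region partition
#'
#' Checks that every base of each haplotype (excluding N runs) is covered
#' by exactly one call's interval on that haplotype.
#'
#' @param calls a `region_calls` data frame.
#' @param ref,qry the two `haplotype_genome`s.
#' @return a list with `ok` and, per haplotype, data frames of uncovered
#'   and overlapped intervals (empty for a valid partition).
#' @export
region_partition_check <- function(calls, ref, qry) {
  side_check <- function(genome, chrom, start, end) {
    has <- !is.na(chrom) & !is.na(start) & end > start
    unc <- list(); ovl <- list()
    for (cid in names(genome$seqs)) {
      L <- length(genome$seqs[[cid]])
      idx <- has & chrom == cid
      ir <- IRanges::IRanges(start[idx] + 1L, end[idx])
      cov <- IRanges::coverage(ir, width = L)
      nruns <- Biostrings::maskMotif(genome$seqs[[cid]], "N")
      nr <- IRanges::IRanges()
      if (length(Biostrings::masks(nruns)) > 0)
        nr <- IRanges::reduce(methods::as(
          Biostrings::masks(nruns)[[1]], "IRanges"))
      u <- IRanges::setdiff(
        methods::as(IRanges::slice(cov, upper = 0, rangesOnly = TRUE),
                    "IRanges"), nr)
      o <- methods::as(IRanges::slice(cov, lower = 2, rangesOnly = TRUE),
                       "IRanges")
      if (length(u)) unc[[cid]] <- data.frame(
        chrom = cid, start = IRanges::start(u) - 1L, end = IRanges::end(u))
      if (length(o)) ovl[[cid]] <- data.frame(
        chrom = cid, start = IRanges::start(o) - 1L, end = IRanges::end(o))
    }
    empty <- data.frame(chrom = character(), start = integer(),
                        end = integer())
    list(uncovered = if (length(unc)) do.call(rbind, unc) else empty,
         overlapped = if (length(ovl)) do.call(rbind, ovl) else empty)
  }
  r <- side_check(ref, calls$ref_chrom, calls$ref_start, calls$ref_end)
  q <- side_check(qry, calls$qry_chrom, calls$qry_start, calls$qry_end)
  list(ok = nrow(r$uncovered) + nrow(r$overlapped) +
         nrow(q$uncovered) + nrow(q$overlapped) == 0L,
       ref_uncovered = r$uncovered, ref_overlapped = r$overlapped,
       qry_uncovered = q$uncovered, qry_overlapped = q$overlapped)
}
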