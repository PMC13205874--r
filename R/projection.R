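## Syntenic projection between haplotypes through the region partition.
## Two-sided co-linear calls (SYN, HDR, INV) define a piecewise coordinate
## map; positions outside any such call are projected through the nearest
## call edge. Used by the hemizygosity and homolog modules to restrict
## partner search to the corresponding locus.

make_projection <- function(calls, from = c("ref", "qry")) {
  from <- match.arg(from)
  two <- calls[calls$type %in% c("SYN", "HDR", "INV"), , drop = FALSE]
  if (from == "ref") {
    src_c <- two$ref_chrom; src_s <- two$ref_start; src_e <- two$ref_end
    dst_c <- two$qry_chrom; dst_s <- two$qry_start; dst_e <- two$qry_end
  } else {
    src_c <- two$qry_chrom; src_s <- two$qry_start; src_e <- two$qry_end
    dst_c <- two$ref_chrom; dst_s <- two$ref_start; dst_e <- two$ref_end
  }
  inv <- two$type == "INV"
  tabs <- split(data.frame(src_s, src_e, dst_c, dst_s, dst_e, inv,
                           stringsAsFactors = FALSE), src_c)
  tabs <- lapply(tabs, function(t) t[order(t$src_s), , drop = FALSE])
  function(chrom, pos) {
    t <- tabs[[chrom]]
    if (is.null(t) || nrow(t) == 0L)
      return(list(chrom = NA_character_, pos = NA_integer_))
    i <- findInterval(pos, t$src_s)
    if (i >= 1L && pos < t$src_e[i]) {          # inside call i
      off <- pos - t$src_s[i]
    } else {                                    # between calls: nearest edge
      d_prev <- if (i >= 1L) pos - t$src_e[i] else Inf
      d_next <- if (i < nrow(t)) t$src_s[i + 1L] - pos else Inf
      if (d_next < d_prev) { i <- i + 1L; off <- -d_next }
      else off <- (t$src_e[i] - t$src_s[i]) + d_prev
    }
    q <- if (t$inv[i]) t$dst_e[i] - off else t$dst_s[i] + off
    list(chrom = t$dst_c[i], pos = as.integer(round(q)))
  }
}

# Global CDS identity between two coding sequences, defined as
# 1 - edit_distance / max(length). Exact equality short-circuits to 1;
# equal-length pairs use the Hamming distance (an upper bound on edit
# distance that is exact for substitution-only divergence, the dominant
# case between haplotypes); unequal lengths use a banded global edit
# distance. The band covers the length difference generously, and a
# truncated band can only *underestimate* identity, which is conservative
# for the homozygosity threshold.
cds_identity <- function(a, b) {
  if (is.na(a) || is.na(b) || nchar(a) == 0L || nchar(b) == 0L)
    return(NA_real_)
  if (a == b) return(1)
  na <- nchar(a); nb <- nchar(b)
  if (na == nb) {
    d <- sum(charToRaw(a) != charToRaw(b))
    dd <- banded_edit_distance_cpp(a, b, 20L)  # catch frame-shift-like cases
    return(1 - min(d, dd) / na)
  }
  d <- banded_edit_distance_cpp(a, b, 2L * abs(na - nb) + 100L)
  1 - d / max(na, nb)
}
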