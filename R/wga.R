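#' @importFrom S4Vectors queryHits subjectHits
NULL

# integer encoding A=0 C=1 G=2 T=3, N/other = NA
seq_int <- function(seq) {
  v <- utf8ToInt(seq)
  lut <- rep(NA_integer_, 128)
  lut[utf8ToInt("A")] <- 0L; lut[utf8ToInt("C")] <- 1L
  lut[utf8ToInt("G")] <- 2L; lut[utf8ToInt("T")] <- 3L
  lut[v]
}

# exact numeric 2-bit k-mer codes (4^k < 2^53 for k <= 26); NA where the
# window contains N
kmer_codes <- function(ci, k) {
  n <- length(ci) - k + 1L
  if (n < 1L) return(numeric(0))
  out <- numeric(n)
  for (j in 0:(k - 1L)) out <- out * 4 + ci[(1L + j):(n + j)]
  out
}

uniq_mask <- function(km) {
  !is.na(km) & !(duplicated(km) | duplicated(km, fromLast = TRUE))
}

# per-sequence anchoring index: integer sequence, k-mer codes for forward
# and reverse-complement orientation, joint-strand uniqueness
kmer_index <- function(seq, k) {
  ci <- seq_int(seq)
  fwd <- kmer_codes(ci, k)
  rci <- rev(3L - ci)
  rc <- kmer_codes(rci, k)
  both_uni <- uniq_mask(c(fwd, rc))
  nf <- length(fwd)
  list(ci = ci, rci = rci, fwd = fwd, rc = rc,
       fwd_uni_self = uniq_mask(fwd),
       fwd_uni_both = both_uni[seq_len(nf)],
       rc_uni_both = both_uni[nf + seq_along(rc)],
       len = length(ci), k = k)
}

match_seeds <- function(ref_km, ref_uni, q_km, q_uni) {
  ri <- which(ref_uni)
  qi <- which(q_uni)
  m <- match(ref_km[ri], q_km[qi])
  keep <- !is.na(m)
  data.frame(ref0 = ri[keep] - 1L, q0 = qi[m[keep]] - 1L)
}

# merge seeds on a shared diagonal when their starts are within k (they then
# overlap or abut, so the union is a verified exact match)
merge_diagonal <- function(seeds, k) {
  if (nrow(seeds) == 0L) {
    return(data.frame(ref0 = integer(0), q0 = integer(0), len = integer(0)))
  }
  d <- seeds$ref0 - seeds$q0
  o <- order(d, seeds$ref0)
  r0 <- seeds$ref0[o]; dd <- d[o]
  brk <- c(TRUE, diff(dd) != 0 | diff(r0) > k)
  run <- cumsum(brk)
  s <- as.integer(tapply(r0, run, min))
  e <- as.integer(tapply(r0, run, max)) + k
  diag_run <- dd[brk]
  data.frame(ref0 = s, q0 = s - diag_run, len = e - s)
}

# extend exact matches left/right base-by-base on integer sequences
# (NA = N never matches)
extend_matches <- function(m, ri, qi) {
  if (nrow(m) == 0L) return(m)
  Lr <- length(ri); Lq <- length(qi)
  for (i in seq_len(nrow(m))) {
    r <- m$ref0[i]; q <- m$q0[i]; len <- m$len[i]
    while (r > 0L && q > 0L) {
      a <- ri[r]; b <- qi[q]
      if (is.na(a) || is.na(b) || a != b) break
      r <- r - 1L; q <- q - 1L; len <- len + 1L
    }
    re <- m$ref0[i] + m$len[i]; qe <- m$q0[i] + m$len[i]
    while (re < Lr && qe < Lq) {
      a <- ri[re + 1L]; b <- qi[qe + 1L]
      if (is.na(a) || is.na(b) || a != b) break
      re <- re + 1L; qe <- qe + 1L; len <- len + 1L
    }
    m$ref0[i] <- r; m$q0[i] <- q; m$len[i] <- len
  }
  m
}

anchors_from_index <- function(ref_idx, qry_idx, ref_chrom, qry_chrom) {
  k <- ref_idx$k
  empty <- data.frame(ref_chrom = character(0), ref_start = integer(0),
                      qry_chrom = character(0), qry_start = integer(0),
                      length = integer(0), strand = character(0))
  plus <- merge_diagonal(match_seeds(ref_idx$fwd, ref_idx$fwd_uni_self,
                                     qry_idx$fwd, qry_idx$fwd_uni_both), k)
  plus <- extend_matches(plus, ref_idx$ci, qry_idx$ci)
  minus <- merge_diagonal(match_seeds(ref_idx$fwd, ref_idx$fwd_uni_self,
                                      qry_idx$rc, qry_idx$rc_uni_both), k)
  minus <- extend_matches(minus, ref_idx$ci, qry_idx$rci)
  Lq <- qry_idx$len
  res <- rbind(
    if (nrow(plus)) data.frame(ref_chrom = ref_chrom, ref_start = plus$ref0,
                               qry_chrom = qry_chrom, qry_start = plus$q0,
                               length = plus$len, strand = "+") else empty,
    if (nrow(minus)) data.frame(ref_chrom = ref_chrom, ref_start = minus$ref0,
                                qry_chrom = qry_chrom,
                                qry_start = Lq - (minus$q0 + minus$len),
                                length = minus$len, strand = "-") else empty)
  res[order(res$ref_start), , drop = FALSE]
}

#' Find maximal unique exact-match anchors between two sequences
#'
#' Seeds are k-mers unique in the reference (forward strand) and unique in
#' the query counting both strands (MUM-like), merged when collinear-adjacent
#' on a shared diagonal and extended to maximal exact matches. N never
#' matches.
#'
#' @param ref,qry DNA strings over A,C,G,T,N.
#' @param k odd k-mer size, 15--51 (codes are exact up to k = 26; larger k
#'   falls back to string matching).
#' @param ref_chrom,qry_chrom names recorded in the output.
#' @return data.frame with columns `ref_chrom`, `ref_start` (0-based),
#'   `qry_chrom`, `qry_start` (0-based, forward-strand coordinate of the
#'   match's left end on either strand), `length`, `strand`.
#' @export
find_anchors <- function(ref, qry, k = 21L, ref_chrom = "ref",
                         qry_chrom = "qry") {
  if (k %% 2L != 1L || k < 15L || k > 51L) {
    stop("k must be odd and within [15, 51]")
  }
  if (k > 26L) stop("k above 26 is not supported by the numeric k-mer codes")
  empty <- data.frame(ref_chrom = character(0), ref_start = integer(0),
                      qry_chrom = character(0), qry_start = integer(0),
                      length = integer(0), strand = character(0))
  if (nchar(ref) < k || nchar(qry) < k) return(empty)
  anchors_from_index(kmer_index(ref, k), kmer_index(qry, k),
                     ref_chrom, qry_chrom)
}

# chaining coordinate: increases along the chain for both strands
chain_coord <- function(a) {
  ifelse(a$strand == "+", a$qry_start, -(a$qry_start + a$length))
}

#' Chain collinear anchors with affine gap costs
#'
#' Sparse dynamic program over anchors from one (ref_chrom, qry_chrom,
#' strand) bucket, maximizing total anchored length minus gap costs, where a
#' gap between linked anchors costs
#' `gap_open + gap_extend_per_bp * max(ref_gap, qry_gap, 0)` and links with
#' either gap above `max_gap` are forbidden, as are links where both gaps
#' exceed `max_mutual_gap` (a clean insertion or deletion leaves one side
#' near zero; a large mutual gap marks sequence -- e.g. an inverted
#' segment -- that must not be chained across). Chains are extracted greedily by
#' descending score, each anchor used at most once; chains scoring below
#' `min_score` are dropped. Small anchor overlaps (from match extension) are
#' resolved by trimming the downstream anchor. The predecessor search is
#' capped at `lookback` anchors for speed.
#'
#' @param anchors data.frame as returned by [find_anchors()].
#' @param gap_open gap opening cost.
#' @param gap_extend_per_bp per-bp gap extension cost.
#' @param max_gap maximum allowed ref or qry gap between linked anchors (bp).
#' @param max_mutual_gap maximum allowed min(ref_gap, qry_gap) (bp).
#' @param min_score minimum chain score retained.
#' @param lookback maximum number of preceding anchors examined per link.
#' @return list of chains; each a list with `anchors` (data.frame), `score`,
#'   `strand`, `ref_chrom`, `qry_chrom`, `ref_span`, `qry_span` (0-based
#'   half-open).
#' @export
chain_anchors <- function(anchors, gap_open = 50, gap_extend_per_bp = 0.01,
                          max_gap = 100000L, max_mutual_gap = 10000L,
                          min_score = 200, lookback = 200L) {
  chains <- list()
  if (is.null(anchors) || nrow(anchors) == 0L) return(chains)
  buckets <- split(anchors,
                   paste(anchors$ref_chrom, anchors$qry_chrom, anchors$strand))
  for (b in buckets) {
    b <- b[order(b$ref_start, chain_coord(b)), ]
    repeat {
      n <- nrow(b)
      if (n == 0L) break
      qc <- chain_coord(b)
      rs <- b$ref_start; ln <- b$length
      score <- as.numeric(ln)
      prev <- rep(NA_integer_, n)
      for (j in seq_len(n)[-1]) {
        lo <- max(1L, j - lookback)
        idx <- lo:(j - 1L)
        rg <- rs[j] - (rs[idx] + ln[idx])
        qg <- qc[j] - (qc[idx] + ln[idx])
        keep <- rs[idx] < rs[j] & qc[idx] < qc[j] &
          rg <= max_gap & qg <= max_gap & pmin(rg, qg) <= max_mutual_gap &
          rg >= -(ln[j] - 1L) & qg >= -(ln[j] - 1L)
        if (!any(keep)) next
        cand <- idx[keep]
        gcost <- gap_open + gap_extend_per_bp * pmax(rg[keep], qg[keep], 0)
        tot <- score[cand] + ln[j] - gcost
        best <- which.max(tot)
        if (tot[best] > score[j]) {
          score[j] <- tot[best]
          prev[j] <- cand[best]
        }
      }
      top <- which.max(score)
      if (score[top] < min_score) break
      path <- integer(0)
      i <- top
      while (!is.na(i)) { path <- c(i, path); i <- prev[i] }
      ch <- trim_chain_overlaps(b[path, , drop = FALSE])
      chains[[length(chains) + 1L]] <- make_chain(ch, score[top])
      b <- b[-path, , drop = FALSE]
    }
  }
  chains[order(vapply(chains, function(c) -c$score, numeric(1)))]
}

# enforce strictly increasing, non-overlapping anchors within a chain by
# trimming the downstream anchor (overlapping sequence matches identically)
trim_chain_overlaps <- function(ch) {
  if (nrow(ch) < 2L) return(ch)
  for (j in 2:nrow(ch)) {
    qc_prev_end <- chain_coord(ch[j - 1L, ]) + ch$length[j - 1L]
    r_over <- (ch$ref_start[j - 1L] + ch$length[j - 1L]) - ch$ref_start[j]
    q_over <- qc_prev_end - chain_coord(ch[j, ])
    t <- max(r_over, q_over, 0L)
    if (t > 0L) {
      ch$ref_start[j] <- ch$ref_start[j] + t
      if (ch$strand[j] == "+") {
        ch$qry_start[j] <- ch$qry_start[j] + t
      } # minus strand: shifting the chain coordinate shrinks from the right
        # end in forward coordinates, so qry_start is unchanged
      ch$length[j] <- ch$length[j] - t
    }
  }
  ch[ch$length > 0L, , drop = FALSE]
}

make_chain <- function(anchors, score) {
  list(anchors = anchors, score = score,
       strand = anchors$strand[1],
       ref_chrom = anchors$ref_chrom[1], qry_chrom = anchors$qry_chrom[1],
       ref_span = c(min(anchors$ref_start),
                    max(anchors$ref_start + anchors$length)),
       qry_span = c(min(anchors$qry_start),
                    max(anchors$qry_start + anchors$length)))
}

#' Build a synteny net from scored chains
#'
#' Greedy best-first tiling of one reference chromosome: chains are inserted
#' by descending score (ties broken by smaller query start); a chain is kept
#' only where its reference span does not overlap previously placed chains.
#' Partially overlapping chains are trimmed at anchor boundaries (overlapping
#' anchors dropped, longest surviving contiguous run kept). The result is the
#' 1-to-1 orthologous cover used for variant extraction.
#'
#' @param chains list of chains for one reference chromosome (both strands,
#'   any query chromosome).
#' @param chrom_length reference chromosome length (for coverage classes).
#' @param min_score minimum score for a (possibly trimmed) chain to enter.
#' @return an object of class `synteny_net`: list with `chains` (kept, in
#'   reference order), `unnetted` (chains excluded entirely), `ref_chrom`,
#'   `chrom_length`.
#' @export
build_net <- function(chains, chrom_length = NA_integer_, min_score = 200) {
  if (length(chains) == 0L) {
    return(structure(list(chains = list(), unnetted = list(),
                          ref_chrom = NA_character_,
                          chrom_length = chrom_length),
                     class = "synteny_net"))
  }
  ord <- order(vapply(chains, function(c) -c$score, numeric(1)),
               vapply(chains, function(c) c$qry_span[1], numeric(1)))
  chains <- chains[ord]
  kept <- list(); unnetted <- list()
  occ_s <- numeric(0); occ_e <- numeric(0)  # 0-based half-open kept spans
  for (ch in chains) {
    a <- ch$anchors
    ov <- vapply(seq_len(nrow(a)), function(i) {
      s <- a$ref_start[i]; e <- s + a$length[i]
      any(occ_s < e & occ_e > s)
    }, logical(1))
    if (all(ov)) { unnetted[[length(unnetted) + 1L]] <- ch; next }
    if (any(ov)) {
      # keep the longest contiguous run of non-overlapping anchors
      r <- rle(!ov)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      runs <- which(r$values)
      lens <- vapply(runs, function(ri) {
        sum(a$length[starts[ri]:ends[ri]])
      }, numeric(1))
      best <- runs[which.max(lens)]
      a <- a[starts[best]:ends[best], , drop = FALSE]
      ch <- make_chain(a, score = sum(a$length))
      if (ch$score < min_score) {
        unnetted[[length(unnetted) + 1L]] <- ch; next
      }
    }
    kept[[length(kept) + 1L]] <- ch
    occ_s <- c(occ_s, ch$ref_span[1]); occ_e <- c(occ_e, ch$ref_span[2])
  }
  ref_ord <- order(vapply(kept, function(c) c$ref_span[1], numeric(1)))
  structure(list(chains = kept[ref_ord], unnetted = unnetted,
                 ref_chrom = if (length(kept)) kept[[1]]$ref_chrom else NA_character_,
                 chrom_length = chrom_length),
            class = "synteny_net")
}

#' Per-base coverage classes of a synteny net
#'
#' Every reference base is classified as `aligned` (inside a netted anchor),
#' `gap` (inside a netted chain span but between anchors) or `unaligned`.
#'
#' @param net a `synteny_net`.
#' @return data.frame of 1-based closed intervals (`start`, `end`, `class`)
#'   tiling the chromosome.
#' @export
net_coverage_class <- function(net) {
  L <- net$chrom_length
  stopifnot(!is.na(L))
  cls <- rep("unaligned", L)
  for (ch in net$chains) {
    sp <- ch$ref_span
    cls[(sp[1] + 1L):sp[2]] <- "gap"
    a <- ch$anchors
    for (i in seq_len(nrow(a))) {
      cls[(a$ref_start[i] + 1L):(a$ref_start[i] + a$length[i])] <- "aligned"
    }
  }
  r <- rle(cls)
  e <- cumsum(r$lengths)
  data.frame(start = e - r$lengths + 1L, end = e, class = r$values,
             stringsAsFactors = FALSE)
}

#' Pairwise whole-genome alignment of two genomes
#'
#' Runs anchoring, chaining and net construction for every reference
#' chromosome of `ref` against all chromosomes of `qry` (per-chromosome
#' k-mer indexes are computed once and reused).
#'
#' @param ref,qry named character vectors of chromosome sequences.
#' @param k k-mer size for anchoring.
#' @param ... passed to [chain_anchors()].
#' @return named list (per reference chromosome) of `synteny_net` objects.
#' @export
wga_align <- function(ref, qry, k = 21L, ...) {
  ref_idx <- lapply(ref, kmer_index, k = k)
  qry_idx <- lapply(qry, kmer_index, k = k)
  nets <- list()
  for (rc in names(ref)) {
    anch <- do.call(rbind, lapply(names(qry), function(qc) {
      anchors_from_index(ref_idx[[rc]], qry_idx[[qc]], rc, qc)
    }))
    chains <- chain_anchors(anch, ...)
    nets[[rc]] <- build_net(chains, chrom_length = nchar(ref[[rc]]))
    nets[[rc]]$ref_chrom <- rc
  }
  nets
}
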