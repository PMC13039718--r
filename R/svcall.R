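sv_record_df <- function() {
  data.frame(sv_type = character(0), ref_chrom = character(0),
             pos = integer(0), end = integer(0), length = integer(0),
             alt_seq = character(0), source = character(0),
             feature_class = character(0), stringsAsFactors = FALSE)
}

small_variant_df <- function() {
  data.frame(chrom = character(0), pos = integer(0), ref = character(0),
             alt = character(0), type = character(0), stringsAsFactors = FALSE)
}

# shift an indel to its leftmost equivalent position (VCF left alignment)
left_align_indel <- function(ref_seq, pos, allele) {
  # pos = 1-based base before the event; allele = inserted or deleted sequence
  len <- nchar(allele)
  while (pos > 1L && len > 0L) {
    last <- substr(allele, len, len)
    if (substr(ref_seq, pos, pos) != last) break
    allele <- paste0(last, substr(allele, 1L, len - 1L))
    pos <- pos - 1L
  }
  list(pos = pos, allele = allele)
}

# align a small ref-gap/qry-gap pair (both < 50 bp): common prefix/suffix
# trimming; returns small variant rows
align_small_gap <- function(rseq, qseq, chrom, gap_pos0, ref_seq) {
  out <- small_variant_df()
  lr <- nchar(rseq); lq <- nchar(qseq)
  if (lr == lq) {
    if (lr == 0L) return(out)
    rv <- strsplit(rseq, "")[[1]]; qv <- strsplit(qseq, "")[[1]]
    mm <- which(rv != qv)
    if (length(mm)) {
      out <- data.frame(chrom = chrom, pos = gap_pos0 + mm, ref = rv[mm],
                        alt = qv[mm], type = "SNV", stringsAsFactors = FALSE)
    }
    return(out)
  }
  # trim common prefix
  p <- 0L
  while (p < min(lr, lq) &&
         substr(rseq, p + 1L, p + 1L) == substr(qseq, p + 1L, p + 1L)) p <- p + 1L
  s <- 0L
  while (s < min(lr, lq) - p &&
         substr(rseq, lr - s, lr - s) == substr(qseq, lq - s, lq - s)) s <- s + 1L
  mid_r <- substr(rseq, p + 1L, lr - s)
  mid_q <- substr(qseq, p + 1L, lq - s)
  anchor <- gap_pos0 + p  # 1-based base before the indel
  if (nchar(mid_r) == 0L && nchar(mid_q) > 0L) {
    la <- left_align_indel(ref_seq, anchor, mid_q)
    out <- data.frame(chrom = chrom, pos = la$pos, ref = "-", alt = la$allele,
                      type = "INS_SMALL", stringsAsFactors = FALSE)
  } else if (nchar(mid_q) == 0L && nchar(mid_r) > 0L) {
    la <- left_align_indel(ref_seq, anchor, mid_r)
    out <- data.frame(chrom = chrom, pos = la$pos, ref = la$allele, alt = "-",
                      type = "DEL_SMALL", stringsAsFactors = FALSE)
  } else if (nchar(mid_r) > 0L && nchar(mid_q) > 0L) {
    # substitution block: per-base SNVs over the overlap + residual indel
    k <- min(nchar(mid_r), nchar(mid_q))
    out <- rbind(align_small_gap(substr(mid_r, 1L, k), substr(mid_q, 1L, k),
                                 chrom, anchor, ref_seq),
                 align_small_gap(substring(mid_r, k + 1L),
                                 substring(mid_q, k + 1L),
                                 chrom, anchor + k, ref_seq))
  }
  out
}

#' Extract structural and small variants from a synteny net
#'
#' Walks consecutive anchors within each netted chain: gaps with
#' `qry_gap - ref_gap >= 50` become insertions (full query gap sequence kept
#' as ALT), `ref_gap - qry_gap >= 50` deletions; gaps with both sides below
#' 50 bp are aligned base-by-base into SNVs and left-aligned small indels.
#' A netted minus-strand chain spanning more than 10 kb is an inversion; a
#' netted chain placed on a different query chromosome than the reference
#' chromosome's dominant partner and spanning more than 100 kb is a
#' translocation. Coordinates follow VCF: `pos` is the last matching base
#' before the event (1-based).
#'
#' @param net a `synteny_net` for one reference chromosome.
#' @param ref,qry named character vectors of chromosome sequences.
#' @param accession label recorded as the record source.
#' @param min_sv_len minimum INS/DEL length (50 bp).
#' @param min_inv_len minimum inversion span (bp, exclusive bound).
#' @param min_tra_len minimum translocation span (bp, exclusive bound).
#' @return list with `sv` (SVRecord data.frame) and `small`
#'   (SmallVariantSet data.frame).
#' @export
call_variants_from_net <- function(net, ref, qry, accession = "qry",
                                   min_sv_len = 50L, min_inv_len = 10000L,
                                   min_tra_len = 100000L) {
  stopifnot(inherits(net, "synteny_net"))
  rc <- net$ref_chrom
  if (!rc %in% names(ref)) stop("net/reference chromosome name mismatch: ", rc)
  ref_seq <- ref[[rc]]
  sv <- sv_record_df(); small <- small_variant_df()
  if (length(net$chains) == 0L) return(list(sv = sv, small = small))
  for (ch in net$chains) {
    if (!ch$qry_chrom %in% names(qry)) {
      stop("net/query chromosome name mismatch: ", ch$qry_chrom)
    }
  }
  # dominant query chromosome = the one contributing most netted bases
  netted_bp <- tapply(
    vapply(net$chains, function(c) sum(c$anchors$length), numeric(1)),
    vapply(net$chains, function(c) c$qry_chrom, character(1)), sum)
  dom_q <- names(netted_bp)[which.max(netted_bp)]

  add_sv <- function(type, pos, end, len, alt, cls = "unclassified") {
    sv[nrow(sv) + 1L, ] <<- list(type, rc, as.integer(pos), as.integer(end),
                                 as.integer(len), alt, accession, cls)
  }

  for (ch in net$chains) {
    span <- ch$ref_span[2] - ch$ref_span[1]
    qseq <- qry[[ch$qry_chrom]]
    if (ch$qry_chrom != dom_q) {
      if (span > min_tra_len) {
        add_sv("TRA", ch$ref_span[1], ch$ref_span[2], span,
               sprintf("%s:%d", ch$qry_chrom, ch$qry_span[1]))
      }
      next
    }
    if (ch$strand == "-" && span > min_inv_len) {
      add_sv("INV", ch$ref_span[1], ch$ref_span[2], span, NA_character_)
    }
    a <- ch$anchors
    if (nrow(a) < 2L) next
    for (j in 2:nrow(a)) {
      i <- j - 1L
      ref_gap <- a$ref_start[j] - (a$ref_start[i] + a$length[i])
      if (ch$strand == "+") {
        qry_gap <- a$qry_start[j] - (a$qry_start[i] + a$length[i])
        qgap_seq <- if (qry_gap > 0)
          substr(qseq, a$qry_start[i] + a$length[i] + 1L, a$qry_start[j])
          else ""
      } else {
        qry_gap <- a$qry_start[i] - (a$qry_start[j] + a$length[j])
        qgap_seq <- if (qry_gap > 0)
          revcomp(substr(qseq, a$qry_start[j] + a$length[j] + 1L,
                         a$qry_start[i]))
          else ""
      }
      gap_pos0 <- a$ref_start[i] + a$length[i]  # 1-based last matching base
      rgap_seq <- if (ref_gap > 0)
        substr(ref_seq, gap_pos0 + 1L, a$ref_start[j]) else ""
      if (qry_gap - ref_gap >= min_sv_len) {
        add_sv("INS", gap_pos0, gap_pos0 + ref_gap, qry_gap - ref_gap,
               qgap_seq)
      } else if (ref_gap - qry_gap >= min_sv_len) {
        add_sv("DEL", gap_pos0, gap_pos0 + (ref_gap - qry_gap),
               ref_gap - qry_gap, NA_character_)
      } else if (ref_gap > 0 || qry_gap > 0) {
        small <- rbind(small, align_small_gap(rgap_seq, qgap_seq, rc,
                                              gap_pos0, ref_seq))
      }
    }
  }
  rownames(sv) <- NULL; rownames(small) <- NULL
  list(sv = sv, small = small)
}

# single-linkage clustering of same-type records: link when breakpoints are
# within max_dist and reciprocal size similarity >= min_sim
cluster_sv_records <- function(rec, max_dist = 1000L, min_sim = 0.5) {
  n <- nrow(rec)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[rj] <<- ri }
  key <- paste(rec$sv_type, rec$ref_chrom)
  for (grp in split(seq_len(n), key)) {
    idx <- grp[order(rec$pos[grp])]
    m <- length(idx)
    if (m < 2L) next
    for (x in seq_len(m - 1L)) {
      for (y in (x + 1L):m) {
        i <- idx[x]; j <- idx[y]
        if (rec$pos[j] - rec$pos[i] > max_dist) break
        sim <- min(rec$length[i], rec$length[j]) /
               max(rec$length[i], rec$length[j])
        if (sim >= min_sim) union(i, j)
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Merge per-accession SV calls into a non-redundant genotyped callset
#'
#' Single-linkage clustering of same-type records whose start breakpoints
#' lie within `max_dist` and whose sizes satisfy reciprocal similarity at
#' least `min_sim`. Each cluster becomes one record at the coordinates of
#' the member from the accession earliest in the (lexicographically fixed)
#' accession ordering; per-accession genotype is 1 where the accession
#' contributed a member, missing where the region is unaligned in that
#' accession's net (if nets are supplied), else 0.
#'
#' @param per_accession named list: accession -> SVRecord data.frame.
#' @param max_dist breakpoint clustering distance (bp).
#' @param min_size records below this length are rejected (with a count
#'   reported as attribute `n_rejected`).
#' @param min_sim reciprocal size-similarity threshold.
#' @param nets optional named list: accession -> list of `synteny_net`
#'   (per reference chromosome), used to assign missing genotypes.
#' @param size_filter_types types subject to `min_size` (INS/DEL).
#' @return an object of class `sv_callset`: list with `records` (data.frame
#'   incl. `support`), `genotypes` (records x accessions matrix in
#'   {0,1,NA}), `params`.
#' @export
merge_callsets <- function(per_accession, max_dist = 1000L, min_size = 50L,
                           min_sim = 0.5, nets = NULL,
                           size_filter_types = c("INS", "DEL")) {
  acc <- sort(names(per_accession))
  all <- do.call(rbind, lapply(acc, function(a) {
    r <- per_accession[[a]]
    if (nrow(r)) r$source <- a
    r
  }))
  n_rej <- 0L
  if (!is.null(all) && nrow(all)) {
    rej <- all$sv_type %in% size_filter_types & all$length < min_size
    n_rej <- sum(rej)
    all <- all[!rej, , drop = FALSE]
  }
  if (is.null(all) || nrow(all) == 0L) {
    cs <- structure(list(records = sv_record_df(),
                         genotypes = matrix(integer(0), 0, length(acc),
                                            dimnames = list(NULL, acc)),
                         params = list(max_dist = max_dist, min_size = min_size,
                                       min_sim = min_sim)),
                    class = "sv_callset")
    attr(cs, "n_rejected") <- n_rej
    return(cs)
  }
  cl <- cluster_sv_records(all, max_dist, min_sim)
  reps <- list(); genos <- list()
  for (g in unique(cl)) {
    members <- all[cl == g, , drop = FALSE]
    members <- members[order(members$source, members$pos), ]
    rep_rec <- members[1L, , drop = FALSE]
    rep_rec$support <- length(unique(members$source))
    gt <- setNames(rep(0L, length(acc)), acc)
    gt[unique(members$source)] <- 1L
    if (!is.null(nets)) {
      for (a in setdiff(acc, unique(members$source))) {
        net <- nets[[a]][[rep_rec$ref_chrom]]
        if (!is.null(net) && region_unaligned(net, rep_rec$pos, rep_rec$end)) {
          gt[a] <- NA_integer_
        }
      }
    }
    reps[[length(reps) + 1L]] <- rep_rec
    genos[[length(genos) + 1L]] <- gt
  }
  records <- do.call(rbind, reps)
  ord <- order(records$ref_chrom, records$pos)
  records <- records[ord, , drop = FALSE]
  genotypes <- do.call(rbind, genos)[ord, , drop = FALSE]
  rownames(records) <- NULL
  rownames(genotypes) <- NULL
  cs <- structure(list(records = records, genotypes = genotypes,
                       params = list(max_dist = max_dist, min_size = min_size,
                                     min_sim = min_sim)),
                  class = "sv_callset")
  attr(cs, "n_rejected") <- n_rej
  cs
}

region_unaligned <- function(net, pos, end) {
  for (ch in net$chains) {
    if (ch$ref_span[1] < end && ch$ref_span[2] > pos) return(FALSE)
  }
  TRUE
}

#' Multi-caller consensus filter
#'
#' Merges calls across callers with the clustering rule of
#' [merge_callsets()] and keeps clusters supported by at least
#' `min_support` distinct callers (the SURVIVOR-style consensus rule).
#'
#' @param calls_by_caller named list: caller -> SVRecord data.frame.
#' @param min_support minimum number of distinct supporting callers.
#' @param max_dist,min_sim clustering parameters.
#' @return SVRecord data.frame of surviving records (one per cluster, from
#'   the first caller in name order), with a `support` column.
#' @export
consensus_filter <- function(calls_by_caller, min_support = 2L,
                             max_dist = 1000L, min_sim = 0.5) {
  if (length(calls_by_caller) < 2L) stop("need at least 2 callers")
  if (min_support > length(calls_by_caller)) {
    stop("min_support exceeds the number of callers")
  }
  cs <- merge_callsets(calls_by_caller, max_dist = max_dist, min_sim = min_sim,
                       min_size = 0L)
  keep <- cs$records$support >= min_support
  out <- cs$records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# flank homology test for tandem duplications: equal-length window identity,
# with a local-alignment fallback for rotation-shifted breakpoints
flank_homology <- function(seq, flank, min_ident = 0.8) {
  if (!nzchar(flank)) return(FALSE)
  L <- nchar(seq)
  if (nchar(flank) >= L &&
      seq_identity(seq, substr(flank, 1L, L)) >= min_ident) return(TRUE)
  if (L > 5000L || nchar(flank) < 0.8 * L) return(FALSE)
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -1)
  pa <- Biostrings::pairwiseAlignment(Biostrings::DNAString(seq),
                                      Biostrings::DNAString(flank),
                                      type = "local", substitutionMatrix = sm,
                                      gapOpening = 5, gapExtension = 2)
  Biostrings::nchar(pa) >= 0.8 * L && Biostrings::pid(pa) >= 100 * min_ident
}

# fraction of positions matching at lag 2 (tandem dinucleotide signal)
dinucleotide_run_frac <- function(seq) {
  L <- nchar(seq)
  if (L < 4L) return(0)
  v <- strsplit(seq, "")[[1]]
  mean(v[seq_len(L - 2L)] == v[3:L])
}

detect_ltr_structure <- function(seq, tdr_lengths = c(300L, 200L, 100L, 50L),
                                 min_ident = 0.8) {
  L <- nchar(seq)
  for (tdr in tdr_lengths) {
    if (L < 2L * tdr) next
    if (seq_identity(substr(seq, 1L, tdr),
                     substring(seq, L - tdr + 1L)) >= min_ident) return(TRUE)
  }
  FALSE
}

detect_tir_structure <- function(seq, tir = 10L, min_ident = 0.9) {
  L <- nchar(seq)
  if (L < 2L * tir + 10L) return(FALSE)
  seq_identity(substr(seq, 1L, tir), revcomp(substring(seq, L - tir + 1L))) >= min_ident
}

#' Classify a structural variant by genomic-feature content
#'
#' Precedence: (i) satellite if at least 80% of the variant sequence is a
#' tandem dinucleotide run; (ii) tandem duplication if the variant sequence
#' matches an equal-length flanking window at >= 80% identity; (iii) LTR-TE
#' or DNA-TE -- for deletions by >= 50% coverage with reference TE
#' annotations of that class, for insertions by terminal-repeat structure of
#' the inserted sequence (long terminal direct repeats, or short terminal
#' inverted repeats); (iv) gene fragment if >= 50% covered by exons;
#' (v) complex if two or more feature classes each cover >= 20%; otherwise
#' unclassified.
#'
#' @param record one-row SVRecord data.frame (INS requires `alt_seq`).
#' @param te_annotations data.frame (chrom, start, end, class) of reference
#'   TE/satellite intervals (1-based closed).
#' @param exons data.frame (chrom, start, end) of exons.
#' @param ref named character vector of reference sequences (needed for the
#'   flank comparison; DEL also uses it for the satellite check).
#' @return feature class string.
#' @export
annotate_sv <- function(record, te_annotations, exons, ref) {
  type <- record$sv_type
  chrom <- record$ref_chrom
  ref_seq <- ref[[chrom]]
  if (type == "INS") {
    if (is.na(record$alt_seq) || !nzchar(record$alt_seq)) {
      stop("INS record without alt_seq cannot be annotated")
    }
    s <- record$alt_seq
    L <- nchar(s)
    if (dinucleotide_run_frac(s) >= 0.8) return("satellite")
    context <- substr(ref_seq, max(1L, record$pos - L + 1L),
                      min(nchar(ref_seq), record$pos + L))
    if (flank_homology(s, context)) return("tandem-dup")
    if (detect_ltr_structure(s)) return("LTR-TE")
    if (detect_tir_structure(s)) return("DNA-TE")
    return("unclassified")
  }
  if (type %in% c("DEL", "INV", "TRA")) {
    s0 <- record$pos + 1L; e0 <- record$end
    s <- substr(ref_seq, s0, e0)
    if (type == "DEL" && dinucleotide_run_frac(s) >= 0.8) return("satellite")
    if (type == "DEL") {
      L <- e0 - s0 + 1L
      context <- paste0(substr(ref_seq, max(1L, s0 - L), s0 - 1L),
                        substr(ref_seq, e0 + 1L, min(nchar(ref_seq), e0 + L)))
      if (flank_homology(s, context)) return("tandem-dup")
    }
    cov <- c()
    for (cls in c("LTR-TE", "DNA-TE")) {
      te <- te_annotations[te_annotations$chrom == chrom &
                             te_annotations$class == cls, , drop = FALSE]
      cov[cls] <- interval_coverage_frac(s0, e0, te$start, te$end)
    }
    ex <- exons[exons$chrom == chrom, , drop = FALSE]
    cov["gene-fragment"] <- interval_coverage_frac(s0, e0, ex$start, ex$end)
    if (any(cov >= 0.5)) return(names(cov)[which.max(cov)])
    if (sum(cov >= 0.2) >= 2L) return("complex")
    return("unclassified")
  }
  "unclassified"
}

#' Annotate every record of a callset
#'
#' @param callset an `sv_callset`.
#' @param te_annotations,exons,ref see [annotate_sv()].
#' @return the callset with `records$feature_class` filled in.
#' @export
annotate_callset <- function(callset, te_annotations, exons, ref) {
  rec <- callset$records
  for (i in seq_len(nrow(rec))) {
    rec$feature_class[i] <- annotate_sv(rec[i, ], te_annotations, exons, ref)
  }
  callset$records <- rec
  callset
}

#' Distance from a structural variant to the nearest gene
#'
#' @param record one-row SVRecord data.frame.
#' @param genes data.frame (chrom, start, end) of gene bodies, 1-based
#'   closed.
#' @return 0 if the variant overlaps any gene body, otherwise the minimum
#'   gap in bp to the nearest gene boundary on the same chromosome.
#' @export
distance_to_gene <- function(record, genes) {
  if (is.null(genes) || nrow(genes) == 0L) stop("empty gene set")
  g <- genes[genes$chrom == record$ref_chrom, , drop = FALSE]
  if (nrow(g) == 0L) return(Inf)
  s <- record$pos + 1L; e <- max(record$end, s)
  if (any(g$start <= e & g$end >= s)) return(0L)
  as.integer(min(pmax(g$start - e, s - g$end)))
}
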