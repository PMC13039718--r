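#' Simulation configuration for a synthetic accession panel
#'
#' Builds the fully-specified configuration consumed by [simulate_panel()].
#' The defaults define the study conditions used throughout the package's
#' tests: an inbred (haploid-representative) panel descended from a common
#' ancestral genome, with planted SNVs, small indels, TE insertions whose
#' length distribution peaks near 12 kb, deletions, tandem duplications,
#' dinucleotide-satellite expansions, one large inversion segregating at
#' intermediate frequency and linked to a binary fruit-colour trait, one
#' large translocation, a copy-number-variable resistance-gene cluster, and
#' one outgroup genome carrying the ancestral allele at every planted site.
#'
#' @param seed integer; fully determines all generator output.
#' @param n_accessions number of panel accessions (haploid-representative).
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length chromosome length in bp.
#' @param snv_rate planted-SNV density per bp (site density, not mutation rate).
#' @param small_indel_rate planted small-indel (< 50 bp) density per bp.
#' @param sv_counts named integer vector of planted SV counts with names
#'   `DEL`, `INS_TE`, `INS_DUP`, `INS_SAT`, `TRA` (the inversion is specified
#'   separately via `inversion_spec`).
#' @param te_length_mode modal TE insertion length in bp (lognormal mode).
#' @param inversion_spec list with `chrom`, `start`, `length`,
#'   `carrier_fraction`: one large inversion at intermediate frequency.
#' @param cnv_spec list describing the copy-number cluster: `chrom`,
#'   `eps_high_frac` and `roq_high_frac` (fractions of accessions in the
#'   high-copy class), copy ranges `eps_low`, `eps_high`, `roq_low`,
#'   `roq_high`.
#' @param trait_spec list of phenotype-model parameters, see
#'   [simulate_phenotypes()].
#' @param n_genes total number of gene models planted on the reference.
#' @param outgroup_snv_rate density of outgroup-private substitutions.
#' @param n_outgroup_deletions number of outgroup-private deletions (these
#'   create reference regions where the outgroup state is unknowable, so a
#'   realistic fraction of sites cannot be polarized).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_accessions = 8L,
                       n_chromosomes = 2L,
                       chrom_length = 1000000L,
                       snv_rate = 0.005,
                       small_indel_rate = 0.0005,
                       sv_counts = c(DEL = 90L, INS_TE = 70L, INS_DUP = 20L,
                                     INS_SAT = 18L, TRA = 1L),
                       te_length_mode = 12000L,
                       inversion_spec = list(chrom = 1L, start = 300001L,
                                             length = 150000L,
                                             carrier_fraction = 0.5044),
                       cnv_spec = list(chrom = NA_integer_,
                                       eps_high_frac = 0.3621,
                                       roq_high_frac = 0.2816,
                                       eps_low = 0:1, eps_high = 3:4,
                                       roq_low = 5:11, roq_high = 16:19),
                       trait_spec = list(carrier_exception_rate = 0.0348,
                                         noncarrier_purple_rate = 0.4911,
                                         incidence_means = c(TGG_Eplus_or_Rplus = 0.15,
                                                             TGG_EmRm = 0.50,
                                                             TGA_Eplus_or_Rplus = 0.60,
                                                             TGA_EmRm = 0.85),
                                         n_batches = 4L,
                                         batch_effects = c(-0.05, 0, 0.02, 0.03),
                                         n_seedlings = 24L,
                                         incidence_sd = 0.05),
                       n_genes = 240L,
                       outgroup_snv_rate = 0.003,
                       n_outgroup_deletions = 20L) {
  rates <- c(snv_rate, small_indel_rate, outgroup_snv_rate)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (inversion_spec$length < 10001) {
    stop("inversion length must exceed the 10 kb minimum inversion size")
  }
  cf <- inversion_spec$carrier_fraction
  if (cf <= 0 || cf >= 1) stop("carrier_fraction must lie in (0, 1)")
  if (n_accessions < 2) stop("need at least 2 accessions")
  sv_needed <- c("DEL", "INS_TE", "INS_DUP", "INS_SAT", "TRA")
  if (!all(sv_needed %in% names(sv_counts))) {
    stop("sv_counts must name: ", paste(sv_needed, collapse = ", "))
  }
  if (is.na(cnv_spec$chrom)) cnv_spec$chrom <- n_chromosomes
  structure(list(seed = as.integer(seed),
                 n_accessions = as.integer(n_accessions),
                 n_chromosomes = as.integer(n_chromosomes),
                 chrom_length = as.integer(chrom_length),
                 snv_rate = snv_rate,
                 small_indel_rate = small_indel_rate,
                 sv_counts = sv_counts,
                 te_length_mode = as.integer(te_length_mode),
                 inversion_spec = inversion_spec,
                 cnv_spec = cnv_spec,
                 trait_spec = trait_spec,
                 n_genes = as.integer(n_genes),
                 outgroup_snv_rate = outgroup_snv_rate,
                 n_outgroup_deletions = as.integer(n_outgroup_deletions)),
            class = "sim_config")
}

# ---- internal placement helpers ----------------------------------------

# sample `n` interval start positions of lengths `lens` on [1, chrom_len],
# avoiding `occupied` (data.frame start/end) with `buffer` bp slack.
place_intervals <- function(n, lens, chrom_len, occupied, buffer = 500L,
                            max_tries = 5000L, required = TRUE) {
  starts <- integer(0)
  occ_s <- occupied$start
  occ_e <- occupied$end
  for (i in seq_len(n)) {
    len <- lens[i]
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      s <- sample.int(max(chrom_len - len - buffer, 1L), 1L) + buffer
      e <- s + len - 1L
      if (e + buffer > chrom_len) next
      if (!any(occ_e >= s - buffer & occ_s <= e + buffer)) { ok <- TRUE; break }
    }
    if (!ok) {
      if (!required) { starts <- c(starts, NA_integer_); next }
      stop("infeasible packing: cannot place an interval of ", len,
           " bp on a ", chrom_len, " bp chromosome with ", buffer,
           " bp buffers; reduce sv_counts or lengths")
    }
    starts <- c(starts, s)
    occ_s <- c(occ_s, s)
    occ_e <- c(occ_e, e)
  }
  starts
}

# carrier counts from a 1/i neutral-like frequency spectrum over n accessions
draw_carrier_counts <- function(n_var, n_acc) {
  i <- seq_len(n_acc - 1L)
  sample(i, n_var, replace = TRUE, prob = 1 / i)
}

sample_carriers <- function(accessions, count) {
  sort(sample(accessions, count))
}

te_insertion_seq <- function(len, class) {
  if (class == "LTR-TE") {
    ltr <- random_dna(min(300L, max(50L, len %/% 4L)))
    body_len <- max(0L, len - 2L * nchar(ltr))
    paste0(ltr, random_dna(body_len), ltr)
  } else { # DNA-TE: 10-bp terminal inverted repeats
    tir <- random_dna(10L)
    body_len <- max(0L, len - 20L)
    paste0(tir, random_dna(body_len), revcomp(tir))
  }
}

#' Generate a synthetic accession panel with recorded ground truth
#'
#' Builds an ancestral reference genome, derives `n_accessions` genomes by
#' planting SNVs, small indels and structural variants with carrier sets
#' drawn from a 1/i frequency spectrum, and emits one outgroup genome that
#' carries the ancestral allele at every planted site (plus outgroup-private
#' divergence so that a realistic fraction of sites cannot be polarized).
#' Every edit is recorded in the returned truth set. Regenerating with the
#' same configuration is byte-identical.
#'
#' @param config a [sim_config()] object.
#' @return a list with elements `panel` (list: `reference`, `accessions`
#'   (named list of genomes), `outgroup`, `accession_names`) and `truth`
#'   (class `truth_set`: `variants`, `genes`, `exons`, `te_bed`,
#'   `expr_effects`, `cnv`, `cnv_loci`, `inversion_id`, `stop_locus`,
#'   `config`).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_acc <- config$n_accessions
  acc <- sprintf("S%03d", seq_len(n_acc))
  chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))
  L <- config$chrom_length

  # 1. ancestral / reference genome
  reference <- setNames(vapply(chroms, function(ch) random_dna(L), character(1)),
                        chroms)

  occupied <- setNames(lapply(chroms, function(ch) {
    data.frame(start = integer(0), end = integer(0))
  }), chroms)
  reserve <- function(ch, s, e) {
    occupied[[ch]] <<- rbind(occupied[[ch]], data.frame(start = s, end = e))
  }

  # 2. CNV cluster loci (annotation-level; coverage is simulated, not embedded)
  cnv_chrom <- chroms[config$cnv_spec$chrom]
  cnv_loci <- list(
    eps = list(chrom = cnv_chrom, start = 50001L, end = 52000L),
    roq = list(chrom = cnv_chrom, start = 60001L, end = 62000L),
    control = list(chrom = cnv_chrom, start = 70001L, end = 72000L))
  for (lc in cnv_loci) reserve(lc$chrom, lc$start, lc$end)

  # 3. inversion interval (reserved so no other SV overlaps it)
  inv <- config$inversion_spec
  inv_chrom <- chroms[inv$chrom]
  inv_start <- as.integer(inv$start)
  inv_end <- inv_start + as.integer(inv$length) - 1L
  if (inv_end > L) stop("infeasible packing: inversion exceeds chromosome length")
  reserve(inv_chrom, inv_start, inv_end)

  # translocation segment(s) are reserved before genes/TEs so a contiguous
  # >100 kb block is still available
  n_tra <- config$sv_counts[["TRA"]]
  tra_coords <- list()
  for (i in seq_len(n_tra)) {
    src_ch <- chroms[1]; dst_ch <- chroms[min(2, length(chroms))]
    tra_len <- 120000L
    s <- place_intervals(1L, tra_len, L, occupied[[src_ch]], buffer = 2000L)
    reserve(src_ch, s, s + tra_len - 1L)
    ins_at <- place_intervals(1L, 1L, L, occupied[[dst_ch]], buffer = 2000L)
    reserve(dst_ch, ins_at, ins_at)
    tra_coords[[i]] <- list(src_ch = src_ch, dst_ch = dst_ch, s = s,
                            len = tra_len, ins_at = ins_at)
  }

  # 4. gene models (annotation on the reference; sequence stays random)
  genes_per_chrom <- ceiling(config$n_genes / length(chroms))
  gene_rows <- list(); exon_rows <- list()
  gid <- 0L
  for (ch in chroms) {
    glens <- sample(1500:4000, genes_per_chrom, replace = TRUE)
    gstarts <- place_intervals(genes_per_chrom, glens, L, occupied[[ch]],
                               buffer = 500L)
    for (i in seq_len(genes_per_chrom)) {
      gid <- gid + 1L
      g_id <- sprintf("gene%04d", gid)
      s <- gstarts[i]; e <- s + glens[i] - 1L
      n_ex <- sample(2:5, 1L)
      # split the body into exons separated by fixed-fraction introns
      cuts <- sort(sample(seq(s + 100L, e - 100L), 2L * (n_ex - 1L)))
      bounds <- c(s, cuts, e)
      ex_s <- bounds[seq(1, length(bounds), by = 2)]
      ex_e <- bounds[seq(2, length(bounds), by = 2)]
      gene_rows[[gid]] <- data.frame(gene_id = g_id, chrom = ch, start = s,
                                     end = e,
                                     strand = sample(c("+", "-"), 1L),
                                     stringsAsFactors = FALSE)
      exon_rows[[gid]] <- data.frame(gene_id = g_id, chrom = ch,
                                     start = ex_s, end = ex_e,
                                     stringsAsFactors = FALSE)
      # genes themselves are not reserved: SVs may fall near or inside them
    }
  }
  genes <- do.call(rbind, gene_rows)
  exons <- do.call(rbind, exon_rows)

  # 5. reference TE / satellite annotation intervals (for DEL classification;
  #    satellites are written into the reference sequence so the deleted
  #    sequence itself is a true dinucleotide run)
  te_rows <- list()
  for (ch in chroms) {
    n_te <- 15L
    te_lens <- pmin(as.integer(round(stats::rlnorm(n_te,
      log(config$te_length_mode) + 0.35^2, 0.35))), 15000L)
    te_lens <- pmax(te_lens, 500L)
    te_starts <- place_intervals(n_te, te_lens, L, occupied[[ch]], buffer = 500L)
    te_class <- sample(c("LTR-TE", "DNA-TE"), n_te, replace = TRUE,
                       prob = c(0.7, 0.3))
    for (i in seq_len(n_te)) reserve(ch, te_starts[i], te_starts[i] + te_lens[i] - 1L)
    te_rows[[ch]] <- data.frame(chrom = ch, start = te_starts,
                                end = te_starts + te_lens - 1L,
                                class = te_class, stringsAsFactors = FALSE)
  }
  te_bed <- do.call(rbind, te_rows)
  rownames(te_bed) <- NULL

  # 6. plant SVs ---------------------------------------------------------
  sv_rows <- list()
  vid <- 0L
  add_variant <- function(type, ch, pos, end, len, alt, class, carriers) {
    vid <<- vid + 1L
    sv_rows[[vid]] <<- data.frame(
      id = sprintf("var%05d", vid), type = type, chrom = ch,
      pos = as.integer(pos), end = as.integer(end), length = as.integer(len),
      alt = alt, class = class,
      carriers = paste(carriers, collapse = ","), stringsAsFactors = FALSE)
    sprintf("var%05d", vid)
  }

  # 6a. translocations reserved above
  for (tc in tra_coords) {
    carriers <- sample_carriers(acc, draw_carrier_counts(1L, n_acc))
    add_variant("TRA", tc$src_ch, tc$s - 1L, tc$s + tc$len - 1L, tc$len,
                alt = sprintf("%s:%d", tc$dst_ch, tc$ins_at),
                class = "unclassified", carriers = carriers)
  }

  # 6b. the large inversion (carrier count is the deterministic rounding of
  #     carrier_fraction * n, recorded in the truth set)
  n_inv_car <- max(1L, min(n_acc - 1L, as.integer(round(inv$carrier_fraction * n_acc))))
  inv_carriers <- sample_carriers(acc, n_inv_car)
  inversion_id <- add_variant("INV", inv_chrom, inv_start - 1L, inv_end,
                              inv_end - inv_start + 1L, alt = NA_character_,
                              class = "unclassified", carriers = inv_carriers)

  # 6c. deletions: ~1/3 inside reference TEs, ~1/10 inside exons, rest neutral
  n_del <- config$sv_counts[["DEL"]]
  te_pool <- te_bed[te_bed$end - te_bed$start + 1L >= 2000L, ]
  n_del_te <- if (nrow(te_pool) > 0L) round(n_del / 3) else 0L
  n_del_exon <- round(n_del / 10)
  n_del_free <- n_del - n_del_te - n_del_exon
  del_counts <- draw_carrier_counts(max(n_del, 1L), n_acc)
  del_i <- 0L
  for (i in seq_len(n_del_te)) {
    row <- te_pool[sample.int(nrow(te_pool), 1L), ]
    dlen <- sample(300:1500, 1L)
    if (row$end - row$start - 100L <= dlen) dlen <- 200L
    s <- row$start + sample.int(row$end - row$start - dlen - 50L, 1L)
    del_i <- del_i + 1L
    add_variant("DEL", row$chrom, s - 1L, s + dlen - 1L, dlen, NA_character_,
                row$class, sample_carriers(acc, del_counts[del_i]))
    te_pool <- te_pool[te_pool$start != row$start | te_pool$chrom != row$chrom, ]
    if (nrow(te_pool) == 0L) break
  }
  big_ex <- exons[exons$end - exons$start + 1L >= 300L, ]
  used_genes <- character(0)
  for (i in seq_len(n_del_exon)) {
    pool <- big_ex[!big_ex$gene_id %in% used_genes, ]
    if (nrow(pool) == 0L) break
    row <- pool[sample.int(nrow(pool), 1L), ]
    used_genes <- c(used_genes, row$gene_id)
    dlen <- min(sample(60:150, 1L), row$end - row$start - 20L)
    s <- row$start + 10L
    del_i <- del_i + 1L
    add_variant("DEL", row$chrom, s - 1L, s + dlen - 1L, dlen, NA_character_,
                "gene-fragment", sample_carriers(acc, del_counts[del_i]))
  }
  for (i in seq_len(n_del_free)) {
    ch <- sample(chroms, 1L)
    dlen <- as.integer(round(exp(stats::runif(1, log(60), log(3000)))))
    s <- place_intervals(1L, dlen, L, occupied[[ch]], buffer = 500L)
    reserve(ch, s, s + dlen - 1L)
    del_i <- del_i + 1L
    add_variant("DEL", ch, s - 1L, s + dlen - 1L, dlen, NA_character_,
                "unclassified", sample_carriers(acc, del_counts[del_i]))
  }

  # 6d. TE insertions (lognormal length, mode te_length_mode, LTR-like or TIR)
  n_ins_te <- config$sv_counts[["INS_TE"]]
  te_ins_counts <- draw_carrier_counts(n_ins_te, n_acc)
  for (i in seq_len(n_ins_te)) {
    ch <- sample(chroms, 1L)
    len <- as.integer(round(stats::rlnorm(1, log(config$te_length_mode) + 0.35^2,
                                          0.35)))
    len <- max(min(len, 40000L), 60L)
    cls <- sample(c("LTR-TE", "DNA-TE"), 1L, prob = c(0.7, 0.3))
    s <- place_intervals(1L, 1L, L, occupied[[ch]], buffer = 500L)
    reserve(ch, s, s)
    add_variant("INS", ch, s, s, len, te_insertion_seq(len, cls), cls,
                sample_carriers(acc, te_ins_counts[i]))
  }

  # 6e. tandem duplications: insertion equal to the immediate left flank
  n_dup <- config$sv_counts[["INS_DUP"]]
  dup_counts <- draw_carrier_counts(n_dup, n_acc)
  for (i in seq_len(n_dup)) {
    ch <- sample(chroms, 1L)
    len <- sample(80:1500, 1L)
    s <- place_intervals(1L, 1L, L, occupied[[ch]], buffer = max(500L, len))
    reserve(ch, s, s)
    alt <- substr(reference[[ch]], s - len + 1L, s)
    add_variant("INS", ch, s, s, len, alt, "tandem-dup",
                sample_carriers(acc, dup_counts[i]))
  }

  # 6f. dinucleotide satellite expansions
  n_sat <- config$sv_counts[["INS_SAT"]]
  sat_counts <- draw_carrier_counts(n_sat, n_acc)
  for (i in seq_len(n_sat)) {
    ch <- sample(chroms, 1L)
    unit <- sample(c("AT", "TA", "CT", "AG"), 1L)
    reps <- sample(30:400, 1L)
    s <- place_intervals(1L, 1L, L, occupied[[ch]], buffer = 500L)
    reserve(ch, s, s)
    add_variant("INS", ch, s, s, 2L * reps, strrep(unit, reps), "satellite",
                sample_carriers(acc, sat_counts[i]))
  }

  variants <- do.call(rbind, sv_rows)

  # 7. SNVs and small indels outside all reserved SV intervals -------------
  small_rows <- list()
  sv_sofar <- variants
  for (ch in chroms) {
    vv <- sv_sofar[sv_sofar$chrom == ch, , drop = FALSE]
    # exclusion zones: DEL/INS edit intervals (padded), INV/TRA breakpoints
    ex_s <- integer(0); ex_e <- integer(0)
    simple <- vv$type %in% c("DEL", "INS")
    ex_s <- c(ex_s, vv$pos[simple] - 50L)
    ex_e <- c(ex_e, vv$end[simple] + 50L)
    brk <- which(vv$type %in% c("INV", "TRA"))
    ex_s <- c(ex_s, vv$pos[brk] - 200L, vv$end[brk] - 200L)
    ex_e <- c(ex_e, vv$pos[brk] + 200L, vv$end[brk] + 200L)
    n_snv <- stats::rpois(1, config$snv_rate * L)
    n_ind <- stats::rpois(1, config$small_indel_rate * L)
    pos <- sort(sample.int(L - 100L, n_snv + n_ind) + 50L)
    bad <- rep(FALSE, length(pos))
    if (length(ex_s)) {
      hit <- IRanges::findOverlaps(IRanges::IRanges(pos, pos),
                                   IRanges::IRanges(ex_s, ex_e))
      bad[unique(S4Vectors::queryHits(hit))] <- TRUE
    }
    pos <- pos[!bad]
    # enforce >= 10 bp spacing so edits never interfere
    if (length(pos) > 1) pos <- pos[c(TRUE, diff(pos) >= 10L)]
    n_tot <- length(pos)
    if (n_tot == 0L) next
    is_ind <- seq_len(n_tot) %in% sample.int(n_tot, min(n_ind, n_tot))
    counts <- draw_carrier_counts(n_tot, n_acc)
    refch <- reference[[ch]]
    typ <- ifelse(is_ind, "INDEL", "SNV")
    alt <- character(n_tot)
    len <- integer(n_tot)
    endp <- integer(n_tot)
    refbase <- substring(refch, pos, pos)
    for (j in seq_len(n_tot)) {
      if (!is_ind[j]) {
        alt[j] <- sample(setdiff(DNA_BASES, refbase[j]), 1L)
        len[j] <- 1L; endp[j] <- pos[j]
      } else if (stats::runif(1) < 0.5) { # small insertion after pos
        l <- sample(1:8, 1L)
        alt[j] <- random_dna(l); len[j] <- l; endp[j] <- pos[j]
      } else {                            # small deletion of pos+1 .. pos+l
        l <- sample(1:8, 1L)
        alt[j] <- NA_character_; len[j] <- -l; endp[j] <- pos[j] + l
      }
    }
    carriers <- vapply(counts, function(k) paste(sample_carriers(acc, k),
                                                 collapse = ","), character(1))
    # the inversion suppresses recombination: the inverted haplotype is a
    # uniform founder copy while the ancestral arrangement keeps
    # segregating, so most variants inside the interval either tag the
    # inversion exactly (arose on the inverted copy) or segregate only
    # among non-carriers
    if (ch == inv_chrom) {
      non_car <- setdiff(acc, inv_carriers)
      linked <- which(pos >= inv_start - 2000L & pos <= inv_end + 2000L &
                        stats::runif(n_tot) < 0.7)
      for (jj in linked) {
        if (stats::runif(1) < 0.3 || length(non_car) < 2L) {
          carriers[jj] <- paste(inv_carriers, collapse = ",")
        } else {
          kk <- sample.int(length(non_car) - 1L, 1L)
          carriers[jj] <- paste(sort(sample(non_car, kk)), collapse = ",")
        }
      }
    }
    small_rows[[ch]] <- data.frame(
      id = sprintf("%s_sm%06d", ch, seq_len(n_tot)), type = typ, chrom = ch,
      pos = pos, end = endp, length = len, alt = alt, class = "small",
      carriers = carriers, stringsAsFactors = FALSE)
  }
  variants <- rbind(variants, do.call(rbind, small_rows))
  rownames(variants) <- NULL

  # 8. the stop-codon locus: a dedicated G->A SNV at ~50% frequency
  stop_ch <- cnv_chrom
  stop_pos <- 80001L
  while (substring(reference[[stop_ch]], stop_pos, stop_pos) == "A" ||
         any(variants$chrom == stop_ch & abs(variants$pos - stop_pos) < 60)) {
    stop_pos <- stop_pos + 13L
  }
  stop_carriers <- sample_carriers(acc, max(1L, round(n_acc / 2)))
  variants <- rbind(variants, data.frame(
    id = "var_stop", type = "SNV", chrom = stop_ch, pos = stop_pos,
    end = stop_pos, length = 1L, alt = "A", class = "stop-codon",
    carriers = paste(stop_carriers, collapse = ","), stringsAsFactors = FALSE))

  # 9. CNV copy numbers per accession
  cs <- config$cnv_spec
  n_eps_hi <- round(cs$eps_high_frac * n_acc)
  n_roq_hi <- round(cs$roq_high_frac * n_acc)
  eps_hi <- sample(acc, n_eps_hi)
  roq_hi <- sample(acc, n_roq_hi)
  cnv <- data.frame(
    accession = acc,
    eps_copies = ifelse(acc %in% eps_hi,
                        sample(cs$eps_high, n_acc, replace = TRUE),
                        sample(cs$eps_low, n_acc, replace = TRUE)),
    roq_copies = ifelse(acc %in% roq_hi,
                        sample(cs$roq_high, n_acc, replace = TRUE),
                        sample(cs$roq_low, n_acc, replace = TRUE)),
    stringsAsFactors = FALSE)

  # 10. expression effects for genes with an SV within 2 kb
  svv <- variants[variants$type %in% c("DEL", "INS"), ]
  eff_rows <- list()
  k <- 0L
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    near <- svv[svv$chrom == g$chrom &
                  svv$end >= g$start - 2000L & svv$pos <= g$end + 2000L, ]
    if (nrow(near) == 0L || stats::runif(1) > 0.6) next
    k <- k + 1L
    n_t <- sample(1:3, 1L)
    eff_rows[[k]] <- data.frame(
      gene_id = g$gene_id,
      sv_id = near$id[1],
      effect_log2 = sample(c(-1, 1), 1L) * stats::runif(1, 0.5, 2),
      tissues = paste(sort(sample.int(5L, n_t)), collapse = ","),
      stringsAsFactors = FALSE)
  }
  expr_effects <- if (k > 0) do.call(rbind, eff_rows) else
    data.frame(gene_id = character(0), sv_id = character(0),
               effect_log2 = numeric(0), tissues = character(0))

  # 11. build accession genomes by applying each accession's edits
  genomes <- setNames(lapply(acc, function(a) {
    apply_truth_edits(reference, variants, a)
  }), acc)

  # 12. outgroup: ancestral at all planted sites + private divergence
  og_variants <- local({
    rows <- list(); m <- 0L
    for (ch in chroms) {
      occ <- occupied[[ch]]
      n_og <- stats::rpois(1, config$outgroup_snv_rate * L)
      pos <- sort(sample.int(L - 100L, n_og) + 50L)
      pos <- pos[!pos %in% variants$pos[variants$chrom == ch]]
      if (length(pos) > 1) pos <- pos[c(TRUE, diff(pos) >= 10L)]
      if (length(pos) > 0) {
        refb <- substring(reference[[ch]], pos, pos)
        alt <- vapply(refb, function(b) sample(setdiff(DNA_BASES, b), 1L),
                      character(1), USE.NAMES = FALSE)
        m <- m + 1L
        rows[[m]] <- data.frame(id = sprintf("%s_og%05d", ch, seq_along(pos)),
                                type = "SNV", chrom = ch, pos = pos, end = pos,
                                length = 1L, alt = alt, class = "outgroup",
                                carriers = "OUT", stringsAsFactors = FALSE)
      }
      # outgroup-private deletions: windows where polarization is impossible
      n_dels <- ceiling(config$n_outgroup_deletions / length(chroms))
      if (n_dels == 0L) next
      dl_max <- max(2000L, min(6000L, L %/% 30L))
      dl <- sample(seq(1000L, dl_max), n_dels, replace = TRUE)
      ds <- place_intervals(n_dels, dl, L, occ, buffer = 100L,
                            required = FALSE)
      placed <- !is.na(ds)
      ds <- ds[placed]; dl <- dl[placed]; n_dels <- sum(placed)
      if (n_dels == 0L) next
      m <- m + 1L
      rows[[m]] <- data.frame(id = sprintf("%s_ogdel%03d", ch, seq_len(n_dels)),
                              type = "DEL", chrom = ch, pos = ds - 1L,
                              end = ds + dl - 1L, length = dl,
                              alt = NA_character_, class = "outgroup",
                              carriers = "OUT", stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
  if (is.null(og_variants)) og_variants <- variants[0, , drop = FALSE]
  outgroup <- apply_truth_edits(reference, og_variants, "OUT")

  truth <- structure(list(variants = variants, genes = genes, exons = exons,
                          te_bed = te_bed, expr_effects = expr_effects,
                          cnv = cnv, cnv_loci = cnv_loci,
                          inversion_id = inversion_id,
                          stop_locus = list(id = "var_stop",
                                            carriers = stop_carriers),
                          outgroup_variants = og_variants,
                          accessions = acc, config = config),
                     class = "truth_set")
  list(panel = list(reference = reference, accessions = genomes,
                    outgroup = outgroup, accession_names = acc),
       truth = truth)
}

#' Apply an accession's recorded edits to the reference genome
#'
#' Reconstructs an accession genome from the reference and the truth-set
#' variant table in a single left-to-right pass per chromosome (the
#' generator itself uses this function, so the round-trip property is
#' testable against an independent re-implementation). Edits nested inside
#' an inversion or translocation segment are applied to the segment before
#' it is inverted or moved.
#'
#' @param reference named character vector of chromosome sequences.
#' @param variants truth-set variant data.frame.
#' @param accession accession name whose carried edits are applied.
#' @return named character vector of edited chromosome sequences.
#' @export
apply_truth_edits <- function(reference, variants, accession) {
  carried <- variants[vapply(strsplit(variants$carriers, ","),
                             function(x) accession %in% x, logical(1)), ,
                      drop = FALSE]
  genome <- reference
  if (nrow(carried) == 0L) return(genome)
  # extract translocated segments first (their internal edits applied at
  # reference coordinates), then run one linear pass per chromosome
  tra <- carried[carried$type == "TRA", , drop = FALSE]
  tra_ins <- list()
  drop_ids <- character(0)
  for (i in seq_len(nrow(tra))) {
    v <- tra[i, ]
    inner <- carried[carried$chrom == v$chrom & carried$type != "TRA" &
                       carried$pos > v$pos & carried$end <= v$end, ,
                     drop = FALSE]
    seg <- apply_edits_linear(substr(reference[[v$chrom]], v$pos + 1L, v$end),
                              shift_edits(inner, -v$pos))
    dst <- strsplit(v$alt, ":", fixed = TRUE)[[1]]
    tra_ins[[length(tra_ins) + 1L]] <- list(chrom = dst[1],
                                            at = as.integer(dst[2]),
                                            seq = seg)
    drop_ids <- c(drop_ids, v$id, inner$id)
  }
  rest <- carried[!carried$id %in% drop_ids, , drop = FALSE]
  for (ch in names(genome)) {
    ed <- rest[rest$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(tra))) {
      if (tra$chrom[i] == ch) {  # source cut behaves like a deletion
        ed <- rbind(ed, data.frame(id = paste0("tra_cut", i), type = "DEL",
                                   chrom = ch, pos = tra$pos[i],
                                   end = tra$end[i], length = tra$length[i],
                                   alt = NA_character_, class = "",
                                   carriers = "", stringsAsFactors = FALSE))
      }
    }
    for (tr in tra_ins) {
      if (tr$chrom == ch) {      # destination paste behaves like an insertion
        ed <- rbind(ed, data.frame(id = "tra_paste", type = "INS", chrom = ch,
                                   pos = tr$at, end = tr$at,
                                   length = nchar(tr$seq), alt = tr$seq,
                                   class = "", carriers = "",
                                   stringsAsFactors = FALSE))
      }
    }
    genome[[ch]] <- apply_edits_linear(genome[[ch]], ed)
  }
  genome
}

shift_edits <- function(ed, off) {
  ed$pos <- ed$pos + off
  ed$end <- ed$end + off
  ed
}

# one ascending pass over non-overlapping edits; edits nested inside an
# inversion are applied to the segment before reverse-complementing
apply_edits_linear <- function(seq, ed) {
  if (nrow(ed) == 0L) return(seq)
  ed <- ed[order(ed$pos), , drop = FALSE]
  pieces <- character(0)
  cur <- 1L
  i <- 1L
  n <- nrow(ed)
  while (i <= n) {
    v <- ed[i, ]
    if (v$type == "INV") {
      j <- i + 1L
      while (j <= n && ed$pos[j] > v$pos && ed$end[j] <= v$end) j <- j + 1L
      inner <- ed[seq_len(n) > i & seq_len(n) < j, , drop = FALSE]
      pieces <- c(pieces, substr(seq, cur, v$pos),
                  revcomp(apply_edits_linear(substr(seq, v$pos + 1L, v$end),
                                             shift_edits(inner, -v$pos))))
      cur <- v$end + 1L
      i <- j
    } else if (v$type == "SNV") {
      pieces <- c(pieces, substr(seq, cur, v$pos - 1L), v$alt)
      cur <- v$pos + 1L; i <- i + 1L
    } else if (v$type == "INS" || (v$type == "INDEL" && v$length > 0)) {
      pieces <- c(pieces, substr(seq, cur, v$pos), v$alt)
      cur <- v$pos + 1L; i <- i + 1L
    } else {  # DEL or deletion-type small indel: remove pos+1 .. end
      pieces <- c(pieces, substr(seq, cur, v$pos))
      cur <- v$end + 1L; i <- i + 1L
    }
  }
  paste(c(pieces, substring(seq, cur)), collapse = "")
}

#' Simulate a tissue-wise TPM expression matrix with planted SV effects
#'
#' Each gene gets a lognormal baseline and per-tissue offsets shared by all
#' accessions; genes listed in the truth set's expression effects are
#' multiplied by `2^effect_log2` in the affected tissues for SV carriers.
#' Effects are tissue-restricted so that carrier profiles change shape, not
#' just scale (a pure scaling would be invisible to a correlation distance).
#'
#' @param truth a `truth_set`.
#' @param n_tissues number of tissues (default 5: leaf, root, stem, flower,
#'   fruit).
#' @param noise_sd log2-scale multiplicative noise SD (0 = deterministic).
#' @param seed optional seed for this stage.
#' @return 3-d array genes x accessions x tissues of TPM-scale values.
#' @export
simulate_expression <- function(truth, n_tissues = 5L, noise_sd = 0.25,
                                seed = NULL) {
  stopifnot(inherits(truth, "truth_set"))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  genes <- truth$genes$gene_id
  acc <- truth$accessions
  tissues <- c("leaf", "root", "stem", "flower", "fruit",
               sprintf("tissue%d", seq_len(max(0, n_tissues - 5))))[seq_len(n_tissues)]
  base <- stats::rnorm(length(genes), 4, 1.5)
  toff <- matrix(stats::rnorm(length(genes) * n_tissues, 0, 1),
                 length(genes), n_tissues)
  log2tpm <- array(rep(base, times = length(acc) * n_tissues),
                   dim = c(length(genes), length(acc), n_tissues),
                   dimnames = list(genes, acc, tissues))
  for (ti in seq_len(n_tissues)) {
    log2tpm[, , ti] <- log2tpm[, , ti] + toff[, ti]
  }
  # planted effects: carriers of the linked SV shift by effect_log2 in the
  # recorded tissues
  ef <- truth$expr_effects
  if (nrow(ef) > 0) {
    vmap <- truth$variants
    for (i in seq_len(nrow(ef))) {
      gi <- match(ef$gene_id[i], genes)
      v <- vmap[vmap$id == ef$sv_id[i], ]
      carriers <- strsplit(v$carriers, ",")[[1]]
      ai <- which(acc %in% carriers)
      tis <- as.integer(strsplit(ef$tissues[i], ",")[[1]])
      tis <- tis[tis <= n_tissues]
      for (ti in tis) log2tpm[gi, ai, ti] <- log2tpm[gi, ai, ti] + ef$effect_log2[i]
    }
  }
  if (noise_sd > 0) {
    log2tpm <- log2tpm + array(stats::rnorm(length(log2tpm), 0, noise_sd),
                               dim = dim(log2tpm))
  }
  2^log2tpm
}

#' Simulate fruit-colour and bacterial-wilt incidence phenotypes
#'
#' Colour: inversion carriers are purple unless they carry the planted
#' second-locus loss-of-function exception (rate
#' `trait_spec$carrier_exception_rate`); non-carriers are purple with
#' probability `noncarrier_purple_rate` (a second, unlinked determinant
#' segregates in the ancestral background). Incidence: the premature-stop
#' locus is epistatic over both copy-number loci; per-batch rates are drawn
#' binomially around the group means in `trait_spec$incidence_means` (with
#' `incidence_sd = 0` and zero batch effects the rates equal the linear
#' predictor exactly).
#'
#' @param truth a `truth_set`.
#' @param trait_spec overrides `truth$config$trait_spec`.
#' @param seed optional seed for this stage.
#' @return a `trait_table` list: `color` (per-accession data.frame),
#'   `incidence` (accession x batch data.frame with counts and rates),
#'   `loci` (per-accession genotype labels: stop_codon TGG/TGA, EPS E+/E-,
#'   ROQ R+/R-, inversion 0/0 or 1/1, combination label).
#' @export
simulate_phenotypes <- function(truth, trait_spec = NULL, seed = NULL) {
  stopifnot(inherits(truth, "truth_set"))
  ts <- trait_spec %||% truth$config$trait_spec
  if (!is.null(seed)) set.seed(seed)
  acc <- truth$accessions
  inv <- truth$variants[truth$variants$id == truth$inversion_id, ]
  if (nrow(inv) == 0L) stop("inversion locus missing from truth set")
  if (is.null(truth$cnv) || nrow(truth$cnv) == 0L) {
    stop("CNV locus missing from truth set")
  }
  inv_car <- strsplit(inv$carriers, ",")[[1]]
  is_car <- acc %in% inv_car

  # colour
  exception <- is_car & stats::runif(length(acc)) < ts$carrier_exception_rate
  purple <- ifelse(is_car, !exception,
                   stats::runif(length(acc)) < ts$noncarrier_purple_rate)
  color <- data.frame(accession = acc,
                      inversion = ifelse(is_car, "1/1", "0/0"),
                      color = ifelse(purple, "purple", "green"),
                      ans_exception = exception, stringsAsFactors = FALSE)

  # locus labels
  stopc <- acc %in% truth$stop_locus$carriers
  eps <- truth$cnv$eps_copies[match(acc, truth$cnv$accession)]
  roq <- truth$cnv$roq_copies[match(acc, truth$cnv$accession)]
  loci <- data.frame(accession = acc,
                     stop_codon = ifelse(stopc, "TGA", "TGG"),
                     EPS = ifelse(eps >= 3, "E+", "E-"),
                     ROQ = ifelse(roq >= 13, "R+", "R-"),
                     inversion = ifelse(is_car, "1/1", "0/0"),
                     stringsAsFactors = FALSE)
  loci$combination <- paste(loci$stop_codon, loci$EPS, loci$ROQ, sep = "_")

  # incidence: stop locus epistatic over both CNV loci
  mu <- ifelse(!stopc & (loci$EPS == "E+" | loci$ROQ == "R+"),
               ts$incidence_means[["TGG_Eplus_or_Rplus"]],
        ifelse(!stopc, ts$incidence_means[["TGG_EmRm"]],
        ifelse(loci$EPS == "E+" | loci$ROQ == "R+",
               ts$incidence_means[["TGA_Eplus_or_Rplus"]],
               ts$incidence_means[["TGA_EmRm"]])))
  nb <- ts$n_batches
  be <- ts$batch_effects[seq_len(nb)]
  rows <- list()
  for (b in seq_len(nb)) {
    p <- pmin(pmax(mu + be[b] +
                     if (ts$incidence_sd > 0)
                       stats::rnorm(length(acc), 0, ts$incidence_sd) else 0,
                   0), 1)
    if (ts$incidence_sd > 0) {
      dead <- stats::rbinom(length(acc), ts$n_seedlings, p)
      rate <- dead / ts$n_seedlings
    } else {
      dead <- p * ts$n_seedlings
      rate <- p
    }
    rows[[b]] <- data.frame(accession = acc, batch = b,
                            n_total = ts$n_seedlings, n_dead_or_wilt = dead,
                            rate = rate, stringsAsFactors = FALSE)
  }
  incidence <- do.call(rbind, rows)
  structure(list(color = color, incidence = incidence, loci = loci,
                 group_means = mu),
            class = "trait_table")
}

#' Simulate per-locus read-depth coverage from copy numbers
#'
#' Mean depth over each interval is proportional to that accession's copy
#' number with multiplicative lognormal noise; the single-copy control
#' interval has copy number 1 in every accession.
#'
#' @param truth a `truth_set`.
#' @param depth_mean haploid mean depth (> 0).
#' @param noise_sd lognormal sd of the multiplicative noise (0 = exact).
#' @param locus_copies optional named list overriding copies: per locus a
#'   named integer vector accession -> copies. Defaults to the truth CNV
#'   table for `eps` and `roq`.
#' @param seed optional seed.
#' @return data.frame (accession, locus, mean_depth).
#' @export
simulate_coverage <- function(truth, depth_mean = 30, noise_sd = 0,
                              locus_copies = NULL, seed = NULL) {
  stopifnot(inherits(truth, "truth_set"))
  if (depth_mean <= 0) stop("depth_mean must be > 0")
  if (!is.null(seed)) set.seed(seed)
  acc <- truth$accessions
  if (is.null(locus_copies)) {
    locus_copies <- list(
      eps = setNames(truth$cnv$eps_copies, truth$cnv$accession),
      roq = setNames(truth$cnv$roq_copies, truth$cnv$accession))
  }
  loci <- c(names(locus_copies), "control")
  rows <- list()
  for (lc in loci) {
    copies <- if (lc == "control") setNames(rep(1L, length(acc)), acc)
              else locus_copies[[lc]]
    noise <- if (noise_sd > 0) exp(stats::rnorm(length(acc), 0, noise_sd)) else 1
    rows[[lc]] <- data.frame(accession = acc, locus = lc,
                             mean_depth = depth_mean * as.numeric(copies[acc]) * noise,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate inversion-breakpoint junction support
#'
#' Emulates short-read junction evidence at the planted inversion:
#' carriers produce inverted-orientation junction reads, non-carriers
#' reference-orientation reads, both Poisson around `depth`, with a small
#' cross-contamination rate.
#'
#' @param truth a `truth_set`.
#' @param depth expected junction support in the true orientation.
#' @param error_rate expected spurious support in the wrong orientation.
#' @param dropout_frac fraction of accessions with (near) no evidence,
#'   producing missing genotype calls.
#' @param seed optional seed.
#' @return data.frame (accession, ref_support, inv_support).
#' @export
simulate_inversion_junctions <- function(truth, depth = 20, error_rate = 0.3,
                                         dropout_frac = 0, seed = NULL) {
  stopifnot(inherits(truth, "truth_set"))
  if (!is.null(seed)) set.seed(seed)
  acc <- truth$accessions
  inv <- truth$variants[truth$variants$id == truth$inversion_id, ]
  carriers <- strsplit(inv$carriers, ",")[[1]]
  is_car <- acc %in% carriers
  lam_true <- rep(depth, length(acc))
  if (dropout_frac > 0) {
    drop <- stats::runif(length(acc)) < dropout_frac
    lam_true[drop] <- 0.2
  }
  inv_support <- stats::rpois(length(acc), ifelse(is_car, lam_true, error_rate))
  ref_support <- stats::rpois(length(acc), ifelse(is_car, error_rate, lam_true))
  data.frame(accession = acc, ref_support = ref_support,
             inv_support = inv_support, stringsAsFactors = FALSE)
}

#' Genotype matrix directly from the truth set
#'
#' Builds the biallelic sites-by-accessions genotype matrix that the panel's
#' emitted genomes imply, straight from the recorded edits (0 = reference
#' allele, 1 = planted derived allele). The outgroup column carries 0
#' everywhere except sites falling inside outgroup-private deletions, which
#' are missing.
#'
#' @param truth a `truth_set`.
#' @param types variant types to include.
#' @param include_outgroup add an `OUT` column with missing calls where the
#'   outgroup sequence is deleted.
#' @return a [variant_matrix()] object.
#' @export
truth_variant_matrix <- function(truth, types = c("SNV", "INDEL", "DEL", "INS"),
                                 include_outgroup = TRUE) {
  v <- truth$variants[truth$variants$type %in% types, ]
  acc <- truth$accessions
  geno <- matrix(0L, nrow(v), length(acc), dimnames = list(v$id, acc))
  carr <- strsplit(v$carriers, ",")
  for (i in seq_len(nrow(v))) geno[i, carr[[i]]] <- 1L
  sites <- data.frame(chrom = v$chrom, pos = v$pos, ref = "N", alt = "N",
                      class = ifelse(v$type %in% c("DEL", "INS"),
                                     paste0("SV-", v$class),
                                     ifelse(v$type == "SNV", "SNV-other",
                                            "indel")),
                      stringsAsFactors = FALSE)
  if (include_outgroup) {
    og <- rep(0L, nrow(v))
    ogd <- truth$outgroup_variants
    ogd <- ogd[ogd$type == "DEL", ]
    for (i in seq_len(nrow(ogd))) {
      inside <- v$chrom == ogd$chrom[i] & v$pos > ogd$pos[i] & v$pos <= ogd$end[i]
      og[inside] <- NA_integer_
    }
    geno <- cbind(geno, OUT = og)
  }
  variant_matrix(sites, geno)
}

#' Write / read a simulation configuration as YAML
#'
#' @param config a `sim_config`.
#' @param path YAML file.
#' @return `write_sim_config` the path; `read_sim_config` a `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  x <- unclass(config)
  x$sv_counts <- as.list(x$sv_counts)
  x$trait_spec$incidence_means <- as.list(x$trait_spec$incidence_means)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$sv_counts <- unlist(x$sv_counts)
  x$trait_spec$incidence_means <- unlist(x$trait_spec$incidence_means)
  do.call(sim_config, x)
}
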