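test_that("planted deletions and insertions are recovered with exact
           breakpoints and alt sequences", {
  sim <- small_sim()
  calls <- small_calls()
  truth <- sim$truth
  a <- sim$panel$accession_names[1]
  sv <- calls$sv[[a]]
  tv <- truth_for(truth, a, c("DEL", "INS"))
  hit <- match_truth_calls(tv, sv)
  expect_true(all(hit))
  # a TE insertion's called alt sequence equals the planted sequence
  te <- tv[tv$type == "INS" & tv$class %in% c("LTR-TE", "DNA-TE"), ][1, ]
  got <- sv[sv$ref_chrom == te$chrom & abs(sv$pos - te$pos) <= 10 &
              sv$sv_type == "INS", ]
  expect_gte(nrow(got), 1L)
  # terminal repeats make the breakpoint ambiguous: the called allele may be
  # a rotation of the planted one (sequence-identical insertion)
  expect_equal(nchar(got$alt_seq[1]), nchar(te$alt))
  expect_true(grepl(got$alt_seq[1], paste0(te$alt, te$alt), fixed = TRUE))
  # windowed oracle: an independent pairwise alignment of the region around
  # a planted DEL must show one indel of exactly the planted length
  # pick a DEL with no other planted edit of this accession nearby, so the
  # window alignment sees exactly one event
  all_carried <- truth_for(truth, a, c("INDEL", "DEL", "INS", "INV", "TRA"))
  isolated <- vapply(seq_len(nrow(tv)), function(i) {
    tv$type[i] == "DEL" &&
      sum(all_carried$chrom == tv$chrom[i] &
            all_carried$end >= tv$pos[i] - 1100 &
            all_carried$pos <= tv$end[i] + 1100) == 1
  }, logical(1))
  d <- tv[isolated, ][1, ]
  win <- 1000L
  ref_win <- substr(sim$panel$reference[[d$chrom]], d$pos - win, d$pos + d$length + win)
  call_d <- sv[sv$sv_type == "DEL" & sv$ref_chrom == d$chrom &
                 abs(sv$pos - d$pos) <= 10, ][1, ]
  # locate the corresponding query window via the flanking sequence
  qry_seq <- sim$panel$accessions[[a]][[d$chrom]]
  left_fl <- substr(ref_win, 1, win)
  qpos <- as.integer(regexpr(left_fl, qry_seq, fixed = TRUE))
  expect_gt(qpos, 0)
  qry_win <- substr(qry_seq, qpos, qpos + win + win)
  pa <- Biostrings::pairwiseAlignment(Biostrings::DNAString(ref_win),
                                      Biostrings::DNAString(qry_win),
                                      type = "global")
  indel_bp <- sum(IRanges::width(Biostrings::deletion(pa)[[1]])) +
    sum(IRanges::width(Biostrings::insertion(pa)[[1]]))
  expect_equal(call_d$length, d$length)
  expect_equal(call_d$pos, d$pos)
  expect_equal(indel_bp, d$length)
})

test_that("inversions follow the >10 kb rule and translocations the
           >100 kb rule", {
  set.seed(31)
  ref <- c(chr1 = random_dna(60000))
  mkinv <- function(len) {
    s <- 20001L; e <- s + len - 1L
    q <- paste0(substr(ref[[1]], 1, s - 1),
                revcomp(substr(ref[[1]], s, e)),
                substring(ref[[1]], e + 1))
    net <- wga_align(ref, c(chr1 = q))[["chr1"]]
    call_variants_from_net(net, ref, c(chr1 = q))$sv
  }
  big <- mkinv(15000)
  expect_equal(sum(big$sv_type == "INV"), 1L)
  inv <- big[big$sv_type == "INV", ]
  expect_lt(abs(inv$pos - 20000), 50)
  expect_lt(abs(inv$length - 15000), 100)
  small <- mkinv(9000)
  expect_equal(sum(small$sv_type == "INV"), 0L)
})

test_that("chromosome-name mismatches are rejected", {
  set.seed(33)
  ref <- c(chrA = random_dna(3000))
  net <- wga_align(ref, ref)[["chrA"]]
  expect_error(call_variants_from_net(net, c(chrB = ref[[1]]), ref),
               "mismatch")
})

test_that("merging matches exhaustive single-linkage clustering and keeps
           type separation", {
  mk <- function(type, pos, len, acc) {
    data.frame(sv_type = type, ref_chrom = "chr1", pos = pos,
               end = pos + ifelse(type == "DEL", len, 0L), length = len,
               alt_seq = NA_character_, source = acc,
               feature_class = "unclassified", stringsAsFactors = FALSE)
  }
  # one accession: records pass through with support 1
  one <- merge_callsets(list(A = mk("DEL", c(100L, 5000L), c(60L, 100L), "A")))
  expect_equal(nrow(one$records), 2L)
  expect_true(all(one$records$support == 1L))
  # same DEL offset by 800 bp in two accessions: one record, support 2
  two <- merge_callsets(list(A = mk("DEL", 1000L, 200L, "A"),
                             B = mk("DEL", 1800L, 210L, "B")))
  expect_equal(nrow(two$records), 1L)
  expect_equal(two$records$support, 2L)
  expect_equal(unname(two$genotypes[1, ]), c(1L, 1L))
  # DEL and INS at the same position never merge
  mix <- merge_callsets(list(A = mk("DEL", 1000L, 100L, "A"),
                             B = mk("INS", 1000L, 100L, "B")))
  expect_equal(nrow(mix$records), 2L)
  # randomized records vs exhaustive O(n^2) single-linkage oracle
  set.seed(7)
  recs <- do.call(rbind, lapply(LETTERS[1:5], function(acc) {
    mk("DEL", sort(sample.int(30000, 10)), sample(c(60L, 70L, 500L), 10,
                                                  replace = TRUE), acc)
  }))
  per_acc <- split(recs, recs$source)
  got <- merge_callsets(per_acc, max_dist = 1000L, min_sim = 0.5)
  # oracle: union-find over all pairs
  n <- nrow(recs)
  par <- seq_len(n)
  findr <- function(i) { while (par[i] != i) i <- par[i]; i }
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (abs(recs$pos[i] - recs$pos[j]) <= 1000 &&
        min(recs$length[i], recs$length[j]) /
          max(recs$length[i], recs$length[j]) >= 0.5) {
      par[findr(j)] <- findr(i)
    }
  }
  n_clusters <- length(unique(vapply(seq_len(n), findr, integer(1))))
  expect_equal(nrow(got$records), n_clusters)
  # idempotence: re-merging the merged records changes nothing
  again <- merge_callsets(split(got$records, got$records$source),
                          max_dist = 1000L, min_sim = 0.5)
  expect_equal(nrow(again$records), nrow(got$records))
  # permutation stability of representative coordinates
  got_rev <- merge_callsets(per_acc[rev(names(per_acc))])
  expect_equal(got$records$pos, got_rev$records$pos)
  # sub-size records are rejected and counted
  small <- merge_callsets(list(A = mk("DEL", 100L, 30L, "A")))
  expect_equal(nrow(small$records), 0L)
  expect_equal(attr(small, "n_rejected"), 1L)
})

test_that("consensus filter keeps records supported by enough callers", {
  mk <- function(pos, acc) data.frame(sv_type = "DEL", ref_chrom = "chr1",
                                      pos = pos, end = pos + 100L,
                                      length = 100L, alt_seq = NA_character_,
                                      source = acc,
                                      feature_class = "unclassified",
                                      stringsAsFactors = FALSE)
  identical3 <- list(svaba = mk(c(100L, 3000L, 9000L), "svaba"),
                     delly = mk(c(100L, 3000L, 9000L), "delly"),
                     manta = mk(c(100L, 3000L, 9000L), "manta"))
  out <- consensus_filter(identical3, min_support = 2)
  expect_equal(nrow(out), 3L)
  expect_true(all(out$support == 3L))
  # a record in exactly 1 of 3 callers is dropped
  lone <- identical3
  lone$svaba <- rbind(lone$svaba, mk(20000L, "svaba"))
  out2 <- consensus_filter(lone, min_support = 2)
  expect_equal(nrow(out2), 3L)
  expect_error(consensus_filter(identical3, min_support = 4), "min_support")
  expect_error(consensus_filter(identical3["svaba"]), "2 callers")
  # randomized sets vs brute-force cluster-support oracle
  set.seed(9)
  toy <- list()
  for (cal in c("x", "y", "z")) {
    toy[[cal]] <- mk(sort(sample(seq(100, 40000, by = 3000), 8)), cal)
  }
  surv <- consensus_filter(toy, min_support = 2)
  all_r <- do.call(rbind, toy)
  n <- nrow(all_r)
  par <- seq_len(n)
  findr <- function(i) { while (par[i] != i) i <- par[i]; i }
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (abs(all_r$pos[i] - all_r$pos[j]) <= 1000) par[findr(j)] <- findr(i)
  }
  roots <- vapply(seq_len(n), findr, integer(1))
  support <- tapply(all_r$source, roots, function(s) length(unique(s)))
  expect_equal(nrow(surv), sum(support >= 2))
})

test_that("feature-class annotation follows the documented precedence", {
  set.seed(41)
  ref <- c(chr1 = random_dna(20000))
  te_ann <- data.frame(chrom = "chr1", start = 5001L, end = 9000L,
                       class = "LTR-TE", stringsAsFactors = FALSE)
  exons <- data.frame(chrom = "chr1", start = 12001L, end = 12500L,
                      stringsAsFactors = FALSE)
  rec <- function(type, pos, end, len, alt = NA_character_) {
    data.frame(sv_type = type, ref_chrom = "chr1", pos = pos, end = end,
               length = len, alt_seq = alt, source = "A",
               feature_class = "unclassified", stringsAsFactors = FALSE)
  }
  # satellite: a pure dinucleotide run
  expect_equal(annotate_sv(rec("INS", 1000L, 1000L, 200L, strrep("AT", 100)),
                           te_ann, exons, ref), "satellite")
  # tandem duplication: insertion equal to its left flank
  flank <- substr(ref[[1]], 901, 1000)
  expect_equal(annotate_sv(rec("INS", 1000L, 1000L, 100L, flank),
                           te_ann, exons, ref), "tandem-dup")
  # LTR-TE: long terminal direct repeats
  ltr <- random_dna(300)
  expect_equal(annotate_sv(rec("INS", 1000L, 1000L, 2600L,
                               paste0(ltr, random_dna(2000), ltr)),
                           te_ann, exons, ref), "LTR-TE")
  # DNA-TE: short terminal inverted repeats
  tir <- random_dna(10)
  expect_equal(annotate_sv(rec("INS", 1000L, 1000L, 520L,
                               paste0(tir, random_dna(500), revcomp(tir))),
                           te_ann, exons, ref), "DNA-TE")
  # DEL inside an annotated LTR-TE
  expect_equal(annotate_sv(rec("DEL", 6000L, 6800L, 800L), te_ann, exons, ref),
               "LTR-TE")
  # DEL covering an exon
  expect_equal(annotate_sv(rec("DEL", 12050L, 12450L, 400L), te_ann, exons,
                           ref), "gene-fragment")
  # neutral DEL stays unclassified
  expect_equal(annotate_sv(rec("DEL", 15000L, 15500L, 500L), te_ann, exons,
                           ref), "unclassified")
  # INS without alt errors
  expect_error(annotate_sv(rec("INS", 1000L, 1000L, 100L), te_ann, exons,
                           ref), "alt_seq")
  # on the simulated panel, planted classes are recovered
  sim <- small_sim()
  calls <- small_calls()
  cs <- merge_callsets(calls$sv, nets = calls$nets)
  cs <- annotate_callset(cs, sim$truth$te_bed, sim$truth$exons,
                         sim$panel$reference)
  tv <- sim$truth$variants
  for (cls in c("LTR-TE", "satellite", "tandem-dup")) {
    planted <- tv[tv$type == "INS" & tv$class == cls, ]
    hits <- vapply(seq_len(nrow(planted)), function(i) {
      tol <- if (cls == "LTR-TE") 10 else 10 + planted$length[i]
      m <- cs$records[cs$records$ref_chrom == planted$chrom[i] &
                        abs(cs$records$pos - planted$pos[i]) <= tol &
                        abs(cs$records$length - planted$length[i]) <=
                          0.1 * planted$length[i], ]
      if (nrow(m) == 0) return(FALSE)
      m <- m[which.min(abs(m$pos - planted$pos[i])), ]
      m$feature_class == cls
    }, logical(1))
    expect_gte(mean(hits), 0.9)
  }
})

test_that("distance to the nearest gene matches a brute-force scan", {
  genes <- data.frame(chrom = "chr1",
                      start = c(1000L, 8000L, 20000L),
                      end = c(3000L, 9000L, 25000L), stringsAsFactors = FALSE)
  rec <- function(pos, end) data.frame(sv_type = "DEL", ref_chrom = "chr1",
                                       pos = pos, end = end,
                                       stringsAsFactors = FALSE)
  expect_equal(distance_to_gene(rec(1500L, 1600L), genes), 0L)
  expect_equal(distance_to_gene(rec(6000L, 6001L), genes), 1999L)
  expect_error(distance_to_gene(rec(1L, 2L), genes[0, ]), "empty")
  set.seed(5)
  for (i in 1:20) {
    p <- sample.int(30000, 1)
    r <- rec(p, p + 10L)
    brute <- min(vapply(seq_len(nrow(genes)), function(g) {
      if (r$pos + 1L <= genes$end[g] && r$end >= genes$start[g]) return(0L)
      min(abs(genes$start[g] - r$end), abs(r$pos + 1L - genes$end[g]))
    }, integer(1)))
    expect_equal(distance_to_gene(r, genes), brute)
  }
})

test_that("VCF round-trips through the reader without loss", {
  sim <- small_sim()
  calls <- small_calls()
  cs <- merge_callsets(calls$sv, nets = calls$nets)
  cs <- annotate_callset(cs, sim$truth$te_bed, sim$truth$exons,
                         sim$panel$reference)
  f <- tempfile(fileext = ".vcf")
  write_sv_vcf(cs, f, sim$panel$reference)
  back <- read_sv_vcf(f)
  expect_equal(nrow(back$records), nrow(cs$records))
  expect_equal(back$records$sv_type, cs$records$sv_type)
  expect_equal(back$records$pos, pmax(cs$records$pos, 1L))
  expect_equal(back$records$length, cs$records$length)
  expect_equal(back$records$end, cs$records$end)
  expect_equal(back$records$feature_class, cs$records$feature_class)
  ins <- which(cs$records$sv_type == "INS")
  expect_equal(back$records$alt_seq[ins], cs$records$alt_seq[ins])
  expect_equal(unname(back$genotypes), unname(cs$genotypes))
})
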