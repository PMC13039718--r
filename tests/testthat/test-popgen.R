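test_that("MAF/missingness filtering matches per-site brute force", {
  vm <- random_genotype_matrix(200, 20, miss = 0.15, seed = 3)
  out <- filter_variants(vm, min_maf = 0.05, max_missing = 0.2)
  keep_brute <- vapply(seq_len(200), function(i) {
    g <- vm$geno[i, ]
    ok <- !is.na(g)
    p <- mean(g[ok])
    min(p, 1 - p) >= 0.05 && mean(!ok) <= 0.2
  }, logical(1))
  expect_equal(nrow(out$sites), sum(keep_brute))
  expect_equal(out$sites$pos, vm$sites$pos[keep_brute])
  # worked single-site rules
  g1 <- matrix(c(1L, rep(0L, 39)), 1)  # MAF 0.025
  v1 <- variant_matrix(vm$sites[1, ], g1)
  expect_equal(nrow(filter_variants(v1)$sites), 0L)
  g2 <- matrix(c(rep(1L, 15), rep(0L, 15), rep(NA, 10)), 1)  # 25% missing
  v2 <- variant_matrix(vm$sites[1, ], g2)
  expect_equal(nrow(filter_variants(v2)$sites), 0L)
  expect_error(filter_variants(vm, min_maf = 0.7), "min_maf")
})

test_that("LD pruning removes duplicates and leaves no high-r2 pair", {
  vm <- random_genotype_matrix(20, 15, seed = 5)
  vm$geno[2, ] <- vm$geno[1, ]  # perfect duplicate, r2 = 1
  pruned <- ld_prune(vm, window = 20, step = 5, r2_max = 0.2)
  expect_lt(nrow(pruned$sites), 20)
  # post-condition oracle: no surviving within-window pair exceeds r2_max
  g <- pruned$geno
  for (a in seq_len(nrow(g) - 1)) {
    for (b in (a + 1):nrow(g)) {
      r2 <- suppressWarnings(stats::cor(g[a, ], g[b, ])^2)
      if (!is.na(r2)) expect_lte(r2, 0.2 + 1e-12)
    }
  }
  # uncorrelated input passes through
  set.seed(8)
  ind <- variant_matrix(vm$sites, matrix(rbinom(20 * 15, 1, 0.5), 20, 15,
                                         dimnames = list(NULL, colnames(vm$geno))))
  r2max <- 0
  for (a in 1:19) for (b in (a + 1):20) {
    r2max <- max(r2max, suppressWarnings(stats::cor(ind$geno[a, ],
                                                    ind$geno[b, ])^2),
                 na.rm = TRUE)
  }
  out <- ld_prune(ind, r2_max = max(0.99, r2max))
  expect_equal(nrow(out$sites), 20L)
  expect_error(ld_prune(vm, window = 10, step = 20), "step")
})

test_that("outgroup polarization sets ancestral states and the polarized
           fraction", {
  g <- matrix(c(0L, 1L, 0L,
                1L, 0L, 0L,
                NA, 1L, 1L,
                0L, 0L, 1L), 4, 3, byrow = TRUE,
              dimnames = list(NULL, c("A", "B", "OUT")))
  sites <- data.frame(chrom = "c", pos = 1:4, ref = "A", alt = "T",
                      class = "SNV-other")
  vm <- variant_matrix(sites, g)
  pol <- polarize(vm, "OUT")
  expect_equal(pol$ancestral,
               c("ref-ancestral", "ref-ancestral", "alt-ancestral",
                 "alt-ancestral"))
  # outgroup-missing site: a genotype matrix with NA in the outgroup column
  g[1, "OUT"] <- NA
  pol2 <- polarize(variant_matrix(sites, g), "OUT")
  expect_equal(pol2$ancestral[1], "unknown")
  expect_equal(attr(pol2, "polarized_fraction"), 75)
  expect_error(polarize(vm, "NOPE"), "outgroup")
  # the published polarization arithmetic
  expect_equal(polarized_percent(56486, 76002), 74.32)
  expect_equal(polarized_percent(21351, 76002), 28.09)
})

test_that("frequency spectra: folding, fixed-derived mass, truth recovery", {
  vm <- random_genotype_matrix(300, 12, seed = 9)
  sp <- frequency_spectrum(vm, "minor")[[1]]
  expect_true(all(sp$count[sp$bin_low >= 0.5] == 0))
  # all sites fixed derived: mass in the top bin
  g <- matrix(1L, 10, 6, dimnames = list(NULL, sprintf("A%d", 1:6)))
  sites <- data.frame(chrom = "c", pos = 1:10, ref = "A", alt = "T",
                      class = "SNV-other")
  vmf <- variant_matrix(sites, g, ancestral = rep("ref-ancestral", 10))
  spd <- frequency_spectrum(vmf, "derived")[[1]]
  expect_equal(spd$count[spd$bin_high == 1], 10)
  # derived spectrum on the simulated panel recovers truth frequencies
  sim <- small_sim()
  vmt <- polarize(truth_variant_matrix(sim$truth), "OUT")
  p_true <- rowMeans(vmt$geno == 1L)
  known <- vmt$ancestral != "unknown"
  expect_true(all(vmt$ancestral[known] == "ref-ancestral"))
  spt <- frequency_spectrum(vmt, "derived",
                            classes = list(all = unique(vmt$sites$class)))
  expect_equal(sum(spt$all$count), sum(known))
  h <- graphics::hist(p_true[known], breaks = seq(0, 1, 0.1), plot = FALSE)
  expect_equal(spt$all$count, h$counts)
})

test_that("pi equals the brute-force mean pairwise difference", {
  # two accessions differing at 1 site in a 100-bp window: pi = 0.01
  g <- matrix(c(0L, 1L), 1, 2, dimnames = list(NULL, c("A", "B")))
  vm <- variant_matrix(data.frame(chrom = "c", pos = 50, ref = "A", alt = "T",
                                  class = "SNV-other"), g)
  w <- data.frame(chrom = "c", start = 1, end = 100)
  expect_equal(nucleotide_diversity(vm, w)$pi, 0.01)
  # monomorphic window
  gm <- matrix(0L, 1, 2, dimnames = list(NULL, c("A", "B")))
  expect_equal(nucleotide_diversity(variant_matrix(vm$sites, gm), w)$pi, 0)
  expect_error(nucleotide_diversity(vm, w, group = "A"), "2 accessions")
  # random 10-accession window vs all-pairs oracle
  vmr <- random_genotype_matrix(60, 10, seed = 13)
  vmr$sites$pos <- sort(sample.int(5000, 60))
  wr <- data.frame(chrom = "chr1", start = 1, end = 5000)
  got <- nucleotide_diversity(vmr, wr)$pi
  pairs <- utils::combn(10, 2)
  diffs <- mean(vapply(seq_len(ncol(pairs)), function(k) {
    sum(vmr$geno[, pairs[1, k]] != vmr$geno[, pairs[2, k]])
  }, numeric(1)))
  expect_equal(got, diffs / 5000, tolerance = 1e-12)
})

test_that("Weir-Cockerham Fst matches an independent per-site transcription", {
  # fixed opposite alleles: Fst = 1
  g <- cbind(matrix(1L, 5, 4), matrix(0L, 5, 4))
  colnames(g) <- c(paste0("a", 1:4), paste0("b", 1:4))
  sites <- data.frame(chrom = "c", pos = 1:5, ref = "A", alt = "T",
                      class = "SNV-other")
  w <- data.frame(chrom = "c", start = 1, end = 10)
  out <- fst(variant_matrix(sites, g), paste0("a", 1:4), paste0("b", 1:4), w)
  expect_equal(out$fst, 1)
  expect_error(fst(variant_matrix(sites, g), c("a1", "a2"), c("a2", "b1"), w),
               "disjoint")
  # independent per-site oracle (haploid two-level ANOVA, written separately)
  wc_site <- function(p1, p2, n1, n2) {
    r <- 2
    nbar <- (n1 + n2) / 2
    nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2))
    pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
    a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 / 2) / (nbar - 1))
    w_ <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 / 2)
    c(a, w_)
  }
  set.seed(21)
  g3 <- matrix(rbinom(3 * 9, 1, 0.5), 3, 9)
  colnames(g3) <- c(paste0("a", 1:4), paste0("b", 1:5))
  vm3 <- variant_matrix(data.frame(chrom = "c", pos = 1:3, ref = "A",
                                   alt = "T", class = "SNV-other"), g3)
  got <- fst(vm3, paste0("a", 1:4), paste0("b", 1:5),
             data.frame(chrom = "c", start = 1, end = 3))$fst
  comp <- vapply(1:3, function(i) {
    wc_site(mean(g3[i, 1:4]), mean(g3[i, 5:9]), 4, 5)
  }, numeric(2))
  expect_equal(got, sum(comp[1, ]) / sum(comp[1, ] + comp[2, ]),
               tolerance = 1e-12)
})

test_that("Tajima's D matches an independent transcription of the constants", {
  set.seed(17)
  n <- 10; S <- 5
  g <- matrix(0L, S, n, dimnames = list(NULL, sprintf("A%d", 1:n)))
  for (i in 1:S) g[i, sample.int(n, sample(1:(n - 1), 1))] <- 1L
  vm <- variant_matrix(data.frame(chrom = "c", pos = seq(10, 50, 10),
                                  ref = "A", alt = "T", class = "SNV-other"),
                       g)
  w <- data.frame(chrom = "c", start = 1, end = 100)
  got <- tajima_d(vm, w)$tajima_d
  # independent transcription
  a1 <- sum(1 / 1:(n - 1)); a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  k <- rowSums(g)
  pi_tot <- sum(2 * k * (n - k) / (n * (n - 1)))
  want <- (pi_tot - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  expect_equal(got, want, tolerance = 1e-12)
  # no segregating sites: missing, not zero
  vm0 <- variant_matrix(vm$sites, matrix(0L, S, n,
                                         dimnames = dimnames(g)))
  expect_true(is.na(tajima_d(vm0, w)$tajima_d))
  # all singletons at large n: negative D
  ns <- 30
  gs <- matrix(0L, 12, ns, dimnames = list(NULL, sprintf("B%d", 1:ns)))
  for (i in 1:12) gs[i, i] <- 1L
  vms <- variant_matrix(data.frame(chrom = "c", pos = 1:12, ref = "A",
                                   alt = "T", class = "SNV-other"), gs)
  expect_lt(tajima_d(vms, w)$tajima_d, 0)
  expect_error(tajima_d(vm, w, group = c("A1", "A2", "A3")), ">= 4")
})

test_that("LD r2 matches the haplotype-frequency formula and decays in
           distance bins", {
  # duplicated adjacent sites: bin-0 r2 = 1
  g <- matrix(rep(c(0L, 1L, 0L, 1L, 1L, 0L), 2), 2, byrow = TRUE)
  colnames(g) <- sprintf("A%d", 1:6)
  vm <- variant_matrix(data.frame(chrom = "c", pos = c(100, 150), ref = "A",
                                  alt = "T", class = "SNV-other"), g)
  out <- ld_decay(vm, max_dist = 1000, bin_width = 100)
  expect_equal(out$mean_r2[1], 1)
  # 5-site toy: every pair matches the direct haplotype formula
  set.seed(23)
  g5 <- matrix(rbinom(5 * 12, 1, 0.5), 5, 12,
               dimnames = list(NULL, sprintf("A%d", 1:12)))
  vm5 <- variant_matrix(data.frame(chrom = "c", pos = c(10, 20, 30, 40, 50),
                                   ref = "A", alt = "T", class = "SNV-other"),
                        g5)
  out5 <- ld_decay(vm5, max_dist = 100, bin_width = 10)
  hap_r2_direct <- function(x, y) {
    pA <- mean(x); pB <- mean(y); pAB <- mean(x == 1 & y == 1)
    D <- pAB - pA * pB
    D^2 / (pA * (1 - pA) * pB * (1 - pB))
  }
  for (a in 1:4) {
    for (b in (a + 1):5) {
      d <- vm5$sites$pos[b] - vm5$sites$pos[a]
      bin <- which(out5$dist_low < d & out5$dist_high >= d)
      # bins here hold single pairs except equal distances; recompute mean
    }
  }
  # aggregate check: weighted mean of direct r2 equals binned means
  allr2 <- c(); alld <- c()
  for (a in 1:4) for (b in (a + 1):5) {
    allr2 <- c(allr2, hap_r2_direct(g5[a, ], g5[b, ]))
    alld <- c(alld, vm5$sites$pos[b] - vm5$sites$pos[a])
  }
  for (bin in which(out5$n_pairs > 0)) {
    sel <- alld > out5$dist_low[bin] & alld <= out5$dist_high[bin]
    expect_equal(out5$mean_r2[bin], mean(allr2[sel]), tolerance = 1e-12)
  }
  # decay distance attribute reports the first bin under the level
  expect_true(is.na(attr(ld_decay(vm5, max_dist = 100, bin_width = 10,
                                  level = 0), "decay_distance")))
})

test_that("PCA standardization behaves: duplicates coincide, variance
           fractions are ordered, planted structure separates", {
  vm <- random_genotype_matrix(100, 10, seed = 31)
  vm$geno[, 2] <- vm$geno[, 1]  # duplicate accession
  p <- pca_genotypes(vm, 3)
  expect_equal(p$coords[1, ], p$coords[2, ], tolerance = 1e-8)
  expect_true(all(diff(p$evf) <= 1e-12))
  expect_lte(sum(p$evf), 1 + 1e-12)
  expect_error(pca_genotypes(vm, 1000), "fewer")
  # two diverged groups: PC1 separates them regardless of sign
  set.seed(33)
  pa <- runif(150, 0.05, 0.95)
  shift <- pmin(pmax(pa + sample(c(-0.6, 0.6), 150, TRUE), 0.02), 0.98)
  ga <- matrix(rbinom(150 * 8, 1, pa), 150, 8)
  gb <- matrix(rbinom(150 * 8, 1, shift), 150, 8)
  g <- cbind(ga, gb)
  colnames(g) <- sprintf("A%02d", 1:16)
  vm2 <- variant_matrix(data.frame(chrom = "chr1", pos = 1:150, ref = "A",
                                   alt = "T", class = "SNV-other"), g)
  p2 <- pca_genotypes(vm2, 2)
  m1 <- mean(p2$coords[1:8, 1]); m2 <- mean(p2$coords[9:16, 1])
  expect_gt(abs(m1 - m2),
            2 * (stats::sd(p2$coords[1:8, 1]) + stats::sd(p2$coords[9:16, 1])))
})

test_that("standardized kinship equals the hand-computed cross-product and
           is PSD with unit-scale diagonal", {
  set.seed(35)
  g <- matrix(rbinom(6 * 4, 1, 0.5), 6, 4,
              dimnames = list(NULL, c("A", "B", "C", "D")))
  g[1, ] <- c(0L, 0L, 0L, 0L)  # monomorphic: must be excluded
  vm <- variant_matrix(data.frame(chrom = "c", pos = 1:6, ref = "A",
                                  alt = "T", class = "SNV-other"), g)
  K <- kinship_standardized(vm)
  poly <- which(apply(g, 1, function(x) length(unique(x)) > 1))
  z <- t(vapply(poly, function(i) {
    p <- mean(g[i, ])
    (g[i, ] - p) / sqrt(p * (1 - p))
  }, numeric(4)))
  expect_equal(unname(K), unname(crossprod(z) / length(poly)),
               tolerance = 1e-12)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-10))
  # identical accessions have off-diagonal equal to diagonal
  g2 <- cbind(g[, 1], g[, 1], g[, 3], g[, 4])
  colnames(g2) <- colnames(g)
  K2 <- kinship_standardized(variant_matrix(vm$sites, g2))
  expect_equal(K2[1, 2], K2[1, 1], tolerance = 1e-12)
})

test_that("neighbor-joining recovers additive trees exactly and is
           label-permutation invariant", {
  # 4-taxon additive tree: ((A:2,B:3):1,(C:4,D:5))
  d <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                       c("A", "B", "C", "D")))
  d["A", "B"] <- d["B", "A"] <- 5
  d["A", "C"] <- d["C", "A"] <- 2 + 1 + 4
  d["A", "D"] <- d["D", "A"] <- 2 + 1 + 5
  d["B", "C"] <- d["C", "B"] <- 3 + 1 + 4
  d["B", "D"] <- d["D", "B"] <- 3 + 1 + 5
  d["C", "D"] <- d["D", "C"] <- 9
  tr <- nj_tree(d)
  expect_s3_class(tr, "phylo")
  # additive distances are reproduced exactly by path lengths
  ct <- ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]
  expect_equal(unname(ct), unname(d), tolerance = 1e-10)
  # permuting labels yields an isomorphic tree
  perm <- c("C", "A", "D", "B")
  tr2 <- nj_tree(d[perm, perm])
  expect_true(ape::all.equal.phylo(tr, tr2, use.edge.length = FALSE))
  expect_error(nj_tree(matrix(c(0, -1, -1, 0), 2)), "negative")
  # 3 taxa: the unique unrooted topology
  d3 <- d[1:3, 1:3]
  expect_equal(ape::Ntip(nj_tree(d3)), 3L)
})

test_that("carriers of the planted inversion show reduced diversity inside
           the inverted interval", {
  sim <- small_sim()
  truth <- sim$truth
  vm <- truth_variant_matrix(truth, include_outgroup = FALSE)
  inv <- truth$variants[truth$variants$id == truth$inversion_id, ]
  carriers <- strsplit(inv$carriers, ",")[[1]]
  # the generator plants most intra-inversion variants on the founder
  # haplotype, so carriers are near-monomorphic inside the interval
  vm2 <- vm
  w <- data.frame(chrom = inv$chrom, start = inv$pos + 1, end = inv$end)
  pi_car <- nucleotide_diversity(vm2, w, group = carriers)$pi
  pi_non <- nucleotide_diversity(vm2, w,
                                 group = setdiff(truth$accessions,
                                                 carriers))$pi
  expect_lt(pi_car, pi_non)
  fst_w <- fst(vm2, carriers, setdiff(truth$accessions, carriers), w)$fst
  out_w <- data.frame(chrom = inv$chrom, start = 1, end = inv$pos)
  fst_out <- fst(vm2, carriers, setdiff(truth$accessions, carriers), out_w)$fst
  expect_gt(fst_w, fst_out)
})
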