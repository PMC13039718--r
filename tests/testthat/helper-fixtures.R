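# shared small synthetic panel, built once per test run
.fixture_env <- new.env(parent = emptyenv())

small_config <- function(seed = 11L) {
  sim_config(seed = seed, n_accessions = 6L, n_chromosomes = 2L,
             chrom_length = 300000L,
             sv_counts = c(DEL = 24L, INS_TE = 14L, INS_DUP = 6L,
                           INS_SAT = 5L, TRA = 0L),
             te_length_mode = 3000L,
             inversion_spec = list(chrom = 1L, start = 120001L,
                                   length = 40000L, carrier_fraction = 0.5),
             n_genes = 60L, n_outgroup_deletions = 8L)
}

small_sim <- function() {
  if (is.null(.fixture_env$sim)) .fixture_env$sim <- simulate_panel(small_config())
  .fixture_env$sim
}

# small panel aligned and called (the expensive shared fixture)
small_calls <- function() {
  if (is.null(.fixture_env$calls)) {
    sim <- small_sim()
    nets <- list(); calls <- list(); smalls <- list()
    for (a in sim$panel$accession_names) {
      nets[[a]] <- wga_align(sim$panel$reference, sim$panel$accessions[[a]])
      res <- lapply(names(nets[[a]]), function(rc) {
        call_variants_from_net(nets[[a]][[rc]], sim$panel$reference,
                               sim$panel$accessions[[a]], accession = a)
      })
      calls[[a]] <- do.call(rbind, lapply(res, `[[`, "sv"))
      smalls[[a]] <- do.call(rbind, lapply(res, `[[`, "small"))
    }
    .fixture_env$calls <- list(nets = nets, sv = calls, small = smalls)
  }
  .fixture_env$calls
}

# truth records of a given accession and type set
truth_for <- function(truth, accession, types) {
  v <- truth$variants[truth$variants$type %in% types, , drop = FALSE]
  v[vapply(strsplit(v$carriers, ","), function(x) accession %in% x,
           logical(1)), , drop = FALSE]
}

# match planted events against calls: breakpoint within pos_tol, length
# within len_tol fraction. Tandem duplications and satellite expansions are
# breakpoint-ambiguous (any placement within the repeated unit yields the
# same sequence), so their positional tolerance is widened by one unit
# length.
match_truth_calls <- function(truth_df, call_df, pos_tol = 10,
                              len_tol = 0.1) {
  vapply(seq_len(nrow(truth_df)), function(i) {
    tol <- pos_tol +
      if (isTRUE(truth_df$class[i] %in% c("tandem-dup", "satellite")))
        truth_df$length[i] else 0
    any(call_df$ref_chrom == truth_df$chrom[i] &
          abs(call_df$pos - truth_df$pos[i]) <= tol &
          abs(call_df$length - truth_df$length[i]) <=
            len_tol * truth_df$length[i])
  }, logical(1))
}

random_genotype_matrix <- function(n_sites, n_acc, miss = 0, seed = 1) {
  set.seed(seed)
  g <- matrix(rbinom(n_sites * n_acc, 1L, runif(n_sites, 0.1, 0.9)[
    rep(seq_len(n_sites), n_acc)]), n_sites, n_acc)
  if (miss > 0) g[runif(length(g)) < miss] <- NA_integer_
  colnames(g) <- sprintf("A%02d", seq_len(n_acc))
  sites <- data.frame(chrom = "chr1", pos = sort(sample.int(1e6, n_sites)),
                      ref = "A", alt = "T", class = "SNV-other",
                      stringsAsFactors = FALSE)
  variant_matrix(sites, g)
}

# full-scale acceptance panel: 8 accessions, 2 x 1 Mb, 200 planted SVs
# (built once; only the acceptance tests use it)
acceptance_panel <- function() {
  if (is.null(.fixture_env$acc_panel)) {
    cfg <- sim_config(seed = 101L)
    sim <- simulate_panel(cfg)
    nets <- list(); calls <- list()
    for (a in sim$panel$accession_names) {
      nets[[a]] <- wga_align(sim$panel$reference, sim$panel$accessions[[a]])
      res <- lapply(names(nets[[a]]), function(rc) {
        call_variants_from_net(nets[[a]][[rc]], sim$panel$reference,
                               sim$panel$accessions[[a]], accession = a)
      })
      calls[[a]] <- do.call(rbind, lapply(res, `[[`, "sv"))
    }
    merged <- merge_callsets(calls, nets = nets)
    .fixture_env$acc_panel <- list(sim = sim, calls = calls, merged = merged)
  }
  .fixture_env$acc_panel
}

# structured two-subpopulation null panel for mixed-model calibration
structured_null <- function(n = 200, m_test = 50000, m_bg = 1000,
                            h2_bg = 0.4, seed = 1) {
  set.seed(seed)
  half <- n / 2
  pop <- rep(1:2, each = half)
  draw_geno <- function(m, fst_like = 0.12) {
    p0 <- runif(m, 0.1, 0.9)
    d <- rnorm(m, 0, sqrt(fst_like * p0 * (1 - p0)))
    p1 <- pmin(pmax(p0 + d, 0.02), 0.98)
    p2 <- pmin(pmax(p0 - d, 0.02), 0.98)
    g <- cbind(matrix(rbinom(m * half, 1, p1), m, half),
               matrix(rbinom(m * half, 1, p2), m, half))
    colnames(g) <- sprintf("A%03d", seq_len(n))
    g
  }
  g_bg <- draw_geno(m_bg)
  sites <- data.frame(chrom = "chr1", pos = seq_len(m_bg), ref = "A",
                      alt = "T", class = "SNV-other")
  K <- kinship_standardized(variant_matrix(sites, g_bg))
  # polygenic background aligned with the kinship structure
  u <- drop(t(chol(K + diag(1e-6, n))) %*% rnorm(n))
  u <- u / stats::sd(u) * sqrt(h2_bg)
  y <- u + rnorm(n, 0, sqrt(1 - h2_bg))
  list(geno = draw_geno(m_test), y = y, K = K, pop = pop)
}
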