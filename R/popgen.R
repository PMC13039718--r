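#' Construct a biallelic variant matrix
#'
#' The shared container for all population-genetic and association stages:
#' biallelic sites by accessions, haploid-representative genotype codes
#' 0 / 1 / NA, with an optional per-site ancestral-state flag.
#'
#' @param sites data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `class`.
#' @param geno integer matrix sites x accessions with entries in
#'   \{0, 1, NA\}.
#' @param ancestral optional character vector per site:
#'   "ref-ancestral", "alt-ancestral" or "unknown".
#' @return object of class `variant_matrix`.
#' @export
variant_matrix <- function(sites, geno, ancestral = NULL) {
  stopifnot(nrow(sites) == nrow(geno))
  ok <- geno %in% c(0L, 1L) | is.na(geno)
  if (!all(ok)) stop("genotype codes must be 0, 1 or NA (inbred panel)")
  if (is.null(ancestral)) ancestral <- rep("unknown", nrow(sites))
  structure(list(sites = sites, geno = geno, ancestral = ancestral),
            class = "variant_matrix")
}

#' @export
print.variant_matrix <- function(x, ...) {
  cat("variant_matrix:", nrow(x$sites), "sites x", ncol(x$geno),
      "accessions\n")
  invisible(x)
}

alt_freq <- function(geno) {
  n <- rowSums(!is.na(geno))
  p <- rowSums(geno == 1L, na.rm = TRUE) / pmax(n, 1L)
  p[n == 0L] <- NA_real_
  p
}

#' Filter sites on minor allele frequency and missingness
#'
#' @param vm a `variant_matrix`.
#' @param min_maf minimum minor allele frequency over non-missing calls.
#' @param max_missing maximum missing fraction per site.
#' @return the filtered `variant_matrix`.
#' @export
filter_variants <- function(vm, min_maf = 0.05, max_missing = 0.2) {
  if (min_maf < 0 || min_maf > 0.5) stop("min_maf must lie in [0, 0.5]")
  if (max_missing < 0 || max_missing > 1) stop("max_missing must lie in [0, 1]")
  p <- alt_freq(vm$geno)
  maf <- pmin(p, 1 - p)
  miss <- rowMeans(is.na(vm$geno))
  keep <- !is.na(maf) & maf >= min_maf & miss <= max_missing
  variant_matrix(vm$sites[keep, , drop = FALSE],
                 vm$geno[keep, , drop = FALSE], vm$ancestral[keep])
}

# squared haplotype correlation between two haploid genotype vectors
hap_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2L) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' Sliding-window LD pruning
#'
#' Greedy removal within windows of `window` sites advanced by `step`:
#' while any retained pair in the window has r-squared above `r2_max`, the
#' member of the worst pair with the lower minor allele frequency is
#' dropped.
#'
#' @param vm a `variant_matrix` sorted by position.
#' @param window window size in sites.
#' @param step advance in sites.
#' @param r2_max maximum tolerated pairwise r-squared.
#' @return the pruned `variant_matrix`.
#' @export
ld_prune <- function(vm, window = 50L, step = 10L, r2_max = 0.2) {
  if (step > window) stop("step must not exceed window")
  m <- nrow(vm$sites)
  keep <- rep(TRUE, m)
  p <- alt_freq(vm$geno)
  maf <- pmin(p, 1 - p)
  for (chrom in unique(vm$sites$chrom)) {
    idx_all <- which(vm$sites$chrom == chrom)
    idx_all <- idx_all[order(vm$sites$pos[idx_all])]
    start <- 1L
    while (start <= length(idx_all)) {
      win <- idx_all[start:min(start + window - 1L, length(idx_all))]
      repeat {
        act <- win[keep[win]]
        if (length(act) < 2L) break
        worst <- NULL; worst_r2 <- r2_max
        for (a in seq_len(length(act) - 1L)) {
          for (b in (a + 1L):length(act)) {
            r2 <- hap_r2(vm$geno[act[a], ], vm$geno[act[b], ])
            if (!is.na(r2) && r2 > worst_r2) {
              worst_r2 <- r2; worst <- c(act[a], act[b])
            }
          }
        }
        if (is.null(worst)) break
        drop <- worst[which.min(maf[worst])]
        keep[drop] <- FALSE
      }
      if (start + window - 1L >= length(idx_all)) break
      start <- start + step
    }
  }
  variant_matrix(vm$sites[keep, , drop = FALSE], vm$geno[keep, , drop = FALSE],
                 vm$ancestral[keep])
}

#' Polarize alleles with an outgroup accession
#'
#' The outgroup's allele defines the ancestral state: where the outgroup
#' carries the reference allele the alternative is derived, and vice versa;
#' sites with a missing outgroup call stay "unknown". The outgroup column is
#' removed from the returned matrix.
#'
#' @param vm a `variant_matrix` containing the outgroup column.
#' @param outgroup outgroup column name.
#' @return the polarized `variant_matrix`; attribute `polarized_fraction`
#'   gives the percentage of sites assigned a state.
#' @export
polarize <- function(vm, outgroup) {
  if (!outgroup %in% colnames(vm$geno)) stop("outgroup absent from matrix: ",
                                             outgroup)
  og <- vm$geno[, outgroup]
  anc <- ifelse(is.na(og), "unknown",
                ifelse(og == 0L, "ref-ancestral", "alt-ancestral"))
  keep_cols <- setdiff(colnames(vm$geno), outgroup)
  out <- variant_matrix(vm$sites, vm$geno[, keep_cols, drop = FALSE], anc)
  attr(out, "polarized_fraction") <- 100 * mean(anc != "unknown")
  out
}

#' Percentage of sites assigned an ancestral state
#'
#' @param n_assigned number of polarized sites.
#' @param n_total total sites.
#' @param digits rounding digits.
#' @return percentage.
#' @export
polarized_percent <- function(n_assigned, n_total, digits = 2) {
  round(100 * n_assigned / n_total, digits)
}

#' Allele-frequency spectra per site class
#'
#' @param vm a `variant_matrix`.
#' @param mode "minor" (folded) or "derived" (requires ancestral states;
#'   unknown-state sites are excluded).
#' @param classes optional named list mapping spectrum names to site-class
#'   values; defaults to one spectrum per distinct site class.
#' @param breaks histogram bin edges on [0, 1].
#' @return named list of data.frames (bin_low, bin_high, count, freq).
#' @export
frequency_spectrum <- function(vm, mode = c("minor", "derived"),
                               classes = NULL, breaks = seq(0, 1, 0.1)) {
  mode <- match.arg(mode)
  p <- alt_freq(vm$geno)
  if (mode == "derived") {
    known <- vm$ancestral != "unknown"
    f <- ifelse(vm$ancestral == "ref-ancestral", p, 1 - p)
    f[!known] <- NA_real_
  } else {
    f <- pmin(p, 1 - p)
  }
  if (is.null(classes)) {
    classes <- as.list(setNames(unique(vm$sites$class), unique(vm$sites$class)))
  }
  out <- list()
  for (nm in names(classes)) {
    sel <- vm$sites$class %in% classes[[nm]] & !is.na(f)
    x <- f[sel]
    if (length(x) == 0L) {
      warning("empty class after exclusions: ", nm)
      out[[nm]] <- data.frame(bin_low = utils::head(breaks, -1),
                              bin_high = breaks[-1], count = 0, freq = NA_real_)
      next
    }
    h <- graphics::hist(x, breaks = breaks, plot = FALSE,
                        include.lowest = TRUE, right = TRUE)
    out[[nm]] <- data.frame(bin_low = utils::head(breaks, -1),
                            bin_high = breaks[-1], count = h$counts,
                            freq = h$counts / sum(h$counts))
  }
  out
}

make_windows <- function(chrom, chrom_length, width) {
  s <- seq(1L, chrom_length, by = width)
  data.frame(chrom = chrom, start = s,
             end = pmin(s + width - 1L, chrom_length))
}

#' Windowed nucleotide diversity (pi)
#'
#' Haploid adaptation: per window,
#' pi = sum over sites of 2 p (1 - p) n / (n - 1) divided by window length,
#' with p the alternative-allele frequency among the n non-missing calls.
#' This equals the average pairwise difference per site.
#'
#' @param vm a `variant_matrix`.
#' @param windows data.frame (chrom, start, end), 1-based closed, tiling.
#' @param group character vector of accession columns (>= 2).
#' @return data.frame (chrom, start, end, n_sites, pi).
#' @export
nucleotide_diversity <- function(vm, windows, group = colnames(vm$geno)) {
  if (length(group) < 2L) stop("group must contain at least 2 accessions")
  g <- vm$geno[, group, drop = FALSE]
  n <- rowSums(!is.na(g))
  p <- rowSums(g == 1L, na.rm = TRUE) / pmax(n, 1L)
  per_site <- ifelse(n >= 2L, 2 * p * (1 - p) * n / (n - 1L), 0)
  windows$n_sites <- 0L
  windows$pi <- 0
  for (i in seq_len(nrow(windows))) {
    w <- windows[i, ]
    sel <- vm$sites$chrom == w$chrom & vm$sites$pos >= w$start &
      vm$sites$pos <= w$end
    windows$n_sites[i] <- sum(sel)
    windows$pi[i] <- sum(per_site[sel]) / (w$end - w$start + 1L)
  }
  windows
}

# per-site Weir-Cockerham variance components, haploid adaptation:
# two-level ANOVA of allele frequencies (no within-individual component)
wc_components <- function(p_i, n_i) {
  keep <- n_i > 0
  p_i <- p_i[keep]; n_i <- n_i[keep]
  r <- length(p_i)
  if (r < 2L) return(c(a = NA_real_, w = NA_real_))
  nbar <- mean(n_i)
  nc <- (sum(n_i) - sum(n_i^2) / sum(n_i)) / (r - 1)
  pbar <- sum(n_i * p_i) / sum(n_i)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  if (nbar <= 1) return(c(a = NA_real_, w = NA_real_))
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r) / (nbar - 1))
  w <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r)
  c(a = a, w = w)
}

#' Windowed Weir-Cockerham Fst between two groups
#'
#' Weighted estimator: the ratio of the summed among-group components to the
#' summed total components over the window's sites (haploid adaptation of
#' Weir & Cockerham 1984; may be negative and is reported unclamped).
#'
#' @param vm a `variant_matrix`.
#' @param group_a,group_b disjoint accession sets, each >= 2.
#' @param windows data.frame (chrom, start, end).
#' @return data.frame (chrom, start, end, n_sites, fst).
#' @export
fst <- function(vm, group_a, group_b, windows) {
  if (length(intersect(group_a, group_b)) > 0L) stop("groups must be disjoint")
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least 2 accessions")
  }
  ga <- vm$geno[, group_a, drop = FALSE]
  gb <- vm$geno[, group_b, drop = FALSE]
  na <- rowSums(!is.na(ga)); nb <- rowSums(!is.na(gb))
  pa <- rowSums(ga == 1L, na.rm = TRUE) / pmax(na, 1L)
  pb <- rowSums(gb == 1L, na.rm = TRUE) / pmax(nb, 1L)
  comp <- t(vapply(seq_len(nrow(vm$sites)), function(i) {
    wc_components(c(pa[i], pb[i]), c(na[i], nb[i]))
  }, numeric(2)))
  windows$n_sites <- 0L
  windows$fst <- NA_real_
  for (i in seq_len(nrow(windows))) {
    w <- windows[i, ]
    sel <- vm$sites$chrom == w$chrom & vm$sites$pos >= w$start &
      vm$sites$pos <= w$end & !is.na(comp[, 1])
    windows$n_sites[i] <- sum(sel)
    tot <- sum(comp[sel, 1] + comp[sel, 2])
    if (sum(sel) > 0L && tot != 0) {
      windows$fst[i] <- sum(comp[sel, 1]) / tot
    }
  }
  windows
}

tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

#' Windowed Tajima's D
#'
#' D = (pi_total - S / a1) / sqrt(e1 S + e2 S (S - 1)) with the standard
#' sample-size constants; windows with no segregating site are reported as
#' missing (not 0). Sites with any missing call in the group are excluded
#' (complete-case), and n is the group size.
#'
#' @param vm a `variant_matrix`.
#' @param windows data.frame (chrom, start, end).
#' @param group accession subset, size >= 4.
#' @return data.frame (chrom, start, end, S, tajima_d).
#' @export
tajima_d <- function(vm, windows, group = colnames(vm$geno)) {
  n <- length(group)
  if (n < 4L) stop("group size must be >= 4")
  g <- vm$geno[, group, drop = FALSE]
  complete <- rowSums(is.na(g)) == 0L
  k <- rowSums(g == 1L, na.rm = TRUE)
  seg <- complete & k > 0L & k < n
  cst <- tajima_constants(n)
  # mean pairwise differences per site: 2 k (n - k) / (n (n - 1))
  pair_diff <- 2 * k * (n - k) / (n * (n - 1))
  windows$S <- 0L
  windows$tajima_d <- NA_real_
  for (i in seq_len(nrow(windows))) {
    w <- windows[i, ]
    sel <- seg & vm$sites$chrom == w$chrom & vm$sites$pos >= w$start &
      vm$sites$pos <= w$end
    S <- sum(sel)
    windows$S[i] <- S
    if (S == 0L) next
    pi_tot <- sum(pair_diff[sel])
    denom <- sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
    if (denom > 0) windows$tajima_d[i] <- (pi_tot - S / cst$a1) / denom
  }
  windows
}

#' LD decay: binned mean r-squared by physical distance
#'
#' r-squared is computed from haplotype counts directly (valid for haploid
#' genotypes) for all intra-chromosome site pairs within `max_dist`, then
#' averaged in distance bins.
#'
#' @param vm a `variant_matrix`.
#' @param max_dist maximum pair distance (bp).
#' @param bin_width distance bin width (bp).
#' @param level optional r-squared reference level; the smallest bin
#'   midpoint at which mean r-squared falls below it is reported as
#'   attribute `decay_distance`.
#' @return data.frame (dist_low, dist_high, n_pairs, mean_r2).
#' @export
ld_decay <- function(vm, max_dist = 1000000L, bin_width = 10000L,
                     level = 0.5) {
  nb <- ceiling(max_dist / bin_width)
  sums <- numeric(nb); cnts <- numeric(nb)
  for (chrom in unique(vm$sites$chrom)) {
    idx <- which(vm$sites$chrom == chrom)
    idx <- idx[order(vm$sites$pos[idx])]
    pos <- vm$sites$pos[idx]
    m <- length(idx)
    for (a in seq_len(max(m - 1L, 0L))) {
      b <- a + 1L
      while (b <= m && pos[b] - pos[a] <= max_dist) {
        r2 <- hap_r2(vm$geno[idx[a], ], vm$geno[idx[b], ])
        if (!is.na(r2)) {
          bin <- max(1L, ceiling((pos[b] - pos[a]) / bin_width))
          sums[bin] <- sums[bin] + r2
          cnts[bin] <- cnts[bin] + 1
        }
        b <- b + 1L
      }
    }
  }
  out <- data.frame(dist_low = (seq_len(nb) - 1L) * bin_width,
                    dist_high = seq_len(nb) * bin_width,
                    n_pairs = cnts,
                    mean_r2 = ifelse(cnts > 0, sums / pmax(cnts, 1), NA_real_))
  below <- which(!is.na(out$mean_r2) & out$mean_r2 < level)
  attr(out, "decay_distance") <- if (length(below))
    (out$dist_low[below[1]] + out$dist_high[below[1]]) / 2 else NA_real_
  out
}

standardize_geno <- function(geno) {
  p <- alt_freq(geno)
  keep <- !is.na(p) & p > 0 & p < 1
  g <- geno[keep, , drop = FALSE]
  p <- p[keep]
  mu <- p
  sd <- sqrt(p * (1 - p))
  z <- (g - mu) / sd
  z[is.na(z)] <- 0  # missing imputed to the site mean
  z
}

#' Principal component analysis of the genotype matrix
#'
#' Eigendecomposition of the covariance of column-standardized genotypes
#' (per-site mean-centred, unit variance, missing imputed to the site mean).
#'
#' @param vm a filtered, pruned `variant_matrix`.
#' @param n_components number of components returned.
#' @return list with `coords` (accessions x components), `evf`
#'   (explained-variance fractions), `values` (eigenvalues).
#' @export
pca_genotypes <- function(vm, n_components = 10L) {
  z <- standardize_geno(vm$geno)
  if (nrow(z) < n_components) stop("fewer polymorphic sites than components")
  cv <- crossprod(z) / nrow(z)      # accessions x accessions
  e <- eigen(cv, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  k <- n_components
  coords <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(vals[seq_len(k)]), k)
  rownames(coords) <- colnames(vm$geno)
  colnames(coords) <- paste0("PC", seq_len(k))
  list(coords = coords, evf = vals[seq_len(k)] / sum(vals), values = vals)
}

#' Standardized kinship matrix
#'
#' K = Z'Z / m with Z the site-standardized genotype matrix (missing calls
#' imputed to the site mean); monomorphic sites are excluded. The average
#' diagonal is close to 1.
#'
#' @param vm a `variant_matrix` with >= 2 accessions.
#' @return symmetric kinship matrix (accessions x accessions).
#' @export
kinship_standardized <- function(vm) {
  if (ncol(vm$geno) < 2L) stop("need at least 2 accessions")
  z <- standardize_geno(vm$geno)
  if (nrow(z) == 0L) stop("no polymorphic sites")
  K <- crossprod(z) / nrow(z)
  dimnames(K) <- list(colnames(vm$geno), colnames(vm$geno))
  K
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical neighbor-joining agglomeration (via ape); recovers the
#' generating tree exactly for additive distances.
#'
#' @param d symmetric distance matrix with zero diagonal, no negative
#'   entries.
#' @return an `ape::phylo` unrooted tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (any(d < 0)) stop("negative distances")
  if (any(abs(diag(d)) > 1e-12)) stop("diagonal must be zero")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8))) stop("matrix must be symmetric")
  ape::nj(stats::as.dist(d))
}

#' Pairwise allele-sharing distance between accessions
#'
#' Proportion of sites (complete pairwise) at which two accessions differ.
#'
#' @param vm a `variant_matrix`.
#' @return symmetric distance matrix.
#' @export
genotype_distance <- function(vm) {
  g <- vm$geno
  n <- ncol(g)
  d <- matrix(0, n, n, dimnames = list(colnames(g), colnames(g)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !is.na(g[, i]) & !is.na(g[, j])
      d[i, j] <- d[j, i] <- if (any(ok)) mean(g[ok, i] != g[ok, j]) else 0
    }
  }
  d
}
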