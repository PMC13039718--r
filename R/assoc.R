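# REML log-likelihood (up to a constant) of the rotated model at ratio
# lambda = sigma2_g / sigma2_e, for design Z (rotated) and response y
# (rotated); d = kinship eigenvalues.
reml_loglik <- function(lambda, ystar, Zstar, d) {
  v <- lambda * d + 1
  u <- 1 / v
  A <- crossprod(Zstar, Zstar * u)
  b <- crossprod(Zstar, ystar * u)
  cf <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(cf)) return(-Inf)
  rss <- sum(ystar^2 * u) - sum(b * cf)
  nmc <- length(ystar) - ncol(Zstar)
  if (rss <= 0) return(-Inf)
  ld <- determinant(A, logarithm = TRUE)$modulus
  -0.5 * (sum(log(v)) + as.numeric(ld) + nmc * log(rss))
}

golden_section_max <- function(f, lo, hi, tol = 1e-4, max_iter = 60L) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  for (i in seq_len(max_iter)) {
    if (b - a < tol) break
    if (f1 < f2) { a <- x1; x1 <- x2; f1 <- f2; x2 <- a + gr * (b - a); f2 <- f(x2) }
    else { b <- x2; x2 <- x1; f2 <- f1; x1 <- b - gr * (b - a); f1 <- f(x1) }
  }
  (a + b) / 2
}

gls_fit <- function(lambda, ystar, Zstar, d) {
  u <- 1 / (lambda * d + 1)
  A <- crossprod(Zstar, Zstar * u)
  b <- crossprod(Zstar, ystar * u)
  Ai <- solve(A)
  beta <- Ai %*% b
  rss <- sum(ystar^2 * u) - sum(b * beta)
  df <- length(ystar) - ncol(Zstar)
  sigma2 <- rss / df
  se <- sqrt(sigma2 * diag(Ai))
  list(beta = drop(beta), se = se, df = df, sigma2 = sigma2)
}

#' Kinship-corrected linear-mixed-model association scan
#'
#' Fits y = W a + x b + u + e with u ~ (0, sigma2_g K) per variant. K is
#' eigendecomposed once; the variance ratio lambda = sigma2_g / sigma2_e is
#' profiled by a log-spaced grid search over 1e-5..1e5 refined by
#' golden-section on the REML likelihood of the rotated data, then GLS
#' estimates and a two-sided Wald test for b are computed. `lambda_mode =
#' "null"` optimizes lambda once under the null model (no variant) and
#' reuses it for every variant (EMMAX-like), which vectorizes the scan.
#'
#' @param geno variants x accessions genotype matrix in \{0, 1, NA\}
#'   (missing imputed to the site mean).
#' @param phenotype numeric vector (finite, one value per accession).
#' @param K kinship matrix from [kinship_standardized()].
#' @param covariates optional accessions x p matrix (an intercept is always
#'   added).
#' @param lambda_mode "pervariant" (GEMMA-like exactness) or "null"
#'   (EMMAX-like speed).
#' @param grid log10 grid of candidate lambda values.
#' @return data.frame (variant, beta, se, lambda, p).
#' @export
lmm_scan <- function(geno, phenotype, K, covariates = NULL,
                     lambda_mode = c("pervariant", "null"),
                     grid = 10^seq(-5, 5, length.out = 21)) {
  lambda_mode <- match.arg(lambda_mode)
  geno <- as.matrix(geno)
  n <- length(phenotype)
  if (any(!is.finite(phenotype))) stop("phenotype must be finite")
  stopifnot(ncol(geno) == n, nrow(K) == n)
  W <- cbind(intercept = rep(1, n), covariates)
  if (qr(W)$rank < ncol(W)) stop("singular covariate design")
  eK <- eigen(K, symmetric = TRUE)
  d <- pmax(eK$values, 0)
  U <- eK$vectors
  ystar <- drop(crossprod(U, phenotype))
  Wstar <- crossprod(U, W)
  # impute missing genotypes to the site mean
  if (anyNA(geno)) {
    mu <- rowMeans(geno, na.rm = TRUE)
    idx <- which(is.na(geno), arr.ind = TRUE)
    geno[idx] <- mu[idx[, 1]]
  }
  Xstar <- tcrossprod(geno, t(U))  # variants x n, rotated
  m <- nrow(geno)

  profile_lambda <- function(Z) {
    ll <- vapply(grid, reml_loglik, numeric(1), ystar = ystar, Zstar = Z, d = d)
    i <- which.max(ll)
    lo <- grid[max(i - 1L, 1L)]; hi <- grid[min(i + 1L, length(grid))]
    golden_section_max(function(lg) reml_loglik(10^lg, ystar, Z, d),
                       log10(lo), log10(hi))
  }

  if (lambda_mode == "null") {
    lam <- 10^profile_lambda(Wstar)
    u <- 1 / (lam * d + 1)
    sw <- sqrt(u)
    yw <- ystar * sw
    Ww <- Wstar * sw
    Xw <- Xstar * rep(sw, each = m)
    qrW <- qr(Ww)
    yr <- qr.resid(qrW, yw)
    Xr <- t(qr.resid(qrW, t(Xw)))
    sxx <- rowSums(Xr^2)
    sxy <- drop(Xr %*% yr)
    syy <- sum(yr^2)
    beta <- ifelse(sxx > 0, sxy / sxx, NA_real_)
    df <- n - ncol(W) - 1L
    rss <- syy - ifelse(sxx > 0, sxy^2 / sxx, 0)
    se <- sqrt(rss / df / sxx)
    tstat <- beta / se
    p <- 2 * stats::pt(-abs(tstat), df)
    return(data.frame(variant = rownames(geno) %||% seq_len(m), beta = beta,
                      se = se, lambda = lam, p = p, stringsAsFactors = FALSE))
  }

  out <- vector("list", m)
  for (j in seq_len(m)) {
    Z <- cbind(Wstar, x = Xstar[j, ])
    if (stats::sd(geno[j, ]) == 0) {
      out[[j]] <- data.frame(variant = j, beta = NA_real_, se = NA_real_,
                             lambda = NA_real_, p = NA_real_)
      next
    }
    lam <- 10^profile_lambda(Z)
    fit <- gls_fit(lam, ystar, Z, d)
    kx <- ncol(Z)
    tstat <- fit$beta[kx] / fit$se[kx]
    out[[j]] <- data.frame(variant = j, beta = fit$beta[kx], se = fit$se[kx],
                           lambda = lam, p = 2 * stats::pt(-abs(tstat), fit$df))
  }
  res <- do.call(rbind, out)
  res$variant <- rownames(geno) %||% seq_len(m)
  res
}

#' Genome-wide significance threshold on -log10(p)
#'
#' Fixed mode returns 5 (the relaxed secondary criterion). Effective-tests
#' mode estimates the effective number of independent tests from the
#' eigenvalues of the variant correlation matrix (Li-Ji style:
#' sum over eigenvalues of I(x >= 1) + (x - floor(x))) and returns
#' -log10(alpha / M_eff).
#'
#' @param geno variants x accessions genotype matrix (needed for
#'   effective-tests mode).
#' @param mode "fixed" or "effective-tests".
#' @param alpha family-wise level for effective-tests mode.
#' @return threshold on the -log10(p) scale.
#' @export
significance_threshold <- function(geno = NULL,
                                   mode = c("fixed", "effective-tests"),
                                   alpha = 0.05) {
  mode <- match.arg(mode)
  if (mode == "fixed") return(5.0)
  stopifnot(!is.null(geno))
  g <- as.matrix(geno)
  keep <- apply(g, 1, function(x) stats::sd(x, na.rm = TRUE) > 0)
  g <- g[keep, , drop = FALSE]
  cm <- suppressWarnings(stats::cor(t(g), use = "pairwise.complete.obs"))
  cm[is.na(cm)] <- 0
  ev <- round(abs(eigen(cm, symmetric = TRUE, only.values = TRUE)$values), 8)
  meff <- sum(as.numeric(ev >= 1) + (ev - floor(ev)))
  -log10(alpha / meff)
}

#' Copy-number genotype from normalized coverage
#'
#' The normalized ratio is the mean depth over the target interval divided
#' by the mean depth over the single-copy control; class is "+" when the
#' ratio exceeds the threshold (default 2 for the EPS locus, 15 for ROQ).
#'
#' @param coverage data.frame (accession, locus, mean_depth) as produced by
#'   [simulate_coverage()].
#' @param target target locus name.
#' @param control single-copy control locus name.
#' @param threshold classification threshold on the ratio.
#' @param labels two labels, c(above, below).
#' @return data.frame (accession, ratio, class).
#' @export
cnv_genotype <- function(coverage, target, control = "control", threshold = 2,
                         labels = c("+", "-")) {
  tg <- coverage[coverage$locus == target, ]
  ct <- coverage[coverage$locus == control, ]
  ct <- ct[match(tg$accession, ct$accession), ]
  if (any(is.na(ct$mean_depth)) || any(ct$mean_depth == 0)) {
    stop("zero or missing control depth")
  }
  ratio <- tg$mean_depth / ct$mean_depth
  data.frame(accession = tg$accession, ratio = ratio,
             class = ifelse(ratio > threshold, labels[1], labels[2]),
             stringsAsFactors = FALSE)
}

#' Genotype an inversion from junction-orientation support
#'
#' 1/1 where inverted-orientation support reaches `min_support` and
#' reference-orientation support stays below it; 0/0 in the mirrored case;
#' missing otherwise.
#'
#' @param evidence data.frame (accession, ref_support, inv_support).
#' @param min_support minimum junction support (default 3).
#' @return data.frame (accession, genotype).
#' @export
genotype_inversion <- function(evidence, min_support = 3L) {
  stopifnot(all(evidence$ref_support >= 0), all(evidence$inv_support >= 0))
  gt <- ifelse(evidence$inv_support >= min_support &
                 evidence$ref_support < min_support, "1/1",
        ifelse(evidence$ref_support >= min_support &
                 evidence$inv_support < min_support, "0/0", "missing"))
  data.frame(accession = evidence$accession, genotype = gt,
             stringsAsFactors = FALSE)
}

#' Incidence rates from per-seedling scores
#'
#' Scores follow the field convention 1 = resistant (normal), 0 = dead or
#' wilt; the incidence rate is the fraction of score-0 seedlings.
#'
#' @param raw data.frame (accession, batch, score) with one row per
#'   seedling, scores in \{0, 1\}.
#' @param min_seedlings accession-batches below this total are flagged.
#' @return list with `per_batch` (accession, batch, n_total,
#'   n_dead_or_wilt, rate, flagged) and `average` (accession, mean_rate over
#'   batches).
#' @export
incidence_rates <- function(raw, min_seedlings = 20L) {
  stopifnot(all(raw$score %in% c(0, 1)))
  key <- interaction(raw$accession, raw$batch, drop = TRUE)
  n_tot <- tapply(raw$score, key, length)
  if (any(n_tot < 1L)) stop("batch with no seedlings")
  n_dead <- tapply(raw$score, key, function(s) sum(s == 0))
  parts <- do.call(rbind, strsplit(names(n_tot), ".", fixed = TRUE))
  per_batch <- data.frame(accession = parts[, 1], batch = parts[, 2],
                          n_total = as.integer(n_tot),
                          n_dead_or_wilt = as.integer(n_dead),
                          rate = as.numeric(n_dead / n_tot),
                          flagged = as.integer(n_tot) < min_seedlings,
                          stringsAsFactors = FALSE)
  avg <- tapply(per_batch$rate, per_batch$accession, mean)
  list(per_batch = per_batch,
       average = data.frame(accession = names(avg), mean_rate = as.numeric(avg),
                            stringsAsFactors = FALSE))
}

# per-batch z-score normalization averaged across batches
normalize_incidence <- function(per_batch, method = c("zscore", "raw", "rank")) {
  method <- match.arg(method)
  x <- per_batch
  if (method == "zscore") {
    x$norm <- stats::ave(x$rate, x$batch, FUN = function(v) {
      s <- stats::sd(v)
      if (is.na(s) || s == 0) v - mean(v) else (v - mean(v)) / s
    })
  } else if (method == "rank") {
    x$norm <- stats::ave(x$rate, x$batch, FUN = function(v) rank(v) / length(v))
  } else {
    x$norm <- x$rate
  }
  agg <- tapply(x$norm, x$accession, mean)
  data.frame(accession = names(agg), norm_incidence = as.numeric(agg),
             stringsAsFactors = FALSE)
}

# compact letter display from a logical "significantly different" matrix
letter_groups <- function(sig) {
  g <- rownames(sig)
  letters_sets <- list()
  for (gr in g) {
    placed <- FALSE
    for (k in seq_along(letters_sets)) {
      if (all(!sig[gr, letters_sets[[k]]])) {
        letters_sets[[k]] <- c(letters_sets[[k]], gr)
        placed <- TRUE
      }
    }
    if (!placed) letters_sets[[length(letters_sets) + 1L]] <- gr
  }
  lab <- setNames(rep("", length(g)), g)
  for (k in seq_along(letters_sets)) {
    for (gr in letters_sets[[k]]) lab[gr] <- paste0(lab[gr], letters[k])
  }
  lab
}

#' Compare incidence across three-locus genotype combinations
#'
#' Forms the eight combination labels TGG/TGA x E+/- x R+/-, drops groups
#' below `min_group` accessions, normalizes incidence (per-batch z-scores
#' averaged across batches by default), and runs pairwise two-sided
#' Wilcoxon rank-sum tests with letter groupings at alpha = 0.05. The exact
#' null distribution is used for group sizes up to 12, the tie-corrected
#' normal approximation above.
#'
#' @param loci data.frame with `accession` and `combination` (or the three
#'   columns `stop_codon`, `EPS`, `ROQ`).
#' @param incidence `per_batch` data.frame from [incidence_rates()] or a
#'   `trait_table$incidence`.
#' @param min_group minimum group size for inclusion (default 10).
#' @param normalization "zscore", "raw" or "rank".
#' @param alpha significance level for letter groupings.
#' @return list with `groups` (label, n, mean_norm, letters) and `pairwise`
#'   (group1, group2, p).
#' @export
combination_test <- function(loci, incidence, min_group = 10L,
                             normalization = "zscore", alpha = 0.05) {
  if (!"combination" %in% names(loci)) {
    loci$combination <- paste(loci$stop_codon, loci$EPS, loci$ROQ, sep = "_")
  }
  norm <- normalize_incidence(incidence, normalization)
  d <- merge(norm, loci[, c("accession", "combination")], by = "accession")
  sizes <- table(d$combination)
  eligible <- names(sizes)[sizes >= min_group]
  if (length(eligible) < 2L) stop("fewer than 2 eligible genotype groups")
  d <- d[d$combination %in% eligible, ]
  groups <- split(d$norm_incidence, d$combination)
  nms <- names(groups)
  pw <- list()
  sig <- matrix(FALSE, length(nms), length(nms), dimnames = list(nms, nms))
  for (i in seq_len(length(nms) - 1L)) {
    for (j in (i + 1L):length(nms)) {
      xi <- groups[[i]]; xj <- groups[[j]]
      exact <- length(xi) <= 12L && length(xj) <= 12L &&
        !any(duplicated(c(xi, xj)))
      p <- suppressWarnings(
        stats::wilcox.test(xi, xj, exact = exact, correct = !exact)$p.value)
      pw[[length(pw) + 1L]] <- data.frame(group1 = nms[i], group2 = nms[j],
                                          p = p, stringsAsFactors = FALSE)
      sig[i, j] <- sig[j, i] <- !is.na(p) && p < alpha
    }
  }
  means <- vapply(groups, mean, numeric(1))
  ord <- order(-means)
  sig <- sig[ord, ord, drop = FALSE]
  lab <- letter_groups(sig)
  list(groups = data.frame(label = nms[ord], n = as.integer(sizes[nms[ord]]),
                           mean_norm = means[ord], letters = lab,
                           stringsAsFactors = FALSE, row.names = NULL),
       pairwise = do.call(rbind, pw))
}

#' Two-by-two genotype-phenotype contingency table
#'
#' Counts, row proportions (percentages, 2 decimals) and a two-sided Fisher
#' exact test for a binary marker against a binary trait.
#'
#' @param genotype per-accession binary labels (e.g. carrier / non-carrier);
#'   factor or character, 2 levels.
#' @param phenotype per-accession binary labels (e.g. purple / non-purple).
#' @return list with `table` (2x2 counts), `row_percent`, `fisher_p`.
#' @export
genotype_phenotype_table <- function(genotype, phenotype) {
  stopifnot(length(genotype) == length(phenotype))
  ok <- !is.na(genotype) & !is.na(phenotype)
  tab <- table(genotype[ok], phenotype[ok])
  if (sum(tab) == 0L) stop("empty table")
  rp <- round(100 * prop.table(tab, 1), 2)
  p <- if (nrow(tab) == 2L && ncol(tab) == 2L) {
    stats::fisher.test(tab)$p.value
  } else 1
  list(table = tab, row_percent = rp, fisher_p = p)
}

#' Percentage with fixed rounding (worked-example arithmetic)
#'
#' @param k numerator count.
#' @param n denominator count.
#' @param digits decimals (default 2).
#' @return 100 k / n rounded.
#' @export
percent_of <- function(k, n, digits = 2) round(100 * k / n, digits)
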