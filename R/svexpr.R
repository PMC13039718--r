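#' Pearson distance between two tissue expression profiles
#'
#' 1 minus the Pearson correlation of the two profiles; ranges over [0, 2].
#' Zero-variance profiles yield a missing distance.
#'
#' @param profile_a,profile_b numeric vectors of equal length >= 3.
#' @return distance in [0, 2], or NA for a zero-variance profile.
#' @export
pearson_distance <- function(profile_a, profile_b) {
  if (length(profile_a) != length(profile_b) || length(profile_a) < 3L) {
    stop("profiles must have equal length >= 3")
  }
  if (stats::sd(profile_a) == 0 || stats::sd(profile_b) == 0) return(NA_real_)
  1 - stats::cor(profile_a, profile_b)
}

# genes with >= 1 genotype-discordant SV within `window` bp of the gene body
genes_with_discordant_sv <- function(genes, callset, accession_pair,
                                     window = 2000L) {
  rec <- callset$records
  gt <- callset$genotypes
  g1 <- gt[, accession_pair[1]]
  g2 <- gt[, accession_pair[2]]
  disc <- which(!is.na(g1) & !is.na(g2) & g1 != g2 &
                  rec$sv_type %in% c("INS", "DEL"))
  flag <- rep(FALSE, nrow(genes))
  for (i in disc) {
    hit <- genes$chrom == rec$ref_chrom[i] &
      genes$start - window <= rec$end[i] &
      genes$end + window >= rec$pos[i]
    flag <- flag | hit
  }
  flag
}

#' Expression-variation contrast between genes with and without nearby SVs
#'
#' Genes are partitioned by the presence of at least one SV whose genotype
#' differs between the two accessions within `window` bp of the gene body.
#' Per gene, expression variation is the Pearson distance between the two
#' accessions' tissue profiles; each set's mean is bootstrapped (genes
#' resampled with replacement) for a percentile 95% CI, and the sets are
#' compared with a two-sided Wilcoxon test.
#'
#' @param expr genes x accessions x tissues array from
#'   [simulate_expression()] (or equivalent).
#' @param accession_pair character vector of two accession names.
#' @param callset an `sv_callset` with genotypes for both accessions.
#' @param genes gene data.frame (gene_id, chrom, start, end).
#' @param window distance window in bp (default 2000).
#' @param n_boot bootstrap replicates (default 10000).
#' @param seed RNG seed for the bootstrap.
#' @return list with `per_set` (data.frame: set, n_genes, mean, ci_low,
#'   ci_high), `wilcox_p`, `distances` (per-gene data.frame), `n_excluded`
#'   (zero-variance profiles).
#' @export
contrast_gene_sets <- function(expr, accession_pair, callset, genes,
                               window = 2000L, n_boot = 10000L, seed = 1L) {
  stopifnot(length(accession_pair) == 2L,
            all(accession_pair %in% dimnames(expr)[[2]]))
  gene_ids <- dimnames(expr)[[1]]
  genes <- genes[match(gene_ids, genes$gene_id), ]
  with_sv <- genes_with_discordant_sv(genes, callset, accession_pair, window)
  dist <- vapply(seq_along(gene_ids), function(i) {
    a <- expr[i, accession_pair[1], ]
    b <- expr[i, accession_pair[2], ]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    1 - stats::cor(a, b)
  }, numeric(1))
  ok <- !is.na(dist)
  n_excluded <- sum(!ok)
  sets <- list(`SV-within-2kb` = dist[ok & with_sv],
               `no-SV` = dist[ok & !with_sv])
  if (any(lengths(sets) == 0L)) stop("one of the gene sets is empty")
  set.seed(seed)
  per_set <- do.call(rbind, lapply(names(sets), function(nm) {
    x <- sets[[nm]]
    bm <- vapply(seq_len(n_boot), function(b) {
      mean(x[sample.int(length(x), replace = TRUE)])
    }, numeric(1))
    ci <- if (n_boot > 1L) stats::quantile(bm, c(0.025, 0.975), names = FALSE)
          else rep(mean(bm), 2L)
    data.frame(set = nm, n_genes = length(x), mean = mean(x),
               ci_low = ci[1], ci_high = ci[2], stringsAsFactors = FALSE)
  }))
  wp <- suppressWarnings(
    stats::wilcox.test(sets[[1]], sets[[2]], exact = FALSE)$p.value)
  list(per_set = per_set, wilcox_p = wp,
       distances = data.frame(gene_id = gene_ids[ok],
                              with_sv = with_sv[ok], distance = dist[ok],
                              stringsAsFactors = FALSE),
       n_excluded = n_excluded)
}

#' SV-genotype differential expression with the magnitude filter rule
#'
#' Per gene: unpaired two-sided t-test of TPM between genotype groups; fold
#' change is the larger group mean over the smaller (direction reported
#' separately); a gene passes iff p <= p_max, fold change >= fc_min and the
#' larger group-mean TPM >= tpm_min.
#'
#' @param expr genes x accessions TPM matrix (one tissue, e.g. fruit).
#' @param sv_genotypes named vector per accession in \{"0/0", "1/1"\} (or
#'   0/1).
#' @param p_max,fc_min,tpm_min filter thresholds.
#' @param min_group minimum accessions per genotype group (genes cannot be
#'   tested below it; scan errors if the design itself is below it).
#' @return data.frame (gene_id, mean_ref, mean_alt, fold_change, direction,
#'   p, passes).
#' @export
sv_de_genes <- function(expr, sv_genotypes, p_max = 0.05, fc_min = 1.5,
                        tpm_min = 10, min_group = 3L) {
  gt <- sv_genotypes[colnames(expr)]
  grp_alt <- gt %in% c("1/1", 1, "1")
  grp_ref <- gt %in% c("0/0", 0, "0")
  if (sum(grp_alt) < min_group || sum(grp_ref) < min_group) {
    stop("each genotype group needs at least ", min_group, " accessions")
  }
  out <- do.call(rbind, lapply(seq_len(nrow(expr)), function(i) {
    a <- expr[i, grp_alt]; r <- expr[i, grp_ref]
    p <- tryCatch(stats::t.test(a, r)$p.value, error = function(e) NA_real_)
    m_a <- mean(a); m_r <- mean(r)
    fc <- max(m_a, m_r) / max(min(m_a, m_r), .Machine$double.eps)
    data.frame(gene_id = rownames(expr)[i] %||% i, mean_ref = m_r,
               mean_alt = m_a, fold_change = fc,
               direction = ifelse(m_a >= m_r, "up", "down"), p = p,
               stringsAsFactors = FALSE)
  }))
  out$passes <- !is.na(out$p) & out$p <= p_max & out$fold_change >= fc_min &
    pmax(out$mean_ref, out$mean_alt) >= tpm_min
  out
}
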