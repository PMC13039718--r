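#' Classify gene families by genome occupancy
#'
#' Occupancy is the number of genomes with at least one member. With N
#' genomes: core (all N), softcore (exactly N-1), dispensable (2 to N-2),
#' private (exactly 1). Composition percentages are class counts over total
#' families, rounded to 2 decimals.
#'
#' @param fm families x genomes count matrix (integer, >= 0), at least one
#'   positive entry per family; N >= 4 genomes.
#' @return list with `class` (factor per family), `summary` (data.frame
#'   class, count, percent).
#' @export
classify_families <- function(fm) {
  fm <- as.matrix(fm)
  N <- ncol(fm)
  if (N < 4L) stop("occupancy classes are undefined for fewer than 4 genomes")
  if (any(fm < 0) || any(fm != round(fm))) stop("counts must be non-negative integers")
  occ <- rowSums(fm >= 1L)
  if (any(occ == 0L)) stop("every family needs at least one positive entry")
  cls <- ifelse(occ == N, "core",
         ifelse(occ == N - 1L, "softcore",
         ifelse(occ == 1L, "private", "dispensable")))
  cls <- factor(cls, levels = c("core", "softcore", "dispensable", "private"))
  cnt <- table(cls)
  summary <- data.frame(class = names(cnt), count = as.integer(cnt),
                        percent = round(100 * as.integer(cnt) / length(cls), 2))
  list(class = cls, summary = summary)
}

#' Composition percentages from class counts
#'
#' @param counts named or ordered integer vector of class counts.
#' @param digits rounding digits.
#' @return percentages summing to ~100.
#' @export
composition_percent <- function(counts, digits = 2) {
  round(100 * counts / sum(counts), digits)
}

#' Pan/core rarefaction curves
#'
#' For each random genome ordering, pan(m) is the number of families present
#' in at least one of the first m genomes and core(m) the number present in
#' all of them; curves are averaged over permutations.
#'
#' @param fm families x genomes count matrix.
#' @param n_permutations number of random orderings (>= 1).
#' @param seed RNG seed.
#' @return data.frame (m, pan_mean, pan_min, pan_max, core_mean, core_min,
#'   core_max).
#' @export
rarefaction <- function(fm, n_permutations = 100L, seed = 1L) {
  stopifnot(n_permutations >= 1L)
  fm <- as.matrix(fm) >= 1L
  N <- ncol(fm)
  set.seed(seed)
  pan <- matrix(0L, n_permutations, N)
  core <- matrix(0L, n_permutations, N)
  for (p in seq_len(n_permutations)) {
    ord <- sample.int(N)
    seen <- rep(FALSE, nrow(fm))
    inall <- rep(TRUE, nrow(fm))
    for (m in seq_len(N)) {
      g <- fm[, ord[m]]
      seen <- seen | g
      inall <- inall & g
      pan[p, m] <- sum(seen)
      core[p, m] <- sum(inall)
    }
  }
  data.frame(m = seq_len(N),
             pan_mean = colMeans(pan), pan_min = apply(pan, 2, min),
             pan_max = apply(pan, 2, max),
             core_mean = colMeans(core), core_min = apply(core, 2, min),
             core_max = apply(core, 2, max))
}

# ---- Nei-Gojobori (1986) Ka/Ks ----------------------------------------

codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

# fraction of the 9 possible single-base changes in a codon that are
# synonymous; changes to stop codons count as nonsynonymous
codon_syn_sites <- function(codon, code) {
  aa <- code[[codon]]
  s <- 0
  for (p in 1:3) {
    base <- substr(codon, p, p)
    for (b in setdiff(DNA_BASES, base)) {
      mut <- codon
      substr(mut, p, p) <- b
      if (code[[mut]] == aa && code[[mut]] != "*") s <- s + 1 / 3
    }
  }
  s
}

# average syn/nonsyn difference counts over minimal mutational pathways
# between two codons; pathways through stop codons are excluded (all
# pathways are used if every one passes through a stop)
codon_path_diffs <- function(c1, c2, code) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  d <- length(pos)
  if (d == 0L) return(c(sd = 0, nd = 0))
  perms <- if (d == 1L) list(pos) else {
    idx <- seq_len(d)
    out <- list()
    permute <- function(cur, rest) {
      if (!length(rest)) out[[length(out) + 1L]] <<- pos[cur]
      else for (r in seq_along(rest)) permute(c(cur, rest[r]), rest[-r])
    }
    permute(integer(0), idx)
    out
  }
  tally <- list()
  for (pth in perms) {
    cur <- c1
    sd <- 0; nd <- 0; blocked <- FALSE
    for (p in pth) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (code[[nxt]] == "*" && nxt != c2) { blocked <- TRUE; break }
      if (code[[nxt]] == code[[cur]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (!blocked) tally[[length(tally) + 1L]] <- c(sd = sd, nd = nd)
  }
  if (!length(tally)) {  # all paths pass through a stop: use them anyway
    for (pth in perms) {
      cur <- c1; sd <- 0; nd <- 0
      for (p in pth) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        if (code[[nxt]] == code[[cur]]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      tally[[length(tally) + 1L]] <- c(sd = sd, nd = nd)
    }
  }
  colMeans(do.call(rbind, tally))
}

jukes_cantor <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 0.75) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}

#' Nei-Gojobori (1986) Ka and Ks for an aligned codon pair
#'
#' Synonymous and nonsynonymous sites are counted by per-codon fractional
#' classification, differences by averaging over minimal mutational
#' pathways, and each proportion receives the Jukes-Cantor correction.
#' Codons containing a gap in either sequence are dropped pairwise.
#'
#' @param seq1,seq2 aligned coding sequences of equal length (multiple of
#'   3), gaps as "-".
#' @return list with `ka`, `ks`, `ratio` (NA when Ks is 0 or a correction
#'   is undefined), and the raw counts `S`, `N`, `Sd`, `Nd`.
#' @export
kaks_ng86 <- function(seq1, seq2) {
  seq1 <- toupper(seq1); seq2 <- toupper(seq2)
  if (nchar(seq1) != nchar(seq2)) stop("sequences must be aligned (equal length)")
  if (nchar(seq1) %% 3L != 0L) stop("alignment length must be a multiple of 3")
  code <- codon_table()
  n_cod <- nchar(seq1) %/% 3L
  S <- 0; Sd <- 0; Nd <- 0; n_used <- 0L
  for (i in seq_len(n_cod)) {
    c1 <- substr(seq1, 3L * i - 2L, 3L * i)
    c2 <- substr(seq2, 3L * i - 2L, 3L * i)
    if (grepl("[^ACGT]", c1) || grepl("[^ACGT]", c2)) next
    if (code[[c1]] == "*" || code[[c2]] == "*") {
      stop("in-frame stop codon at codon ", i)
    }
    n_used <- n_used + 1L
    S <- S + (codon_syn_sites(c1, code) + codon_syn_sites(c2, code)) / 2
    d <- codon_path_diffs(c1, c2, code)
    Sd <- Sd + d[["sd"]]
    Nd <- Nd + d[["nd"]]
  }
  if (n_used == 0L) stop("no gap-free codons to compare")
  N <- 3 * n_used - S
  pS <- Sd / S; pN <- Nd / N
  ks <- jukes_cantor(pS); ka <- jukes_cantor(pN)
  ratio <- if (is.na(ka) || is.na(ks) || ks == 0) NA_real_ else ka / ks
  list(ka = ka, ks = ks, ratio = ratio, S = S, N = N, Sd = Sd, Nd = Nd)
}

#' Hypergeometric term enrichment of a gene set
#'
#' Fold enrichment is the term's proportion in the query set relative to the
#' background; the p-value is the one-sided upper-tail hypergeometric
#' probability P(X >= k).
#'
#' @param set_counts named integer vector: per term, genes in the query set
#'   annotated with it (k).
#' @param set_size query-set size (n).
#' @param bg_counts named integer vector: per term, genes in the background
#'   annotated with it (K).
#' @param bg_size background size (M).
#' @param adjust apply Benjamini-Hochberg adjustment across terms.
#' @return data.frame (term, k, n, K, M, fold, p [, p_adj]).
#' @export
enrichment <- function(set_counts, set_size, bg_counts, bg_size,
                       adjust = FALSE) {
  terms <- names(set_counts)
  stopifnot(!is.null(terms), all(terms %in% names(bg_counts)))
  k <- as.integer(set_counts)
  K <- as.integer(bg_counts[terms])
  if (any(k > K)) stop("query-set term count exceeds background count")
  if (set_size > bg_size) stop("query set larger than background")
  fold <- (k / set_size) / (K / bg_size)
  p <- stats::phyper(k - 1L, K, bg_size - K, set_size, lower.tail = FALSE)
  out <- data.frame(term = terms, k = k, n = set_size, K = K, M = bg_size,
                    fold = fold, p = p, stringsAsFactors = FALSE)
  if (adjust) out$p_adj <- stats::p.adjust(out$p, "BH")
  out
}
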