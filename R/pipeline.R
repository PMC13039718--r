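#' Run the full synthetic-panel pipeline
#'
#' Orchestrates simulate -> whole-genome alignment -> SV calling/merging/
#' annotation -> population genetics -> pangene classification -> trait
#' association -> SV-expression integration on a synthetic panel, writing
#' all stage outputs and a manifest (parameters plus md5 checksums) to
#' `out_dir`. Re-running with an identical configuration reproduces
#' identical checksums.
#'
#' @param config a [sim_config()]; its seed drives every stochastic stage.
#' @param out_dir output directory (created if needed).
#' @param k anchoring k-mer size.
#' @param write_fasta also write per-accession FASTA files (off by default;
#'   they are the largest outputs).
#' @return invisible list with the in-memory stage results and the manifest.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = tempfile("subpansv"),
                         k = 21L, write_fasta = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(...) message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                                             sprintf(...)))
  t0 <- Sys.time()

  log_stage("simulate: %d accessions, %d x %d bp", config$n_accessions,
            config$n_chromosomes, config$chrom_length)
  sim <- simulate_panel(config)
  panel <- sim$panel; truth <- sim$truth
  if (write_fasta) {
    write_fasta_genome(panel$reference, file.path(out_dir, "reference.fa"))
    for (a in panel$accession_names) {
      write_fasta_genome(panel$accessions[[a]], file.path(out_dir, paste0(a, ".fa")))
    }
    write_fasta_genome(panel$outgroup, file.path(out_dir, "outgroup.fa"))
  }
  write_gff3(truth$genes, truth$exons, file.path(out_dir, "genes.gff3"))
  write_bed(truth$te_bed, file.path(out_dir, "te_annotations.bed"))
  write_tsv(truth$variants, file.path(out_dir, "truth_variants.tsv"))

  log_stage("wga + svcall: %d pairwise comparisons", config$n_accessions)
  nets <- list(); calls <- list(); smalls <- list()
  for (a in panel$accession_names) {
    nets[[a]] <- wga_align(panel$reference, panel$accessions[[a]], k = k)
    res <- lapply(names(nets[[a]]), function(rc) {
      call_variants_from_net(nets[[a]][[rc]], panel$reference,
                             panel$accessions[[a]], accession = a)
    })
    calls[[a]] <- do.call(rbind, lapply(res, `[[`, "sv"))
    smalls[[a]] <- do.call(rbind, lapply(res, `[[`, "small"))
  }
  callset <- merge_callsets(calls, nets = nets)
  callset <- annotate_callset(callset, truth$te_bed, truth$exons,
                              panel$reference)
  log_stage("svcall: %d merged SV records (%d sub-size rejected)",
            nrow(callset$records), attr(callset, "n_rejected"))
  write_sv_vcf(callset, file.path(out_dir, "svs.vcf"), panel$reference)

  log_stage("popgen: truth-matrix summaries")
  vm <- truth_variant_matrix(truth)
  vmp <- polarize(vm, "OUT")
  windows <- do.call(rbind, lapply(seq_len(config$n_chromosomes), function(i) {
    make_windows(sprintf("chr%d", i), config$chrom_length, 100000L)
  }))
  pi_all <- nucleotide_diversity(vmp, windows)
  td <- tajima_d(vmp, windows)
  write_tsv(pi_all, file.path(out_dir, "pi_windows.tsv"))
  write_tsv(td, file.path(out_dir, "tajima_windows.tsv"))
  K <- kinship_standardized(filter_variants(vmp, min_maf = 0.05,
                                            max_missing = 0.2))
  write_tsv(as.data.frame(K), file.path(out_dir, "kinship.tsv"))
  tree <- nj_tree(genotype_distance(vmp))
  ape::write.tree(tree, file.path(out_dir, "nj_tree.nwk"))

  log_stage("pangene: occupancy from deletion-induced gene absence")
  fam <- gene_family_matrix(truth)
  cls <- classify_families(fam)
  write_tsv(cls$summary, file.path(out_dir, "pangene_summary.tsv"))

  log_stage("assoc: phenotypes, CNV and inversion genotyping")
  ph <- simulate_phenotypes(truth, seed = config$seed + 1L)
  cov <- simulate_coverage(truth, noise_sd = 0.05, seed = config$seed + 2L)
  e_cls <- cnv_genotype(cov, "eps", threshold = 2, labels = c("E+", "E-"))
  r_cls <- cnv_genotype(cov, "roq", threshold = 15, labels = c("R+", "R-"))
  junc <- simulate_inversion_junctions(truth, seed = config$seed + 3L)
  inv_gt <- genotype_inversion(junc)
  write_tsv(ph$loci, file.path(out_dir, "locus_genotypes.tsv"))
  write_tsv(ph$incidence, file.path(out_dir, "incidence.tsv"))
  write_tsv(merge(merge(e_cls, r_cls, by = "accession",
                        suffixes = c("_eps", "_roq")), inv_gt,
                  by = "accession"),
            file.path(out_dir, "marker_genotypes.tsv"))

  log_stage("svexpr: tissue expression and SV contrast")
  expr <- simulate_expression(truth, seed = config$seed + 4L)
  pair <- panel$accession_names[1:2]
  contrast <- tryCatch(
    contrast_gene_sets(expr, pair, callset, truth$genes, n_boot = 1000L,
                       seed = config$seed + 5L),
    error = function(e) NULL)
  if (!is.null(contrast)) {
    write_tsv(contrast$per_set, file.path(out_dir, "expr_contrast.tsv"))
  }

  files <- sort(list.files(out_dir, full.names = TRUE))
  manifest <- data.frame(file = basename(files),
                         md5 = as.character(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  log_stage("done in %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(list(truth = truth, panel = panel, callset = callset,
                 variant_matrix = vmp, pi = pi_all, tajima = td, kinship = K,
                 tree = tree, pangene = cls, phenotypes = ph,
                 cnv = list(E = e_cls, R = r_cls), inversion = inv_gt,
                 contrast = contrast, manifest = manifest, out_dir = out_dir))
}

#' Gene-family presence matrix implied by deletion polymorphisms
#'
#' Treats every planted gene as a single-member family present in a genome
#' unless a deletion carried by that accession removes at least half of one
#' of its exons; the reference genome is included as a column.
#'
#' @param truth a `truth_set`.
#' @return families x genomes binary count matrix.
#' @export
gene_family_matrix <- function(truth) {
  acc <- truth$accessions
  genes <- truth$genes
  dels <- truth$variants[truth$variants$type == "DEL", ]
  fam <- matrix(1L, nrow(genes), length(acc) + 1L,
                dimnames = list(genes$gene_id, c("REF", acc)))
  for (i in seq_len(nrow(dels))) {
    d <- dels[i, ]
    carr <- strsplit(d$carriers, ",")[[1]]
    hit <- which(genes$chrom == d$chrom & genes$start <= d$end &
                   genes$end >= d$pos + 1L)
    for (gi in hit) {
      ex <- truth$exons[truth$exons$gene_id == genes$gene_id[gi], ]
      ov <- pmax(0L, pmin(ex$end, d$end) - pmax(ex$start, d$pos + 1L) + 1L)
      if (any(ov >= 0.5 * (ex$end - ex$start + 1L))) {
        fam[gi, carr] <- 0L
      }
    }
  }
  fam
}
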