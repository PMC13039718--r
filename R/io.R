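#' Write an SV callset as VCF 4.2
#'
#' INS records carry the full inserted sequence in ALT (prefixed by the
#' reference anchor base); DEL, INV and TRA use symbolic ALT alleles with
#' END (and CHR2 for translocations). INFO keys: SVTYPE, SVLEN, END,
#' FEATCLASS, SUPP. Genotypes are haploid-representative 0/0, 1/1 or ./.
#'
#' @param callset an `sv_callset`.
#' @param path output file.
#' @param ref optional named character vector of reference sequences (used
#'   for the anchor REF base; otherwise N).
#' @export
write_sv_vcf <- function(callset, path, ref = NULL) {
  rec <- callset$records
  acc <- colnames(callset$genotypes)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=subpansv",
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
           "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
           "##INFO=<ID=CHR2,Number=1,Type=String,Description=\"Destination chromosome of a translocation\">",
           "##INFO=<ID=FEATCLASS,Number=1,Type=String,Description=\"Genomic feature class\">",
           "##INFO=<ID=SUPP,Number=1,Type=Integer,Description=\"Supporting accessions or callers\">",
           "##ALT=<ID=DEL,Description=\"Deletion\">",
           "##ALT=<ID=INV,Description=\"Inversion\">",
           "##ALT=<ID=TRA,Description=\"Translocation\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", acc), collapse = "\t"))
  lines <- character(nrow(rec))
  for (i in seq_len(nrow(rec))) {
    r <- rec[i, ]
    pos <- max(r$pos, 1L)
    refb <- if (!is.null(ref)) substr(ref[[r$ref_chrom]], pos, pos) else "N"
    alt <- switch(r$sv_type,
                  INS = paste0(refb, r$alt_seq),
                  DEL = "<DEL>", INV = "<INV>", TRA = "<TRA>")
    info <- sprintf("SVTYPE=%s;SVLEN=%d;END=%d;FEATCLASS=%s;SUPP=%d",
                    r$sv_type,
                    if (r$sv_type == "DEL") -r$length else r$length,
                    r$end, r$feature_class,
                    if ("support" %in% names(rec)) r$support else 1L)
    if (r$sv_type == "TRA" && !is.na(r$alt_seq)) {
      info <- paste0(info, ";CHR2=", sub(":.*$", "", r$alt_seq))
    }
    gt <- callset$genotypes[i, ]
    gts <- ifelse(is.na(gt), "./.", ifelse(gt == 1L, "1/1", "0/0"))
    lines[i] <- paste(c(r$ref_chrom, pos, sprintf("sv%05d", i), refb, alt,
                        ".", "PASS", info, "GT", gts), collapse = "\t")
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read an SV VCF back into a callset
#'
#' Parses a VCF written by [write_sv_vcf()] (or any VCF with SVTYPE/SVLEN/
#' END INFO keys and haploid-representative GT calls) via vcfR.
#'
#' @param path VCF file.
#' @return an `sv_callset`.
#' @export
read_sv_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  info_get <- function(key) {
    m <- regmatches(fix$INFO <- v@fix[, "INFO"],
                    regexpr(paste0("(?<=", key, "=)[^;]+"), v@fix[, "INFO"],
                            perl = TRUE))
    out <- rep(NA_character_, nrow(fix))
    has <- grepl(paste0(key, "="), v@fix[, "INFO"])
    out[has] <- m
    out
  }
  svtype <- info_get("SVTYPE")
  svlen <- abs(as.integer(info_get("SVLEN")))
  endp <- as.integer(info_get("END"))
  featclass <- info_get("FEATCLASS")
  supp <- as.integer(info_get("SUPP"))
  chr2 <- info_get("CHR2")
  alt_seq <- ifelse(svtype == "INS", substring(fix$ALT, 2L),
                    ifelse(svtype == "TRA", chr2, NA_character_))
  pos <- as.integer(fix$POS)
  records <- data.frame(sv_type = svtype, ref_chrom = fix$CHROM, pos = pos,
                        end = endp, length = svlen, alt_seq = alt_seq,
                        source = "vcf", feature_class = featclass,
                        support = supp, stringsAsFactors = FALSE)
  gt_raw <- vcfR::extract.gt(v)
  geno <- matrix(NA_integer_, nrow(gt_raw), ncol(gt_raw),
                 dimnames = dimnames(gt_raw))
  geno[gt_raw %in% c("0/0", "0|0", "0")] <- 0L
  geno[gt_raw %in% c("1/1", "1|1", "1")] <- 1L
  structure(list(records = records, genotypes = geno,
                 params = list(source = path)),
            class = "sv_callset")
}

#' Write gene models as GFF3
#'
#' @param genes data.frame (gene_id, chrom, start, end, strand).
#' @param exons data.frame (gene_id, chrom, start, end).
#' @param path output file.
#' @export
write_gff3 <- function(genes, exons, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    writeLines(paste(g$chrom, "subpansv", "gene", g$start, g$end, ".",
                     g$strand, ".", paste0("ID=", g$gene_id), sep = "\t"), con)
    ex <- exons[exons$gene_id == g$gene_id, , drop = FALSE]
    for (j in seq_len(nrow(ex))) {
      writeLines(paste(g$chrom, "subpansv", "exon", ex$start[j], ex$end[j],
                       ".", g$strand, ".", paste0("Parent=", g$gene_id),
                       sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Write classed intervals as BED (0-based half-open)
#'
#' @param bed data.frame (chrom, start, end, class) with 1-based closed
#'   coordinates (converted on output).
#' @param path output file.
#' @export
write_bed <- function(bed, path) {
  utils::write.table(data.frame(bed$chrom, bed$start - 1L, bed$end,
                                bed$class %||% "."),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write a data.frame as TSV
#' @param x data.frame.
#' @param path output file.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
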