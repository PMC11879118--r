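# Plain-text serialization of a synthetic world: GTF-like annotation, BED
# fragment files, TSV matrices/tables, VCF-like haplotype panel, BEDPE
# interactions, JSON planted truth.

tsv_write <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a synthetic world to a directory of plain-text files
#'
#' Emits: `annotation.gtf` (transcript records with TSS-bearing coordinates),
#' `fragments_<library>_rep<k>.bed`, `expression.tsv`, `panel.vcf` (phased
#' GT columns), `gwas_catalog.tsv`, `eqtls.tsv`, `pp_interactions.bedpe`,
#' `crispri_z.tsv`, one BED/TSV per feature track, `chrom_sizes.tsv` and
#' `planted_truth.json`. All interval files are 0-based half-open BED except
#' the VCF (1-based).
#'
#' @param world a `synthetic_world`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "synthetic_world"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ann <- world$annotation
  # GTF-like: 1-based inclusive single-bp TSS feature per transcript
  gtf <- data.frame(
    seqname = ann$chrom, source = "synthetic", feature = "transcript",
    start = ann$tss + 1L, end = ann$tss + 1L, score = ".",
    strand = ann$strand, frame = ".",
    attribute = sprintf('gene_id "%s"; transcript_id "%s";',
                        ann$gene_id, ann$transcript_id)
  )
  utils::write.table(gtf, file.path(dir, "annotation.gtf"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  for (lib in names(world$fragments)) {
    for (r in seq_along(world$fragments[[lib]])) {
      fs <- world$fragments[[lib]][[r]]
      bed <- fs$fragments
      bed$name <- "."
      bed$score <- 0L
      bed <- bed[, c("chrom", "start", "end", "name", "score", "strand")]
      f <- file.path(dir, sprintf("fragments_%s_rep%d.bed", lib, r))
      utils::write.table(bed, f, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
    }
  }
  expr <- data.frame(gene_id = rownames(world$expression),
                     world$expression, check.names = FALSE)
  tsv_write(expr, file.path(dir, "expression.tsv"))

  # VCF-like panel: phased haplotype pairs in GT columns
  hap <- world$panel$haplotypes
  n_ind <- floor(nrow(hap) / 2)
  gt <- vapply(seq_len(n_ind), function(i) {
    paste(hap[2 * i - 1, ], hap[2 * i, ], sep = "|")
  }, character(ncol(hap)))
  vcf <- data.frame(
    CHROM = world$panel$sites$chrom, POS = world$panel$sites$pos,
    ID = world$panel$sites$snp_id, REF = "A", ALT = "G", QUAL = ".",
    FILTER = "PASS", INFO = ".", FORMAT = "GT", gt, check.names = FALSE
  )
  names(vcf)[1] <- "#CHROM"
  names(vcf)[10:ncol(vcf)] <- sprintf("IND%04d", seq_len(n_ind))
  con <- file(file.path(dir, "panel.vcf"), "w")
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
             con)
  utils::write.table(vcf, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)

  tsv_write(world$gwas, file.path(dir, "gwas_catalog.tsv"))
  tsv_write(world$eqtls, file.path(dir, "eqtls.tsv"))
  utils::write.table(world$pp_interactions, file.path(dir, "pp_interactions.bedpe"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  zm <- data.frame(promoter_id = rownames(world$crispri$z_matrix),
                   world$crispri$z_matrix, check.names = FALSE)
  tsv_write(zm, file.path(dir, "crispri_z.tsv"))
  writeLines(world$mpra_snps, file.path(dir, "mpra_skew_snps.txt"))
  writeLines(world$tfskew_snps, file.path(dir, "tf_skew_snps.txt"))
  for (tk in names(world$tracks)) {
    tsv_write(world$tracks[[tk]], file.path(dir, sprintf("track_%s.tsv", tk)))
  }
  tsv_write(data.frame(chrom = names(world$chrom_sizes),
                       size = unname(world$chrom_sizes)),
            file.path(dir, "chrom_sizes.tsv"))
  truth <- world$truth
  truth$ld_proxies <- NULL  # tabular; serialized separately
  jsonlite::write_json(truth, file.path(dir, "planted_truth.json"),
                       auto_unbox = FALSE, digits = NA, pretty = TRUE)
  tsv_write(world$truth$ld_proxies, file.path(dir, "ld_proxies.tsv"))
  invisible(dir)
}
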