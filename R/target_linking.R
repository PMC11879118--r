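# eQTL target classification, P-P interaction consistency, CRISPRi
# distal-regulation screen, and four-layer evidence integration.

#' Classify eQTLs by target distance
#'
#' Records are first merged non-redundantly across tissues by (SNP, target);
#' a SNP is `proximal` if all its targets lie within `proximal_bp` of their
#' TSS, `distal` if all lie beyond, `both` otherwise. The boundary itself
#' (|distance| == `proximal_bp`) counts as proximal.
#'
#' @param eqtls data.frame: `snp_id`, `target_gene_id`, `tissue`, `effect_z`,
#'   `tss_distance_bp` (signed; the absolute value is classified).
#' @param proximal_bp distance boundary in bp (default 2000).
#' @return List: `classes` (data.frame `snp_id`, `class`), `merged` (the
#'   non-redundant (SNP, target) table with a `distal` flag).
#' @export
classify_eqtls <- function(eqtls, proximal_bp = 2000) {
  key <- paste(eqtls$snp_id, eqtls$target_gene_id)
  merged <- eqtls[!duplicated(key), c("snp_id", "target_gene_id",
                                      "tss_distance_bp"), drop = FALSE]
  merged$distal <- abs(merged$tss_distance_bp) > proximal_bp
  by_snp <- split(merged$distal, merged$snp_id)
  classes <- data.frame(
    snp_id = names(by_snp),
    class = vapply(by_snp, function(d) {
      if (all(d)) "distal" else if (all(!d)) "proximal" else "both"
    }, character(1)),
    stringsAsFactors = FALSE
  )
  rownames(classes) <- rownames(merged) <- NULL
  list(classes = classes, merged = merged)
}

#' Consistency of distal eQTL targets with promoter-promoter interactions
#'
#' A (SNP, distal target) pair is consistent iff some interaction has one
#' anchor overlapping the SNP's Epromoter region and the other anchor
#' overlapping any promoter of the target gene (gene-level union over
#' alternative TSSs).
#'
#' @param snp_regions data.frame (`snp_id`, `chrom`, `start`, `end`): the
#'   Epromoter region harbouring each SNP.
#' @param eqtl_targets data.frame (`snp_id`, `target_gene_id`) of distal
#'   eQTL pairs to test.
#' @param interactions data.frame (`chrom_a`, `start_a`, `end_a`, `chrom_b`,
#'   `start_b`, `end_b`): promoter-anchored interaction pairs.
#' @param promoters promoter table from [define_promoters()].
#' @return `eqtl_targets` with a logical `consistent` column.
#' @export
pp_consistency <- function(snp_regions, eqtl_targets, interactions, promoters) {
  eqtl_targets$consistent <- rep(FALSE, nrow(eqtl_targets))
  if (nrow(eqtl_targets) == 0 || nrow(interactions) == 0) return(eqtl_targets)
  anc_a <- data.frame(chrom = interactions$chrom_a,
                      start = interactions$start_a, end = interactions$end_a)
  anc_b <- data.frame(chrom = interactions$chrom_b,
                      start = interactions$start_b, end = interactions$end_b)
  # genes whose promoters overlap each anchor
  genes_at <- function(anchors) {
    ov <- overlap_pairs(anchors, promoters)
    split(promoters$gene_id[ov$b_idx], factor(ov$a_idx, seq_len(nrow(anchors))))
  }
  genes_a <- genes_at(anc_a)
  genes_b <- genes_at(anc_b)
  # interactions touching each SNP's Epromoter region, one overlap pass each
  ova <- overlap_pairs(snp_regions, anc_a)
  ovb <- overlap_pairs(snp_regions, anc_b)
  snp_ia <- split(ova$b_idx, snp_regions$snp_id[ova$a_idx])
  snp_ib <- split(ovb$b_idx, snp_regions$snp_id[ovb$a_idx])
  for (i in seq_len(nrow(eqtl_targets))) {
    snp <- eqtl_targets$snp_id[i]
    target <- eqtl_targets$target_gene_id[i]
    hit <- target %in% unlist(genes_b[snp_ia[[snp]]], use.names = FALSE) ||
      target %in% unlist(genes_a[snp_ib[[snp]]], use.names = FALSE)
    eqtl_targets$consistent[i] <- hit
  }
  eqtl_targets
}

#' CRISPRi distal-regulation screen
#'
#' A targeted promoter is efficiently inactivated iff its own gene ranks
#' among the `top_inactivated` most repressed genes of its perturbation
#' profile (lower z = more repressed). Its `top_regulated` most repressed
#' genes form its regulated set; the promoter is a distal regulator iff a
#' regulated gene other than its own has a TSS within `cis_window_bp`. The
#' overlap of a promoter set with the distal regulators, within the universe
#' of efficiently inactivated promoters, is tested by an upper-tail
#' hypergeometric.
#'
#' @param z_matrix numeric matrix, targeted promoters x genes (dimnames
#'   required); z-normalised expression change, negative = repressed.
#' @param promoter_info data.frame (`promoter_id`, `gene_id`, `chrom`,
#'   `tss`) for the rows of `z_matrix`.
#' @param gene_tss data.frame (`gene_id`, `chrom`, `tss`) for the columns.
#' @param sets named list of promoter-ID vectors to test (e.g. Epromoters,
#'   controls).
#' @param top_inactivated own-gene rank cut (default 2).
#' @param top_regulated regulated-set size (default 30).
#' @param cis_window_bp cis distance window (default 1e6).
#' @return List: `inactivated` (promoter IDs), `distal_regulators`
#'   (promoter IDs), `regulated` (named list promoter -> regulated genes),
#'   `tests` (data.frame per set: overlap counts and hypergeometric P).
#' @export
crispri_screen <- function(z_matrix, promoter_info, gene_tss, sets = list(),
                           top_inactivated = 2L, top_regulated = 30L,
                           cis_window_bp = 1e6) {
  stopifnot(!is.null(rownames(z_matrix)), !is.null(colnames(z_matrix)))
  genes <- colnames(z_matrix)
  if (ncol(z_matrix) < top_regulated) {
    warning("fewer genes than the regulated-set size; using all genes")
    top_regulated <- ncol(z_matrix)
  }
  info <- promoter_info[match(rownames(z_matrix), promoter_info$promoter_id), ]
  tss_chrom <- stats::setNames(gene_tss$chrom, gene_tss$gene_id)
  tss_pos <- stats::setNames(gene_tss$tss, gene_tss$gene_id)

  inact <- logical(nrow(z_matrix))
  distal <- logical(nrow(z_matrix))
  regulated <- vector("list", nrow(z_matrix))
  for (i in seq_len(nrow(z_matrix))) {
    z <- z_matrix[i, ]
    ord <- order(z)
    own <- info$gene_id[i]
    inact[i] <- match(own, genes[ord]) <= top_inactivated
    reg <- genes[ord][seq_len(top_regulated)]
    regulated[[i]] <- reg
    others <- setdiff(reg, own)
    if (length(others) > 0) {
      same <- tss_chrom[others] == info$chrom[i]
      d <- abs(tss_pos[others] - info$tss[i])
      distal[i] <- any(same & d < cis_window_bp, na.rm = TRUE)
    }
  }
  names(regulated) <- rownames(z_matrix)
  universe <- rownames(z_matrix)[inact]
  distal_set <- rownames(z_matrix)[inact & distal]
  tests <- do.call(rbind, lapply(names(sets), function(nm) {
    in_universe <- intersect(sets[[nm]], universe)
    k <- length(intersect(in_universe, distal_set))
    data.frame(
      set = nm, n_in_universe = length(in_universe), n_distal = k,
      p_hyper = stats::phyper(k - 1, length(distal_set),
                              length(universe) - length(distal_set),
                              length(in_universe), lower.tail = FALSE),
      stringsAsFactors = FALSE
    )
  }))
  list(inactivated = universe, distal_regulators = distal_set,
       regulated = regulated[inact], tests = tests)
}

#' Integrate the four evidence layers into the final pleiotropic SNP list
#'
#' A SNP enters the final list iff it has a distal eQTL target, a P-P
#' interaction consistent with a distal target, MPRA allelic skew, and
#' skewed TF binding. Members are labelled pleiotropic iff they carry >= 2
#' GWAS traits.
#'
#' @param snp_traits data.frame (`snp_id`, `n_traits`).
#' @param eqtl_classes data.frame (`snp_id`, `class`) from
#'   [classify_eqtls()]; distal evidence = class `distal` or `both`.
#' @param pp_flags data.frame (`snp_id`, `consistent`) from
#'   [pp_consistency()] (any consistent target counts).
#' @param mpra_snps,tfskew_snps character vectors of SNPs with significant
#'   allelic skew (pre-thresholded upstream).
#' @return List: `profiles` (per-SNP evidence flags, `in_final_list`,
#'   `pleiotropic`), `final` (the final-list subset), `summary` (counts by
#'   trait bins 1, 2, >= 3 within the final list).
#' @export
integrate_evidence <- function(snp_traits, eqtl_classes, pp_flags,
                               mpra_snps, tfskew_snps) {
  prof <- data.frame(snp_id = snp_traits$snp_id,
                     n_traits = snp_traits$n_traits,
                     stringsAsFactors = FALSE)
  distal_snps <- eqtl_classes$snp_id[eqtl_classes$class %in% c("distal", "both")]
  pp_snps <- unique(pp_flags$snp_id[pp_flags$consistent])
  prof$has_distal_eqtl <- prof$snp_id %in% distal_snps
  prof$has_pp_consistent_target <- prof$snp_id %in% pp_snps
  prof$has_mpra_skew <- prof$snp_id %in% mpra_snps
  prof$has_tf_binding_skew <- prof$snp_id %in% tfskew_snps
  prof$in_final_list <- prof$has_distal_eqtl & prof$has_pp_consistent_target &
    prof$has_mpra_skew & prof$has_tf_binding_skew
  prof$pleiotropic <- prof$n_traits >= 2
  final <- prof[prof$in_final_list, , drop = FALSE]
  summary <- data.frame(
    bin = c("1", "2", ">=3"),
    n_snps = c(sum(final$n_traits == 1), sum(final$n_traits == 2),
               sum(final$n_traits >= 3))
  )
  rownames(final) <- NULL
  list(profiles = prof, final = final, summary = summary)
}
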