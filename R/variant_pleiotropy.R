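# LD expansion of GWAS lead SNPs, promoter overlap, pleiotropy counts and
# enrichment statistics.

#' Squared allelic correlation (r2) between two panel sites
#'
#' Computed from phased haplotype frequencies:
#' r2 = (p_AB - p_A p_B)^2 / (p_A (1 - p_A) p_B (1 - p_B)).
#'
#' @param panel 0/1 matrix, haplotypes x sites, with site IDs as colnames.
#' @param snp_a,snp_b site IDs or column indices.
#' @return r2 in `[0, 1]`; error for monomorphic sites (undefined).
#' @export
compute_r2 <- function(panel, snp_a, snp_b) {
  a <- panel[, snp_a]
  b <- panel[, snp_b]
  pa <- mean(a); pb <- mean(b)
  if (pa %in% c(0, 1) || pb %in% c(0, 1)) {
    stop("r2 undefined for a monomorphic site")
  }
  pab <- mean(a * b)
  (pab - pa * pb)^2 / (pa * (1 - pa) * pb * (1 - pb))
}

# vectorised r2 of one site against many columns of the panel
r2_one_vs_many <- function(panel, lead, cols) {
  a <- panel[, lead]
  M <- panel[, cols, drop = FALSE]
  pa <- mean(a)
  pb <- colMeans(M)
  pab <- as.numeric(crossprod(a, M)) / nrow(panel)
  den <- pa * (1 - pa) * pb * (1 - pb)
  r2 <- (pab - pa * pb)^2 / den
  r2[den == 0] <- NA_real_  # monomorphic candidates are skipped by callers
  stats::setNames(r2, cols)
}

#' Expand GWAS lead SNPs through linkage disequilibrium
#'
#' Every panel variant within +/- `window_kb` of a lead and with r2 strictly
#' greater than `r2_min` inherits that lead's traits; the lead itself is
#' always included. Variants proxying several leads union their traits and
#' categories. Leads absent from the panel are skipped with a message.
#'
#' @param leads data.frame of GWAS associations: `lead_snp_id`,
#'   `trait_efo_id`, `trait_label`, `parent_category` (one row per
#'   association; a lead may recur with several traits).
#' @param panel list with `sites` (data.frame `snp_id`, `chrom`, `pos`
#'   1-based) and `haplotypes` (0/1 matrix, haplotypes x sites, colnames =
#'   `snp_id`).
#' @param window_kb LD window in kb (default 1000, i.e. +/- 1 Mb).
#' @param r2_min r2 threshold, strict (default 0.8).
#' @param maf_common minor-allele-frequency cut separating common from rare
#'   variants (default 0.01).
#' @return data.frame of annotated variants: `snp_id`, `chrom`, `pos`
#'   (1-based), `maf`, `is_common`, and list columns `lead_links` (named r2
#'   vector), `traits`, `categories`.
#' @export
expand_ld <- function(leads, panel, window_kb = 1000, r2_min = 0.8,
                      maf_common = 0.01) {
  sites <- panel$sites
  hap <- panel$haplotypes
  stopifnot(identical(colnames(hap), sites$snp_id))
  lead_ids <- unique(leads$lead_snp_id)
  missing <- setdiff(lead_ids, sites$snp_id)
  if (length(missing) > 0) {
    message(length(missing), " lead SNP(s) absent from the panel; skipped")
    lead_ids <- setdiff(lead_ids, missing)
  }
  traits_by_lead <- split(leads$trait_efo_id, leads$lead_snp_id)
  cats_by_lead <- split(leads$parent_category, leads$lead_snp_id)
  window <- window_kb * 1000

  hits <- list()  # variant snp_id -> named r2 vector over leads
  for (lead in lead_ids) {
    li <- match(lead, sites$snp_id)
    cand <- which(sites$chrom == sites$chrom[li] &
                    abs(sites$pos - sites$pos[li]) <= window)
    r2 <- r2_one_vs_many(hap, li, cand)
    sel <- cand[!is.na(r2) & r2 > r2_min]
    sel_r2 <- r2[!is.na(r2) & r2 > r2_min]
    if (!li %in% sel) { sel <- c(li, sel); sel_r2 <- c(1, sel_r2) }
    for (k in seq_along(sel)) {
      id <- sites$snp_id[sel[k]]
      hits[[id]] <- c(hits[[id]], stats::setNames(sel_r2[k], lead))
    }
  }
  if (length(hits) == 0) {
    return(data.frame(snp_id = character(), chrom = character(),
                      pos = integer(), maf = numeric(),
                      is_common = logical()))
  }
  ids <- names(hits)
  i <- match(ids, sites$snp_id)
  p <- colMeans(hap[, i, drop = FALSE])
  maf <- pmin(p, 1 - p)
  out <- data.frame(snp_id = ids, chrom = sites$chrom[i], pos = sites$pos[i],
                    maf = unname(maf), is_common = unname(maf) >= maf_common,
                    stringsAsFactors = FALSE)
  out$lead_links <- unname(hits)
  out$traits <- lapply(hits, function(h) {
    sort(unique(unlist(traits_by_lead[names(h)], use.names = FALSE)))
  })
  out$categories <- lapply(hits, function(h) {
    sort(unique(unlist(cats_by_lead[names(h)], use.names = FALSE)))
  })
  rownames(out) <- NULL
  out
}

#' Assign variants to regions by position
#'
#' Half-open membership: a variant at 1-based position p belongs to a BED
#' region `[start, end)` iff `start <= p - 1 < end`.
#'
#' @param variants data.frame with `snp_id`, `chrom`, `pos` (1-based).
#' @param regions BED-convention data.frame with a `region_id` (or
#'   `merged_id`/`promoter_id`) column, or an `epromoter_set`.
#' @return data.frame (`region_id`, `snp_id`), one row per membership.
#' @export
overlap_variants <- function(variants, regions) {
  if (inherits(regions, "epromoter_set")) {
    regions <- regions$regions
    regions$region_id <- regions$merged_id
  }
  if (!"region_id" %in% names(regions)) {
    idc <- intersect(c("merged_id", "promoter_id"), names(regions))[1]
    if (is.na(idc)) stop("regions need an id column")
    regions$region_id <- regions[[idc]]
  }
  if (nrow(variants) == 0 || nrow(regions) == 0) {
    return(data.frame(region_id = character(), snp_id = character()))
  }
  v <- data.frame(chrom = variants$chrom, start = variants$pos - 1L,
                  end = variants$pos)
  ov <- overlap_pairs(v, regions)
  out <- data.frame(region_id = regions$region_id[ov$b_idx],
                    snp_id = variants$snp_id[ov$a_idx],
                    stringsAsFactors = FALSE)
  out[order(out$region_id, out$snp_id), , drop = FALSE]
}

#' Non-redundant trait and category counts per SNP and per region
#'
#' Per-region counts are the size of the union of member SNPs' trait
#' (category) sets; a region with >= 2 distinct traits is pleiotropic.
#'
#' @param memberships data.frame (`region_id`, `snp_id`) from
#'   [overlap_variants()].
#' @param variants annotated variants from [expand_ld()] (list columns
#'   `traits`, `categories`).
#' @return List of data.frames `per_snp` (`snp_id`, `n_traits`,
#'   `n_categories`) and `per_region` (`region_id`, `n_snps`, `n_traits`,
#'   `n_categories`, `pleiotropic`).
#' @export
pleiotropy_counts <- function(memberships, variants) {
  tr <- stats::setNames(variants$traits, variants$snp_id)
  ca <- stats::setNames(variants$categories, variants$snp_id)
  snps <- unique(memberships$snp_id)
  per_snp <- data.frame(
    snp_id = snps,
    n_traits = vapply(tr[snps], function(x) length(unique(x)), integer(1)),
    n_categories = vapply(ca[snps], function(x) length(unique(x)), integer(1)),
    stringsAsFactors = FALSE
  )
  by_region <- split(memberships$snp_id, memberships$region_id)
  per_region <- data.frame(
    region_id = names(by_region),
    n_snps = lengths(by_region),
    n_traits = vapply(by_region, function(s) {
      length(unique(unlist(tr[s], use.names = FALSE)))
    }, integer(1)),
    n_categories = vapply(by_region, function(s) {
      length(unique(unlist(ca[s], use.names = FALSE)))
    }, integer(1)),
    stringsAsFactors = FALSE
  )
  per_region$pleiotropic <- per_region$n_traits >= 2
  rownames(per_snp) <- rownames(per_region) <- NULL
  list(per_snp = per_snp, per_region = per_region)
}

#' Trait and category enrichment between promoter sets and the genome
#'
#' Per trait (or category): an upper-tail hypergeometric P of drawing the
#' observed number of trait-carrying SNPs in the set, with the population
#' being all GWAS-SNPs genome-wide, plus a Pearson chi-squared comparison of
#' the trait proportion between set A and set B.
#'
#' @param snps_a,snps_b character vectors of SNP IDs in the two sets (e.g.
#'   Epromoter and control promoter SNPs).
#' @param background annotated variants from [expand_ld()]: the genome-wide
#'   GWAS-SNP universe.
#' @param by count by `"traits"` or `"categories"`.
#' @param correct apply Yates continuity correction (default FALSE).
#' @return data.frame per trait: genome/set counts, hypergeometric P for each
#'   set, chi-squared statistic and P between sets, and BH-adjusted columns.
#' @export
enrichment_tests <- function(snps_a, snps_b, background, by = c("traits", "categories"),
                             correct = FALSE) {
  by <- match.arg(by)
  if (length(snps_a) == 0 && length(snps_b) == 0) {
    return(data.frame(trait = character()))
  }
  sets <- stats::setNames(background[[by]], background$snp_id)
  long <- data.frame(
    snp_id = rep(background$snp_id, lengths(background[[by]])),
    trait = unlist(background[[by]], use.names = FALSE),
    stringsAsFactors = FALSE
  )
  N <- nrow(background)                       # population: all GWAS-SNPs
  traits <- sort(unique(long$trait))
  snps_by_trait <- split(long$snp_id, long$trait)
  n_a <- length(unique(snps_a)); n_b <- length(unique(snps_b))
  rows <- lapply(traits, function(t) {
    carriers <- unique(snps_by_trait[[t]])
    K <- length(carriers)
    k_a <- sum(unique(snps_a) %in% carriers)
    k_b <- sum(unique(snps_b) %in% carriers)
    p_a <- stats::phyper(k_a - 1, K, N - K, n_a, lower.tail = FALSE)
    p_b <- stats::phyper(k_b - 1, K, N - K, n_b, lower.tail = FALSE)
    tab <- matrix(c(k_a, n_a - k_a, k_b, n_b - k_b), nrow = 2)
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0) &&
        !identical(tab[, 1], tab[, 2])) {
      cs <- suppressWarnings(stats::chisq.test(tab, correct = correct))
      chisq <- unname(cs$statistic); p_chisq <- cs$p.value
    } else if (identical(tab[, 1], tab[, 2])) {
      chisq <- 0; p_chisq <- 1
    } else {
      chisq <- NA_real_; p_chisq <- NA_real_
    }
    data.frame(trait = t, n_genome = K, n_set_a = k_a, n_set_b = k_b,
               p_hyper_a = p_a, p_hyper_b = p_b,
               chisq = chisq, p_chisq = p_chisq, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr_hyper_a <- stats::p.adjust(out$p_hyper_a, method = "BH")
  out$fdr_chisq <- stats::p.adjust(out$p_chisq, method = "BH")
  rownames(out) <- NULL
  out
}
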