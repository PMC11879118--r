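# Synthetic-data generator: a miniature genome with planted Epromoters,
# distal targets and pleiotropic variants, driving every downstream stage.

#' Configuration for the synthetic world
#'
#' Defaults describe the study conditions used throughout the package's
#' recovery tests: a 2 x 8 Mb genome carrying 2000 genes, 10% of which are
#' planted Epromoters with a 5-fold output/input enrichment over a 1-fold
#' background at 40x mean captured-region depth, two replicates, 314-nt
#' fragments, a 200-haplotype panel with 50-kb LD blocks, and 600 GWAS lead
#' SNPs of which a quarter are pleiotropic leads planted inside Epromoters.
#'
#' @param n_chromosomes,chrom_length_bp genome shape.
#' @param n_genes,n_tissues gene count and expression-matrix width.
#' @param frac_epromoters fraction of genes planted as Epromoters.
#' @param epromoter_fold_effect expected output/input fold-change of planted
#'   Epromoter regions; must exceed `background_fold_mean`.
#' @param background_fold_mean expected fold-change of background regions.
#' @param n_replicates replicates per library.
#' @param fragment_length_nt captured-fragment length (reads are emitted at
#'   50 nt and extended back to this length by the pipeline).
#' @param mean_depth mean fragments per captured region in the input library.
#' @param nb_size negative-binomial size (inverse overdispersion) of
#'   per-region fragment counts.
#' @param n_haplotypes phased haplotypes in the panel (>= 4).
#' @param ld_block_bp span within which a lead's LD proxies are placed.
#' @param n_gwas_leads GWAS catalog lead SNPs.
#' @param pleiotropy_boost mean number of extra traits (beyond the 2 that
#'   make a SNP pleiotropic) carried by each planted pleiotropic lead.
#' @param seed integer RNG seed; fully determines the world.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_chromosomes = 2L, chrom_length_bp = 8e6,
                             n_genes = 2000L, n_tissues = 30L,
                             frac_epromoters = 0.1,
                             epromoter_fold_effect = 5,
                             background_fold_mean = 1,
                             n_replicates = 2L, fragment_length_nt = 314L,
                             mean_depth = 40, nb_size = 20,
                             n_haplotypes = 200L, ld_block_bp = 50000L,
                             n_gwas_leads = 600L, pleiotropy_boost = 2,
                             seed = 1L) {
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_bp = as.numeric(chrom_length_bp),
    n_genes = as.integer(n_genes), n_tissues = as.integer(n_tissues),
    frac_epromoters = frac_epromoters,
    epromoter_fold_effect = epromoter_fold_effect,
    background_fold_mean = background_fold_mean,
    n_replicates = as.integer(n_replicates),
    fragment_length_nt = as.integer(fragment_length_nt),
    mean_depth = mean_depth, nb_size = nb_size,
    n_haplotypes = as.integer(n_haplotypes),
    ld_block_bp = as.numeric(ld_block_bp),
    n_gwas_leads = as.integer(n_gwas_leads),
    pleiotropy_boost = pleiotropy_boost,
    seed = as.integer(seed)
  )
  counts <- c("n_chromosomes", "n_genes", "n_tissues", "n_replicates",
              "fragment_length_nt", "n_haplotypes", "n_gwas_leads")
  stopifnot(all(vapply(cfg[counts], function(x) x > 0, logical(1))),
            cfg$frac_epromoters >= 0, cfg$frac_epromoters <= 1,
            cfg$epromoter_fold_effect > cfg$background_fold_mean,
            cfg$mean_depth > 0, cfg$nb_size > 0, cfg$n_tissues >= 2)
  if (cfg$n_haplotypes < 4) {
    stop("n_haplotypes < 4: r2 is degenerate on such panels")
  }
  promoter_window <- 500L
  slot <- floor(cfg$chrom_length_bp /
                  ceiling(cfg$n_genes / cfg$n_chromosomes))
  if (cfg$fragment_length_nt > promoter_window || slot < 6000) {
    stop("fragments cannot tile the genome: enlarge chrom_length_bp or ",
         "shrink n_genes/fragment_length_nt")
  }
  structure(cfg, class = "synthetic_config")
}

# internal constants of the generator (documented in the methods vignette)
.gen <- list(
  promoter_window = 500L,   # promoter span; also the captured-region width
  tx_spacing = 600L,        # TSS spacing within a gene: promoters disjoint
  gene_offset = 1000L,      # first TSS offset inside the gene slot
  read_len = 50L,           # emitted read length before extension
  capture_rate = 0.5,       # captured fraction of the library's mapped reads
  frac_pleiotropic_leads = 0.25,
  n_proxies_high = 2L, n_proxies_low = 1L,
  mut_high = 0.01, mut_low = 0.35,
  n_rare = 100L,
  n_trait_vocab = 400L
)

#' EFO parent-category vocabulary
#'
#' The fixed 17-label parent-trait vocabulary used to group GWAS traits.
#' @format Character vector of length 17.
#' @export
efo_parent_categories <- c(
  "Cancer", "Cardiovascular disease", "Digestive system disorder",
  "Immune system disorder", "Metabolic disorder", "Neurological disorder",
  "Response to drug", "Biological process", "Body measurement",
  "Cardiovascular measurement", "Hematological measurement",
  "Inflammatory measurement", "Lipid or lipoprotein measurement",
  "Liver enzyme measurement", "Other measurement", "Other disease",
  "Other trait"
)

#' Generate a synthetic world with planted ground truth
#'
#' Builds annotation, per-replicate STARR fragment libraries, an expression
#' matrix spanning the tau range, a block-LD haplotype panel, a GWAS catalog
#' whose pleiotropic leads sit inside planted Epromoters, eQTLs and
#' promoter-promoter interactions consistent with planted distal targets, a
#' CRISPRi z-matrix, and feature tracks - plus the `PlantedTruth` needed for
#' recovery tests. The same seed reproduces the world exactly.
#'
#' @param config a [synthetic_config()].
#' @return A list of class `synthetic_world`; see the package vignette for
#'   the component inventory.
#' @export
generate_world <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(config$seed)
  g <- .gen

  ## ---- genome & annotation -------------------------------------------
  chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))
  chrom_sizes <- stats::setNames(rep(config$chrom_length_bp, config$n_chromosomes), chroms)
  genes_per_chrom <- ceiling(config$n_genes / config$n_chromosomes)
  slot <- floor(config$chrom_length_bp / genes_per_chrom)
  gene_id <- sprintf("gene%05d", seq_len(config$n_genes))
  gene_chrom <- chroms[((seq_len(config$n_genes) - 1) %/% genes_per_chrom) + 1]
  gene_slot0 <- ((seq_len(config$n_genes) - 1) %% genes_per_chrom) * slot
  gene_strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
  n_tx <- sample.int(6L, config$n_genes, replace = TRUE)
  annotation <- do.call(rbind, lapply(seq_len(config$n_genes), function(i) {
    k <- seq_len(n_tx[i])
    data.frame(
      gene_id = gene_id[i],
      transcript_id = sprintf("%s.t%d", gene_id[i], k),
      chrom = gene_chrom[i],
      strand = gene_strand[i],
      tss = as.integer(gene_slot0[i] + g$gene_offset + (k - 1) * g$tx_spacing),
      stringsAsFactors = FALSE
    )
  }))
  promoters <- define_promoters(annotation, window = g$promoter_window,
                                chrom_sizes = chrom_sizes)
  first_tx <- promoters[!duplicated(promoters$gene_id), , drop = FALSE]
  rownames(first_tx) <- first_tx$gene_id

  ## ---- planted Epromoters --------------------------------------------
  n_ep <- round(config$frac_epromoters * config$n_genes)
  ep_genes <- sort(sample(gene_id, n_ep))
  # the planted regulatory element is the first-transcript promoter
  ep_promoters <- first_tx[ep_genes, , drop = FALSE]
  true_epromoter_ids <- ep_promoters$promoter_id

  ## ---- STARR fragment libraries --------------------------------------
  regions <- promoters[, c("promoter_id", "chrom", "start", "end")]
  names(regions)[1] <- "region_id"
  fold <- ifelse(promoters$promoter_id %in% true_epromoter_ids,
                 config$epromoter_fold_effect, config$background_fold_mean)
  n_regions <- nrow(regions)
  mean_fold <- mean(fold)
  declared_total <- round(n_regions * config$mean_depth *
                            max(1 / g$capture_rate, 1.25 * mean_fold))
  draw_library <- function(mu_per_region, library, replicate) {
    counts <- stats::rnbinom(n_regions, mu = mu_per_region, size = config$nb_size)
    idx <- rep.int(seq_len(n_regions), counts)
    L <- config$fragment_length_nt
    fstart <- regions$start[idx] +
      floor(stats::runif(length(idx)) * (regions$end[idx] - regions$start[idx] - L + 1))
    strand <- sample(c("+", "-"), length(idx), replace = TRUE)
    reads <- data.frame(
      chrom = regions$chrom[idx],
      start = as.integer(ifelse(strand == "+", fstart, fstart + L - g$read_len)),
      end = as.integer(ifelse(strand == "+", fstart + g$read_len, fstart + L)),
      strand = strand, stringsAsFactors = FALSE
    )
    fragment_set(reads, library = library, replicate = replicate,
                 total_mapped = max(declared_total, nrow(reads)))
  }
  fragments <- list(
    input = lapply(seq_len(config$n_replicates), function(r) {
      draw_library(config$mean_depth, "input", r)
    }),
    output = lapply(seq_len(config$n_replicates), function(r) {
      draw_library(config$mean_depth * fold, "output", r)
    })
  )

  ## ---- expression matrix (tau-spanning tissue profiles) --------------
  # Genes draw their tissue profile from a finite set of shared expression
  # programs (co-expression modules), with gene-level log-normal peak
  # expression and multiplicative noise. Program concentrations span the
  # breadth spectrum, so tau covers its range while every gene has
  # shape-mates - the structure that makes expression matching meaningful.
  tissues <- sprintf("tissue%02d", seq_len(config$n_tissues))
  n_programs <- 60L
  prog_alpha <- 10^stats::runif(n_programs, -1.3, 1.7)
  programs <- t(vapply(seq_len(n_programs), function(k) {
    v <- stats::rgamma(config$n_tissues, shape = prog_alpha[k])
    v / max(v)
  }, numeric(config$n_tissues)))
  gene_prog <- sample.int(n_programs, config$n_genes, replace = TRUE)
  base_expr <- stats::rlnorm(config$n_genes, log(10), 1)
  noise <- matrix(exp(stats::rnorm(config$n_genes * config$n_tissues, 0, 0.25)),
                  nrow = config$n_genes)
  expression <- programs[gene_prog, , drop = FALSE] * noise
  expression <- base_expr * expression / apply(expression, 1, max)
  dimnames(expression) <- list(gene_id, tissues)

  ## ---- GWAS leads, traits, haplotype panel ---------------------------
  trait_ids <- sprintf("EFO_%07d", seq_len(g$n_trait_vocab))
  trait_cat <- sample(efo_parent_categories, g$n_trait_vocab, replace = TRUE)
  n_pleio <- min(round(g$frac_pleiotropic_leads * config$n_gwas_leads), n_ep)
  n_bg <- config$n_gwas_leads - n_pleio

  pleio_prom <- if (n_pleio > 0) {
    ep_promoters[sort(sample.int(n_ep, n_pleio)), , drop = FALSE]
  } else ep_promoters[0, , drop = FALSE]
  # 1-based variant position inside the planted promoter
  pleio_pos <- pleio_prom$start +
    sample.int(g$promoter_window - 2L, max(n_pleio, 1), replace = TRUE)[seq_len(n_pleio)] + 1L
  nonep_first <- first_tx[setdiff(gene_id, ep_genes), , drop = FALSE]
  n_bg_prom <- min(round(0.85 * n_bg), nrow(nonep_first))
  bg_prom <- nonep_first[sort(sample.int(nrow(nonep_first), n_bg_prom)), , drop = FALSE]
  bg_prom_pos <- bg_prom$start +
    sample.int(g$promoter_window - 2L, max(n_bg_prom, 1), replace = TRUE)[seq_len(n_bg_prom)] + 1L
  n_bg_inter <- n_bg - n_bg_prom
  inter_gene <- sample.int(config$n_genes, n_bg_inter, replace = TRUE)
  inter_pos <- as.integer(gene_slot0[inter_gene] + 5000 +
                            floor(stats::runif(n_bg_inter) * (slot - 5100))) + 1L

  leads <- data.frame(
    lead_snp_id = sprintf("rs%06d", seq_len(config$n_gwas_leads)),
    chrom = c(pleio_prom$chrom, bg_prom$chrom, gene_chrom[inter_gene]),
    pos = c(pleio_pos, bg_prom_pos, inter_pos),
    pleiotropic = rep(c(TRUE, FALSE), c(n_pleio, n_bg)),
    host_promoter = c(pleio_prom$promoter_id, bg_prom$promoter_id,
                      rep(NA_character_, n_bg_inter)),
    host_gene = c(pleio_prom$gene_id, bg_prom$gene_id,
                  rep(NA_character_, n_bg_inter)),
    stringsAsFactors = FALSE
  )
  n_traits_per_lead <- ifelse(leads$pleiotropic,
                              2 + stats::rpois(config$n_gwas_leads, config$pleiotropy_boost),
                              1L)
  gwas <- do.call(rbind, lapply(seq_len(nrow(leads)), function(i) {
    tr <- sample.int(g$n_trait_vocab, n_traits_per_lead[i])
    data.frame(
      lead_snp_id = leads$lead_snp_id[i], chrom = leads$chrom[i],
      pos = leads$pos[i], trait_efo_id = trait_ids[tr],
      trait_label = sprintf("trait %d", tr), parent_category = trait_cat[tr],
      stringsAsFactors = FALSE
    )
  }))

  # block-copy haplotypes: lead + proxies copy a founder, per-site mutation
  half_block <- round(config$ld_block_bp / 2)
  site_rows <- list(); hap_cols <- list(); proxy_rows <- list()
  for (i in seq_len(nrow(leads))) {
    founder <- stats::rbinom(config$n_haplotypes, 1, stats::runif(1, 0.15, 0.5))
    flip <- function(q) {
      v <- abs(founder - stats::rbinom(config$n_haplotypes, 1, q))
      # keep sites polymorphic so r2 is defined everywhere
      if (all(v == v[1])) v[sample.int(config$n_haplotypes, 1)] <- 1 - v[1]
      v
    }
    ids <- c(leads$lead_snp_id[i],
             sprintf("%s_px%d", leads$lead_snp_id[i],
                     seq_len(g$n_proxies_high + g$n_proxies_low)))
    muts <- c(g$mut_high, rep(g$mut_high, g$n_proxies_high),
              rep(g$mut_low, g$n_proxies_low))
    offs <- c(0L, as.integer(round(stats::runif(
      g$n_proxies_high + g$n_proxies_low, -half_block, half_block))))
    pos <- pmin(pmax(leads$pos[i] + offs, 1), config$chrom_length_bp)
    cols <- vapply(muts, flip, numeric(config$n_haplotypes))
    site_rows[[i]] <- data.frame(snp_id = ids, chrom = leads$chrom[i],
                                 pos = as.integer(pos), stringsAsFactors = FALSE)
    hap_cols[[i]] <- cols
    proxy_rows[[i]] <- data.frame(lead_snp_id = leads$lead_snp_id[i],
                                  snp_id = ids[-1], stringsAsFactors = FALSE)
  }
  # rare singleton variants inside promoters (no GWAS annotation)
  rare_prom <- promoters[sample.int(nrow(promoters), g$n_rare, replace = TRUE), ]
  rare <- data.frame(
    snp_id = sprintf("rare%04d", seq_len(g$n_rare)),
    chrom = rare_prom$chrom,
    pos = rare_prom$start +
      sample.int(g$promoter_window - 2L, g$n_rare, replace = TRUE) + 1L,
    stringsAsFactors = FALSE
  )
  rare_cols <- vapply(seq_len(g$n_rare), function(i) {
    v <- numeric(config$n_haplotypes)
    v[sample.int(config$n_haplotypes, 1)] <- 1
    v
  }, numeric(config$n_haplotypes))
  sites <- rbind(do.call(rbind, site_rows), rare)
  hap <- cbind(do.call(cbind, hap_cols), rare_cols)
  colnames(hap) <- sites$snp_id
  # drop duplicated snp ids (cannot happen by construction, but keep panel sane)
  panel <- list(sites = sites, haplotypes = hap)
  proxies <- do.call(rbind, proxy_rows)
  proxies$r2 <- vapply(seq_len(nrow(proxies)), function(i) {
    compute_r2(hap, proxies$lead_snp_id[i], proxies$snp_id[i])
  }, numeric(1))

  ## ---- eQTLs, distal targets, P-P interactions -----------------------
  cis_genes_within <- function(gi, max_bp = 1e6) {
    same <- which(gene_chrom == gene_chrom[gi] &
                    abs(gene_slot0 - gene_slot0[gi]) <= max_bp - slot &
                    seq_len(config$n_genes) != gi)
    same
  }
  eqtl_rows <- list(); pp_rows <- list()
  true_distal <- list(); true_class <- character(0)
  pleio_idx <- which(leads$pleiotropic)
  class_draw <- if (length(pleio_idx) > 0) {
    sample(c("proximal", "distal", "both"), length(pleio_idx),
           replace = TRUE, prob = c(0.2, 0.3, 0.5))
  } else character(0)
  add_eqtl <- function(snp, target_gene, dist) {
    tis <- sample(tissues, sample.int(3L, 1))
    data.frame(snp_id = snp, target_gene_id = target_gene, tissue = tis,
               effect_z = round(sample(c(-1, 1), 1) * stats::runif(1, 2, 6), 2),
               tss_distance_bp = as.integer(dist), stringsAsFactors = FALSE)
  }
  for (k in seq_along(pleio_idx)) {
    i <- pleio_idx[k]
    snp <- leads$lead_snp_id[i]
    host_gene <- leads$host_gene[i]
    gi <- match(host_gene, gene_id)
    cls <- class_draw[k]
    true_class[snp] <- cls
    if (cls %in% c("proximal", "both")) {
      d <- (leads$pos[i] - 1) - first_tx[host_gene, "tss"]
      eqtl_rows[[length(eqtl_rows) + 1]] <- add_eqtl(snp, host_gene, d)
    }
    if (cls %in% c("distal", "both")) {
      cand <- cis_genes_within(gi)
      n_tg <- min(sample.int(3L, 1), length(cand))
      tg <- gene_id[cand[sample.int(length(cand), n_tg)]]
      for (tgt in tg) {
        d <- (leads$pos[i] - 1) - first_tx[tgt, "tss"]
        eqtl_rows[[length(eqtl_rows) + 1]] <- add_eqtl(snp, tgt, d)
        if (stats::runif(1) < 0.9) {  # planted 3D support for distal targets
          ep_reg <- leads$host_promoter[i]
          e <- promoters[match(ep_reg, promoters$promoter_id), ]
          p <- first_tx[tgt, ]
          pp_rows[[length(pp_rows) + 1]] <- data.frame(
            chrom_a = e$chrom, start_a = e$start, end_a = e$end,
            chrom_b = p$chrom, start_b = p$start, end_b = p$end,
            source = "planted", stringsAsFactors = FALSE
          )
        }
      }
      true_distal[[leads$host_promoter[i]]] <- tg
    }
  }
  # background eQTLs: proximal own-gene signals and unsupported distal ones
  bg_idx <- which(!leads$pleiotropic & !is.na(leads$host_gene))
  for (i in bg_idx) {
    if (stats::runif(1) < 0.6) {
      d <- (leads$pos[i] - 1) - first_tx[leads$host_gene[i], "tss"]
      eqtl_rows[[length(eqtl_rows) + 1]] <-
        add_eqtl(leads$lead_snp_id[i], leads$host_gene[i], d)
      true_class[leads$lead_snp_id[i]] <- "proximal"
    } else if (stats::runif(1) < 0.25) {
      gi <- match(leads$host_gene[i], gene_id)
      cand <- cis_genes_within(gi)
      tgt <- gene_id[cand[sample.int(length(cand), 1)]]
      d <- (leads$pos[i] - 1) - first_tx[tgt, "tss"]
      eqtl_rows[[length(eqtl_rows) + 1]] <- add_eqtl(leads$lead_snp_id[i], tgt, d)
      true_class[leads$lead_snp_id[i]] <- "distal"
    }
  }
  eqtls <- if (length(eqtl_rows) > 0) do.call(rbind, eqtl_rows) else
    data.frame(snp_id = character(), target_gene_id = character(),
               tissue = character(), effect_z = numeric(),
               tss_distance_bp = integer())
  # background P-P interactions between random promoter pairs
  n_bg_pp <- 200L
  bi <- matrix(sample.int(nrow(promoters), 2 * n_bg_pp, replace = TRUE), ncol = 2)
  pp_bg <- data.frame(
    chrom_a = promoters$chrom[bi[, 1]], start_a = promoters$start[bi[, 1]],
    end_a = promoters$end[bi[, 1]],
    chrom_b = promoters$chrom[bi[, 2]], start_b = promoters$start[bi[, 2]],
    end_b = promoters$end[bi[, 2]], source = "background",
    stringsAsFactors = FALSE
  )
  pp <- rbind(if (length(pp_rows) > 0) do.call(rbind, pp_rows) else NULL, pp_bg)

  ## ---- CRISPRi z-matrix ----------------------------------------------
  z <- matrix(stats::rnorm(config$n_genes * config$n_genes),
              nrow = config$n_genes,
              dimnames = list(first_tx$promoter_id[match(gene_id, first_tx$gene_id)],
                              gene_id))
  efficient <- stats::runif(config$n_genes) < 0.9
  z[cbind(which(efficient), which(efficient))] <- -8
  for (pid in names(true_distal)) {
    gi <- match(promoters$gene_id[match(pid, promoters$promoter_id)], gene_id)
    if (!efficient[gi]) next
    z[gi, true_distal[[pid]]] <- -5 + stats::rnorm(length(true_distal[[pid]]), 0, 0.3)
  }
  crispri <- list(
    z_matrix = z,
    promoter_info = data.frame(
      promoter_id = rownames(z), gene_id = gene_id,
      chrom = gene_chrom, tss = first_tx[gene_id, "tss"],
      stringsAsFactors = FALSE
    )
  )

  ## ---- MPRA / TF-binding skew tables ---------------------------------
  pleio_snps <- leads$lead_snp_id[leads$pleiotropic]
  other_snps <- setdiff(sites$snp_id, pleio_snps)
  mpra_snps <- sort(c(pleio_snps[stats::runif(length(pleio_snps)) < 0.9],
                      sample(other_snps, round(0.05 * length(other_snps)))))
  tfskew_snps <- sort(c(pleio_snps[stats::runif(length(pleio_snps)) < 0.9],
                        sample(other_snps, round(0.05 * length(other_snps)))))

  ## ---- feature tracks -------------------------------------------------
  planted_first <- first_tx$gene_id %in% ep_genes
  tracks <- local({
    ft <- first_tx
    np <- nrow(ft)
    p_cgi <- ifelse(planted_first, 0.7, 0.4)
    cgi_i <- which(stats::runif(np) < p_cgi)
    cgi <- data.frame(chrom = ft$chrom[cgi_i],
                      start = pmax(0L, ft$start[cgi_i] - 100L),
                      end = ft$end[cgi_i] + 100L)
    g4_n <- stats::rpois(np, ifelse(planted_first, 1.2, 0.5))
    g4_i <- rep.int(seq_len(np), g4_n)
    g4_w <- sample(20:60, length(g4_i), replace = TRUE)
    g4_s <- ft$start[g4_i] +
      floor(stats::runif(length(g4_i)) * (500 - g4_w))
    g4 <- data.frame(chrom = ft$chrom[g4_i], start = as.integer(g4_s),
                     end = as.integer(g4_s + g4_w))
    tf_n <- stats::rpois(np, ifelse(planted_first, 8, 3))
    tf_i <- rep.int(seq_len(np), tf_n)
    tf_s <- ft$start[tf_i] + floor(stats::runif(length(tf_i)) * 490)
    tfbs <- data.frame(chrom = ft$chrom[tf_i], start = as.integer(tf_s),
                       end = as.integer(tf_s + 10L),
                       family = sample(sprintf("FAM%02d", 1:20),
                                       length(tf_i), replace = TRUE),
                       score = round(stats::runif(length(tf_i), 200, 600)))
    ch_n <- stats::rpois(np, ifelse(planted_first, 6, 2))
    ch_i <- rep.int(seq_len(np), ch_n)
    ch_c <- ft$start[ch_i] + floor(stats::runif(length(ch_i)) * 500)
    chip <- data.frame(chrom = ft$chrom[ch_i],
                       start = pmax(0L, as.integer(ch_c - 100L)),
                       end = as.integer(ch_c + 100L),
                       tf = sample(sprintf("TF%03d", 1:50), length(ch_i),
                                   replace = TRUE),
                       biotype = sample(sprintf("biotype%02d", 1:18),
                                        length(ch_i), replace = TRUE))
    sense_pk <- data.frame(chrom = ft$chrom,
                           start = pmax(0L, ft$tss - 30L), end = ft$tss + 30L,
                           strand = ft$strand)
    anti_i <- which(stats::runif(np) < ifelse(planted_first, 0.7, 0.25))
    anti_pk <- data.frame(chrom = ft$chrom[anti_i],
                          start = pmax(0L, ft$tss[anti_i] - 120L),
                          end = ft$tss[anti_i] - 60L,
                          strand = ifelse(ft$strand[anti_i] == "+", "-", "+"))
    cage_peaks <- rbind(sense_pk, anti_pk)
    cage_signal <- rbind(
      data.frame(chrom = ft$chrom, start = pmax(0L, ft$tss - 50L),
                 end = ft$tss + 50L, strand = ft$strand,
                 score = round(stats::rlnorm(np, log(5), 1), 2)),
      data.frame(chrom = ft$chrom[anti_i],
                 start = pmax(0L, ft$tss[anti_i] - 150L),
                 end = ft$tss[anti_i] - 50L,
                 strand = ifelse(ft$strand[anti_i] == "+", "-", "+"),
                 score = round(stats::rlnorm(length(anti_i), log(2), 1), 2))
    )
    tile_w <- 25L
    n_tiles <- g$promoter_window %/% tile_w
    cons_off <- rep(0:(n_tiles - 1L), times = np) * tile_w
    cons_start <- ft$start[rep(seq_len(np), each = n_tiles)] + cons_off
    cons <- data.frame(
      chrom = ft$chrom[rep(seq_len(np), each = n_tiles)],
      start = as.integer(cons_start), end = as.integer(cons_start + tile_w),
      score = round(stats::rnorm(np * n_tiles,
                                 rep(ifelse(planted_first, 0.25, 0.1),
                                     each = n_tiles), 0.2), 3)
    )
    seg_w <- 5000L
    states <- do.call(rbind, lapply(chroms, function(ch) {
      s <- seq(0, config$chrom_length_bp - seg_w, by = seg_w)
      data.frame(chrom = ch, start = as.integer(s),
                 end = as.integer(pmin(s + seg_w, config$chrom_length_bp)),
                 state = sample(sprintf("state%d", 1:5), length(s),
                                replace = TRUE, prob = c(0.1, 0.15, 0.2, 0.25, 0.3)))
    }))
    list(cgi = cgi, g4 = g4, tfbs = tfbs, chip = chip,
         cage_peaks = cage_peaks, cage_signal = cage_signal,
         conservation = cons, states = states)
  })

  truth <- list(
    true_epromoter_promoter_ids = true_epromoter_ids,
    true_epromoter_genes = ep_genes,
    true_distal_targets = true_distal,
    true_pleiotropic_snp_ids = pleio_snps,
    planted_trait_counts = stats::setNames(
      n_traits_per_lead[leads$pleiotropic], pleio_snps),
    true_eqtl_classes = true_class,
    ld_proxies = proxies
  )
  structure(list(
    config = config, chrom_sizes = chrom_sizes, annotation = annotation,
    promoters = promoters, regions = regions, fragments = fragments,
    expression = expression, tissues = tissues, panel = panel,
    gwas = gwas, leads = leads, eqtls = eqtls, pp_interactions = pp,
    crispri = crispri, mpra_snps = mpra_snps, tfskew_snps = tfskew_snps,
    tracks = tracks, truth = truth
  ), class = "synthetic_world")
}
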