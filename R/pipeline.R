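# End-to-end orchestration: STARR activity -> Epromoter calling -> control
# matching -> variant pleiotropy -> target linking -> feature statistics,
# with a demo mode measuring recovery against planted truth.

#' Pipeline parameter defaults
#'
#' All method thresholds surfaced in one place: promoter window 500 bp,
#' input-library FPKM filter 1, overlap fraction 0.5 (either-feature mode),
#' LD window 1 Mb with r2 > 0.8, proximal/distal eQTL boundary 2 kb,
#' CRISPRi own-gene rank cut 2 and regulated-set size 30, cis window 1 Mb,
#' fragment extension 314 nt, common-variant MAF cut 0.01.
#'
#' @param ... overrides for any default.
#' @return Named list of parameters.
#' @export
pipeline_params <- function(...) {
  p <- list(
    promoter_window = 500L, min_input_fpkm = 1, overlap_frac = 0.5,
    either = TRUE, ld_window_kb = 1000, r2_min = 0.8, proximal_bp = 2000,
    crispri_top_inactivated = 2L, crispri_top_regulated = 30L,
    cis_window_bp = 1e6, fragment_length = 314L, maf_common = 0.01
  )
  dots <- list(...)
  stopifnot(all(names(dots) %in% names(p)))
  p[names(dots)] <- dots
  stopifnot(all(vapply(p[c("promoter_window", "min_input_fpkm", "overlap_frac",
                           "ld_window_kb", "r2_min", "proximal_bp",
                           "crispri_top_inactivated", "crispri_top_regulated",
                           "cis_window_bp", "fragment_length", "maf_common")],
                       function(x) x > 0, logical(1))))
  p
}

#' Run the full Epromoter pipeline on a synthetic world
#'
#' Stages: (1) fragment extension, FPKM, fold-change and knee thresholding
#' per replicate, replicate merging; (2) promoter definition and Epromoter
#' calling/merging; (3) tau and expression-matched control selection;
#' (4) LD expansion, promoter overlap, pleiotropy counts and the
#' Epromoter-vs-control trait comparison; (5) eQTL classification, P-P
#' consistency, CRISPRi screen and evidence integration; (6) feature
#' statistics. Returns all stage outputs plus a summary and, when the world
#' carries planted truth, a recovery report.
#'
#' @param world a `synthetic_world` from [generate_world()].
#' @param params a [pipeline_params()] list.
#' @return A list of class `epromoter_report` with elements `stages`,
#'   `summary`, `recovery` and `timings` (seconds per stage).
#' @export
run_pipeline <- function(world, params = pipeline_params()) {
  stopifnot(inherits(world, "synthetic_world"))
  stages <- list(); timings <- c()
  tick <- function() proc.time()[["elapsed"]]

  ## stage 1: STARR activity ------------------------------------------
  t0 <- tick()
  regions <- world$regions
  calls <- lapply(seq_len(world$config$n_replicates), function(r) {
    inp <- extend_fragments(world$fragments$input[[r]],
                            params$fragment_length, world$chrom_sizes)
    out <- extend_fragments(world$fragments$output[[r]],
                            params$fragment_length, world$chrom_sizes)
    call_active_regions(compute_fpkm(regions, inp),
                        compute_fpkm(regions, out),
                        min_input_fpkm = params$min_input_fpkm,
                        regions = regions)
  })
  # common peaks: regions active in every replicate, activity averaged
  rep_actives <- lapply(calls, function(x) x[x$active, , drop = FALSE])
  merged_calls <- suppressWarnings(
    merge_replicate_calls(rep_actives, mode = "key", rethreshold = FALSE))
  active <- merged_calls[merged_calls$active, , drop = FALSE]
  stages$starr <- list(replicates = calls, merged = merged_calls,
                       thresholds = vapply(calls, attr, numeric(1),
                                           "threshold"))
  timings["starr"] <- tick() - t0

  ## stage 2: Epromoter calling ---------------------------------------
  t0 <- tick()
  promoters <- define_promoters(world$annotation,
                                window = params$promoter_window,
                                chrom_sizes = world$chrom_sizes)
  flagged <- call_epromoters(promoters, active,
                             min_frac = params$overlap_frac,
                             either = params$either)
  epset <- merge_epromoters(flagged)
  ep_genes <- sort(unique(epset$members$gene_id))
  stages$epromoters <- list(promoters = flagged, set = epset,
                            genes = ep_genes)
  timings["epromoters"] <- tick() - t0

  ## stage 3: tau and control matching --------------------------------
  t0 <- tick()
  tau <- tau_index(world$expression)
  controls <- if (length(ep_genes) > 0) {
    match_controls(world$expression, ep_genes)
  } else {
    data.frame(epromoter_gene = character(), control_gene = character(),
               distance = numeric())
  }
  first_prom <- promoters[!duplicated(promoters$gene_id), , drop = FALSE]
  ctrl_prom <- first_prom[match(controls$control_gene, first_prom$gene_id), , drop = FALSE]
  stages$controls <- list(tau = tau, assignment = controls,
                          promoters = ctrl_prom)
  timings["controls"] <- tick() - t0

  ## stage 4: variant pleiotropy --------------------------------------
  t0 <- tick()
  variants <- expand_ld(world$gwas, world$panel,
                        window_kb = params$ld_window_kb,
                        r2_min = params$r2_min,
                        maf_common = params$maf_common)
  ep_regions <- epset$regions
  ep_mem <- overlap_variants(variants, epset)
  ctrl_regions <- ctrl_prom
  ctrl_mem <- overlap_variants(variants, ctrl_regions)
  ep_counts <- pleiotropy_counts(ep_mem, variants)
  ctrl_counts <- pleiotropy_counts(ctrl_mem, variants)
  wilcox <- if (nrow(ep_counts$per_region) > 0 && nrow(ctrl_counts$per_region) > 0) {
    suppressWarnings(stats::wilcox.test(ep_counts$per_region$n_traits,
                                        ctrl_counts$per_region$n_traits,
                                        alternative = "greater"))
  } else NULL
  enrich <- enrichment_tests(ep_mem$snp_id, ctrl_mem$snp_id, variants,
                             by = "categories")
  stages$pleiotropy <- list(
    variants = variants, ep_memberships = ep_mem, ctrl_memberships = ctrl_mem,
    ep_counts = ep_counts, ctrl_counts = ctrl_counts,
    wilcox_traits_per_promoter = wilcox, category_enrichment = enrich
  )
  timings["pleiotropy"] <- tick() - t0

  ## stage 5: target linking ------------------------------------------
  t0 <- tick()
  eq <- classify_eqtls(world$eqtls, proximal_bp = params$proximal_bp)
  ep_snps <- unique(ep_mem$snp_id)
  distal_pairs <- eq$merged[eq$merged$distal & eq$merged$snp_id %in% ep_snps,
                            c("snp_id", "target_gene_id"), drop = FALSE]
  snp_regions <- merge(ep_mem, ep_regions, by.x = "region_id",
                       by.y = "merged_id")[, c("snp_id", "chrom", "start", "end")]
  ppf <- pp_consistency(snp_regions, distal_pairs, world$pp_interactions,
                        promoters)
  cr <- crispri_screen(
    world$crispri$z_matrix, world$crispri$promoter_info,
    data.frame(gene_id = world$crispri$promoter_info$gene_id,
               chrom = world$crispri$promoter_info$chrom,
               tss = world$crispri$promoter_info$tss),
    sets = list(epromoters = world$crispri$promoter_info$promoter_id[
                  world$crispri$promoter_info$gene_id %in% ep_genes],
                controls = world$crispri$promoter_info$promoter_id[
                  world$crispri$promoter_info$gene_id %in% controls$control_gene]),
    top_inactivated = params$crispri_top_inactivated,
    top_regulated = params$crispri_top_regulated,
    cis_window_bp = params$cis_window_bp
  )
  snp_traits <- ep_counts$per_snp[, c("snp_id", "n_traits")]
  evidence <- integrate_evidence(snp_traits, eq$classes, ppf,
                                 world$mpra_snps, world$tfskew_snps)
  stages$targets <- list(eqtl = eq, pp = ppf, crispri = cr,
                         evidence = evidence)
  timings["targets"] <- tick() - t0

  ## stage 6: feature statistics --------------------------------------
  t0 <- tick()
  feat_regions <- ep_regions
  feat_regions$region_id <- feat_regions$merged_id
  ctrl_feat <- ctrl_prom
  ctrl_feat$region_id <- ctrl_prom$promoter_id
  features <- list(
    ep = list(
      cgi = region_feature_stats(feat_regions, world$tracks$cgi, "cgi"),
      g4 = region_feature_stats(feat_regions, world$tracks$g4, "g4"),
      tfbs = tfbs_density_diversity(feat_regions, world$tracks$tfbs)
    ),
    ctrl = list(
      cgi = region_feature_stats(ctrl_feat, world$tracks$cgi, "cgi"),
      g4 = region_feature_stats(ctrl_feat, world$tracks$g4, "g4"),
      tfbs = tfbs_density_diversity(ctrl_feat, world$tracks$tfbs)
    ),
    states = if (nrow(feat_regions) > 0) state_fold_enrichment(
      feat_regions, world$tracks$states,
      sum(world$chrom_sizes)) else NULL
  )
  stages$features <- features
  timings["features"] <- tick() - t0

  ## summary & recovery ------------------------------------------------
  truth <- world$truth
  called <- flagged$promoter_id[flagged$is_epromoter]
  planted <- truth$true_epromoter_promoter_ids
  tp <- length(intersect(called, planted))
  recovery <- list(
    n_called = length(called), n_planted = length(planted),
    sensitivity = if (length(planted) > 0) tp / length(planted) else NA_real_,
    precision = if (length(called) > 0) tp / length(called) else NA_real_,
    wilcox_p = if (!is.null(wilcox)) wilcox$p.value else NA_real_,
    wilcox_direction_positive = if (nrow(ep_counts$per_region) > 0 &&
                                    nrow(ctrl_counts$per_region) > 0) {
      mean(ep_counts$per_region$n_traits) > mean(ctrl_counts$per_region$n_traits)
    } else NA
  )
  summary <- list(
    n_regions_tested = nrow(calls[[1]]), n_active = nrow(active),
    activity_thresholds = vapply(calls, attr, numeric(1), "threshold"),
    n_epromoters = nrow(epset$regions),
    n_epromoter_genes = length(ep_genes),
    n_controls = nrow(controls),
    n_gwas_snps = nrow(variants),
    n_ep_snps = length(unique(ep_mem$snp_id)),
    n_ep_snp_promoters = length(unique(ep_mem$region_id)),
    n_final_evidence_snps = nrow(evidence$final),
    trait_bins = evidence$summary,
    seed = world$config$seed
  )
  structure(list(stages = stages, summary = summary, recovery = recovery,
                 timings = timings),
            class = "epromoter_report")
}

#' Demo: run the pipeline on generated worlds and report recovery
#'
#' Generates `n_seeds` worlds (seeds `seed, seed + 1, ...`), runs the full
#' pipeline on each, and aggregates planted-Epromoter sensitivity/precision
#' and the Epromoter-vs-control traits-per-promoter Wilcoxon comparison.
#'
#' @param seed base seed.
#' @param n_seeds number of worlds (default 10).
#' @param config_args named list of [synthetic_config()] overrides.
#' @param params a [pipeline_params()] list.
#' @param outdir optional directory; if given, writes `demo_summary.json`.
#' @return List: `per_seed` data.frame and `aggregate` list (mean
#'   sensitivity/precision, number of seeds with a directionally positive
#'   Wilcoxon at p < 0.05).
#' @export
eprom_demo <- function(seed = 1L, n_seeds = 10L, config_args = list(),
                       params = pipeline_params(), outdir = NULL) {
  per_seed <- do.call(rbind, lapply(seq_len(n_seeds) - 1L, function(i) {
    cfg <- do.call(synthetic_config, c(list(seed = seed + i), config_args))
    rpt <- run_pipeline(generate_world(cfg), params)
    data.frame(
      seed = seed + i,
      n_epromoters = rpt$summary$n_epromoters,
      sensitivity = rpt$recovery$sensitivity,
      precision = rpt$recovery$precision,
      wilcox_p = rpt$recovery$wilcox_p,
      direction_positive = isTRUE(rpt$recovery$wilcox_direction_positive),
      n_final_evidence_snps = rpt$summary$n_final_evidence_snps
    )
  }))
  aggregate <- list(
    mean_sensitivity = mean(per_seed$sensitivity, na.rm = TRUE),
    mean_precision = mean(per_seed$precision, na.rm = TRUE),
    n_seeds = n_seeds,
    n_significant_positive = sum(per_seed$direction_positive &
                                   per_seed$wilcox_p < 0.05, na.rm = TRUE)
  )
  res <- list(per_seed = per_seed, aggregate = aggregate)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(res, file.path(outdir, "demo_summary.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows",
                         pretty = TRUE)
  }
  res
}
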