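# r2, LD expansion, promoter overlap, pleiotropy counting, enrichment.

# a panel from explicit two-site haplotype counts (AB, Ab, aB, ab)
panel_from_counts <- function(ab, aB_, bA_, ab0) {
  a <- c(rep(1, ab), rep(1, aB_), rep(0, bA_), rep(0, ab0))
  b <- c(rep(1, ab), rep(0, aB_), rep(1, bA_), rep(0, ab0))
  m <- cbind(s1 = a, s2 = b)
  m
}

test_that("r2 from haplotype frequencies matches hand-computed cases", {
  m <- panel_from_counts(3, 1, 1, 3)
  expect_equal(compute_r2(m, "s1", "s2"), 0.25)  # (3/8 - 1/4)^2 / (1/4 * 1/4)
  expect_equal(compute_r2(panel_from_counts(2, 2, 2, 2), "s1", "s2"), 0)
  ident <- cbind(s1 = rep(c(1, 0), 5), s2 = rep(c(1, 0), 5))
  expect_equal(compute_r2(ident, "s1", "s2"), 1)
  mono <- cbind(s1 = rep(1, 8), s2 = rep(c(0, 1), 4))
  expect_error(compute_r2(mono, "s1", "s2"), "monomorphic")
  # symmetric, and equal to the squared Pearson correlation oracle
  set.seed(3)
  for (i in 1:50) {
    n <- sample(c(8, 12, 16), 1)
    m <- cbind(s1 = rbinom(n, 1, 0.5), s2 = rbinom(n, 1, 0.5))
    if (length(unique(m[, 1])) < 2 || length(unique(m[, 2])) < 2) next
    expect_equal(compute_r2(m, "s1", "s2"), compute_r2(m, "s2", "s1"))
    expect_equal(compute_r2(m, "s1", "s2"), oracle_r2(m[, 1], m[, 2]))
  }
})

make_panel <- function(haps, pos, chrom = "chr1") {
  list(sites = data.frame(snp_id = colnames(haps), chrom = chrom, pos = pos),
       haplotypes = haps)
}

test_that("LD expansion inherits traits through r2 > threshold within the window", {
  f <- rep(c(1, 0), each = 10)
  haps <- cbind(lead1 = f, px = f, far = f,
                weak = c(f[1:6], 1 - f[7:14], f[15:20]),
                lead2 = rep(c(1, 0), 10))
  panel <- make_panel(haps, pos = c(5e5, 5e5 + 1000, 5e5 + 2e6, 5e5 + 2000, 5e5 + 500))
  leads <- data.frame(
    lead_snp_id = c("lead1", "lead1", "lead2", "ghost"),
    trait_efo_id = c("T1", "T2", "T3", "T9"),
    trait_label = c("t1", "t2", "t3", "t9"),
    parent_category = c("Cancer", "Cancer", "Other trait", "Other trait"))
  expect_message(res <- expand_ld(leads, panel), "absent from the panel")
  # perfect proxy inside the window inherits the lead's traits
  expect_equal(res$traits[[match("px", res$snp_id)]], c("T1", "T2"))
  # identical haplotypes but 2 Mb away: outside the 1 Mb window
  expect_false("far" %in% res$snp_id)
  # r2 below the strict threshold: excluded
  expect_false("weak" %in% res$snp_id)
  # the boundary is strict: a proxy at exactly r2_min is excluded
  r2_weak <- compute_r2(haps, "lead1", "weak")
  res_b <- expand_ld(leads[1:3, ], panel, r2_min = 1)  # px has r2 exactly 1
  expect_false("px" %in% res_b$snp_id)
  expect_true(r2_weak < 0.8)
  # leads are annotated even without proxies
  res2 <- expand_ld(leads[1:3, ], panel, r2_min = 0.5)
  expect_true("lead2" %in% res2$snp_id)
})

test_that("a variant proxying two leads unions their trait sets", {
  u <- rep(c(1, 0), each = 8)
  haps <- cbind(lu1 = u, lu2 = u, pu = u)
  panel <- make_panel(haps, pos = c(1000L, 3000L, 2000L))
  leads <- data.frame(lead_snp_id = c("lu1", "lu2"),
                      trait_efo_id = c("TA", "TB"),
                      trait_label = c("ta", "tb"),
                      parent_category = c("Cancer", "Other trait"))
  res <- expand_ld(leads, panel)
  expect_equal(res$traits[[match("pu", res$snp_id)]], c("TA", "TB"))
  expect_equal(res$categories[[match("pu", res$snp_id)]],
               c("Cancer", "Other trait"))
})

test_that("variant-region membership is half-open", {
  regions <- data.frame(region_id = c("rA", "rB"), chrom = "chr1",
                        start = c(100L, 5000L), end = c(600L, 5500L))
  variants <- data.frame(snp_id = c("v_start", "v_end", "v_in1", "v_in2", "v_out"),
                         chrom = "chr1",
                         pos = c(101L, 601L, 300L, 400L, 4999L))
  mem <- overlap_variants(variants, regions)
  expect_setequal(mem$snp_id[mem$region_id == "rA"],
                  c("v_start", "v_in1", "v_in2"))  # start base in, end base out
  expect_equal(sum(mem$region_id == "rB"), 0)
})

test_that("trait counts are non-redundant unions per SNP and region", {
  variants <- data.frame(snp_id = c("v1", "v2", "v3"), chrom = "chr1",
                         pos = c(1L, 2L, 3L), maf = 0.1, is_common = TRUE)
  variants$traits <- list(c("T1", "T2", "T1"), c("T2", "T3"), "T4")
  variants$categories <- list("C1", c("C1", "C2"), "C2")
  mem <- data.frame(region_id = c("p1", "p1", "p2"),
                    snp_id = c("v1", "v2", "v3"))
  pc <- pleiotropy_counts(mem, variants)
  expect_equal(pc$per_snp$n_traits[pc$per_snp$snp_id == "v1"], 2)
  p1 <- pc$per_region[pc$per_region$region_id == "p1", ]
  expect_equal(p1$n_traits, 3)   # union of {T1,T2} and {T2,T3}
  expect_true(p1$pleiotropic)
  expect_false(pc$per_region$pleiotropic[pc$per_region$region_id == "p2"])
  # region count bounded by max and sum of member SNP counts
  snp_counts <- pc$per_snp$n_traits[pc$per_snp$snp_id %in% c("v1", "v2")]
  expect_gte(p1$n_traits, max(snp_counts))
  expect_lte(p1$n_traits, sum(snp_counts))
})

test_that("hypergeometric enrichment matches exact enumeration", {
  # population 10 GWAS-SNPs, 5 carrying the trait, 4 drawn, all 4 carriers
  bg <- data.frame(snp_id = sprintf("v%02d", 1:10), chrom = "chr1",
                   pos = 1:10, maf = 0.2, is_common = TRUE)
  bg$traits <- c(rep(list("TT"), 5), rep(list("other"), 5))
  bg$categories <- bg$traits
  res <- enrichment_tests(sprintf("v%02d", 1:4), sprintf("v%02d", 6:9), bg)
  tt <- res[res$trait == "TT", ]
  expect_equal(tt$p_hyper_a, 5 / 210)  # C(5,4) C(5,0) / C(10,4)
  expect_equal(tt$p_hyper_a, oracle_hyper_upper(4, 5, 10, 4))
  expect_equal(tt$p_hyper_b, 1)        # observing 0 is certain or better
  # identical sets: chi-squared statistic 0, p = 1
  res_id <- enrichment_tests(sprintf("v%02d", 1:4), sprintf("v%02d", 1:4), bg)
  expect_equal(res_id$chisq[res_id$trait == "TT"], 0)
  expect_equal(res_id$p_chisq[res_id$trait == "TT"], 1)
  # random agreement with the enumeration oracle
  set.seed(9)
  for (i in 1:50) {
    N <- sample(5:20, 1); K <- sample.int(N - 1, 1)
    n <- sample.int(N, 1); k <- sample(0:min(K, n), 1)
    expect_equal(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 oracle_hyper_upper(k, K, N, n))
  }
})

test_that("planted LD proxies and MAF classes verify against the panel", {
  # 240 haplotypes: a singleton carrier sits below the 1% MAF boundary
  w <- tiny_world(seed = 21, n_haplotypes = 240L)
  pr <- w$truth$ld_proxies
  high <- pr[pr$r2 > 0.8, ]
  expect_gt(nrow(high), 0)
  for (i in sample(nrow(high), min(25, nrow(high)))) {
    expect_equal(compute_r2(w$panel$haplotypes, high$lead_snp_id[i],
                            high$snp_id[i]),
                 oracle_r2(w$panel$haplotypes[, high$lead_snp_id[i]],
                           w$panel$haplotypes[, high$snp_id[i]]))
    expect_gt(high$r2[i], 0.8)
  }
  freqs <- colMeans(w$panel$haplotypes)
  maf <- pmin(freqs, 1 - freqs)
  rare <- grepl("^rare", w$panel$sites$snp_id)
  expect_true(all(maf[rare] < 0.01))
  expect_true(all(maf[!rare] >= 0.01))
})

test_that("Epromoter SNPs carry more traits than control SNPs on planted worlds", {
  hits <- 0
  for (s in 1:4) {
    w <- tiny_world(seed = 30 + s, n_gwas_leads = 120L)
    variants <- expand_ld(w$gwas, w$panel)
    truth_ids <- w$truth$true_epromoter_promoter_ids
    ep_reg <- w$promoters[w$promoters$promoter_id %in% truth_ids, ]
    ep_reg$region_id <- ep_reg$promoter_id
    ctl <- match_controls(w$expression, w$truth$true_epromoter_genes)
    first <- w$promoters[!duplicated(w$promoters$gene_id), ]
    ct_reg <- first[first$gene_id %in% ctl$control_gene, ]
    ct_reg$region_id <- ct_reg$promoter_id
    ep_c <- pleiotropy_counts(overlap_variants(variants, ep_reg), variants)
    ct_c <- pleiotropy_counts(overlap_variants(variants, ct_reg), variants)
    p <- suppressWarnings(
      stats::wilcox.test(ep_c$per_region$n_traits, ct_c$per_region$n_traits,
                         alternative = "greater"))$p.value
    hits <- hits + (p < 0.05)
  }
  expect_gte(hits, 3)
})
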