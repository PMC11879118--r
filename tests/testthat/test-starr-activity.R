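# STARR-seq activity quantification: extension, FPKM, knee thresholding,
# replicate merging, allelic counts.

chrom10k <- c(chrA = 10000L)

test_that("fragments extend from the 5' start and clip at chromosome bounds", {
  fr <- data.frame(chrom = "chrA", start = c(1000L, 2000L, 9900L),
                   end = c(1050L, 2314L, 9950L),
                   strand = c("+", "+", "+"))
  ext <- extend_fragments(fr, 314L, chrom10k)
  expect_equal(ext$start, c(1000L, 2000L, 9900L))
  expect_equal(ext$end, c(1314L, 2314L, 10000L))  # last one clipped to 100 nt
  # minus-strand reads extend from their 3' coordinate leftwards
  mfr <- data.frame(chrom = "chrA", start = 5000L, end = 5050L, strand = "-")
  mext <- extend_fragments(mfr, 314L, chrom10k)
  expect_equal(c(mext$start, mext$end), c(5050L - 314L, 5050L))
  expect_error(
    extend_fragments(data.frame(chrom = "chrZ", start = 1L, end = 50L),
                     314L, chrom10k),
    "unknown chromosome")
})

test_that("FPKM follows count / (kb x million mapped) with >=1 bp membership", {
  regions <- data.frame(region_id = c("r1", "r2", "r3"), chrom = "chrA",
                        start = c(1000L, 3000L, 5000L),
                        end = c(1500L, 3700L, 5500L))
  frags <- data.frame(chrom = "chrA",
                      start = c(rep(1100L, 10), rep(3100L, 7)),
                      end = c(rep(1200L, 10), rep(3200L, 7)))
  fs <- fragment_set(frags, "input", total_mapped = 1e6)
  expect_equal(unname(compute_fpkm(regions, fs)[c("r1", "r3")]), c(20, 0))
  fs2 <- fragment_set(frags, "input", total_mapped = 2e6)
  expect_equal(unname(compute_fpkm(regions, fs2)[["r2"]]), 7 / (0.7 * 2))
  # scale equivariance: duplicating every fragment and the total changes nothing
  fs_dbl <- fragment_set(rbind(frags, frags), "input", total_mapped = 2e6)
  expect_equal(compute_fpkm(regions, fs_dbl), compute_fpkm(regions, fs))
  bad <- data.frame(region_id = "z", chrom = "chrA", start = 10L, end = 10L)
  expect_error(compute_fpkm(bad, fs), "zero-length")
})

test_that("knee point matches exhaustive max-distance enumeration", {
  # two-plateau curve: knee at the first point of the lower plateau, which
  # makes strict-greater membership select exactly the upper plateau
  v <- c(10, 9, 8, 1.05, 1.0, 0.95, 0.9)
  expect_equal(find_inflection_point(v), 1.05)
  expect_equal(oracle_knee(v), 1.05)
  v2 <- c(100, 90, 80, 70, 5, 4, 3, 2, 1)
  expect_equal(find_inflection_point(v2), 5)   # knee at the 70 -> 5 drop
  expect_equal(oracle_knee(v2), 5)
  expect_equal(find_inflection_point(c(5, 5, 5, 5)), 5)  # flat curve
  expect_error(find_inflection_point(c(1, 2, 3)), "descending")
  expect_error(find_inflection_point(c(2, 1)))
  set.seed(42)
  for (i in 1:200) {
    v <- random_descending(sample(3:12, 1))
    expect_equal(find_inflection_point(v), oracle_knee(v))
  }
})

test_that("active calls drop low-input regions and use strict-greater membership", {
  fc <- c(10, 9, 8, 1.05, 1.0, 0.95, 0.9)
  inp <- stats::setNames(rep(2, 7), paste0("r", 1:7))
  out <- stats::setNames(fc * 2, paste0("r", 1:7))
  calls <- call_active_regions(inp, out)
  expect_equal(calls$region_id[calls$active], c("r1", "r2", "r3"))
  expect_equal(attr(calls, "threshold"), 1.05)
  # an input FPKM below 1 removes the region no matter how active it looks
  inp2 <- inp; inp2["r1"] <- 0.5
  calls2 <- call_active_regions(inp2, out)
  expect_false("r1" %in% calls2$region_id)
  # flat fold-changes: threshold equals the common value, nothing above it
  flat <- call_active_regions(stats::setNames(rep(2, 4), paste0("r", 1:4)),
                              stats::setNames(rep(6, 4), paste0("r", 1:4)))
  expect_equal(sum(flat$active), 0)
  expect_error(call_active_regions(inp[1:2], out[1:2]), "fewer than 3")
})

test_that("rescaling all fold-changes rescales the threshold, not the call set", {
  set.seed(7)
  fc <- sort(c(runif(5, 5, 9), runif(20, 0.5, 2)), decreasing = TRUE)
  ids <- paste0("r", seq_along(fc))
  inp <- stats::setNames(rep(1, length(fc)), ids)
  base <- call_active_regions(inp, stats::setNames(fc, ids))
  for (c_mult in c(0.1, 3, 42)) {
    scaled <- call_active_regions(inp, stats::setNames(fc * c_mult, ids))
    expect_equal(attr(scaled, "threshold"),
                 attr(base, "threshold") * c_mult, tolerance = 1e-12)
    expect_equal(scaled$region_id[scaled$active],
                 base$region_id[base$active])
  }
})

test_that("replicate merging keeps common regions and averages activity", {
  mk <- function(ids, fc) {
    inp <- stats::setNames(rep(2, length(ids)), ids)
    call_active_regions(inp, stats::setNames(fc * 2, ids))
  }
  r1 <- mk(paste0("r", 1:7), c(10, 9, 8, 1.05, 1.0, 0.95, 0.9))
  # identical replicates: idempotent
  m <- merge_replicate_calls(list(r1, r1))
  expect_equal(m$region_id[m$active], r1$region_id[r1$active])
  expect_equal(m$fold_change, r1$fold_change)
  # averaged activity: 4 and 6 -> 5
  r2 <- mk(paste0("r", 1:7), c(10, 9, 8, 1.05, 1.0, 0.95, 0.9))
  r2$fold_change[r2$region_id == "r1"] <- 4
  r1b <- r1; r1b$fold_change[r1b$region_id == "r1"] <- 6
  m2 <- merge_replicate_calls(list(r1b, r2))
  expect_equal(m2$fold_change[m2$region_id == "r1"], 5)
  # region present in one replicate only is excluded from the common set
  r_small <- mk(paste0("r", 2:7), c(9, 8, 1.05, 1.0, 0.95, 0.9))
  m3 <- merge_replicate_calls(list(r1, r_small))
  expect_false("r1" %in% m3$region_id)
  # empty intersection warns and returns an empty table
  r_other <- mk(paste0("q", 1:4), c(5, 4, 1, 0.9))
  expect_warning(m4 <- merge_replicate_calls(list(r1, r_other)),
                 "no regions common")
  expect_equal(nrow(m4), 0)
  # rethreshold = FALSE marks every common region active (common-peak mode)
  m5 <- merge_replicate_calls(list(r1[r1$active, ], r2[r2$active, ]),
                              rethreshold = FALSE)
  expect_true(all(m5$active))
})

test_that("allelic counts average replicates and normalise to no-stimulation", {
  mk_fs <- function(n_c, n_t, rep) {
    fr <- data.frame(chrom = "chrA",
                     start = rep(900L, n_c + n_t), end = rep(1214L, n_c + n_t),
                     allele = rep(c("C", "T"), c(n_c, n_t)))
    fragment_set(fr, "output", replicate = rep)
  }
  snp <- list(chrom = "chrA", pos = 1000L)
  tab <- allelic_read_counts(
    list(NS = list(mk_fs(10, 5, 1), mk_fs(20, 5, 2)),
         IFNa = list(mk_fs(30, 5, 1), mk_fs(30, 5, 2))),
    snp, reference_condition = "NS")
  c_ns <- tab[tab$condition == "NS" & tab$allele == "C", ]
  c_if <- tab[tab$condition == "IFNa" & tab$allele == "C", ]
  expect_equal(c_ns$mean_count, 15)      # (10 + 20) / 2
  expect_equal(c_ns$normalized, 1)       # baseline is 1 by construction
  expect_equal(c_if$normalized, 2)       # 30 / 15
  # allele absent everywhere: missing normalised values, no crash
  tab0 <- allelic_read_counts(
    list(NS = list(mk_fs(10, 0, 1)), IFNa = list(mk_fs(12, 0, 1))),
    list(chrom = "chrA", pos = 5000L))  # position nothing overlaps
  expect_true(all(is.na(tab0$normalized)))
})
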