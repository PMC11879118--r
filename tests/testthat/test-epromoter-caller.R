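# Promoter definition, either-fraction Epromoter calling, >=1-nt merging,
# sharing and the distal-enhancer set.

test_that("promoters are the 500 bp upstream of the TSS, strand-aware", {
  ann <- data.frame(gene_id = c("g1", "g2", "g3"),
                    transcript_id = c("g1.t1", "g2.t1", "g3.t1"),
                    chrom = "chr1", strand = c("+", "-", "+"),
                    tss = c(10000L, 10000L, 200L))
  pr <- define_promoters(ann)
  g1 <- pr[pr$gene_id == "g1", ]
  g2 <- pr[pr$gene_id == "g2", ]
  g3 <- pr[pr$gene_id == "g3", ]
  expect_equal(c(g1$start, g1$end), c(9500L, 10000L))
  expect_equal(c(g2$start, g2$end), c(10000L, 10500L))
  expect_equal(c(g3$start, g3$end), c(0L, 200L))  # clipped at the boundary
  # duplicate (region, gene) records collapse to one promoter
  ann_dup <- rbind(ann, transform(ann[1, ], transcript_id = "g1.t2"))
  expect_equal(nrow(define_promoters(ann_dup)), 3)
  ann_bad <- transform(ann, strand = c("+", NA, "+"))
  expect_error(define_promoters(ann_bad), "strand")
})

test_that("the either-fraction rule flags on >=50% of promoter OR enhancer", {
  pr <- define_promoters(data.frame(
    gene_id = "g1", transcript_id = "g1.t1", chrom = "chr1",
    strand = "+", tss = 10000L))  # promoter [9500, 10000)
  # 250 of the 500-bp promoter covered: flagged
  e1 <- data.frame(chrom = "chr1", start = 9750L, end = 10600L)
  expect_true(call_epromoters(pr, e1)$is_epromoter)
  # 150 bp of a 200-bp enhancer (75% of the enhancer): flagged
  e2 <- data.frame(chrom = "chr1", start = 9400L, end = 9600L)
  expect_true(call_epromoters(pr, e2)$is_epromoter)
  # 100 bp of 500-bp promoter and 300-bp enhancer (20% / 33%): not flagged
  e3 <- data.frame(chrom = "chr1", start = 9300L, end = 9600L)
  expect_false(call_epromoters(pr, e3)$is_epromoter)
  # without either-mode, the enhancer-fraction path is off
  expect_false(call_epromoters(pr, e2, either = FALSE)$is_epromoter)
  expect_false(call_epromoters(pr, pr[0, c("chrom", "start", "end")])$is_epromoter)
})

test_that("adding enhancers never unflags a promoter", {
  set.seed(11)
  ann <- data.frame(gene_id = sprintf("g%02d", 1:20),
                    transcript_id = sprintf("g%02d.t1", 1:20),
                    chrom = "chr1", strand = "+",
                    tss = sort(sample(5000:100000, 20)))
  pr <- define_promoters(ann)
  enh <- data.frame(chrom = "chr1",
                    start = sample(4000:100000, 30))
  enh$end <- enh$start + sample(100:800, 30, replace = TRUE)
  for (k in c(5, 15, 30)) {
    before <- call_epromoters(pr, enh[seq_len(k - 4), , drop = FALSE])$is_epromoter
    after <- call_epromoters(pr, enh[seq_len(k), , drop = FALSE])$is_epromoter
    expect_true(all(after[before]))
  }
})

test_that("flagged regions merge single-linkage on >=1 nt overlap", {
  mk <- function(starts, ends) {
    data.frame(promoter_id = sprintf("p%d", seq_along(starts)),
               gene_id = sprintf("g%d", seq_along(starts)), chrom = "chr1",
               start = starts, end = ends, is_epromoter = TRUE)
  }
  m <- merge_epromoters(mk(c(100L, 550L), c(600L, 1050L)))
  expect_equal(c(m$regions$start, m$regions$end), c(100L, 1050L))
  expect_equal(sort(m$members$promoter_id), c("p1", "p2"))
  # disjoint (and merely abutting) regions stay separate
  m2 <- merge_epromoters(mk(c(100L, 600L), c(600L, 1100L)))
  expect_equal(nrow(m2$regions), 2)
  # transitive chain A-B, B-C merges all three
  m3 <- merge_epromoters(mk(c(100L, 500L, 900L), c(600L, 1000L, 1400L)))
  expect_equal(nrow(m3$regions), 1)
  expect_equal(m3$regions$n_members, 3)
  # idempotence: merging the merged regions changes nothing
  rg <- m3$regions
  again <- merge_epromoters(data.frame(
    promoter_id = rg$merged_id, gene_id = rg$merged_id, chrom = rg$chrom,
    start = rg$start, end = rg$end, is_epromoter = TRUE))
  expect_equal(again$regions[, c("chrom", "start", "end")],
               rg[, c("chrom", "start", "end")])
  empty <- mk(100L, 600L)[0, , drop = FALSE]
  expect_equal(nrow(merge_epromoters(empty)$regions), 0)
})

test_that("sharing counts datasets per union region", {
  mk_set <- function(starts, ends) {
    merge_epromoters(data.frame(
      promoter_id = sprintf("p%d", seq_along(starts)),
      gene_id = sprintf("g%d", seq_along(starts)), chrom = "chr1",
      start = starts, end = ends, is_epromoter = TRUE))
  }
  a <- mk_set(c(100L, 5000L), c(600L, 5500L))
  b <- mk_set(c(150L, 9000L), c(650L, 9500L))
  c3 <- mk_set(9100L, 9600L)
  sh <- sharing_stats(list(A = a, B = b, C = c3))
  # [100,650) shared by A+B; [5000,5500) only A; [9000,9600) shared by B+C
  expect_equal(sort(sh$per_region$n_datasets), c(1L, 2L, 2L))
  expect_equal(sh$fraction_shared, 2 / 3)
  ident <- sharing_stats(list(A = a, B = a))
  expect_equal(ident$fraction_shared, 1)
})

test_that("distal enhancers exclude Epromoters and take reference centers", {
  starr <- data.frame(chrom = "chr1", start = c(100L, 5000L), end = c(700L, 5600L))
  epr <- data.frame(chrom = "chr1", start = 600L, end = 1100L)
  ref <- data.frame(chrom = "chr1", start = c(4800L, 9000L), end = c(5800L, 9400L))
  out <- define_distal_enhancers(starr, ref, epr)
  # the STARR enhancer at [100,700) touches the Epromoter and is dropped;
  # [5000,5600) intersects ref [4800,5800) at >=50%, emit its center 500 bp
  expect_equal(out, data.frame(chrom = "chr1", start = 5050L, end = 5550L))
  # a reference enhancer shorter than 500 bp is emitted whole
  ref_short <- data.frame(chrom = "chr1", start = 5100L, end = 5400L)
  out2 <- define_distal_enhancers(starr, ref_short, epr)
  expect_equal(c(out2$start, out2$end), c(5100L, 5400L))
  none <- define_distal_enhancers(starr, data.frame(
    chrom = "chr1", start = 90000L, end = 91000L), epr)
  expect_equal(nrow(none), 0)
})

test_that("with the true active set, called Epromoters equal planted truth", {
  w <- tiny_world(seed = 3)
  truth_ids <- w$truth$true_epromoter_promoter_ids
  true_active <- w$promoters[w$promoters$promoter_id %in% truth_ids,
                             c("chrom", "start", "end")]
  flagged <- call_epromoters(w$promoters, true_active)
  expect_setequal(flagged$promoter_id[flagged$is_epromoter], truth_ids)
  eps <- merge_epromoters(flagged)
  expect_setequal(eps$members$promoter_id, truth_ids)
  # zero planted Epromoters: empty truth, nothing called from it
  w0 <- tiny_world(seed = 4, frac_epromoters = 0)
  expect_length(w0$truth$true_epromoter_promoter_ids, 0)
  f0 <- call_epromoters(w0$promoters,
                        w0$promoters[0, c("chrom", "start", "end")])
  expect_equal(sum(f0$is_epromoter), 0)
})
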