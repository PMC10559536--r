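test_that("TSS distance classification uses midpoints with strict 3 kb rule", {
  genes <- gene_annotation(c("gA", "gB"), "chr1", c(10000, 30000),
                           c(12000, 32000), c("+", "-"))
  # gA TSS = 10000; gB TSS = 31999
  mids <- c(10000, 13001, 13000, 21000)  # at TSS; 3001 away; 3000 away; far
  peaks <- genomic_intervals("chr1", mids - 200, mids + 200,
                             id = paste0("p", 1:4))
  ann <- classify_tss_distance(peaks, genes, 3000)
  expect_equal(ann$distance_bp[1], 0)
  expect_false(ann$is_distal[1])
  expect_equal(ann$distance_bp[2], 3001)
  expect_true(ann$is_distal[2])
  expect_equal(ann$distance_bp[3], 3000)
  expect_false(ann$is_distal[3])     # "> 3 kb" is strict
  expect_equal(ann$nearest_gene_id[1], "gA")
})

test_that("equidistant TSSs break ties by gene start then gene id", {
  genes <- gene_annotation(c("gZ", "gA"), "chr1", c(1000, 5000),
                           c(2000, 6000), c("+", "+"))
  # TSSs at 1000 and 5000; midpoint 3000 is equidistant
  pk <- genomic_intervals("chr1", 2800, 3200, id = "p")
  ann <- classify_tss_distance(pk, genes, 3000)
  expect_equal(ann$nearest_gene_id, "gZ")  # smaller gene start wins
  # same start: lexicographic id
  genes2 <- gene_annotation(c("gB", "gA"), "chr1", c(1000, 1000),
                            c(2000, 1500), c("+", "+"))
  pk2 <- genomic_intervals("chr1", 900, 1100, id = "p")
  expect_equal(classify_tss_distance(pk2, genes2, 3000)$nearest_gene_id, "gA")
  expect_warning(
    out <- classify_tss_distance(pk, genes[0, ], 3000), "distal")
  expect_true(out$is_distal)
})

test_that("classification ignores gene strand beyond the TSS position", {
  plus <- gene_annotation("g1", "chr1", 5000, 7000, "+")
  pk <- genomic_intervals("chr1", 4000, 4400, id = "p")
  d_plus <- classify_tss_distance(pk, plus, 3000)$distance_bp
  # a minus-strand gene with the same TSS position
  minus <- gene_annotation("g1", "chr1", 3001, 5001, "-")
  expect_equal(plus$tss, minus$tss)
  expect_equal(classify_tss_distance(pk, minus, 3000)$distance_bp, d_plus)
})

test_that("distal enrichment reproduces a strong published-scale signal", {
  flags_diff <- c(rep(TRUE, 100), rep(FALSE, 300))
  flags_dist <- c(rep(TRUE, 70), rep(FALSE, 30), rep(TRUE, 150), rep(FALSE, 150))
  en <- distal_enrichment(flags_diff, flags_dist)
  expect_equal(unname(en$table[1, ]), c(70, 30))
  expect_lt(en$p, 0.01)
  expect_gt(en$or, 1)
  # equal distal proportions in both groups: no signal
  null_en <- distal_enrichment(rep(c(TRUE, FALSE), each = 200),
                               rep(c(TRUE, FALSE), 200))
  expect_gt(null_en$p, 0.9)
})

test_that("conservation profile has 200 bins and matches per-base averaging", {
  set.seed(41)
  len <- 6000
  scores <- rnorm(len, 0, 1)
  scores[sample(len, 500)] <- NA
  tr <- conservation_track(list(chr1 = scores))
  pk <- genomic_intervals("chr1", c(2800, 4100), c(3200, 4500),
                          id = c("p1", "p2"))
  prof <- conservation_profile(pk, tr, halfwidth = 1000, bin = 10)
  expect_equal(nrow(prof), 200)
  expect_equal(prof$bin_center[1], -995)
  expect_equal(prof$bin_center[200], 995)
  o1 <- oracle_profile_one(scores, 3000, 1000, 10)
  o2 <- oracle_profile_one(scores, 4300, 1000, 10)
  expect_equal(prof$mean_score, colMeans(rbind(o1, o2), na.rm = TRUE))
  # single peak equals its own oracle even at the contig edge
  edge <- genomic_intervals("chr1", 100, 500, id = "e")
  pe <- conservation_profile(edge, tr, 1000, 10)
  expect_equal(pe$mean_score, oracle_profile_one(scores, 300, 1000, 10))
})

test_that("profiles of disjoint groups average with peak-count weights", {
  set.seed(42)
  tr <- conservation_track(list(chr1 = rnorm(20000, 0.5, 0.2)))
  mids <- seq(2000, 17000, by = 2500)
  pk <- genomic_intervals("chr1", mids - 200, mids + 200,
                          id = paste0("p", seq_along(mids)))
  g1 <- pk[1:2]; g2 <- pk[3:7]
  p1 <- conservation_profile(g1, tr, 1000, 10)
  p2 <- conservation_profile(g2, tr, 1000, 10)
  pall <- conservation_profile(pk, tr, 1000, 10)
  expect_equal(pall$mean_score,
               (2 * p1$mean_score + 5 * p2$mean_score) / 7,
               tolerance = 1e-12)
  # constant track gives flat profile at that constant
  flat <- conservation_track(list(chr1 = rep(0.7, 20000)))
  expect_equal(conservation_profile(pk, flat, 1000, 10)$mean_score,
               rep(0.7, 200))
})
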