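test_that("simulation is deterministic in the seed and responsive to it", {
  spec <- simulation_spec(n_genes = 60, n_peaks = 60, seed = 5)
  s1 <- simulate_study(spec)
  s2 <- simulate_study(spec)
  expect_identical(assay(s1$atac$counts, "counts"), assay(s2$atac$counts, "counts"))
  expect_identical(s1$atac$truth, s2$atac$truth)
  expect_identical(s1$eqtl, s2$eqtl)
  expect_identical(granges_to_bed_frame(s1$atac$calls),
                   granges_to_bed_frame(s2$atac$calls))
  s3 <- simulate_study(simulation_spec(n_genes = 60, n_peaks = 60, seed = 6))
  expect_false(identical(assay(s1$atac$counts, "counts"),
                         assay(s3$atac$counts, "counts")))
})

test_that("generated annotation obeys the strand-aware TSS rule", {
  ann <- generate_annotation(simulation_spec(n_genes = 40, n_peaks = 40))
  g <- ann$genes
  expect_equal(g$tss[g$strand == "+"], g$start[g$strand == "+"])
  expect_equal(g$tss[g$strand == "-"], g$end[g$strand == "-"] - 1L)
  expect_true(all(g$end <= ann$contig_lengths[g$chrom]))
  # no overlapping genes
  gr <- genomic_intervals(g$chrom, g$start, g$end)
  expect_true(all(countOverlaps(gr, gr) == 1))
})

test_that("gene-free simulations place every peak distal", {
  spec <- simulation_spec(n_genes = 0, n_peaks = 30, seed = 2)
  ann <- generate_annotation(spec)
  expect_equal(nrow(ann$genes), 0)
  atac <- generate_atac(spec, ann)
  expect_true(all(atac$truth$is_distal))
})

test_that("planted distal/proximal status agrees with TSS distances", {
  spec <- simulation_spec(n_genes = 150, n_peaks = 150, seed = 3)
  sim <- simulate_study(spec)
  tr <- sim$atac$truth
  tg <- genomic_intervals(tr$chrom, tr$start, tr$end, id = tr$peak_id)
  ann <- classify_tss_distance(tg, sim$annotation$genes, 3000)
  expect_equal(ann$is_distal, tr$is_distal)
})

test_that("zero planted effects yield an all-null truth table", {
  spec <- simulation_spec(n_genes = 30, n_peaks = 30, frac_differential = 0,
                          seed = 4)
  sim <- simulate_study(spec)
  expect_true(all(sim$atac$truth$true_lfc == 0))
  expect_true(all(is.na(sim$atac$truth$diff_condition)))
  expect_true(all(sim$rna$gene_truth$true_lfc == 0))
})

test_that("call probability one puts every peak in every sample's call list", {
  spec <- simulation_spec(n_genes = 20, n_peaks = 20, call_prob_high = 1,
                          frac_low_detect = 0, seed = 8)
  atac <- generate_atac(spec, generate_annotation(spec))
  per_sample <- table(mcols(atac$calls)$sample_id)
  expect_true(all(per_sample == 20))
})

test_that("null-feature count means match NB expectations", {
  spec <- simulation_spec(n_genes = 200, n_peaks = 200, frac_differential = 0,
                          donor_sd = 0, depth_sd = 0, seed = 9)
  atac <- generate_atac(spec, generate_annotation(spec))
  m <- assay(atac$counts, "counts")
  mu <- atac$truth$mu0
  n <- ncol(m)
  se <- sqrt((mu + spec$nb_dispersion * mu^2) / n)
  z <- (rowMeans(m) - mu) / se
  # each feature within 3 SE with rare excursions; ~99.7% expected inside
  expect_gt(mean(abs(z) < 3), 0.97)
})

test_that("eQTL catalogue structure is coherent", {
  spec <- simulation_spec(n_genes = 120, n_peaks = 120, seed = 10)
  sim <- simulate_study(spec)
  eq <- sim$eqtl
  # one lead per credible set, at the set's most significant association
  leads <- eq[eq$is_lead, ]
  expect_equal(anyDuplicated(leads$credible_set_id), 0)
  for (cs in unique(leads$credible_set_id)) {
    sub <- eq[eq$credible_set_id == cs, ]
    expect_equal(min(sub$p), sub$p[sub$is_lead])
  }
  # variants lie inside their source peak
  tr <- sim$atac$truth
  pk <- tr[match(sub("cs_", "", eq$credible_set_id), tr$peak_id), ]
  expect_true(all(eq$pos >= pk$start & eq$pos < pk$end))
})
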