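mk_eqtl <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(variant_id = r[[1]], chrom = "chr1", pos = as.integer(r[[2]]),
               gene_id = r[[3]], condition = r[[4]], p = as.numeric(r[[5]]),
               beta = 0.3,
               credible_set_id = if (length(r) >= 6) r[[6]] else NA_character_,
               is_lead = if (length(r) >= 7) r[[7]] else FALSE,
               stringsAsFactors = FALSE)
  }))
}

peaks1 <- genomic_intervals("chr1", c(100, 1000), c(500, 1400),
                            id = c("pk1", "pk2"))

test_that("eGene assignment takes the most significant sub-threshold eQTL", {
  eq <- mk_eqtl(
    list("v1", 150, "geneA", "UT", 1e-6),
    list("v2", 200, "geneB", "LPS2", 1e-8),
    list("v3", 1100, "geneC", "UT", 1e-4)   # above threshold
  )
  links <- assign_egenes(peaks1, eq, 1e-5)
  expect_equal(nrow(links), 1)
  expect_equal(links$gene_id, "geneB")
  expect_equal(links$peak_id, "pk1")
  # lowering the threshold never adds links
  expect_lte(nrow(assign_egenes(peaks1, eq, 1e-7)), nrow(links))
  expect_equal(nrow(assign_egenes(peaks1, eq, 1e-3)), 2)
})

test_that("exact ties break deterministically and order-independently", {
  eq <- mk_eqtl(
    list("v1", 300, "geneB", "UT", 1e-6),
    list("v2", 200, "geneB", "UT", 1e-6),   # same p, smaller pos
    list("v2", 200, "geneB", "LPS2", 1e-2)  # secondary condition support
  )
  l1 <- assign_egenes(peaks1, eq, 1e-5)
  l2 <- assign_egenes(peaks1, eq[rev(seq_len(nrow(eq))), ], 1e-5)
  expect_identical(l1, l2)
  expect_equal(l1$variant_id, "v2")
  # the linked variant lies inside its peak
  expect_true(l1$p < 1e-5)
  pk <- peaks1[mcols(peaks1)$id == l1$peak_id]
  expect_true(eq$pos[eq$variant_id == "v2"][1] >= start(pk) - 1 &&
                eq$pos[eq$variant_id == "v2"][1] < end(pk))
})

test_that("assigned variants always fall inside their peak on simulated data", {
  sim <- simulate_study(simulation_spec(n_genes = 120, n_peaks = 120, seed = 13))
  tr <- sim$atac$truth
  tg <- genomic_intervals(tr$chrom, tr$start, tr$end, id = tr$peak_id)
  links <- assign_egenes(tg, sim$eqtl)
  eqpos <- sim$eqtl$pos[match(links$variant_id, sim$eqtl$variant_id)]
  ptr <- tr[match(links$peak_id, tr$peak_id), ]
  expect_true(all(eqpos >= ptr$start & eqpos < ptr$end))
})

test_that("ATAC-eGene concordance recovers planted coupling and nulls", {
  mk_res <- function(ids, lfc, diff) {
    data.frame(feature_id = ids, base_mean = 10, log2fc = lfc, p = 0.001,
               q = 0.001, is_differential = diff)
  }
  links <- data.frame(peak_id = paste0("pk", 1:100),
                      gene_id = paste0("g", 1:100),
                      variant_id = paste0("v", 1:100),
                      p = 1e-8, condition = "IFNG")
  lfc <- seq(-3, 3, length.out = 100)
  atac <- mk_res(paste0("pk", 1:100), lfc, TRUE)
  rna <- mk_res(paste0("g", 1:100), 0.9 * lfc, TRUE)
  out <- atac_egene_concordance(links, atac, rna)
  expect_equal(out$r, 1)
  set.seed(61)
  rna_shuf <- mk_res(paste0("g", 1:100), sample(lfc), TRUE)
  expect_lt(abs(atac_egene_concordance(links, atac, rna_shuf)$r), 0.25)
})

test_that("context-specificity enrichment builds the lead-condition table", {
  # 6 leads: 4 focal (3 in matched set), 2 reference (0 in set)
  links <- data.frame(peak_id = paste0("pk", 1:6), gene_id = paste0("g", 1:6),
                      variant_id = paste0("v", 1:6), p = 1e-8,
                      condition = "IFNG")
  eq <- mk_eqtl(
    list("v1", 1, "g1", "IFNG", 1e-9, "cs1", TRUE),
    list("v2", 2, "g2", "IFNG", 1e-9, "cs2", TRUE),
    list("v3", 3, "g3", "IFNG", 1e-9, "cs3", TRUE),
    list("v4", 4, "g4", "IFNG", 1e-9, "cs4", TRUE),
    list("v5", 5, "g5", "LPS24", 1e-9, "cs5", TRUE),
    list("v6", 6, "g6", "LPS24", 1e-9, "cs6", TRUE)
  )
  out <- context_specific_enrichment(
    links, eq,
    diff_peak_ids = paste0("pk", 1:3), de_gene_ids = paste0("g", 1:3),
    focal_condition = "IFNG", reference_conditions = "LPS24"
  )
  expect_equal(unname(out$table), matrix(c(3, 1, 0, 2), 2, byrow = TRUE))
  expect_equal(out$prop_focal, 0.75)
  expect_gt(out$or, 1)

  # proportions equalised by construction: OR near 1, not significant
  links2 <- data.frame(peak_id = paste0("pk", 1:40), gene_id = paste0("g", 1:40),
                       variant_id = paste0("v", 1:40), p = 1e-8,
                       condition = "IFNG")
  eq2 <- do.call(rbind, lapply(1:40, function(i) {
    mk_eqtl(list(paste0("v", i), i, paste0("g", i),
                 if (i <= 20) "IFNG" else "LPS24", 1e-9,
                 paste0("cs", i), TRUE))
  }))
  in_set <- c(1:10, 21:30)  # half of each arm
  out2 <- context_specific_enrichment(
    links2, eq2, diff_peak_ids = paste0("pk", in_set),
    de_gene_ids = paste0("g", in_set),
    focal_condition = "IFNG", reference_conditions = "LPS24"
  )
  expect_equal(out2$or, 1, tolerance = 0.2)
  expect_gt(out2$p, 0.05)

  # no leads at all: degenerate flag
  eq3 <- eq; eq3$is_lead <- FALSE
  expect_true(context_specific_enrichment(links, eq3, "pk1", "g1",
                                          "IFNG", "LPS24")$degenerate)
})
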