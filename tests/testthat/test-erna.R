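test_that("TPM normalises by length and library, summing to 1e6 per sample", {
  sheet <- tiny_sheet(2)
  m <- matrix(c(10L, 0L, 100L, 40L, 0L, 0L, 200L, 80L), 4,
              dimnames = list(paste0("g", 1:4), sheet$sample_id))
  len <- setNames(c(1000, 2000, 500, 4000), rownames(m))
  cm <- count_matrix(m, sheet, feature_lengths = len)
  tpm <- tpm_matrix(cm)
  expect_equal(unname(colSums(tpm)), c(1e6, 1e6))
  # hand-computed oracle for sample 1
  rate <- m[, 1] / (len / 1e3)
  expect_equal(unname(tpm[, 1]), unname(rate / sum(rate) * 1e6))
  # all-zero gene excluded, others kept at default threshold
  expect_equal(expressed_genes(cm, 0.5), c("g1", "g3", "g4"))
  # single-gene library: TPM = 1e6 wherever nonzero
  cm1 <- count_matrix(m[3, , drop = FALSE], sheet, feature_lengths = len[3])
  expect_equal(unname(tpm_matrix(cm1)[1, ]), c(1e6, 1e6))
})

test_that("eRNA regions are midpoint windows clear of padded expressed genes", {
  cons <- genomic_intervals("chr1", c(10000, 20000, 50000),
                            c(10400, 20400, 50400), id = paste0("p", 1:3))
  # midpoints 10200, 20200, 50200
  genes <- gene_annotation(c("gE", "gN"), "chr1", c(5000, 22000),
                           c(7200, 23000), c("+", "+"))
  # expressed gE padded: [2000, 10200) -> abuts region [9200, 11200)? no:
  # region of p1 = [9200, 11200) overlaps [2000, 10200) -> dropped
  regions <- define_erna_regions(cons, genes, expressed_ids = "gE",
                                 pad = 3000, halfwidth = 1000)
  expect_equal(mcols(regions)$source_peak_id, c("p2", "p3"))
  expect_equal(start(regions) - 1L, c(19200L, 49200L))
  expect_equal(end(regions), c(21200L, 51200L))
  # non-expressed gN (padded [19000, 26000)) does not mask p2
  # exact abutment is retained: gene padded start 2000..; region ending at
  # 2000 survives
  cons2 <- genomic_intervals("chr1", 800, 1200, id = "pA")  # midpoint 1000
  reg2 <- define_erna_regions(cons2, genes, "gE", 3000, 1000)
  expect_length(reg2, 1)  # window [0, 2000) abuts padded start 2000
  # everything retained when the expressed set is empty
  expect_length(define_erna_regions(cons, genes, character(), 3000, 1000), 3)
})

test_that("eRNA quantification matches the overlap oracle and CPM semantics", {
  set.seed(51)
  mids <- seq(5000, 40000, by = 5000)
  regions <- genomic_intervals("chr1", mids - 1000, mids + 1000,
                               id = paste0("r", seq_along(mids)))
  sheet <- tiny_sheet(3)
  frags <- lapply(1:3, function(i) {
    st <- sample(0:45000, 400, TRUE)
    genomic_intervals("chr1", st, st + 100)
  })
  names(frags) <- sheet$sample_id
  q <- quantify_erna(regions, frags, sheet, cpm_min = 1)
  expect_equal(unname(assay(q$counts, "counts")),
               unname(oracle_overlap_counts(regions, frags)))

  # CPM boundary: one fragment in a library of exactly 1e6 gives CPM 1
  counts <- matrix(c(1L, 0L), 1, 2, dimnames = list("r1", c("S1", "S2")))
  fl <- erna_cpm_flags(counts, lib_sizes = c(1e6, 1e6), cpm_min = 1)
  expect_true(fl$is_expressed[["r1"]])
  expect_equal(fl$max_cpm[["r1"]], 1)
  # all-zero region excluded
  z <- erna_cpm_flags(matrix(0L, 1, 2, dimnames = list("rz", NULL)), c(10, 10))
  expect_false(z$is_expressed[["rz"]])
  expect_error(quantify_erna(regions, lapply(frags, function(x) x[0]), sheet),
               "zero library")
})

test_that("eRNA-ATAC correlation pairs differential regions with source peaks", {
  mk_res <- function(ids, lfc, diff) {
    data.frame(feature_id = ids, base_mean = 10, log2fc = lfc, p = 0.01,
               q = 0.01, is_differential = diff)
  }
  map <- data.frame(region_id = paste0("r", 1:6),
                    source_peak_id = paste0("p", 1:6))
  atac <- mk_res(paste0("p", 1:6), c(1, 2, 3, -1, -2, -3), TRUE)
  # perfectly proportional eRNA changes
  erna <- mk_res(paste0("r", 1:6), c(1, 2, 3, -1, -2, -3) / 2, TRUE)
  out <- erna_atac_correlation(erna, atac, map)
  expect_equal(out$r, 1)
  expect_equal(out$n, 6)
  # only differential eRNAs enter
  erna2 <- erna; erna2$is_differential[4:6] <- FALSE
  expect_equal(erna_atac_correlation(erna2, atac, map)$n, 3)
  expect_error(erna_atac_correlation(mk_res("r1", 1, TRUE), atac, map),
               "insufficient pairs")
  # independent effects give near-zero correlation
  set.seed(52)
  mapN <- data.frame(region_id = paste0("r", 1:500),
                     source_peak_id = paste0("p", 1:500))
  atacN <- mk_res(paste0("p", 1:500), rnorm(500), TRUE)
  ernaN <- mk_res(paste0("r", 1:500), rnorm(500), TRUE)
  expect_lt(abs(erna_atac_correlation(ernaN, atacN, mapN)$r), 0.1)
})
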