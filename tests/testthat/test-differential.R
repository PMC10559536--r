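make_cm <- function(m, conds = NULL, donors = NULL) {
  n <- ncol(m)
  sheet <- tiny_sheet(n)
  if (!is.null(conds)) sheet$condition <- conds
  if (!is.null(donors)) sheet$donor <- donors
  colnames(m) <- sheet$sample_id
  if (is.null(rownames(m))) rownames(m) <- paste0("f", seq_len(nrow(m)))
  count_matrix(m, sheet)
}

test_that("expression filter keeps genes reaching the count in enough samples", {
  m <- rbind(
    three_of_30 = c(rep(5L, 3), rep(0L, 27)),   # exactly 10% of samples
    two_of_30 = c(rep(100L, 2), rep(0L, 28)),
    zeros = rep(0L, 30)
  )
  cm <- make_cm(m, conds = rep(c("UT", "LPS2"), 15))
  kept <- rownames(filter_expressed_genes(cm, 5, 0.10))
  expect_equal(kept, "three_of_30")
  expect_equal(nrow(filter_expressed_genes(cm, 5, 0)), 3)
  expect_error(filter_expressed_genes(cm[0, ]), "empty")
})

test_that("size factors follow the median-of-ratios definition", {
  m1 <- matrix(c(10L, 40L, 20L, 80L), 2, dimnames = list(c("a", "b"), NULL))
  sf <- size_factors(make_cm(m1))
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)))
  m2 <- matrix(rep(c(7L, 13L, 29L), 3), 3, dimnames = list(letters[1:3], NULL))
  expect_equal(unname(size_factors(make_cm(m2))), rep(1, 3))

  set.seed(11)
  m3 <- matrix(rnbinom(5 * 3, mu = 50, size = 5), 5,
               dimnames = list(paste0("g", 1:5), NULL))
  expect_equal(unname(size_factors(m3)), unname(oracle_size_factors(m3)))
  # independent established implementation agrees
  expect_equal(unname(size_factors(m3)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m3)),
               tolerance = 1e-10)

  m4 <- matrix(c(0L, 5L, 3L, 0L), 2, dimnames = list(c("a", "b"), NULL))
  expect_error(size_factors(make_cm(m4)), "pseudo-reference")
})

sim_two_group <- function(n_feat, mu, lfc_idx = integer(), lfc = 0,
                          n_per = 3, alpha = 0.1) {
  conds <- rep(c("LPS2", "UT"), each = n_per)
  m <- matrix(rnbinom(n_feat * 2 * n_per, mu = mu, size = 1 / alpha), n_feat)
  if (length(lfc_idx)) {
    m[lfc_idx, conds == "LPS2"] <-
      rnbinom(length(lfc_idx) * n_per, mu = mu * 2^lfc, size = 1 / alpha)
  }
  rownames(m) <- paste0("f", seq_len(n_feat))
  make_cm(m, conds = conds, donors = paste0("D", rep(seq_len(n_per), 2)))
}

test_that("identical counts across arms give log2fc zero", {
  m <- matrix(rep(c(30L, 60L), each = 6), 2, byrow = TRUE,
              dimnames = list(c("a", "b"), NULL))
  cm <- make_cm(m, conds = rep(c("UT", "LPS2"), 3),
                donors = paste0("D", rep(1:3, each = 2)))
  res <- nb_wald(cm, "LPS2", "UT")
  expect_equal(res$log2fc, c(0, 0), tolerance = 1e-6)
})

test_that("swapping contrast arms negates fold changes and keeps p-values", {
  set.seed(21)
  cm <- sim_two_group(50, mu = 80, lfc_idx = 1:5, lfc = 2)
  a <- nb_wald(cm, "LPS2", "UT")
  b <- nb_wald(cm, "UT", "LPS2")
  expect_equal(a$log2fc, -b$log2fc, tolerance = 1e-6)
  expect_equal(a$p, b$p, tolerance = 1e-6)
})

test_that("scaling one sample's counts leaves fold-change estimates unchanged", {
  set.seed(22)
  cm <- sim_two_group(40, mu = 60, lfc_idx = 1:4, lfc = 1.5)
  m <- assay(cm, "counts")
  sf0 <- size_factors(cm)
  m2 <- m
  m2[, 1] <- m2[, 1] * 4L
  cm2 <- count_matrix(m2, as.data.frame(colData(cm)))
  sf2 <- size_factors(cm2)
  # relative factor of the scaled sample grows by exactly k
  expect_equal(sf2[1] / sf2[2], 4 * sf0[1] / sf0[2], tolerance = 1e-10)
  # fold changes essentially unchanged (dispersion re-estimation on the
  # rescaled normalised counts perturbs the GLM weights slightly)
  expect_lt(max(abs(nb_wald(cm2, "LPS2", "UT")$log2fc -
                      nb_wald(cm, "LPS2", "UT")$log2fc)), 0.1)
})

test_that("fully null simulations give uniform-ish p-values", {
  set.seed(23)
  fracs <- replicate(5, {
    cm <- sim_two_group(500, mu = 100)
    r <- nb_wald(cm, "LPS2", "UT")
    mean(r$p < 0.05, na.rm = TRUE)
  })
  expect_lt(abs(mean(fracs) - 0.05), 0.02)
})

test_that("planted effects are recovered with controlled FDR (3v3 design)", {
  set.seed(24)
  stats <- replicate(10, {
    cm <- sim_two_group(600, mu = 100, lfc_idx = 1:60, lfc = 2)
    r <- call_differential(nb_wald(cm, "LPS2", "UT"), 2, 0.05)
    called <- which(r$is_differential)
    c(fdr = ifelse(length(called), mean(called > 60), 0),
      sens = mean(1:60 %in% called))
  })
  expect_lte(mean(stats["fdr", ]), 0.10)
  expect_gte(mean(stats["sens", ]), 0.6)
})

test_that("large-count near-Poisson Wald p approaches the log-scale z-test", {
  set.seed(25)
  n_per <- 50
  m <- matrix(rnbinom(30 * 2 * n_per, mu = 1e4, size = 1e6), 30)
  rownames(m) <- paste0("f", 1:30)
  conds <- rep(c("LPS2", "UT"), each = n_per)
  cm <- make_cm(m, conds = conds, donors = paste0("D", rep(1:n_per, 2)))
  r <- nb_wald(cm, "LPS2", "UT", adjust_donor = FALSE, sf = rep(1, 2 * n_per))
  zp <- apply(m, 1, function(y) {
    la <- log(y[conds == "LPS2"]); lb <- log(y[conds == "UT"])
    z <- (mean(la) - mean(lb)) / sqrt(var(la) / n_per + var(lb) / n_per)
    2 * pnorm(-abs(z))
  })
  ok <- r$p > 1e-3  # compare away from the extreme tail
  expect_lt(median(abs(r$p[ok] - zp[ok]) / zp[ok]), 0.10)
})

test_that("differential calling is strict at both thresholds", {
  res <- data.frame(
    feature_id = c("at_fc", "at_q", "clear"),
    base_mean = 10,
    log2fc = c(log2(1.5), 3, 3),
    p = c(1e-4, 1e-4, 1e-6),
    q = c(1e-3, 0.05, 1e-6),
    is_differential = FALSE
  )
  out <- call_differential(res, 1.5, 0.05)
  expect_equal(out$is_differential, c(FALSE, FALSE, TRUE))
  out2 <- call_differential(res, 2, 0.05)
  expect_equal(out2$is_differential[1], FALSE)
})
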