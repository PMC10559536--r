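# Independent brute-force oracles and tiny fixture builders shared across
# the suite.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(SummarizedExperiment)
})

# two-tailed Fisher p by direct enumeration of the hypergeometric support,
# with masses from choose() -- independent of the package's log-space path
oracle_fisher_p <- function(a, b, c, d) {
  n1 <- a + b; n2 <- c + d; m1 <- a + c
  lo <- max(0, m1 - n2); hi <- min(m1, n1)
  ks <- lo:hi
  mass <- choose(n1, ks) * choose(n2, m1 - ks) / choose(n1 + n2, m1)
  obs <- mass[ks == a]
  sum(mass[mass <= obs * (1 + 1e-7)])
}

# median-of-ratios size factors computed the long way
oracle_size_factors <- function(m) {
  geo <- apply(m, 1, function(r) exp(mean(log(r))))
  ok <- is.finite(geo) & geo > 0
  apply(m, 2, function(col) median(col[ok] / geo[ok]))
}

# quadratic all-pairs overlap counting of fragments in regions (0-based
# half-open semantics via GRanges closed intervals)
oracle_overlap_counts <- function(regions, fragments_by_sample) {
  sapply(fragments_by_sample, function(fr) {
    vapply(seq_along(regions), function(i) {
      sum(as.character(GenomicRanges::seqnames(fr)) ==
            as.character(GenomicRanges::seqnames(regions[i])) &
            GenomicRanges::start(fr) <= GenomicRanges::end(regions[i]) &
            GenomicRanges::end(fr) >= GenomicRanges::start(regions[i]))
    }, numeric(1))
  })
}

# per-base binned profile for a single peak midpoint on a numeric score
# vector (0-based positions, NA = uncovered)
oracle_profile_one <- function(scores0, mid0, halfwidth, bin) {
  pos <- (mid0 - halfwidth):(mid0 + halfwidth - 1)
  v <- rep(NA_real_, length(pos))
  ok <- pos >= 0 & pos < length(scores0)
  v[ok] <- scores0[pos[ok] + 1]
  nbin <- 2 * halfwidth / bin
  vapply(seq_len(nbin), function(b) {
    mean(v[((b - 1) * bin + 1):(b * bin)], na.rm = TRUE)
  }, numeric(1))
}

# step-up BH the slow way
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    r <- which(o == i)  # rank of p[i]
    cand <- vapply(r:m, function(j) p[o[j]] * m / j, numeric(1))
    q[i] <- min(1, min(cand))
  }
  q
}

tiny_sheet <- function(n, assay = "RNA", conds = NULL) {
  if (is.null(conds)) conds <- rep(c("UT", "LPS2"), length.out = n)
  data.frame(
    sample_id = paste0("S", seq_len(n)),
    donor = paste0("D", rep(seq_len(max(1, n %/% 2)), length.out = n)),
    condition = conds,
    assay = assay,
    stringsAsFactors = FALSE
  )
}

random_table <- function() {
  repeat {
    t <- matrix(sample(0:15, 4, replace = TRUE), 2)
    if (all(rowSums(t) > 0) && all(colSums(t) > 0)) return(t)
  }
}
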