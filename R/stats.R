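# Shared statistics: BH FDR, the two-tailed Fisher exact test with a
# conditional-MLE odds ratio, and Pearson correlation. The Fisher machinery
# is written in log space so tables with margins in the tens of thousands
# (where individual hypergeometric masses underflow) still give usable
# p-values.

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment. `NA`/`NaN` p-values are propagated and excluded
#' from the number of tests.
#'
#' @param p numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return q-values in input order, clipped to \[0, 1\].
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))
bh_fdr <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  q[ok] <- p.adjust(p[ok], method = "BH")
  q
}

# Hypergeometric support and log masses for a 2x2 table with fixed margins.
# X = top-left cell; m1 = first column margin, n1 = first row margin.
hyper_support <- function(a, b, c, d) {
  n1 <- a + b
  m1 <- a + c
  N <- a + b + c + d
  lo <- max(0L, n1 - (b + d))
  hi <- min(n1, m1)
  k <- lo:hi
  list(k = k, logp = dhyper(k, m1, b + d, n1, log = TRUE), lo = lo, hi = hi,
       n1 = n1, m1 = m1, n2 = b + d)
}

logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

# Expectation of the noncentral (Fisher) hypergeometric distribution with
# log-odds parameter lpsi, given the support and central log masses.
nchg_mean <- function(sup, lpsi) {
  lw <- sup$logp + sup$k * lpsi
  lw <- lw - max(lw)
  w <- exp(lw)
  sum(sup$k * w) / sum(w)
}

#' Two-tailed Fisher exact test with conditional-MLE odds ratio
#'
#' The two-sided p-value follows the probability-mass rule: it sums the
#' hypergeometric masses of all outcomes no more likely than the observed
#' table (masses within relative 1e-7 of the observed mass count as ties and
#' are included). The odds ratio is the conditional maximum-likelihood
#' estimate: the value of psi for which the noncentral hypergeometric mean
#' equals the observed cell, found by root-finding on log(psi). Tables at
#' the boundary of the support return an odds ratio of 0 or `Inf` and a
#' one-tailed p-value. Computation is in log space, so very large margins
#' are handled without underflow.
#'
#' @param a,b,c,d non-negative integer cell counts; rows are groups, columns
#'   outcomes (`a` = group 1 with outcome 1).
#' @return list with `p_two_tailed`, `or_cmle`, `degenerate` (TRUE when a
#'   row or column margin is zero; then p = 1 and the OR is `NA`).
#' @export
#' @examples
#' fisher_exact_two_tailed(52, 35, 8, 52)  # p ~ 9.3e-09, OR ~ 9.5
fisher_exact_two_tailed <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cells must be non-negative integers")
  }
  if ((a + b == 0) || (c + d == 0) || (a + c == 0) || (b + d == 0)) {
    return(list(p_two_tailed = 1, or_cmle = NA_real_, degenerate = TRUE))
  }
  sup <- hyper_support(a, b, c, d)
  obs <- sup$logp[sup$k == a]
  # probability-mass rule with relative tie tolerance
  sel <- sup$logp <= obs + log(1 + 1e-7)
  p <- exp(logsumexp(sup$logp[sel]))
  p <- min(1, p)

  if (a == sup$lo) {
    or <- if (a == sup$hi) 1 else 0
  } else if (a == sup$hi) {
    or <- Inf
  } else {
    f <- function(lpsi) nchg_mean(sup, lpsi) - a
    lo <- -1; hi <- 1
    while (f(lo) > 0) lo <- lo * 2
    while (f(hi) < 0) hi <- hi * 2
    or <- exp(uniroot(f, c(lo, hi), tol = 1e-10)$root)
  }
  list(p_two_tailed = p, or_cmle = or, degenerate = FALSE)
}

#' @rdname fisher_exact_two_tailed
#' @param tab 2x2 matrix or a length-4 vector `(a, b, c, d)`.
#' @export
fisher_table <- function(tab) {
  v <- if (is.matrix(tab)) c(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]) else tab
  fisher_exact_two_tailed(v[1], v[2], v[3], v[4])
}

#' Pearson correlation with p-value
#'
#' Product-moment correlation; the p-value comes from the t transform with
#' n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 3, finite, non-constant.
#' @return list with `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("inputs must be finite")
  if (var(x) == 0 || var(y) == 0) stop("constant input")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
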