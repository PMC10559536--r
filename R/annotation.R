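# Peak annotation relative to gene TSSs, distal-enrichment testing, and
# binned conservation profiles around peak midpoints.

#' Classify peaks as promoter-proximal or distal
#'
#' Distance is measured from the peak midpoint (`floor((start + end) / 2)`
#' in 0-based coordinates) to the nearest TSS over all genes, regardless of
#' strand. A peak is distal when that distance strictly exceeds `window`.
#' Equidistant TSSs are broken deterministically: smaller gene start, then
#' lexicographic gene id.
#'
#' @param peaks consensus `GRanges` with `id` metadata.
#' @param genes gene annotation data.frame ([gene_annotation()]).
#' @param window distal/proximal boundary in bp (default 3000, strict).
#' @return data.frame: `peak_id`, `nearest_gene_id`, `distance_bp`,
#'   `is_distal`. With no genes, all peaks are distal with `NA` gene and
#'   infinite distance (a warning is raised).
#' @export
classify_tss_distance <- function(peaks, genes, window = 3000) {
  peak_id <- mcols(peaks)$id
  if (is.null(peak_id)) peak_id <- as.character(seq_along(peaks))
  mid <- interval_midpoint0(peaks)
  chrom <- as.character(seqnames(peaks))
  out <- data.frame(
    peak_id = peak_id,
    nearest_gene_id = NA_character_,
    distance_bp = Inf,
    is_distal = TRUE,
    stringsAsFactors = FALSE
  )
  if (nrow(genes) == 0) {
    warning("no genes supplied; all peaks classified distal")
    return(out)
  }
  for (ch in unique(chrom)) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    pi <- which(chrom == ch)
    if (!nrow(g)) next
    # order genes by the tie-break rule so the first minimum wins
    g <- g[order(g$start, g$gene_id), , drop = FALSE]
    d <- abs(outer(mid[pi], g$tss, "-"))
    j <- apply(d, 1, which.min)
    out$nearest_gene_id[pi] <- g$gene_id[j]
    out$distance_bp[pi] <- d[cbind(seq_along(pi), j)]
  }
  out$is_distal <- out$distance_bp > window
  out
}

#' Test enrichment of differential peaks among distal regions
#'
#' Builds the 2x2 table {differential, non-differential} x {distal,
#' proximal} and applies the two-tailed Fisher exact test.
#'
#' @param diff_flags,distal_flags aligned logical vectors over one peak
#'   set.
#' @return list with `table` (2x2 matrix), `p`, `or`, `degenerate`.
#' @export
distal_enrichment <- function(diff_flags, distal_flags) {
  if (length(diff_flags) != length(distal_flags)) stop("flag vectors must align")
  a <- sum(diff_flags & distal_flags)
  b <- sum(diff_flags & !distal_flags)
  c_ <- sum(!diff_flags & distal_flags)
  d <- sum(!diff_flags & !distal_flags)
  ft <- fisher_exact_two_tailed(a, b, c_, d)
  tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE,
                dimnames = list(c("differential", "non_differential"),
                                c("distal", "proximal")))
  list(table = tab, p = ft$p_two_tailed, or = ft$or_cmle,
       degenerate = ft$degenerate)
}

#' Binned conservation profile around peak midpoints
#'
#' For each peak the window midpoint +/- `halfwidth` is split into
#' `bin`-bp bins; each bin's score is the mean over its covered (non-`NA`)
#' bases, and the profile is the unweighted mean over peaks of those
#' per-peak bin means, so every peak contributes equally regardless of
#' coverage gaps.
#'
#' @param peaks `GRanges` of peaks.
#' @param track a [conservation_track()].
#' @param halfwidth window half-width in bp (default 1000).
#' @param bin bin width in bp (default 10); `2 * halfwidth / bin` bins (200
#'   at defaults).
#' @return data.frame: `bin_center` (offset of the bin centre from the
#'   midpoint, e.g. -995 ... 995), `mean_score`, `n_peaks` (peaks with any
#'   covered base in that bin).
#' @export
conservation_profile <- function(peaks, track, halfwidth = 1000, bin = 10) {
  nbin <- (2 * halfwidth) %/% bin
  if (nbin * bin != 2 * halfwidth) stop("bin must divide 2 * halfwidth")
  mid <- interval_midpoint0(peaks)
  chrom <- as.character(seqnames(peaks))
  binned <- matrix(NA_real_, length(peaks), nbin)
  for (i in seq_along(peaks)) {
    v <- track_window(track, chrom[i], mid[i] - halfwidth, mid[i] + halfwidth)
    binned[i, ] <- colMeans(matrix(v, nrow = bin), na.rm = TRUE)
  }
  binned[is.nan(binned)] <- NA
  data.frame(
    bin_center = seq(-halfwidth, halfwidth - bin, by = bin) + bin / 2,
    mean_score = colMeans(binned, na.rm = TRUE),
    n_peaks = colSums(!is.na(binned))
  )
}
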