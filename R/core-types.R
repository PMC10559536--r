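# Core containers. Genomic intervals live in GRanges (1-based closed, the
# native R convention); every file reader/writer converts to/from the
# 0-based half-open convention of BED-family formats, so on-disk coordinates
# are always BED-like. Counts live in a SummarizedExperiment whose colData
# is the sample sheet.

#' Construct a genomic interval set
#'
#' Builds a `GRanges` from 0-based half-open coordinates, validating the
#' interval invariants (`start >= 0`, `end > start`, non-empty contig name).
#'
#' @param chrom character vector of contig names.
#' @param start,end integer vectors, 0-based half-open.
#' @param ... further per-interval metadata columns (e.g. `id`,
#'   `sample_id`, `neglog10_p`).
#' @return A `GRanges` (1-based internally; use [granges_to_bed_frame()] to
#'   recover BED coordinates).
#' @export
genomic_intervals <- function(chrom, start, end, ...) {
  if (any(!nzchar(chrom))) stop("chrom must be non-empty")
  if (any(start < 0)) stop("start must be >= 0")
  if (any(end <= start)) stop("end must be > start")
  GRanges(chrom, IRanges(start + 1L, end), ...)
}

#' @rdname genomic_intervals
#' @param gr a `GRanges`.
#' @return `granges_to_bed_frame()`: a data.frame with 0-based half-open
#'   `chrom`, `start`, `end` plus any metadata columns.
#' @export
granges_to_bed_frame <- function(gr) {
  df <- data.frame(
    chrom = as.character(seqnames(gr)),
    start = start(gr) - 1L,
    end = end(gr),
    stringsAsFactors = FALSE
  )
  md <- as.data.frame(mcols(gr))
  if (ncol(md)) df <- cbind(df, md)
  df
}

# 0-based midpoint of each interval: floor((start0 + end0) / 2).
interval_midpoint0 <- function(gr) {
  (start(gr) - 1L + end(gr)) %/% 2L
}

#' Validate a sample sheet
#'
#' A sample sheet is a data.frame with columns `sample_id`, `donor`,
#' `condition` and `assay`; conditions must belong to the five activation
#' states of the study design (UT, LPS2, LPS6_6, LPS24, IFNG) and sample ids
#' must be unique.
#'
#' @param samples a data.frame.
#' @return The validated data.frame (invisibly usable), with `condition`
#'   kept as character.
#' @export
validate_sample_sheet <- function(samples) {
  need <- c("sample_id", "donor", "condition", "assay")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("sample sheet lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample_id in sample sheet")
  bad <- setdiff(unique(samples$condition), CONDITIONS)
  if (length(bad)) {
    stop("unknown condition(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(CONDITIONS, collapse = ", "), ")")
  }
  if (any(!samples$assay %in% c("ATAC", "RNA"))) stop("assay must be ATAC or RNA")
  samples
}

#' Construct a count matrix
#'
#' Wraps a features x samples integer matrix and its sample sheet in a
#' `SummarizedExperiment`. Counts must be non-negative integers; feature ids
#' unique; columns are reordered to match the sample sheet.
#'
#' @param counts integer matrix with rownames (feature ids) and colnames
#'   (sample ids).
#' @param samples sample sheet (see [validate_sample_sheet()]).
#' @param feature_lengths optional numeric vector of feature lengths in bp
#'   (named by feature id or in row order), required for TPM.
#' @return A `SummarizedExperiment` with assay `"counts"`.
#' @export
count_matrix <- function(counts, samples, feature_lengths = NULL) {
  samples <- validate_sample_sheet(samples)
  if (is.null(rownames(counts))) stop("counts must have feature ids as rownames")
  if (anyDuplicated(rownames(counts))) stop("feature ids must be unique")
  if (is.null(colnames(counts))) stop("counts must have sample ids as colnames")
  if (!setequal(colnames(counts), samples$sample_id)) {
    stop("count matrix samples and sample sheet disagree")
  }
  counts <- counts[, samples$sample_id, drop = FALSE]
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("counts must be integral")
  storage.mode(counts) <- "integer"
  rd <- S4Vectors::DataFrame(row.names = rownames(counts))
  if (!is.null(feature_lengths)) {
    if (!is.null(names(feature_lengths))) {
      feature_lengths <- feature_lengths[rownames(counts)]
    }
    if (length(feature_lengths) != nrow(counts) || any(is.na(feature_lengths))) {
      stop("feature_lengths must cover every feature")
    }
    rd$length <- as.numeric(feature_lengths)
  }
  SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(samples, row.names = samples$sample_id),
    rowData = rd
  )
}

#' Gene annotation table
#'
#' Builds the annotation container used downstream: a data.frame with one
#' row per gene carrying 0-based half-open coordinates, strand and the
#' strand-aware TSS (`start` for `+` genes, `end - 1` for `-` genes).
#'
#' @param gene_id character vector of unique gene ids.
#' @param chrom,start,end 0-based half-open gene coordinates.
#' @param strand `"+"` or `"-"` per gene.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `tss` (0-based position).
#' @export
gene_annotation <- function(gene_id, chrom, start, end, strand) {
  if (anyDuplicated(gene_id)) stop("gene ids must be unique")
  if (any(!strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(end <= start)) stop("gene end must be > start")
  data.frame(
    gene_id = as.character(gene_id),
    chrom = as.character(chrom),
    start = as.integer(start), end = as.integer(end),
    strand = as.character(strand),
    tss = as.integer(ifelse(strand == "+", start, end - 1L)),
    stringsAsFactors = FALSE
  )
}

genes_to_granges <- function(genes) {
  genomic_intervals(genes$chrom, genes$start, genes$end,
                    gene_id = genes$gene_id, gene_strand = genes$strand,
                    tss = genes$tss)
}

#' Per-base conservation track
#'
#' A conservation track stores per-base scores (phyloP semantics: positive =
#' conserved, negative = fast-evolving) as one run-length-encoded vector per
#' contig; bases without a score are `NA` and are excluded from all means.
#'
#' @param scores named list of numeric vectors or `Rle`s, one per contig,
#'   starting at base 0 of the contig.
#' @param contig_lengths named integer vector of contig lengths (bp);
#'   defaults to the score vector lengths.
#' @return An object of class `conservation_track`.
#' @export
conservation_track <- function(scores, contig_lengths = NULL) {
  if (is.null(names(scores)) || any(!nzchar(names(scores)))) {
    stop("scores must be a named list (one element per contig)")
  }
  scores <- lapply(scores, function(x) if (inherits(x, "Rle")) x else Rle(as.numeric(x)))
  if (is.null(contig_lengths)) {
    contig_lengths <- vapply(scores, length, integer(1))
  }
  contig_lengths <- contig_lengths[names(scores)]
  if (any(vapply(scores, length, integer(1)) != contig_lengths)) {
    stop("score vectors must match contig lengths")
  }
  vals <- unlist(lapply(scores, runValue))
  if (any(is.infinite(vals))) stop("conservation scores must be finite or NA")
  structure(list(scores = scores, contig_lengths = contig_lengths),
            class = "conservation_track")
}

#' @export
print.conservation_track <- function(x, ...) {
  covered <- vapply(x$scores, function(r) sum(!is.na(r)), numeric(1))
  cat("conservation_track:", length(x$scores), "contig(s),",
      format(sum(covered), big.mark = ","), "covered bases\n")
  invisible(x)
}

# Extract scores (NA-padded) over the 0-based half-open window [from0, to0)
# of a contig; positions outside the contig come back NA.
track_window <- function(track, chrom, from0, to0) {
  n <- to0 - from0
  out <- rep(NA_real_, n)
  rle <- track$scores[[chrom]]
  if (is.null(rle)) return(out)
  len <- length(rle)
  lo <- max(from0, 0L)
  hi <- min(to0, len)
  if (hi > lo) {
    out[(lo - from0 + 1):(hi - from0)] <- as.numeric(S4Vectors::window(rle, lo + 1L, hi))
  }
  out
}
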