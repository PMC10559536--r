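# Readers and writers for the plain-text formats the workflow touches.
# BED/bedGraph and the eQTL table are 0-based half-open on disk; GTF is
# 1-based inclusive and converted on read/write. No other module parses
# files.

#' Read a BED3+ file
#'
#' Whitespace-delimited, at least three columns; `track`/`browser` lines and
#' `#` comments are skipped. Column 4 is taken as an interval id and column
#' 5, when present, as the peak-call significance on the -log10 scale.
#'
#' @param path file path.
#' @return A `GRanges`; empty for an empty file.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(GRanges())
  fields <- strsplit(lines, "[ \t]+")
  ncols <- lengths(fields)
  if (any(ncols < 3)) {
    stop("fewer than 3 columns at line ", lineno[which(ncols < 3)[1]])
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) stop("non-numeric coordinate at line ", lineno[bad[1]])
  bad <- which(end <= start)
  if (length(bad)) stop("end <= start at line ", lineno[bad[1]])
  gr <- genomic_intervals(chrom, as.integer(start), as.integer(end))
  if (all(ncols >= 4)) mcols(gr)$id <- vapply(fields, `[[`, "", 4L)
  if (all(ncols >= 5)) {
    score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
    bad <- which(is.na(score) | score < 0)
    if (length(bad)) stop("invalid score at line ", lineno[bad[1]])
    mcols(gr)$neglog10_p <- score
  }
  gr
}

#' Write intervals as BED
#'
#' @param gr a `GRanges`; metadata columns `id` and `neglog10_p` (or
#'   `score`) become BED columns 4 and 5.
#' @param path output path.
#' @export
write_bed <- function(gr, path) {
  df <- granges_to_bed_frame(gr)
  cols <- c("chrom", "start", "end")
  if ("id" %in% names(df)) {
    cols <- c(cols, "id")
    score_col <- intersect(c("neglog10_p", "score", "n_supporting_samples"), names(df))
    if (length(score_col)) cols <- c(cols, score_col[1])
  }
  fwrite(df[cols], path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read gene annotations from a GTF file
#'
#' Keeps `gene` feature rows, converts the 1-based inclusive GTF coordinates
#' to the internal convention and derives the strand-aware TSS.
#'
#' @param path GTF file path.
#' @return A gene annotation data.frame (see [gene_annotation()]).
#' @export
read_gtf_genes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(gene_annotation(character(), character(), integer(), integer() + 1L, character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < 9)) stop("fewer than 9 GTF columns at line ", lineno[which(ncols < 9)[1]])
  feat <- vapply(fields, `[[`, "", 3L)
  sel <- feat == "gene"
  fields <- fields[sel]; lineno <- lineno[sel]
  if (!length(fields)) return(gene_annotation(character(), character(), integer(), integer() + 1L, character()))
  chrom <- vapply(fields, `[[`, "", 1L)
  start1 <- as.integer(vapply(fields, `[[`, "", 4L))
  end1 <- as.integer(vapply(fields, `[[`, "", 5L))
  strand <- vapply(fields, `[[`, "", 7L)
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad)) stop("unknown strand '", strand[bad[1]], "' at line ", lineno[bad[1]])
  attrs <- vapply(fields, `[[`, "", 9L)
  m <- regmatches(attrs, regexpr('gene_id "[^"]*"', attrs))
  has_id <- grepl('gene_id "', attrs, fixed = TRUE)
  if (any(!has_id)) stop("missing gene_id attribute at line ", lineno[which(!has_id)[1]])
  gene_id <- sub('gene_id "([^"]*)"', "\\1", m)
  gene_annotation(gene_id, chrom, start1 - 1L, end1, strand)
}

#' Write gene annotations as GTF
#'
#' @param genes gene annotation data.frame.
#' @param path output path.
#' @param source source field for column 2.
#' @export
write_gtf_genes <- function(genes, path, source = "ernalink") {
  lines <- sprintf('%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s";',
                   genes$chrom, source, genes$start + 1L, genes$end,
                   genes$strand, genes$gene_id)
  writeLines(lines, path)
  invisible(path)
}

#' Read a TSV count matrix against a sample sheet
#'
#' First column holds feature ids; remaining header names must all appear in
#' the sample sheet. Columns are returned in sample-sheet order.
#'
#' @param path TSV path.
#' @param samples sample sheet data.frame.
#' @param feature_lengths optional lengths passed through to
#'   [count_matrix()].
#' @return A `SummarizedExperiment`.
#' @export
read_counts_tsv <- function(path, samples, feature_lengths = NULL) {
  samples <- validate_sample_sheet(samples)
  dt <- fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  if (ncol(dt) < 2) stop("count table needs a feature column and >= 1 sample")
  ids <- as.character(dt[[1]])
  extra <- setdiff(names(dt)[-1], samples$sample_id)
  if (length(extra)) {
    stop("sample(s) in header absent from sample sheet: ", paste(extra, collapse = ", "))
  }
  keep <- samples$sample_id %in% names(dt)[-1]
  samples <- samples[keep, , drop = FALSE]
  m <- as.matrix(dt[, samples$sample_id, drop = FALSE])
  if (!is.numeric(m) || any(is.na(m))) stop("non-numeric count in ", path)
  if (any(m < 0) || any(m != round(m))) stop("counts must be non-negative integers")
  rownames(m) <- ids
  count_matrix(m, samples, feature_lengths)
}

#' Write a count matrix as TSV
#'
#' @param cm a `SummarizedExperiment` from [count_matrix()].
#' @param path output path.
#' @param feature_col name for the feature-id column.
#' @export
write_counts_tsv <- function(cm, path, feature_col = "feature_id") {
  m <- assay(cm, "counts")
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- feature_col
  fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Read/write a sample sheet TSV
#'
#' Columns: `sample_id`, `donor`, `condition`, `assay`.
#' @param path TSV path.
#' @return data.frame.
#' @export
read_sample_sheet <- function(path) {
  validate_sample_sheet(fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                              colClasses = "character"))
}

#' @rdname read_sample_sheet
#' @param samples sample sheet.
#' @export
write_sample_sheet <- function(samples, path) {
  fwrite(validate_sample_sheet(samples), path, sep = "\t")
  invisible(path)
}

#' Read a bedGraph score track
#'
#' Four columns (chrom, start, end, value; 0-based half-open); bases not
#' covered by any record stay `NA`.
#'
#' @param path bedGraph path.
#' @param contig_lengths optional named contig lengths; defaults to the last
#'   covered base per contig.
#' @return A [conservation_track()].
#' @export
read_bedgraph_track <- function(path, contig_lengths = NULL) {
  dt <- fread(path, sep = "\t", header = FALSE, data.table = FALSE,
              col.names = c("chrom", "start", "end", "value"))
  if (any(dt$end <= dt$start)) stop("end <= start in bedGraph record")
  chroms <- unique(dt$chrom)
  if (is.null(contig_lengths)) {
    contig_lengths <- vapply(chroms, function(ch) max(dt$end[dt$chrom == ch]), numeric(1))
  }
  scores <- lapply(chroms, function(ch) {
    len <- contig_lengths[[ch]]
    v <- rep(NA_real_, len)
    d <- dt[dt$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(d))) v[(d$start[i] + 1):d$end[i]] <- d$value[i]
    Rle(v)
  })
  names(scores) <- chroms
  conservation_track(scores, setNames(as.integer(contig_lengths[chroms]), chroms))
}

#' Write a conservation track as bedGraph
#'
#' Emits one record per constant run of covered bases; `NA` runs are
#' omitted.
#'
#' @param track a [conservation_track()].
#' @param path output path.
#' @param digits value precision.
#' @export
write_bedgraph <- function(track, path, digits = 4) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(track$scores)) {
    r <- track$scores[[ch]]
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- c(0L, head(ends, -1L))
    vals <- runValue(r)
    keep <- !is.na(vals)
    if (!any(keep)) next
    writeLines(sprintf("%s\t%d\t%d\t%s", ch, starts[keep], ends[keep],
                       formatC(vals[keep], digits = digits, format = "g")), con)
  }
  invisible(path)
}

#' Read an eQTL summary-statistics table
#'
#' TSV with columns `variant_id`, `chrom`, `pos`, `gene_id`, `condition`,
#' `p`, `beta`, and optionally `credible_set_id` and `is_lead`. Positions
#' may be declared 0- or 1-based; they are stored 0-based.
#'
#' @param path TSV path.
#' @param pos_base 0 or 1: the coordinate dialect of the `pos` column.
#' @return data.frame with 0-based `pos`.
#' @export
read_eqtl_tsv <- function(path, pos_base = 0) {
  if (!pos_base %in% c(0, 1)) stop("pos_base must be 0 or 1")
  dt <- fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  need <- c("variant_id", "chrom", "pos", "gene_id", "condition", "p", "beta")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("eQTL table lacks column(s): ", paste(miss, collapse = ", "))
  dt$pos <- as.integer(dt$pos) - as.integer(pos_base)
  if (any(dt$pos < 0)) stop("negative position after coordinate conversion")
  if (any(dt$p <= 0 | dt$p > 1)) stop("eQTL p-values must lie in (0, 1]")
  if (is.null(dt$credible_set_id)) dt$credible_set_id <- NA_character_
  if (is.null(dt$is_lead)) dt$is_lead <- FALSE
  dt$is_lead <- as.logical(dt$is_lead)
  dt
}

#' @rdname read_eqtl_tsv
#' @param eqtl eQTL data.frame (0-based `pos`).
#' @export
write_eqtl_tsv <- function(eqtl, path) {
  fwrite(eqtl, path, sep = "\t")
  invisible(path)
}
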