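#!/usr/bin/env Rscript
# Stage 5: enhancer-RNA analysis. Expressed genes (max TPM >= 0.5) define
# the padded boundaries that candidate eRNA windows (consensus-peak
# midpoint +-1 kb) must avoid; surviving regions are quantified, filtered
# at max CPM >= 1, tested for differential expression (FC > 2, FDR <
# 0.05) and their fold changes correlated with the source peaks' ATAC
# fold changes.

suppressMessages(library(ernalink))
indir <- "results/simulated"
outdir <- "results"
cfg <- pipeline_config()
contrasts <- c("LPS2", "LPS6_6", "LPS24", "IFNG")

consensus <- read_bed(file.path(outdir, "consensus_peaks.bed"))
genes <- read_gtf_genes(file.path(indir, "genes.gtf"))
rna_samples <- read_sample_sheet(file.path(indir, "rna_samples.tsv"))
lens <- setNames(genes$end - genes$start, genes$gene_id)
gene_cm <- read_counts_tsv(file.path(indir, "gene_counts.tsv"), rna_samples,
                           feature_lengths = lens)

expr_ids <- expressed_genes(gene_cm, cfg$expressed_tpm_min)
regions <- define_erna_regions(consensus, genes, expr_ids,
                               cfg$gene_boundary_pad_bp, cfg$erna_halfwidth_bp)
write_bed(regions, file.path(outdir, "erna_regions.bed"))

# simulated eRNA counts are keyed by true peak; re-key onto the regions
tmap <- data.table::fread(file.path(outdir, "consensus_truth_map.tsv"), data.table = FALSE)
erna_sim <- read_counts_tsv(file.path(indir, "erna_counts.tsv"), rna_samples)
m <- SummarizedExperiment::assay(erna_sim, "counts")
src <- S4Vectors::mcols(regions)$source_peak_id
true_ids <- paste0(tmap$true_peak_id[match(src, tmap$peak_id)], "_eRNA")
keep <- true_ids %in% rownames(m)
m2 <- m[true_ids[keep], , drop = FALSE]
rownames(m2) <- S4Vectors::mcols(regions)$id[keep]
erna_cm <- count_matrix(m2, rna_samples)

lib <- colSums(SummarizedExperiment::assay(gene_cm, "counts")) + colSums(m)
flags <- erna_cpm_flags(m2, lib, cfg$erna_cpm_min)
cat(sprintf("%d eRNA regions; %.1f%% expressed at max CPM >= %g\n",
            length(regions), 100 * mean(flags$is_expressed), cfg$erna_cpm_min))
erna_expr <- erna_cm[flags$is_expressed, ]

region_map <- data.frame(region_id = S4Vectors::mcols(regions)$id,
                         source_peak_id = src)
pairs <- NULL
for (cc in contrasts) {
  res <- call_differential(nb_wald(erna_expr, cc, "UT"), cfg$erna_fc, cfg$fdr)
  data.table::fwrite(res, file.path(outdir, sprintf("differential_erna_%s_vs_UT.tsv", cc)),
                     sep = "\t")
  atac <- data.table::fread(file.path(outdir, sprintf("differential_atac_%s_vs_UT.tsv", cc)),
                            data.table = FALSE)
  cres <- tryCatch(erna_atac_correlation(res, atac, region_map),
                   error = function(e) NULL)
  if (!is.null(cres)) pairs <- rbind(pairs, cbind(contrast = cc, cres$pairs))
}
ct <- pearson_r(pairs$erna_log2fc, pairs$atac_log2fc)
cat(sprintf("eRNA vs ATAC log2FC over %d differential-eRNA pairs: r = %.3f (p = %.3g)\n",
            ct$n, ct$r, ct$p))
data.table::fwrite(pairs, file.path(outdir, "erna_atac_pairs.tsv"), sep = "\t")
data.table::fwrite(data.frame(r = ct$r, p = ct$p, n = ct$n),
                   file.path(outdir, "erna_atac_correlation.tsv"), sep = "\t")
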