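#!/usr/bin/env Rscript
# Stage 3: negative-binomial Wald tests with donor adjustment for every
# stimulated-vs-UT contrast, for ATAC consensus peaks (FC > 1.5, FDR <
# 0.05) and genes (expression filter, then FC > 2, FDR < 0.05).

suppressMessages(library(ernalink))
indir <- "results/simulated"
outdir <- "results"
cfg <- pipeline_config()
contrasts <- c("LPS2", "LPS6_6", "LPS24", "IFNG")

atac_samples <- read_sample_sheet(file.path(indir, "atac_samples.tsv"))
atac <- read_counts_tsv(file.path(outdir, "consensus_counts.tsv"), atac_samples)
atac_sf <- size_factors(atac)
for (cc in contrasts) {
  res <- call_differential(nb_wald(atac, cc, "UT", sf = atac_sf),
                           cfg$atac_fc, cfg$fdr)
  data.table::fwrite(res, file.path(outdir, sprintf("differential_atac_%s_vs_UT.tsv", cc)),
                     sep = "\t")
  cat(sprintf("ATAC %s vs UT: %d differential of %d tested\n",
              cc, sum(res$is_differential), sum(!is.na(res$p))))
}

rna_samples <- read_sample_sheet(file.path(indir, "rna_samples.tsv"))
genes <- read_gtf_genes(file.path(indir, "genes.gtf"))
rna <- read_counts_tsv(file.path(indir, "gene_counts.tsv"), rna_samples,
                       feature_lengths = setNames(genes$end - genes$start,
                                                  genes$gene_id))
rna <- filter_expressed_genes(rna, cfg$gene_min_count, cfg$gene_min_fraction)
rna_sf <- size_factors(rna)
for (cc in contrasts) {
  res <- call_differential(nb_wald(rna, cc, "UT", sf = rna_sf),
                           cfg$gene_fc, cfg$fdr)
  data.table::fwrite(res, file.path(outdir, sprintf("differential_rna_%s_vs_UT.tsv", cc)),
                     sep = "\t")
  cat(sprintf("RNA %s vs UT: %d differential of %d tested\n",
              cc, sum(res$is_differential), sum(!is.na(res$p))))
}
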