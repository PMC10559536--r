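#!/usr/bin/env Rscript
# Stage 1: simulate the miniature stimulation study (6 donors x 5
# conditions; 2,000 genes, 2,000 ATAC peaks) and write every pipeline
# input as plain text under results/simulated/, together with the truth
# tables used later for parameter-recovery checks. The conservation track
# is regenerated deterministically from the same seed in stage 4 rather
# than serialised (it is by far the largest object).

suppressMessages(library(ernalink))

seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1
outdir <- "results/simulated"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

spec <- simulation_spec(seed = seed)
sim <- simulate_study(spec)

write_gtf_genes(sim$annotation$genes, file.path(outdir, "genes.gtf"))
write_sample_sheet(sim$atac$samples, file.path(outdir, "atac_samples.tsv"))
write_sample_sheet(sim$rna$samples, file.path(outdir, "rna_samples.tsv"))
data.table::fwrite(granges_to_bed_frame(sim$atac$calls),
                   file.path(outdir, "peak_calls.tsv"), sep = "\t")
if (length(sim$atac$blacklist)) {
  write_bed(sim$atac$blacklist, file.path(outdir, "blacklist.bed"))
}
write_counts_tsv(sim$atac$counts, file.path(outdir, "atac_counts.tsv"),
                 feature_col = "peak_id")
write_counts_tsv(sim$rna$gene_counts, file.path(outdir, "gene_counts.tsv"),
                 feature_col = "gene_id")
write_counts_tsv(sim$rna$erna_counts, file.path(outdir, "erna_counts.tsv"),
                 feature_col = "region_id")
write_eqtl_tsv(sim$eqtl, file.path(outdir, "eqtl.tsv"))
data.table::fwrite(sim$atac$truth, file.path(outdir, "truth_atac.tsv"), sep = "\t")
data.table::fwrite(sim$rna$gene_truth, file.path(outdir, "truth_genes.tsv"), sep = "\t")
data.table::fwrite(sim$rna$erna_truth, file.path(outdir, "truth_erna.tsv"), sep = "\t")
writeLines(as.character(seed), file.path(outdir, "seed.txt"))

cat(sprintf(
  "simulated %d genes, %d peaks (%d differential, %.0f%% distal), %d eQTL records; seed %d\n",
  nrow(sim$annotation$genes), nrow(sim$atac$truth),
  sum(sim$atac$truth$true_lfc != 0), 100 * mean(sim$atac$truth$is_distal),
  nrow(sim$eqtl), seed
))
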