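#!/usr/bin/env Rscript
# Stage 2: filter the per-sample peak calls (call p <= 1e-5, blacklist
# excluded) and build the recurrent peak set (called in >= 30% of the 60
# ATAC samples), then transfer the simulated counts onto the consensus
# coordinates via the truth map.

suppressMessages(library(ernalink))
indir <- "results/simulated"
outdir <- "results"

calls_df <- data.table::fread(file.path(indir, "peak_calls.tsv"), data.table = FALSE)
calls <- genomic_intervals(calls_df$chrom, calls_df$start, calls_df$end,
                           sample_id = calls_df$sample_id,
                           neglog10_p = calls_df$neglog10_p)
bl_path <- file.path(indir, "blacklist.bed")
blacklist <- if (file.exists(bl_path)) read_bed(bl_path) else NULL
samples <- read_sample_sheet(file.path(indir, "atac_samples.tsv"))

cfg <- pipeline_config()
filtered <- filter_sample_peaks(calls, blacklist, cfg$peak_p_threshold)
consensus <- build_recurrent(filtered, n_samples = nrow(samples),
                             recurrence_fraction = cfg$recurrence_fraction)
write_bed(consensus, file.path(outdir, "consensus_peaks.bed"))

truth <- data.table::fread(file.path(indir, "truth_atac.tsv"), data.table = FALSE)
tmap <- match_consensus_to_truth(consensus, truth)
data.table::fwrite(tmap, file.path(outdir, "consensus_truth_map.tsv"), sep = "\t")

atac_sim <- read_counts_tsv(file.path(indir, "atac_counts.tsv"), samples)
m <- SummarizedExperiment::assay(atac_sim, "counts")
m2 <- m[tmap$true_peak_id, , drop = FALSE]
rownames(m2) <- tmap$peak_id
write_counts_tsv(count_matrix(m2, samples),
                 file.path(outdir, "consensus_counts.tsv"),
                 feature_col = "peak_id")

cat(sprintf("%d of %d filtered calls -> %d consensus peaks (support >= %d)\n",
            length(filtered), length(calls), length(consensus),
            ceiling(cfg$recurrence_fraction * nrow(samples))))
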