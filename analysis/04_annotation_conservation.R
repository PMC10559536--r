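#!/usr/bin/env Rscript
# Stage 4: classify consensus peaks as promoter-proximal vs distal
# (midpoint > 3 kb from the nearest TSS), test whether differential peaks
# are enriched among distal regions, and compute the 200-bin conservation
# profiles (+-1 kb, 10-bp bins) for differential vs non-differential
# peaks. The conservation track is regenerated deterministically from the
# recorded seed.

suppressMessages(library(ernalink))
indir <- "results/simulated"
outdir <- "results"
cfg <- pipeline_config()
contrasts <- c("LPS2", "LPS6_6", "LPS24", "IFNG")

consensus <- read_bed(file.path(outdir, "consensus_peaks.bed"))
genes <- read_gtf_genes(file.path(indir, "genes.gtf"))
annot <- classify_tss_distance(consensus, genes, cfg$tss_window_bp)
data.table::fwrite(annot, file.path(outdir, "peak_annotation.tsv"), sep = "\t")

diff_any <- rep(FALSE, length(consensus))
for (cc in contrasts) {
  res <- data.table::fread(file.path(outdir, sprintf("differential_atac_%s_vs_UT.tsv", cc)),
                           data.table = FALSE)
  flag <- res$is_differential[match(annot$peak_id, res$feature_id)]
  diff_any <- diff_any | (!is.na(flag) & flag)
}
enrich <- distal_enrichment(diff_any, annot$is_distal)
cat(sprintf("distal: %.1f%% of differential vs %.1f%% of non-differential peaks (p = %.3g, OR = %.2f)\n",
            100 * enrich$table[1, 1] / sum(enrich$table[1, ]),
            100 * enrich$table[2, 1] / sum(enrich$table[2, ]),
            enrich$p, enrich$or))
data.table::fwrite(
  data.frame(cell = c("diff_distal", "diff_proximal", "nondiff_distal",
                      "nondiff_proximal"),
             count = as.integer(t(enrich$table)), p = enrich$p, or = enrich$or),
  file.path(outdir, "distal_enrichment.tsv"), sep = "\t")

seed <- as.integer(readLines(file.path(indir, "seed.txt")))
spec <- simulation_spec(seed = seed)
truth <- data.table::fread(file.path(indir, "truth_atac.tsv"), data.table = FALSE)
track <- generate_conservation(spec, generate_annotation(spec), truth)
for (grp in c("differential", "nondifferential")) {
  sel <- if (grp == "differential") diff_any else !diff_any
  prof <- conservation_profile(consensus[sel], track,
                               cfg$conservation_halfwidth_bp,
                               cfg$conservation_bin_bp)
  data.table::fwrite(prof, file.path(outdir, sprintf("conservation_profile_%s.tsv", grp)),
                     sep = "\t")
}
cat("conservation profiles written (200 bins per group)\n")
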