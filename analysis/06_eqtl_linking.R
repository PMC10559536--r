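#!/usr/bin/env Rscript
# Stage 6: link consensus peaks to eGenes through the most significant
# in-peak eQTL (p < 1e-5), correlate differential-peak ATAC change with
# eGene expression change (IFNG vs UT), and test whether IFNG lead eQTLs
# are enriched among IFNG differential-peak / DE-gene links relative to
# LPS24 leads (two-tailed Fisher exact test, conditional-MLE OR).

suppressMessages(library(ernalink))
indir <- "results/simulated"
outdir <- "results"
cfg <- pipeline_config()
focal <- "IFNG"; reference <- "LPS24"

consensus <- read_bed(file.path(outdir, "consensus_peaks.bed"))
eqtl <- read_eqtl_tsv(file.path(indir, "eqtl.tsv"))
links <- assign_egenes(consensus, eqtl, cfg$eqtl_p_threshold)
data.table::fwrite(links, file.path(outdir, "egene_links.tsv"), sep = "\t")

atac <- data.table::fread(file.path(outdir, sprintf("differential_atac_%s_vs_UT.tsv", focal)),
                          data.table = FALSE)
rna <- data.table::fread(file.path(outdir, sprintf("differential_rna_%s_vs_UT.tsv", focal)),
                         data.table = FALSE)
conc <- atac_egene_concordance(links, atac, rna)
cat(sprintf("ATAC-eGene concordance (%s vs UT): r = %.3f over %d links\n",
            focal, conc$r, conc$n))

context <- context_specific_enrichment(
  links, eqtl,
  diff_peak_ids = atac$feature_id[atac$is_differential],
  de_gene_ids = rna$feature_id[rna$is_differential],
  focal_condition = focal, reference_conditions = reference
)
cat(sprintf("context specificity: %.1f%% of %s leads vs %.1f%% of %s leads in matched set (p = %.3g, OR = %s)\n",
            100 * context$prop_focal, focal, 100 * context$prop_reference,
            reference, context$p, format(context$or, digits = 3)))
data.table::fwrite(
  data.frame(cell = c("focal_in_set", "focal_out", "reference_in_set",
                      "reference_out"),
             count = as.integer(t(context$table)),
             p = context$p, or = context$or,
             concordance_r = conc$r, concordance_n = conc$n),
  file.path(outdir, "context_enrichment.tsv"), sep = "\t")
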