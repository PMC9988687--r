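#!/usr/bin/env Rscript
# Probe-to-transcript overlap analysis on the toy transcriptome: for each
# gene, match the microarray probe and the qRT-PCR amplicon against the
# spliced transcript set, aggregate TPM over each match set, and quantify
# cross-platform concordance.

suppressPackageStartupMessages(library(gepbridge))

tx <- generate_transcriptome(n_samples = 24, seed = 20260921)
genes <- unique(tx$probes$gene)

report <- do.call(rbind, lapply(genes, function(g) {
  pa <- tx$probes[tx$probes$gene == g & tx$probes$platform == "microarray", ]
  pb <- tx$probes[tx$probes$gene == g & tx$probes$platform == "qrt-pcr", ]
  ma <- match_probe(pa$sequence, tx$transcripts, pa$probe_id, "microarray")
  mb <- match_probe(pb$sequence, tx$transcripts, pb$probe_id, "qrt-pcr")
  set_a <- unique(ma$matches$transcript_id)
  set_b <- unique(mb$matches$transcript_id)
  agg_a <- aggregate_probe_tpm(ma, tx$tpm)
  agg_b <- aggregate_probe_tpm(mb, tx$tpm)
  conc <- platform_concordance(agg_a, agg_b)
  data.frame(gene = g, n_matched_array = length(set_a),
             n_matched_pcr = length(set_b),
             jaccard = length(intersect(set_a, set_b)) /
               length(union(set_a, set_b)),
             r_squared = round(conc$r_squared, 4),
             p = signif(conc$p_value, 3),
             intronless = pb$intronless, spans_junction = pb$spans_junction)
}))

dir.create("results", showWarnings = FALSE)
write.table(report, "results/transcript_overlap.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(report, row.names = FALSE)
cat("\nIdentical match sets give R^2 = 1; platform-exclusive isoform",
    "matches (GENEB) degrade concordance.\n")
cat("Report written to results/transcript_overlap.tsv\n")
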