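#!/usr/bin/env Rscript
# The bridging analysis proper, on the simulated cohort from 01_simulate.R:
# RIN quality filter, delta-Ct against the two reference genes, unstable-
# target exclusion, bridge regressions, classifier reweighting, leave-one-
# out cross-validated ROC, per-condition score summaries, and the RIN bias
# check on the excluded stratum.

suppressPackageStartupMessages(library(gepbridge))

indir <- "results/sim"
if (!file.exists(file.path(indir, "ct.tsv")))
  stop("run analysis/01_simulate.R first")

expr <- read_expression(file.path(indir, "expression.tsv"),
                        file.path(indir, "meta.tsv"))
ct <- read_ct(file.path(indir, "ct.tsv"))
pair <- cohort_pair(expr, ct)
original <- kids_gep_model("original")
probe_map <- kids_gep_probe_map()

# delta-Ct and unstable-target bookkeeping (all paired samples)
dct <- compute_delta_ct(ct, "AURKAIP1", "SSU72")
stab <- assess_stability(dct)
included <- stab$target[stab$included]
cat("Included delta-Ct features:", length(included),
    "(excluded:", paste(stab$target[!stab$included], collapse = ", "), ")\n")

# headline analysis uses the high-quality stratum only
keep <- intersect(filter_rin(ct), rownames(dct$delta_ct))
cat("Samples with RIN > 8:", length(keep), "of", length(pair$pairing), "\n")
x_tgt <- dct$delta_ct[keep, included]
x_src <- expr$values[keep, ]

br <- suppressWarnings(fit_bridge(x_src, x_tgt))
bridge_report <- data.frame(probe = br$source_features,
                            gene = probe_map$gene[match(br$source_features,
                                                        probe_map$probe)],
                            r_squared = round(unname(br$r_squared), 3))
write.table(bridge_report, "results/bridge_report.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
kids_gep <- reweight(original, br)
write_classifier(kids_gep, "results/kids_gep_refit.json")

complete <- rownames(x_tgt)[complete.cases(x_tgt) & complete.cases(x_src)]
cv <- suppressWarnings(loocv(x_src[complete, ], x_tgt[complete, ], original))
cond <- expr$condition[complete]

# ROC: KD vs febrile conditions, healthy controls excluded
roc_keep <- cond != "HC"
r_cv <- roc_metrics(cv$oof_scores[roc_keep], cond[roc_keep])
r_orig <- roc_metrics(cv$original_scores[roc_keep], cond[roc_keep])
cat(sprintf("Cross-validated bridged AUC: %.3f [%.3f-%.3f]\n",
            r_cv$auc, r_cv$ci["low"], r_cv$ci["high"]))
cat(sprintf("Original-model AUC:          %.3f [%.3f-%.3f]\n",
            r_orig$auc, r_orig$ci["low"], r_orig$ci["high"]))
cat(sprintf("Bridged Youden point: threshold %.2f, sens %.2f, spec %.2f\n",
            r_cv$youden$threshold, r_cv$youden$sensitivity,
            r_cv$youden$specificity))

cs <- condition_summaries(cv$oof_scores, cond)
print(cs, digits = 4)

# RIN bias: score every paired sample (including the excluded stratum) with
# the refit bridged model and compare KD scores across RIN strata
all_complete <- rownames(dct$delta_ct)[complete.cases(dct$delta_ct[, included])]
all_scores <- score(kids_gep, dct$delta_ct[all_complete, included])
kd <- expr$condition[all_complete] == "KD"
bias <- rin_bias_test(all_scores[kd], ct$rin[all_complete][kd])
cat(sprintf("RIN bias (KD, low vs high stratum): p = %.3f (%s; n = %d vs %d)\n",
            bias$p_value, bias$method, bias$n_low, bias$n_high))

out <- list(
  n_paired = length(pair$pairing), n_rin_pass = length(keep),
  included_features = included,
  auc_cv = r_cv$auc, auc_cv_ci = unname(r_cv$ci),
  auc_original = r_orig$auc, auc_original_ci = unname(r_orig$ci),
  youden = r_cv$youden,
  condition_summaries = cs,
  rin_bias_p = bias$p_value)
jsonlite::write_json(out, "results/cv_summary.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
write.table(data.frame(sample = complete, condition = cond,
                       score_bridged_cv = unname(cv$oof_scores),
                       score_original = unname(cv$original_scores)),
            "results/cv_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Wrote results/cv_summary.json, results/cv_scores.tsv,",
    "results/bridge_report.tsv\n")
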