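#!/usr/bin/env Rscript
# Therapy: (a) paired pre/post-treatment comparison of scores -- a working
# therapy pulls the progenitor program down; (b) drug-sensitivity screen --
# Spearman correlation of score with each drug's dose-response AUC (higher
# AUC = more resistant), BH-adjusted across drugs.
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE))), "00_common.R"))

pre <- utils::read.table(file.path(score_dir, "treatment_pre_scores.tsv"),
                         header = TRUE, sep = "\t", stringsAsFactors = FALSE)
post <- utils::read.table(file.path(score_dir, "treatment_post_scores.tsv"),
                          header = TRUE, sep = "\t", stringsAsFactors = FALSE)
tr <- monitor_treatment(pre, post)
cat(sprintf("paired signed-rank p = %.3g %s; median ES change = %.1f (%d pairs)\n",
            tr$p, p_stars(tr$p), tr$median_change, tr$n_pairs))
write_tsv(data.frame(p = tr$p, median_change = tr$median_change,
                     n_pairs = tr$n_pairs, decreased = tr$decreased),
          file.path(report_dir, "treatment.tsv"))

# cell-line screen: score a fresh line panel, simulate its drug AUCs
lines <- sim_expression(sim_config(n_per_arm = 50, delta = 1, seed = sub_seed(61L)))
lsc <- score_matrix(lines$matrix, lines$set)
dr <- sim_drug_response(lsc$nes, sim_config(drug_slope = 2, drug_noise = 0.2,
                                            seed = sub_seed(62L)))
write_tsv(cbind(cell_line = rownames(dr$auc), dr$auc),
          file.path(sim_dir, "drug_auc.tsv"))
scr <- screen_drug_correlations(lsc, dr$auc)
cat(sprintf("drugs flagged at FDR < 0.05: %d of %d (%d truly associated)\n",
            sum(scr$flagged), nrow(scr), sum(dr$truth)))
cat(sprintf("power on true drugs: %.2f; false flags: %d\n",
            mean(scr$flagged[dr$truth[scr$drug]]),
            sum(scr$flagged & !dr$truth[scr$drug])))
write_tsv(scr, file.path(report_dir, "drug_screen.tsv"))
write_manifest(report_dir, stage = "treatment_drugs", seed = SEED)
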