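#!/usr/bin/env Rscript
# Diagnosis: can the score separate tumours from normals? Rank-sum test
# plus ROC/AUROC on the scored tumour/normal cohort.
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE))), "00_common.R"))

sc <- utils::read.table(file.path(score_dir, "diagnosis_matrix_scores.tsv"),
                        header = TRUE, sep = "\t", stringsAsFactors = FALSE)
labels <- utils::read.table(file.path(sim_dir, "diagnosis_labels.tsv"),
                            header = TRUE, sep = "\t", stringsAsFactors = FALSE)
stopifnot(identical(sc$sample_id, labels$sample_id))

rep_ <- diagnose_groups(sc, labels$label)
cat(sprintf("tumour median %.3f vs normal median %.3f (NES)\n",
            rep_$medians["tumour"], rep_$medians["normal"]))
cat(sprintf("rank-sum p = %.3g (%s), AUROC = %.3f, direction ok: %s\n",
            rep_$ranksum_p, p_stars(rep_$ranksum_p), rep_$auroc,
            rep_$direction_ok))

write_tsv(data.frame(metric = c("auroc", "ranksum_p", "median_tumour",
                                "median_normal"),
                     value = c(rep_$auroc, rep_$ranksum_p,
                               rep_$medians["tumour"], rep_$medians["normal"])),
          file.path(report_dir, "diagnosis.tsv"))
write_tsv(data.frame(threshold = rep_$roc$thresholds,
                     sensitivity = rep_$roc$sensitivity,
                     specificity = rep_$roc$specificity),
          file.path(report_dir, "diagnosis_roc.tsv"))
write_manifest(report_dir, stage = "diagnose", seed = SEED,
               inputs = file.path(score_dir, "diagnosis_matrix_scores.tsv"))
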