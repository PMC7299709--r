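#!/usr/bin/env Rscript
# Grading: does the score rise with tumour grade? Per-grade medians, all
# pairwise rank-sum tests with the star convention, and the Spearman trend.
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE))), "00_common.R"))

sc <- utils::read.table(file.path(score_dir, "graded_matrix_scores.tsv"),
                        header = TRUE, sep = "\t", stringsAsFactors = FALSE)
grades <- utils::read.table(file.path(sim_dir, "graded_labels.tsv"),
                            header = TRUE, sep = "\t", stringsAsFactors = FALSE)
stopifnot(identical(sc$sample_id, grades$sample_id))

rep_ <- grade_trend(sc, factor(grades$grade, ordered = TRUE))
cat("median NES by grade:",
    paste(sprintf("%s=%.3f", names(rep_$medians), rep_$medians),
          collapse = ", "), "\n")
cat(sprintf("monotone increase: %s; Spearman trend rho = %.3f\n",
            all(diff(rep_$medians) > 0), rep_$trend_rho))
print(rep_$pairwise, row.names = FALSE)

write_tsv(data.frame(grade = names(rep_$medians), median = rep_$medians),
          file.path(report_dir, "grade_medians.tsv"))
write_tsv(rep_$pairwise, file.path(report_dir, "grade_pairwise.tsv"))
write_manifest(report_dir, stage = "grade", seed = SEED,
               inputs = file.path(score_dir, "graded_matrix_scores.tsv"))
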