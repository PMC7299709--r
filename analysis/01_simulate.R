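#!/usr/bin/env Rscript
# Generate every synthetic cohort the downstream stages analyse: a
# tumour/normal cohort, a graded cohort, a large prognosis cohort, paired
# pre/post-treatment profiles, and a drug-response screen. All draws flow
# from the single --seed.
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE))), "00_common.R"))

cfg_diag <- sim_config(seed = sub_seed(1L))
diag <- sim_expression(cfg_diag)
write_expression_matrix(diag$matrix, file.path(sim_dir, "diagnosis_matrix.tsv"))
write_tsv(data.frame(sample_id = colnames(diag$matrix), label = diag$labels),
          file.path(sim_dir, "diagnosis_labels.tsv"))
write_gmt(diag$set, file.path(sim_dir, "signature.gmt"))
cat("diagnosis cohort:", ncol(diag$matrix), "samples,",
    nrow(diag$matrix), "genes\n")

grd <- sim_graded(sim_config(seed = sub_seed(2L)))
write_expression_matrix(grd$matrix, file.path(sim_dir, "graded_matrix.tsv"))
write_tsv(data.frame(sample_id = colnames(grd$matrix), grade = grd$grades),
          file.path(sim_dir, "graded_labels.tsv"))
cat("graded cohort:", ncol(grd$matrix), "samples over",
    nlevels(grd$grades), "grades\n")

prog <- sim_expression(sim_config(n_per_arm = 1000, delta = 1,
                                  seed = sub_seed(3L)))
write_expression_matrix(prog$matrix, file.path(sim_dir, "prognosis_matrix.tsv"))
cat("prognosis cohort:", ncol(prog$matrix), "samples\n")

pt <- sim_paired_treatment(sim_config(seed = sub_seed(4L)), dose = 1)
write_expression_matrix(pt$pre, file.path(sim_dir, "treatment_pre.tsv"))
write_expression_matrix(pt$post, file.path(sim_dir, "treatment_post.tsv"))
cat("treatment cohort:", length(pt$pairing), "pairs\n")

write_manifest(sim_dir, stage = "simulate",
               params = list(designs = c("diagnosis", "graded", "prognosis",
                                         "treatment")),
               seed = SEED)
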