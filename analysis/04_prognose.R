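#!/usr/bin/env Rscript
# Prognosis: survival simulated from the scored cohort under a unit
# log-hazard per NES, then analysed blind to the generator -- univariate
# and covariate-adjusted Cox, and the median-split Kaplan-Meier log-rank.
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE))), "00_common.R"))

sc <- utils::read.table(file.path(score_dir, "prognosis_matrix_scores.tsv"),
                        header = TRUE, sep = "\t", stringsAsFactors = FALSE)
surv <- sim_survival(sc$nes, sim_config(surv_beta = 1, seed = sub_seed(31L)),
                     covariates = TRUE)
write_tsv(surv, file.path(sim_dir, "prognosis_survival.tsv"))

rep_ <- evaluate_prognosis(sc, surv, adjust = c("age", "gender", "grade"))
cat(sprintf("unadjusted: HR/unit = %.3g (95%% CI %.3g-%.3g), p = %.3g, n = %d\n",
            rep_$cox$hr, rep_$cox$ci95[1], rep_$cox$ci95[2], rep_$cox$p,
            rep_$cox$n))
cat(sprintf("            HR per +0.1 = %.3f, per +1 SD = %.3f\n",
            rep_$cox$hr_per_0.1, rep_$cox$hr_per_sd))
cat(sprintf("adjusted:   HR/unit = %.3g, p = %.3g\n",
            rep_$cox_adjusted$hr, rep_$cox_adjusted$p))
cat(sprintf("log-rank (median split): chi2 = %.1f, p = %.3g %s\n",
            rep_$km$logrank_chi2, rep_$km$logrank_p,
            p_stars(rep_$km$logrank_p)))

write_tsv(data.frame(
  model = c("unadjusted", "adjusted"),
  beta = c(rep_$cox$beta, rep_$cox_adjusted$beta),
  hr = c(rep_$cox$hr, rep_$cox_adjusted$hr),
  ci_low = c(rep_$cox$ci95[1], rep_$cox_adjusted$ci95[1]),
  ci_high = c(rep_$cox$ci95[2], rep_$cox_adjusted$ci95[2]),
  p = c(rep_$cox$p, rep_$cox_adjusted$p),
  n = c(rep_$cox$n, rep_$cox_adjusted$n)),
  file.path(report_dir, "prognosis_cox.tsv"))
write_tsv(data.frame(logrank_chi2 = rep_$km$logrank_chi2,
                     logrank_p = rep_$km$logrank_p),
          file.path(report_dir, "prognosis_logrank.tsv"))
write_manifest(report_dir, stage = "prognose", seed = SEED,
               inputs = file.path(score_dir, "prognosis_matrix_scores.tsv"))
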