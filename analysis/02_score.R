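#!/usr/bin/env Rscript
# Score every simulated cohort with the signature: rank-normalized
# single-sample enrichment (alpha = 0.25), batch-range NES within each
# cohort; raw ES only for the paired design, whose comparison must not
# depend on a per-batch range.
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE))), "00_common.R"))

set <- read_gmt(file.path(sim_dir, "signature.gmt"))[[1]]

score_file <- function(stem, params = scoring_params()) {
  m <- read_expression_matrix(file.path(sim_dir, paste0(stem, ".tsv")))
  m <- collapse_duplicates(m)
  sc <- score_matrix(m, set, params)
  write_tsv(sc, file.path(score_dir, paste0(stem, "_scores.tsv")))
  cat(stem, ": scored", nrow(sc), "samples; ES range",
      sprintf("%.1f .. %.1f", min(sc$es), max(sc$es)), "\n")
  sc
}

invisible(score_file("diagnosis_matrix"))
invisible(score_file("graded_matrix"))
invisible(score_file("prognosis_matrix"))
invisible(score_file("treatment_pre", scoring_params(batch_norm = FALSE)))
invisible(score_file("treatment_post", scoring_params(batch_norm = FALSE)))

write_manifest(score_dir, stage = "score",
               params = list(alpha = 0.25, sample_norm = "rank"),
               inputs = file.path(sim_dir, "signature.gmt"), seed = SEED)
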