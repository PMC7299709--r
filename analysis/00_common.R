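# Shared prologue for the analysis drivers: seed/output parsing and paths.
suppressPackageStartupMessages(library(progenitorness))

.args <- commandArgs(trailingOnly = TRUE)
arg_or <- function(flag, default) {
  i <- which(.args == flag)
  if (length(i) == 1 && i < length(.args)) .args[i + 1] else default
}
SEED <- as.integer(arg_or("--seed", "1"))
OUT <- arg_or("--out", "results")
sim_dir <- file.path(OUT, "sim")
score_dir <- file.path(OUT, "scores")
report_dir <- file.path(OUT, "reports")
for (d in c(sim_dir, score_dir, report_dir)) {
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
}
sub_seed <- function(k) (SEED * 1000L + k) %% .Machine$integer.max

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
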