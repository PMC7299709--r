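#' Significance stars
#'
#' Figure-legend star convention: `*` p < 0.05, `**` p < 0.01,
#' `***` p < 0.001; `"ns"` otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector.
#' @export
p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

score_vector <- function(scores) {
  stopifnot(inherits(scores, "data.frame"), "es" %in% names(scores))
  v <- if ("nes" %in% names(scores)) scores$nes else scores$es
  stats::setNames(v, scores$sample_id)
}

#' Diagnosis stage: tumour versus normal
#'
#' Combines the two-sided rank-sum test with ROC/AUROC on a scored cohort.
#' The expected direction (tumour scores higher) is annotated so a
#' reversed signature is visible at a glance.
#'
#' @param scores A `score_table` from [score_matrix()] (NES used when
#'   present, else raw ES).
#' @param labels Factor or character per sample; `positive` names the
#'   tumour class.
#' @param positive Label of the class expected to score higher.
#' @return List of class `diagnosis_report`: `ranksum_p`, `roc`
#'   (a `roc_result`), `auroc`, `direction_ok`, `medians`.
#' @export
diagnose_groups <- function(scores, labels, positive = "tumour") {
  v <- score_vector(scores)
  labels <- as.character(labels)
  stopifnot(length(v) == length(labels))
  if (length(unique(labels)) != 2L) {
    stop("diagnosis needs exactly two classes; got: ",
         paste(unique(labels), collapse = ", "))
  }
  if (!positive %in% labels) stop("positive class absent: ", positive)
  pos <- labels == positive
  rs <- rank_sum_test(v[pos], v[!pos])
  roc <- roc_auroc(v, pos)
  medians <- tapply(v, labels, stats::median)
  structure(list(ranksum_p = rs$p, roc = roc, auroc = roc$auroc,
                 direction_ok = unname(medians[positive] == max(medians)),
                 medians = medians),
            class = "diagnosis_report")
}

#' Prognosis stage: Cox regression and median-split Kaplan-Meier
#'
#' Fits the unadjusted Cox model of survival on the score, the adjusted
#' model when covariates are requested, and the median-split Kaplan-Meier
#' comparison with the log-rank test.
#'
#' @param scores A `score_table`.
#' @param surv Survival data.frame (`time`, `event`, covariates), rows
#'   aligned with `scores`.
#' @param adjust Optional character vector of covariate columns.
#' @return List of class `prognosis_report`: `cox` (a `cox_result`),
#'   `cox_adjusted` (or `NULL`), `km` (a `km_result`).
#' @export
evaluate_prognosis <- function(scores, surv, adjust = NULL) {
  v <- score_vector(scores)
  structure(list(cox = cox_fit(v, surv),
                 cox_adjusted = if (length(adjust) > 0) cox_fit(v, surv, adjust),
                 km = km_logrank(v, surv)),
            class = "prognosis_report")
}

#' Grading stage: score distribution across ordered grades
#'
#' Per-grade medians, all pairwise two-sided rank-sum tests with the star
#' convention, and the Spearman trend of score against grade order. A
#' single grade level yields medians only.
#'
#' @param scores A `score_table`.
#' @param grades Ordered factor (or coercible) per sample.
#' @return List of class `grade_report`: `medians`, `pairwise`
#'   (data.frame: grade_a, grade_b, p, stars), `trend_rho`.
#' @export
grade_trend <- function(scores, grades) {
  v <- score_vector(scores)
  grades <- as.factor(grades)
  stopifnot(length(v) == length(grades))
  lvls <- levels(droplevels(grades))
  medians <- tapply(v, grades, stats::median)[lvls]
  pairwise <- NULL
  trend_rho <- NA_real_
  if (length(lvls) > 1L) {
    combs <- utils::combn(lvls, 2L)
    pairwise <- do.call(rbind, lapply(seq_len(ncol(combs)), function(k) {
      a <- combs[1L, k]; b <- combs[2L, k]
      p <- rank_sum_test(v[grades == a], v[grades == b])$p
      data.frame(grade_a = a, grade_b = b, p = p, stars = p_stars(p),
                 stringsAsFactors = FALSE)
    }))
    trend_rho <- stats::cor(v, as.integer(grades), method = "spearman")
  }
  structure(list(medians = medians, pairwise = pairwise, trend_rho = trend_rho),
            class = "grade_report")
}

#' Treatment-monitoring stage: paired pre/post comparison
#'
#' Paired signed-rank test of post- versus pre-treatment scores of the same
#' subjects, reporting the direction (a working therapy lowers the score).
#'
#' @param pre_scores,post_scores `score_table`s over the same subjects;
#'   rows matched by `sample_id`.
#' @return List of class `treatment_report`: `p`, `median_change`,
#'   `decreased`, `n_pairs`.
#' @export
monitor_treatment <- function(pre_scores, post_scores) {
  pre <- score_vector(pre_scores)
  post <- score_vector(post_scores)
  common <- intersect(names(pre), names(post))
  if (length(common) < 1L) stop("no shared sample IDs between pre and post")
  pre <- pre[common]; post <- post[common]
  sr <- signed_rank_test(pre, post)
  chg <- stats::median(post - pre)
  structure(list(p = sr$p, median_change = chg, decreased = chg < 0,
                 n_pairs = sr$n_pairs_used),
            class = "treatment_report")
}

#' Drug-correlation stage
#'
#' Spearman screen of score against every drug's dose-response AUC with BH
#' FDR (see [spearman_screen()]); a thin stage wrapper that accepts a
#' `score_table` directly.
#'
#' @param scores A `score_table`.
#' @param auc Cell lines x drugs AUC table, rows aligned with `scores`.
#' @param fdr_cutoff Discovery threshold (default 0.05).
#' @return A `correlation_screen` data.frame.
#' @export
screen_drug_correlations <- function(scores, auc, fdr_cutoff = 0.05) {
  spearman_screen(score_vector(scores), auc, fdr_cutoff = fdr_cutoff)
}

#' Write a run manifest
#'
#' Records what produced an output directory: the stage name, parameters,
#' input-file MD5 digests, package version, seed and timestamp, so a run
#' can be audited and reproduced. One manifest per output directory.
#'
#' @param out_dir Output directory (created if needed).
#' @param stage Stage name.
#' @param params Named list of parameters (must be JSON-representable).
#' @param inputs Character vector of input file paths to digest.
#' @param seed The run seed.
#' @return Path to the written `manifest.json`, invisibly.
#' @export
write_manifest <- function(out_dir, stage, params = list(), inputs = character(),
                           seed = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  digests <- if (length(inputs) > 0) {
    as.list(tools::md5sum(inputs))
  } else NULL
  manifest <- list(
    stage = stage,
    parameters = params,
    input_md5 = digests,
    package_version = as.character(utils::packageVersion("progenitorness")),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' @export
#' @method print diagnosis_report
print.diagnosis_report <- function(x, ...) {
  cat(sprintf("Diagnosis: AUROC = %.3f, rank-sum p = %.3g %s\n",
              x$auroc, x$ranksum_p, p_stars(x$ranksum_p)))
  cat("  median score by class:",
      paste(sprintf("%s = %.3f", names(x$medians), x$medians), collapse = ", "),
      "\n")
  cat("  expected direction (positive class highest):",
      if (x$direction_ok) "yes" else "NO", "\n")
  invisible(x)
}

#' @export
#' @method print grade_report
print.grade_report <- function(x, ...) {
  cat("Grade trend: median score by grade:",
      paste(sprintf("%s = %.3f", names(x$medians), x$medians), collapse = ", "),
      "\n")
  if (!is.null(x$pairwise)) {
    cat(sprintf("  Spearman trend rho = %.3f; pairwise rank-sum tests:\n",
                x$trend_rho))
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

#' @export
#' @method print treatment_report
print.treatment_report <- function(x, ...) {
  cat(sprintf("Treatment response: signed-rank p = %.3g %s over %d pairs\n",
              x$p, p_stars(x$p), x$n_pairs))
  cat(sprintf("  median score change = %.3g (%s)\n", x$median_change,
              if (x$decreased) "decrease" else "no decrease"))
  invisible(x)
}
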