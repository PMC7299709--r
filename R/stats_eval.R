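#' Two-sample Wilcoxon rank-sum test
#'
#' Two-sided test that two groups of scores come from the same distribution.
#' Exact enumeration when the combined sample size is at most 20 and there
#' are no ties; otherwise the normal approximation with tie and continuity
#' corrections.
#'
#' @param group_a,group_b Numeric score vectors (both non-empty).
#' @return List with `statistic` (W), `p`, and `method`.
#' @export
rank_sum_test <- function(group_a, group_b) {
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop("both groups must be non-empty")
  }
  pooled <- c(group_a, group_b)
  exact <- (length(pooled) <= 20L) && !anyDuplicated(pooled)
  ht <- stats::wilcox.test(group_a, group_b, alternative = "two.sided",
                           exact = exact, correct = TRUE)
  list(statistic = unname(ht$statistic), p = ht$p.value,
       method = if (exact) "exact" else "normal approximation")
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided test on paired (pre, post) scores. Zero differences are
#' dropped with a warning; all-zero differences are a degenerate pairing
#' and an error. Exact for 15 or fewer informative pairs without tied
#' absolute differences, otherwise the normal approximation.
#'
#' @param pre,post Equal-length paired numeric vectors.
#' @return List with `statistic` (V), `p`, `n_pairs_used`, and `method`.
#' @export
signed_rank_test <- function(pre, post) {
  stopifnot(length(pre) == length(post))
  d <- post - pre
  if (all(d == 0)) stop("degenerate pairing: all paired differences are zero")
  if (any(d == 0)) {
    warning(sum(d == 0), " zero difference(s) dropped")
    keep <- d != 0
    pre <- pre[keep]; post <- post[keep]; d <- d[keep]
  }
  exact <- (length(d) <= 15L) && !anyDuplicated(abs(d))
  ht <- stats::wilcox.test(post, pre, paired = TRUE,
                           alternative = "two.sided",
                           exact = exact, correct = TRUE)
  list(statistic = unname(ht$statistic), p = ht$p.value,
       n_pairs_used = length(d),
       method = if (exact) "exact" else "normal approximation")
}

#' ROC curve and AUROC
#'
#' Sweeps every distinct score as a threshold (call positive when
#' score >= threshold) and integrates the curve by the trapezoid rule. The
#' positive class is the one expected to score higher (tumour, by the
#' direction the signature is built for); the trapezoid area equals the
#' Mann-Whitney U statistic divided by n1*n2 with ties half-credited.
#'
#' @param scores Numeric vector.
#' @param labels Logical (or 0/1) vector; `TRUE` = positive class.
#' @return List of class `roc_result`: `thresholds`, `sensitivity`,
#'   `specificity`, `auroc`, `n_pos`, `n_neg`.
#' @export
roc_auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  thresholds <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(thresholds, function(t) sum(scores[labels] >= t) / n_pos, 0)
  spec <- vapply(thresholds, function(t) sum(scores[!labels] < t) / n_neg, 0)
  fpr <- 1 - spec
  auroc <- sum(diff(fpr) * (sens[-1] + sens[-length(sens)]) / 2)
  structure(list(thresholds = thresholds, sensitivity = sens,
                 specificity = spec, auroc = auroc,
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' Cox proportional-hazards fit of a score
#'
#' Fits `Surv(time, event) ~ score (+ covariates)` by partial likelihood
#' with the Efron tie correction, optionally adjusted for covariates
#' (complete cases only; the drop is logged). Categorical covariates are
#' dummy-coded against the first level by sorted label. Because the score
#' lives on a unit-ish scale, the hazard ratio per +1.0 score can be
#' astronomically large; HR per +0.1 and per +1 SD are reported alongside.
#'
#' @param score Numeric vector, one value per sample.
#' @param surv Data.frame with columns `time` (>= 0) and `event` (logical or
#'   0/1), plus any covariate columns, rows aligned with `score`.
#' @param adjust Character vector of covariate column names, or `NULL`.
#' @return List of class `cox_result`: `beta`, `hr`, `ci95`, `p`, `n`,
#'   `n_events`, `hr_per_0.1`, `hr_per_sd`, and the `fit` object.
#' @export
cox_fit <- function(score, surv, adjust = NULL) {
  stopifnot(is.data.frame(surv), all(c("time", "event") %in% names(surv)),
            length(score) == nrow(surv), all(surv$time >= 0, na.rm = TRUE))
  df <- data.frame(time = surv$time, event = as.integer(as.logical(surv$event)),
                   score = score)
  for (v in adjust) {
    if (!v %in% names(surv)) stop("covariate not found: ", v)
    col <- surv[[v]]
    if (!is.numeric(col)) {
      col <- factor(as.character(col), levels = sort(unique(as.character(col[!is.na(col)]))))
    }
    df[[v]] <- col
  }
  cc <- stats::complete.cases(df)
  if (sum(!cc) > 0) {
    message("dropped ", sum(!cc), " incomplete case(s); n = ", sum(cc))
  }
  df <- df[cc, , drop = FALSE]
  if (sum(df$event) < 2L) stop("need at least 2 observed events")
  if (stats::sd(df$score) == 0) stop("degenerate covariate: score is constant")
  rhs <- paste(c("score", adjust), collapse = " + ")
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~", rhs))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = "efron"),
    warning = function(w) {
      if (grepl("Ran out of iterations|did not converge", conditionMessage(w))) {
        stop("Cox fit did not converge: ", conditionMessage(w))
      }
    })
  beta <- unname(stats::coef(fit)["score"])
  se <- sqrt(diag(fit$var))[which(names(stats::coef(fit)) == "score")]
  z <- stats::qnorm(0.975)
  ci <- exp(beta + c(-1, 1) * z * se)
  structure(list(beta = beta, hr = exp(beta), ci95 = ci,
                 p = 2 * stats::pnorm(-abs(beta / se)),
                 n = nrow(df), n_events = sum(df$event),
                 hr_per_0.1 = exp(beta * 0.1),
                 hr_per_sd = exp(beta * stats::sd(df$score)),
                 fit = fit),
            class = "cox_result")
}

#' Kaplan-Meier curves with a median-split log-rank test
#'
#' Dichotomizes the cohort at the median score (samples exactly at the
#' median go to the low group, deterministically), estimates the
#' product-limit survival curve per arm, and compares the arms with the
#' two-group log-rank test (1 df).
#'
#' @param score Numeric vector.
#' @param surv Data.frame with `time` and `event`, rows aligned with `score`.
#' @return List of class `km_result`: `group` (factor low/high), `fit`
#'   (a `survfit` object), `logrank_chi2`, `logrank_p`.
#' @export
km_logrank <- function(score, surv) {
  stopifnot(is.data.frame(surv), all(c("time", "event") %in% names(surv)),
            length(score) == nrow(surv))
  med <- stats::median(score)
  group <- factor(ifelse(score <= med, "low", "high"), levels = c("low", "high"))
  if (any(table(group) == 0)) stop("median split leaves an empty group")
  df <- data.frame(time = surv$time, event = as.integer(as.logical(surv$event)),
                   group = group)
  if (sum(df$event) < 1L) stop("no observed events")
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  chi2 <- unname(sd_$chisq)
  structure(list(group = group, fit = fit, logrank_chi2 = chi2,
                 logrank_p = stats::pchisq(chi2, df = 1L, lower.tail = FALSE)),
            class = "km_result")
}

#' Spearman correlation screen with BH FDR
#'
#' Correlates a score with each drug's dose-response AUC (higher AUC = more
#' resistant) over pairwise-complete observations, computes two-sided
#' p-values from the t-approximation, and adjusts across drugs by
#' Benjamini-Hochberg. Drugs with fewer than 3 complete pairs are dropped
#' with a warning.
#'
#' @param score Numeric vector, one value per sample/cell line.
#' @param responses Numeric matrix or data.frame, samples x drugs.
#' @param fdr_cutoff Discovery threshold on the adjusted p (default 0.05).
#' @return Data.frame of class `correlation_screen`: `drug`, `rho`, `p`,
#'   `fdr`, `n`, `flagged`.
#' @export
spearman_screen <- function(score, responses, fdr_cutoff = 0.05) {
  responses <- as.data.frame(responses)
  stopifnot(length(score) == nrow(responses))
  res <- lapply(names(responses), function(drug) {
    y <- responses[[drug]]
    ok <- !is.na(score) & !is.na(y)
    if (sum(ok) < 3L) return(NULL)
    ht <- suppressWarnings(
      stats::cor.test(score[ok], y[ok], method = "spearman", exact = FALSE))
    data.frame(drug = drug, rho = unname(ht$estimate), p = ht$p.value,
               n = sum(ok), stringsAsFactors = FALSE)
  })
  dropped <- names(responses)[vapply(res, is.null, TRUE)]
  if (length(dropped) > 0) {
    warning(length(dropped), " drug(s) dropped (fewer than 3 complete pairs): ",
            paste(utils::head(dropped, 5L), collapse = ", "))
  }
  out <- do.call(rbind, res[!vapply(res, is.null, TRUE)])
  if (is.null(out) || nrow(out) == 0) stop("no drug has 3 or more complete pairs")
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out$flagged <- out$fdr < fdr_cutoff
  rownames(out) <- NULL
  class(out) <- c("correlation_screen", "data.frame")
  out
}

#' @export
#' @method print cox_result
print.cox_result <- function(x, ...) {
  cat(sprintf("Cox PH: HR per +1 score = %.3g (95%% CI %.3g-%.3g), p = %.3g\n",
              x$hr, x$ci95[1], x$ci95[2], x$p))
  cat(sprintf("  per +0.1 = %.3f, per +1 SD = %.3f; n = %d (%d events)\n",
              x$hr_per_0.1, x$hr_per_sd, x$n, x$n_events))
  invisible(x)
}

#' @export
#' @method print km_result
print.km_result <- function(x, ...) {
  cat(sprintf("Kaplan-Meier (median split): log-rank chi2 = %.3g, p = %.3g %s\n",
              x$logrank_chi2, x$logrank_p, p_stars(x$logrank_p)))
  cat("  arm sizes:", paste(sprintf("%s = %d", names(table(x$group)),
                                    table(x$group)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
#' @method print roc_result
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUROC = %.3f (%d positives, %d negatives, %d thresholds)\n",
              x$auroc, x$n_pos, x$n_neg, length(x$thresholds)))
  invisible(x)
}
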