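test_that("rank-sum test: exact small-sample p-values and degenerate cases", {
  rs <- rank_sum_test(c(1, 2), c(3, 4))
  expect_equal(rs$p, 1 / 3, tolerance = 1e-12) # 2 of C(4,2)=6 assignments
  expect_identical(rs$method, "exact")
  same <- rank_sum_test(c(1, 2, 3), c(1, 2, 3))
  expect_gte(same$p, 0.99)
  expect_lt(rank_sum_test(1:20, 31:50)$p, 0.001)
  expect_error(rank_sum_test(numeric(0), 1:3), "non-empty")
})

test_that("rank-sum exact and approximate branches agree near the crossover", {
  set.seed(61)
  for (rep in 1:20) {
    a <- rnorm(10); b <- rnorm(10, 0.5)
    p_exact <- rank_sum_test(a, b)$p # n = 20, no ties -> exact
    p_approx <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
    # the normal approximation tracks the exact law in the body of the
    # distribution; its relative error grows in the far tail, so the
    # agreement property is asserted for non-extreme p
    if (p_exact >= 0.05) expect_lt(abs(p_exact - p_approx) / p_exact, 0.10)
    else expect_lt(abs(p_exact - p_approx), 0.005)
  }
})

test_that("signed-rank test: exact enumeration, zero-diff handling, symmetry", {
  pre <- c(5, 6, 7, 8, 9, 10)
  post <- pre - c(0.5, 1, 1.5, 2, 2.5, 3) # uniformly decreased, distinct |d|
  sr <- signed_rank_test(pre, post)
  expect_equal(sr$p, 2 / 64, tolerance = 1e-12) # both tails of 2^6 sign flips
  expect_identical(sr$method, "exact")

  expect_error(signed_rank_test(pre, pre), "degenerate pairing")
  expect_warning(sz <- signed_rank_test(c(1, 2, 3, 4), c(1, 3, 2, 6)), "dropped")
  expect_identical(sz$n_pairs_used, 3L)
  sym <- signed_rank_test(c(1, 2), c(2, 1)) # diffs +1, -1
  expect_gte(sym$p, 0.99)
})

test_that("ROC sweep gives known areas and the curve runs (0,0) to (1,1)", {
  expect_equal(roc_auroc(c(5, 4, 3, 2, 1), c(1, 1, 1, 0, 0))$auroc, 1)
  expect_equal(roc_auroc(c(3, 1, 2, 0), c(1, 1, 0, 0))$auroc, 0.75)
  expect_equal(roc_auroc(c(2, 2), c(1, 0))$auroc, 0.5)
  r <- roc_auroc(rnorm(20), rep(c(TRUE, FALSE), 10))
  expect_equal(r$sensitivity[1], 0)
  expect_equal(r$sensitivity[length(r$sensitivity)], 1)
  expect_equal(r$specificity[1], 1)
  expect_error(roc_auroc(1:3, c(1, 1, 1)), "both classes")
})

test_that("trapezoid AUROC equals the pairwise U probability to 1e-12", {
  set.seed(71)
  for (rep in 1:200) {
    n1 <- sample(2:15, 1); n0 <- sample(2:15, 1)
    scores <- c(rnorm(n1, 0.3), rnorm(n0))
    if (rep %% 4 == 0) scores <- round(scores) # heavy ties
    labels <- rep(c(TRUE, FALSE), c(n1, n0))
    expect_equal(roc_auroc(scores, labels)$auroc, u_auroc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUROC matches the pROC reference on random data", {
  skip_if_not_installed("pROC")
  set.seed(73)
  scores <- c(rnorm(30, 0.5), rnorm(25))
  labels <- rep(c(1, 0), c(30, 25))
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auroc(scores, labels)$auroc, ref, tolerance = 1e-12)
})

test_that("Cox fit maximizes the partial likelihood (grid-search oracle)", {
  surv <- data.frame(time = c(1, 2, 3, 4), event = c(1, 1, 1, 1))
  z <- c(1, 0, 1, 0)
  fit <- cox_fit(z, surv)
  grid <- seq(-5, 5, by = 1e-3)
  ll <- vapply(grid, cox_pl_loglik, 0, time = surv$time, event = surv$event, z = z)
  expect_equal(fit$beta, grid[which.max(ll)], tolerance = 2e-3)
  expect_equal(fit$hr, exp(fit$beta), tolerance = 1e-12)
  expect_true(fit$ci95[1] < fit$hr && fit$hr < fit$ci95[2])
})

test_that("Cox fit guards: events, convergence inputs, degenerate covariate", {
  surv <- data.frame(time = 1:4, event = c(0, 0, 0, 0))
  expect_error(cox_fit(rnorm(4), surv), "2 observed events")
  surv2 <- data.frame(time = 1:4, event = c(1, 1, 1, 1))
  expect_error(cox_fit(rep(2, 4), surv2), "degenerate covariate")
})

test_that("adjusted Cox drops incomplete cases and dummy-codes factors", {
  set.seed(79)
  n <- 120
  s <- rnorm(n)
  surv <- sim_survival(s, sim_config(surv_beta = 1, seed = 80), covariates = TRUE)
  surv$age[1:5] <- NA
  fit <- suppressMessages(cox_fit(s, surv, adjust = c("age", "gender", "grade")))
  expect_equal(fit$n, n - 5)
  expect_true(all(c("genderM", "gradeG2", "gradeG3") %in%
                    names(coef(fit$fit)))) # first sorted level is reference
})

test_that("KM median split: identical groups give chi2 0; worked example; ties to low", {
  surv <- data.frame(time = c(1, 2, 3, 1, 2, 3), event = rep(1, 6))
  same <- km_logrank(c(1, 1, 1, 2, 2, 2), surv)
  expect_equal(same$logrank_chi2, 0, tolerance = 1e-12)
  expect_gte(same$logrank_p, 0.99)

  # two high-score subjects die first: hand-evaluated log-rank sums give
  # E_high = 1/2 + 1/3 = 5/6, V = 1/4 + 2/9, chi2 = (2 - 5/6)^2 / V = 49/17
  ex <- km_logrank(c(2, 2, 1, 1), data.frame(time = 1:4, event = rep(1, 4)))
  expect_equal(ex$logrank_chi2, 49 / 17, tolerance = 1e-10)

  med <- km_logrank(c(1, 2, 2, 3), data.frame(time = 1:4, event = rep(1, 4)))
  expect_identical(as.vector(table(med$group)), c(3L, 1L)) # ties go low
  expect_error(km_logrank(rep(1, 4), data.frame(time = 1:4, event = rep(1, 4))),
               "empty group")
})

test_that("KM estimate with no censoring equals the empirical survival function", {
  set.seed(83)
  times <- sort(sample(1:50, 20))
  surv <- data.frame(time = times, event = 1)
  km <- km_logrank(rep(c(0, 1), 10), surv)
  sf <- summary(km$fit)
  for (g in c("group=low", "group=high")) {
    grp <- km$group == sub("group=", "", g)
    idx <- sf$strata == g
    emp <- vapply(sf$time[idx], function(t) mean(times[grp] > t), 0)
    expect_equal(unname(sf$surv[idx]), emp, tolerance = 1e-12)
  }
  expect_true(all(diff(sf$surv[sf$strata == "group=low"]) <= 0))
})

test_that("Spearman screen: identity, reversal, BH ties, and pair filtering", {
  set.seed(89)
  s <- rnorm(30)
  resp <- data.frame(up = s, down = -s, noise = rnorm(30),
                     thin = c(s[1:2], rep(NA, 28)))
  expect_warning(out <- spearman_screen(s, resp), "dropped")
  expect_equal(out$rho[out$drug == "up"], 1, tolerance = 1e-12)
  expect_equal(out$rho[out$drug == "down"], -1, tolerance = 1e-12)
  expect_false("thin" %in% out$drug)
  # BH with equal p-values leaves them equal
  p0 <- 0.02
  fdr <- p.adjust(rep(p0, 5), method = "BH")
  expect_true(all(fdr == p0))
})

test_that("BH-adjusted q-values are order-invariant and step-up monotone", {
  set.seed(97)
  s <- rnorm(40)
  resp <- as.data.frame(matrix(rnorm(40 * 25), nrow = 40))
  resp[[1]] <- s + rnorm(40, 0, 0.3)
  out <- spearman_screen(s, resp)
  perm <- sample(ncol(resp))
  out_perm <- spearman_screen(s, resp[, perm])
  merged <- merge(out, out_perm, by = "drug")
  expect_equal(merged$fdr.x, merged$fdr.y, tolerance = 1e-12)
  ord <- order(out$p)
  expect_true(all(diff(out$fdr[ord]) >= -1e-15))
})
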