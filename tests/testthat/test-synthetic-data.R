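small_cfg <- function(...) {
  sim_config(n_genes = 400, set_size = 20, n_per_arm = 25, ...)
}

test_that("every generator is a pure function of its config and seed", {
  cfg <- small_cfg(seed = 5)
  expect_identical(sim_expression(cfg), sim_expression(cfg))
  expect_identical(sim_graded(cfg), sim_graded(cfg))
  s <- seq(-1, 1, length.out = 40)
  expect_identical(sim_survival(s, cfg), sim_survival(s, cfg))
  expect_identical(sim_paired_treatment(cfg), sim_paired_treatment(cfg))
  expect_identical(sim_drug_response(s, cfg), sim_drug_response(s, cfg))
  m <- sim_expression(cfg)$matrix
  expect_identical(sim_dropout(m, 0.3, seed = 6), sim_dropout(m, 0.3, seed = 6))
  # and a different seed actually changes the draw
  cfg2 <- small_cfg(seed = 7)
  expect_false(identical(sim_expression(cfg)$matrix, sim_expression(cfg2)$matrix))
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(sim_expression(small_cfg(seed = 9)))
  expect_identical(.Random.seed, before)
})

test_that("expression generator shifts exactly the signature genes", {
  cfg <- small_cfg(delta = 3, seed = 15)
  sim <- sim_expression(cfg)
  expect_identical(dim(sim$matrix), c(400L, 50L))
  expect_identical(levels(sim$labels), c("normal", "tumour"))
  logm <- log(sim$matrix)
  in_set <- rownames(logm) %in% sim$set$symbols
  tum <- sim$labels == "tumour"
  expect_gt(mean(logm[in_set, tum]) - mean(logm[in_set, !tum]), 2)
  expect_lt(abs(mean(logm[!in_set, tum]) - mean(logm[!in_set, !tum])), 0.2)
  expect_error(sim_expression(sim_config(n_genes = 10, set_size = 11)),
               "set_size exceeds")
})

test_that("null effect gives chance-level separation", {
  cfg <- sim_config(n_genes = 1000, set_size = 50, n_per_arm = 100,
                    delta = 0, seed = 19)
  sim <- sim_expression(cfg)
  sc <- suppressMessages(score_matrix(sim$matrix, sim$set))
  auroc <- diagnose_groups(sc, sim$labels)$auroc
  expect_lt(abs(auroc - 0.5), 0.13) # 3 sd of the null AUROC at n=100/arm
})

test_that("graded generator enforces strictly increasing effects", {
  expect_error(sim_graded(small_cfg(grade_deltas = c(0, 1, 1))),
               "strictly increasing")
  g <- sim_graded(small_cfg(grade_deltas = c(0, 1.5), n_per_grade = 30, seed = 21))
  expect_identical(levels(g$grades), c("G1", "G2"))
  expect_true(is.ordered(g$grades))
})

test_that("survival generator respects the hazard model and censoring target", {
  set.seed(25)
  s <- rnorm(3000)
  cfg <- sim_config(surv_beta = 0.8, baseline_hazard = 0.2, censor_rate = 0.4,
                    seed = 26)
  sv <- sim_survival(s, cfg)
  expect_true(all(sv$time > 0))
  expect_lt(abs(mean(!sv$event) - 0.4), 0.04) # hits the censor rate
  full <- sim_survival(s, sim_config(censor_rate = 0, seed = 27))
  expect_true(all(full$event))
  expect_error(sim_survival(s, sim_config(baseline_hazard = 0)), "positive")
  # higher score -> stochastically shorter uncensored time
  expect_lt(cor(s, full$time, method = "spearman"), -0.2)
})

test_that("null survival effect yields calibrated log-rank p-values", {
  set.seed(29)
  pvals <- vapply(1:100, function(i) {
    s <- rnorm(60)
    sv <- sim_survival(s, sim_config(surv_beta = 0, seed = 7000 + i))
    km_logrank(s, sv)$logrank_p
  }, 0)
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("paired generator lowers only the signature, dose-dependently", {
  cfg <- small_cfg(n_pairs = 30, treatment_delta = 1, seed = 33)
  pt <- sim_paired_treatment(cfg, dose = 2)
  expect_identical(colnames(pt$pre), colnames(pt$post))
  expect_identical(pt$pairing, colnames(pt$pre))
  in_set <- rownames(pt$pre) %in% pt$set$symbols
  drop_set <- mean(log(pt$pre[in_set, ])) - mean(log(pt$post[in_set, ]))
  drop_bg <- mean(log(pt$pre[!in_set, ])) - mean(log(pt$post[!in_set, ]))
  expect_gt(drop_set, 1.5)
  expect_lt(abs(drop_bg), 0.2)
  null <- sim_paired_treatment(cfg, dose = 0)
  in0 <- rownames(null$pre) %in% null$set$symbols
  expect_lt(abs(mean(log(null$pre[in0, ])) - mean(log(null$post[in0, ]))), 0.2)
})

test_that("drug-response generator marks the truly associated drugs", {
  set.seed(37)
  s <- rnorm(80)
  cfg <- sim_config(n_drugs = 40, frac_true_drugs = 0.25, drug_slope = 3,
                    drug_noise = 0.1, seed = 38)
  dr <- sim_drug_response(s, cfg)
  expect_identical(sum(dr$truth), 10L)
  expect_identical(dim(dr$auc), c(80L, 40L))
  cors <- vapply(dr$auc, function(y) cor(s, y), 0)
  expect_true(all(cors[dr$truth] > 0.9))
  expect_true(all(abs(cors[!dr$truth]) < 0.5))
})

test_that("dropout zeroes nonzero entries at the requested rate", {
  m <- sim_expression(small_cfg(seed = 41))$matrix
  expect_identical(sim_dropout(m, 0, seed = 42), m)
  expect_true(all(sim_dropout(m, 1, seed = 42) == 0))
  half <- sim_dropout(m, 0.5, seed = 43)
  kept <- colSums(half > 0)
  orig <- colSums(m > 0)
  expect_true(all(abs(kept - 0.5 * orig) < 4.5 * sqrt(0.25 * orig)))
  expect_true(all(half == m | half == 0))
})
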