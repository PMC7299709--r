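#' Synthetic-cohort configuration
#'
#' Bundles the knobs of every generator with the defaults used throughout
#' the package's own evaluation: cohorts of 5000 genes carrying a 77-gene
#' signature, 50 samples per arm, a +2 log-scale up-shift of signature
#' genes in the affected arm over lognormal(0, 1) background noise,
#' strictly increasing grade effects (0, 1, 2), a true log-hazard of 1 per
#' unit score with 30% censoring, 100 drugs of which 30% are truly
#' score-associated, and 50% single-cell dropout.
#'
#' @param n_genes Total genes in the simulated matrix.
#' @param set_size Signature size (error in generators if > `n_genes`).
#' @param n_per_arm Samples per arm (tumour/normal; pre/post).
#' @param delta Mean log-scale up-shift of signature genes in the affected arm.
#' @param noise_sd Log-scale background standard deviation.
#' @param grade_deltas Per-grade log-scale shifts, strictly increasing.
#' @param n_per_grade Samples per grade level.
#' @param surv_beta True log hazard ratio per unit score.
#' @param baseline_hazard Baseline exponential event rate (> 0).
#' @param censor_rate Expected fraction censored, in [0, 1).
#' @param n_drugs,frac_true_drugs,drug_slope,drug_noise Drug-screen design:
#'   number of drugs, fraction truly associated, AUC slope per unit score,
#'   residual AUC noise SD.
#' @param n_pairs Pre/post treatment pairs.
#' @param treatment_delta Log-scale down-shift of signature genes per unit
#'   dose after treatment.
#' @param dropout_rate Probability a nonzero entry is zeroed (single-cell
#'   emulation), in [0, 1].
#' @param seed Integer seed; together with the other fields it fully
#'   determines every generator's output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 5000, set_size = 77, n_per_arm = 50,
                       delta = 2, noise_sd = 1,
                       grade_deltas = c(0, 1, 2), n_per_grade = 50,
                       surv_beta = 1, baseline_hazard = 0.1, censor_rate = 0.3,
                       n_drugs = 100, frac_true_drugs = 0.3,
                       drug_slope = 1, drug_noise = 0.5,
                       n_pairs = 30, treatment_delta = 1,
                       dropout_rate = 0.5, seed = 1) {
  stopifnot(n_genes >= 2, set_size >= 1, n_per_arm >= 1,
            noise_sd > 0, censor_rate >= 0, censor_rate < 1,
            dropout_rate >= 0, dropout_rate <= 1,
            frac_true_drugs >= 0, frac_true_drugs <= 1)
  structure(as.list(environment()), class = "sim_config")
}

# Run code under a seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    get(".Random.seed", envir = .GlobalEnv)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
        rm(".Random.seed", envir = .GlobalEnv)
      }
    } else {
      assign(".Random.seed", old, envir = .GlobalEnv)
    }
  })
  set.seed(seed)
  force(code)
}

sim_gene_names <- function(cfg) {
  list(set = sprintf("PG%03d", seq_len(cfg$set_size)),
       bg = sprintf("BG%05d", seq_len(cfg$n_genes - cfg$set_size)))
}

#' Simulate a tumour/normal expression cohort
#'
#' Background expression is lognormal(0, `noise_sd`) on the natural scale;
#' signature genes in the tumour arm receive an additional `delta` on the
#' log scale. This is the minimal generative structure under which a
#' rank-based signature score separates the arms, emulating the
#' tumour-versus-normal contrast the score is designed for.
#'
#' @param cfg A [sim_config()].
#' @return List: `matrix` (genes x samples), `labels` (factor
#'   normal/tumour per sample), `set` (the signature as a [gene_set]).
#' @export
sim_expression <- function(cfg = sim_config()) {
  if (cfg$set_size > cfg$n_genes) stop("set_size exceeds n_genes")
  with_seed(cfg$seed, {
    nm <- sim_gene_names(cfg)
    genes <- c(nm$set, nm$bg)
    n <- 2L * cfg$n_per_arm
    logx <- matrix(stats::rnorm(cfg$n_genes * n, 0, cfg$noise_sd),
                   nrow = cfg$n_genes,
                   dimnames = list(genes, c(sprintf("N%03d", seq_len(cfg$n_per_arm)),
                                            sprintf("T%03d", seq_len(cfg$n_per_arm)))))
    tumour <- rep(c(FALSE, TRUE), each = cfg$n_per_arm)
    logx[seq_len(cfg$set_size), tumour] <-
      logx[seq_len(cfg$set_size), tumour] + cfg$delta
    list(matrix = exp(logx),
         labels = factor(ifelse(tumour, "tumour", "normal"),
                         levels = c("normal", "tumour")),
         set = gene_set("sim_signature", nm$set,
                        description = "simulated signature genes"))
  })
}

#' Simulate a graded cohort
#'
#' One arm per grade level with strictly increasing log-scale signature
#' shifts, emulating a monotone grade effect (higher grade, higher score).
#'
#' @param cfg A [sim_config()]; `grade_deltas` must be strictly increasing.
#' @return List: `matrix`, `grades` (ordered factor), `set`.
#' @export
sim_graded <- function(cfg = sim_config()) {
  if (cfg$set_size > cfg$n_genes) stop("set_size exceeds n_genes")
  k <- length(cfg$grade_deltas)
  if (k < 1L) stop("need at least one grade level")
  if (k > 1L && any(diff(cfg$grade_deltas) <= 0)) {
    stop("grade_deltas must be strictly increasing")
  }
  with_seed(cfg$seed, {
    nm <- sim_gene_names(cfg)
    genes <- c(nm$set, nm$bg)
    n <- k * cfg$n_per_grade
    lvls <- sprintf("G%d", seq_len(k))
    grades <- factor(rep(lvls, each = cfg$n_per_grade), levels = lvls,
                     ordered = TRUE)
    logx <- matrix(stats::rnorm(cfg$n_genes * n, 0, cfg$noise_sd),
                   nrow = cfg$n_genes,
                   dimnames = list(genes, sprintf("S%04d", seq_len(n))))
    shift <- cfg$grade_deltas[as.integer(grades)]
    logx[seq_len(cfg$set_size), ] <-
      sweep(logx[seq_len(cfg$set_size), , drop = FALSE], 2L, shift, `+`)
    list(matrix = exp(logx), grades = grades,
         set = gene_set("sim_signature", nm$set,
                        description = "simulated signature genes"))
  })
}

#' Simulate proportional-hazards survival linked to a score
#'
#' Event times are exponential with rate
#' `baseline_hazard * exp(surv_beta * score)`. Censoring is independent
#' exponential, with its rate solved numerically so the expected censored
#' fraction equals `censor_rate`; `censor_rate = 0` observes every event.
#' Optional covariates (age, gender, grade) are generated independently of
#' the score, for adjusted-model testing.
#'
#' @param scores Numeric vector, one per sample.
#' @param cfg A [sim_config()].
#' @param covariates If `TRUE`, add age/gender/grade columns.
#' @return Data.frame: `sample_id`, `time`, `event` (logical), and any
#'   covariates.
#' @export
sim_survival <- function(scores, cfg = sim_config(), covariates = FALSE) {
  if (cfg$baseline_hazard <= 0) stop("baseline_hazard must be positive")
  n <- length(scores)
  with_seed(cfg$seed, {
    lambda <- cfg$baseline_hazard * exp(cfg$surv_beta * scores)
    t_event <- stats::rexp(n, rate = lambda)
    if (cfg$censor_rate > 0) {
      frac_cens <- function(log_rho) {
        mean(exp(log_rho) / (lambda + exp(log_rho))) - cfg$censor_rate
      }
      rho <- exp(stats::uniroot(frac_cens, c(-40, 40))$root)
      t_cens <- stats::rexp(n, rate = rho)
      time <- pmin(t_event, t_cens)
      event <- t_event <= t_cens
    } else {
      time <- t_event
      event <- rep(TRUE, n)
    }
    out <- data.frame(sample_id = sprintf("S%04d", seq_len(n)),
                      time = time, event = event,
                      stringsAsFactors = FALSE)
    if (covariates) {
      out$age <- round(stats::rnorm(n, 60, 10))
      out$gender <- sample(c("F", "M"), n, replace = TRUE)
      out$grade <- sample(c("G1", "G2", "G3"), n, replace = TRUE)
    }
    out
  })
}

#' Simulate a paired pre/post-treatment cohort
#'
#' Pre-treatment profiles are drawn as lognormal background with signature
#' genes up-shifted by `delta`; post-treatment profiles of the same
#' subjects have the signature shifted back down by
#' `treatment_delta * dose`, emulating a dose-dependent loss of the
#' progenitor expression program under therapy. Background noise is
#' redrawn, so pairs differ everywhere but systematically only in the
#' signature.
#'
#' @param cfg A [sim_config()].
#' @param dose Non-negative dose multiplier (0 = null treatment).
#' @return List: `pre`, `post` (matrices with identical dimnames),
#'   `pairing` (sample IDs), `set`.
#' @export
sim_paired_treatment <- function(cfg = sim_config(), dose = 1) {
  if (cfg$set_size > cfg$n_genes) stop("set_size exceeds n_genes")
  stopifnot(dose >= 0)
  with_seed(cfg$seed, {
    nm <- sim_gene_names(cfg)
    genes <- c(nm$set, nm$bg)
    ids <- sprintf("P%03d", seq_len(cfg$n_pairs))
    draw <- function(shift) {
      logx <- matrix(stats::rnorm(cfg$n_genes * cfg$n_pairs, 0, cfg$noise_sd),
                     nrow = cfg$n_genes, dimnames = list(genes, ids))
      logx[seq_len(cfg$set_size), ] <- logx[seq_len(cfg$set_size), ] + shift
      exp(logx)
    }
    list(pre = draw(cfg$delta),
         post = draw(cfg$delta - cfg$treatment_delta * dose),
         pairing = ids,
         set = gene_set("sim_signature", nm$set,
                        description = "simulated signature genes"))
  })
}

#' Simulate a drug-sensitivity screen
#'
#' For a configured fraction of drugs the dose-response AUC (higher = more
#' resistant) is `drug_slope * score` plus Gaussian noise; the remaining
#' drugs are pure noise. The truth vector of which drugs are genuinely
#' associated is returned for power and false-discovery evaluation.
#'
#' @param scores Numeric vector, one per cell line.
#' @param cfg A [sim_config()].
#' @return List: `auc` (cell lines x drugs data.frame), `truth` (named
#'   logical vector).
#' @export
sim_drug_response <- function(scores, cfg = sim_config()) {
  n <- length(scores)
  with_seed(cfg$seed, {
    drugs <- sprintf("drug%03d", seq_len(cfg$n_drugs))
    n_true <- round(cfg$frac_true_drugs * cfg$n_drugs)
    truth <- stats::setNames(seq_len(cfg$n_drugs) <= n_true, drugs)
    auc <- sapply(seq_len(cfg$n_drugs), function(j) {
      signal <- if (truth[j]) cfg$drug_slope * scores else 0
      signal + stats::rnorm(n, 0, cfg$drug_noise)
    })
    auc <- as.data.frame(auc)
    names(auc) <- drugs
    rownames(auc) <- sprintf("CL%04d", seq_len(n))
    list(auc = auc, truth = truth)
  })
}

#' Sparsify a matrix by single-cell dropout
#'
#' Independently zeroes each nonzero entry with probability `rate`,
#' emulating capture inefficiency: the detected-gene count per cell shrinks
#' by the same factor in expectation.
#'
#' @param m Numeric matrix.
#' @param rate Dropout probability in [0, 1].
#' @param seed Integer seed.
#' @return Matrix of the same shape with dropped entries set to zero.
#' @export
sim_dropout <- function(m, rate, seed = 1) {
  stopifnot(is.matrix(m), rate >= 0, rate <= 1)
  with_seed(seed, {
    drop <- matrix(stats::runif(length(m)) < rate, nrow = nrow(m))
    m[drop & m != 0] <- 0
    m
  })
}
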