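# Independent oracles, written literally from the defining formulas and kept
# separate from the package's implementation paths.

# Literal two-ECDF enrichment score: walk the descending ordering position by
# position, recomputing both cumulative distributions from scratch each step.
brute_es <- function(values, membership, alpha) {
  stopifnot(any(membership), any(!membership))
  ord <- order(-values) # stable for ties
  v <- values[ord]
  m <- membership[ord]
  n <- length(v)
  w_total <- sum(abs(v[m])^alpha)
  es <- 0
  for (i in seq_len(n)) {
    upto <- seq_len(i)
    p_in <- sum(abs(v[upto][m[upto]])^alpha) / w_total
    p_out <- sum(!m[upto]) / (n - sum(m))
    es <- es + (p_in - p_out)
  }
  es
}

# AUROC as the Mann-Whitney U probability: average over every
# positive-negative pair, ties half-credited.
u_auroc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# Cox partial log-likelihood for untied event times (Breslow = Efron = exact
# when there are no ties), for grid-search verification of the fitted beta.
cox_pl_loglik <- function(beta, time, event, z) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * z[i] - log(sum(exp(beta * z[risk])))
  }
  ll
}

# All membership vectors of length n with at least one member and one
# non-member, as a logical matrix (rows = vectors).
all_memberships <- function(n) {
  grid <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  grid[rowSums(grid) > 0 & rowSums(grid) < n, , drop = FALSE]
}

random_matrix <- function(n_genes, n_samples, seed) {
  set.seed(seed)
  matrix(rlnorm(n_genes * n_samples), nrow = n_genes,
         dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                         sprintf("s%03d", seq_len(n_samples))))
}
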