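#' Scoring parameters for the progenitorness score
#'
#' @param alpha Weight exponent applied to the (rank-normalized) expression
#'   value of in-set genes; `alpha = 0` weights all set genes equally,
#'   larger values up-weight highly expressed set genes. Default 0.25, the
#'   conventional single-sample GSEA choice.
#' @param sample_norm `"rank"` (default): replace each sample's values by
#'   ascending ranks (average ties) before scoring, making the score
#'   invariant to any strictly monotone per-sample transform -- the property
#'   that lets one statistic serve FPKM, microarray intensities, single-cell
#'   counts and protein abundances alike. `"none"`: use raw values as
#'   weights.
#' @param batch_norm If `TRUE` (default), also report, per batch of scored
#'   samples, NES = ES / (max ES - min ES). NES values are batch-dependent;
#'   compare across datasets on raw ES or renormalize within each dataset.
#' @param min_overlap Minimum fraction of the gene set that must be present
#'   among the matrix rows (default 0.8); below it scoring errors out and
#'   lists the missing symbols.
#' @return A list of class `scoring_params`.
#' @export
scoring_params <- function(alpha = 0.25, sample_norm = c("rank", "none"),
                           batch_norm = TRUE, min_overlap = 0.8) {
  sample_norm <- match.arg(sample_norm)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha >= 0,
            is.numeric(min_overlap), length(min_overlap) == 1L,
            min_overlap > 0, min_overlap <= 1)
  structure(list(alpha = alpha, sample_norm = sample_norm,
                 batch_norm = isTRUE(batch_norm), min_overlap = min_overlap),
            class = "scoring_params")
}

#' Rank-transform one expression profile
#'
#' Ascending ranks in 1..N with ties given the average rank. Missing values
#' are placed at the bottom of the ranking (below every observed value) with
#' a warning; a constant profile still ranks (all ties) but yields a
#' degenerate score, also warned.
#'
#' @param x Numeric vector, one sample's expression values.
#' @return Numeric vector of ranks, same length and names as `x`.
#' @export
rank_transform <- function(x) {
  stopifnot(length(x) >= 2L)
  n_miss <- sum(is.na(x))
  if (n_miss > 0) {
    warning(n_miss, " missing value(s) placed at the bottom of the ranking")
    x[is.na(x)] <- -Inf
  }
  if (length(unique(x)) == 1L) {
    warning("all values identical: ranks are all tied and the score is degenerate")
  }
  rank(x, ties.method = "average")
}

#' Single-sample enrichment score
#'
#' The integrated-difference running-sum statistic: genes are ordered by
#' decreasing (rank-transformed) value, and at every position i the weighted
#' in-set cumulative distribution P_in(i) is compared with the unweighted
#' out-of-set cumulative distribution P_out(i),
#' \deqn{ES = \sum_{i=1}^{N} [P_{in}(i) - P_{out}(i)],}
#' with in-set gene g carrying weight |value_g|^alpha. Positive ES means
#' set genes concentrate at the top of the profile. Ties in the descending
#' ordering are broken by stable input order, so the statistic is
#' deterministic.
#'
#' @param ranked Numeric vector, one sample's (rank-transformed) values.
#' @param membership Logical vector, same length: is each gene in the set?
#' @param alpha Weight exponent (see [scoring_params()]).
#' @return The enrichment score ES (a real number, |ES| <= N - 1).
#' @export
enrichment_score <- function(ranked, membership, alpha = 0.25) {
  stopifnot(length(ranked) == length(membership), !anyNA(membership))
  n <- length(ranked)
  n_set <- sum(membership)
  if (n_set == 0L) stop("gene set has no genes in the profile")
  if (n_set == n) stop("gene set covers the whole profile; no out-of-set genes")
  ord <- order(-ranked)                      # stable: ties keep input order
  mem <- membership[ord]
  w <- abs(ranked[ord])^alpha
  w[!mem] <- 0
  p_in <- cumsum(w) / sum(w)
  p_out <- cumsum(!mem) / (n - n_set)
  sum(p_in - p_out)
}

#' Score a cohort: the progenitorness score per sample
#'
#' Applies [rank_transform()] and [enrichment_score()] to every sample
#' (column) of an expression matrix for one gene set. With
#' `params$batch_norm`, scores are additionally normalized by the batch
#' range: NES = ES / (max ES - min ES) over the scored samples.
#'
#' @param m Numeric matrix, genes x samples, unique rownames (run
#'   [collapse_duplicates()] first if needed).
#' @param set A [gene_set].
#' @param params A [scoring_params()] object.
#' @return A data.frame of class `score_table` with columns `sample_id`,
#'   `es`, and `nes` when batch-normalized; attributes `set_name` and
#'   `n_set_genes_used`.
#' @export
score_matrix <- function(m, set, params = scoring_params()) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (anyDuplicated(rownames(m))) {
    stop("matrix has duplicated gene symbols; run collapse_duplicates() first")
  }
  if (nrow(m) < 2L || ncol(m) < 1L) stop("need at least 2 genes and 1 sample")
  present <- set$symbols %in% rownames(m)
  if (!any(present)) stop("gene set ", sQuote(set$name),
                          " shares no symbols with the matrix")
  overlap <- mean(present)
  if (overlap < params$min_overlap) {
    stop("only ", round(100 * overlap, 1), "% of set ", sQuote(set$name),
         " present (need ", 100 * params$min_overlap, "%); missing: ",
         paste(set$symbols[!present], collapse = ", "))
  }
  membership <- rownames(m) %in% set$symbols
  es <- vapply(seq_len(ncol(m)), function(j) {
    prof <- m[, j]
    if (params$sample_norm == "rank") prof <- rank_transform(prof)
    enrichment_score(prof, membership, params$alpha)
  }, numeric(1))
  out <- data.frame(sample_id = colnames(m), es = es,
                    stringsAsFactors = FALSE)
  if (params$batch_norm) {
    rng <- max(es) - min(es)
    if (ncol(m) == 1L || rng == 0) {
      warning("batch range undefined or zero; emitting raw ES only")
    } else {
      out$nes <- es / rng
    }
  }
  message("scored ", ncol(m), " sample(s); set overlap ",
          sum(present), "/", length(set$symbols), " genes")
  attr(out, "set_name") <- set$name
  attr(out, "n_set_genes_used") <- sum(present)
  class(out) <- c("score_table", "data.frame")
  out
}
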