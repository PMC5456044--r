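#' Trimmed-mean-of-M-values normalization factors
#'
#' Between-sample scale factors from doubly trimmed log-ratios against a
#' reference column. The reference is the sample whose 75th count-proportion
#' percentile is closest to the mean 75th percentile. For each sample, M
#' (log2 ratio of proportions) and A (average log2 abundance) are computed
#' over genes expressed in both the sample and the reference; the most
#' extreme 30% of M (15% each tail) and 5% of A (2.5% each tail) are
#' discarded and the factor is the inverse-asymptotic-variance weighted mean
#' of the surviving M values. Factors are rescaled to geometric mean 1, so a
#' pure sequencing-depth difference leaves all factors at 1.
#'
#' @param x A `count_matrix` or plain count matrix.
#' @param logratio_trim,sum_trim Total trimmed fractions for M resp. A.
#' @return Object of class `norm_factors`: list with `factors` (named,
#'   geometric mean 1), `lib_sizes` (column sums) and `effective`
#'   (`lib_sizes * factors`).
#' @export
tmm_factors <- function(x, logratio_trim = 0.3, sum_trim = 0.05) {
  counts <- if (inherits(x, "count_matrix")) x$counts else x
  if (ncol(counts) < 2) stop("need at least 2 samples")
  lib <- colSums(counts)
  if (any(lib == 0)) stop("all-zero sample column: ",
                          colnames(counts)[which(lib == 0)[1]])
  uq <- apply(counts, 2, function(y) quantile(y / sum(y), 0.75))
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(k) {
    if (k == ref) return(1)
    tmm_pair(counts[, k], counts[, ref], lib[k], lib[ref],
             logratio_trim, sum_trim)
  }, numeric(1))
  f <- f / exp(mean(log(f)))    # rescale to geometric mean 1
  names(f) <- colnames(counts)
  structure(list(factors = f, lib_sizes = lib, effective = lib * f),
            class = "norm_factors")
}

tmm_pair <- function(obs, ref, n_obs, n_ref, logratio_trim, sum_trim) {
  keep <- obs > 0 & ref > 0
  if (!any(keep))
    stop("sample shares no expressed gene with the reference")
  p_o <- obs[keep] / n_obs
  p_r <- ref[keep] / n_ref
  M <- log2(p_o / p_r)
  A <- (log2(p_o) + log2(p_r)) / 2
  # asymptotic variance of M by the delta method
  w <- (n_obs - obs[keep]) / (n_obs * obs[keep]) +
       (n_ref - ref[keep]) / (n_ref * ref[keep])
  lo_M <- quantile(M, logratio_trim / 2)
  hi_M <- quantile(M, 1 - logratio_trim / 2)
  lo_A <- quantile(A, sum_trim / 2)
  hi_A <- quantile(A, 1 - sum_trim / 2)
  keep2 <- M >= lo_M & M <= hi_M & A >= lo_A & A <= hi_A
  if (!any(keep2)) return(1)
  2^(sum(M[keep2] / w[keep2]) / sum(1 / w[keep2]))
}

#' Counts per million on effective library sizes
#'
#' @param x `count_matrix` or matrix.
#' @param nf `norm_factors` from [tmm_factors()]; computed if missing.
#' @param log If `TRUE` return `log2(cpm + prior)`.
#' @param prior Offset used for the log transform.
#' @export
cpm <- function(x, nf = NULL, log = FALSE, prior = 0.5) {
  counts <- if (inherits(x, "count_matrix")) x$counts else x
  if (is.null(nf)) nf <- tmm_factors(counts)
  v <- sweep(counts, 2, nf$effective / 1e6, `/`)
  if (log) log2(v + prior) else v
}
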