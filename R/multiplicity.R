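#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return q-values: monotone in the ranks, capped at 1.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must be in [0, 1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(m / (m:1) * p[o]))[ro]
  q
}

#' Storey-type q-values (optional alternative to BH)
#'
#' BH rescaled by the estimated null proportion
#' `pi0 = #\{p > lambda\} / (m (1 - lambda))`, capped at 1.
#'
#' @param p p-values.
#' @param lambda Tuning point for the pi0 estimate.
#' @export
storey_q <- function(p, lambda = 0.5) {
  pi0 <- min(1, mean(p > lambda) / (1 - lambda))
  pmin(1, pi0 * bh_adjust(p))
}

#' Independent filtering to raise discoveries at fixed FDR
#'
#' Scans filter quantiles `theta` in \{0, 0.01, ..., 0.50\}: at each, the
#' lowest-`theta` fraction of genes by the filter statistic (overall mean
#' normalized count across all supplied samples, which is independent of
#' the two-group split under the null) is dropped and BH is re-applied to
#' the survivors. The `theta` maximizing the number of `q <= fdr`
#' discoveries wins (smallest such `theta` on ties); survivors keep their
#' recomputed q-values.
#'
#' @param results Data frame with columns `gene`, `p_value` (e.g.
#'   [exact_test()] output).
#' @param counts Full-study `count_matrix` (all samples/time points) used
#'   for the filter statistic; 1-month samples are dropped.
#' @param nf Optional [tmm_factors()] for `counts`.
#' @param fdr FDR threshold driving the scan.
#' @param quantiles Candidate `theta` grid.
#' @return List: `results` (survivors with `q_value`), `theta`, `n_sig`,
#'   and the full `scan` table.
#' @export
independent_filter <- function(results, counts, nf = NULL, fdr = 0.10,
                               quantiles = seq(0, 0.5, by = 0.01)) {
  cm <- if (inherits(counts, "count_matrix")) active_samples(counts)
        else counts
  stat_all <- rowMeans(cpm(cm, nf))
  stat <- stat_all[results$gene]
  if (anyNA(stat)) stop("filter statistic missing for some genes")
  cuts <- quantile(stat, quantiles, type = 7)
  best <- NULL
  scan <- data.frame(theta = quantiles, n_sig = NA_integer_)
  for (i in seq_along(quantiles)) {
    keep <- if (quantiles[i] == 0) rep(TRUE, length(stat))
            else stat > cuts[i]
    q <- bh_adjust(results$p_value[keep])
    ns <- sum(q <= fdr)
    scan$n_sig[i] <- ns
    if (is.null(best) || ns > best$n_sig)
      best <- list(theta = quantiles[i], keep = keep, q = q, n_sig = ns)
  }
  out <- results[best$keep, , drop = FALSE]
  out$q_value <- best$q
  list(results = out, theta = best$theta, n_sig = best$n_sig, scan = scan)
}
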