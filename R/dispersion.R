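#' Equalize library sizes by mean-preserving count scaling
#'
#' The conditional likelihood behind both the dispersion estimator and the
#' exact test assumes equal library sizes. Counts are scaled to the
#' geometric mean of the TMM-effective library sizes and re-rounded to
#' integers ("pseudo-counts").
#'
#' @param x `count_matrix` or matrix.
#' @param nf [tmm_factors()] output.
#' @return Integer matrix of pseudo-counts with attribute
#'   `"common_lib_size"`.
#' @export
equalize_counts <- function(x, nf) {
  counts <- if (inherits(x, "count_matrix")) x$counts else x
  nstar <- exp(mean(log(nf$effective)))
  ps <- round(sweep(counts, 2, nstar / nf$effective, `*`))
  storage.mode(ps) <- "integer"
  attr(ps, "common_lib_size") <- nstar
  ps
}

# Per-gene NB conditional log-likelihood given per-group totals, summed
# over groups; terms free of phi are dropped.  `group_idx` is a list of
# column index vectors.
cond_loglik <- function(pseudo, group_idx, phi) {
  r <- 1 / phi
  ll <- numeric(nrow(pseudo))
  for (idx in group_idx) {
    n <- length(idx)
    z <- rowSums(pseudo[, idx, drop = FALSE])
    ll <- ll + rowSums(lgamma(pseudo[, idx, drop = FALSE] + r)) -
      n * lgamma(r) + lgamma(n * r) - lgamma(z + n * r)
  }
  ll
}

#' Quantile-adjusted conditional likelihood dispersion estimation
#'
#' The common dispersion maximizes the conditional log-likelihood (given
#' per-group totals on equalized libraries) summed over genes. Tagwise
#' dispersions maximize a weighted combination of the gene's own conditional
#' likelihood and the all-gene average, the weight expressed as a prior
#' degree of freedom (default 10); `prior_df = Inf` collapses every tagwise
#' value onto the common estimate.
#'
#' @param x `count_matrix` or matrix.
#' @param groups Factor (or coercible) of group membership, any number of
#'   levels with >= 2 samples each.
#' @param nf [tmm_factors()] for the same samples.
#' @param prior_df Shrinkage prior degrees of freedom.
#' @param span Search interval for phi.
#' @param grid_length Number of log-spaced grid points for the tagwise
#'   profile (a parabolic refinement is applied around the grid maximum).
#' @return Object of class `dispersion_estimates`: list with `common_phi`
#'   and `tagwise_phi` (named per gene).
#' @export
estimate_dispersion <- function(x, groups, nf, prior_df = 10,
                                span = c(1e-6, 10), grid_length = 41) {
  counts <- if (inherits(x, "count_matrix")) x$counts else x
  if (!is.factor(groups)) groups <- factor(groups)
  groups <- droplevels(groups)
  if (any(table(groups) < 2)) stop("each group needs >= 2 samples")
  pseudo <- equalize_counts(counts, nf)
  gidx <- split(seq_len(ncol(pseudo)), groups)

  total_ll <- function(phi) sum(cond_loglik(pseudo, gidx, phi))
  opt <- optimize(total_ll, interval = span, maximum = TRUE,
                  tol = 1e-6)
  common <- opt$maximum
  if (common <= span[1] * 1.01 || common >= span[2] * 0.99)
    warning("common dispersion estimate at search boundary (",
            signif(common, 3), ")")

  if (is.infinite(prior_df)) {
    tag <- rep(common, nrow(pseudo))
  } else {
    grid <- exp(seq(log(span[1]), log(span[2]), length.out = grid_length))
    ll <- vapply(grid, function(phi) cond_loglik(pseudo, gidx, phi),
                 numeric(nrow(pseudo)))          # genes x grid
    df_resid <- ncol(pseudo) - nlevels(groups)
    prior_n <- prior_df / max(df_resid, 1)
    obj <- ll + prior_n * matrix(colMeans(ll), nrow(ll), ncol(ll),
                                 byrow = TRUE)
    k <- max.col(obj, ties.method = "first")
    at_edge <- k == 1L | k == grid_length
    if (any(at_edge))
      warning(sum(at_edge), " tagwise dispersion estimate(s) at search ",
              "boundary")
    # parabolic refinement on the log-phi grid
    lg <- log(grid)
    tag <- vapply(seq_len(nrow(obj)), function(g) {
      i <- k[g]
      if (i == 1L || i == grid_length) return(grid[i])
      y0 <- obj[g, i - 1]; y1 <- obj[g, i]; y2 <- obj[g, i + 1]
      denom <- y0 - 2 * y1 + y2
      if (denom >= 0) return(grid[i])
      exp(lg[i] - 0.5 * (y2 - y0) / denom * (lg[i + 1] - lg[i]))
    }, numeric(1))
  }
  names(tag) <- rownames(counts)
  structure(list(common_phi = common, tagwise_phi = tag),
            class = "dispersion_estimates")
}

#' Exact negative-binomial test for a two-group contrast
#'
#' Counts are equalized to a common library size; each gene's two group
#' sums are then compared conditionally on their total: the two-sided
#' p-value is the conditional probability mass of all splits no more
#' probable than the observed one (ties included, capped at 1). The log2
#' fold change is computed from the equalized group mean abundances with a
#' prior count of 0.125 per sample to avoid infinities.
#'
#' @param x `count_matrix` or matrix covering exactly the contrast samples.
#' @param groups Two-level factor; the fold change is oriented
#'   `levels[2]` over `levels[1]` (set levels accordingly, e.g.
#'   `factor(g, levels = c("AC", "CS"))` for CS-over-AC).
#' @param nf [tmm_factors()] for these samples.
#' @param disp [estimate_dispersion()] output (tagwise values are used).
#' @param prior_count Per-sample prior count for the fold change.
#' @return Data frame `gene`, `log2_fc`, `p_value`.
#' @export
exact_test <- function(x, groups, nf, disp, prior_count = 0.125) {
  counts <- if (inherits(x, "count_matrix")) x$counts else x
  if (!is.factor(groups)) groups <- factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) != 2) stop("exact_test needs exactly two groups")
  pseudo <- equalize_counts(counts, nf)
  i2 <- groups == levels(groups)[2]   # numerator group
  i1 <- !i2
  n1 <- sum(i1); n2 <- sum(i2)
  z1 <- rowSums(pseudo[, i1, drop = FALSE])
  z2 <- rowSums(pseudo[, i2, drop = FALSE])
  phi <- disp$tagwise_phi
  if (length(phi) != nrow(pseudo)) phi <- rep(disp$common_phi, nrow(pseudo))
  p <- exact_nb_pvals(as.integer(z2), as.integer(z1), n2, n1,
                      pmax(phi, 1e-8))
  lfc <- log2((z2 + prior_count * n2) / n2) -
         log2((z1 + prior_count * n1) / n1)
  zero <- (z1 + z2) == 0
  lfc[zero] <- 0
  data.frame(gene = rownames(counts), log2_fc = lfc, p_value = p,
             row.names = NULL, stringsAsFactors = FALSE)
}
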