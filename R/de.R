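#' Pairwise differential expression at one time point
#'
#' Full stack for one contrast: TMM normalization, qCML dispersion, the NB
#' exact test, independent filtering (optional), BH (or Storey) q-values,
#' and the significance call `q <= fdr & |log2FC| >= log2(min_fc)`.
#'
#' @param x Full-study `count_matrix`; the contrast samples are selected
#'   internally.
#' @param contrast `c(numerator_group, denominator_group)`, e.g.
#'   `c("CS", "AC")` for the usual smoke-over-air orientation.
#' @param time Time label of the contrast (SS exists only at `"9mo"`).
#' @param fdr FDR threshold (default 0.10).
#' @param min_fc Fold-change threshold on the natural scale (default 1.5).
#' @param filter Apply [independent_filter()]? If `FALSE`, plain BH over
#'   all genes.
#' @param dispersion_samples Optional sample ids over which normalization
#'   and dispersion are estimated (e.g. all three month-9 groups, as done
#'   for the cessation contrasts); defaults to the two contrast groups.
#' @param prior_df Dispersion shrinkage prior df.
#' @param adjust `"bh"` (default) or `"storey"`.
#' @return A `de_result` data frame: `gene`, `log2_fc`, `p_value`,
#'   `q_value`, `significant`, with attributes `contrast`, `time`, `theta`,
#'   `common_phi`, `norm_factors`. Genes removed by the filter are absent.
#' @export
de_test <- function(x, contrast = c("CS", "AC"), time = "9mo",
                    fdr = 0.10, min_fc = 1.5, filter = TRUE,
                    dispersion_samples = NULL, prior_df = 10,
                    adjust = c("bh", "storey")) {
  adjust <- match.arg(adjust)
  s <- x$samples
  in_contrast <- s$group %in% contrast & s$time_label == time & !s$excluded
  if (!any(in_contrast)) stop("no samples for contrast ",
                              paste(contrast, collapse = " vs "),
                              " at ", time)
  disp_ids <- if (is.null(dispersion_samples))
    s$sample_id[in_contrast] else dispersion_samples
  xd <- subset_samples(x, disp_ids)
  nf_d <- tmm_factors(xd)
  disp <- estimate_dispersion(xd, xd$samples$group, nf_d,
                              prior_df = prior_df)

  xc <- subset_samples(x, s$sample_id[in_contrast])
  nf_c <- tmm_factors(xc)
  groups <- factor(xc$samples$group, levels = rev(contrast))
  res <- exact_test(xc, groups, nf_c, disp)

  if (filter) {
    fil <- independent_filter(res, x, fdr = fdr)
    res <- fil$results
    theta <- fil$theta
  } else {
    res$q_value <- bh_adjust(res$p_value)
    theta <- NA_real_
  }
  if (adjust == "storey") res$q_value <- storey_q(res$p_value)
  res$significant <- res$q_value <= fdr & abs(res$log2_fc) >= log2(min_fc)
  attr(res, "contrast") <- contrast
  attr(res, "time") <- time
  attr(res, "theta") <- theta
  attr(res, "common_phi") <- disp$common_phi
  attr(res, "norm_factors") <- nf_c$factors
  attr(res, "fdr") <- fdr
  attr(res, "min_fc") <- min_fc
  class(res) <- c("de_result", "data.frame")
  res
}

#' The three month-9 cessation contrasts with shared modeling
#'
#' Computes CS-vs-AC, SS-vs-CS and SS-vs-AC at month 9 with normalization
#' and dispersion estimated jointly from all three groups, as the pattern
#' machinery expects.
#'
#' @inheritParams de_test
#' @return Named list `CSvAC`, `SSvCS`, `SSvAC` of `de_result` objects.
#' @export
month9_contrasts <- function(x, fdr = 0.10, min_fc = 1.5, filter = TRUE,
                             prior_df = 10) {
  s <- x$samples
  ids9 <- s$sample_id[s$time_label == "9mo"]
  list(
    CSvAC = de_test(x, c("CS", "AC"), "9mo", fdr, min_fc, filter,
                    dispersion_samples = ids9, prior_df = prior_df),
    SSvCS = de_test(x, c("SS", "CS"), "9mo", fdr, min_fc, filter,
                    dispersion_samples = ids9, prior_df = prior_df),
    SSvAC = de_test(x, c("SS", "AC"), "9mo", fdr, min_fc, filter,
                    dispersion_samples = ids9, prior_df = prior_df))
}
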