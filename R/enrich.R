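#' Per-gene, per-sample-pair log-ratio statistics
#'
#' The enrichment engine compares every treatment sample against every
#' control sample one on one: for treatment sample i and control sample j,
#' `stat[g, (i,j)] = log2((cpm_gi + c) / (cpm_gj + c))` with a small
#' moderation constant `c` (default 8 counts at the mean effective library
#' size, expressed in CPM) guarding low counts. Depth differences are
#' absorbed by the CPM scaling, so doubling one sample's depth leaves its
#' columns unchanged.
#'
#' @param x `count_matrix` covering the contrast samples.
#' @param groups Two-level factor; `levels[2]` is treatment.
#' @param nf [tmm_factors()] for these samples.
#' @param moderation Moderation constant in CPM; default
#'   `8 / mean(effective lib size) * 1e6`.
#' @return Matrix genes x (treatment, control) pairs; column names
#'   `"trt|ctl"`.
#' @export
gene_level_stats <- function(x, groups, nf, moderation = NULL) {
  counts <- if (inherits(x, "count_matrix")) x$counts else x
  if (!is.factor(groups)) groups <- factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) != 2) stop("need exactly two groups")
  if (is.null(moderation)) moderation <- 8 / mean(nf$effective) * 1e6
  v <- log2(cpm(counts, nf) + moderation)
  trt <- which(groups == levels(groups)[2])
  ctl <- which(groups == levels(groups)[1])
  pairs <- expand.grid(ctl = ctl, trt = trt)
  out <- v[, pairs$trt, drop = FALSE] - v[, pairs$ctl, drop = FALSE]
  colnames(out) <- paste(colnames(counts)[pairs$trt],
                         colnames(counts)[pairs$ctl], sep = "|")
  attr(out, "n_trt") <- length(trt)
  attr(out, "n_ctl") <- length(ctl)
  out
}

#' One-sided gene-set test against the genome-wide background
#'
#' Per pair column, a two-sample t-like statistic compares the set members'
#' log-ratios with all genes' log-ratios; the one-sided p-value uses a t
#' reference with `|set| - 1` degrees of freedom. Per-column p-values are
#' combined across pairs by Stouffer's method with a correlation-adjusted
#' denominator: two pair columns sharing a sample have correlation 1/2
#' under the null (each column is a difference of two sample effects), so
#' for the full `n1 x n2` pair grid `Var(sum z) = K (n1 + n2) / 2` rather
#' than `K`; using the naive `sqrt(K)` would make null set p-values badly
#' anti-conservative. The set statistic is the mean per-column t.
#'
#' @param stats Matrix from [gene_level_stats()].
#' @param set Character vector of member gene ids.
#' @param direction `"up"` or `"down"`.
#' @param min_set_size Sets with fewer tested members are skipped
#'   (returned as `NA` with a message attribute).
#' @return List `set_stat`, `p_value`, `n_genes`.
#' @export
set_test <- function(stats, set, direction = c("up", "down"),
                     min_set_size = 5) {
  direction <- match.arg(direction)
  idx <- which(rownames(stats) %in% set)
  m <- length(idx)
  if (m < min_set_size)
    return(list(set_stat = NA_real_, p_value = NA_real_, n_genes = m))
  mu_all <- colMeans(stats)
  var_all <- apply(stats, 2, var)
  sub <- stats[idx, , drop = FALSE]
  mu_set <- colMeans(sub)
  var_set <- apply(sub, 2, var)
  M <- nrow(stats)
  tt <- (mu_set - mu_all) / sqrt(var_set / m + var_all / M)
  tt[!is.finite(tt)] <- 0
  p_col <- if (direction == "up") pt(tt, df = m - 1, lower.tail = FALSE)
           else pt(tt, df = m - 1, lower.tail = TRUE)
  p_col <- pmin(pmax(p_col, 1e-15), 1 - 1e-15)
  z <- qnorm(p_col, lower.tail = FALSE)
  n1 <- attr(stats, "n_trt") %||% NULL
  n2 <- attr(stats, "n_ctl") %||% NULL
  denom <- if (!is.null(n1) && !is.null(n2) &&
               length(z) == n1 * n2)
    sqrt(length(z) * (n1 + n2) / 2) else sqrt(length(z))
  p <- pnorm(sum(z) / denom, lower.tail = FALSE)
  list(set_stat = mean(tt), p_value = p, n_genes = m)
}

#' Influential (core) genes of an enriched set
#'
#' Members whose mean pair-column log-ratio carries the enrichment sign and
#' exceeds `sd_mult` standard deviations of the all-gene mean-statistic
#' distribution: the genes that substantially drive the set's signal.
#'
#' @inheritParams set_test
#' @param sd_mult Magnitude threshold in background SDs (default 1).
#' @return Character vector of gene ids.
#' @export
core_genes <- function(stats, set, direction = c("up", "down"),
                       sd_mult = 1) {
  direction <- match.arg(direction)
  gm <- rowMeans(stats)
  cut <- sd_mult * sd(gm)
  idx <- rownames(stats) %in% set
  g <- gm[idx]
  keep <- if (direction == "up") g >= cut else g <= -cut
  names(g)[keep]
}

#' Directional set enrichment across all time points
#'
#' For every time point, the CS-vs-AC contrast (or any `contrast`) is
#' scored for every set in both directions; BH q-values are computed per
#' direction, significance is `q <= fdr`, and core genes are extracted.
#' Also emits the set x time direction grid ("up"/"down"/"ns") consumed by
#' the concordance and pathway-pattern stages.
#'
#' @param x Full-study `count_matrix`.
#' @param sets `geneset_db`.
#' @param contrast `c(numerator, denominator)` group pair.
#' @param times Time labels to test (default: all non-excluded AC/CS time
#'   points present).
#' @param fdr Significance threshold on q.
#' @param min_set_size Passed to [set_test()].
#' @return List: `table` (long data frame set x time x direction with
#'   stat, p, q, significance, core genes) and `grid` (set x time
#'   character matrix "up"/"down"/"ns").
#' @export
enrich_all <- function(x, sets, contrast = c("CS", "AC"), times = NULL,
                       fdr = 0.10, min_set_size = 5) {
  s <- x$samples
  if (is.null(times)) {
    times <- intersect(names(TIME_DAYS),
                       unique(s$time_label[!s$excluded &
                                             s$group %in% contrast]))
    times <- times[vapply(times, function(t)
      all(table(factor(s$group[s$time_label == t &
                                 s$group %in% contrast],
                       levels = contrast)) > 0), logical(1))]
  }
  rows <- list()
  grid <- matrix("ns", length(sets), length(times),
                 dimnames = list(names(sets), times))
  for (t in times) {
    keep <- s$group %in% contrast & s$time_label == t & !s$excluded
    xc <- subset_samples(x, s$sample_id[keep])
    nf <- tmm_factors(xc)
    groups <- factor(xc$samples$group, levels = rev(contrast))
    stats <- gene_level_stats(xc, groups, nf)
    for (dir in c("up", "down")) {
      res <- lapply(sets, set_test, stats = stats, direction = dir,
                    min_set_size = min_set_size)
      p <- vapply(res, `[[`, 0, "p_value")
      tested <- !is.na(p)
      q <- rep(NA_real_, length(p))
      q[tested] <- bh_adjust(p[tested])
      core <- character(length(sets))
      for (i in which(tested))
        core[i] <- paste(core_genes(stats, sets[[i]], dir),
                         collapse = ";")
      rows[[paste(t, dir)]] <- data.frame(
        set = names(sets), time = t, direction = dir,
        set_stat = vapply(res, `[[`, 0, "set_stat"),
        p_value = p, q_value = q,
        significant = !is.na(q) & q <= fdr,
        n_genes = vapply(res, `[[`, 0L, "n_genes"),
        core_genes = core,
        row.names = NULL, stringsAsFactors = FALSE)
    }
    up <- rows[[paste(t, "up")]]
    dn <- rows[[paste(t, "down")]]
    sig_up <- up$significant
    sig_dn <- dn$significant
    both <- sig_up & sig_dn
    pick_up <- (sig_up & !sig_dn) | (both & up$q_value <= dn$q_value)
    pick_dn <- (sig_dn & !sig_up) | (both & dn$q_value < up$q_value)
    grid[pick_up, t] <- "up"
    grid[pick_dn, t] <- "down"
  }
  list(table = do.call(rbind, rows), grid = grid, fdr = fdr,
       contrast = contrast)
}
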