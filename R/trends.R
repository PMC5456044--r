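#' Orthonormal polynomial contrasts over (possibly unequal) time spacing
#'
#' Gram-Schmidt orthonormalization of (1, t, t^2) evaluated at the
#' replicated design's time values; the constant direction is removed and
#' the linear column's sign fixed to increase with time. Works for any
#' spacing, e.g. days 1, 7, 90, 180, 270.
#'
#' @param times Numeric vector of per-sample day values (>= 3 distinct).
#' @return A `contrast_basis`: matrix with orthonormal columns `linear`,
#'   `quadratic`, attribute `times`.
#' @export
build_contrasts <- function(times) {
  if (length(unique(times)) < 3)
    stop("need >= 3 distinct time values for a quadratic contrast")
  X <- cbind(1, times, times^2)
  # modified Gram-Schmidt
  Q <- matrix(0, nrow(X), 3)
  for (j in 1:3) {
    v <- X[, j]
    for (k in seq_len(j - 1)) v <- v - sum(Q[, k] * v) * Q[, k]
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) stop("degenerate time design")
    Q[, j] <- v / nv
  }
  C <- Q[, 2:3, drop = FALSE]
  if (C[which.max(times)[1], 1] < C[which.min(times)[1], 1])
    C[, 1] <- -C[, 1]
  if (C[which.min(times)[1], 2] < 0) C[, 2] <- -C[, 2]
  colnames(C) <- c("linear", "quadratic")
  structure(C, class = c("contrast_basis", "matrix"), times = times)
}

#' Fit per-gene time-course linear models
#'
#' Ordinary least squares on `log2(CPM + 0.5)` with terms group,
#' linear(t), quadratic(t), group x linear, group x quadratic, where the
#' time terms are the orthonormal polynomial contrasts of
#' [build_contrasts()]. The SS arm and excluded (1-month) samples are never
#' used: trends describe the AC/CS series only.
#'
#' @param x Full-study `count_matrix`.
#' @param nf Optional [tmm_factors()] over the trend samples.
#' @return A `trend_fit`: list with matrices `coef`, `t`, `p` (genes x
#'   terms), `df_resid`, and the design metadata.
#' @export
fit_gene_trends <- function(x, nf = NULL) {
  s <- x$samples
  keep <- s$group %in% c("AC", "CS") & !s$excluded
  xt <- subset_samples(x, keep)
  st <- xt$samples
  if (length(unique(st$time_days)) < 3)
    stop("need >= 3 shared time points for both groups")
  if (is.null(nf)) nf <- tmm_factors(xt)
  Y <- cpm(xt, nf, log = TRUE)                # genes x samples
  C <- build_contrasts(st$time_days)
  grp <- as.numeric(st$group == "CS")
  X <- cbind(intercept = 1, group = grp, linear = C[, 1],
             quadratic = C[, 2], `group:linear` = grp * C[, 1],
             `group:quadratic` = grp * C[, 2])
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) stop("rank-deficient trend design")
  coefs <- t(qr.coef(qr_x, t(Y)))             # genes x terms
  fitted <- coefs %*% t(X)
  rss <- rowSums((Y - fitted)^2)
  df <- nrow(X) - ncol(X)
  sigma2 <- rss / df
  xtx_inv <- chol2inv(qr.R(qr_x))
  se <- sqrt(outer(sigma2, diag(xtx_inv)))
  tstat <- coefs / se
  tstat[se == 0] <- 0
  pval <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  colnames(coefs) <- colnames(tstat) <- colnames(pval) <- colnames(X)
  structure(list(coef = coefs, t = tstat, p = pval, df_resid = df,
                 basis = C, design = X, genes = rownames(Y)),
            class = "trend_fit")
}

#' Protected hierarchical trend testing
#'
#' Tests, per gene, the model terms highest order first: (1) group x
#' quadratic, (2) group x linear, (3) quadratic, (4) linear, (5) group.
#' At each tier, BH is applied across the genes still in play; a gene
#' stopping at a tier receives its category there (interaction tiers
#' directly; time tiers additionally check the group main effect — BH
#' across the stopping set — to distinguish `group_plus_*` from
#' `time_only`), and drops out of later tiers.
#'
#' @param fits A `trend_fit` from [fit_gene_trends()].
#' @param alpha FDR level per tier (default 0.10).
#' @return Data frame `gene`, `category`, per-term estimates, p and
#'   within-tier q-values.
#' @export
protected_test <- function(fits, alpha = 0.10) {
  p <- fits$p
  G <- nrow(p)
  category <- rep("none", G)
  qmat <- matrix(NA_real_, G, 5,
                 dimnames = list(NULL, c("group:quadratic", "group:linear",
                                         "quadratic", "linear", "group")))
  in_play <- rep(TRUE, G)
  tiers <- list(
    list(term = "group:quadratic", cat = "quad_interaction"),
    list(term = "group:linear", cat = "linear_interaction"),
    list(term = "quadratic", cat = "group_plus_quad", alt = "time_only"),
    list(term = "linear", cat = "group_plus_linear", alt = "time_only"),
    list(term = "group", cat = "group_only"))
  for (ti in seq_along(tiers)) {
    tier <- tiers[[ti]]
    idx <- which(in_play)
    if (!length(idx)) break
    q <- bh_adjust(p[idx, tier$term])
    qmat[idx, tier$term] <- q
    hit <- q <= alpha
    stopped <- idx[hit]
    if (length(stopped)) {
      if (is.null(tier$alt)) {
        category[stopped] <- tier$cat
      } else {
        qg <- bh_adjust(p[stopped, "group"])
        category[stopped] <- ifelse(qg <= alpha, tier$cat, tier$alt)
      }
      in_play[stopped] <- FALSE
    }
  }
  out <- data.frame(gene = fits$genes, category = category,
                    stringsAsFactors = FALSE)
  est <- fits$coef[, colnames(qmat), drop = FALSE]
  colnames(est) <- paste0("est_", colnames(est))
  pv <- p[, colnames(qmat), drop = FALSE]
  colnames(pv) <- paste0("p_", colnames(qmat))
  colnames(qmat) <- paste0("q_", colnames(qmat))
  cbind(out, est, pv, qmat)
}

#' One-call trend analysis
#'
#' @inheritParams fit_gene_trends
#' @inheritParams protected_test
#' @export
trend_analysis <- function(x, alpha = 0.10, nf = NULL) {
  protected_test(fit_gene_trends(x, nf), alpha)
}
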