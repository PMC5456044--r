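#' Per-metabolite two-group tests at one time point
#'
#' Welch's unequal-variance t-test on `log2(abundance + 1)` for each
#' metabolite, CS minus AC orientation (or any two groups). Metabolites
#' with fewer than `min_n` non-missing values in either group are reported
#' with status `"untested"` rather than a p-value: untargeted LC-MS panels
#' routinely lose cells to matrix interference.
#'
#' @param m A `metabolite_matrix`.
#' @param contrast `c(numerator_group, denominator_group)`.
#' @param time Time label.
#' @param min_n Minimum non-missing values per group (default 3).
#' @return Data frame `metabolite`, `p_value`, `direction` (+1/-1 sign of
#'   the log-scale mean difference), `n1`, `n2`, `status`.
#' @export
test_metabolites <- function(m, contrast = c("CS", "AC"), time,
                             min_n = 3) {
  s <- m$samples
  i2 <- s$group == contrast[1] & (s$group == "SS" | s$time_label == time)
  i1 <- s$group == contrast[2] & (s$group == "SS" | s$time_label == time)
  a <- log2(m$abundances + 1)
  res <- lapply(rownames(a), function(id) {
    x2 <- a[id, i2]; x2 <- x2[!is.na(x2)]
    x1 <- a[id, i1]; x1 <- x1[!is.na(x1)]
    if (length(x1) < min_n || length(x2) < min_n)
      return(data.frame(metabolite = id, p_value = NA_real_,
                        direction = NA_real_, n1 = length(x2),
                        n2 = length(x1), status = "untested"))
    w <- welch_t(x2, x1)
    data.frame(metabolite = id, p_value = w$p,
               direction = sign(w$diff), n1 = length(x2),
               n2 = length(x1), status = "tested")
  })
  do.call(rbind, res)
}

# Welch two-sample t-test; degenerate zero-variance cases resolve to
# p = 1 when the means agree and p = 0 otherwise.
welch_t <- function(x, y) {
  dm <- mean(x) - mean(y)
  v <- var(x) / length(x) + var(y) / length(y)
  if (v == 0) return(list(p = as.numeric(dm == 0), diff = dm))
  t <- dm / sqrt(v)
  df <- v^2 / ((var(x) / length(x))^2 / (length(x) - 1) +
                 (var(y) / length(y))^2 / (length(y) - 1))
  list(p = 2 * pt(abs(t), df, lower.tail = FALSE), diff = dm)
}

#' Fisher's combined probability
#'
#' `-2 * sum(log p)` referred to the chi-square distribution with `2k`
#' degrees of freedom.
#'
#' @param p Vector of independent p-values.
#' @export
fisher_combine <- function(p) {
  p <- p[!is.na(p)]
  if (!length(p)) return(NA_real_)
  pchisq(-2 * sum(log(pmax(p, 1e-300))), df = 2 * length(p),
         lower.tail = FALSE)
}

#' Pathways recurring across the transcriptomic time course
#'
#' @param grid Set x time direction grid from [enrich_all()]
#'   ("up"/"down"/"ns").
#' @param min_times Minimum number of significant time points (default 2).
#' @return Character vector of pathway names.
#' @export
recurring_pathways <- function(grid, min_times = 2) {
  rownames(grid)[rowSums(grid != "ns") >= min_times]
}

#' Metabolome-level call for one pathway
#'
#' Aggregates member-metabolite p-values by Fisher's method (primary) and
#' the minimum p (alternative, reported alongside); the pathway is called
#' significant when the combined p is below `alpha`. No multiplicity
#' correction is applied at the metabolite level, matching the raw
#' `p < 0.05` convention of compound-level screening.
#'
#' @param tests [test_metabolites()] output.
#' @param pathway Pathway name.
#' @param members Character vector of member metabolite ids (e.g. from
#'   `pathway_members()`).
#' @param alpha Compound/pathway significance level (default 0.05).
#' @return List `significant`, `combined_p`, `min_p`, `n_tested`,
#'   `detail` (per-metabolite flags), `status`.
#' @export
pathway_metabolome_call <- function(tests, pathway, members,
                                    alpha = 0.05) {
  d <- tests[tests$metabolite %in% members & tests$status == "tested", ,
             drop = FALSE]
  if (!nrow(d))
    return(list(significant = NA, combined_p = NA_real_,
                min_p = NA_real_, n_tested = 0L, detail = NULL,
                status = "not_evaluable"))
  cp <- fisher_combine(d$p_value)
  d$flag <- d$p_value < alpha
  list(significant = cp < alpha, combined_p = cp,
       min_p = min(d$p_value), n_tested = nrow(d), detail = d,
       status = "evaluated")
}

#' Transcriptome-metabolome concordance matrix
#'
#' Rows are the transcriptomically recurring pathways; columns the time
#' points plus a cessation column. Each cell pairs the transcriptomic
#' enrichment direction ("up"/"down"/"ns") with the metabolome
#' significance flag. A pathway is flagged concordant when the metabolome
#' is significant at two or more of the time points where it shows a
#' transcriptomic signal. The cessation column uses the SS-vs-AC results
#' from both omics, so a metabolic perturbation that outlives a reversed
#' transcriptomic signal shows up as a checked, unshaded cell.
#'
#' @param trans_grid Set x time grid from [enrich_all()] (CS vs AC).
#' @param met A `metabolite_matrix`.
#' @param cess_grid Optional one-column (or wider) grid for the SS-vs-AC
#'   enrichment; its first column is used for cessation shading.
#' @param times Time labels to evaluate (default: the grid's columns).
#' @param alpha Metabolite-level significance (default 0.05).
#' @param min_times Recurrence threshold (default 2).
#' @param min_n Minimum per-group non-missing metabolite values.
#' @return A `concordance_matrix`: list with `pathways`, `transcriptome`
#'   (direction grid incl. cessation), `metabolome` (logical grid),
#'   `combined_p`, `concordant` (logical per pathway), and the per-time
#'   metabolite test tables.
#' @export
build_concordance <- function(trans_grid, met, cess_grid = NULL,
                              times = colnames(trans_grid), alpha = 0.05,
                              min_times = 2, min_n = 3) {
  pws <- recurring_pathways(trans_grid, min_times)
  members <- pathway_members(met$pathway_map)
  cols <- c(times, "cessation")
  tdir <- matrix("ns", length(pws), length(cols),
                 dimnames = list(pws, cols))
  tdir[, times] <- trans_grid[pws, times]
  if (!is.null(cess_grid))
    tdir[, "cessation"] <- cess_grid[pws, 1]
  msig <- matrix(NA, length(pws), length(cols),
                 dimnames = list(pws, cols))
  mp <- matrix(NA_real_, length(pws), length(cols),
               dimnames = list(pws, cols))
  tests <- list()
  for (t in times) {
    tests[[t]] <- test_metabolites(met, c("CS", "AC"), t, min_n)
    for (pw in pws) {
      call <- pathway_metabolome_call(tests[[t]], pw, members[[pw]],
                                      alpha)
      msig[pw, t] <- isTRUE(call$significant)
      mp[pw, t] <- call$combined_p
    }
  }
  tests[["cessation"]] <- test_metabolites(met, c("SS", "AC"), "9mo",
                                           min_n)
  for (pw in pws) {
    call <- pathway_metabolome_call(tests[["cessation"]], pw,
                                    members[[pw]], alpha)
    msig[pw, "cessation"] <- isTRUE(call$significant)
    mp[pw, "cessation"] <- call$combined_p
  }
  concordant <- vapply(pws, function(pw) {
    at <- times[tdir[pw, times] != "ns"]
    sum(msig[pw, at], na.rm = TRUE) >= min_times
  }, logical(1))
  structure(list(pathways = pws, transcriptome = tdir,
                 metabolome = msig, combined_p = mp,
                 concordant = concordant, tests = tests),
            class = "concordance_matrix")
}

#' @export
print.concordance_matrix <- function(x, ...) {
  disp <- x$transcriptome
  disp[] <- paste0(c(up = "U", down = "D", ns = "-")[x$transcriptome],
                   ifelse(x$metabolome %in% TRUE, "*", ""))
  print(disp, quote = FALSE)
  cat("U/D: enrichment direction, *: metabolome p<0.05;",
      sum(x$concordant), "pathway(s) concordant at >=2 time points\n")
  invisible(x)
}
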