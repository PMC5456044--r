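#' Assemble the three month-9 contrast triples
#'
#' Joins CS-vs-AC, SS-vs-CS and SS-vs-AC results per gene into the
#' (significance, sign, magnitude) triple the cessation classifier needs.
#' Genes dropped by independent filtering in a contrast count as not
#' significant there with log2FC 0.
#'
#' @param m9 Named list `CSvAC`, `SSvCS`, `SSvAC` of `de_result` data
#'   frames (see [month9_contrasts()]).
#' @return Data frame with columns `gene`, and `sig_*`, `lfc_*` for the
#'   three contrasts.
#' @export
contrast_triples <- function(m9) {
  stopifnot(all(c("CSvAC", "SSvCS", "SSvAC") %in% names(m9)))
  genes <- unique(unlist(lapply(m9, `[[`, "gene")))
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (nm in c("CSvAC", "SSvCS", "SSvAC")) {
    i <- match(genes, m9[[nm]]$gene)
    sig <- m9[[nm]]$significant[i]
    lfc <- m9[[nm]]$log2_fc[i]
    sig[is.na(sig)] <- FALSE
    lfc[is.na(lfc)] <- 0
    out[[paste0("sig_", nm)]] <- sig
    out[[paste0("lfc_", nm)]] <- lfc
  }
  out
}

#' Classify genes into smoking-cessation patterns
#'
#' Applies the decision rules, in order, to each (CSvAC, SSvCS, SSvAC)
#' triple:
#' \describe{
#'   \item{reversible}{DE in CSvAC, DE in SSvCS with the opposite sign,
#'     and *not* DE in SSvAC: expression returned to the air-control
#'     level after cessation.}
#'   \item{persistent}{DE in CSvAC and in SSvAC with the same sign, not
#'     DE in SSvCS: the smoke effect did not move at all.}
#'   \item{semi_reversible / semi_persistent}{DE in all three, SSvCS
#'     opposite to CSvAC and SSvAC sharing its sign: partial return.
#'     Split by relative distance: closer to AC than to CS
#'     (`|log2FC(SSvAC)| < |log2FC(SSvCS)|`) is semi_reversible,
#'     otherwise semi_persistent.}
#'   \item{continuing}{DE in SSvAC with the CSvAC sign but a *larger*
#'     magnitude: the change kept growing after cessation.}
#'   \item{recovery}{DE only in SSvCS: a response triggered by cessation
#'     itself.}
#'   \item{unclassified}{anything else.}
#' }
#' Direction is the CS-vs-AC sign (SS-vs-CS sign for recovery).
#'
#' @param triples Data frame from [contrast_triples()] (or with the same
#'   columns).
#' @return Data frame `gene`, `label`, `direction`.
#' @export
classify_patterns <- function(triples) {
  n <- nrow(triples)
  s1 <- triples$sig_CSvAC; f1 <- triples$lfc_CSvAC
  s2 <- triples$sig_SSvCS; f2 <- triples$lfc_SSvCS
  s3 <- triples$sig_SSvAC; f3 <- triples$lfc_SSvAC
  g1 <- sign(f1); g2 <- sign(f2); g3 <- sign(f3)

  lab <- rep("unclassified", n)
  rev_ <- s1 & s2 & g2 == -g1 & g1 != 0 & !s3
  per_ <- !rev_ & s1 & s3 & g3 == g1 & g1 != 0 & !s2
  semi <- !rev_ & !per_ & s1 & s2 & s3 & g2 == -g1 & g3 == g1 & g1 != 0
  semr <- semi & abs(f3) < abs(f2)
  semp <- semi & !semr
  cont <- !rev_ & !per_ & !semi & s3 & g3 == g1 & abs(f3) > abs(f1)
  reco <- !rev_ & !per_ & !semi & !cont & s2 & !s1 & !s3
  lab[rev_] <- "reversible"
  lab[per_] <- "persistent"
  lab[semr] <- "semi_reversible"
  lab[semp] <- "semi_persistent"
  lab[cont] <- "continuing"
  lab[reco] <- "recovery"

  dir <- ifelse(lab == "recovery", ifelse(g2 > 0, "up", "down"),
                ifelse(g1 != 0, ifelse(g1 > 0, "up", "down"),
                       ifelse(g3 > 0, "up", "down")))
  dir[lab == "unclassified"] <- NA_character_
  data.frame(gene = triples$gene, label = lab, direction = dir,
             stringsAsFactors = FALSE)
}

#' Single-gene pattern call
#'
#' @param sig Logical length-3 vector: significance in CSvAC, SSvCS, SSvAC.
#' @param lfc Numeric length-3 vector of the matching log2 fold changes.
#' @return List `label`, `direction`.
#' @export
classify_gene <- function(sig, lfc) {
  tr <- data.frame(gene = "g", sig_CSvAC = sig[1], lfc_CSvAC = lfc[1],
                   sig_SSvCS = sig[2], lfc_SSvCS = lfc[2],
                   sig_SSvAC = sig[3], lfc_SSvAC = lfc[3])
  out <- classify_patterns(tr)
  list(label = out$label, direction = out$direction)
}

#' Recovery genes: changes unique to the cessation comparison
#'
#' Genes significant in SS-vs-CS but in none of the supplied CS-vs-AC
#' results (month 9 only by default; pass all time points' results to
#' require uniqueness across the whole course), and, when an SS-vs-AC
#' result is supplied, not significant there either.
#'
#' @param de_SSvCS `de_result` for SS vs CS.
#' @param de_CSvAC A `de_result` or list of them (one per time point).
#' @param de_SSvAC Optional `de_result` for SS vs AC.
#' @return Character vector of gene ids.
#' @export
find_recovery_genes <- function(de_SSvCS, de_CSvAC, de_SSvAC = NULL) {
  if (is.data.frame(de_CSvAC)) de_CSvAC <- list(de_CSvAC)
  hits <- de_SSvCS$gene[de_SSvCS$significant]
  for (d in de_CSvAC) hits <- setdiff(hits, d$gene[d$significant])
  if (!is.null(de_SSvAC))
    hits <- setdiff(hits, de_SSvAC$gene[de_SSvAC$significant])
  hits
}

#' Summarize cessation-pattern calls (Table-2-style)
#'
#' Counts by label x direction over the five cessation classes; the
#' percentage denominator is the total of those classes (the genes DE
#' between CS and AC at month 9), excluding recovery and unclassified.
#'
#' @param calls Data frame from [classify_patterns()].
#' @return A `pattern_summary`: list with `counts` (2 x 5 matrix Up/Down),
#'   `percent` (per label, 2 decimals), `total`, and
#'   `percent_reversible_any` (fully or semi reversible share, 1 decimal).
#' @export
summarize_patterns <- function(calls) {
  labs <- PATTERN_LEVELS[1:5]
  cnt <- matrix(0L, 2, length(labs),
                dimnames = list(c("Up", "Down"), labs))
  if (nrow(calls)) {
    keep <- calls$label %in% labs
    tt <- table(factor(ifelse(calls$direction[keep] == "up", "Up", "Down"),
                       levels = c("Up", "Down")),
                factor(calls$label[keep], levels = labs))
    cnt[] <- as.integer(tt)
  }
  pattern_summary_from_counts(cnt["Up", ], cnt["Down", ])
}

#' @rdname summarize_patterns
#' @param up,down Integer vectors of length 5 in the order reversible,
#'   semi_reversible, persistent, semi_persistent, continuing — e.g. a
#'   published table's printed rows.
#' @export
pattern_summary_from_counts <- function(up, down) {
  labs <- PATTERN_LEVELS[1:5]
  stopifnot(length(up) == 5, length(down) == 5)
  cnt <- rbind(Up = as.integer(up), Down = as.integer(down))
  colnames(cnt) <- labs
  total <- sum(cnt)
  pct <- if (total > 0) round(100 * colSums(cnt) / total, 2)
         else setNames(numeric(5), labs)
  rev_any <- if (total > 0)
    round(100 * sum(cnt[, c("reversible", "semi_reversible")]) / total, 1)
    else 0
  structure(list(counts = cnt, percent = pct, total = total,
                 percent_reversible_any = rev_any),
            class = "pattern_summary")
}

#' @export
print.pattern_summary <- function(x, ...) {
  m <- rbind(x$counts, `% of Total` = x$percent)
  print(m)
  cat("total classified:", x$total,
      "| fully or partially reversible:",
      paste0(x$percent_reversible_any, "%\n"))
  invisible(x)
}

#' Classify pathways into cessation patterns
#'
#' The gene rule set applied at the set level: significance comes from the
#' directional enrichment q-values, the sign from the enriched direction,
#' and the magnitude from `|set_stat|`.
#'
#' @param enr_CSvAC,enr_SSvCS,enr_SSvAC [enrich_all()] outputs for the
#'   three month-9 contrasts (their `table` components restricted to
#'   month 9 are used; single-time outputs work directly).
#' @param fdr Significance threshold on q.
#' @return List: `calls` (set-level pattern calls) and `summary`
#'   (a `pattern_summary`).
#' @export
classify_pathways <- function(enr_CSvAC, enr_SSvCS, enr_SSvAC,
                              fdr = 0.10) {
  tri <- data.frame(gene = set_triple(enr_CSvAC, fdr)$set,
                    stringsAsFactors = FALSE)
  for (nm in c("CSvAC", "SSvCS", "SSvAC")) {
    e <- set_triple(switch(nm, CSvAC = enr_CSvAC, SSvCS = enr_SSvCS,
                           SSvAC = enr_SSvAC), fdr)
    i <- match(tri$gene, e$set)
    tri[[paste0("sig_", nm)]] <- e$sig[i] %in% TRUE
    lfc <- e$stat[i]
    lfc[is.na(lfc)] <- 0
    tri[[paste0("lfc_", nm)]] <- lfc
  }
  calls <- classify_patterns(tri)
  names(calls)[1] <- "set"
  list(calls = calls, summary = summarize_patterns(
    data.frame(gene = calls$set, label = calls$label,
               direction = calls$direction)))
}

# reduce a directional enrichment table to one (sig, signed stat) per set
set_triple <- function(enr, fdr) {
  tab <- if (is.list(enr) && !is.data.frame(enr)) enr$table else enr
  sp <- split(tab, tab$set)
  out <- data.frame(set = names(sp), sig = FALSE, stat = 0,
                    stringsAsFactors = FALSE)
  for (i in seq_along(sp)) {
    d <- sp[[i]]
    tested <- !is.na(d$q_value)
    if (!any(tested)) next
    d <- d[tested, , drop = FALSE]
    j <- which.min(d$q_value)
    s <- abs(d$set_stat[j]) * ifelse(d$direction[j] == "up", 1, -1)
    out$sig[i] <- d$q_value[j] <= fdr
    out$stat[i] <- s
  }
  out[match(unique(tab$set), out$set), ]
}
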