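#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> per-time differential expression ->
#' set enrichment -> cessation patterns -> time trends -> metabolome
#' concordance, writing tab-delimited stage outputs, three summary tables
#' and a JSON run manifest (seed, thresholds, decision flags, file hashes)
#' into `output_dir`. Re-running the same config reproduces byte-identical
#' outputs.
#'
#' @param config A list, or path to a YAML file, with optional blocks
#'   `simulate` (arguments to [simulation_spec()]) or `input` (paths:
#'   `counts`, `design`, `gmt`, and optionally `metabolites`,
#'   `metabolite_map`), plus `seed`, `fdr`, `min_fc`, `met_alpha`.
#' @param output_dir Output directory (created if absent).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = list(), output_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  fdr <- config$fdr %||% 0.10
  min_fc <- config$min_fc %||% 1.5
  met_alpha <- config$met_alpha %||% 0.05
  seed <- config$seed %||% 1L
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)

  # ---- stage: data ------------------------------------------------------
  met <- NULL
  if (!is.null(config$input)) {
    inp <- config$input
    x <- read_counts(inp$counts, inp$design)
    sets <- read_gmt(inp$gmt)
    if (!is.null(inp$metabolites))
      met <- read_metabolites(inp$metabolites, inp$metabolite_map,
                              inp$design)
    truth <- NULL
  } else {
    spec <- do.call(simulation_spec,
                    c(config$simulate, list(seed = seed)))
    sim <- simulate_dataset(spec)
    x <- sim$counts
    sets <- sim$sets
    met <- sim$metabolites
    truth <- sim$truth
  }
  x <- active_samples(x, include_1mo = isTRUE(config$include_1mo))
  s <- x$samples
  times <- unique(s$time_label[s$group %in% c("AC", "CS")])
  times <- names(TIME_DAYS)[names(TIME_DAYS) %in% times]

  # ---- stage: differential expression -----------------------------------
  de <- lapply(times, function(t)
    de_test(x, c("CS", "AC"), t, fdr = fdr, min_fc = min_fc))
  names(de) <- times
  m9 <- month9_contrasts(x, fdr = fdr, min_fc = min_fc)
  de[["9mo"]] <- m9$CSvAC
  for (t in times)
    write_tsv(de[[t]], file.path(output_dir, paste0("de_CSvAC_", t,
                                                    ".tsv")))
  write_tsv(m9$SSvCS, file.path(output_dir, "de_SSvCS_9mo.tsv"))
  write_tsv(m9$SSvAC, file.path(output_dir, "de_SSvAC_9mo.tsv"))

  # ---- stage: enrichment ------------------------------------------------
  enr <- enrich_all(x, sets, c("CS", "AC"), times = times, fdr = fdr)
  enr_sscs <- enrich_all(x, sets, c("SS", "CS"), times = "9mo",
                         fdr = fdr)
  enr_ssac <- enrich_all(x, sets, c("SS", "AC"), times = "9mo",
                         fdr = fdr)
  write_tsv(enr$table, file.path(output_dir, "enrichment_CSvAC.tsv"))

  # ---- stage: cessation patterns ----------------------------------------
  calls <- classify_patterns(contrast_triples(m9))
  pat_sum <- summarize_patterns(calls)
  recovery <- find_recovery_genes(m9$SSvCS, m9$CSvAC, m9$SSvAC)
  pw <- classify_pathways(sub_time(enr, "9mo"), enr_sscs, enr_ssac,
                          fdr = fdr)
  write_tsv(calls, file.path(output_dir, "pattern_calls.tsv"))
  writeLines(recovery, file.path(output_dir, "recovery_genes.txt"))

  # ---- stage: trends ----------------------------------------------------
  trends <- trend_analysis(x, alpha = fdr)
  write_tsv(trends, file.path(output_dir, "trend_calls.tsv"))

  # ---- stage: concordance -----------------------------------------------
  conc <- NULL
  if (!is.null(met)) {
    conc <- build_concordance(enr$grid, met, cess_grid = enr_ssac$grid,
                              times = times, alpha = met_alpha)
    write_tsv(concordance_table(conc),
              file.path(output_dir, "concordance.tsv"))
  }

  # ---- summaries + manifest ---------------------------------------------
  tabs <- table_summaries(de, m9, enr, enr_sscs, enr_ssac, pat_sum,
                          pw$summary, conc)
  write_tsv(tabs$table1, file.path(output_dir, "table1_counts.tsv"))
  write_tsv(tabs$table2, file.path(output_dir, "table2_patterns.tsv"))
  if (!is.null(tabs$table3))
    write_tsv(tabs$table3, file.path(output_dir, "table3_concordance.tsv"))

  files <- list.files(output_dir, pattern = "\\.(tsv|txt)$",
                      full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("smokecourse")),
    seed = seed,
    thresholds = list(fdr = fdr, min_fc = min_fc,
                      metabolite_alpha = met_alpha),
    decisions = list(pattern_tie_break = "relative distance |SSvAC| vs |SSvCS|",
                     recovery_scope = "month9",
                     metabolome_aggregation = "fisher (min-p reported)",
                     tier_error_control = "BH across genes within tier"),
    n_genes = nrow(x$counts), n_samples = ncol(x$counts),
    times = times,
    metabolites_included = !is.null(met),
    hashes = as.list(setNames(unname(tools::md5sum(sort(files))),
                              basename(sort(files)))))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(manifest, list(truth = truth, pattern_summary = pat_sum,
                             pathway_summary = pw$summary,
                             concordance = conc)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tsv <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

sub_time <- function(enr, t) {
  list(table = enr$table[enr$table$time == t, , drop = FALSE],
       grid = enr$grid[, t, drop = FALSE], fdr = enr$fdr)
}

concordance_table <- function(conc) {
  code <- matrix(paste0(c(up = "U", down = "D", ns = "ns")[conc$transcriptome],
                        ifelse(conc$metabolome %in% TRUE, "/M+", "/M-")),
                 nrow = nrow(conc$transcriptome),
                 dimnames = dimnames(conc$transcriptome))
  data.frame(pathway = conc$pathways, code,
             concordant = conc$concordant, check.names = FALSE,
             row.names = NULL)
}

#' Summary tables across all stages
#'
#' Builds the three study-style summary tables: per-time significant
#' gene/pathway counts split by direction (plus the two cessation
#' contrasts), the cessation-pattern summary for genes and pathways with
#' "% of Total" rows, and the concordance grid.
#'
#' @param de Named list of CS-vs-AC `de_result`s per time.
#' @param m9 [month9_contrasts()] output.
#' @param enr,enr_sscs,enr_ssac [enrich_all()] outputs (CSvAC across
#'   times; SSvCS and SSvAC at month 9).
#' @param pat_sum,pw_sum `pattern_summary` objects for genes resp.
#'   pathways.
#' @param conc Optional `concordance_matrix`.
#' @return List `table1`, `table2`, `table3` of data frames.
#' @export
table_summaries <- function(de, m9, enr, enr_sscs, enr_ssac, pat_sum,
                            pw_sum, conc = NULL) {
  times <- names(de)
  count_de <- function(d, dir)
    sum(d$significant & (if (dir == "up") d$log2_fc > 0
                         else d$log2_fc < 0))
  count_enr <- function(e, t, dir)
    sum(e$table$significant[e$table$time == t &
                              e$table$direction == dir])
  t1 <- data.frame(row.names = NULL,
    quantity = c("genes_up", "genes_down", "pathways_up",
                 "pathways_down"))
  for (t in times)
    t1[[t]] <- c(count_de(de[[t]], "up"), count_de(de[[t]], "down"),
                 count_enr(enr, t, "up"), count_enr(enr, t, "down"))
  t1[["SSvCS"]] <- c(count_de(m9$SSvCS, "up"), count_de(m9$SSvCS, "down"),
                     count_enr(enr_sscs, "9mo", "up"),
                     count_enr(enr_sscs, "9mo", "down"))
  t1[["SSvAC"]] <- c(count_de(m9$SSvAC, "up"), count_de(m9$SSvAC, "down"),
                     count_enr(enr_ssac, "9mo", "up"),
                     count_enr(enr_ssac, "9mo", "down"))

  t2 <- rbind(
    data.frame(block = "genes", row = c("Up", "Down", "pct_of_total"),
               rbind(pat_sum$counts, pat_sum$percent),
               total = c(rowSums(pat_sum$counts), 100),
               check.names = FALSE, row.names = NULL),
    data.frame(block = "pathways", row = c("Up", "Down", "pct_of_total"),
               rbind(pw_sum$counts, pw_sum$percent),
               total = c(rowSums(pw_sum$counts), 100),
               check.names = FALSE, row.names = NULL))

  list(table1 = t1, table2 = t2,
       table3 = if (!is.null(conc)) concordance_table(conc))
}
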