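#' Read and validate a sample design sheet
#'
#' The design sheet declares the experimental unit behind every column of the
#' count (or metabolite) matrix: an air-control (AC), smoke-exposed (CS), or
#' stop-smoking (SS) animal sacrificed at one of the study time points.
#' Cessation (SS) animals exist only in the month-9 cohort: they smoked six
#' months and then breathed ambient air for three.
#'
#' @param path Tab-delimited file with columns `sample_id`, `group`,
#'   `time_label`.
#' @return A data frame with columns `sample_id`, `group`, `time_label`,
#'   `time_days` (via the 30-day-month mapping) and `excluded`, which flags
#'   the 1-month cohort excluded by default on data-quality grounds.
#' @export
read_design <- function(path) {
  d <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                  colClasses = "character")
  need <- c("sample_id", "group", "time_label")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("design file is missing column(s): ", paste(miss, collapse = ", "))
  validate_design(d[need])
}

validate_design <- function(d) {
  if (anyDuplicated(d$sample_id))
    stop("duplicate sample_id in design: ",
         d$sample_id[duplicated(d$sample_id)][1])
  bad <- setdiff(unique(d$group), GROUPS)
  if (length(bad))
    stop("unknown group label: ", bad[1])
  bad <- setdiff(unique(d$time_label), names(TIME_DAYS))
  if (length(bad))
    stop("unknown time_label: ", bad[1])
  ss_off <- d$group == "SS" & d$time_label != "9mo"
  if (any(ss_off))
    stop("SS sample not at 9mo: ", d$sample_id[ss_off][1])
  d$time_days <- unname(TIME_DAYS[d$time_label])
  d$excluded <- d$time_label == "1mo"
  d
}

#' Read a gene-by-sample count matrix with its design
#'
#' @param path Tab-delimited text: header row of sample ids, first column
#'   gene ids, integer counts.
#' @param design_path Design sheet, see [read_design()]. Columns of the
#'   returned object are reordered to the design order.
#' @return A `count_matrix`: list with integer matrix `counts`
#'   (genes x samples) and data frame `samples`.
#' @export
read_counts <- function(path, design_path) {
  samples <- read_design(design_path)
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  gene_ids <- as.character(tab[[1]])
  if (anyDuplicated(gene_ids))
    stop("duplicate gene id: ", gene_ids[duplicated(gene_ids)][1])
  m <- as.matrix(tab[, -1, drop = FALSE])
  miss <- setdiff(samples$sample_id, colnames(m))
  if (length(miss))
    stop("design sample absent from count matrix: ", miss[1])
  extra <- setdiff(colnames(m), samples$sample_id)
  if (length(extra))
    stop("count matrix sample absent from design: ", extra[1])
  if (!is.numeric(m) || anyNA(m))
    stop("non-numeric or missing count value in ", path)
  if (any(m < 0)) {
    i <- which(m < 0, arr.ind = TRUE)[1, ]
    stop("negative count for gene ", gene_ids[i[1]])
  }
  if (any(m != round(m))) {
    i <- which(m != round(m), arr.ind = TRUE)[1, ]
    stop("non-integer count for gene ", gene_ids[i[1]])
  }
  m <- m[, samples$sample_id, drop = FALSE]
  storage.mode(m) <- "integer"
  rownames(m) <- gene_ids
  count_matrix(m, samples)
}

#' Construct a count matrix object
#'
#' @param counts Non-negative integer matrix, genes in rows; rownames are
#'   gene ids.
#' @param samples Design data frame (one row per column of `counts`).
#' @export
count_matrix <- function(counts, samples) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)))
  if (!all(c("time_days", "excluded") %in% names(samples)))
    samples <- validate_design(samples)
  if (ncol(counts) != nrow(samples))
    stop("counts has ", ncol(counts), " columns but design has ",
         nrow(samples), " samples")
  if (is.null(colnames(counts))) colnames(counts) <- samples$sample_id
  if (!identical(colnames(counts), samples$sample_id))
    stop("count columns do not match design sample order")
  structure(list(counts = counts, samples = samples),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix: ", nrow(x$counts), " genes x ", ncol(x$counts),
      " samples\n", sep = "")
  print(table(group = x$samples$group, time = x$samples$time_label))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix by sample and/or gene
#'
#' @param x A `count_matrix`.
#' @param samples Logical or index vector over samples, or sample ids.
#' @param genes Optional gene-id or index vector.
#' @export
subset_samples <- function(x, samples, genes = NULL) {
  if (is.character(samples)) samples <- match(samples, x$samples$sample_id)
  cm <- x$counts[, samples, drop = FALSE]
  if (!is.null(genes)) cm <- cm[genes, , drop = FALSE]
  count_matrix(cm, x$samples[samples, , drop = FALSE])
}

#' Drop samples flagged `excluded` (the 1-month cohort)
#'
#' @param x A `count_matrix` or `metabolite_matrix`.
#' @param include_1mo Set `TRUE` to keep the flagged samples.
#' @export
active_samples <- function(x, include_1mo = FALSE) {
  keep <- if (include_1mo) rep(TRUE, nrow(x$samples)) else !x$samples$excluded
  if (inherits(x, "count_matrix")) return(subset_samples(x, keep))
  x$abundances <- x$abundances[, keep, drop = FALSE]
  x$samples <- x$samples[keep, , drop = FALSE]
  x
}

#' Write a count matrix (and optionally its design) to tab-delimited text
#'
#' @param x A `count_matrix`.
#' @param path Output path for the counts table.
#' @param design_path Optional output path for the design sheet.
#' @export
write_counts <- function(x, path, design_path = NULL) {
  df <- data.frame(gene_id = rownames(x$counts), x$counts,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(design_path)) write_design(x$samples, design_path)
  invisible(path)
}

#' @rdname write_counts
#' @param samples A design data frame.
#' @export
write_design <- function(samples, path) {
  write.table(samples[c("sample_id", "group", "time_label")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' One set per line: name, description, then member gene ids, tab-separated.
#' Duplicate members within a set are dropped.
#'
#' @param path GMT file path.
#' @return A `geneset_db`: named list of unique character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("GMT line ", i, " has fewer than 3 fields")
    if (f[1] %in% names(sets))
      stop("duplicate set name at GMT line ", i, ": ", f[1])
    sets[[f[1]]] <- unique(f[-(1:2)])
  }
  structure(sets, class = "geneset_db")
}

#' @rdname read_gmt
#' @param db A `geneset_db` (or plain named list of gene-id vectors).
#' @param descriptions Optional character vector of per-set descriptions.
#' @export
write_gmt <- function(db, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(db))
  lines <- vapply(seq_along(db), function(i) {
    paste(c(names(db)[i], descriptions[i], db[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a metabolite abundance matrix with a metabolite-to-pathway map
#'
#' Abundances are non-negative; a configurable token (default `"NA"`) marks
#' values missing due to instrument sensitivity or matrix interference.
#' Missingness is explicit: a zero is a measured value, not a gap.
#'
#' @param path Tab-delimited abundance table (metabolite ids in first
#'   column, samples in header).
#' @param map_path Two-column tab-delimited file: metabolite id, pathway
#'   name; one pair per line, repeated ids allowed (multi-pathway
#'   metabolites).
#' @param design_path Design sheet shared with the transcriptome.
#' @param missing_token Cell content interpreted as missing.
#' @return A `metabolite_matrix`: list with numeric matrix `abundances`
#'   (NA = missing), `samples`, and `pathway_map` (named list metabolite ->
#'   character vector of pathways).
#' @export
read_metabolites <- function(path, map_path, design_path,
                             missing_token = "NA") {
  samples <- read_design(design_path)
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", na.strings = character(0))
  ids <- tab[[1]]
  if (anyDuplicated(ids))
    stop("duplicate metabolite id: ", ids[duplicated(ids)][1])
  raw <- as.matrix(tab[, -1, drop = FALSE])
  m <- suppressWarnings(
    matrix(as.numeric(ifelse(raw == missing_token, NA, raw)),
           nrow = nrow(raw), dimnames = list(ids, colnames(raw))))
  bad_tok <- is.na(m) & raw != missing_token
  if (any(bad_tok))
    stop("non-numeric abundance token: ", raw[bad_tok][1])
  if (any(m < 0, na.rm = TRUE))
    stop("negative abundance for metabolite ",
         ids[which(rowSums(m < 0, na.rm = TRUE) > 0)[1]])
  miss <- setdiff(samples$sample_id, colnames(m))
  if (length(miss))
    stop("design sample absent from metabolite matrix: ", miss[1])
  extra <- setdiff(colnames(m), samples$sample_id)
  if (length(extra))
    stop("metabolite matrix sample absent from design: ", extra[1])
  m <- m[, samples$sample_id, drop = FALSE]

  map_tab <- read.delim(map_path, header = FALSE, sep = "\t",
                        colClasses = "character")
  if (ncol(map_tab) < 2) stop("pathway map needs 2 columns")
  unknown <- setdiff(unique(map_tab[[1]]), ids)
  if (length(unknown))
    warning("pathway map metabolite(s) absent from matrix: ",
            paste(head(unknown, 3), collapse = ", "))
  keep <- map_tab[[1]] %in% ids
  pathway_map <- split(map_tab[[2]][keep], map_tab[[1]][keep])
  pathway_map <- lapply(pathway_map, unique)

  metabolite_matrix(m, samples, pathway_map)
}

#' @rdname read_metabolites
#' @param abundances Numeric matrix with NA for missing.
#' @param samples Design data frame.
#' @param pathway_map Named list: metabolite id -> pathway names.
#' @export
metabolite_matrix <- function(abundances, samples, pathway_map) {
  if (!all(c("time_days", "excluded") %in% names(samples)))
    samples <- validate_design(samples)
  stopifnot(ncol(abundances) == nrow(samples))
  if (is.null(colnames(abundances)))
    colnames(abundances) <- samples$sample_id
  structure(list(abundances = abundances, samples = samples,
                 pathway_map = pathway_map),
            class = "metabolite_matrix")
}

#' @rdname read_metabolites
#' @param x A `metabolite_matrix`.
#' @export
write_metabolites <- function(x, path, map_path = NULL, design_path = NULL,
                              missing_token = "NA") {
  out <- x$abundances
  chr <- matrix(ifelse(is.na(out), missing_token, format(out, digits = 15,
                                                         trim = TRUE)),
                nrow = nrow(out), dimnames = dimnames(out))
  df <- data.frame(metabolite_id = rownames(out), chr, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(map_path)) {
    pairs <- data.frame(
      metabolite = rep(names(x$pathway_map),
                       lengths(x$pathway_map)),
      pathway = unlist(x$pathway_map, use.names = FALSE))
    write.table(pairs, map_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(design_path)) write_design(x$samples, design_path)
  invisible(path)
}

# invert metabolite -> pathways map into pathway -> metabolites
pathway_members <- function(pathway_map) {
  pairs <- data.frame(
    met = rep(names(pathway_map), lengths(pathway_map)),
    pw = unlist(pathway_map, use.names = FALSE))
  lapply(split(pairs$met, pairs$pw), unique)
}
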