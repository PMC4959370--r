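#' Read a gene-expression matrix from TSV
#'
#' Reads a tab-separated expression table (first column = probe or gene
#' identifiers, header row = sample identifiers) into a numeric matrix with
#' genes in rows.  When a probe-to-gene map is supplied, probes mapping to the
#' same gene are collapsed to their per-sample median and probes absent from
#' the map are dropped (the count is logged).
#'
#' @param path Path to a UTF-8 TSV file.  Rows are genes (or probes) unless
#'   `transpose = TRUE`.
#' @param probe_map Optional probe-to-gene mapping: either a two-column
#'   data.frame (probe, gene) or a path to a headerless two-column TSV.
#'   Each probe must map to exactly one gene.
#' @param transpose If `TRUE` the file stores samples in rows and the matrix
#'   is transposed after reading.
#' @param na_action What to do with missing expression values: `"error"`
#'   (default; correlation and scoring require complete data) or
#'   `"drop_genes"`, which removes genes containing any missing value and
#'   logs how many were dropped.
#' @return Numeric matrix (genes x samples) with unique `rownames` and
#'   `colnames`.
#' @seealso [collapse_probes()], [read_survival()], [align_samples()]
#' @export
read_expression <- function(path, probe_map = NULL, transpose = FALSE,
                            na_action = c("error", "drop_genes")) {
  na_action <- match.arg(na_action)
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(raw) < 2L)
    stop("expression file must have an identifier column plus >= 1 sample column: ", path)
  ids <- raw[[1L]]
  sample_ids <- colnames(raw)[-1L]
  if (anyDuplicated(sample_ids))
    stop("duplicate sample IDs in header: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  mat <- matrix(NA_real_, nrow = nrow(raw), ncol = length(sample_ids),
                dimnames = list(ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    col <- raw[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col) & !col %in% c("NA", "NaN", ""))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at row %d, column '%s' of %s",
                   col[bad[1L]], bad[1L], sample_ids[j], path))
    mat[, j] <- num
  }
  if (transpose) mat <- t(mat)
  if (anyDuplicated(rownames(mat)) && is.null(probe_map))
    stop("duplicate gene IDs and no probe_map to collapse them")
  if (!is.null(probe_map)) mat <- collapse_probes(mat, probe_map)
  if (anyNA(mat)) {
    if (na_action == "error") {
      idx <- which(is.na(mat), arr.ind = TRUE)[1L, ]
      stop(sprintf("missing expression value at gene '%s', sample '%s' (use na_action = 'drop_genes' to remove incomplete genes)",
                   rownames(mat)[idx[1L]], colnames(mat)[idx[2L]]))
    }
    drop <- rowSums(is.na(mat)) > 0L
    .log("dropped %d/%d genes with missing values", sum(drop), nrow(mat))
    mat <- mat[!drop, , drop = FALSE]
  }
  if (!all(is.finite(mat))) stop("expression matrix contains non-finite values")
  mat
}

#' Collapse probe-level rows to gene level by the per-sample median
#'
#' Probes sharing a gene are reduced to one row holding, for every sample,
#' the median of the probe values.  Probes absent from the map are dropped
#' with a logged count; a map with one probe per gene leaves values unchanged
#' (rows are renamed and reordered by gene).
#'
#' @param mat Numeric matrix, probes in rows.
#' @param probe_map Two-column data.frame (probe, gene) or path to a
#'   headerless two-column TSV.
#' @return Numeric matrix with one row per mapped gene.
#' @export
collapse_probes <- function(mat, probe_map) {
  if (is.character(probe_map) && length(probe_map) == 1L)
    probe_map <- read.delim(probe_map, header = FALSE, sep = "\t",
                            stringsAsFactors = FALSE)
  probe_map <- as.data.frame(probe_map)
  if (ncol(probe_map) < 2L) stop("probe_map needs two columns: probe, gene")
  probes <- as.character(probe_map[[1L]])
  genes <- as.character(probe_map[[2L]])
  if (anyDuplicated(probes))
    stop("probe_map maps some probe to more than one gene")
  keep <- rownames(mat) %in% probes
  if (!any(keep)) stop("no probes in the matrix are present in probe_map")
  if (any(!keep))
    .log("dropped %d/%d probes absent from the probe map", sum(!keep), nrow(mat))
  mat <- mat[keep, , drop = FALSE]
  gene_of <- setNames(genes, probes)[rownames(mat)]
  groups <- split(seq_len(nrow(mat)), gene_of)
  out <- matrix(NA_real_, nrow = length(groups), ncol = ncol(mat),
                dimnames = list(names(groups), colnames(mat)))
  for (k in seq_along(groups)) {
    rows <- groups[[k]]
    out[k, ] <- if (length(rows) == 1L) mat[rows, ]
                else apply(mat[rows, , drop = FALSE], 2L, median)
  }
  out
}

#' Read a clinical survival table from TSV
#'
#' @param path Path to a TSV file with one row per sample.
#' @param sample_col,time_col,event_col Column names holding the sample
#'   identifier, the follow-up time (non-negative) and the event indicator
#'   (1 = event observed, 0 = right-censored).
#' @param covariate_cols Optional character vector of categorical covariate
#'   columns to retain (e.g. ER status, TNBC flag, grade).  `NULL` keeps every
#'   remaining column.  Unknown values (`NA` in the file) stay missing.
#' @return data.frame with columns `sample`, `time`, `event` followed by the
#'   covariates, covariates as factors.
#' @export
read_survival <- function(path, sample_col = "sample", time_col = "time",
                          event_col = "event", covariate_cols = NULL) {
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  for (col in c(sample_col, time_col, event_col))
    if (!col %in% colnames(tab))
      stop(sprintf("clinical file %s is missing required column '%s'", path, col))
  out <- data.frame(sample = as.character(tab[[sample_col]]),
                    time = as.numeric(tab[[time_col]]),
                    event = as.numeric(tab[[event_col]]),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$sample))
    stop("duplicate sample IDs in clinical table")
  if (anyNA(out$time) || any(out$time < 0))
    stop("column '", time_col, "' must be non-negative and complete")
  if (anyNA(out$event) || !all(out$event %in% c(0, 1)))
    stop("column '", event_col, "' must contain only 0 (censored) and 1 (event)")
  covs <- setdiff(colnames(tab), c(sample_col, time_col, event_col))
  if (!is.null(covariate_cols)) {
    missing_cov <- setdiff(covariate_cols, colnames(tab))
    if (length(missing_cov))
      stop("covariate column(s) not found: ", paste(missing_cov, collapse = ", "))
    covs <- covariate_cols
  }
  for (col in covs) out[[col]] <- factor(tab[[col]])
  out
}

#' Restrict an expression matrix and survival table to their shared samples
#'
#' Both inputs are reduced to the intersection of their sample identifiers,
#' in the expression matrix's column order.  The intersection size is logged.
#'
#' @param expr Numeric matrix, samples in columns.
#' @param surv data.frame as returned by [read_survival()].
#' @return List with elements `expr` and `surv`, sample-aligned.
#' @export
align_samples <- function(expr, surv) {
  shared <- intersect(colnames(expr), surv$sample)
  if (!length(shared))
    stop("no samples shared between expression matrix and survival table")
  .log("aligned on %d shared samples (%d expression, %d clinical)",
       length(shared), ncol(expr), nrow(surv))
  expr <- expr[, shared, drop = FALSE]
  surv <- surv[match(shared, surv$sample), , drop = FALSE]
  rownames(surv) <- NULL
  list(expr = expr, surv = surv)
}

#' Write prognostic modules to a GMT gene-set file
#'
#' Each module emits two tab-separated lines, `<label>_high` and
#' `<label>_low`, holding the module's high-risk and low-risk gene sets.
#'
#' @param modules Non-empty list of modules as produced by [build_modules()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_modules_gmt <- function(modules, path) {
  if (!length(modules)) stop("cannot write an empty module list to ", path)
  lines <- unlist(lapply(modules, function(m) {
    tag <- gsub("[^A-Za-z0-9]+", "_", m$label)
    c(paste(c(paste0(tag, "_high"), "high-risk side", m$high), collapse = "\t"),
      paste(c(paste0(tag, "_low"), "low-risk side", m$low), collapse = "\t"))
  }))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read prognostic modules back from a GMT file written by [write_modules_gmt()]
#'
#' @param path Path to a GMT file whose set names carry `_high` / `_low`
#'   suffixes pairing the two sides of each module.
#' @return List of modules (label, high, low).
#' @export
read_modules_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1L), 1L)
  is_high <- grepl("_high$", names(sets))
  labels <- sub("_(high|low)$", "", names(sets))
  out <- lapply(unique(labels), function(lab) {
    list(label = gsub("_", " ", lab),
         high = unlist(sets[is_high & labels == lab], use.names = FALSE),
         low = unlist(sets[!is_high & labels == lab], use.names = FALSE))
  })
  out
}

#' Serialize results to JSON / read them back
#'
#' Thin wrappers around jsonlite with settings that round-trip numeric
#' content losslessly (full precision, scalars unboxed).
#'
#' @param obj List or data.frame to serialize.
#' @param path File path.
#' @return `path` (write) or the parsed object (read).
#' @export
write_results_json <- function(obj, path) {
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_results_json
#' @export
read_results_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
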