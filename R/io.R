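## Plain-text I/O: panel TSV + JSON sidecar, cohort CSV, edge CSV,
## results JSON, and the flat key=value pipeline configuration.
## Numeric text is written at 17 significant digits so that write/read
## round-trips are exact for doubles.

fmtNum <- function(x) sprintf("%.17g", x)

#' Read and write time-series panels, cohort tables and edge matrices
#'
#' Panels are stored one subject per TSV file (rows = timepoints,
#' columns = `node_1..node_N`, tab-separated, 17 significant digits) with
#' a JSON sidecar carrying `tr_seconds`, `subject_id` and optionally
#' `group`. Cohort tables are CSV with columns
#' `subject_id,group,age,sex,headcoil,motion`. Edge matrices are CSV with
#' a `subject_id` column plus `edge_0001..`, accompanied by a pair-map
#' CSV (`edge,node_i,node_j`). Malformed headers, non-finite cells and
#' TR mismatches are rejected with the offending file and line.
#'
#' @param panel a [TimeSeriesPanel-class].
#' @param dir directory for the per-subject TSV/JSON files.
#' @param cohort optional cohort data.frame; its `group` column is copied
#'   into each subject's sidecar.
#' @return `writePanels` returns the file paths invisibly; `readPanels`
#'   a [TimeSeriesPanel-class].
#' @export
writePanels <- function(panel, dir, cohort = NULL) {
  stopifnot(is(panel, "TimeSeriesPanel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(nSubjects(panel))
  for (s in seq_len(nSubjects(panel))) {
    sid <- subjectIds(panel)[s]
    m <- t(panel@values[[s]])          # timepoints x nodes
    txt <- apply(m, 2, fmtNum)
    colnames(txt) <- sprintf("node_%d", seq_len(nNodes(panel)))
    path <- file.path(dir, paste0(sid, ".tsv"))
    utils::write.table(txt, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    side <- list(tr_seconds = trSeconds(panel), subject_id = sid)
    if (!is.null(cohort)) {
      g <- cohort$group[match(sid, cohort$subject_id)]
      if (!is.na(g)) side$group <- g
    }
    jsonlite::write_json(side, file.path(dir, paste0(sid, ".json")),
                         auto_unbox = TRUE, digits = NA)
    paths[s] <- path
  }
  invisible(paths)
}

#' @rdname writePanels
#' @export
readPanels <- function(dir) {
  tsv <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  if (!length(tsv)) stop("no panel TSV files found in ", dir)
  vals <- list(); ids <- character(); trs <- numeric()
  for (path in tsv) {
    side <- sub("\\.tsv$", ".json", path)
    if (!file.exists(side))
      stop("missing JSON sidecar for ", basename(path))
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (is.null(meta$tr_seconds) || is.null(meta$subject_id))
      stop("sidecar ", basename(side),
           " must define tr_seconds and subject_id")
    d <- utils::read.delim(path, check.names = FALSE)
    expected <- sprintf("node_%d", seq_len(ncol(d)))
    if (!identical(colnames(d), expected))
      stop(sprintf("%s line 1: header must be %s..%s", basename(path),
                   expected[1], expected[length(expected)]))
    m <- unname(as.matrix(d))
    if (!all(is.finite(m))) {
      badRow <- which(!apply(is.finite(m), 1, all))[1]
      stop(sprintf("%s line %d: non-finite cell", basename(path),
                   badRow + 1L))
    }
    vals[[length(vals) + 1L]] <- t(m)
    ids <- c(ids, meta$subject_id)
    trs <- c(trs, meta$tr_seconds)
  }
  if (length(unique(trs)) != 1L)
    stop(sprintf("TR mismatch across subjects: %s",
                 paste(unique(trs), collapse = ", ")))
  timeSeriesPanel(vals, trSeconds = trs[1], subjectIds = ids)
}

cohortColumns <- c("subject_id", "group", "age", "sex", "headcoil",
                   "motion")

#' @rdname writePanels
#' @param path file path.
#' @export
writeCohort <- function(cohort, path) {
  miss <- setdiff(cohortColumns, colnames(cohort))
  if (length(miss))
    stop(paste0("cohort table is missing column(s): ",
                paste(miss, collapse = ", ")))
  out <- cohort[, cohortColumns]
  for (cc in c("age", "motion")) out[[cc]] <- fmtNum(out[[cc]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writePanels
#' @export
readCohort <- function(path) {
  d <- utils::read.csv(path)
  miss <- setdiff(cohortColumns, colnames(d))
  if (length(miss))
    stop(paste0(basename(path), ": missing column(s): ",
                paste(miss, collapse = ", ")))
  if (any(!stats::complete.cases(d[, cohortColumns]))) {
    bad <- which(!stats::complete.cases(d[, cohortColumns]))[1]
    stop(sprintf("%s line %d: missing value", basename(path), bad + 1L))
  }
  d
}

#' @rdname writePanels
#' @param ce a [ConnectivityExperiment-class].
#' @export
writeEdgeMatrix <- function(ce, path) {
  stopifnot(is(ce, "ConnectivityExperiment"))
  m <- edgeValues(ce)                  # subjects x edges
  txt <- apply(m, 2, fmtNum)
  if (is.null(dim(txt))) txt <- matrix(txt, nrow = 1L)
  colnames(txt) <- sprintf("edge_%04d", seq_len(ncol(m)))
  out <- cbind(subject_id = subjectIds(ce), txt)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  pairPath <- sub("\\.csv$", "_pairs.csv", path)
  pairs <- edgePairs(nNodes(ce))
  utils::write.csv(data.frame(edge = seq_len(nrow(pairs)),
                              node_i = pairs[, 1], node_j = pairs[, 2]),
                   pairPath, row.names = FALSE, quote = FALSE)
  invisible(c(path, pairPath))
}

#' @rdname writePanels
#' @param metric metric tag for the reconstructed experiment.
#' @export
readEdgeMatrix <- function(path, metric = "sfc_z") {
  d <- utils::read.csv(path, check.names = FALSE)
  if (colnames(d)[1] != "subject_id")
    stop(basename(path), ": first column must be subject_id")
  ne <- ncol(d) - 1L
  n <- (1 + sqrt(1 + 8 * ne)) / 2
  if (n != round(n))
    stop(sprintf("%s: %d edge columns do not match any whole node count",
                 basename(path), ne))
  expected <- sprintf("edge_%04d", seq_len(ne))
  if (!identical(colnames(d)[-1], expected))
    stop(basename(path), ": edge columns must be named edge_0001..")
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$subject_id
  connectivityExperiment(m, metric = metric, nNodes = as.integer(n))
}

#' Flat key=value pipeline configuration
#'
#' The pipeline configuration is a flat text file of `key = value` lines
#' (units in key names, `#` comments allowed) that round-trips
#' losslessly. Keys: `panels_dir`, `cohort_csv`, `out_dir`,
#' `band_low_hz`, `band_high_hz`, `trim`, `lambda`, `n_surrogates`,
#' `n_perm`, `primary_p`, `sd_convention`, `reference_group`,
#' `seed_surrogate`, `seed_nbs`.
#'
#' @param path config file path.
#' @return named list of configuration values.
#' @export
readPipelineConfig <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(.*)$", lines))
  bad <- which(vapply(kv, length, integer(1)) != 3L)
  if (length(bad))
    stop(sprintf("%s line %d: expected 'key = value'", basename(path),
                 bad[1]))
  vals <- lapply(kv, function(m) {
    v <- trimws(m[3])
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num) && grepl("^[-+0-9.eE]+$", v)) num else v
  })
  cfg <- setNames(vals, vapply(kv, `[`, character(1), 2))
  defaults <- list(band_low_hz = 0.04, band_high_hz = 0.07, trim = 10,
                   lambda = 0.1, n_surrogates = 1000, n_perm = 5000,
                   primary_p = 0.05, sd_convention = "sample",
                   reference_group = "SCI", seed_surrogate = 1,
                   seed_nbs = 1)
  for (k in names(defaults))
    if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  cfg
}

#' @rdname readPipelineConfig
#' @param config named list of configuration values.
#' @export
writePipelineConfig <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    v <- if (is.numeric(v)) fmtNum(v) else as.character(v)
    sprintf("%s = %s", k, v)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
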