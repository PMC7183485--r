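# Delimiter auto-detection between comma and tab: whichever occurs more
# often in the header line wins; ties go to tab.
detect_delim <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (lengths(regmatches(hdr, gregexpr(",", hdr, fixed = TRUE))) >
      lengths(regmatches(hdr, gregexpr("\t", hdr, fixed = TRUE)))) "," else "\t"
}

# Fixed-precision delimited writer (6 significant digits on numeric
# columns) so repeated runs produce diff-stable files.
write_delim_num <- function(df, path, sep = "\t") {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 6))
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Read a concentration table
#'
#' Delimited text (comma or tab, auto-detected), header row, samples as
#' rows; the first column holds sample ids and remaining columns hold one
#' metabolite each. An empty cell is missing; the token `<LOD` marks a
#' value below the limit of detection. Any other non-numeric cell is an
#' error with its location.
#'
#' @param path file path.
#' @return a raw-stage [conc_matrix()] with missing/below-LOD provenance.
#' @export
read_concentrations <- function(path) {
  sep <- detect_delim(path)
  df <- read.delim(path, sep = sep, check.names = FALSE,
                   colClasses = "character", na.strings = NULL)
  if (ncol(df) < 2) stop("concentration table needs a sample id column and ",
                         "at least one metabolite column")
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop("duplicate sample id: ", ids[duplicated(ids)][1])
  cells <- as.matrix(df[, -1, drop = FALSE])
  status <- matrix("observed", nrow(cells), ncol(cells))
  status[cells == ""] <- "missing"
  status[cells == "<LOD"] <- "lod"
  vals <- suppressWarnings(matrix(as.numeric(cells), nrow(cells)))
  bad <- which(is.na(vals) & status == "observed", arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric cell '%s' at row %d (sample %s), column %s",
                 cells[bad[1, 1], bad[1, 2]], bad[1, 1], ids[bad[1, 1]],
                 colnames(df)[-1][bad[1, 2]]))
  vals[status != "observed"] <- NA_real_
  dimnames(vals) <- list(ids, colnames(df)[-1])
  conc_matrix(vals, status, stage = "raw")
}

#' Write a concentration table
#'
#' Inverse of [read_concentrations()]: missing cells are written empty,
#' below-LOD cells as `<LOD`. Outlier-masked cells are written empty with
#' a note, since the raw text format carries no outlier provenance.
#'
#' @param x a [conc_matrix()].
#' @param path output file path.
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_concentrations <- function(x, path, sep = "\t") {
  stopifnot(inherits(x, "conc_matrix"))
  cells <- matrix(as.character(signif(x$values, 10)), nrow(x$values))
  cells[is.na(x$values)] <- ""
  cells[x$status == "lod"] <- "<LOD"
  df <- data.frame(sample_id = sample_ids(x), cells, check.names = FALSE)
  colnames(df) <- c("sample_id", metabolite_ids(x))
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table
#'
#' Delimited text with columns `sample_id`, `baseline_pain`,
#' `followup_pain`, `baseline_function`, `followup_function`, and
#' optionally `joint` (TKR/THR) and `primary_oa` (logical). Empty cells
#' are missing.
#'
#' @param path file path.
#' @return an [outcome_records()] table.
#' @export
read_phenotypes <- function(path) {
  sep <- detect_delim(path)
  df <- read.delim(path, sep = sep, check.names = FALSE,
                   na.strings = c("", "NA"))
  if (!is.null(df$primary_oa)) df$primary_oa <- as.logical(df$primary_oa)
  if (!is.null(df$joint)) df$joint <- as.character(df$joint)
  df$sample_id <- as.character(df$sample_id)
  outcome_records(df)
}

#' Write a phenotype table
#' @param records an [outcome_records()] table.
#' @param path output file path.
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(records, path, sep = "\t") {
  write.table(outcome_records(records), path, sep = sep, quote = FALSE,
              row.names = FALSE, na = "")
  invisible(path)
}

#' Write a synthetic cohort to disk
#'
#' Emits the delimited formats the pipeline reads: the concentration
#' table, the phenotype table, and the planted-edge truth list
#' (`truth_edges.tsv`).
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_concentrations(cohort$concentrations,
                       file.path(dir, "concentrations.tsv"))
  write_phenotypes(cohort$outcomes, file.path(dir, "phenotypes.tsv"))
  pe <- cohort$truth$planted_edges
  if (is.null(pe))
    pe <- data.frame(i = integer(), j = integer(),
                     r_case = numeric(), r_control = numeric())
  met <- metabolite_ids(cohort$concentrations)
  pe$metabolite_i <- met[pe$i]
  pe$metabolite_j <- met[pe$j]
  write_delim_num(pe, file.path(dir, "truth_edges.tsv"))
  invisible(dir)
}

#' Write a differential edge table
#' @param edges a [diff_edges()] table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edges <- function(edges, path) {
  write_delim_num(as.data.frame(edges), path)
}

#' Read a differential edge table written by [write_edges()]
#' @param path file path.
#' @return a `diffcorr_edges` data frame.
#' @export
read_edges <- function(path) {
  df <- read.delim(path, sep = detect_delim(path), check.names = FALSE,
                   na.strings = c("", "NA"))
  df$metabolite_i <- as.character(df$metabolite_i)
  df$metabolite_j <- as.character(df$metabolite_j)
  class(df) <- c("diffcorr_edges", class(df))
  df
}
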