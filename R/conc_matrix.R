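#' Concentration matrix container
#'
#' A samples x metabolites numeric matrix together with a cell-level status
#' grid recording why a value is unavailable. Values are `NA` exactly where
#' the status marks a cell as unavailable (`"missing"`, `"lod"`, `"outlier"`);
#' cells filled by mean imputation carry status `"imputed"` and a numeric
#' value. The `stage` attribute tracks progress through the QC pipeline:
#' `raw` -> `imputed` -> `normalized`.
#'
#' @param values numeric matrix, samples as rows, metabolites as columns.
#'   Row and column names are used as sample and metabolite identifiers and
#'   are generated (`S1...`, `M1...`) when absent. `NA` entries are marked
#'   `"missing"` unless `status` says otherwise.
#' @param status optional character matrix of the same shape with entries in
#'   `"observed"`, `"missing"`, `"lod"`, `"outlier"`, `"imputed"`.
#' @param stage one of `"raw"`, `"imputed"`, `"normalized"`.
#' @return an object of class `conc_matrix`.
#' @export
conc_matrix <- function(values, status = NULL, stage = "raw") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (samples x metabolites)")
  if (is.null(rownames(values)))
    rownames(values) <- paste0("S", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("M", seq_len(ncol(values)))
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample ids in concentration matrix")
  if (anyDuplicated(colnames(values)))
    stop("duplicate metabolite ids in concentration matrix")
  if (is.null(status)) {
    status <- matrix("observed", nrow(values), ncol(values))
    status[is.na(values)] <- "missing"
  }
  if (!identical(dim(status), dim(values)))
    stop("`status` and `values` must have identical shape")
  dimnames(status) <- dimnames(values)
  bad <- setdiff(unique(as.vector(status)), .cm_statuses)
  if (length(bad))
    stop("unknown status value(s): ", paste(bad, collapse = ", "))
  stage <- match.arg(stage, c("raw", "imputed", "normalized"))
  masked <- matrix(status %in% c("missing", "lod", "outlier"), nrow(values))
  values[masked] <- NA_real_
  if (any(!masked & is.na(values)))
    stop("NA value in a cell whose status is not missing/lod/outlier")
  structure(list(values = values, status = status, stage = stage),
            class = "conc_matrix")
}

.cm_statuses <- c("observed", "missing", "lod", "outlier", "imputed")

#' @export
print.conc_matrix <- function(x, ...) {
  cat(sprintf("<conc_matrix> %d samples x %d metabolites, stage=%s\n",
              nrow(x$values), ncol(x$values), x$stage))
  tab <- table(factor(x$status, levels = .cm_statuses))
  cat("  cells:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.conc_matrix <- function(x) dim(x$values)

#' Sample and metabolite identifiers
#' @param x a [conc_matrix()].
#' @return character vector of identifiers.
#' @export
sample_ids <- function(x) rownames(x$values)

#' @rdname sample_ids
#' @export
metabolite_ids <- function(x) colnames(x$values)

#' Mask of unavailable cells
#'
#' `TRUE` where a value is unavailable for analysis: originally missing,
#' censored below the limit of detection, or removed as an outlier.
#' @param x a [conc_matrix()].
#' @return logical matrix, samples x metabolites.
#' @export
masked_cells <- function(x) {
  m <- x$status == "missing" | x$status == "lod" | x$status == "outlier"
  dimnames(m) <- dimnames(x$values)
  m
}
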