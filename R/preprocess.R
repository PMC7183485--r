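#' Exclude metabolites with too many values below the limit of detection
#'
#' Drops every metabolite whose fraction of below-LOD values strictly
#' exceeds `max_below_lod_fraction` ("more than" is read as a strict
#' inequality, so a metabolite at exactly the threshold is retained).
#'
#' @param x a [conc_matrix()] at stage `raw`, with below-LOD cells flagged
#'   as status `"lod"`.
#' @param max_below_lod_fraction maximum tolerated below-LOD fraction,
#'   in \[0, 1\]. Default 0.10.
#' @return a list with elements `matrix` (the filtered [conc_matrix()]) and
#'   `report` (a [qc_report()]).
#' @export
filter_lod <- function(x, max_below_lod_fraction = 0.10) {
  stopifnot(inherits(x, "conc_matrix"))
  if (x$stage != "raw") stop("filter_lod() expects a raw-stage matrix")
  if (!is.numeric(max_below_lod_fraction) || max_below_lod_fraction < 0 ||
      max_below_lod_fraction > 1)
    stop("`max_below_lod_fraction` must be in [0, 1]")
  frac <- colMeans(x$status == "lod")
  drop <- frac > max_below_lod_fraction
  if (all(drop)) stop("all metabolites exceed the below-LOD threshold")
  excluded <- data.frame(metabolite = metabolite_ids(x)[drop],
                         below_lod_fraction = unname(frac[drop]))
  out <- conc_matrix(x$values[, !drop, drop = FALSE],
                     x$status[, !drop, drop = FALSE], stage = "raw")
  rep <- qc_report(excluded_metabolites = excluded,
                   retained_metabolites = sum(!drop))
  list(matrix = out, report = rep)
}

#' Impute unavailable values with the metabolite mean
#'
#' Replaces every missing or below-LOD value by the mean of that
#' metabolite's observed values, on the raw concentration scale.
#' Observed values are never altered.
#'
#' @param x a [conc_matrix()] at stage `raw` (after LOD filtering).
#' @return a list with elements `matrix` (stage `imputed`) and `report`.
#' @export
impute_mean <- function(x) {
  stopifnot(inherits(x, "conc_matrix"))
  if (x$stage != "raw") stop("impute_mean() expects a raw-stage matrix")
  v <- x$values
  s <- x$status
  need <- is.na(v)
  if (any(colSums(!need) == 0)) {
    bad <- metabolite_ids(x)[colSums(!need) == 0]
    stop("cannot impute metabolite(s) with zero observed values: ",
         paste(bad, collapse = ", "))
  }
  mu <- colMeans(v, na.rm = TRUE)
  v[need] <- mu[col(v)[need]]
  s[need] <- "imputed"
  rep <- qc_report(imputed_count = sum(need),
                   retained_metabolites = ncol(v))
  list(matrix = conc_matrix(v, s, stage = "imputed"), report = rep)
}

#' Natural-log transform and Z-score standardization
#'
#' Per metabolite: takes the natural logarithm, then centers and scales the
#' column to mean 0 and sample standard deviation 1 (n - 1 denominator).
#'
#' @param x a [conc_matrix()] at stage `imputed` with strictly positive
#'   values.
#' @return a [conc_matrix()] at stage `normalized`.
#' @export
log_zscore <- function(x) {
  stopifnot(inherits(x, "conc_matrix"))
  if (x$stage != "imputed") stop("log_zscore() expects an imputed-stage matrix")
  v <- x$values
  nonpos <- which(!is.na(v) & v <= 0, arr.ind = TRUE)
  if (nrow(nonpos)) {
    stop(sprintf("non-positive concentration at sample %s, metabolite %s",
                 rownames(v)[nonpos[1, 1]], colnames(v)[nonpos[1, 2]]))
  }
  lv <- log(v)
  mu <- colMeans(lv, na.rm = TRUE)
  sdv <- apply(lv, 2, sd, na.rm = TRUE)
  if (any(!is.na(sdv) & sdv == 0)) {
    bad <- colnames(v)[!is.na(sdv) & sdv == 0]
    stop("zero-variance metabolite(s) cannot be Z-scored: ",
         paste(bad, collapse = ", "))
  }
  z <- sweep(sweep(lv, 2, mu, "-"), 2, sdv, "/")
  conc_matrix(z, x$status, stage = "normalized")
}

#' Mask outlying values
#'
#' Re-masks individual cells whose normalized value lies strictly beyond
#' `k` standard deviations from the mean (|z| > k). Masked cells are
#' excluded from downstream correlations via pairwise-complete handling;
#' they are not imputed again. A value exactly at `k` is retained.
#'
#' @param x a [conc_matrix()] at stage `normalized`.
#' @param k standard-deviation multiple; default 3.
#' @return a list with elements `matrix` and `report`.
#' @export
mask_outliers <- function(x, k = 3) {
  stopifnot(inherits(x, "conc_matrix"))
  if (x$stage != "normalized") stop("mask_outliers() expects a normalized matrix")
  if (!is.numeric(k) || k <= 0) stop("`k` must be positive")
  v <- x$values
  s <- x$status
  out <- !is.na(v) & abs(v) > k
  v[out] <- NA_real_
  s[out] <- "outlier"
  rep <- qc_report(outlier_count = sum(out), retained_metabolites = ncol(v))
  list(matrix = conc_matrix(v, s, stage = "normalized"), report = rep)
}

#' Full QC and normalization pipeline
#'
#' Applies, in order: below-LOD metabolite exclusion, mean imputation,
#' natural-log + Z-score normalization, and outlier masking.
#'
#' @inheritParams filter_lod
#' @inheritParams mask_outliers
#' @param lod_threshold maximum tolerated below-LOD fraction (default 0.10).
#' @param outlier_k outlier threshold in standard deviations (default 3).
#' @return a list with elements `matrix` (normalized, outlier-masked) and
#'   `report` (merged [qc_report()]).
#' @export
preprocess <- function(x, lod_threshold = 0.10, outlier_k = 3) {
  st1 <- filter_lod(x, lod_threshold)
  st2 <- impute_mean(st1$matrix)
  st3 <- log_zscore(st2$matrix)
  st4 <- mask_outliers(st3, outlier_k)
  rep <- qc_report(excluded_metabolites = st1$report$excluded_metabolites,
                   imputed_count = st2$report$imputed_count,
                   outlier_count = st4$report$outlier_count,
                   retained_metabolites = st4$report$retained_metabolites)
  list(matrix = st4$matrix, report = rep)
}

#' Quality-control report
#'
#' @param excluded_metabolites data frame with columns `metabolite` and
#'   `below_lod_fraction`.
#' @param imputed_count number of values filled by mean imputation.
#' @param outlier_count number of values masked as outliers.
#' @param retained_metabolites number of metabolites retained.
#' @return an object of class `qc_report`.
#' @export
qc_report <- function(excluded_metabolites = data.frame(
                        metabolite = character(), below_lod_fraction = numeric()),
                      imputed_count = 0L, outlier_count = 0L,
                      retained_metabolites = NA_integer_) {
  structure(list(excluded_metabolites = excluded_metabolites,
                 imputed_count = as.integer(imputed_count),
                 outlier_count = as.integer(outlier_count),
                 retained_metabolites = as.integer(retained_metabolites)),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  cat("  excluded metabolites:", nrow(x$excluded_metabolites), "\n")
  cat("  retained metabolites:", x$retained_metabolites, "\n")
  cat("  imputed values:      ", x$imputed_count, "\n")
  cat("  outlier values masked:", x$outlier_count, "\n")
  invisible(x)
}
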