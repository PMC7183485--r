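#' Fisher z-transformation of a Pearson correlation
#'
#' `z = 0.5 * ln((1 + r) / (1 - r))`, the variance-stabilizing transform
#' with approximate variance `1 / (n - 3)`. Correlations numerically at
#' +/-1 are clamped to `1 - 1e-12` in magnitude so collinear pairs give a
#' large finite z rather than infinity.
#'
#' @param r numeric vector of correlations, `|r| <= 1`.
#' @return numeric vector of z values (odd function of `r`).
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r)))
    stop("fisher_z() requires finite input correlations")
  if (any(abs(r) > 1 + 1e-8))
    stop("correlation magnitude exceeds 1")
  cap <- 1 - 1e-12
  r <- pmin(pmax(r, -cap), cap)
  atanh(r)
}

#' Sample-size-adjusted differential correlation statistic
#'
#' Standardized difference of Fisher z-transformed correlations between
#' the case and control groups:
#' `(z_case - z_control) / sqrt(1/(n_case - 3) + 1/(n_control - 3))`.
#' Approximately standard normal under the null of equal population
#' correlations; antisymmetric under swapping the groups.
#'
#' @param r_case,r_control Pearson correlations of a metabolite pair in
#'   each group (vectors recycle).
#' @param n_case,n_control complete-observation counts per group; must
#'   exceed 3.
#' @return the statistic (numeric vector).
#' @export
differential_statistic <- function(r_case, r_control, n_case, n_control) {
  if (any(n_case <= 3) || any(n_control <= 3))
    stop("group sizes must exceed 3 (Fisher variance 1/(n-3))")
  (fisher_z(r_case) - fisher_z(r_control)) /
    sqrt(1 / (n_case - 3) + 1 / (n_control - 3))
}

#' Per-group Pearson correlations with pairwise-complete counts
#'
#' Computes, within each group, the Pearson correlation matrix over
#' pairwise-complete observations and the per-pair complete-observation
#' count. Pairs with fewer than 4 complete observations in a group, or
#' involving a zero-variance metabolite, are unusable (`NA` correlation).
#'
#' @param x a [conc_matrix()] at stage `normalized`.
#' @param is_case logical vector over the samples of `x`: `TRUE` = case
#'   (non-responder), `FALSE` = control (responder). Alternatively a
#'   `responder_labels` data frame; then `outcome` selects the column and
#'   excluded samples are dropped.
#' @param outcome `"pain"` or `"function"`, used when `is_case` is a
#'   `responder_labels` table.
#' @return a list with elements `case` and `control`, each a
#'   `group_correlation` list with `r` (correlation matrix), `n_pairwise`
#'   (complete-observation counts) and `n_group`.
#' @export
group_correlations <- function(x, is_case, outcome = c("pain", "function")) {
  stopifnot(inherits(x, "conc_matrix"))
  if (x$stage != "normalized")
    stop("group_correlations() expects a normalized matrix")
  sel <- case_mask(x, is_case, outcome)
  v <- x$values[sel$keep, , drop = FALSE]
  is_case <- sel$is_case
  if (sum(is_case) < 4 || sum(!is_case) < 4)
    stop("each group needs at least 4 samples")
  list(case = group_cor_one(v[is_case, , drop = FALSE], "case"),
       control = group_cor_one(v[!is_case, , drop = FALSE], "control"))
}

# Resolve a labels argument to a logical case mask over the rows of x.
case_mask <- function(x, is_case, outcome = c("pain", "function")) {
  if (inherits(is_case, "responder_labels") || is.data.frame(is_case)) {
    outcome <- match.arg(outcome)
    col <- if (outcome == "pain") "pain" else "function."
    lab <- is_case[[col]][match(sample_ids(x), is_case$sample_id)]
    if (any(is.na(lab)))
      stop("labels missing for sample(s): ",
           paste(head(sample_ids(x)[is.na(lab)], 3), collapse = ", "))
    keep <- lab != "excluded"
    list(keep = keep, is_case = lab[keep] == "non-responder")
  } else {
    if (!is.logical(is_case) || length(is_case) != nrow(x$values))
      stop("`is_case` must be a logical vector over samples or a labels table")
    list(keep = rep(TRUE, length(is_case)), is_case = is_case)
  }
}

group_cor_one <- function(v, group) {
  n_pair <- crossprod(!is.na(v))
  if (anyNA(v)) {
    r <- suppressWarnings(cor(v, use = "pairwise.complete.obs"))
  } else {
    r <- suppressWarnings(cor(v))
  }
  zerovar <- apply(v, 2, function(col) {
    obs <- col[!is.na(col)]
    length(obs) >= 1 && (length(unique(obs)) == 1L)
  })
  if (any(zerovar)) {
    warning("zero-variance metabolite(s) in ", group, " group: ",
            paste(colnames(v)[zerovar], collapse = ", "),
            "; their pairs are unusable")
    r[zerovar, ] <- NA_real_
    r[, zerovar] <- NA_real_
  }
  r[n_pair < 4] <- NA_real_
  diag(r) <- 1
  structure(list(group = group, r = r, n_pairwise = n_pair,
                 n_group = nrow(v)), class = "group_correlation")
}

#' Differential correlation statistics for all metabolite pairs
#'
#' One row per unordered metabolite pair (`m (m - 1) / 2` for `m`
#' metabolites), ordered lexicographically by metabolite id. The statistic
#' uses the pairwise-complete observation count of each group for the
#' pair, which equals the group size when no values are masked. Unusable
#' pairs (fewer than 4 complete observations or zero variance in either
#' group) are dropped.
#'
#' @inheritParams group_correlations
#' @return a `diffcorr_edges` data frame with columns `metabolite_i`,
#'   `metabolite_j`, `r_case`, `r_control`, `z_case`, `z_control`,
#'   `n_case`, `n_control`, `r_diff`, `p_perm` (`NA` until
#'   [permutation_test()] fills it), `sign`.
#' @export
diff_edges <- function(x, is_case, outcome = c("pain", "function")) {
  gc <- group_correlations(x, is_case, outcome)
  ids <- metabolite_ids(x)
  ord <- order(ids)
  m <- length(ids)
  pr <- which(upper.tri(diag(m)), arr.ind = TRUE)
  # pairs in lexicographic order of (id_i, id_j)
  ii <- ord[pr[, 1]]; jj <- ord[pr[, 2]]
  swap <- ids[ii] > ids[jj]
  tmp <- ii[swap]; ii[swap] <- jj[swap]; jj[swap] <- tmp
  o <- order(ids[ii], ids[jj])
  ii <- ii[o]; jj <- jj[o]
  idx <- cbind(ii, jj)
  rc <- gc$case$r[idx]; r0 <- gc$control$r[idx]
  nc <- gc$case$n_pairwise[idx]; n0 <- gc$control$n_pairwise[idx]
  usable <- !is.na(rc) & !is.na(r0)
  if (!all(usable))
    message(sum(!usable), " unusable pair(s) dropped")
  ed <- data.frame(metabolite_i = ids[ii], metabolite_j = ids[jj],
                   r_case = rc, r_control = r0,
                   z_case = NA_real_, z_control = NA_real_,
                   n_case = nc, n_control = n0,
                   r_diff = NA_real_, p_perm = NA_real_,
                   sign = NA_character_,
                   stringsAsFactors = FALSE)[usable, , drop = FALSE]
  ed$z_case <- fisher_z(ed$r_case)
  ed$z_control <- fisher_z(ed$r_control)
  ed$r_diff <- differential_statistic(ed$r_case, ed$r_control,
                                      ed$n_case, ed$n_control)
  ed$sign <- ifelse(ed$r_diff >= 0, "positive", "negative")
  rownames(ed) <- NULL
  class(ed) <- c("diffcorr_edges", class(ed))
  ed
}

# Fast m x m matrix of differential statistics for a values matrix and a
# case mask; used by the permutation engine. Returns NA for unusable pairs.
diffstat_matrix <- function(v, is_case) {
  vc <- v[is_case, , drop = FALSE]
  v0 <- v[!is_case, , drop = FALSE]
  if (anyNA(v)) {
    rc <- suppressWarnings(cor(vc, use = "pairwise.complete.obs"))
    r0 <- suppressWarnings(cor(v0, use = "pairwise.complete.obs"))
    nc <- crossprod(!is.na(vc)); n0 <- crossprod(!is.na(v0))
    rc[nc < 4] <- NA_real_; r0[n0 < 4] <- NA_real_
    denom <- sqrt(1 / (nc - 3) + 1 / (n0 - 3))
  } else {
    rc <- suppressWarnings(cor(vc))
    r0 <- suppressWarnings(cor(v0))
    denom <- sqrt(1 / (nrow(vc) - 3) + 1 / (nrow(v0) - 3))
  }
  cap <- 1 - 1e-12
  (atanh(pmin(pmax(rc, -cap), cap)) - atanh(pmin(pmax(r0, -cap), cap))) / denom
}
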