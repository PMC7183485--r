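#' Permutation test for differential correlations
#'
#' Assesses each pair's differential correlation statistic against a null
#' built by shuffling the phenotype labels. Each replicate applies one
#' global shuffle shared by all pairs (group sizes are preserved),
#' recomputes the full statistic matrix, and accumulates per-pair
#' exceedance counts `b` of permuted `|r_diff| >=` observed `|r_diff|`
#' (ties count as exceedances). The two-sided p-value uses the add-one
#' estimator `p = (b + 1) / (B + 1)`, which is never zero. A non-finite
#' permuted statistic counts as an exceedance (conservative).
#'
#' @inheritParams group_correlations
#' @param n_permutations number of label shuffles `B` (default 1000).
#' @param seed optional RNG seed for reproducible shuffles.
#' @return the [diff_edges()] table with `p_perm` filled in, plus
#'   attributes `n_permutations` and `seed`.
#' @export
permutation_test <- function(x, is_case, outcome = c("pain", "function"),
                             n_permutations = 1000, seed = NULL) {
  stopifnot(n_permutations >= 1)
  ed <- diff_edges(x, is_case, outcome)
  sel <- case_mask(x, is_case, outcome)
  v <- x$values[sel$keep, , drop = FALSE]
  mask <- sel$is_case
  if (!is.null(seed)) set.seed(seed)

  m <- ncol(v)
  ids <- colnames(v)
  pos_i <- match(ed$metabolite_i, ids)
  pos_j <- match(ed$metabolite_j, ids)
  flat <- (pos_j - 1L) * m + pos_i  # upper-triangle linear indices
  obs <- abs(ed$r_diff)
  b <- integer(length(obs))
  n_nonfinite <- 0L
  for (k in seq_len(n_permutations)) {
    perm <- sample(mask)
    s <- abs(diffstat_matrix(v, perm)[flat])
    bad <- !is.finite(s)
    if (any(bad)) {
      n_nonfinite <- n_nonfinite + sum(bad)
      s[bad] <- Inf
    }
    b <- b + (s >= obs)
  }
  if (n_nonfinite > 0)
    message(n_nonfinite,
            " non-finite permuted statistic(s) counted as exceedances")
  ed$p_perm <- (b + 1) / (n_permutations + 1)
  attr(ed, "n_permutations") <- n_permutations
  attr(ed, "seed") <- seed
  ed
}

#' Type I error calibration of the permutation test
#'
#' Generates replicate null cohorts (no planted differential edges) from a
#' [cohort_spec()], runs the QC pipeline and permutation test on each, and
#' reports the fraction of pairs rejected at each significance level. Under
#' a valid test this fraction matches the nominal level up to Monte-Carlo
#' error; [binomial_bounds()] gives the reference interval.
#'
#' @param spec a [cohort_spec()] with `planted_edges = NULL`.
#' @param n_replicates number of replicate cohorts.
#' @param n_permutations permutations per cohort (default 1000).
#' @param alpha significance levels to tabulate (default 0.01 and 0.05).
#' @param seed RNG seed governing cohort generation and shuffles.
#' @return data frame with columns `alpha`, `n_pairs`, `n_rejected`,
#'   `rejection_rate`, `lower_99`, `upper_99` (binomial 99% bounds at the
#'   nominal level).
#' @export
type1_calibration <- function(spec, n_replicates = 20, n_permutations = 1000,
                              alpha = c(0.01, 0.05), seed = 1L) {
  if (!is.null(spec$planted_edges) && nrow(spec$planted_edges) > 0)
    stop("type1_calibration() requires a spec with no planted edges")
  pvals <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    spec_r <- spec
    spec_r$seed <- seed + r
    coh <- generate_cohort(spec_r)
    qc <- preprocess(coh$concentrations)
    ed <- permutation_test(qc$matrix, coh$labels == "case",
                           n_permutations = n_permutations,
                           seed = seed + 100000L + r)
    pvals[[r]] <- ed$p_perm
  }
  p <- unlist(pvals)
  out <- lapply(alpha, function(a) {
    bb <- binomial_bounds(length(p), a)
    data.frame(alpha = a, n_pairs = length(p), n_rejected = sum(p < a),
               rejection_rate = mean(p < a),
               lower_99 = bb[1], upper_99 = bb[2])
  })
  do.call(rbind, out)
}

#' Binomial 99% bounds on an empirical rejection rate
#'
#' Central 99% interval of `Binomial(n, p) / n`, used as the Monte-Carlo
#' reference band for type I error calibration.
#'
#' @param n number of independent trials.
#' @param p nominal rejection probability.
#' @return numeric vector `c(lower, upper)`.
#' @export
binomial_bounds <- function(n, p) {
  stats::qbinom(c(0.005, 0.995), n, p) / n
}
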