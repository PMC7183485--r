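#' Specification of a synthetic two-group metabolomics cohort
#'
#' Defaults emulate the analyzed study conditions: 67 cases
#' (non-responders) versus 378 controls (responders), 131 metabolites, a
#' mild baseline correlation among metabolites, low-level below-LOD
#' censoring, sparse missingness, and rare extreme outliers. Planted
#' differential edges specify per-group target correlations on the log
#' scale (the scale the pipeline analyzes after its natural-log
#' transform).
#'
#' @param n_case,n_control group sizes; each at least 4 so the Fisher
#'   variance `1/(n - 3)` is defined.
#' @param n_metabolites number of metabolites.
#' @param planted_edges `NULL`, or a data frame with columns `i`, `j`
#'   (metabolite indices), `r_case`, `r_control` (target log-scale
#'   correlations, magnitude at most 0.99).
#' @param background_r baseline within-group correlation shared by all
#'   non-planted pairs, in `[0, 1)`.
#' @param lod_fraction expected fraction of values censored below the
#'   limit of detection, per metabolite: a scalar applied to all
#'   metabolites or a vector of length `n_metabolites`.
#' @param missing_fraction expected fraction of additional missing values.
#' @param outlier_fraction expected fraction of values replaced by extreme
#'   deviates (at least 4 SD from the metabolite mean on the log scale).
#' @param seed RNG seed; fixing it reproduces the cohort exactly.
#' @param womac_params means/SDs for baseline and change scores of the
#'   WOMAC pain (0-20) and function (0-68) subscales per group; see
#'   [default_womac_params()].
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_case = 67, n_control = 378, n_metabolites = 131,
                        planted_edges = NULL, background_r = 0.2,
                        lod_fraction = 0.02, missing_fraction = 0.01,
                        outlier_fraction = 0.002, seed = 1L,
                        womac_params = default_womac_params()) {
  if (n_case < 4 || n_control < 4)
    stop("n_case and n_control must each be at least 4")
  if (background_r < 0 || background_r >= 1)
    stop("background_r must be in [0, 1)")
  if (length(lod_fraction) == 1)
    lod_fraction <- rep(lod_fraction, n_metabolites)
  if (length(lod_fraction) != n_metabolites)
    stop("lod_fraction must be scalar or length n_metabolites")
  fr <- c(lod_fraction, missing_fraction, outlier_fraction)
  if (any(fr < 0) || any(fr >= 1))
    stop("censoring/missing/outlier fractions must be in [0, 1)")
  if (!is.null(planted_edges)) {
    planted_edges <- as.data.frame(planted_edges)
    stopifnot(all(c("i", "j", "r_case", "r_control") %in% names(planted_edges)))
    if (any(planted_edges$i == planted_edges$j))
      stop("planted edges must join distinct metabolites")
    if (any(abs(c(planted_edges$r_case, planted_edges$r_control)) > 0.99))
      stop("planted |r| must be at most 0.99")
    if (any(planted_edges$i > n_metabolites | planted_edges$j > n_metabolites))
      stop("planted edge index exceeds n_metabolites")
  }
  structure(list(n_case = n_case, n_control = n_control,
                 n_metabolites = n_metabolites,
                 planted_edges = planted_edges,
                 background_r = background_r,
                 lod_fraction = lod_fraction,
                 missing_fraction = missing_fraction,
                 outlier_fraction = outlier_fraction,
                 seed = seed, womac_params = womac_params),
            class = "cohort_spec")
}

#' Default WOMAC score parameters for the synthetic generator
#'
#' Baseline scores are drawn high enough that every synthetic patient
#' clears the baseline-floor exclusion; change scores are drawn so cases
#' fall below the MCID (pain 7, function 22) and controls at or above it.
#'
#' @return nested list of means and SDs per subscale and group.
#' @export
default_womac_params <- function() {
  list(pain = list(baseline = c(mean = 14, sd = 2.5), range = c(0, 20),
                   mcid = 7,
                   change_case = c(mean = 3, sd = 2),
                   change_control = c(mean = 11, sd = 3)),
       fun = list(baseline = c(mean = 45, sd = 8), range = c(0, 68),
                  mcid = 22,
                  change_case = c(mean = 10, sd = 5),
                  change_control = c(mean = 32, sd = 8)))
}

# Target correlation matrix for one group: background plus planted entries.
target_correlation <- function(spec, group) {
  m <- spec$n_metabolites
  sig <- matrix(spec$background_r, m, m)
  diag(sig) <- 1
  pe <- spec$planted_edges
  if (!is.null(pe) && nrow(pe) > 0) {
    rcol <- if (group == "case") pe$r_case else pe$r_control
    for (k in seq_len(nrow(pe))) {
      sig[pe$i[k], pe$j[k]] <- rcol[k]
      sig[pe$j[k], pe$i[k]] <- rcol[k]
    }
  }
  ev <- eigen(sig, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    off <- if (is.null(pe)) "background correlation" else
      paste(sprintf("(%d,%d)", pe$i, pe$j), collapse = ", ")
    stop("target correlation matrix for the ", group,
         " group is not positive definite; check planted edges ", off)
  }
  sig
}

#' Generate a synthetic two-group metabolomics cohort
#'
#' Per group, log-scale abundances are drawn from a multivariate normal
#' whose correlation matrix is the background plus the planted per-group
#' entries, then mapped through per-metabolite affine transforms and
#' exponentiated to a strictly positive raw scale (so the pipeline's
#' natural-log transform recovers the planted correlations exactly).
#' Outliers are injected on the log scale at 4 or more SD from the
#' metabolite mean; below-LOD censoring uses each metabolite's empirical
#' lower quantile as the detection floor; missing values are sprinkled
#' uniformly. WOMAC baseline and follow-up scores are drawn so that cases
#' are non-responders (change below the MCID) on both subscales and
#' controls are responders on both.
#'
#' @param spec a [cohort_spec()].
#' @return an object of class `synthetic_cohort`: a list with
#'   `concentrations` (a raw-stage [conc_matrix()]), `labels` (character,
#'   `"case"`/`"control"` per sample), `outcomes` (an [outcome_records()]
#'   table), and `truth` (planted edges plus logical `lod_mask`,
#'   `missing_mask`, `outlier_mask` matrices of the same shape as the
#'   concentration matrix).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  m <- spec$n_metabolites
  n <- spec$n_case + spec$n_control
  met_ids <- sprintf("M%03d", seq_len(m))
  samp_ids <- sprintf("P%04d", seq_len(n))
  labels <- c(rep("case", spec$n_case), rep("control", spec$n_control))

  sig_case <- target_correlation(spec, "case")
  sig_control <- target_correlation(spec, "control")
  z <- matrix(NA_real_, n, m, dimnames = list(samp_ids, met_ids))
  z[labels == "case", ] <- MASS::mvrnorm(spec$n_case, rep(0, m), sig_case)
  z[labels == "control", ] <- MASS::mvrnorm(spec$n_control, rep(0, m), sig_control)

  # per-metabolite log-location and log-scale: raw medians ~ 1-55 units
  log_mu <- runif(m, 0, 4)
  log_sd <- runif(m, 0.3, 0.8)

  # inject outliers on the log scale, >= 4 SD from the metabolite mean
  outlier_mask <- matrix(runif(n * m) < spec$outlier_fraction, n, m,
                         dimnames = dimnames(z))
  if (any(outlier_mask)) {
    k <- sum(outlier_mask)
    z[outlier_mask] <- sample(c(-1, 1), k, replace = TRUE) * (4 + rexp(k, rate = 2))
  }

  raw <- exp(sweep(sweep(z, 2, log_sd, "*"), 2, log_mu, "+"))

  # below-LOD censoring at the metabolite's empirical lower quantile
  lod_mask <- matrix(FALSE, n, m, dimnames = dimnames(z))
  for (j in seq_len(m)) {
    f <- spec$lod_fraction[j]
    if (f > 0) {
      thr <- quantile(raw[, j], probs = f, names = FALSE)
      lod_mask[, j] <- raw[, j] < thr
    }
  }
  outlier_mask <- outlier_mask & !lod_mask
  missing_mask <- matrix(runif(n * m) < spec$missing_fraction, n, m,
                         dimnames = dimnames(z)) & !lod_mask
  outlier_mask <- outlier_mask & !missing_mask

  status <- matrix("observed", n, m, dimnames = dimnames(z))
  status[missing_mask] <- "missing"
  status[lod_mask] <- "lod"
  vals <- raw
  vals[missing_mask | lod_mask] <- NA_real_
  conc <- conc_matrix(vals, status, stage = "raw")

  outcomes <- synth_womac(labels, samp_ids, spec$womac_params)
  truth <- list(planted_edges = spec$planted_edges,
                lod_mask = lod_mask, missing_mask = missing_mask,
                outlier_mask = outlier_mask)
  structure(list(concentrations = conc, labels = labels,
                 outcomes = outcomes, truth = truth, spec = spec),
            class = "synthetic_cohort")
}

# Integer WOMAC scores clipped to subscale ranges, with case change
# scores below the MCID and control change scores at or above it.
synth_womac <- function(labels, samp_ids, wp) {
  n <- length(labels)
  one <- function(p) {
    base <- round(rnorm(n, p$baseline["mean"], p$baseline["sd"]))
    base <- pmin(pmax(base, p$mcid + 1), p$range[2])
    ch <- ifelse(labels == "case",
                 round(rnorm(n, p$change_case["mean"], p$change_case["sd"])),
                 round(rnorm(n, p$change_control["mean"], p$change_control["sd"])))
    # force the responder/non-responder contract, then keep follow-up in range
    ch <- ifelse(labels == "case", pmin(ch, p$mcid - 1), pmax(ch, p$mcid))
    fol <- pmin(pmax(base - ch, p$range[1]), p$range[2])
    list(base = as.integer(base), fol = as.integer(fol))
  }
  pain <- one(wp$pain)
  fun <- one(wp$fun)
  data.frame(sample_id = samp_ids,
             baseline_pain = pain$base, followup_pain = pain$fol,
             baseline_function = fun$base, followup_function = fun$fol,
             joint = sample(c("TKR", "THR"), n, replace = TRUE,
                            prob = c(0.724, 0.276)),
             primary_oa = TRUE, stringsAsFactors = FALSE)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d case + %d control samples, %d metabolites\n",
              sum(x$labels == "case"), sum(x$labels == "control"),
              ncol(x$concentrations$values)))
  np <- if (is.null(x$truth$planted_edges)) 0L else nrow(x$truth$planted_edges)
  cat("  planted differential edges:", np, "\n")
  invisible(x)
}
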