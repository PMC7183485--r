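#' Validate WOMAC outcome records
#'
#' Checks a per-patient outcome table: WOMAC pain subscale scores in 0-20,
#' function subscale scores in 0-68, joint type in `TKR`/`THR`/`unknown`.
#' Missing scores are allowed (`NA`) and handled by [classify_responders()].
#'
#' @param records data frame with columns `sample_id`, `baseline_pain`,
#'   `followup_pain`, `baseline_function`, `followup_function`, and
#'   optionally `joint` (default `"unknown"`) and `primary_oa`
#'   (default `TRUE`).
#' @return the validated data frame (columns completed with defaults).
#' @export
outcome_records <- function(records) {
  req <- c("sample_id", "baseline_pain", "followup_pain",
           "baseline_function", "followup_function")
  miss <- setdiff(req, names(records))
  if (length(miss))
    stop("outcome records lack column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(records$sample_id))
    stop("duplicate sample_id in outcome records")
  if (is.null(records$joint)) records$joint <- "unknown"
  records$joint[is.na(records$joint)] <- "unknown"
  if (!all(records$joint %in% c("TKR", "THR", "unknown")))
    stop("`joint` must be one of TKR, THR, unknown")
  if (is.null(records$primary_oa)) records$primary_oa <- TRUE
  chk <- function(col, lo, hi) {
    v <- records[[col]]
    bad <- which(!is.na(v) & (v < lo | v > hi))
    if (length(bad))
      stop(sprintf("%s out of range [%d, %d] for sample %s",
                   col, lo, hi, records$sample_id[bad[1]]))
  }
  chk("baseline_pain", 0L, 20L); chk("followup_pain", 0L, 20L)
  chk("baseline_function", 0L, 68L); chk("followup_function", 0L, 68L)
  records
}

#' Classify responders and non-responders by WOMAC MCID
#'
#' Change score is `baseline - followup`, so improvement is positive
#' (0 = no symptoms). Per outcome, a patient is a non-responder when the
#' change score is strictly below the minimal clinically important
#' difference (MCID), and a responder otherwise. Patients are excluded,
#' with the first applicable reason recorded in this order:
#' `missing_womac` (the outcome's scores are unavailable),
#' `non_primary_oa`, and `baseline_floor` (baseline pain below `mcid_pain`
#' AND baseline function below `mcid_function`, so neither MCID is
#' attainable).
#'
#' @param records an [outcome_records()] table.
#' @param mcid_pain MCID for the pain subscale (default 7).
#' @param mcid_function MCID for the function subscale (default 22).
#' @return a `responder_labels` data frame with columns `sample_id`,
#'   `pain`, `function.` (each `responder`/`non-responder`/`excluded`),
#'   and `pain_reason`, `function_reason` (`NA` unless excluded).
#' @export
classify_responders <- function(records, mcid_pain = 7, mcid_function = 22) {
  stopifnot(mcid_pain > 0, mcid_function > 0)
  records <- outcome_records(records)
  floor_hit <- !is.na(records$baseline_pain) &
    !is.na(records$baseline_function) &
    records$baseline_pain < mcid_pain &
    records$baseline_function < mcid_function

  one <- function(baseline, followup, mcid) {
    label <- rep("responder", nrow(records))
    reason <- rep(NA_character_, nrow(records))
    change <- baseline - followup
    label[!is.na(change) & change < mcid] <- "non-responder"
    # exclusion precedence: missing scores, then non-primary OA, then floor
    excl_floor <- floor_hit
    excl_nonprim <- !records$primary_oa
    excl_missing <- is.na(baseline) | is.na(followup)
    label[excl_floor] <- "excluded"; reason[excl_floor] <- "baseline_floor"
    label[excl_nonprim] <- "excluded"; reason[excl_nonprim] <- "non_primary_oa"
    label[excl_missing] <- "excluded"; reason[excl_missing] <- "missing_womac"
    list(label = label, reason = reason)
  }
  p <- one(records$baseline_pain, records$followup_pain, mcid_pain)
  f <- one(records$baseline_function, records$followup_function, mcid_function)
  out <- data.frame(sample_id = records$sample_id,
                    pain = p$label, `function.` = f$label,
                    pain_reason = p$reason, function_reason = f$reason,
                    stringsAsFactors = FALSE)
  class(out) <- c("responder_labels", class(out))
  out
}

#' Round to one decimal, half away from zero
#' @noRd
pct1 <- function(x) sign(x) * floor(abs(x) * 10 + 0.5) / 10

#' Cohort summary: analyzable counts, non-responder rates, joint types
#'
#' Per outcome: the analyzable n (not excluded), the non-responder count
#' and percentage (one decimal, rounded half away from zero). Joint-type
#' counts are over patients analyzable for at least one outcome whose
#' joint is known.
#'
#' @param labels a [classify_responders()] result.
#' @param records the matching [outcome_records()] table.
#' @return a list with elements `pain`, `fun` (each with `analyzable_n`,
#'   `nonresponder_n`, `nonresponder_pct`) and `joint` (counts and
#'   percentages for TKR/THR).
#' @export
cohort_summary <- function(labels, records) {
  records <- outcome_records(records)
  stopifnot(identical(labels$sample_id, records$sample_id))
  per <- function(lab) {
    analyzable <- lab != "excluded"
    n <- sum(analyzable)
    nr <- sum(lab == "non-responder")
    list(analyzable_n = n, nonresponder_n = nr,
         nonresponder_pct = if (n > 0) pct1(100 * nr / n) else NA_real_)
  }
  pain <- per(labels$pain)
  fun <- per(labels$`function.`)
  if (pain$analyzable_n == 0 && fun$analyzable_n == 0)
    stop("zero analyzable patients")
  any_ok <- labels$pain != "excluded" | labels$`function.` != "excluded"
  jk <- records$joint[any_ok & records$joint != "unknown"]
  nj <- length(jk)
  joint <- list(known_n = nj,
                tkr_n = sum(jk == "TKR"), thr_n = sum(jk == "THR"),
                tkr_pct = if (nj > 0) pct1(100 * sum(jk == "TKR") / nj) else NA_real_,
                thr_pct = if (nj > 0) pct1(100 * sum(jk == "THR") / nj) else NA_real_)
  list(pain = pain, fun = fun, joint = joint,
       analyzable_any_n = sum(any_ok))
}
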