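#' Synthetic outcome table at the scale of the TJR cohort
#'
#' A deterministic, synthetic per-patient WOMAC table reproducing the
#' bookkeeping structure of a 704-patient total-joint-replacement cohort:
#' 188 patients with all WOMAC scores missing, 48 with non-primary OA, 7
#' below the baseline floor (baseline pain < 7 and baseline function
#' < 22), and 461 analyzable for at least one outcome. Of those, 16 lack
#' the pain subscale and 6 the function subscale, so 445 are analyzable
#' for pain (67 non-responders) and 455 for function (73 non-responders);
#' 439 have a known joint type (318 TKR, 121 THR). Scores are synthetic:
#' only the counts and the exclusion structure are meaningful.
#'
#' @return an [outcome_records()] table with 704 rows.
#' @export
fixture_outcome_records <- function() {
  n <- 704
  df <- data.frame(sample_id = sprintf("T%04d", seq_len(n)),
                   baseline_pain = NA_integer_, followup_pain = NA_integer_,
                   baseline_function = NA_integer_,
                   followup_function = NA_integer_,
                   joint = "unknown", primary_oa = TRUE,
                   stringsAsFactors = FALSE)
  i_missing <- 1:188
  i_nonprim <- 189:236
  i_floor <- 237:243
  i_pain_na <- 244:259    # function-only patients
  i_fun_na <- 260:265     # pain-only patients
  i_full <- 266:704       # both subscales present

  df[i_nonprim, c("baseline_pain", "followup_pain")] <- list(15L, 5L)
  df[i_nonprim, c("baseline_function", "followup_function")] <- list(50L, 20L)
  df$primary_oa[i_nonprim] <- FALSE
  df[i_floor, c("baseline_pain", "followup_pain")] <- list(5L, 3L)
  df[i_floor, c("baseline_function", "followup_function")] <- list(20L, 10L)

  # pain subscale for the 445 pain-analyzable patients: 67 non-responders
  # (change 5 < 7), the rest responders (change 10)
  i_pain <- c(i_fun_na, i_full)
  nr_pain <- i_pain[1:67]
  df[i_pain, c("baseline_pain", "followup_pain")] <- list(15L, 5L)
  df[nr_pain, "followup_pain"] <- 10L

  # function subscale for the 455 function-analyzable: 73 non-responders
  # (change 15 < 22), the rest responders (change 30)
  i_fun <- c(i_pain_na, i_full)
  nr_fun <- i_fun[1:73]
  df[i_fun, c("baseline_function", "followup_function")] <- list(50L, 20L)
  df[nr_fun, "followup_function"] <- 35L

  # joint type known for the 439 patients with both subscales
  df$joint[i_full[1:318]] <- "TKR"
  df$joint[i_full[319:439]] <- "THR"
  outcome_records(df)
}

# Shared scaffolding for the figure-topology fixtures: expand a sign
# annotated edge list into a full diffcorr_edges table with consistent
# correlations, z values and the group sizes of the analyzed cohort.
fixture_edge_table <- function(sig_edges, sig_signs, null_edges = NULL,
                               n_case = 67, n_control = 378) {
  to_df <- function(e) data.frame(metabolite_i = vapply(e, `[`, "", 1),
                                  metabolite_j = vapply(e, `[`, "", 2),
                                  stringsAsFactors = FALSE)
  ed <- to_df(sig_edges)
  ed$r_case <- ifelse(sig_signs == "positive", 0.55, 0.05)
  ed$r_control <- ifelse(sig_signs == "positive", 0.05, 0.55)
  ed$p_perm <- 0.000999001  # 0/1000 exceedances under the add-one rule
  if (!is.null(null_edges)) {
    nu <- to_df(null_edges)
    nu$r_case <- 0.12; nu$r_control <- 0.10
    nu$p_perm <- 0.35
    ed <- rbind(ed, nu)
  }
  ed$z_case <- fisher_z(ed$r_case)
  ed$z_control <- fisher_z(ed$r_control)
  ed$n_case <- n_case
  ed$n_control <- n_control
  ed$r_diff <- differential_statistic(ed$r_case, ed$r_control,
                                      ed$n_case, ed$n_control)
  ed$sign <- ifelse(ed$r_diff >= 0, "positive", "negative")
  ed <- ed[, c("metabolite_i", "metabolite_j", "r_case", "r_control",
               "z_case", "z_control", "n_case", "n_control", "r_diff",
               "p_perm", "sign")]
  class(ed) <- c("diffcorr_edges", class(ed))
  ed
}

#' Synthetic edge table with the pain-network topology
#'
#' Encodes the textual description of the pain non-responder network at
#' p < 0.01 — 12 metabolites in an 8-node central component plus two
#' separate pairs, proline the most connected node with three edges, and
#' taurine's two phosphatidylcholine edges negative — as a synthetic
#' significant edge table, plus a few non-significant filler edges. The
#' exact published edge list is only available graphically; this fixture
#' reproduces the described component structure, not the figure itself.
#'
#' @return a `diffcorr_edges` data frame (p_perm filled).
#' @export
fixture_pain_edges <- function() {
  sig <- list(c("Proline", "Glutamine"), c("Proline", "Isoleucine"),
              c("Proline", "PC aa C38:6"), c("Glutamine", "PC aa C38:0"),
              c("Taurine", "PC aa C38:0"), c("Taurine", "PC ae C40:6"),
              c("PC aa C38:6", "PC aa C40:6"),
              c("C2", "C14:2"), c("Valine", "PC aa C36:4"))
  signs <- c("positive", "positive", "positive", "negative", "negative",
             "negative", "positive", "positive", "positive")
  null <- list(c("Proline", "C2"), c("Glutamine", "Valine"),
               c("Isoleucine", "PC aa C36:4"))
  fixture_edge_table(sig, signs, null)
}

#' Synthetic edge table with the function-network topology
#'
#' Encodes the textual description of the function non-responder network
#' at p < 0.01 — 23 metabolites in components of 14, 3, 2, 2 and 2 nodes,
#' PC aa C36:8 the most connected node with five edges, 14
#' phosphatidylcholines, seven amino acids, one lysoPC and carnitine —
#' as a synthetic significant edge table plus non-significant filler.
#' Five nodes (glutamine, isoleucine, PC aa C38:0, PC aa C38:6,
#' PC aa C40:6) are shared with [fixture_pain_edges()], and the negative
#' glutamine-PC aa C38:0 edge appears in both.
#'
#' @return a `diffcorr_edges` data frame (p_perm filled).
#' @export
fixture_function_edges <- function() {
  hub <- "PC aa C36:8"
  sig <- list(c(hub, "lysoPC a C18:2"), c(hub, "PC aa C32:2"),
              c(hub, "PC aa C34:4"), c(hub, "PC aa C36:2"),
              c(hub, "Isoleucine"),
              c("Isoleucine", "Glutamine"),
              c("Glutamine", "PC aa C38:0"), c("Glutamine", "PC aa C38:6"),
              c("PC aa C38:0", "PC aa C40:6"),
              c("PC aa C34:4", "PC aa C38:4"),
              c("PC aa C32:2", "PC ae C36:2"),
              c("PC ae C36:2", "PC ae C38:2"),
              c("lysoPC a C18:2", "PC aa C42:6"),
              c("C0", "Threonine"), c("Threonine", "Leucine"),
              c("Serine", "PC ae C40:1"), c("Histidine", "PC aa C40:2"),
              c("Tryptophan", "PC ae C42:3"))
  signs <- rep("positive", length(sig))
  signs[c(7, 8, 13)] <- "negative"
  null <- list(c("C0", "Serine"), c("Leucine", "PC aa C42:6"))
  fixture_edge_table(sig, signs, null)
}
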