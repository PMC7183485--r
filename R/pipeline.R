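#' Run configuration for the full pipeline
#'
#' Bundles file paths and analysis thresholds. Defaults are the study
#' settings: below-LOD exclusion above 10%, outlier masking beyond 3 SD,
#' MCIDs of 7 (pain) and 22 (function), 1000 permutations, primary
#' significance level 0.01 and exploratory level 0.05.
#'
#' @param concentrations path to the concentration table.
#' @param phenotypes path to the phenotype table.
#' @param out_dir output directory for run artifacts.
#' @param lod_threshold maximum tolerated below-LOD fraction.
#' @param outlier_k outlier threshold in standard deviations.
#' @param mcid_pain,mcid_function minimal clinically important differences.
#' @param n_permutations permutation count for the significance test.
#' @param alpha_primary,alpha_exploratory significance levels.
#' @param seed RNG seed recorded in every artifact.
#' @param outcomes outcomes to analyze: subset of `c("pain", "function")`.
#' @return an object of class `run_config`.
#' @export
run_config <- function(concentrations, phenotypes, out_dir,
                       lod_threshold = 0.10, outlier_k = 3,
                       mcid_pain = 7, mcid_function = 22,
                       n_permutations = 1000,
                       alpha_primary = 0.01, alpha_exploratory = 0.05,
                       seed = 1L, outcomes = c("pain", "function")) {
  stopifnot(lod_threshold >= 0, lod_threshold <= 1, outlier_k > 0,
            mcid_pain > 0, mcid_function > 0, n_permutations >= 1,
            alpha_primary > 0, alpha_primary < 1,
            alpha_exploratory > 0, alpha_exploratory < 1)
  outcomes <- match.arg(outcomes, c("pain", "function"), several.ok = TRUE)
  structure(list(concentrations = concentrations, phenotypes = phenotypes,
                 out_dir = out_dir, lod_threshold = lod_threshold,
                 outlier_k = outlier_k, mcid_pain = mcid_pain,
                 mcid_function = mcid_function,
                 n_permutations = n_permutations,
                 alpha_primary = alpha_primary,
                 alpha_exploratory = alpha_exploratory,
                 seed = as.integer(seed), outcomes = outcomes),
            class = "run_config")
}

#' Run the full differential correlation network pipeline
#'
#' Executes QC/normalization, responder classification, per-pair
#' differential correlation with permutation significance, and network
#' construction at both significance levels for each selected outcome,
#' writing all artifacts under `config$out_dir`:
#' `qc_report.tsv`, `labels.tsv`, `cohort_summary.json`,
#' `edges_<outcome>.tsv`, `network_<outcome>_a<alpha>.graphml` and
#' `.edges.tsv`, `overlap.json` (when both outcomes run), and
#' `manifest.json` (configuration, seed, counts).
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the normalized matrix, QC report,
#'   labels, cohort summary, per-outcome edge tables and networks, and
#'   the overlap report.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  raw <- read_concentrations(config$concentrations)
  records <- read_phenotypes(config$phenotypes)
  qc <- preprocess(raw, config$lod_threshold, config$outlier_k)
  labels <- classify_responders(records, config$mcid_pain,
                                config$mcid_function)
  summary <- cohort_summary(labels, records)

  write_delim_num(qc$report$excluded_metabolites,
                  file.path(config$out_dir, "qc_excluded.tsv"))
  write.table(data.frame(metric = c("retained_metabolites", "imputed_count",
                                    "outlier_count"),
                         value = c(qc$report$retained_metabolites,
                                   qc$report$imputed_count,
                                   qc$report$outlier_count)),
              file.path(config$out_dir, "qc_report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(labels, file.path(config$out_dir, "labels.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  jsonlite::write_json(summary, file.path(config$out_dir, "cohort_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  nets <- list(); edges <- list()
  for (oc in config$outcomes) {
    ed <- permutation_test(qc$matrix, labels, oc,
                           n_permutations = config$n_permutations,
                           seed = config$seed)
    edges[[oc]] <- ed
    write_edges(ed, file.path(config$out_dir, paste0("edges_", oc, ".tsv")))
    nets[[oc]] <- list()
    for (a in c(config$alpha_primary, config$alpha_exploratory)) {
      net <- suppressWarnings(build_network(ed, a))
      nets[[oc]][[as.character(a)]] <- net
      stem <- file.path(config$out_dir, sprintf("network_%s_a%g", oc, a))
      export_network(net, paste0(stem, ".graphml"), "graphml")
      export_network(net, paste0(stem, ".edges.tsv"), "edge-list")
    }
  }
  overlap <- NULL
  if (length(config$outcomes) == 2) {
    a <- as.character(config$alpha_primary)
    overlap <- network_overlap(nets$pain[[a]], nets[["function"]][[a]])
    jsonlite::write_json(overlap, file.path(config$out_dir, "overlap.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  manifest <- list(
    config = unclass(config),
    config_hash = config_hash(config),
    seed = config$seed,
    n_samples = nrow(raw$values),
    n_metabolites_input = ncol(raw$values),
    n_metabolites_retained = qc$report$retained_metabolites,
    imputed_count = qc$report$imputed_count,
    outlier_count = qc$report$outlier_count,
    analyzable = list(pain = summary$pain$analyzable_n,
                      fun = summary$fun$analyzable_n),
    n_edges_tested = vapply(edges, nrow, integer(1)),
    n_edges_significant = lapply(nets, function(x)
      vapply(x, function(n) as.integer(igraph::ecount(n$graph)), integer(1))),
    r_version = as.character(getRversion()))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(matrix = qc$matrix, qc_report = qc$report, labels = labels,
                 summary = summary, edges = edges, networks = nets,
                 overlap = overlap, manifest = manifest))
}

# Stable hash of the configuration: deterministic serialization followed
# by a polynomial rolling hash (no external digest dependency).
config_hash <- function(config) {
  x <- unclass(config)
  x <- x[order(names(x))]
  bytes <- as.integer(charToRaw(paste(names(x),
                                      vapply(x, function(v)
                                        paste(format(v, digits = 15),
                                              collapse = ","),
                                        character(1)),
                                      sep = "=", collapse = ";")))
  h1 <- 17; h2 <- 19
  for (b in bytes) {
    h1 <- (h1 * 31 + b) %% 67108859   # primes < 2^26 keep products exact
    h2 <- (h2 * 37 + b) %% 67108837
  }
  sprintf("%07x%07x", h1, h2)
}
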