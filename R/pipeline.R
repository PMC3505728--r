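#' @importFrom jsonlite write_json read_json
#' @importFrom yaml read_yaml
NULL

#' Run the full prediction-response analysis on synthetic data
#'
#' One-command orchestration of the pipeline: simulate a ground-truthed
#' study (UTRs, predictions, expression), scan the UTRs, filter
#' below-background genes per cell line, normalize, call modulation,
#' evaluate the stratified confusion grid in both orientations, correlate
#' canonical against non-canonical statistics, attribute bidirectionally
#' modulated genes, test TF-regulon enrichment in the MRE-devoid set, and
#' recover planted reporter responses.  Identical config + seed gives an
#' identical summary.
#'
#' @param config a [SimulationConfig-class] (or path to a YAML/JSON file
#'   of `simulationConfig()` arguments).
#' @param mir a [MatureMiRNA-class] used for UTR simulation and scanning;
#'   defaults to the bundled miR-181b-5p.
#' @param mode modulation-call mode, "fc_only" (default, matching the
#'   fold-change-only restricted analysis) or "fc_and_p".
#' @param fc_threshold linear fold-change threshold.
#' @param reporter_percents planted reporter percent changes.
#' @param utr_length simulated UTR length (nt).
#' @param scan_utrs logical; also simulate UTRs and cross-check the
#'   scanner-derived prediction table against the planted site classes
#'   (slower; the check is exact by construction).
#' @return list with elements `truth`, `predictions`, `calls`,
#'   `evaluation` (stratified data.frame), `orientation_correlation`,
#'   `attribution`, `tf_consistency`, `reporter`, and `summary` (plain
#'   named numbers, JSON-serializable).
#' @export
runPipeline <- function(config = simulationConfig(),
                        mir = bundledMiRNAs()[[1]],
                        mode = c("fc_only", "fc_and_p"),
                        fc_threshold = 1.5,
                        reporter_percents = c(KCNMB2_like = -60,
                                              FGA_like = -20,
                                              BIK_like = -10,
                                              null_construct = 0,
                                              E2F1_like = 52),
                        utr_length = 60L,
                        scan_utrs = FALSE) {
  mode <- match.arg(mode)
  if (is.character(config)) config <- readRunConfig(config)
  stopifnot(is(config, "SimulationConfig"))

  truth <- generateTruth(config)
  g <- truthGenes(truth)
  predictions <- truthPredictions(truth, mirna = mirID(mir))

  if (scan_utrs) {
    utrs <- generateUTRs(truth, mir, utr_length)
    scanned <- scanToPredictions(utrs, mir)
    stopifnot(identical(sort(scanned$gene), sort(predictions$gene)))
    m <- match(predictions$gene, scanned$gene)
    stopifnot(identical(scanned$site_type[m], predictions$site_type))
  }

  experiments <- generateExpression(truth, config)
  calls <- do.call(rbind, lapply(experiments, function(e) {
    retained <- filterBackground(e)
    callModulation(normalize(e[retained, ]), fc_threshold = fc_threshold,
                   mode = mode)
  }))
  rownames(calls) <- NULL

  evaluation <- stratifiedEvaluation(calls, predictions)

  # canonical vs non-canonical correlation of each statistic across the
  # (modulation x cell x parameter) strata
  key <- c("modulation", "cell_type", "parameter")
  can <- evaluation[evaluation$orientation == "canonical", ]
  non <- evaluation[evaluation$orientation == "noncanonical", ]
  m <- match(interaction(can[key]), interaction(non[key]))
  ocorr <- lapply(c(accuracy = "accuracy", fpr = "fpr", fnr = "fnr"),
                  function(s) orientationCorrelation(can[[s]],
                                                     non[[s]][m]))

  # attribution of bidirectionally modulated genes (>= 2 cell types)
  cells <- unique(calls$cell_type)
  bidir <- lapply(cells, function(cl)
    bidirectionalSet(calls, cl, "canonical"))
  bidir2 <- multiCellTypeSet(bidir, min_cells = min(2L, length(cells)))
  regulon <- g$gene[g$in_tf_regulon | g$is_tf_gene]
  attribution <- if (length(bidir2))
    attributeGenes(bidir2, predictions, tf_regulon = regulon)
  else NULL

  # TF-regulon enrichment among modulated genes devoid of an MRE
  universe <- sort(unique(calls$gene))
  modulated_any <- sort(unique(unlist(lapply(cells, function(cl) {
    cc <- calls[calls$cell_type == cl & calls$direction != "unchanged", ]
    cc$gene
  }))))
  no_mre <- setdiff(modulated_any, predictions$gene)
  tf_cons <- if (length(no_mre))
    tfSecondaryConsistency(no_mre, universe,
                           annotation = list(TF_regulon = regulon),
                           regulon_term = "TF_regulon")
  else NULL

  reporter_data <- generateReporterData(reporter_percents,
                                        seed = config@rng_seed)
  reporter <- do.call(rbind, lapply(split(reporter_data,
                                          reporter_data$construct),
    function(d) {
      r <- reporterResponse(d)
      data.frame(construct = r$construct,
                 percent_change = r$percent_change,
                 p_value = r$p_value, validated = r$validated,
                 stringsAsFactors = FALSE)
    }))
  rownames(reporter) <- NULL

  meanAcc <- meanOverParameters(evaluation[
    evaluation$orientation == "canonical", ], "accuracy", "modulation")
  acc <- structure(meanAcc$mean_accuracy, names = meanAcc$modulation)

  summary <- list(
    seed = config@rng_seed,
    n_genes = config@n_genes,
    n_cell_types = config@n_cell_types,
    mean_accuracy_miR = unname(acc["miR"]),
    mean_accuracy_anti_miR = unname(acc["anti_miR"]),
    mean_accuracy_bidirectional = unname(acc["bidirectional"]),
    orientation_r2_accuracy = ocorr$accuracy$r2,
    orientation_r2_fnr = ocorr$fnr$r2,
    n_bidirectional_2plus = length(bidir2),
    explained_fraction = if (!is.null(attribution))
      unname(attribution$explained_fraction) else NA_real_,
    tf_regulon_p = if (!is.null(tf_cons)) tf_cons$regulon_p else NA_real_)
  list(truth = truth, predictions = predictions, calls = calls,
       evaluation = evaluation, orientation_correlation = ocorr,
       attribution = attribution, tf_consistency = tf_cons,
       reporter = reporter, summary = summary)
}

#' Read a run configuration file
#'
#' YAML or JSON mapping of [simulationConfig()] argument names to values.
#'
#' @param path config file (extension .yaml/.yml or .json).
#' @return A [SimulationConfig-class].
#' @export
readRunConfig <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    read_yaml(path)
  else
    read_json(path, simplifyVector = TRUE)
  known <- names(formals(simulationConfig))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown configuration field(s): ",
         paste(unknown, collapse = ", "))
  do.call(simulationConfig, vals)
}

#' Write a machine-readable run summary
#'
#' @param result list returned by [runPipeline()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeRunSummary <- function(result, path) {
  payload <- list(summary = result$summary,
                  evaluation = result$evaluation,
                  reporter = result$reporter)
  if (!is.null(result$attribution))
    payload$attribution_fractions <- as.list(result$attribution$fractions)
  write_json(payload, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
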