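#' @importFrom stats pt pf var cor cor.test aov
NULL

expectedDirection <- function(modulation, orientation) {
  if (!modulation %in% c("miR", "anti_miR"))
    stop("unknown modulation: ", modulation)
  if (!orientation %in% ORIENTATIONS)
    stop("unknown orientation: ", orientation)
  if (orientation == "canonical") {
    if (modulation == "miR") "down" else "up"
  } else {
    if (modulation == "miR") "up" else "down"
  }
}

#' Classify one gene into the confusion matrix
#'
#' A predicted target differentially expressed in the direction expected
#' for the orientation is a true positive; a predicted target otherwise
#' (unchanged, or changed against the expected direction) is a false
#' positive; a non-predicted gene changed in the expected direction is a
#' false negative; a non-predicted gene otherwise is a true negative.
#' Canonical orientation expects `down` under miR over-expression and
#' `up` under anti-miR inhibition; non-canonical is the reverse.
#'
#' @param predicted logical: is the gene a predicted target?
#' @param direction observed call: "up", "down" or "unchanged".
#' @param modulation "miR" or "anti_miR".
#' @param orientation "canonical" or "noncanonical".
#' @return One of "TP", "FP", "FN", "TN".
#' @examples
#' classifyGene(TRUE, "down", "miR", "canonical")   # TP
#' classifyGene(TRUE, "unchanged", "miR", "canonical")  # FP
#' @export
classifyGene <- function(predicted, direction,
                         modulation = c("miR", "anti_miR"),
                         orientation = c("canonical", "noncanonical")) {
  modulation <- match.arg(modulation)
  orientation <- match.arg(orientation)
  stopifnot(direction %in% c("up", "down", "unchanged"))
  responsive <- direction == expectedDirection(modulation, orientation)
  if (predicted) {
    if (responsive) "TP" else "FP"
  } else {
    if (responsive) "FN" else "TN"
  }
}

predictedFlagForParameter <- function(genes, predictions, parameter) {
  pr <- predictions
  sel <- switch(parameter,
    all = rep(TRUE, nrow(pr)),
    conserved = !is.na(pr$conserved) & pr$conserved,
    nonconserved = !is.na(pr$conserved) & !pr$conserved,
    "8mer" = pr$site_type == "8mer",
    "7mer-m8" = pr$site_type == "7mer-m8",
    "7mer-1A" = pr$site_type == "7mer-1A",
    stop("unknown prediction parameter: ", parameter))
  genes %in% pr$gene[sel]
}

#' Evaluate predictions against calls in one stratum
#'
#' Tallies every retained gene exactly once into TP/TN/FP/FN for one
#' (modulation, cell type, prediction parameter, orientation) stratum.
#' For `modulation = "bidirectional"` a gene counts as responsive iff it
#' lies in the [bidirectionalSet()] of the orientation.  For a parameter
#' stratum (e.g. "8mer") the predicted flag means predicted with that
#' parameter; all other retained genes — including genes predicted under
#' other parameters — form the negative class.
#'
#' @param calls modulation-call data.frame (restricted to retained genes).
#' @param predictions prediction table (`gene`, `mirna`, `site_type`,
#'   `conserved`, `pct`).
#' @param modulation "miR", "anti_miR" or "bidirectional".
#' @param cell_type cell type label present in `calls`.
#' @param parameter "all", "conserved", "nonconserved", "8mer",
#'   "7mer-m8" or "7mer-1A".
#' @param orientation "canonical" or "noncanonical".
#' @return A [ConfusionSummary-class].
#' @export
evaluateStratum <- function(calls, predictions,
                            modulation = c("miR", "anti_miR",
                                           "bidirectional"),
                            cell_type, parameter = "all",
                            orientation = c("canonical", "noncanonical")) {
  modulation <- match.arg(modulation)
  orientation <- match.arg(orientation)
  cc <- calls[calls$cell_type == cell_type, , drop = FALSE]
  if (!nrow(cc)) stop("empty gene universe for cell type ", cell_type)
  universe <- sort(unique(cc$gene))
  if (modulation == "bidirectional") {
    responsive <- universe %in% bidirectionalSet(cc, cell_type, orientation)
  } else {
    arm <- cc[cc$modulation == modulation, , drop = FALSE]
    if (!nrow(arm)) stop("no calls for modulation arm ", modulation)
    want <- expectedDirection(modulation, orientation)
    responsive <- universe %in% arm$gene[arm$direction == want]
  }
  predicted <- predictedFlagForParameter(universe, predictions, parameter)
  confusionSummary(
    tp = sum(predicted & responsive),
    fp = sum(predicted & !responsive),
    fn = sum(!predicted & responsive),
    tn = sum(!predicted & !responsive),
    stratum = c(modulation = modulation, cell_type = cell_type,
                parameter = parameter, orientation = orientation))
}

#' Stratified prediction-response evaluation
#'
#' One [ConfusionSummary-class] per cell of the requested
#' (modulation x cell type x prediction parameter x orientation) grid,
#' returned as a tidy data.frame (one row per stratum).
#'
#' @param calls modulation-call data.frame.
#' @param predictions prediction table.
#' @param modulations,parameters,orientations character vectors defining
#'   the grid; cell types are taken from `calls`.
#' @return data.frame with stratum labels, counts and derived rates.
#' @export
stratifiedEvaluation <- function(calls, predictions,
                                 modulations = MODULATIONS,
                                 parameters = c("all", "conserved",
                                                "nonconserved", "8mer",
                                                "7mer-m8", "7mer-1A"),
                                 orientations = ORIENTATIONS) {
  cells <- unique(calls$cell_type)
  grid <- expand.grid(modulation = modulations, cell_type = cells,
                      parameter = parameters, orientation = orientations,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i)
    as.data.frame(evaluateStratum(calls, predictions,
                                  modulation = grid$modulation[i],
                                  cell_type = grid$cell_type[i],
                                  parameter = grid$parameter[i],
                                  orientation = grid$orientation[i])))
  do.call(rbind, rows)
}

#' Mean of a confusion statistic across parameter strata
#'
#' Arithmetic mean of the requested statistic across prediction-parameter
#' strata within each group (e.g. mean accuracy per modulation arm across
#' conservation and seed-class parameters).
#'
#' @param summaries data.frame from [stratifiedEvaluation()].
#' @param statistic column to average (e.g. "accuracy").
#' @param group_by character vector of grouping columns.
#' @return data.frame of group labels and the group mean.
#' @export
meanOverParameters <- function(summaries, statistic = "accuracy",
                               group_by = "modulation") {
  if (!nrow(summaries)) stop("no summaries supplied")
  if (!statistic %in% names(summaries))
    stop("unknown statistic: ", statistic)
  agg <- stats::aggregate(summaries[[statistic]],
                          by = summaries[group_by],
                          FUN = function(x) mean(x, na.rm = TRUE))
  names(agg)[ncol(agg)] <- paste0("mean_", statistic)
  agg
}

#' Paired two-tailed Student's t-test
#'
#' Compares a statistic between two conditions paired by stratum.
#' Zero variance of the paired differences yields an `NA` p-value with a
#' diagnostic message rather than an error.
#'
#' @param values_a,values_b equal-length numeric vectors (>= 2), paired.
#' @return list with elements `t`, `df`, `p` and `note`.
#' @export
pairedTTest <- function(values_a, values_b) {
  if (length(values_a) != length(values_b))
    stop("paired vectors must have equal length")
  if (length(values_a) < 2) stop("at least 2 pairs are required")
  d <- values_a - values_b
  if (var(d) == 0) {
    if (all(d == 0))
      return(list(t = 0, df = length(d) - 1L, p = 1,
                  note = "all differences zero"))
    return(list(t = NA_real_, df = length(d) - 1L, p = NA_real_,
                note = "zero variance of non-zero differences"))
  }
  ht <- t.test(values_a, values_b, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, note = NA_character_)
}

#' One-way repeated-measures ANOVA
#'
#' Within-subject F test across k conditions measured on n subjects,
#' with (k-1, (k-1)(n-1)) degrees of freedom.  Computed from the standard
#' sums-of-squares decomposition (subject, condition, residual).
#'
#' @param values numeric matrix, subjects x conditions, complete.
#' @return list with `F`, `df1`, `df2`, `p`.
#' @export
rmAnova <- function(values) {
  values <- as.matrix(values)
  if (any(!is.finite(values))) stop("complete matrix required")
  n <- nrow(values); k <- ncol(values)
  if (n < 2 || k < 2) stop("need >= 2 subjects and >= 2 conditions")
  grand <- mean(values)
  ss_cond <- n * sum((colMeans(values) - grand)^2)
  ss_subj <- k * sum((rowMeans(values) - grand)^2)
  ss_tot <- sum((values - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1L; df2 <- (k - 1L) * (n - 1L)
  if (ss_cond <= .Machine$double.eps * ss_tot || ss_tot == 0)
    return(list(F = 0, df1 = df1, df2 = df2, p = 1))
  if (ss_err <= 0)
    return(list(F = Inf, df1 = df1, df2 = df2, p = 0))
  Fstat <- (ss_cond / df1) / (ss_err / df2)
  list(F = Fstat, df1 = df1, df2 = df2,
       p = pf(Fstat, df1, df2, lower.tail = FALSE))
}

#' Correlation between canonical and non-canonical statistics
#'
#' Squared Pearson correlation (and its two-tailed p) between a
#' confusion statistic measured across matching strata in the canonical
#' and non-canonical orientations.  R-squared is sign-blind by
#' definition.  Zero variance in either vector yields `NA` with a
#' diagnostic note.
#'
#' @param stats_canonical,stats_noncanonical paired numeric vectors
#'   (length >= 3) of a statistic across matching strata.
#' @return list with `r2`, `p`, `n` and `note`.
#' @export
orientationCorrelation <- function(stats_canonical, stats_noncanonical) {
  if (length(stats_canonical) != length(stats_noncanonical))
    stop("paired vectors must have equal length")
  keep <- is.finite(stats_canonical) & is.finite(stats_noncanonical)
  a <- stats_canonical[keep]; b <- stats_noncanonical[keep]
  if (length(a) < 3) stop("at least 3 complete pairs are required")
  if (var(a) == 0 || var(b) == 0)
    return(list(r2 = NA_real_, p = NA_real_, n = length(a),
                note = "zero variance in one vector"))
  ct <- cor.test(a, b)
  list(r2 = unname(ct$estimate)^2, p = ct$p.value, n = length(a),
       note = NA_character_)
}

#' Fraction of modulated predicted targets with PCT below a cutoff
#'
#' @param pct numeric vector of probability-of-conserved-targeting scores
#'   for the predicted targets among modulated genes.
#' @param cutoff PCT cutoff (default 0.1); strictly-below counting.
#' @return Proportion in [0,1].
#' @export
pctFractionBelow <- function(pct, cutoff = 0.1) {
  pct <- pct[!is.na(pct)]
  if (!length(pct)) stop("no PCT scores supplied")
  mean(pct < cutoff)
}
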