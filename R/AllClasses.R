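#' @import methods
#' @importFrom S4Vectors metadata DataFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

RNA_ALPHABET <- c("A", "C", "G", "U")
DNA_ALPHABET <- c("A", "C", "G", "T", "N")
SITE_CLASSES <- c("8mer", "7mer-m8", "7mer-1A")
CONDITIONS <- c("control", "miR", "anti_miR")
ORIENTATIONS <- c("canonical", "noncanonical")
MODULATIONS <- c("miR", "anti_miR", "bidirectional")
ATTRIBUTION_CATEGORIES <- c(
  "TS_conserved", "TS_nonconserved_pct_lt", "TS_nonconserved_pct_ge",
  "alt_algorithm_only", "tf_motif_only", "unexplained"
)

#' MatureMiRNA: a mature miRNA sequence
#'
#' Holds a miRNA identifier and its mature sequence, written 5'->3' in the
#' RNA alphabet.  Position indexing is 1-based from the 5' end; the seed
#' region spans positions 2-7 (extended to position 8 for the 7mer-m8 and
#' 8mer site classes).
#'
#' @slot id single character identifier (e.g. "hsa-miR-181b-5p").
#' @slot sequence single character string over {A,C,G,U}, length >= 8.
#' @export
setClass("MatureMiRNA",
  representation(id = "character", sequence = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@id) != 1L || !nzchar(object@id))
      msg <- c(msg, "'id' must be a single non-empty string")
    if (length(object@sequence) != 1L)
      msg <- c(msg, "'sequence' must be a single string")
    else {
      s <- strsplit(object@sequence, "")[[1]]
      if (length(s) < 8L)
        msg <- c(msg, "mature sequence must be at least 8 nt")
      if (!all(s %in% RNA_ALPHABET))
        msg <- c(msg, sprintf(
          "sequence of '%s' is not RNA (allowed: A,C,G,U)", object@id))
    }
    if (length(msg)) msg else TRUE
  }
)

#' Construct a MatureMiRNA
#'
#' @param id miRNA identifier.
#' @param sequence mature sequence 5'->3'.  'T' is accepted and converted
#'   to 'U'; lower case is accepted.
#' @return A [MatureMiRNA-class] object.
#' @examples
#' mir <- matureMiRNA("hsa-miR-181b-5p", "AACAUUCAUUGCUGUCGGUGGGU")
#' seedSiteStrings(mir)
#' @export
matureMiRNA <- function(id, sequence) {
  sequence <- chartr("tT", "uU", as.character(sequence))
  new("MatureMiRNA", id = as.character(id), sequence = toupper(sequence))
}

setMethod("show", "MatureMiRNA", function(object) {
  cat(sprintf("MatureMiRNA %s (%d nt)\n  5'-%s-3'\n",
              object@id, nchar(object@sequence), object@sequence))
})

#' @describeIn MatureMiRNA-class identifier accessor
#' @param object a `MatureMiRNA`
#' @export
mirID <- function(object) object@id

#' @describeIn MatureMiRNA-class mature sequence accessor
#' @export
mirSequence <- function(object) object@sequence

#' SimulationConfig: parameters of the synthetic transfection study
#'
#' Describes the simulated study design: cell types x {control, miR
#' over-expression, anti-miR inhibition} x replicates, the planted target
#' structure (fraction predicted, conservation, response modes), effect
#' sizes, replicate noise, below-background structure and a
#' transcription-factor regulon responding secondarily because the TF is
#' itself a miRNA target.
#'
#' @slot n_genes number of genes on the simulated array.
#' @slot n_cell_types number of cell types.
#' @slot replicates_per_condition replicates per (cell type, condition).
#' @slot frac_predicted_targets proportion of genes carrying a predicted
#'   miRNA recognition element.
#' @slot frac_conserved_among_predicted proportion of predicted targets
#'   flagged conserved.
#' @slot frac_canonical_responders proportion of predicted targets that
#'   respond canonically (down with miR, up with anti-miR).
#' @slot frac_noncanonical_responders proportion of predicted targets that
#'   respond positively (up with miR, down with anti-miR).
#' @slot background_de_rate proportion of non-target genes spuriously
#'   differentially expressed, independently per modulation arm, with a
#'   random direction.
#' @slot effect_fold_range linear fold bounds for planted effects.
#' @slot anti_mir_attenuation anti-miR effect as a fraction of the
#'   over-expression effect on the log2 scale (anti fold = fold^a).
#' @slot noise_sd_log2 SD of log2 replicate noise.
#' @slot background_expression_level intensity floor; doubles as the
#'   below-background threshold.
#' @slot frac_below_background_per_cell proportion of genes unexpressed in
#'   each cell type (drawn independently per cell type).
#' @slot tf_regulon_size number of genes in the TF regulon (0 disables).
#' @slot tf_effect_orientation "canonical" or "noncanonical": direction in
#'   which the regulon (and the TF gene itself) responds.
#' @slot rng_seed integer seed; all randomness derives from it.
#' @export
setClass("SimulationConfig",
  representation(
    n_genes = "integer",
    n_cell_types = "integer",
    replicates_per_condition = "integer",
    frac_predicted_targets = "numeric",
    frac_conserved_among_predicted = "numeric",
    frac_canonical_responders = "numeric",
    frac_noncanonical_responders = "numeric",
    background_de_rate = "numeric",
    effect_fold_range = "numeric",
    anti_mir_attenuation = "numeric",
    noise_sd_log2 = "numeric",
    background_expression_level = "numeric",
    frac_below_background_per_cell = "numeric",
    tf_regulon_size = "integer",
    tf_effect_orientation = "character",
    rng_seed = "integer"
  ),
  validity = function(object) {
    msg <- character()
    chkProp <- function(x, nm) {
      if (length(x) != 1L || is.na(x) || x < 0 || x > 1)
        sprintf("'%s' must be a proportion in [0,1]", nm) else character()
    }
    msg <- c(msg,
      chkProp(object@frac_predicted_targets, "frac_predicted_targets"),
      chkProp(object@frac_conserved_among_predicted,
              "frac_conserved_among_predicted"),
      chkProp(object@frac_canonical_responders, "frac_canonical_responders"),
      chkProp(object@frac_noncanonical_responders,
              "frac_noncanonical_responders"),
      chkProp(object@background_de_rate, "background_de_rate"),
      chkProp(object@frac_below_background_per_cell,
              "frac_below_background_per_cell"),
      chkProp(object@anti_mir_attenuation, "anti_mir_attenuation"))
    if (object@frac_canonical_responders +
        object@frac_noncanonical_responders > 1 + 1e-12)
      msg <- c(msg, paste0("'frac_canonical_responders' + ",
        "'frac_noncanonical_responders' must not exceed 1"))
    if (object@n_genes < 1L)
      msg <- c(msg, "'n_genes' must be positive")
    if (object@n_cell_types < 1L)
      msg <- c(msg, "'n_cell_types' must be positive")
    if (object@replicates_per_condition < 2L)
      msg <- c(msg, "'replicates_per_condition' must be at least 2")
    if (length(object@effect_fold_range) != 2L ||
        object@effect_fold_range[1] < 1 ||
        diff(object@effect_fold_range) < 0)
      msg <- c(msg, paste0("'effect_fold_range' must be an increasing pair ",
        "with lower bound >= 1"))
    if (object@noise_sd_log2 < 0)
      msg <- c(msg, "'noise_sd_log2' must be non-negative")
    if (object@background_expression_level <= 0)
      msg <- c(msg, "'background_expression_level' must be positive")
    if (object@tf_regulon_size < 0L)
      msg <- c(msg, "'tf_regulon_size' must be non-negative")
    if (!object@tf_effect_orientation %in% ORIENTATIONS)
      msg <- c(msg, "'tf_effect_orientation' must be one of ",
               paste(ORIENTATIONS, collapse = ", "))
    if (length(msg)) msg else TRUE
  }
)

#' Construct a SimulationConfig
#'
#' Defaults describe the emulated study: 3 cell types, n=2 replicates per
#' condition, 1.5-3.0-fold planted effects, anti-miR effects attenuated to
#' half the over-expression effect on the log2 scale, and a 150-gene TF
#' regulon whose TF is itself a predicted target.
#'
#' @param n_genes,n_cell_types,replicates_per_condition study dimensions.
#' @param frac_predicted_targets,frac_conserved_among_predicted,
#'   frac_canonical_responders,frac_noncanonical_responders,
#'   background_de_rate,frac_below_background_per_cell proportions in [0,1].
#' @param effect_fold_range pair of linear fold bounds (lower >= 1).
#' @param anti_mir_attenuation anti-miR log2-effect fraction in [0,1].
#' @param noise_sd_log2 replicate noise SD on log2 intensities.
#' @param background_expression_level intensity floor / filter threshold.
#' @param tf_regulon_size,tf_effect_orientation TF regulon settings.
#' @param rng_seed integer seed.
#' @return A [SimulationConfig-class] object (validated).
#' @examples
#' cfg <- simulationConfig(n_genes = 200, rng_seed = 1)
#' truth <- generateTruth(cfg)
#' @export
simulationConfig <- function(n_genes = 2000L,
                             n_cell_types = 3L,
                             replicates_per_condition = 2L,
                             frac_predicted_targets = 0.2,
                             frac_conserved_among_predicted = 0.3,
                             frac_canonical_responders = 0.4,
                             frac_noncanonical_responders = 0.1,
                             background_de_rate = 0.05,
                             effect_fold_range = c(1.5, 3.0),
                             anti_mir_attenuation = 0.5,
                             noise_sd_log2 = 0.15,
                             background_expression_level = 50,
                             frac_below_background_per_cell = 0.1,
                             tf_regulon_size = 150L,
                             tf_effect_orientation = "canonical",
                             rng_seed = 1L) {
  new("SimulationConfig",
      n_genes = as.integer(n_genes),
      n_cell_types = as.integer(n_cell_types),
      replicates_per_condition = as.integer(replicates_per_condition),
      frac_predicted_targets = frac_predicted_targets,
      frac_conserved_among_predicted = frac_conserved_among_predicted,
      frac_canonical_responders = frac_canonical_responders,
      frac_noncanonical_responders = frac_noncanonical_responders,
      background_de_rate = background_de_rate,
      effect_fold_range = as.numeric(effect_fold_range),
      anti_mir_attenuation = anti_mir_attenuation,
      noise_sd_log2 = noise_sd_log2,
      background_expression_level = background_expression_level,
      frac_below_background_per_cell = frac_below_background_per_cell,
      tf_regulon_size = as.integer(tf_regulon_size),
      tf_effect_orientation = tf_effect_orientation,
      rng_seed = as.integer(rng_seed))
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:",
      object@n_genes, "genes x", object@n_cell_types, "cell types x",
      "{control,miR,anti_miR} x", object@replicates_per_condition,
      "replicates\n")
  cat(sprintf("  predicted targets: %.0f%% (%.0f%% conserved); responders: %.0f%% canonical, %.0f%% non-canonical\n",
      100 * object@frac_predicted_targets,
      100 * object@frac_conserved_among_predicted,
      100 * object@frac_canonical_responders,
      100 * object@frac_noncanonical_responders))
  cat(sprintf("  effects %.2g-%.2gx (anti-miR attenuation %.2g), noise sd(log2) %.3g, seed %d\n",
      object@effect_fold_range[1], object@effect_fold_range[2],
      object@anti_mir_attenuation, object@noise_sd_log2, object@rng_seed))
})

#' GroundTruth: planted per-gene labels of a synthetic study
#'
#' One row per gene: prediction status, site class, conservation, PCT,
#' response mode, TF-regulon membership, per-cell expressed flags, the
#' planted linear effect fold and the per-arm spurious background effects.
#' This is the oracle against which the pipeline's calls are evaluated.
#'
#' @slot genes data.frame of per-gene records.
#' @slot config the [SimulationConfig-class] that generated it.
#' @export
setClass("GroundTruth",
  representation(genes = "data.frame", config = "SimulationConfig"),
  validity = function(object) {
    g <- object@genes
    need <- c("gene", "is_predicted_target", "site_class", "conserved",
              "pct", "response_mode", "in_tf_regulon", "is_tf_gene",
              "true_effect_fold")
    miss <- setdiff(need, names(g))
    if (length(miss))
      return(sprintf("missing truth columns: %s", paste(miss, collapse = ", ")))
    if (anyDuplicated(g$gene)) return("duplicate gene ids")
    bad <- g$site_class[g$is_predicted_target] == "none"
    if (any(bad)) return("predicted targets must carry a site class")
    bad <- g$site_class[!g$is_predicted_target] != "none"
    if (any(bad)) return("non-targets must have site_class 'none'")
    TRUE
  }
)

setMethod("show", "GroundTruth", function(object) {
  g <- object@genes
  cat(sprintf("GroundTruth: %d genes, %d predicted targets (%d canonical, %d non-canonical responders)\n",
      nrow(g), sum(g$is_predicted_target),
      sum(g$response_mode == "canonical" & g$is_predicted_target),
      sum(g$response_mode == "noncanonical" & g$is_predicted_target)))
  if (any(g$is_tf_gene))
    cat(sprintf("  TF gene %s with a %d-gene regulon (%s secondary response)\n",
        g$gene[g$is_tf_gene][1], sum(g$in_tf_regulon),
        object@config@tf_effect_orientation))
})

#' @describeIn GroundTruth-class per-gene truth table accessor
#' @param object a `GroundTruth`
#' @export
truthGenes <- function(object) object@genes

#' @describeIn GroundTruth-class generating configuration accessor
#' @export
truthConfig <- function(object) object@config

#' MirExperiment: an expression experiment under miRNA modulation
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one `intensity`
#' assay (non-negative array intensities), sample metadata columns
#' `cell_type`, `condition` (control / miR / anti_miR) and `replicate`,
#' and a below-background intensity threshold in `metadata()`.
#'
#' @export
setClass("MirExperiment", contains = "SummarizedExperiment",
  validity = function(object) {
    msg <- character()
    cd <- colData(object)
    need <- c("cell_type", "condition", "replicate")
    miss <- setdiff(need, names(cd))
    if (length(miss))
      msg <- c(msg, sprintf("colData lacks: %s", paste(miss, collapse = ", ")))
    else if (!all(cd$condition %in% CONDITIONS))
      msg <- c(msg, sprintf("condition values must be in {%s}",
                            paste(CONDITIONS, collapse = ", ")))
    if (!"intensity" %in% SummarizedExperiment::assayNames(object))
      msg <- c(msg, "an 'intensity' assay is required")
    else if (any(assay(object, "intensity") < 0, na.rm = TRUE))
      msg <- c(msg, "intensities must be non-negative")
    if (anyDuplicated(rownames(object)))
      msg <- c(msg, "gene ids must be unique")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a MirExperiment
#'
#' @param intensity numeric genes x samples matrix of non-negative
#'   intensities with gene row names.
#' @param cell_type,condition,replicate per-sample metadata vectors;
#'   `condition` must be one of control, miR, anti_miR.
#' @param background_threshold intensity below which a measurement counts
#'   as below background.
#' @return A [MirExperiment-class].
#' @examples
#' m <- matrix(c(10, 10, 20, 20), 1, dimnames = list("g1", NULL))
#' mirExperiment(m, "HEK293", c("control", "control", "miR", "miR"),
#'               c(1, 2, 1, 2), background_threshold = 1)
#' @export
mirExperiment <- function(intensity, cell_type, condition, replicate,
                          background_threshold = 0) {
  intensity <- as.matrix(intensity)
  if (is.null(colnames(intensity)))
    colnames(intensity) <- paste(cell_type, condition, replicate, sep = ".")
  se <- SummarizedExperiment(
    assays = list(intensity = intensity),
    colData = DataFrame(
      cell_type = as.character(rep(cell_type, length.out = ncol(intensity))),
      condition = as.character(rep(condition, length.out = ncol(intensity))),
      replicate = as.integer(rep(replicate, length.out = ncol(intensity))),
      row.names = colnames(intensity)))
  obj <- new("MirExperiment", se)
  S4Vectors::metadata(obj)$background_threshold <- background_threshold
  obj
}

#' @describeIn MirExperiment-class below-background threshold accessor
#' @param object a `MirExperiment`
#' @export
backgroundThreshold <- function(object)
  S4Vectors::metadata(object)$background_threshold

#' ConfusionSummary: prediction-vs-response tallies for one stratum
#'
#' TP/TN/FP/FN counts for one (modulation, cell type, prediction
#' parameter, orientation) stratum, with derived rates: accuracy =
#' (TP+TN)/N, sensitivity = TP/(TP+FN), specificity = TN/(TN+FP),
#' FNR = 1 - sensitivity, FPR = 1 - specificity.  Rates with a zero
#' denominator are `NA`, never coerced to 0 or 1.
#'
#' @slot stratum named character vector of stratum labels.
#' @slot tp,tn,fp,fn numeric tallies (may be expected, hence fractional).
#' @export
setClass("ConfusionSummary",
  representation(stratum = "character", tp = "numeric", tn = "numeric",
                 fp = "numeric", fn = "numeric"),
  validity = function(object) {
    counts <- c(object@tp, object@tn, object@fp, object@fn)
    if (any(counts < 0)) return("counts must be non-negative")
    TRUE
  }
)

confusionSummary <- function(tp, tn, fp, fn, stratum = character()) {
  new("ConfusionSummary", stratum = stratum,
      tp = as.numeric(tp), tn = as.numeric(tn),
      fp = as.numeric(fp), fn = as.numeric(fn))
}

rateOrNA <- function(num, den) if (den > 0) num / den else NA_real_

#' @describeIn ConfusionSummary-class (TP+TN)/(TP+TN+FP+FN)
#' @param object a `ConfusionSummary`
#' @export
accuracy <- function(object)
  rateOrNA(object@tp + object@tn, object@tp + object@tn + object@fp + object@fn)

#' @describeIn ConfusionSummary-class TP/(TP+FN)
#' @export
sensitivity <- function(object) rateOrNA(object@tp, object@tp + object@fn)

#' @describeIn ConfusionSummary-class TN/(TN+FP)
#' @export
specificity <- function(object) rateOrNA(object@tn, object@tn + object@fp)

#' @describeIn ConfusionSummary-class 1 - specificity (Type I error)
#' @export
fpr <- function(object) 1 - specificity(object)

#' @describeIn ConfusionSummary-class 1 - sensitivity (Type II error)
#' @export
fnr <- function(object) 1 - sensitivity(object)

setMethod("show", "ConfusionSummary", function(object) {
  if (length(object@stratum))
    cat("ConfusionSummary [",
        paste(names(object@stratum), object@stratum, sep = "=",
              collapse = ", "), "]\n", sep = "")
  else cat("ConfusionSummary\n")
  cat(sprintf("  TP=%g TN=%g FP=%g FN=%g\n",
              object@tp, object@tn, object@fp, object@fn))
  cat(sprintf("  accuracy=%.4g sensitivity=%.4g specificity=%.4g fpr=%.4g fnr=%.4g\n",
              accuracy(object), sensitivity(object), specificity(object),
              fpr(object), fnr(object)))
})

#' @describeIn ConfusionSummary-class one-row data.frame of labels, counts
#'   and rates
#' @param x a `ConfusionSummary`
#' @param row.names,optional,... ignored (S3 compatibility)
#' @export
as.data.frame.ConfusionSummary <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  labs <- as.list(x@stratum)
  df <- data.frame(labs, tp = x@tp, tn = x@tn, fp = x@fp, fn = x@fn,
                   accuracy = accuracy(x), sensitivity = sensitivity(x),
                   specificity = specificity(x), fpr = fpr(x), fnr = fnr(x),
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}
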