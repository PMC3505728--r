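#' @importFrom stats t.test sd
#' @importFrom BiocGenerics normalize
NULL

#' @describeIn MirExperiment-class per-chip and per-gene normalization.
#'   Per chip, each sample is divided by its size factor — the median,
#'   over retained genes, of the ratios to the within-cell-type control
#'   reference (the per-gene median of control samples); this keeps
#'   treatment chips comparable without letting genuinely responding
#'   genes drag the scaling.  Per gene, each gene is then divided by the
#'   median of its (chip-scaled) control samples, so control levels sit
#'   at 1.0 and treatment values read as fold changes.  Genes whose
#'   control median is zero cannot be referenced and are dropped with a
#'   warning.  On noiseless data with a majority of unresponsive genes
#'   the transformation is exact and idempotent.  `per_chip = FALSE`
#'   skips the size-factor step (useful for toy matrices with so few
#'   genes that a robust chip factor is meaningless).
#' @param object a `MirExperiment`
#' @param per_chip logical, apply the per-chip size-factor step
#' @param ... unused
#' @export
setMethod("normalize", "MirExperiment", function(object, per_chip = TRUE,
                                                 ...) {
  mat <- assay(object, "intensity")
  cd <- colData(object)
  for (cell in unique(cd$cell_type)) {
    ctrl <- which(cd$cell_type == cell & cd$condition == "control")
    incell <- which(cd$cell_type == cell)
    if (!length(ctrl)) stop("no control samples for cell type ", cell)
    ref <- apply(mat[, ctrl, drop = FALSE], 1, median)
    zero <- ref <= 0
    if (any(zero)) {
      warning(sum(zero), " gene(s) with all-zero control values excluded: ",
              paste(utils::head(rownames(mat)[zero], 5), collapse = ", "))
      mat <- mat[!zero, , drop = FALSE]
      object <- object[!zero, ]
      cd <- colData(object)
      ref <- ref[!zero]
      ctrl <- which(cd$cell_type == cell & cd$condition == "control")
      incell <- which(cd$cell_type == cell)
    }
    if (per_chip) {
      # per chip: size factor = median ratio to the control reference
      sf <- apply(mat[, incell, drop = FALSE], 2,
                  function(x) median(x / ref))
      if (any(sf <= 0))
        stop("sample(s) with non-positive size factor in cell type ", cell)
      mat[, incell] <- sweep(mat[, incell, drop = FALSE], 2, sf, "/")
    }
    # per gene: reference to the chip-scaled control median
    ref2 <- apply(mat[, ctrl, drop = FALSE], 1, median)
    mat[, incell] <- mat[, incell, drop = FALSE] / ref2
  }
  SummarizedExperiment::assay(object, "intensity") <- mat
  object
})

#' Below-background gene filter
#'
#' A gene is excluded when its raw intensity is below the background
#' threshold in more than half of the samples of the cell line; at the
#' boundary (below background in exactly half) the gene is retained.
#'
#' @param experiment a [MirExperiment-class] (raw intensities).
#' @param threshold background intensity; defaults to the experiment's
#'   stored [backgroundThreshold()].
#' @return Character vector of retained gene ids.
#' @export
filterBackground <- function(experiment, threshold = NULL) {
  stopifnot(is(experiment, "MirExperiment"))
  if (is.null(threshold)) threshold <- backgroundThreshold(experiment)
  if (is.null(threshold)) stop("no background threshold available")
  mat <- assay(experiment, "intensity")
  cd <- colData(experiment)
  keep <- rep(TRUE, nrow(mat))
  for (cell in unique(cd$cell_type)) {
    incell <- cd$cell_type == cell
    n_below <- rowSums(mat[, incell, drop = FALSE] < threshold)
    keep <- keep & (n_below <= sum(incell) / 2)
  }
  rownames(mat)[keep]
}

pooledT <- function(x, y) {
  # two-sample pooled-variance t-test (Welch df is degenerate at n=2)
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) return(NA_real_)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  if (sp2 == 0) return(NA_real_)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  2 * stats::pt(-abs(t), nx + ny - 2)
}

#' Call per-gene modulation from a normalized experiment
#'
#' For every gene and modulation arm (miR, anti_miR) of every cell type:
#' fold change = mean(treatment) / mean(control) of normalized
#' intensities on the linear scale.  Direction is `up` when fold change
#' >= `fc_threshold`, `down` when <= 1/`fc_threshold`, else `unchanged`
#' (the threshold is inclusive).  In `fc_and_p` mode a two-sample
#' pooled-variance t-test on log2 values additionally gates the call
#' (p >= `p_threshold` forces `unchanged`); p-values are never corrected
#' for multiplicity.  In `fc_only` mode no test is run and `p_value` is
#' `NA`.
#'
#' @param experiment a normalized [MirExperiment-class].
#' @param fc_threshold linear fold-change threshold (default 1.5).
#' @param p_threshold per-gene alpha in `fc_and_p` mode (default 0.05).
#' @param mode "fc_and_p" or "fc_only".
#' @return data.frame of calls: `gene`, `cell_type`, `modulation`,
#'   `direction`, `fold_change`, `p_value`.
#' @export
callModulation <- function(experiment, fc_threshold = 1.5,
                           p_threshold = 0.05,
                           mode = c("fc_and_p", "fc_only")) {
  mode <- match.arg(mode)
  stopifnot(is(experiment, "MirExperiment"))
  mat <- assay(experiment, "intensity")
  cd <- colData(experiment)
  out <- list()
  for (cell in unique(cd$cell_type)) {
    ctrl <- cd$cell_type == cell & cd$condition == "control"
    if (!any(ctrl)) stop("no control samples for cell type ", cell)
    cmeans <- rowMeans(mat[, ctrl, drop = FALSE])
    for (arm in c("miR", "anti_miR")) {
      trt <- cd$cell_type == cell & cd$condition == arm
      if (!any(trt)) next
      tmeans <- rowMeans(mat[, trt, drop = FALSE])
      ok <- cmeans > 0
      if (any(!ok))
        warning(sum(!ok), " gene(s) with zero control mean skipped in ",
                cell, "/", arm)
      fc <- tmeans[ok] / cmeans[ok]
      p <- rep(NA_real_, sum(ok))
      if (mode == "fc_and_p") {
        lmat <- log2(pmax(mat, .Machine$double.xmin))
        ti <- which(trt); ci <- which(ctrl)
        p <- vapply(which(ok), function(i)
          pooledT(lmat[i, ti], lmat[i, ci]), numeric(1))
      }
      dir <- ifelse(fc >= fc_threshold, "up",
                    ifelse(fc <= 1 / fc_threshold, "down", "unchanged"))
      if (mode == "fc_and_p")
        dir[is.na(p) | p >= p_threshold] <- "unchanged"
      out[[paste(cell, arm)]] <- data.frame(
        gene = rownames(mat)[ok], cell_type = cell, modulation = arm,
        direction = dir, fold_change = fc, p_value = p,
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Bidirectionally modulated gene set
#'
#' Canonical orientation: genes down-regulated under miR over-expression
#' and up-regulated under anti-miR inhibition; non-canonical orientation:
#' the reverse intersection.
#'
#' @param calls modulation-call data.frame from [callModulation()].
#' @param cell_type cell type to evaluate.
#' @param orientation "canonical" or "noncanonical".
#' @return Character vector of gene ids.
#' @export
bidirectionalSet <- function(calls, cell_type,
                             orientation = c("canonical", "noncanonical")) {
  orientation <- match.arg(orientation)
  cc <- calls[calls$cell_type == cell_type, , drop = FALSE]
  arms <- split(cc, cc$modulation)
  if (!all(c("miR", "anti_miR") %in% names(arms)))
    stop("calls for cell type '", cell_type,
         "' must cover both miR and anti_miR arms")
  if (orientation == "canonical") {
    intersect(arms$miR$gene[arms$miR$direction == "down"],
              arms$anti_miR$gene[arms$anti_miR$direction == "up"])
  } else {
    intersect(arms$miR$gene[arms$miR$direction == "up"],
              arms$anti_miR$gene[arms$anti_miR$direction == "down"])
  }
}

#' Combine per-cell-type gene sets
#'
#' Returns the genes present in at least `min_cells` of the supplied
#' per-cell-type sets (`min_cells = 1` is the plain union).
#'
#' @param sets list of character vectors, one per cell type.
#' @param min_cells minimum number of cell types a gene must appear in.
#' @return Character vector of gene ids.
#' @export
multiCellTypeSet <- function(sets, min_cells = 2L) {
  if (min_cells > length(sets))
    stop("'min_cells' (", min_cells, ") exceeds the number of cell types (",
         length(sets), ")")
  tab <- table(unlist(lapply(sets, unique)))
  sort(names(tab)[tab >= min_cells])
}
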