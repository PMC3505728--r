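#' @importFrom stats rnorm runif rbeta pnorm median
NULL

# Deterministic child seed for a named simulation stage, kept < 2^31.
stageSeed <- function(seed, stage) {
  offs <- c(truth = 11, utr = 23, expression = 37, reporter = 53)
  as.integer((as.numeric(seed) * 1009 + offs[[stage]]) %% 2147483647)
}

firstN <- function(idx, n) idx[seq_len(min(n, length(idx)))]

#' Generate the ground truth of a synthetic modulation study
#'
#' Plants per-gene labels according to the configured proportions:
#' predicted targets (with site class, conservation flag and PCT score),
#' canonical / non-canonical / unresponsive response modes, a TF gene that
#' is itself a predicted target together with its secondary-responding
#' regulon, per-cell-type expressed flags, linear effect folds drawn
#' uniformly from `effect_fold_range`, and per-arm spurious background
#' effects at `background_de_rate` with random direction.
#' Deterministic for a fixed `rng_seed`.
#'
#' @param config a [SimulationConfig-class].
#' @return A [GroundTruth-class].
#' @export
generateTruth <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  n <- config@n_genes
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(stageSeed(config@rng_seed, "truth"))

  gene <- sprintf("G%05d", seq_len(n))
  n_pred <- round(config@frac_predicted_targets * n)
  perm <- sample.int(n)
  pred_idx <- firstN(perm, n_pred)
  is_pred <- rep(FALSE, n); is_pred[pred_idx] <- TRUE

  site_class <- rep("none", n)
  site_class[pred_idx] <- sample(SITE_CLASSES, n_pred, replace = TRUE)

  conserved <- rep(NA, n)
  n_cons <- round(config@frac_conserved_among_predicted * n_pred)
  cons_idx <- firstN(sample(pred_idx), n_cons)
  conserved[pred_idx] <- FALSE; conserved[cons_idx] <- TRUE

  pct <- rep(NA_real_, n)
  # conserved sites well-conserved; non-conserved sites mostly PCT < 0.1
  pct[cons_idx] <- runif(length(cons_idx), 0.5, 1)
  noncons_idx <- setdiff(pred_idx, cons_idx)
  pct[noncons_idx] <- rbeta(length(noncons_idx), 0.8, 8)

  response_mode <- rep("unresponsive", n)
  n_can <- round(config@frac_canonical_responders * n_pred)
  n_non <- round(config@frac_noncanonical_responders * n_pred)
  resp_perm <- sample(pred_idx)
  can_idx <- firstN(resp_perm, n_can)
  non_idx <- resp_perm[seq_len(min(n_can + n_non, length(resp_perm)))]
  non_idx <- setdiff(non_idx, can_idx)
  response_mode[can_idx] <- "canonical"
  response_mode[non_idx] <- "noncanonical"

  # the TF is itself a predicted target; its regulon responds secondarily
  is_tf <- rep(FALSE, n)
  in_regulon <- rep(FALSE, n)
  if (config@tf_regulon_size > 0L && n_pred > 0L) {
    tf <- pred_idx[1L]
    is_tf[tf] <- TRUE
    response_mode[tf] <- config@tf_effect_orientation
    free <- which(!is_pred)
    reg <- firstN(sample(free), config@tf_regulon_size)
    in_regulon[reg] <- TRUE
    response_mode[reg] <- config@tf_effect_orientation
  }

  # spurious background DE: independent per modulation arm, random sign
  spur_pool <- !is_pred & !in_regulon
  spurArm <- function() {
    hit <- spur_pool & runif(n) < config@background_de_rate
    dirs <- rep(NA_character_, n)
    dirs[hit] <- sample(c("up", "down"), sum(hit), replace = TRUE)
    folds <- rep(1, n)
    folds[hit] <- runif(sum(hit), config@effect_fold_range[1],
                        config@effect_fold_range[2])
    list(dir = dirs, fold = folds)
  }
  s_mir <- spurArm(); s_anti <- spurArm()

  fold <- rep(1, n)
  active <- response_mode != "unresponsive"
  fold[active] <- runif(sum(active), config@effect_fold_range[1],
                        config@effect_fold_range[2])

  # below-background assignment, independent per cell type; the TF gene
  # is kept expressed everywhere so its regulon has a driver
  cells <- paste0("cell", seq_len(config@n_cell_types))
  expressed <- matrix(TRUE, n, config@n_cell_types,
                      dimnames = list(gene, cells))
  for (j in seq_len(config@n_cell_types)) {
    below <- runif(n) < config@frac_below_background_per_cell
    below[is_tf] <- FALSE
    expressed[below, j] <- FALSE
  }

  g <- data.frame(gene = gene, is_predicted_target = is_pred,
                  site_class = site_class, conserved = conserved,
                  pct = pct, response_mode = response_mode,
                  in_tf_regulon = in_regulon, is_tf_gene = is_tf,
                  true_effect_fold = fold,
                  spurious_miR_dir = s_mir$dir,
                  spurious_miR_fold = s_mir$fold,
                  spurious_anti_dir = s_anti$dir,
                  spurious_anti_fold = s_anti$fold,
                  stringsAsFactors = FALSE)
  for (j in seq_along(cells))
    g[[paste0("expressed_", cells[j])]] <- expressed[, j]
  new("GroundTruth", genes = g, config = config)
}

#' Ground-truth prediction table
#'
#' The TargetScan-like table implied by a [GroundTruth-class]: one row per
#' predicted target with its site type, conserved flag and PCT.
#'
#' @param truth a [GroundTruth-class].
#' @param mirna miRNA id recorded in the table.
#' @return data.frame with columns `gene`, `mirna`, `site_type`,
#'   `conserved`, `pct`.
#' @export
truthPredictions <- function(truth, mirna = "miR-sim") {
  g <- truthGenes(truth)
  p <- g[g$is_predicted_target, , drop = FALSE]
  data.frame(gene = p$gene, mirna = mirna, site_type = p$site_class,
             conserved = p$conserved, pct = p$pct,
             stringsAsFactors = FALSE, row.names = NULL)
}

randomDNA <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Generate 3'-UTR sequences honouring the planted truth
#'
#' Every predicted-target gene receives a UTR containing at least one site
#' of its assigned class for `mir` (and, by rejection, whose best detected
#' class is exactly the assigned class); every non-target UTR is free of
#' sites of any class.  Correctness is enforced with the scanner itself:
#' sequences are rejection-sampled until clean, so the truth labels are
#' exact by construction.
#'
#' @param truth a [GroundTruth-class].
#' @param mir a [MatureMiRNA-class].
#' @param utr_length UTR length in nt (>= 30).
#' @return Named character vector of DNA sequences (names = gene ids).
#' @export
generateUTRs <- function(truth, mir, utr_length = 60L) {
  stopifnot(is(truth, "GroundTruth"), is(mir, "MatureMiRNA"))
  utr_length <- as.integer(utr_length)
  if (utr_length < 30L) stop("'utr_length' must be at least 30 nt")
  pats <- seedSiteStrings(mir)
  if (utr_length < max(nchar(pats)) + 2L)
    stop("UTR too short to host a seed site")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(stageSeed(truthConfig(truth)@rng_seed, "utr"))

  g <- truthGenes(truth)
  out <- character(nrow(g))
  names(out) <- g$gene
  for (i in seq_len(nrow(g))) {
    cls <- g$site_class[i]
    repeat {
      seq <- randomDNA(utr_length)
      if (cls == "none") {
        if (nrow(scanSeedSites(seq, mir)) == 0L) break
      } else {
        site <- pats[[cls]]
        k <- nchar(site)
        # keep one flanking position on each side so class-defining
        # context (trailing A / preceding m8 base) can be controlled
        pos <- sample(2:(utr_length - k), 1L)
        flank_ok <- function(s) {
          left <- substr(s, pos - 1L, pos - 1L)
          right <- substr(s, pos + k, pos + k)
          if (cls == "7mer-m8" && right == "A") return(FALSE)
          if (cls == "7mer-1A" &&
              left == substr(pats[["7mer-m8"]], 1L, 1L)) return(FALSE)
          TRUE
        }
        substr(seq, pos, pos + k - 1L) <- site
        if (!flank_ok(seq)) next
        found <- scanSeedSites(seq, mir)
        if (nrow(found) &&
            SITE_CLASSES[min(match(found$site_class, SITE_CLASSES))] == cls)
          break
      }
    }
    out[i] <- seq
  }
  out
}

plantedLog2Effect <- function(g, config, arm) {
  # signed log2 treatment/control effect per gene for one modulation arm,
  # in the cell types where the gene is expressed
  a <- config@anti_mir_attenuation
  eff <- rep(0, nrow(g))
  l2f <- log2(g$true_effect_fold)
  can <- g$response_mode == "canonical"
  non <- g$response_mode == "noncanonical"
  if (arm == "miR") {
    eff[can] <- -l2f[can]
    eff[non] <- +l2f[non]
    sd_dir <- ifelse(g$spurious_miR_dir == "up", 1, -1)
    spur <- !is.na(g$spurious_miR_dir)
    eff[spur] <- sd_dir[spur] * log2(g$spurious_miR_fold[spur])
  } else if (arm == "anti_miR") {
    eff[can] <- +a * l2f[can]
    eff[non] <- -a * l2f[non]
    sd_dir <- ifelse(g$spurious_anti_dir == "up", 1, -1)
    spur <- !is.na(g$spurious_anti_dir)
    eff[spur] <- sd_dir[spur] * log2(g$spurious_anti_fold[spur])
  } else stop("unknown arm: ", arm)
  eff
}

#' Generate expression experiments per cell type
#'
#' Log-normal intensity model: expressed genes get a base intensity well
#' above `background_expression_level`; below-background genes are centred
#' at 0.3x the threshold.  Effects are multiplicative on the linear scale:
#' canonical responders have expected treatment/control ratio
#' `1/true_effect_fold` under miR over-expression and
#' `true_effect_fold^anti_mir_attenuation` under anti-miR inhibition;
#' non-canonical responders are reversed; TF-regulon genes respond in
#' `tf_effect_orientation`; spurious background effects apply per arm.
#' Replicate noise is Normal(0, `noise_sd_log2`) on log2 intensities.
#'
#' @param truth a [GroundTruth-class].
#' @param config the generating [SimulationConfig-class] (defaults to the
#'   one stored in `truth`).
#' @return Named list of [MirExperiment-class], one per cell type.
#' @export
generateExpression <- function(truth, config = truthConfig(truth)) {
  stopifnot(is(truth, "GroundTruth"))
  validObject(config)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(stageSeed(config@rng_seed, "expression"))

  g <- truthGenes(truth)
  n <- nrow(g)
  cells <- paste0("cell", seq_len(config@n_cell_types))
  reps <- config@replicates_per_condition
  bkg <- config@background_expression_level
  # base abundances 4x-256x above the background threshold
  base_l2 <- log2(bkg) + runif(n, 2, 8)
  eff <- list(miR = plantedLog2Effect(g, config, "miR"),
              anti_miR = plantedLog2Effect(g, config, "anti_miR"))

  out <- list()
  for (cell in cells) {
    expr_flag <- g[[paste0("expressed_", cell)]]
    cols <- expand.grid(replicate = seq_len(reps), condition = CONDITIONS,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    mat <- matrix(0, n, nrow(cols),
                  dimnames = list(g$gene,
                                  paste(cell, cols$condition, cols$replicate,
                                        sep = ".")))
    for (j in seq_len(nrow(cols))) {
      cond <- cols$condition[j]
      mu <- ifelse(expr_flag, base_l2, log2(0.3 * bkg))
      if (cond != "control")
        mu <- mu + ifelse(expr_flag, eff[[cond]], 0)
      mat[, j] <- 2^(mu + rnorm(n, 0, config@noise_sd_log2))
    }
    out[[cell]] <- mirExperiment(mat, cell_type = cell,
                                 condition = cols$condition,
                                 replicate = cols$replicate,
                                 background_threshold = bkg)
  }
  out
}

#' Per-gene probabilities of a fold-change call in each arm
#'
#' The analytic machinery behind [expectedConfusion()]: for each gene and
#' modulation arm, the probability that the fold-change-only modulation
#' call (threshold `fc_threshold` on the ratio of replicate means) lands
#' `up`, `down` or `unchanged`.  The log2 fold estimate over
#' `r` replicates per group is Normal(planted effect,
#' `noise_sd_log2^2 * 2/r`) to delta-method accuracy.
#'
#' @param truth a [GroundTruth-class].
#' @param config the generating [SimulationConfig-class].
#' @param fc_threshold linear fold-change threshold (default 1.5).
#' @return list with matrices `p_up`, `p_down` (genes x arms miR/anti_miR).
#' @export
responseProbabilities <- function(truth, config = truthConfig(truth),
                                  fc_threshold = 1.5) {
  g <- truthGenes(truth)
  sd_fc <- config@noise_sd_log2 * sqrt(2 / config@replicates_per_condition)
  thr <- log2(fc_threshold)
  arms <- c("miR", "anti_miR")
  p_up <- p_down <- matrix(0, nrow(g), 2, dimnames = list(g$gene, arms))
  for (arm in arms) {
    mu <- plantedLog2Effect(g, config, arm)
    if (sd_fc == 0) {
      p_up[, arm] <- as.numeric(mu >= thr)
      p_down[, arm] <- as.numeric(mu <= -thr)
    } else {
      p_up[, arm] <- pnorm((mu - thr) / sd_fc)
      p_down[, arm] <- pnorm((-mu - thr) / sd_fc)
    }
  }
  list(p_up = p_up, p_down = p_down)
}

resolveParameterFlag <- function(g, parameter) {
  switch(parameter,
    all = g$is_predicted_target,
    conserved = g$is_predicted_target & !is.na(g$conserved) & g$conserved,
    nonconserved = g$is_predicted_target & !is.na(g$conserved) & !g$conserved,
    "8mer" = g$site_class == "8mer",
    "7mer-m8" = g$site_class == "7mer-m8",
    "7mer-1A" = g$site_class == "7mer-1A",
    stop("unknown prediction parameter: ", parameter))
}

#' Expected confusion statistics implied by the planted truth
#'
#' Analytic oracle for the confusion-matrix evaluation: combines the
#' planted per-gene effects, the anti-miR attenuation, the spurious
#' background rates and the replicate noise into exact per-gene
#' probabilities of being called responsive in the requested orientation,
#' and returns the implied expected TP/TN/FP/FN together with per-cell SEs
#' for Monte-Carlo comparison.  Assumes fold-change-only calling.
#'
#' @param truth a [GroundTruth-class].
#' @param config the generating [SimulationConfig-class].
#' @param stratum list with elements `modulation` (miR, anti_miR or
#'   bidirectional), `cell_type` (e.g. "cell1") and `parameter` (all,
#'   conserved, nonconserved, 8mer, 7mer-m8, 7mer-1A).
#' @param orientation "canonical" or "noncanonical".
#' @param fc_threshold linear fold-change threshold.
#' @return A [ConfusionSummary-class] of expected (fractional) counts,
#'   with attributes `p_resp` (per-gene responsive probability over the
#'   stratum universe) and `predicted` (per-gene predicted flag).
#' @export
expectedConfusion <- function(truth, config = truthConfig(truth),
                              stratum = list(modulation = "miR",
                                             cell_type = "cell1",
                                             parameter = "all"),
                              orientation = c("canonical", "noncanonical"),
                              fc_threshold = 1.5) {
  orientation <- match.arg(orientation)
  stopifnot(is(truth, "GroundTruth"))
  g <- truthGenes(truth)
  modulation <- match.arg(stratum$modulation, MODULATIONS)
  expr_col <- paste0("expressed_", stratum$cell_type)
  if (!expr_col %in% names(g))
    stop("unknown cell type in stratum: ", stratum$cell_type)
  keep <- g[[expr_col]]
  if (!any(keep)) stop("empty stratum: no expressed genes in ",
                       stratum$cell_type)
  g <- g[keep, , drop = FALSE]
  pr <- responseProbabilities(truth, config, fc_threshold)
  p_up <- pr$p_up[keep, , drop = FALSE]
  p_down <- pr$p_down[keep, , drop = FALSE]

  # probability of responding in the orientation-expected direction
  pArm <- function(arm) {
    if (orientation == "canonical") {
      if (arm == "miR") p_down[, "miR"] else p_up[, "anti_miR"]
    } else {
      if (arm == "miR") p_up[, "miR"] else p_down[, "anti_miR"]
    }
  }
  p_resp <- switch(modulation,
    miR = pArm("miR"),
    anti_miR = pArm("anti_miR"),
    bidirectional = pArm("miR") * pArm("anti_miR"))  # independent noise

  predicted <- resolveParameterFlag(g, stratum$parameter)
  tp <- sum(p_resp[predicted]); fp <- sum(1 - p_resp[predicted])
  fn <- sum(p_resp[!predicted]); tn <- sum(1 - p_resp[!predicted])
  out <- confusionSummary(tp, tn, fp, fn,
    stratum = c(modulation = modulation, cell_type = stratum$cell_type,
                parameter = stratum$parameter, orientation = orientation))
  attr(out, "p_resp") <- p_resp
  attr(out, "predicted") <- predicted
  out
}

#' Generate dual-luciferase reporter measurements
#'
#' Emulates the validation assay: for each construct, 4 experiments x 3
#' replicate wells of (firefly, renilla) luminescence under a treatment
#' miRNA oligo and a mutant control oligo.  The planted percent change
#' acts multiplicatively on the treatment firefly/renilla ratio;
#' experiment-level transfection efficiency varies and cancels in the
#' within-experiment normalization.
#'
#' @param planted_percent named numeric vector of planted percent changes
#'   (e.g. `c(KCNMB2 = -60)`); names become construct ids.
#' @param noise_sd SD of log-normal well noise on ratios (0 = noiseless).
#' @param n_experiments,n_replicates assay layout (defaults 4 x 3).
#' @param seed integer seed.
#' @return data.frame with columns `construct`, `oligo`
#'   (treatment/control), `experiment`, `replicate`, `firefly`, `renilla`.
#' @export
generateReporterData <- function(planted_percent, noise_sd = 0.05,
                                 n_experiments = 4L, n_replicates = 3L,
                                 seed = 1L) {
  if (!length(planted_percent)) stop("at least one construct is required")
  if (is.null(names(planted_percent)))
    names(planted_percent) <- paste0("construct", seq_along(planted_percent))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(stageSeed(seed, "reporter"))
  rows <- list()
  for (con in names(planted_percent)) {
    mult <- 1 + planted_percent[[con]] / 100
    for (e in seq_len(n_experiments)) {
      eff_e <- exp(rnorm(1, 0, 0.2))       # transfection efficiency
      base_ratio <- 2 * exp(rnorm(1, 0, 0.1))
      for (oligo in c("treatment", "control")) {
        m <- if (oligo == "treatment") mult else 1
        for (r in seq_len(n_replicates)) {
          ren <- 1e5 * eff_e * exp(rnorm(1, 0, noise_sd))
          fir <- ren * base_ratio * m * exp(rnorm(1, 0, noise_sd))
          rows[[length(rows) + 1L]] <- data.frame(
            construct = con, oligo = oligo, experiment = e, replicate = r,
            firefly = fir, renilla = ren, stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}
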