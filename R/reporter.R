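#' @importFrom stats complete.cases
NULL

#' Normalized response of one reporter construct
#'
#' For one construct of a dual-luciferase assay: each well's response is
#' firefly / renilla; within each experiment the mean treatment ratio is
#' divided by the mean control ratio (so transfection efficiency cancels);
#' the percent change is (grand mean of the per-experiment normalized
#' ratios - 1) x 100.  A one-tailed paired t-test compares the
#' experiment-level normalized ratios against 1, with the tail in the
#' observed direction; `validated` requires p < 0.05.  Zero variance
#' across experiments yields an `NA` p-value with a note.
#'
#' @param measurements data.frame with columns `construct`, `oligo`
#'   (treatment/control), `experiment`, `replicate`, `firefly`,
#'   `renilla`, covering complete blocks for both oligos of a single
#'   construct.
#' @return list with `construct`, `percent_change`, `p_value`,
#'   `validated` and `note`.
#' @export
reporterResponse <- function(measurements) {
  m <- measurements
  need <- c("construct", "oligo", "experiment", "replicate",
            "firefly", "renilla")
  miss <- setdiff(need, names(m))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (length(unique(m$construct)) != 1L)
    stop("measurements must cover a single construct")
  if (any(m$renilla <= 0)) stop("non-positive renilla luminescence")
  if (!all(c("treatment", "control") %in% m$oligo))
    stop("both treatment and control oligo blocks are required")
  exps <- sort(unique(m$experiment))
  norm <- vapply(exps, function(e) {
    trt <- m$oligo == "treatment" & m$experiment == e
    ctl <- m$oligo == "control" & m$experiment == e
    if (!any(trt) || !any(ctl))
      stop("incomplete block: experiment ", e, " lacks an oligo arm")
    mean(m$firefly[trt] / m$renilla[trt]) /
      mean(m$firefly[ctl] / m$renilla[ctl])
  }, numeric(1))
  pc <- (mean(norm) - 1) * 100
  note <- NA_character_
  if (length(norm) < 2 ||
      stats::sd(norm) <= 1e-10 * max(1, abs(mean(norm)))) {
    p <- NA_real_
    note <- "zero variance across experiments; p-value unavailable"
  } else {
    tail <- if (mean(norm) < 1) "less" else "greater"
    p <- stats::t.test(norm, mu = 1, alternative = tail)$p.value
  }
  list(construct = m$construct[1], percent_change = pc, p_value = p,
       validated = isTRUE(p < 0.05), note = note)
}

#' Apply the reporter validation filter to a results table
#'
#' Counts the records passing validation — p < 0.05 with a negative
#' percent change (repression) — and the distinct genes among them.
#' Labels may carry `_1`, `_2`, ... suffixes denoting distinct
#' recognition elements of one gene; suffixes are stripped before
#' counting genes.
#'
#' @param results data.frame with columns `gene` (label, optionally
#'   suffixed), `percent_change` (signed percent) and `p_value` (numeric,
#'   or strings such as "<0.0001" which are read as their bound).
#' @return list with `n_validated_records` and `n_distinct_genes`.
#' @export
summarizeValidation <- function(results) {
  need <- c("gene", "percent_change", "p_value")
  miss <- setdiff(need, names(results))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!nrow(results))
    return(list(n_validated_records = 0L, n_distinct_genes = 0L))
  lab <- as.character(results$gene)
  if (any(!grepl("^[A-Za-z0-9.-]+(_[0-9]+)?$", lab)))
    stop("malformed gene label(s): ",
         paste(utils::head(lab[!grepl("^[A-Za-z0-9.-]+(_[0-9]+)?$", lab)], 3),
               collapse = ", "))
  p <- parsePValue(results$p_value)
  pc <- as.numeric(results$percent_change)
  pass <- !is.na(p) & p < 0.05 & pc < 0
  genes <- sub("_[0-9]+$", "", lab[pass])
  list(n_validated_records = sum(pass),
       n_distinct_genes = length(unique(genes)))
}

# "<0.0001" -> 0.0001 (an upper bound); plain numbers pass through
parsePValue <- function(x) {
  if (is.numeric(x)) return(x)
  x <- trimws(as.character(x))
  bounded <- grepl("^<", x)
  x[bounded] <- sub("^<\\s*", "", x[bounded])
  as.numeric(x)
}
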