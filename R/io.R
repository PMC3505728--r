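#' @importFrom utils read.delim write.table head
#' @importFrom Biostrings readDNAStringSet readBStringSet writeXStringSet DNAStringSet
NULL

requireColumns <- function(df, need, what) {
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(what, " is missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' Read 3'-UTR sequences from FASTA
#'
#' Accepts wrapped or unwrapped FASTA in DNA or RNA spelling ('U' is
#' converted to 'T').
#'
#' @param path FASTA file.
#' @return Named character vector of DNA sequences.
#' @export
readUTRFasta <- function(path) {
  x <- readDNAStringSet(path)
  out <- toupper(chartr("U", "T", as.character(x)))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences as unwrapped FASTA
#'
#' @param sequences named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(sequences, path) {
  writeXStringSet(DNAStringSet(sequences), path, width = 20000L)
  invisible(path)
}

#' Read mature miRNA sequences from FASTA
#'
#' @param path FASTA file in RNA or DNA spelling.
#' @return List of [MatureMiRNA-class] objects, one per record.
#' @export
readMiRNAFasta <- function(path) {
  x <- readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  lapply(seq_along(x),
         function(i) matureMiRNA(ids[i], as.character(x[[i]])))
}

#' Read an expression matrix TSV
#'
#' First column gene id; remaining header columns sample ids.
#'
#' @param path TSV file.
#' @return Numeric matrix with gene row names.
#' @export
readExpressionTSV <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expression TSV needs a gene column plus samples")
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- df[[1]]
  mat
}

#' Read sample metadata TSV
#'
#' Columns: `sample`, `cell_type`, `condition` (control / miR /
#' anti_miR), `replicate`.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
readSampleMetadata <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  requireColumns(df, c("sample", "cell_type", "condition", "replicate"),
                 "sample metadata")
  bad <- setdiff(unique(df$condition), CONDITIONS)
  if (length(bad))
    stop("unknown condition value(s): ", paste(bad, collapse = ", "))
  df
}

#' Assemble MirExperiments from matrix + metadata files
#'
#' @param matrix_path,metadata_path TSV files as written by
#'   [writeExperiment()].
#' @param background_threshold below-background intensity threshold.
#' @return Named list of [MirExperiment-class], one per cell type.
#' @export
readExperiment <- function(matrix_path, metadata_path,
                           background_threshold = 0) {
  mat <- readExpressionTSV(matrix_path)
  meta <- readSampleMetadata(metadata_path)
  miss <- setdiff(meta$sample, colnames(mat))
  if (length(miss))
    stop("metadata sample(s) absent from matrix: ",
         paste(head(miss, 5), collapse = ", "))
  out <- list()
  for (cell in unique(meta$cell_type)) {
    mm <- meta[meta$cell_type == cell, , drop = FALSE]
    out[[cell]] <- mirExperiment(mat[, mm$sample, drop = FALSE],
                                 cell_type = mm$cell_type,
                                 condition = mm$condition,
                                 replicate = mm$replicate,
                                 background_threshold = background_threshold)
  }
  out
}

#' Write MirExperiments as matrix + metadata TSVs
#'
#' @param experiments list of [MirExperiment-class] (or a single one).
#' @param matrix_path,metadata_path output TSV paths.
#' @return Invisibly, the two paths.
#' @export
writeExperiment <- function(experiments, matrix_path, metadata_path) {
  if (is(experiments, "MirExperiment")) experiments <- list(experiments)
  mats <- lapply(experiments, assay, "intensity")
  genes <- rownames(mats[[1]])
  for (m in mats) stopifnot(identical(rownames(m), genes))
  mat <- do.call(cbind, mats)
  df <- data.frame(gene = genes, mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  writeTSV(df, matrix_path)
  meta <- do.call(rbind, lapply(experiments, function(e)
    data.frame(sample = colnames(e), cell_type = colData(e)$cell_type,
               condition = colData(e)$condition,
               replicate = colData(e)$replicate,
               stringsAsFactors = FALSE)))
  writeTSV(meta, metadata_path)
  invisible(c(matrix_path, metadata_path))
}

writeTSV <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read a target-prediction table TSV
#'
#' Columns: `gene`, `mirna`, `site_type`, `conserved` (0/1 or NA),
#' `pct` (numeric or NA).
#'
#' @param path TSV file.
#' @return data.frame with logical `conserved` and numeric `pct`.
#' @export
readPredictionTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  requireColumns(df, c("gene", "mirna", "site_type", "conserved", "pct"),
                 "prediction table")
  bad <- setdiff(stats::na.omit(unique(df$site_type)), SITE_CLASSES)
  if (length(bad))
    stop("unknown site_type value(s): ", paste(bad, collapse = ", "))
  df$conserved <- as.logical(as.integer(df$conserved))
  df$pct <- as.numeric(df$pct)
  df
}

#' Write a target-prediction table TSV
#'
#' `conserved` is emitted as 0/1 and missing values as "NA".
#'
#' @param predictions data.frame (`gene`, `mirna`, `site_type`,
#'   `conserved`, `pct`).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writePredictionTable <- function(predictions, path) {
  df <- predictions
  df$conserved <- as.integer(df$conserved)
  writeTSV(df, path)
}

#' Read a GMT annotation file
#'
#' Standard tab-separated GMT: term, description, then member genes.
#'
#' @param path GMT file.
#' @return Named list of character vectors (term -> genes); descriptions
#'   in the `"description"` attribute.
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 3L
  if (any(bad))
    stop("malformed GMT line(s): ", paste(which(bad), collapse = ", "))
  out <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(out) <- vapply(parts, `[[`, character(1), 1L)
  attr(out, "description") <- vapply(parts, `[[`, character(1), 2L)
  out
}

#' Write a GMT annotation file
#'
#' @param annotation named list of character vectors.
#' @param path output file.
#' @param description per-term description (recycled).
#' @return `path`, invisibly.
#' @export
writeGMT <- function(annotation, path, description = "na") {
  description <- rep(description, length.out = length(annotation))
  lines <- vapply(seq_along(annotation), function(i)
    paste(c(names(annotation)[i], description[i], annotation[[i]]),
          collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a reporter measurement or results TSV
#'
#' @param path TSV with either measurement columns (`construct`, `oligo`,
#'   `experiment`, `replicate`, `firefly`, `renilla`) or validation-table
#'   columns (`gene`, `percent_change`, `p_value`).
#' @return data.frame.
#' @export
readReporterTable <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Bundled reporter validation table
#'
#' The packaged table of 14 dual-luciferase reporter constructs covering
#' 11 genes whose candidate miR-181b recognition elements were assayed
#' against a mutant-oligo control (signed percent fold change, one-tailed
#' p-value and the cloned MRE sequence per construct).
#'
#' @return data.frame with columns `gene`, `percent_change`, `p_value`,
#'   `mre_sequence`.
#' @examples
#' summarizeValidation(reporterValidationTable())
#' @export
reporterValidationTable <- function() {
  path <- system.file("extdata", "mir181b_reporter_validation.tsv",
                      package = "mirfate", mustWork = TRUE)
  readReporterTable(path)
}

#' Bundled mature miRNA sequences
#'
#' Public mature sequences of hsa-miR-181b-5p, hsa-miR-107 and
#' hsa-miR-20a-5p (miRBase spellings), used throughout the examples and
#' tests.
#'
#' @return List of [MatureMiRNA-class] objects.
#' @export
bundledMiRNAs <- function() {
  path <- system.file("extdata", "mature_mirnas.fa",
                      package = "mirfate", mustWork = TRUE)
  readMiRNAFasta(path)
}
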