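#' @importFrom Biostrings DNAString matchPattern reverseComplement
NULL

# DNA reverse complement of an RNA subsequence, as a character string.
rnaRevCompDNA <- function(rna) {
  dna <- chartr("U", "T", rna)
  as.character(reverseComplement(DNAString(dna)))
}

cleanUTR <- function(utr) {
  utr <- toupper(as.character(utr))
  utr <- chartr("U", "T", utr)
  bad <- setdiff(unique(strsplit(utr, "")[[1]]), DNA_ALPHABET)
  if (length(bad))
    stop("invalid UTR alphabet: ", paste(bad, collapse = ", "),
         " (allowed: A,C,G,T,N; U is converted to T)")
  utr
}

#' Seed-match strings for the three canonical site classes
#'
#' Computes, for a mature miRNA, the DNA strings that a 3'-UTR must
#' contain (on the sense strand) to constitute each seed-site class:
#' \describe{
#'   \item{8mer}{reverse complement of miRNA positions 2-8 followed by an
#'     'A' (8 nt). The 'A' opposite miRNA position 1 is required literally,
#'     irrespective of the miRNA's own position-1 base.}
#'   \item{7mer-m8}{reverse complement of positions 2-8 (7 nt).}
#'   \item{7mer-1A}{reverse complement of positions 2-7 followed by an
#'     'A' (7 nt).}
#' }
#'
#' @param mir a [MatureMiRNA-class] (or id-less RNA string).
#' @return Named character vector with elements `8mer`, `7mer-m8`,
#'   `7mer-1A`.
#' @examples
#' seedSiteStrings(matureMiRNA("hsa-miR-181b-5p", "AACAUUCAUUGCUGUCGGUGGGU"))
#' @export
seedSiteStrings <- function(mir) {
  if (is.character(mir)) mir <- matureMiRNA("miRNA", mir)
  stopifnot(is(mir, "MatureMiRNA"))
  s <- mirSequence(mir)
  if (nchar(s) < 8L)
    stop("mature miRNA sequence must be at least 8 nt to derive seed sites")
  rc28 <- rnaRevCompDNA(substr(s, 2L, 8L))
  rc27 <- rnaRevCompDNA(substr(s, 2L, 7L))
  c("8mer" = paste0(rc28, "A"),
    "7mer-m8" = rc28,
    "7mer-1A" = paste0(rc27, "A"))
}

allMatchStarts <- function(pattern, subject) {
  # all (overlapping) exact occurrences; N in the subject never matches
  m <- matchPattern(pattern, subject, fixed = TRUE)
  BiocGenerics::start(m)
}

#' Scan a 3'-UTR for miRNA seed-match sites
#'
#' Reports every maximal seed match on the sense strand exactly once, with
#' class precedence 8mer > 7mer-m8 > 7mer-1A at overlapping coordinates:
#' an 8mer occurrence is not additionally reported as either of its two
#' 7mer sub-patterns.  Coordinates are 0-based half-open on the UTR.
#' Scanning is case-insensitive; 'U' in the UTR is treated as 'T'; 'N'
#' never matches.
#'
#' @param utr_sequence UTR sequence (character, sense strand).
#' @param mir a [MatureMiRNA-class].
#' @param gene optional gene id recorded in the output.
#' @return data.frame with columns `gene`, `mirna`, `site_class`, `start`,
#'   `end` (0-based half-open) and `site_sequence`, sorted by `start`.
#'   Zero rows when nothing matches (an empty UTR is not an error).
#' @examples
#' mir181b <- matureMiRNA("hsa-miR-181b-5p", "AACAUUCAUUGCUGUCGGUGGGU")
#' scanSeedSites("TTCACGACAGAGTTGAATGTAT", mir181b)
#' @export
scanSeedSites <- function(utr_sequence, mir, gene = NA_character_) {
  stopifnot(is(mir, "MatureMiRNA"))
  utr <- cleanUTR(utr_sequence)
  empty <- data.frame(gene = character(), mirna = character(),
                      site_class = character(), start = integer(),
                      end = integer(), site_sequence = character(),
                      stringsAsFactors = FALSE)
  if (!nzchar(utr)) return(empty)
  pats <- seedSiteStrings(mir)
  subj <- DNAString(utr)
  L <- nchar(utr)
  chars <- strsplit(utr, "")[[1]]
  m8anchor <- substr(pats[["7mer-m8"]], 1L, 1L)  # base opposite miR pos 8

  s8 <- allMatchStarts(pats[["8mer"]], subj)
  s7m8 <- allMatchStarts(pats[["7mer-m8"]], subj)
  # a 7mer-m8 occurrence followed by 'A' is that same locus's 8mer
  s7m8 <- s7m8[!(s7m8 + 7L <= L & chars[pmin(s7m8 + 7L, L)] == "A")]
  s71a <- allMatchStarts(pats[["7mer-1A"]], subj)
  # a 7mer-1A occurrence preceded by the m8-pairing base is that 8mer
  s71a <- s71a[!(s71a > 1L & chars[pmax(s71a - 1L, 1L)] == m8anchor)]

  rows <- rbind(
    if (length(s8)) data.frame(site_class = "8mer", start1 = s8, len = 8L),
    if (length(s7m8)) data.frame(site_class = "7mer-m8", start1 = s7m8,
                                 len = 7L),
    if (length(s71a)) data.frame(site_class = "7mer-1A", start1 = s71a,
                                 len = 7L))
  if (is.null(rows) || !nrow(rows)) return(empty)
  rows <- rows[order(rows$start1,
                     match(rows$site_class, SITE_CLASSES)), , drop = FALSE]
  data.frame(gene = gene, mirna = mirID(mir),
             site_class = rows$site_class,
             start = rows$start1 - 1L,
             end = rows$start1 - 1L + rows$len,
             site_sequence = substring(utr, rows$start1,
                                       rows$start1 + rows$len - 1L),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Scan a UTR for AU-rich-element pentamers
#'
#' Counts non-overlapping, left-greedy occurrences of the minimal ARE
#' motif ATTTA.  A UTR is ARE-positive when it carries at least one
#' pentamer.
#'
#' @param utr_sequence UTR sequence (character).
#' @param gene optional gene id.
#' @return list with `gene`, `pentamer_count`, `positions` (0-based
#'   starts) and `are_positive`.
#' @examples
#' scanARE("GGATTTAGG")$positions   # 2
#' scanARE("ATTTATTTA")$pentamer_count  # 1 (left-greedy, non-overlapping)
#' @export
scanARE <- function(utr_sequence, gene = NA_character_) {
  utr <- cleanUTR(utr_sequence)
  pos <- integer()
  if (nchar(utr) >= 5L) {
    i <- 1L
    while (i <= nchar(utr) - 4L) {
      if (substr(utr, i, i + 4L) == "ATTTA") {
        pos <- c(pos, i - 1L)
        i <- i + 5L
      } else i <- i + 1L
    }
  }
  list(gene = gene, pentamer_count = length(pos), positions = pos,
       are_positive = length(pos) >= 1L)
}

#' Build a prediction table from scanner output
#'
#' One record per (gene, miRNA) pair with the best site class present
#' (8mer > 7mer-m8 > 7mer-1A); genes with no site are absent.  Scanner
#' output carries no conservation information, so `conserved` and `pct`
#' are `NA`.
#'
#' @param utrs named character vector (or `DNAStringSet`) of UTR
#'   sequences; names are gene ids and must be unique.
#' @param mirs a [MatureMiRNA-class] or list of them.
#' @return data.frame with columns `gene`, `mirna`, `site_type`,
#'   `conserved`, `pct`.
#' @export
scanToPredictions <- function(utrs, mirs) {
  if (is(mirs, "MatureMiRNA")) mirs <- list(mirs)
  nm <- names(utrs)
  utrs <- as.character(utrs)
  names(utrs) <- nm
  if (is.null(names(utrs)) || anyDuplicated(names(utrs)))
    stop("UTRs must carry unique gene ids as names")
  out <- list()
  for (mir in mirs) {
    for (g in names(utrs)) {
      sites <- scanSeedSites(utrs[[g]], mir, gene = g)
      if (nrow(sites)) {
        best <- SITE_CLASSES[min(match(sites$site_class, SITE_CLASSES))]
        out[[length(out) + 1L]] <- data.frame(
          gene = g, mirna = mirID(mir), site_type = best,
          conserved = NA, pct = NA_real_, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(gene = character(), mirna = character(),
                      site_type = character(), conserved = logical(),
                      pct = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
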