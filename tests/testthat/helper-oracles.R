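# Independent oracles, kept deliberately naive.

MIR181B <- matureMiRNA("hsa-miR-181b-5p", "AACAUUCAUUGCUGUCGGUGGGU")
MIR107 <- matureMiRNA("hsa-miR-107", "AGCAGCAUUGUACAGGGCUAUCA")

# Brute-force seed scanner: compares every substring against the three
# site strings and applies the stated precedence (an 8mer occurrence is
# not re-reported as its 7mer sub-patterns).  Independent of the package
# path: plain substring extraction at every position.
oracleScan <- function(utr, mir) {
  utr <- chartr("uU", "tT", toupper(utr))
  pats <- seedSiteStrings(mir)
  chars <- strsplit(utr, "")[[1]]
  L <- nchar(utr)
  if (L < 7L)
    return(data.frame(site_class = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  starts <- seq_len(L)
  sub8 <- substring(utr, starts, starts + 7L)
  sub7 <- substring(utr, starts, starts + 6L)
  m8first <- substr(pats[["7mer-m8"]], 1L, 1L)
  next_after7 <- c(chars[-seq_len(7L)], rep("", 7L))   # base at i+7
  prev_before <- c("", chars[-L])                      # base at i-1
  is8 <- sub8 == pats[["8mer"]] & starts + 7L <= L
  is7m8 <- sub7 == pats[["7mer-m8"]] & starts + 6L <= L &
    next_after7 != "A"
  is71a <- sub7 == pats[["7mer-1A"]] & starts + 6L <= L &
    prev_before != m8first
  mk <- function(cls, w, len)
    data.frame(site_class = rep(cls, length(w)), start = w - 1L,
               len = rep(len, length(w)), stringsAsFactors = FALSE)
  df <- rbind(mk("8mer", which(is8), 8L),
              mk("7mer-m8", which(is7m8), 7L),
              mk("7mer-1A", which(is71a), 7L))
  df$end <- df$start + df$len
  df$len <- NULL
  df <- df[order(df$start, match(df$site_class, c("8mer", "7mer-m8",
                                                  "7mer-1A"))), ]
  rownames(df) <- NULL
  df[, c("site_class", "start", "end")]
}

randomSeq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Exhaustive hypergeometric upper tail via choose(), no phyper.
oracleHyperTail <- function(k, K, N, n) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# Monte-Carlo 3-SE comparison helper for rates implied by per-gene
# Bernoulli probabilities.
rateWithin3SE <- function(observed, expected, p_terms) {
  se <- sqrt(sum(p_terms * (1 - p_terms))) / length(p_terms)
  abs(observed - expected) <= 3 * se + 1e-9
}
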