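test_that("gene classification follows the TP/TN/FP/FN definitions", {
  expect_identical(classifyGene(TRUE, "down", "miR", "canonical"), "TP")
  expect_identical(classifyGene(TRUE, "unchanged", "miR", "canonical"), "FP")
  expect_identical(classifyGene(TRUE, "up", "miR", "canonical"), "FP")
  expect_identical(classifyGene(FALSE, "up", "anti_miR", "canonical"), "FN")
  expect_identical(classifyGene(FALSE, "down", "anti_miR", "canonical"), "TN")
  # non-canonical orientation reverses the expected direction
  expect_identical(classifyGene(TRUE, "up", "miR", "noncanonical"), "TP")
  expect_identical(classifyGene(TRUE, "down", "anti_miR", "noncanonical"),
                   "TP")
  expect_error(classifyGene(TRUE, "sideways", "miR", "canonical"))
})

toyCalls <- function() {
  # 10-gene universe; predictions: A,B,C (A conserved 8mer; B nonconserved
  # 7mer-m8; C nonconserved 7mer-1A)
  genes <- LETTERS[1:10]
  dir_mir <- c(A = "down", B = "down", C = "unchanged", D = "down",
               E = "unchanged", F = "unchanged", G = "up", H = "unchanged",
               I = "unchanged", J = "unchanged")
  dir_anti <- c(A = "up", B = "unchanged", C = "unchanged", D = "up",
                E = "unchanged", F = "unchanged", G = "down",
                H = "unchanged", I = "unchanged", J = "unchanged")
  rbind(
    data.frame(gene = genes, cell_type = "c1", modulation = "miR",
               direction = unname(dir_mir[genes]), fold_change = 1,
               p_value = NA_real_, stringsAsFactors = FALSE),
    data.frame(gene = genes, cell_type = "c1", modulation = "anti_miR",
               direction = unname(dir_anti[genes]), fold_change = 1,
               p_value = NA_real_, stringsAsFactors = FALSE))
}

toyPredictions <- function() {
  data.frame(gene = c("A", "B", "C"), mirna = "m",
             site_type = c("8mer", "7mer-m8", "7mer-1A"),
             conserved = c(TRUE, FALSE, FALSE), pct = c(0.8, 0.05, 0.2),
             stringsAsFactors = FALSE)
}

test_that("stratum evaluation tallies every retained gene once", {
  # miR arm, canonical: responsive = {A,B,D}; predicted = {A,B,C}
  cs <- evaluateStratum(toyCalls(), toyPredictions(), "miR", "c1", "all",
                        "canonical")
  expect_equal(cs@tp, 2); expect_equal(cs@fp, 1)
  expect_equal(cs@fn, 1); expect_equal(cs@tn, 6)
  expect_equal(cs@tp + cs@tn + cs@fp + cs@fn, 10)
  # quoted-formula arithmetic on a hand-built table
  expect_equal(accuracy(cs), 0.8)
  expect_equal(sensitivity(cs), 2 / 3)
  expect_equal(fnr(cs), 1 / 3)
  expect_equal(specificity(cs), 6 / 7)
  expect_equal(fpr(cs), 1 / 7)
  # bidirectional: responsive = {A, D}
  cb <- evaluateStratum(toyCalls(), toyPredictions(), "bidirectional",
                        "c1", "all", "canonical")
  expect_equal(cb@tp, 1); expect_equal(cb@fp, 2)
  expect_equal(cb@fn, 1); expect_equal(cb@tn, 6)
  # noncanonical bidirectional: responsive = {G}
  cn <- evaluateStratum(toyCalls(), toyPredictions(), "bidirectional",
                        "c1", "all", "noncanonical")
  expect_equal(cn@fn, 1); expect_equal(cn@tp, 0)
})

test_that("parameter strata use predicted-with-that-parameter flags", {
  cs8 <- evaluateStratum(toyCalls(), toyPredictions(), "miR", "c1",
                         "8mer", "canonical")
  expect_equal(cs8@tp, 1)           # A only
  expect_equal(cs8@fp, 0)
  expect_equal(cs8@fn, 2)           # B and D now negative-class responders
  cons <- evaluateStratum(toyCalls(), toyPredictions(), "miR", "c1",
                          "conserved", "canonical")
  noncons <- evaluateStratum(toyCalls(), toyPredictions(), "miR", "c1",
                             "nonconserved", "canonical")
  expect_equal(cons@tp, 1); expect_equal(noncons@tp, 1)
  # restricting the prediction set can only lower FPR and raise FNR
  all_s <- evaluateStratum(toyCalls(), toyPredictions(), "miR", "c1",
                           "all", "canonical")
  expect_lte(fpr(cons), fpr(all_s))
  expect_gte(fnr(cons), fnr(all_s))
})

test_that("degenerate denominators give absent rates, not 0 or 1", {
  calls <- toyCalls()
  empty_pred <- toyPredictions()[0, ]
  cs <- evaluateStratum(calls, empty_pred, "miR", "c1", "all", "canonical")
  expect_true(is.na(sensitivity(cs)) || cs@tp + cs@fn > 0)
  # zero predicted targets: sensitivity defined by responders only;
  # specificity defined; precision-type identities still hold
  expect_equal(cs@tp, 0); expect_equal(cs@fp, 0)
  expect_false(is.na(specificity(cs)))
  no_resp <- calls; no_resp$direction <- "unchanged"
  cs2 <- evaluateStratum(no_resp, empty_pred, "miR", "c1", "all",
                         "canonical")
  expect_true(is.na(sensitivity(cs2)))
  expect_true(is.na(fnr(cs2)))
})

test_that("stratified grid has full cardinality and stable content", {
  calls <- toyCalls()
  grid <- stratifiedEvaluation(calls, toyPredictions())
  expect_identical(nrow(grid), 3L * 1L * 6L * 2L)
  # purity: identical on recomputation
  expect_identical(grid, stratifiedEvaluation(calls, toyPredictions()))
  # universe identity in every row
  expect_true(all(grid$tp + grid$tn + grid$fp + grid$fn == 10))
  m <- meanOverParameters(grid[grid$orientation == "canonical", ],
                          "accuracy", "modulation")
  expect_identical(nrow(m), 3L)
  expect_equal(m$mean_accuracy[m$modulation == "miR"],
               mean(grid$accuracy[grid$orientation == "canonical" &
                                    grid$modulation == "miR"]))
})

test_that("paired t-test matches the textbook formula and handles ties", {
  r <- pairedTTest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t, 0); expect_equal(r$p, 1)
  r2 <- pairedTTest(c(2, 3, 4, 5), c(1, 2, 3, 4))
  expect_true(is.na(r2$p))
  expect_match(r2$note, "zero variance")
  a <- c(1.1, 2.3, 2.9); b <- c(2.2, 3.1, 4.2)
  r3 <- pairedTTest(a, b)
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(3))
  expect_equal(r3$t, t_hand)
  expect_equal(r3$p, 2 * pt(-abs(t_hand), 2))
  expect_error(pairedTTest(1, 1), "2 pairs")
})

test_that("repeated-measures ANOVA matches aov and its identities", {
  # all-equal matrix: F = 0, p = 1
  r0 <- rmAnova(matrix(5, 3, 3))
  expect_equal(r0$F, 0); expect_equal(r0$p, 1)
  # 2 conditions reduce to the paired t-test: F = t^2
  m <- cbind(c(1.2, 2.4, 3.1), c(2.0, 3.5, 3.9))
  ra <- rmAnova(m)
  tt <- pairedTTest(m[, 2], m[, 1])
  expect_equal(ra$F, tt$t^2)
  expect_equal(ra$p, tt$p)
  # 4 subjects x 3 conditions against stats::aov as the oracle
  set.seed(12)
  m2 <- matrix(rnorm(12, 10, 2), 4, 3) + outer(rep(0, 4), c(0, 1, 2))
  df <- data.frame(y = as.vector(m2),
                   subj = factor(rep(1:4, 3)),
                   cond = factor(rep(1:3, each = 4)))
  fit <- summary(aov(y ~ cond + Error(subj/cond), data = df))
  ftab <- fit[["Error: subj:cond"]][[1]]
  r2 <- rmAnova(m2)
  expect_equal(r2$F, ftab["cond", "F value"], tolerance = 1e-10)
  expect_equal(r2$p, ftab["cond", "Pr(>F)"], tolerance = 1e-10)
  expect_error(rmAnova(matrix(c(1, NA, 2, 3), 2)), "complete")
})

test_that("orientation correlation is sign-blind R-squared", {
  expect_equal(orientationCorrelation(c(1, 2, 3), c(1, 2, 3))$r2, 1)
  expect_equal(orientationCorrelation(c(1, 2, 3), c(3, 2, 1))$r2, 1)
  near0 <- orientationCorrelation(c(1, 2, 1, 2), c(1, 1, 2, 2))
  expect_lt(near0$r2, 0.1)
  flat <- orientationCorrelation(c(1, 1, 1), c(1, 2, 3))
  expect_true(is.na(flat$r2))
  expect_match(flat$note, "zero variance")
  # agrees with cor()^2
  set.seed(3)
  a <- rnorm(10); b <- a + rnorm(10, 0, 0.5)
  expect_equal(orientationCorrelation(a, b)$r2, cor(a, b)^2)
})

test_that("PCT fraction below cutoff counts strictly", {
  expect_equal(pctFractionBelow(c(0.05, 0.2, 0.01)), 2 / 3)
  expect_equal(pctFractionBelow(c(0.5, 0.9)), 0)
  expect_equal(pctFractionBelow(c(0.1, 0.05)), 0.5)  # boundary excluded
  expect_error(pctFractionBelow(numeric(0)), "no PCT")
})

test_that("orientation duality conserves the non-predicted universe", {
  calls <- toyCalls()
  for (mod in c("miR", "anti_miR", "bidirectional")) {
    a <- evaluateStratum(calls, toyPredictions(), mod, "c1", "all",
                         "canonical")
    b <- evaluateStratum(calls, toyPredictions(), mod, "c1", "all",
                         "noncanonical")
    expect_equal(a@tp + a@fp, b@tp + b@fp)   # predicted universe
    expect_equal(a@tn + a@fn, b@tn + b@fn)   # non-predicted universe
  }
})
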