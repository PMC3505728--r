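toyExperiment <- function(mat, reps = 2L, cell = "HEK293") {
  conds <- rep(c("control", "miR", "anti_miR"), each = reps)
  mirExperiment(mat, cell_type = cell, condition = conds,
                replicate = rep(seq_len(reps), 3),
                background_threshold = 1)
}

test_that("normalization references genes to control and chips to size factors", {
  # single gene, controls (10,10), treatment (20,20): the per-gene step
  # leaves controls at 1.0 and the treatment ratio at 2.0
  mat <- matrix(c(10, 10, 20, 20, 10, 10), 1,
                dimnames = list("g1", NULL))
  ne <- normalize(toyExperiment(mat), per_chip = FALSE)
  v <- SummarizedExperiment::assay(ne, "intensity")
  expect_equal(unname(v[1, 1:2]), c(1, 1))
  expect_equal(unname(v[1, 3:4]), c(2, 2))
  # a chip-wide intensity inflation is removed by the size-factor step
  set.seed(31)
  mat2 <- matrix(10 * runif(60, 0.9, 1.1), 10,
                 dimnames = list(paste0("g", 1:10), NULL))
  inflated <- mat2
  inflated[, 3:4] <- inflated[, 3:4] * 5   # miR chips scanned 5x brighter
  na <- SummarizedExperiment::assay(normalize(toyExperiment(mat2)),
                                    "intensity")
  nb <- SummarizedExperiment::assay(normalize(toyExperiment(inflated)),
                                    "intensity")
  expect_equal(na, nb)
  # per-gene control medians sit at exactly 1 after normalization
  expect_equal(unname(apply(na[, 1:2, drop = FALSE], 1, median)),
               rep(1, 10))
})

test_that("normalization is idempotent in the noiseless limit", {
  cfg <- simulationConfig(n_genes = 50L, n_cell_types = 1L,
                          noise_sd_log2 = 0, tf_regulon_size = 5L,
                          frac_below_background_per_cell = 0,
                          rng_seed = 9L)
  ex <- generateExpression(generateTruth(cfg), cfg)[[1]]
  once <- normalize(ex)
  twice <- normalize(once)
  expect_equal(SummarizedExperiment::assay(twice, "intensity"),
               SummarizedExperiment::assay(once, "intensity"))
})

test_that("all-zero control genes are excluded with a warning", {
  mat <- rbind(g1 = c(0, 0, 5, 5, 5, 5), g2 = c(4, 4, 8, 8, 2, 2))
  expect_warning(ne <- normalize(toyExperiment(mat)), "excluded")
  expect_identical(rownames(ne), "g2")
})

test_that("background filter applies the more-than-half exclusion rule", {
  mk <- function(n_below) {
    vals <- c(rep(0.5, n_below), rep(2, 6 - n_below))
    matrix(vals, 1, dimnames = list("g", NULL))
  }
  expect_identical(filterBackground(toyExperiment(mk(4))), character(0))
  # boundary: below in exactly half of the samples retains
  expect_identical(filterBackground(toyExperiment(mk(3))), "g")
  expect_identical(filterBackground(toyExperiment(mk(0))), "g")
})

test_that("modulation calls follow direction and threshold conventions", {
  # ratios 2.0 (up), 1.4 (unchanged), 0.5 (down), 1.5 boundary (up)
  mat <- rbind(g_up = c(10, 10, 20, 20, 10, 10),
               g_mid = c(10, 10, 14, 14, 10, 10),
               g_dn = c(10, 10, 5, 5, 10, 10),
               g_edge = c(10, 10, 15, 15, 10, 10))
  conds <- rep(c("control", "miR", "anti_miR"), each = 2)
  ex <- mirExperiment(mat, "c1", conds, rep(1:2, 3),
                      background_threshold = 1)
  calls <- callModulation(ex, mode = "fc_only")
  mir <- calls[calls$modulation == "miR", ]
  expect_identical(mir$direction[match(c("g_up", "g_mid", "g_dn", "g_edge"),
                                       mir$gene)],
                   c("up", "unchanged", "down", "up"))
  expect_true(all(is.na(mir$p_value)))
  expect_equal(mir$fold_change[mir$gene == "g_dn"], 0.5)
})

test_that("fc_and_p mode gates calls on the pooled t-test", {
  set.seed(1)
  # strong consistent effect vs noisy inconsistent one
  mat <- rbind(g_sig = c(10, 10.2, 20, 20.5, 10, 10.1),
               g_noisy = c(10, 30, 2, 90, 11, 28))
  conds <- rep(c("control", "miR", "anti_miR"), each = 2)
  ex <- mirExperiment(mat, "c1", conds, rep(1:2, 3),
                      background_threshold = 1)
  calls <- callModulation(ex, mode = "fc_and_p")
  mir <- calls[calls$modulation == "miR", ]
  expect_identical(mir$direction[mir$gene == "g_sig"], "up")
  expect_lt(mir$p_value[mir$gene == "g_sig"], 0.05)
  expect_identical(mir$direction[mir$gene == "g_noisy"], "unchanged")
})

test_that("direction is antisymmetric under label swap", {
  set.seed(7)
  mat <- matrix(runif(40, 5, 50), 10,
                dimnames = list(paste0("g", 1:10), NULL))
  mat <- cbind(mat, mat[, 1:2])  # anti_miR arm copies controls
  ex <- mirExperiment(mat, "c1", rep(c("control", "miR", "anti_miR"),
                                     each = 2),
                      rep(1:2, 3), background_threshold = 1)
  swapped <- mirExperiment(mat[, c(3, 4, 1, 2, 5, 6)], "c1",
                           rep(c("control", "miR", "anti_miR"), each = 2),
                           rep(1:2, 3), background_threshold = 1)
  a <- callModulation(ex, mode = "fc_only")
  b <- callModulation(swapped, mode = "fc_only")
  a <- a[a$modulation == "miR", ]; b <- b[b$modulation == "miR", ]
  expect_equal(a$fold_change, 1 / b$fold_change)
  map <- c(up = "down", down = "up", unchanged = "unchanged")
  expect_identical(unname(map[a$direction]), b$direction)
})

test_that("bidirectional and multi-cell set logic", {
  calls <- data.frame(
    gene = c("A", "B", "C", "B", "C", "D", "X", "X"),
    cell_type = "c1",
    modulation = c("miR", "miR", "miR", "anti_miR", "anti_miR",
                   "anti_miR", "miR", "anti_miR"),
    direction = c("down", "down", "down", "up", "up", "up", "up", "down"),
    fold_change = 1, p_value = NA_real_, stringsAsFactors = FALSE)
  expect_setequal(bidirectionalSet(calls, "c1", "canonical"), c("B", "C"))
  expect_setequal(bidirectionalSet(calls, "c1", "noncanonical"), "X")
  # canonical and noncanonical bidirectional sets are disjoint
  expect_length(intersect(bidirectionalSet(calls, "c1", "canonical"),
                          bidirectionalSet(calls, "c1", "noncanonical")), 0)
  expect_error(bidirectionalSet(calls[calls$modulation == "miR", ], "c1"),
               "both")
  sets <- list(c("A", "B"), c("B", "C"), "B")
  expect_identical(multiCellTypeSet(sets, 3), "B")
  expect_setequal(multiCellTypeSet(sets, 1), c("A", "B", "C"))
  expect_identical(multiCellTypeSet(sets, 2), "B")
  expect_error(multiCellTypeSet(sets, 4), "exceeds")
})

test_that("noiseless synthetic calls equal truth response modes", {
  cfg <- simulationConfig(n_genes = 150L, n_cell_types = 1L,
                          noise_sd_log2 = 0, background_de_rate = 0,
                          tf_regulon_size = 10L,
                          frac_below_background_per_cell = 0.1,
                          rng_seed = 21L)
  tr <- generateTruth(cfg)
  g <- truthGenes(tr)
  ex <- generateExpression(tr, cfg)[[1]]
  retained <- filterBackground(ex)
  expect_setequal(retained, g$gene[g$expressed_cell1])
  calls <- callModulation(normalize(ex[retained, ]), mode = "fc_only")
  mir <- calls[calls$modulation == "miR", ]
  gg <- g[match(mir$gene, g$gene), ]
  want <- ifelse(gg$response_mode == "canonical", "down",
                 ifelse(gg$response_mode == "noncanonical", "up",
                        "unchanged"))
  expect_identical(mir$direction, want)
})
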