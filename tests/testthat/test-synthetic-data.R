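smallConfig <- function(...) {
  simulationConfig(n_genes = 100L, n_cell_types = 2L,
                   tf_regulon_size = 10L,
                   frac_below_background_per_cell = 0.1, rng_seed = 11L, ...)
}

test_that("configuration invariants are enforced with named errors", {
  expect_error(simulationConfig(frac_predicted_targets = 1.2),
               "frac_predicted_targets")
  expect_error(simulationConfig(frac_canonical_responders = 0.7,
                                frac_noncanonical_responders = 0.7),
               "exceed 1")
  expect_error(simulationConfig(effect_fold_range = c(0.8, 2)),
               "effect_fold_range")
  expect_error(simulationConfig(replicates_per_condition = 1),
               "replicates_per_condition")
})

test_that("truth generation matches configured proportions and is deterministic", {
  cfg <- smallConfig(frac_predicted_targets = 0.2)
  tr <- generateTruth(cfg)
  g <- truthGenes(tr)
  expect_identical(sum(g$is_predicted_target), 20L)
  expect_identical(generateTruth(cfg), tr)
  # proportions-sum-to-one leaves no unresponsive predicted target
  tr2 <- generateTruth(smallConfig(frac_canonical_responders = 0.5,
                                   frac_noncanonical_responders = 0.5))
  g2 <- truthGenes(tr2)
  expect_identical(sum(g2$is_predicted_target &
                         g2$response_mode == "unresponsive"), 0L)
  # the TF gene is itself a predicted target
  expect_true(g$is_predicted_target[g$is_tf_gene])
  expect_identical(sum(g$is_tf_gene), 1L)
  expect_identical(sum(g$in_tf_regulon), 10L)
  # PCT present exactly for predicted targets
  expect_true(all(is.na(g$pct[!g$is_predicted_target])))
  expect_true(all(!is.na(g$pct[g$is_predicted_target])))
})

test_that("generated UTRs carry exactly the planted site structure", {
  cfg <- smallConfig()
  tr <- generateTruth(cfg)
  utrs <- generateUTRs(tr, MIR181B, utr_length = 60L)
  g <- truthGenes(tr)
  for (i in seq_len(nrow(g))) {
    found <- scanSeedSites(utrs[[g$gene[i]]], MIR181B)
    if (g$site_class[i] == "none") {
      expect_identical(nrow(found), 0L, info = g$gene[i])
    } else {
      best <- c("8mer", "7mer-m8", "7mer-1A")[
        min(match(found$site_class, c("8mer", "7mer-m8", "7mer-1A")))]
      expect_identical(best, g$site_class[i], info = g$gene[i])
    }
  }
  expect_true(all(grepl("^[ACGT]+$", utrs)))
  expect_error(generateUTRs(tr, MIR181B, utr_length = 20L), "at least 30")
})

test_that("noiseless expression reproduces planted effects exactly", {
  cfg <- simulationConfig(n_genes = 100L, n_cell_types = 2L,
                          noise_sd_log2 = 0, background_de_rate = 0,
                          tf_regulon_size = 0L,
                          frac_below_background_per_cell = 0,
                          rng_seed = 11L)
  tr <- generateTruth(cfg)
  g <- truthGenes(tr)
  ex <- generateExpression(tr, cfg)[[1]]
  mat <- SummarizedExperiment::assay(ex, "intensity")
  cd <- SummarizedExperiment::colData(ex)
  ctrl <- rowMeans(mat[, cd$condition == "control", drop = FALSE])
  mirm <- rowMeans(mat[, cd$condition == "miR", drop = FALSE])
  anti <- rowMeans(mat[, cd$condition == "anti_miR", drop = FALSE])
  can <- g$response_mode == "canonical"
  expect_equal(unname(mirm[can] / ctrl[can]), 1 / g$true_effect_fold[can])
  expect_equal(unname(anti[can] / ctrl[can]),
               g$true_effect_fold[can]^cfg@anti_mir_attenuation)
  non <- g$response_mode == "noncanonical"
  expect_equal(unname(mirm[non] / ctrl[non]), g$true_effect_fold[non])
  flat <- g$response_mode == "unresponsive"
  expect_equal(mirm[flat], ctrl[flat])
  expect_equal(anti[flat], ctrl[flat])
})

test_that("unresponsive log2 ratios match the noise-only expectation", {
  cfg <- simulationConfig(n_genes = 2000L, n_cell_types = 1L,
                          frac_predicted_targets = 0,
                          frac_canonical_responders = 0,
                          frac_noncanonical_responders = 0,
                          background_de_rate = 0, tf_regulon_size = 0L,
                          frac_below_background_per_cell = 0,
                          noise_sd_log2 = 0.1, rng_seed = 5L)
  tr <- generateTruth(cfg)
  ex <- generateExpression(tr, cfg)[[1]]
  mat <- SummarizedExperiment::assay(ex, "intensity")
  cd <- SummarizedExperiment::colData(ex)
  lr <- log2(rowMeans(mat[, cd$condition == "miR", drop = FALSE]) /
               rowMeans(mat[, cd$condition == "control", drop = FALSE]))
  # |log2 ratio| is half-normal with sd ~ noise * sqrt(2/replicates)
  sd_fc <- 0.1 * sqrt(2 / cfg@replicates_per_condition)
  expected_mean <- sd_fc * sqrt(2 / pi)
  se <- sd_fc * sqrt(1 - 2 / pi) / sqrt(2000)
  expect_lt(abs(mean(abs(lr)) - expected_mean), 4 * se)
})

test_that("expected confusion reproduces hand-enumerated category sums", {
  # deterministic limit: all effects well above threshold, no noise
  cfg <- simulationConfig(n_genes = 200L, n_cell_types = 1L,
                          frac_predicted_targets = 0.2,
                          frac_canonical_responders = 0.4,
                          frac_noncanonical_responders = 0,
                          background_de_rate = 0.1, tf_regulon_size = 0L,
                          frac_below_background_per_cell = 0,
                          effect_fold_range = c(2.5, 3), noise_sd_log2 = 0,
                          anti_mir_attenuation = 1, rng_seed = 2L)
  tr <- generateTruth(cfg)
  g <- truthGenes(tr)
  ec <- expectedConfusion(tr, cfg, list(modulation = "miR",
                                        cell_type = "cell1",
                                        parameter = "all"), "canonical")
  # brute-force expectation over the planted per-gene records
  n_pred <- sum(g$is_predicted_target)
  n_can <- sum(g$response_mode == "canonical")
  n_spur_dn <- sum(!is.na(g$spurious_miR_dir) & g$spurious_miR_dir == "down")
  expect_equal(ec@tp, n_can)
  expect_equal(ec@fp, n_pred - n_can)
  expect_equal(ec@fn, n_spur_dn)
  expect_equal(ec@tn, 200 - n_pred - n_spur_dn)
  # spec-style arithmetic: acc = P(target)P(resp) + P(non-target)P(quiet)
  expect_equal(accuracy(ec),
               (n_can + (200 - n_pred - n_spur_dn)) / 200)
  expect_error(expectedConfusion(tr, cfg,
    list(modulation = "miR", cell_type = "cell9", parameter = "all")),
    "cell")
})

test_that("reporter generator recovers planted percent changes", {
  # noiseless: exact recovery, zero-variance p flagged
  d <- generateReporterData(c(dn20 = -20), noise_sd = 0, seed = 3L)
  r <- reporterResponse(d)
  expect_equal(r$percent_change, -20)
  expect_true(is.na(r$p_value))
  expect_match(r$note, "zero variance")
  # planted +52 percent (TF-like elevation) recovered under mild noise
  d2 <- generateReporterData(c(up52 = 52), noise_sd = 0.03, seed = 4L)
  r2 <- reporterResponse(d2)
  expect_lt(abs(r2$percent_change - 52), 8)
  expect_true(r2$validated)
})
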