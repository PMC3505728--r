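# Shared synthetic study, built once per test run and reused across
# test files (3 cell types x 2000 genes is the recovery-scale design).

.study_cache <- new.env(parent = emptyenv())

standardStudy <- function() {
  if (!is.null(.study_cache$std)) return(.study_cache$std)
  cfg <- simulationConfig(n_genes = 2000L, n_cell_types = 3L,
                          frac_canonical_responders = 0.4,
                          background_de_rate = 0.05, rng_seed = 42L)
  truth <- generateTruth(cfg)
  experiments <- generateExpression(truth, cfg)
  calls <- do.call(rbind, lapply(experiments, function(e) {
    retained <- filterBackground(e)
    callModulation(normalize(e[retained, ]), mode = "fc_only")
  }))
  rownames(calls) <- NULL
  .study_cache$std <- list(cfg = cfg, truth = truth,
                           experiments = experiments, calls = calls,
                           predictions = truthPredictions(truth))
  .study_cache$std
}

# Same design but with fully symmetric canonical / non-canonical
# structure (equal responder fractions, no one-sided TF regulon), for
# orientation-symmetry checks.
symmetricStudy <- function() {
  if (!is.null(.study_cache$sym)) return(.study_cache$sym)
  cfg <- simulationConfig(n_genes = 2000L, n_cell_types = 3L,
                          frac_canonical_responders = 0.35,
                          frac_noncanonical_responders = 0.35,
                          background_de_rate = 0.05,
                          tf_regulon_size = 0L, rng_seed = 43L)
  truth <- generateTruth(cfg)
  experiments <- generateExpression(truth, cfg)
  calls <- do.call(rbind, lapply(experiments, function(e) {
    retained <- filterBackground(e)
    callModulation(normalize(e[retained, ]), mode = "fc_only")
  }))
  rownames(calls) <- NULL
  .study_cache$sym <- list(cfg = cfg, truth = truth, calls = calls,
                           predictions = truthPredictions(truth))
  .study_cache$sym
}
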