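# Memoized replicate simulations shared by the acceptance tests: the same
# seeded cohorts serve every check that needs them, so each replicate set is
# simulated once per test run.

.rep_cache <- new.env(parent = emptyenv())

# Cohorts with the default localized FA effect (raw Cohen's d ~ 1.2 at the
# locus) and PANSS total coupled at rho = -0.6. Records, per replicate, the
# Bonferroni-flagged points of the FA group test and of the patients-only
# FA-PANSS partial correlation.
effect_replicates <- function(n_reps = 100L) {
  key <- paste0("effect", n_reps)
  if (!is.null(.rep_cache[[key]])) return(.rep_cache[[key]])
  out <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    cfg <- pipeline_config(seed = 202600L + i, panss_coupling = -0.6)
    ex <- tract_experiment(cfg, metrics = "fa", clinical = TRUE,
                           scores = "panss_total")
    out[[i]] <- list(
      group_flags = ex$pointwise$point[ex$pointwise$significant],
      clin_neg_flags = ex$clinical$point[ex$clinical$significant &
                                           ex$clinical$r < 0],
      affected = ex$cohort$truth$affected_points,
      locus = ex$cohort$truth$locus_index)
  }
  .rep_cache[[key]] <- out
  out
}

# Null cohorts: no group effect, no clinical coupling. Same dual recording.
null_replicates <- function(n_reps = 500L) {
  key <- paste0("null", n_reps)
  if (!is.null(.rep_cache[[key]])) return(.rep_cache[[key]])
  out <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    cfg <- pipeline_config(seed = 716000L + i, effect_delta = 0,
                           panss_coupling = 0)
    ex <- tract_experiment(cfg, metrics = "fa", clinical = TRUE,
                           scores = "panss_total")
    out[[i]] <- list(
      any_group_flag = any(ex$pointwise$significant),
      any_clin_flag = any(ex$clinical$significant))
  }
  .rep_cache[[key]] <- out
  out
}
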