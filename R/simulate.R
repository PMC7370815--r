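#' End-to-end cohort replicate, in memory
#'
#' Realizes one synthetic cohort, runs the full analysis chain on it —
#' 8-bit quantized images, luminance conversion, spectral contrast, exact
#' rank test — and also runs the same rank test directly on the drawn truth
#' targets. The PNG disk round-trip is lossless for 8-bit data (verified in
#' the unit suite), so this is the pipeline minus file I/O; it exists so
#' thousands of replicates fit in a test-time budget.
#'
#' @param spec a `synth_cohort_spec`.
#' @param metric,sidedness passed to [compare_conditions()].
#' @return list with `p_pipeline` (p-value from estimated contrasts),
#'   `p_truth` (p-value of the same test on the drawn targets), and the
#'   cohort `table`.
#' @export
simulate_cohort_test <- function(spec, metric = "rms",
                                 sidedness = "two_sided") {
  coh <- realize_cohort(spec)
  cfg <- pipeline_config(seed = spec$seed, log_level = "quiet")
  contrasts <- lapply(seq_along(coh$images), function(i) {
    contrast_one(coh$images[[i]], cfg, image_id = coh$catalog$image_id[i])
  })
  tab <- assemble_timeline(coh$catalog, contrasts)
  cmp <- compare_conditions(tab, metric = metric, sidedness = sidedness)
  truth_cmp <- mann_whitney_u(
    coh$truth$target_rms_contrast[coh$truth$condition == "low"],
    coh$truth$target_rms_contrast[coh$truth$condition == "high"],
    sidedness = sidedness)
  list(p_pipeline = cmp$p_value, p_truth = truth_cmp$p_value, table = tab)
}

#' Rejection-rate simulation over cohort replicates
#'
#' Repeats [simulate_cohort_test()] with per-replicate seeds derived from
#' `seed` and returns the fraction of replicates rejecting at `alpha`, for
#' both the end-to-end pipeline and the direct truth-target test.
#'
#' @param spec a `synth_cohort_spec`; its `seed` field is overridden per
#'   replicate.
#' @param n_rep number of replicates.
#' @param alpha rejection level.
#' @param seed master seed for the replicate seed stream.
#' @return list with `rate_pipeline`, `rate_truth`, `n_rep`, `alpha`.
#' @export
simulate_rejection_rate <- function(spec, n_rep = 200L, alpha = 0.05,
                                    seed = 1L) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_rep)
  rej_pipe <- logical(n_rep)
  rej_truth <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    spec$seed <- rep_seeds[r]
    res <- simulate_cohort_test(spec)
    rej_pipe[r] <- res$p_pipeline <= alpha
    rej_truth[r] <- res$p_truth <= alpha
  }
  list(rate_pipeline = mean(rej_pipe), rate_truth = mean(rej_truth),
       n_rep = n_rep, alpha = alpha)
}
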