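#' Run a simulation scenario over many replicates
#'
#' Repeatedly generates a dataset with [simulate_nb_counts()], runs the full
#' pipeline with [run_degps()] and evaluates the result against the known
#' truth.  Replicate r uses seed `seed + r` for both the generator and the
#' test (kept below 2^31), so results are reproducible and replicates
#' independent.
#'
#' @param config a [scenario_config()]; its `seed` field is overridden
#'   per replicate.
#' @param n_reps number of replicates.
#' @param method normalization method for [run_degps()].
#' @param seed master seed.
#' @param alpha significance level for the metrics (default 0.05).
#' @param max_perms passed to [run_degps()].
#' @return A data.frame with one row per replicate: `replicate`,
#'   `type_i_error`, `fdr`, `tpr`, `pauc`, `n_called`, `n_true_de`.
#' @examples
#' \donttest{
#' met <- benchmark_scenario(scenario_config(n_transcripts = 200),
#'                           n_reps = 3, seed = 1)
#' apply(met[c("fdr", "tpr")], 2, median)
#' }
#' @export
benchmark_scenario <- function(config, n_reps = 100L, method = "gp-theta",
                               seed = 1L, alpha = 0.05, max_perms = 1000L) {
  stopifnot(inherits(config, "degps_scenario"), n_reps >= 1)
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    rep_seed <- (seed + r - 1L) %% .Machine$integer.max
    cfg <- config
    cfg$seed <- rep_seed
    sim <- simulate_nb_counts(cfg)
    res <- run_degps(sim$counts, sim$design, method = method,
                     max_perms = max_perms, fdr_threshold = alpha,
                     seed = rep_seed)
    met <- evaluate_de(res, sim$truth, alpha = alpha)
    rows[[r]] <- cbind(data.frame(replicate = r), met)
  }
  do.call(rbind, rows)
}
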