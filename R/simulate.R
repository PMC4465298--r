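#' Simulation scenario configuration
#'
#' Collects the knobs of the negative-binomial benchmark generator and the
#' resampling transformations into one validated object.
#'
#' @param n_transcripts number of transcripts (default 2000).
#' @param n_per_group samples per group; the evaluation grid uses 5, 8, 10.
#' @param de_fraction fraction of transcripts made differentially expressed
#'   (default 0.1).
#' @param upregulated_fraction fraction of DE transcripts upregulated
#'   (default 0.5).
#' @param outlier_prob per-entry probability of a random outlier
#'   (grid: 0, 0.005, 0.01, 0.02; default 0).
#' @param effect_size mean fold change applied to DE transcripts in the NB
#'   generator (default 3).
#' @param shift_magnitude added read counts for the "shift" transformation;
#'   the per-transcript addition varies with standard deviation
#'   `magnitude/5` (default 50).
#' @param scale_magnitude multiplicative factor for the "scaling and shift"
#'   transformation, varied with standard deviation `magnitude/5`
#'   (default 2).
#' @param outlier_range multiplier range for outlier entries (default
#'   `c(5, 10)`).
#' @param perturbation law for the "varied quantities": `"normal"`
#'   (default) or `"uniform"` (same mean and standard deviation).
#' @param seed integer seed.
#' @return A validated list of class `"degps_scenario"`.
#' @export
scenario_config <- function(n_transcripts = 2000L, n_per_group = 5L,
                            de_fraction = 0.1, upregulated_fraction = 0.5,
                            outlier_prob = 0, effect_size = 3,
                            shift_magnitude = 50, scale_magnitude = 2,
                            outlier_range = c(5, 10),
                            perturbation = c("normal", "uniform"),
                            seed = 1L) {
  perturbation <- match.arg(perturbation)
  stopifnot(n_transcripts >= 1, n_per_group >= 2,
            de_fraction >= 0, de_fraction <= 1,
            upregulated_fraction >= 0, upregulated_fraction <= 1,
            effect_size > 0, shift_magnitude > 0, scale_magnitude > 0,
            length(outlier_range) == 2L, all(outlier_range > 0))
  if (outlier_prob < 0 || outlier_prob > 1)
    stop("outlier_prob must lie in [0, 1]")
  structure(list(n_transcripts = as.integer(n_transcripts),
                 n_per_group = as.integer(n_per_group),
                 de_fraction = de_fraction,
                 upregulated_fraction = upregulated_fraction,
                 outlier_prob = outlier_prob, effect_size = effect_size,
                 shift_magnitude = shift_magnitude,
                 scale_magnitude = scale_magnitude,
                 outlier_range = outlier_range,
                 perturbation = perturbation, seed = as.integer(seed)),
            class = "degps_scenario")
}

new_sim_dataset <- function(counts, design, truth) {
  structure(list(counts = counts, design = design, truth = truth),
            class = "degps_simdata")
}

#' @export
print.degps_simdata <- function(x, ...) {
  cat(sprintf("Simulated dataset: %d transcripts x %d samples, %d DE\n",
              nrow(x$counts), ncol(x$counts), sum(x$truth$is_de)))
  invisible(x)
}

# "varied quantities (variation = one fifth of the value)": one draw per
# transcript around magnitude m with sd m/5, floored at 0.
varied_quantity <- function(n, magnitude, law) {
  s <- magnitude / 5
  v <- if (law == "normal") stats::rnorm(n, magnitude, s)
       else stats::runif(n, magnitude - s * sqrt(3), magnitude + s * sqrt(3))
  pmax(v, 0)
}

#' Overdispersed source matrix for resampling simulations
#'
#' A stand-in for a large real RNA-Seq compendium (which is out of scope):
#' transcript abundances follow a log-normal profile spanning roughly five
#' orders of magnitude (log10 mean ~ Normal(2, 1)), each sample has its own
#' library-depth factor (log-normal, sd 0.25), and counts are negative
#' binomial with per-transcript dispersion Uniform(0.1, 0.6).  The result is
#' heavy-tailed and overdispersed, with uneven library sizes, suitable as a
#' `source` for [resample_null()].
#'
#' @param n_transcripts,n_samples matrix dimensions.
#' @param seed integer seed.
#' @return A transcripts-by-samples integer count matrix.
#' @export
make_source_matrix <- function(n_transcripts, n_samples, seed = 1L) {
  stopifnot(n_transcripts >= 1, n_samples >= 1)
  set.seed(seed)
  mu <- 10^stats::rnorm(n_transcripts, 2, 1)
  disp <- stats::runif(n_transcripts, 0.1, 0.6)
  depth <- exp(stats::rnorm(n_samples, 0, 0.25))
  m <- matrix(0L, n_transcripts, n_samples,
              dimnames = list(paste0("transcript_", seq_len(n_transcripts)),
                              paste0("sample_", seq_len(n_samples))))
  for (j in seq_len(n_samples))
    m[, j] <- stats::rnbinom(n_transcripts, mu = mu * depth[j], size = 1 / disp)
  m
}

#' Null dataset by resampling columns of a source matrix
#'
#' Draws `2 * n_per_group` distinct sample columns without replacement from
#' `source` and splits them randomly into two equal groups.  Since both
#' groups come from the same population, every transcript is truly non-DE.
#'
#' @param source a count matrix with at least `2 * n_per_group` columns.
#' @param n_per_group samples per group.
#' @param seed integer seed.
#' @return A `"degps_simdata"`: `counts`, `design`, `truth` (all non-DE).
#' @export
resample_null <- function(source, n_per_group, seed = 1L) {
  source <- check_count_matrix(source)
  n <- 2L * n_per_group
  if (ncol(source) < n)
    stop("source has ", ncol(source), " samples; need >= ", n)
  set.seed(seed)
  cols <- sample.int(ncol(source), n)
  counts <- source[, cols, drop = FALSE]
  split_a <- sample.int(n, n_per_group)
  design <- de_design(colnames(counts)[split_a],
                      colnames(counts)[setdiff(seq_len(n), split_a)])
  truth <- data.frame(transcript_id = rownames(counts),
                      is_de = FALSE, direction = 0L,
                      stringsAsFactors = FALSE)
  new_sim_dataset(counts, design, truth)
}

select_de <- function(data, de_fraction) {
  G <- nrow(data$counts)
  n_de <- round(de_fraction * G)
  if (n_de > G) stop("de_fraction too large for the matrix")
  sample.int(G, n_de)
}

#' "Shift" transformation: additive differential expression
#'
#' Selects `round(de_fraction * n_transcripts)` transcripts of a null
#' dataset and adds a varied quantity of read counts (mean
#' `magnitude`, standard deviation `magnitude/5`, floored at zero, rounded
#' to integer) to all samples of one group per transcript.  The receiving
#' group is group A with probability `upregulated_fraction` ("upregulated"
#' means higher in group A).
#'
#' @param data a `"degps_simdata"` null dataset.
#' @param magnitude mean added count.
#' @param de_fraction fraction of transcripts to shift.
#' @param upregulated_fraction fraction shifted upwards in group A.
#' @param seed integer seed.
#' @param perturbation `"normal"` or `"uniform"` law for the variation.
#' @return The transformed `"degps_simdata"` with updated `truth`.
#' @export
apply_shift <- function(data, magnitude, de_fraction,
                        upregulated_fraction = 0.5, seed = 1L,
                        perturbation = "normal") {
  stopifnot(inherits(data, "degps_simdata"))
  if (any(data$truth$is_de)) stop("apply_shift expects a null dataset")
  set.seed(seed)
  sel <- select_de(data, de_fraction)
  if (!length(sel)) return(data)
  counts <- data$counts
  idx <- design_indices(data$design, counts)
  up <- stats::runif(length(sel)) < upregulated_fraction
  add <- round(varied_quantity(length(sel), magnitude, perturbation))
  for (k in seq_along(sel)) {
    g <- if (up[k]) idx$a else idx$b
    counts[sel[k], g] <- counts[sel[k], g] + add[k]
  }
  truth <- data$truth
  truth$is_de[sel] <- TRUE
  truth$direction[sel] <- ifelse(up, 1L, -1L)
  new_sim_dataset(counts, data$design, truth)
}

#' "Scaling and shift" transformation
#'
#' Applies [apply_shift()] and then multiplies the affected group's counts
#' of each selected transcript by a varied factor (mean `scale_magnitude`,
#' standard deviation `scale_magnitude/5`), rounding back to integers.
#'
#' @param data a `"degps_simdata"` null dataset.
#' @param scale_magnitude mean multiplicative factor.
#' @param shift_magnitude mean added count for the shift step.
#' @param de_fraction fraction of transcripts transformed.
#' @param upregulated_fraction fraction affected in group A.
#' @param seed integer seed.
#' @param perturbation `"normal"` or `"uniform"`.
#' @return The transformed `"degps_simdata"`.
#' @export
apply_scale_shift <- function(data, scale_magnitude, shift_magnitude,
                              de_fraction, upregulated_fraction = 0.5,
                              seed = 1L, perturbation = "normal") {
  shifted <- apply_shift(data, shift_magnitude, de_fraction,
                         upregulated_fraction, seed, perturbation)
  sel <- which(shifted$truth$is_de)
  if (!length(sel)) return(shifted)
  counts <- shifted$counts
  idx <- design_indices(shifted$design, counts)
  fac <- varied_quantity(length(sel), scale_magnitude, perturbation)
  for (k in seq_along(sel)) {
    g <- if (shifted$truth$direction[sel[k]] > 0) idx$a else idx$b
    counts[sel[k], g] <- round(counts[sel[k], g] * fac[k])
  }
  new_sim_dataset(counts, shifted$design, shifted$truth)
}

#' Negative-binomial benchmark generator with random outliers
#'
#' Simulates a transcripts-by-samples count matrix in the style of NB
#' benchmark generators: per-transcript baseline means are log-normal
#' (log10 mean ~ Normal(2, 1)), dispersions Uniform(0.1, 0.6); a
#' `de_fraction` of transcripts has its mean multiplied by `effect_size` in
#' one group (`upregulated_fraction` of them up in group A); independently,
#' each matrix entry becomes an outlier with probability `outlier_prob`, in
#' which case it is multiplied by a random factor in `outlier_range`
#' (default 5-10) to model abnormally high counts.
#'
#' @param config a [scenario_config()].
#' @return A `"degps_simdata"` with `counts`, `design` and `truth`.
#' @examples
#' sim <- simulate_nb_counts(scenario_config(n_transcripts = 100, seed = 3))
#' table(sim$truth$is_de)
#' @export
simulate_nb_counts <- function(config) {
  stopifnot(inherits(config, "degps_scenario"))
  set.seed(config$seed)
  G <- config$n_transcripts
  npg <- config$n_per_group
  n <- 2L * npg
  mu <- 10^stats::rnorm(G, 2, 1)
  disp <- stats::runif(G, 0.1, 0.6)
  n_de <- round(config$de_fraction * G)
  sel <- if (n_de) sample.int(G, n_de) else integer(0)
  up <- stats::runif(n_de) < config$upregulated_fraction
  fold <- rep(1, G)
  mu_a <- mu; mu_b <- mu
  if (n_de) {
    mu_a[sel[up]]  <- mu[sel[up]]  * config$effect_size
    mu_b[sel[!up]] <- mu[sel[!up]] * config$effect_size
  }
  counts <- matrix(0, G, n,
                   dimnames = list(paste0("transcript_", seq_len(G)),
                                   paste0("sample_", seq_len(n))))
  for (j in seq_len(npg))
    counts[, j] <- stats::rnbinom(G, mu = mu_a, size = 1 / disp)
  for (j in seq_len(npg) + npg)
    counts[, j] <- stats::rnbinom(G, mu = mu_b, size = 1 / disp)
  if (config$outlier_prob > 0) {
    hit <- stats::runif(G * n) < config$outlier_prob
    if (any(hit)) {
      fac <- stats::runif(sum(hit), config$outlier_range[1],
                          config$outlier_range[2])
      counts[hit] <- round(counts[hit] * fac)
    }
    attr(counts, "n_outliers") <- sum(hit)
  }
  design <- de_design(colnames(counts)[seq_len(npg)],
                      colnames(counts)[seq_len(npg) + npg])
  truth <- data.frame(transcript_id = rownames(counts),
                      is_de = FALSE, direction = 0L,
                      stringsAsFactors = FALSE)
  truth$is_de[sel] <- TRUE
  truth$direction[sel] <- ifelse(up, 1L, -1L)
  new_sim_dataset(counts, design, truth)
}
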