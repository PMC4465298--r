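#' Validate a transcripts-by-samples count matrix
#'
#' @param counts numeric matrix of nonnegative integers with unique rownames
#'   (transcript ids) and colnames (sample ids); missing names are filled in.
#' @return The validated matrix (storage mode numeric), invisibly usable.
#' @keywords internal
check_count_matrix <- function(counts) {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("counts must be a numeric matrix (transcripts x samples)")
  if (anyNA(counts)) stop("counts must not contain NA")
  if (any(counts < 0)) {
    idx <- which(counts < 0, arr.ind = TRUE)[1L, ]
    stop("negative count at row ", idx[1L], ", column ", idx[2L])
  }
  if (any(counts != floor(counts)))
    stop("counts must be integers")
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("transcript_", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("sample_", seq_len(ncol(counts)))
  if (anyDuplicated(rownames(counts))) stop("duplicate transcript ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids")
  counts
}

new_normalized <- function(values, method, factors = NULL, fits = NULL) {
  structure(values, method = method, per_sample_factors = factors,
            gp_fits = fits, class = c("degps_normalized", class(values)))
}

#' @export
print.degps_normalized <- function(x, ...) {
  cat(sprintf("Normalized matrix (%s): %d transcripts x %d samples\n",
              attr(x, "method"), nrow(x), ncol(x)))
  f <- attr(x, "per_sample_factors")
  if (!is.null(f)) {
    cat("Per-sample factors:\n")
    print(signif(f, 4))
  }
  invisible(x)
}

fit_gp_columns <- function(counts) {
  fits <- vector("list", ncol(counts))
  names(fits) <- colnames(counts)
  for (j in seq_len(ncol(counts))) {
    fits[[j]] <- tryCatch(fit_gp_mle(counts[, j]), error = function(e)
      stop("GP fit failed for sample '", colnames(counts)[j], "': ",
           conditionMessage(e), call. = FALSE))
  }
  fits
}

#' Normalize a count matrix
#'
#' Dispatches to one of six per-sample normalization strategies:
#' \describe{
#'   \item{`gp-theta`}{each sample's counts are divided by the fitted GP
#'     \eqn{\hat\theta = \bar X(1-\hat\lambda)}, a dispersion-shrunk library
#'     size factor ([normalize_gp_theta()]).}
#'   \item{`gp-quantile`}{each count is mapped to its fitted-GP cumulative
#'     probability \eqn{P(X < x)} ([normalize_gp_quantile()]).}
#'   \item{`global`}{library-size scaling to the grand mean column total.}
#'   \item{`quantile`}{classic quantile normalization.}
#'   \item{`tmm`}{trimmed mean of M-values scaling factors.}
#'   \item{`lowess`}{MA-style lowess trend removal against a geometric-mean
#'     pseudo-reference.}
#' }
#'
#' @param counts transcripts-by-samples nonnegative integer matrix.
#' @param method normalization name (see above).
#' @param ... passed to the method-specific function.
#' @return A `"degps_normalized"` matrix with attributes `method`,
#'   `per_sample_factors` (for factor-based methods) and `gp_fits` (for the
#'   GP methods).
#' @examples
#' m <- matrix(rpois(60, 20), 10, 6,
#'             dimnames = list(paste0("t", 1:10), paste0("s", 1:6)))
#' nm <- normalize_counts(m, "global")
#' colSums(nm)  # all equal
#' @export
normalize_counts <- function(counts,
                             method = c("gp-theta", "gp-quantile", "global",
                                        "quantile", "tmm", "lowess"),
                             ...) {
  method <- match.arg(method)
  switch(method,
         "gp-theta"    = normalize_gp_theta(counts, ...),
         "gp-quantile" = normalize_gp_quantile(counts, ...),
         "global"      = normalize_global(counts),
         "quantile"    = normalize_quantile(counts),
         "tmm"         = normalize_tmm(counts, ...),
         "lowess"      = normalize_lowess(counts, ...))
}

#' GP-Theta normalization
#'
#' Fits a generalized Poisson distribution to every sample and divides the
#' sample's counts by its fitted \eqn{\hat\theta = \bar X(1 - \hat\lambda)}.
#' \eqn{\hat\theta} is the sample mean shrunk by the fitted overdispersion,
#' so this is a robustified library-size normalization.
#'
#' @param counts transcripts-by-samples nonnegative integer matrix.
#' @return Normalized matrix; `per_sample_factors` holds \eqn{\hat\theta_j},
#'   `gp_fits` the full fitted parameter objects.
#' @export
normalize_gp_theta <- function(counts) {
  counts <- check_count_matrix(counts)
  fits <- fit_gp_columns(counts)
  theta <- vapply(fits, `[[`, numeric(1), "theta")
  out <- sweep(counts, 2L, theta, "/")
  new_normalized(out, "gp-theta", factors = theta, fits = fits)
}

#' GP-Quantile normalization
#'
#' Fits a generalized Poisson distribution to every sample and replaces each
#' count x by the fitted cumulative probability \eqn{P(X < x)} (strict by
#' default), mapping all samples into \eqn{[0, 1)} on a common probability
#' scale.  Rank order within a sample is preserved.
#'
#' @param counts transcripts-by-samples nonnegative integer matrix.
#' @param lower CDF convention passed to [pgp()]: `"strict"` (default),
#'   `"le"` or `"mid"`.
#' @return Normalized matrix of probabilities; `gp_fits` holds the fits.
#' @export
normalize_gp_quantile <- function(counts, lower = c("strict", "le", "mid")) {
  counts <- check_count_matrix(counts)
  lower <- match.arg(lower)
  fits <- fit_gp_columns(counts)
  out <- counts
  for (j in seq_len(ncol(counts)))
    out[, j] <- pgp(counts[, j], fits[[j]], lower = lower)
  new_normalized(out, "gp-quantile", fits = fits)
}

#' Global (library size) normalization
#'
#' Scales each column so that all column totals equal the grand mean of the
#' original column totals.  The choice of common target is immaterial for
#' the scale-free T statistic downstream.
#'
#' @param counts transcripts-by-samples nonnegative integer matrix.
#' @return Normalized matrix; `per_sample_factors` holds the multipliers.
#' @export
normalize_global <- function(counts) {
  counts <- check_count_matrix(counts)
  totals <- colSums(counts)
  if (any(totals == 0))
    stop("sample '", colnames(counts)[which(totals == 0)[1L]],
         "' has zero total count")
  f <- mean(totals) / totals
  new_normalized(sweep(counts, 2L, f, "*"), "global", factors = f)
}

#' Quantile normalization
#'
#' Classic quantile normalization: each column's sorted values are replaced
#' by the across-column means of sorted values and mapped back through the
#' column's ranks; ties receive the average of the reference values over the
#' tie block.  Afterwards all columns share an identical empirical
#' distribution.
#'
#' @param counts transcripts-by-samples numeric matrix (>= 2 samples).
#' @return Normalized matrix.
#' @export
normalize_quantile <- function(counts) {
  counts <- check_count_matrix(counts)
  if (ncol(counts) < 2L) stop("quantile normalization needs >= 2 samples")
  sorted <- apply(counts, 2L, sort)
  ref <- rowMeans(sorted)
  out <- counts
  for (j in seq_len(ncol(counts))) {
    r <- rank(counts[, j], ties.method = "average")
    # interpolate reference at (possibly fractional) average ranks
    out[, j] <- stats::approx(seq_along(ref), ref, xout = r, rule = 2)$y
  }
  new_normalized(out, "quantile")
}

# One TMM factor: trimmed, weighted mean of M-values of column obs against ref.
# lib_obs/lib_ref are library sizes; trim fractions follow the published
# defaults (30% on M, 5% on A); weights are inverse asymptotic variances.
tmm_factor <- function(obs, ref, lib_obs, lib_ref,
                       logratio_trim = 0.3, abs_trim = 0.05) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  if (!length(obs)) stop("no transcripts shared by both samples; matrix too sparse for TMM")
  M <- log2((obs / lib_obs) / (ref / lib_ref))
  A <- 0.5 * log2((obs / lib_obs) * (ref / lib_ref))
  w <- (lib_obs - obs) / (lib_obs * obs) + (lib_ref - ref) / (lib_ref * ref)
  fin <- is.finite(M) & is.finite(A)
  M <- M[fin]; A <- A[fin]; w <- w[fin]
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
  loA <- floor(n * abs_trim) + 1;      hiA <- n + 1 - loA
  keep2 <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
  if (!any(keep2))
    stop("no transcripts survive TMM trimming; use a larger matrix")
  f <- sum(w[keep2] * M[keep2]) / sum(w[keep2])
  if (!is.finite(f)) f <- 0
  2^f
}

#' TMM (trimmed mean of M-values) normalization
#'
#' Per-sample scaling factors computed against a reference sample: transcripts
#' zero in either sample are removed, M (log2 ratio) and A (log2 abundance)
#' values formed on library-size-scaled counts, the top and bottom 30% of M
#' and 5% of A are trimmed, and the factor is 2 to the inverse-variance
#' weighted mean of the surviving M values.  Factors are rescaled to
#' geometric mean 1 and multiplied into library-size scaling: the output
#' columns are counts divided by their effective library size
#' (library size x TMM factor), rescaled to the mean effective size.
#'
#' @param counts transcripts-by-samples nonnegative integer matrix.
#' @param ref_sample optional sample id (or index) to use as reference;
#'   default is the column whose 75th percentile of scaled counts is closest
#'   to the mean 75th percentile.
#' @return Normalized matrix; `per_sample_factors` holds the TMM factors
#'   (geometric mean 1).
#' @export
normalize_tmm <- function(counts, ref_sample = NULL) {
  counts <- check_count_matrix(counts)
  if (ncol(counts) < 2L) stop("TMM needs >= 2 samples")
  lib <- colSums(counts)
  if (any(lib == 0)) stop("TMM requires positive column totals")
  uq <- apply(sweep(counts, 2L, lib, "/"), 2L, stats::quantile, probs = 0.75)
  if (is.null(ref_sample)) {
    ref_j <- which.min(abs(uq - mean(uq)))
  } else if (is.character(ref_sample)) {
    ref_j <- match(ref_sample, colnames(counts))
    if (is.na(ref_j)) stop("unknown reference sample '", ref_sample, "'")
  } else ref_j <- as.integer(ref_sample)
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref_j) return(1)
    tmm_factor(counts[, j], counts[, ref_j], lib[j], lib[ref_j])
  }, numeric(1))
  f <- f / exp(mean(log(f)))              # geometric mean 1, as is conventional
  eff <- lib * f
  out <- sweep(counts, 2L, eff, "/") * mean(eff)
  new_normalized(out, "tmm", factors = f)
}

#' Lowess (MA-trend) normalization
#'
#' Each sample is normalized against the per-transcript geometric-mean
#' pseudo-reference on the log2 scale (pseudocount 1): a lowess trend of
#' M = log2(sample) - log2(reference) against A = average log2 abundance is
#' fitted and subtracted, then values are mapped back to the count scale.
#' Removes intensity-dependent biases that a single scale factor cannot.
#'
#' @param counts transcripts-by-samples nonnegative integer matrix.
#' @param span lowess smoother span (fraction of points), default 0.4.
#' @param iter robustness iterations, default 3.
#' @return Normalized matrix (nonnegative reals).
#' @export
normalize_lowess <- function(counts, span = 0.4, iter = 3L) {
  counts <- check_count_matrix(counts)
  if (ncol(counts) < 2L) stop("lowess normalization needs >= 2 samples")
  lg <- log2(counts + 1)
  ref <- rowMeans(lg)                     # log of geometric-mean pseudo-reference
  out <- counts
  for (j in seq_len(ncol(counts))) {
    M <- lg[, j] - ref
    A <- (lg[, j] + ref) / 2
    fit <- stats::lowess(A, M, f = span, iter = iter)
    trend <- stats::approx(fit$x, fit$y, xout = A, rule = 2, ties = mean)$y
    out[, j] <- pmax(2^(lg[, j] - trend) - 1, 0)
  }
  new_normalized(out, "lowess")
}
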