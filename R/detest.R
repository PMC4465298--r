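#' Two-group design
#'
#' @param group_a,group_b character vectors of sample ids (or integer column
#'   indices) for the two compared groups.  Both groups need at least two
#'   samples for variance estimation; two per group is explicitly supported.
#' @return An object of class `"degps_design"` with elements `group_a`,
#'   `group_b`, `n_a`, `n_b`.
#' @export
de_design <- function(group_a, group_b) {
  if (length(intersect(group_a, group_b)))
    stop("samples assigned to both groups: ",
         paste(intersect(group_a, group_b), collapse = ", "))
  if (anyDuplicated(group_a) || anyDuplicated(group_b))
    stop("duplicated sample in design")
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs >= 2 samples for variance estimation")
  structure(list(group_a = group_a, group_b = group_b,
                 n_a = length(group_a), n_b = length(group_b)),
            class = "degps_design")
}

design_indices <- function(design, counts) {
  resolve <- function(g) {
    if (is.numeric(g)) {
      if (any(g < 1 | g > ncol(counts))) stop("group index out of range")
      return(as.integer(g))
    }
    idx <- match(g, colnames(counts))
    if (anyNA(idx))
      stop("sample(s) not found in count matrix: ",
           paste(g[is.na(idx)], collapse = ", "))
    idx
  }
  list(a = resolve(design$group_a), b = resolve(design$group_b))
}

#' Remove transcripts with zero counts in every sample
#'
#' Pre-filter applied before normalization and testing: transcripts whose
#' counts are zero across all samples of the two compared groups carry no
#' information and destabilize the per-sample GP fits.
#'
#' @param counts transcripts-by-samples count matrix.
#' @param design optional [de_design()]; if given, only the design's samples
#'   are examined (and kept).
#' @return The surviving submatrix, with attribute `removed` holding the
#'   dropped transcript ids.
#' @export
filter_all_zero <- function(counts, design = NULL) {
  counts <- check_count_matrix(counts)
  if (!is.null(design)) {
    idx <- design_indices(design, counts)
    counts <- counts[, c(idx$a, idx$b), drop = FALSE]
  }
  keep <- rowSums(counts) > 0
  out <- counts[keep, , drop = FALSE]
  attr(out, "removed") <- rownames(counts)[!keep]
  out
}

#' Welch T statistic
#'
#' \deqn{T = \frac{\bar x - \bar y}{\sqrt{s_x^2/n_x + s_y^2/n_y}}}
#' with unbiased (n-1) sample variances.  Returns `NA` when both group
#' variances are zero (the statistic is undefined there).
#'
#' @param x,y numeric vectors of normalized values, each of length >= 2.
#' @return A single real, or `NA_real_` if undefined.
#' @examples
#' t_statistic(c(2, 4), c(1, 3))  # 1/sqrt(2)
#' @export
t_statistic <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("both groups need >= 2 values")
  se2 <- stats::var(x) / length(x) + stats::var(y) / length(y)
  if (se2 == 0) return(NA_real_)
  (mean(x) - mean(y)) / sqrt(se2)
}

#' Row-wise Welch T statistics
#'
#' Vectorized [t_statistic()] over every row of a matrix: the workhorse of
#' the permutation engine.
#'
#' @param M normalized transcripts-by-samples matrix.
#' @param idx_a,idx_b column indices of the two groups (each of size >= 2).
#' @return Numeric vector of per-row statistics, `NA` where both group
#'   variances are zero.
#' @export
row_t_statistic <- function(M, idx_a, idx_b) {
  na <- length(idx_a); nb <- length(idx_b)
  A <- M[, idx_a, drop = FALSE]; B <- M[, idx_b, drop = FALSE]
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- (rowSums(A * A) - na * ma^2) / (na - 1)
  vb <- (rowSums(B * B) - nb * mb^2) / (nb - 1)
  va <- pmax(va, 0); vb <- pmax(vb, 0)    # guard roundoff negatives
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  t[se2 == 0] <- NA_real_
  t
}

#' Regularized (variance-shrunk) T statistic, row-wise
#'
#' Per-transcript group variances are replaced by convex combinations of the
#' transcript's own variance and the median variance across transcripts,
#' with a James-Stein-style weight estimated from the spread of the variances
#' (per group): \eqn{w = \min(1, \sum \widehat{Var}(s_g^2) / \sum (s_g^2 -
#' median)^2)} where \eqn{\widehat{Var}(s^2) = 2 s^4/(n-1)} under
#' approximate normality.  `shrink = 0` recovers the ordinary Welch T;
#' `shrink = 1` gives every transcript the pooled (median) variance.
#'
#' @param M normalized transcripts-by-samples matrix.
#' @param idx_a,idx_b column indices of the two groups.
#' @param shrink optional fixed shrinkage weight in `[0, 1]`; `NULL`
#'   (default) estimates it from the data, separately per group.
#' @return Numeric vector of moderated T statistics, `NA` where undefined.
#' @export
row_regularized_t <- function(M, idx_a, idx_b, shrink = NULL) {
  na <- length(idx_a); nb <- length(idx_b)
  A <- M[, idx_a, drop = FALSE]; B <- M[, idx_b, drop = FALSE]
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- pmax((rowSums(A * A) - na * ma^2) / (na - 1), 0)
  vb <- pmax((rowSums(B * B) - nb * mb^2) / (nb - 1), 0)
  shrunk <- function(v, n) {
    target <- stats::median(v)
    w <- if (is.null(shrink)) {
      ss <- sum((v - target)^2)
      if (ss == 0) 1 else min(1, sum(2 * v^2 / (n - 1)) / ss)
    } else shrink
    w * target + (1 - w) * v
  }
  va <- shrunk(va, na); vb <- shrunk(vb, nb)
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  t[se2 == 0] <- NA_real_
  t
}

# All choose(n, n_a) group-A index sets as an n x P 0/1 matrix (columns =
# assignments), or a seeded without-replacement sample of max_perms of them.
# The identity assignment (observed grouping) is excluded when drop_identity.
permutation_assignments <- function(n, idx_a, max_perms, seed = NULL,
                                    drop_identity = TRUE) {
  n_a <- length(idx_a)
  total <- choose(n, n_a)
  n_avail <- total - as.integer(drop_identity)
  if (n_avail < 1L)
    stop("degenerate design: no non-identity permutation exists")
  is_identity <- function(cols) length(cols) == n_a && all(sort(cols) == sort(idx_a))
  if (total <= max(max_perms + 1, 1e6)) {
    combs <- utils::combn(n, n_a)
    if (drop_identity) {
      id <- apply(combs, 2L, is_identity)
      combs <- combs[, !id, drop = FALSE]
    }
    if (ncol(combs) > max_perms) {
      if (!is.null(seed)) set.seed(seed)
      combs <- combs[, sample.int(ncol(combs), max_perms), drop = FALSE]
      exhaustive <- FALSE
    } else exhaustive <- TRUE
  } else {
    # universe too large to enumerate: rejection-sample distinct subsets
    if (!is.null(seed)) set.seed(seed)
    seen <- new.env(hash = TRUE)
    combs <- matrix(0L, n_a, 0L)
    while (ncol(combs) < max_perms) {
      cand <- sort(sample.int(n, n_a))
      key <- paste(cand, collapse = ",")
      if (drop_identity && is_identity(cand)) next
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      combs <- cbind(combs, cand)
    }
    exhaustive <- FALSE
  }
  list(assignments = combs, exhaustive = exhaustive)
}

#' Build the pooled permutation null distribution
#'
#' Samples are reshuffled between the two groups; for every reassignment the
#' Welch T statistic is computed for every transcript, and all statistics
#' are merged - without averaging - into one pooled empirical null.  Because
#' the pool spans all transcripts, it is dense even at two samples per
#' group.  When the number of distinct assignments `choose(n, n_a)`
#' (identity excluded by default) is at most `max_perms`, all are
#' enumerated; otherwise `max_perms` distinct assignments are sampled
#' without replacement under `seed`.
#'
#' @param norm normalized transcripts-by-samples matrix.
#' @param design a [de_design()].
#' @param max_perms maximum number of reassignments (default 1000; the
#'   5-vs-5 design's 252 assignments are enumerated exhaustively).
#' @param seed integer seed used only when sampling assignments.
#' @param include_identity keep the observed assignment in the null pool
#'   (default `FALSE`: it only re-adds the observed statistics).
#' @return An object of class `"degps_null"`: list with `pooled_stats`
#'   (numeric vector), `n_perms`, `exhaustive`, `n_dropped` (count of
#'   undefined statistics excluded from the pool).
#' @export
build_null <- function(norm, design, max_perms = 1000L, seed = NULL,
                       include_identity = FALSE) {
  idx <- design_indices(design, norm)
  M <- norm[, c(idx$a, idx$b), drop = FALSE]
  n <- ncol(M)
  perms <- permutation_assignments(n, seq_len(design$n_a), max_perms, seed,
                                   drop_identity = !include_identity)
  combs <- perms$assignments
  P <- ncol(combs)
  n_a <- design$n_a; n_b <- design$n_b
  # vectorized over permutations: group-A sums via matrix products
  W <- matrix(0, n, P)
  W[cbind(as.vector(combs), rep(seq_len(P), each = n_a))] <- 1
  tot_s  <- rowSums(M)
  tot_s2 <- rowSums(M * M)
  Sa  <- M %*% W
  Sa2 <- (M * M) %*% W
  ma <- Sa / n_a
  mb <- (tot_s - Sa) / n_b
  va <- pmax((Sa2 - n_a * ma^2) / (n_a - 1), 0)
  vb <- pmax(((tot_s2 - Sa2) - n_b * mb^2) / (n_b - 1), 0)
  se2 <- va / n_a + vb / n_b
  t <- (ma - mb) / sqrt(se2)
  t[se2 == 0] <- NA_real_
  pooled <- as.vector(t)
  n_dropped <- sum(is.na(pooled))
  structure(list(pooled_stats = pooled[!is.na(pooled)],
                 n_perms = P, exhaustive = perms$exhaustive,
                 n_dropped = n_dropped),
            class = "degps_null")
}

#' @export
print.degps_null <- function(x, ...) {
  cat(sprintf("Pooled permutation null: %d statistics from %d %s permutations",
              length(x$pooled_stats), x$n_perms,
              if (x$exhaustive) "exhaustive" else "random"))
  if (x$n_dropped) cat(sprintf(" (%d undefined statistics excluded)", x$n_dropped))
  cat("\n")
  invisible(x)
}

#' Empirical p-values from the pooled null
#'
#' Two-sided p-value for each observed statistic against the pooled null:
#' \deqn{p_g = \frac{1 + \#\{s : |s| \ge |t_g|\}}{1 + N}.}
#' The add-one convention keeps p strictly positive, as the BH step-up
#' procedure requires.  Undefined observed statistics (`NA`) get p = 1.
#'
#' @param t_obs numeric vector of observed per-transcript statistics.
#' @param null a `"degps_null"` from [build_null()] (or a plain numeric
#'   vector of pooled statistics).
#' @details The tail count treats pooled values within relative distance
#' 1e-8 of \eqn{|t_g|} as ties (counted in the numerator).  Exact ties are
#' structural here - the complement of the observed assignment sits in the
#' pool with statistic \eqn{-t_g} - and must be counted as "at least as
#' extreme" regardless of floating-point evaluation order, which also makes
#' p-values exactly invariant under rescaling of the normalized matrix.
#' @return Numeric vector of p-values in `(0, 1]`.
#' @export
empirical_pvalues <- function(t_obs, null) {
  pool <- if (inherits(null, "degps_null")) null$pooled_stats else null
  if (!length(pool)) stop("empty null pool")
  sorted <- sort(abs(pool))
  N <- length(sorted)
  # count of pool values with |s| >= |t| (to within 1e-8 relative)
  thr <- abs(t_obs) * (1 - 1e-8)
  n_less <- findInterval(thr, sorted, left.open = TRUE)
  p <- (1 + (N - n_less)) / (1 + N)
  p[is.na(t_obs)] <- 1
  p
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up procedure: sort p ascending, multiply \eqn{p_{(i)}} by
#' \eqn{m/i}, enforce monotonicity by a cumulative minimum from the largest
#' rank, cap at 1 and restore the input order.
#'
#' @param p numeric vector of p-values in `(0, 1]`.
#' @return Adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(is.na(p)) || any(p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(m / (m:1) * p[o]))[ro]
  adj
}

#' Run the full two-step differential expression pipeline
#'
#' Filters all-zero transcripts, normalizes, computes the observed Welch T
#' per transcript, builds the pooled permutation null, converts to empirical
#' two-sided p-values, BH-adjusts, and calls significance at
#' `fdr_threshold`.  Fully reproducible under `seed`.
#'
#' @param counts transcripts-by-samples nonnegative integer matrix.
#' @param design a [de_design()] naming the two groups.
#' @param method normalization method (see [normalize_counts()]).
#' @param max_perms maximum permutations for the null (default 1000).
#' @param fdr_threshold adjusted-p cutoff for significance calls
#'   (default 0.05).
#' @param seed integer seed (used when permutations are subsampled).
#' @param statistic `"t"` (ordinary Welch, default) or `"regularized-t"`
#'   (variance-shrunk; see [row_regularized_t()]).
#' @return An object of class `"degps_result"`: list with `table` (a
#'   data.frame: transcript_id, t_stat, p_value, p_adjusted, significant),
#'   `null` (the `"degps_null"`), `normalized`, `method`, `removed`
#'   (filtered transcript ids), `fdr_threshold`.
#' @examples
#' set.seed(7)
#' counts <- matrix(rnbinom(2000, mu = 50, size = 5), 200, 10,
#'                  dimnames = list(paste0("t", 1:200), paste0("s", 1:10)))
#' des <- de_design(paste0("s", 1:5), paste0("s", 6:10))
#' res <- run_degps(counts, des, method = "gp-theta", seed = 1)
#' head(res$table)
#' @export
run_degps <- function(counts, design,
                      method = c("gp-theta", "gp-quantile", "global",
                                 "quantile", "tmm", "lowess"),
                      max_perms = 1000L, fdr_threshold = 0.05, seed = NULL,
                      statistic = c("t", "regularized-t")) {
  method <- match.arg(method)
  statistic <- match.arg(statistic)
  counts <- check_count_matrix(counts)
  filtered <- filter_all_zero(counts, design)
  removed <- attr(filtered, "removed")
  norm <- normalize_counts(filtered, method)
  idx <- design_indices(design, norm)
  stat_fun <- if (statistic == "t") row_t_statistic else row_regularized_t
  t_obs <- stat_fun(unclass(norm), idx$a, idx$b)
  null <- build_null(unclass(norm), design, max_perms = max_perms, seed = seed)
  p <- empirical_pvalues(t_obs, null)
  padj <- bh_adjust(p)
  tab <- data.frame(transcript_id = rownames(filtered),
                    t_stat = t_obs,
                    p_value = p,
                    p_adjusted = padj,
                    significant = padj < fdr_threshold,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, null = null, normalized = norm,
                 method = method, statistic = statistic,
                 removed = removed, fdr_threshold = fdr_threshold),
            class = "degps_result")
}

#' @export
print.degps_result <- function(x, ...) {
  cat(sprintf("deGPS result: %d transcripts tested (%s normalization, %s statistic)\n",
              nrow(x$table), x$method, x$statistic))
  if (length(x$removed))
    cat(sprintf("  %d all-zero transcripts filtered before testing\n",
                length(x$removed)))
  cat(sprintf("  null pool: %d statistics from %d %s permutations\n",
              length(x$null$pooled_stats), x$null$n_perms,
              if (x$null$exhaustive) "exhaustive" else "random"))
  cat(sprintf("  significant at adjusted p < %g: %d\n",
              x$fdr_threshold, sum(x$table$significant)))
  invisible(x)
}
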