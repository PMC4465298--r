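#' Type I error under the null
#'
#' Proportion of transcripts with nominal p-value below `alpha`.  Defined
#' only for null scenarios; the call errors if any transcript is truly DE.
#'
#' @param p_values nominal p-values.
#' @param truth logical vector (or `degps_simdata` truth data.frame) of true
#'   DE status; must be all `FALSE`.
#' @param alpha nominal level (default 0.05).
#' @return Proportion in `[0, 1]`.
#' @export
type_i_error <- function(p_values, truth, alpha = 0.05) {
  is_de <- if (is.data.frame(truth)) truth$is_de else as.logical(truth)
  if (length(is_de) != length(p_values)) stop("truth/p length mismatch")
  if (any(is_de)) stop("type I error is defined under the null only")
  mean(p_values < alpha)
}

#' Observed FDR and TPR of a call set
#'
#' Calls are transcripts with adjusted p below `alpha`.  FDR is the
#' proportion of calls that are truly non-DE (0 when there are no calls, by
#' convention); TPR is the proportion of truly DE transcripts called.
#'
#' @param adjusted_p adjusted p-values.
#' @param truth logical vector (or truth data.frame) of true DE status.
#' @param alpha significance level on the adjusted scale (default 0.05).
#' @return List with elements `fdr`, `tpr`, `n_called`, `n_true_de`.
#' @export
fdr_tpr <- function(adjusted_p, truth, alpha = 0.05) {
  is_de <- if (is.data.frame(truth)) truth$is_de else as.logical(truth)
  if (!length(is_de)) stop("empty truth")
  if (length(is_de) != length(adjusted_p)) stop("truth/p length mismatch")
  called <- adjusted_p < alpha
  n_called <- sum(called)
  fdr <- if (n_called == 0) 0 else sum(called & !is_de) / n_called
  tpr <- if (!any(is_de)) NA_real_ else sum(called & is_de) / sum(is_de)
  list(fdr = fdr, tpr = tpr, n_called = n_called, n_true_de = sum(is_de))
}

#' Partial AUC of the ROC curve below an FPR cutoff
#'
#' Transcripts are ranked by `scores` (smaller = stronger DE call, e.g.
#' nominal p-values).  The step ROC is integrated by the trapezoidal rule
#' over FPR in `[0, fpr_max]`; tied scores contribute a single diagonal
#' segment (equivalent to averaging over all tie-consistent orderings).
#'
#' @param scores numeric scores, smaller meaning more significant.
#' @param truth logical vector (or truth data.frame) of true DE status;
#'   both classes must be present.
#' @param fpr_max FPR cutoff (default 0.05).
#' @param normalized if `TRUE` (default) divide by `fpr_max` so a perfect
#'   ranking scores 1; if `FALSE` return the raw area (maximum `fpr_max`).
#' @return Partial AUC.
#' @export
partial_auc <- function(scores, truth, fpr_max = 0.05, normalized = TRUE) {
  is_de <- if (is.data.frame(truth)) truth$is_de else as.logical(truth)
  if (length(is_de) != length(scores)) stop("truth/score length mismatch")
  n_pos <- sum(is_de); n_neg <- sum(!is_de)
  if (n_pos == 0 || n_neg == 0)
    stop("partial AUC needs both DE and non-DE transcripts")
  o <- order(scores)
  s <- scores[o]; lab <- is_de[o]
  # collapse tie blocks: each block is one diagonal ROC segment
  blocks <- cumsum(!duplicated(s))
  tp <- c(0, cumsum(unname(tapply(lab, blocks, sum))))
  fp <- c(0, cumsum(unname(tapply(!lab, blocks, sum))))
  tpr <- tp / n_pos
  fpr <- fp / n_neg
  # clip the polyline at fpr_max by linear interpolation
  area <- 0
  for (i in seq_len(length(fpr) - 1L)) {
    x0 <- fpr[i]; x1 <- fpr[i + 1L]
    y0 <- tpr[i]; y1 <- tpr[i + 1L]
    if (x0 >= fpr_max) break
    if (x1 > fpr_max) {
      y1 <- y0 + (y1 - y0) * (fpr_max - x0) / (x1 - x0)
      x1 <- fpr_max
    }
    area <- area + (x1 - x0) * (y0 + y1) / 2
  }
  if (normalized) area / fpr_max else area
}

#' Evaluate one DE result against known truth
#'
#' Convenience wrapper collecting [type_i_error()] (null scenarios only),
#' [fdr_tpr()] and [partial_auc()] into one row of metrics.
#'
#' @param result a `"degps_result"` from [run_degps()].
#' @param truth truth data.frame (`transcript_id`, `is_de`, `direction`) as
#'   produced by the simulators; matched to the result by transcript id.
#' @param alpha significance level (default 0.05).
#' @return A one-row data.frame: `type_i_error` (NA unless null scenario),
#'   `fdr`, `tpr`, `pauc` (NA unless both classes present), `n_called`,
#'   `n_true_de`.
#' @export
evaluate_de <- function(result, truth, alpha = 0.05) {
  stopifnot(inherits(result, "degps_result"))
  tab <- result$table
  m <- match(tab$transcript_id, truth$transcript_id)
  if (anyNA(m)) stop("truth is missing tested transcripts")
  is_de <- truth$is_de[m]
  t1 <- if (any(is_de)) NA_real_ else type_i_error(tab$p_value, is_de, alpha)
  ft <- fdr_tpr(tab$p_adjusted, is_de, alpha)
  pauc <- if (any(is_de) && any(!is_de))
    partial_auc(tab$p_value, is_de) else NA_real_
  data.frame(type_i_error = t1, fdr = ft$fdr, tpr = ft$tpr, pauc = pauc,
             n_called = ft$n_called, n_true_de = ft$n_true_de)
}
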