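#' Generalized Poisson parameter container
#'
#' Validates and stores the parameter pair \eqn{(\theta, \lambda)} of the
#' generalized Poisson (GP) distribution
#' \deqn{P(X = x) = \theta (\theta + x\lambda)^{x-1} e^{-\theta - x\lambda} / x!}
#' with \eqn{\theta > 0} and \eqn{\max(-1, -\theta/q) \le \lambda \le 1}.
#' When \eqn{\lambda < 0} the support is truncated at \eqn{q}, the largest
#' positive integer with \eqn{\theta + q\lambda > 0}; parameter pairs implying
#' \eqn{q < 4} are rejected.  The distribution has mean
#' \eqn{\theta(1-\lambda)^{-1}} and variance \eqn{\theta(1-\lambda)^{-3}}:
#' \eqn{\lambda > 0} gives overdispersion, \eqn{\lambda = 0} recovers the
#' Poisson.
#'
#' @param theta positive real; mean of the underlying Poisson process
#'   (read-count units).
#' @param lambda real dispersion parameter in \eqn{[\max(-1,-\theta/q), 1]}.
#' @return An object of class `"gp_params"`: a list with elements `theta`,
#'   `lambda`, `q` (truncation bound, `Inf` when `lambda >= 0`), `mean` and
#'   `variance` (finite only for `lambda < 1`).
#' @examples
#' p <- gp_params(theta = 2, lambda = 0.5)
#' p$mean      # 4
#' p$variance  # 16
#' @export
gp_params <- function(theta, lambda) {
  stopifnot(is.numeric(theta), length(theta) == 1L,
            is.numeric(lambda), length(lambda) == 1L)
  if (!is.finite(theta) || theta <= 0)
    stop("invalid GP parameters: theta must be a positive finite real (theta = ",
         format(theta), ")")
  if (!is.finite(lambda) || lambda > 1)
    stop("invalid GP parameters: lambda must satisfy lambda <= 1 (lambda = ",
         format(lambda), ")")
  if (lambda < 0) {
    if (lambda < -1)
      stop("invalid GP parameters: lambda must satisfy lambda >= -1 (lambda = ",
           format(lambda), ")")
    # q = largest positive integer with theta + q*lambda > 0
    q <- ceiling(theta / (-lambda)) - 1L
    if (theta + q * lambda <= 0) q <- q - 1L      # boundary exactness guard
    if (q < 4)
      stop("invalid GP parameters: truncation bound q = ", q,
           " < 4 (requires theta + 4*lambda > 0 when lambda < 0)")
    if (lambda < max(-1, -theta / q))
      stop("invalid GP parameters: lambda below max(-1, -theta/q)")
  } else {
    q <- Inf
  }
  mu  <- if (lambda < 1) theta / (1 - lambda)   else Inf
  v   <- if (lambda < 1) theta / (1 - lambda)^3 else Inf
  structure(list(theta = theta, lambda = lambda, q = q, mean = mu, variance = v),
            class = "gp_params")
}

#' @export
print.gp_params <- function(x, ...) {
  cat(sprintf("Generalized Poisson parameters: theta = %.6g, lambda = %.6g\n",
              x$theta, x$lambda))
  cat(sprintf("  mean = %.6g, variance = %.6g", x$mean, x$variance))
  if (is.finite(x$q)) cat(sprintf(", support truncated at q = %d", x$q))
  cat("\n")
  invisible(x)
}

as_gp_params <- function(params) {
  if (inherits(params, "gp_params")) return(params)
  if (is.numeric(params) && length(params) == 2L)
    return(gp_params(params[[1L]], params[[2L]]))
  stop("params must be a 'gp_params' object or a numeric (theta, lambda) pair")
}

#' Generalized Poisson probability mass function
#'
#' Computed in log space: factorials via `lgamma`, the \eqn{(\theta+x\lambda)^{x-1}}
#' factor as \eqn{(x-1)\log(\theta+x\lambda)}, so counts of order 1e5 do not
#' overflow.  For `lambda < 0` the pmf is 0 above the truncation bound `q`.
#'
#' @param x vector of nonnegative integers.
#' @param params a [gp_params()] object (or a numeric `(theta, lambda)` pair).
#' @param log_p return log probabilities.
#' @return Probabilities (or log probabilities) of the same length as `x`.
#' @examples
#' dgp(0, gp_params(2, 0.3))   # exp(-2)
#' dgp(0:5, gp_params(2, 0))   # Poisson(2) pmf
#' @export
dgp <- function(x, params, log_p = FALSE) {
  p <- as_gp_params(params)
  stopifnot(is.numeric(x))
  if (any(x < 0 | x != floor(x), na.rm = TRUE))
    stop("x must contain nonnegative integers")
  th <- p$theta; lam <- p$lambda
  arg <- th + x * lam
  ok  <- arg > 0 & (is.infinite(p$q) | x <= p$q)
  lp  <- rep(-Inf, length(x))
  xs  <- x[ok]
  lp[ok] <- log(th) + (xs - 1) * log(th + xs * lam) - th - xs * lam - lgamma(xs + 1)
  if (log_p) lp else exp(lp)
}

#' Generalized Poisson cumulative distribution function
#'
#' By default uses the strict convention \eqn{P(X < x)} that the GP-Quantile
#' normalization maps counts through; `lower = "le"` gives \eqn{P(X \le x)}
#' and `lower = "mid"` the mid-probability
#' \eqn{P(X < x) + P(X = x)/2}.  For `lambda < 0` the truncated pmf mass
#' (which sums to slightly less than 1 over `0..q`) is renormalized so the
#' CDF reaches exactly 1 at `q`.
#'
#' @param x vector of nonnegative integers.
#' @param params a [gp_params()] object.
#' @param lower one of `"strict"` (\eqn{P(X<x)}, default), `"le"`, `"mid"`.
#' @return Probabilities in `[0, 1]`, same length as `x`.
#' @examples
#' pgp(3, gp_params(2, 0))                # P(X < 3) = Poisson P(X <= 2)
#' pgp(3, gp_params(2, 0), lower = "le")
#' @export
pgp <- function(x, params, lower = c("strict", "le", "mid")) {
  p <- as_gp_params(params)
  lower <- match.arg(lower)
  stopifnot(is.numeric(x))
  if (any(x < 0 | x != floor(x), na.rm = TRUE))
    stop("x must contain nonnegative integers")
  if (length(x) == 0L) return(numeric(0))
  xmax <- max(x, 0L)
  if (is.finite(p$q)) xmax <- min(xmax, p$q)
  pmf <- dgp(0:xmax, p)
  if (is.finite(p$q)) {
    # truncated support: renormalize over the full support 0..q
    total <- sum(dgp(0:p$q, p))
    pmf <- pmf / total
  }
  cdf_le <- cumsum(pmf)                   # P(X <= k), k = 0..xmax
  xi <- pmin(x, xmax)
  le     <- cdf_le[xi + 1L]
  strict <- le - pmf[xi + 1L]
  beyond <- x > xmax                      # only when q is finite and x > q
  le[beyond] <- 1
  strict[beyond] <- 1
  out <- switch(lower,
                strict = strict,
                le     = le,
                mid    = (strict + le) / 2)
  pmin(pmax(out, 0), 1)
}

#' Generalized Poisson log-likelihood
#'
#' Sum of log pmf values of `counts` under `params`.  Counts outside the
#' support (possible only when `lambda < 0`) make the data impossible and the
#' function returns `-Inf`.
#'
#' @param counts nonnegative integer vector.
#' @param params a [gp_params()] object.
#' @return A single real, `-Inf` if any count is outside the support.
#' @export
gp_loglik <- function(counts, params) {
  p <- as_gp_params(params)
  sum(dgp(counts, p, log_p = TRUE))
}

# Corrected GP estimating equation for lambda (Consul's MLE form):
#   sum_i Xi*(Xi - 1) / (Xbar + (Xi - Xbar)*lambda) - n*Xbar = 0
# Aggregated over unique count values for speed on long vectors.
gp_score <- function(lambda, vals, wts, xbar, n) {
  denom <- xbar + (vals - xbar) * lambda
  sum(wts * vals * (vals - 1) / denom) - n * xbar
}

#' Maximum-likelihood fit of the generalized Poisson distribution
#'
#' Solves the MLE estimating equation for \eqn{\lambda},
#' \deqn{\sum_i \frac{X_i(X_i - 1)}{\bar X + (X_i - \bar X)\hat\lambda} - n\bar X = 0,}
#' by bracketed root finding over the admissible range, then sets
#' \eqn{\hat\theta = \bar X (1 - \hat\lambda)}.  If no sign change is
#' bracketed (boundary cases), falls back to bounded likelihood maximization
#' via [stats::optimize()].  \eqn{\hat\lambda} is capped at `1 - 1e-6` so the
#' implied mean and variance remain finite, and bounded below so the fitted
#' support covers the data with truncation bound `q >= 4`.
#'
#' @param counts nonnegative integer vector, `length >= 2`, with nonzero
#'   variance and at least one positive count.
#' @param tol absolute tolerance for the root of the estimating equation.
#' @return A [gp_params()] object with extra fields `n`, `xbar`,
#'   `converged`, and `score` (estimating-equation value at the solution).
#' @examples
#' set.seed(1)
#' x <- rgp(gp_params(2, 0.5), 5000)
#' fit_gp_mle(x)
#' @export
fit_gp_mle <- function(counts, tol = 1e-8) {
  stopifnot(is.numeric(counts))
  counts <- as.numeric(counts)
  n <- length(counts)
  if (n < 2L) stop("GP fit requires at least 2 counts")
  if (any(counts < 0 | counts != floor(counts)))
    stop("counts must be nonnegative integers")
  xbar <- mean(counts)
  if (xbar == 0)
    stop("GP fit failed: all counts are zero; filter this sample before fitting")
  if (stats::var(counts) == 0)
    stop("GP fit failed: counts have zero variance; filter this sample before fitting")

  tab  <- table(counts)
  vals <- as.numeric(names(tab))
  wts  <- as.numeric(tab)
  eps  <- 1e-6
  xmax <- max(vals)

  # denominators must stay positive: for lambda < 0 this requires
  # lambda > -xbar / (xmax - xbar); also keep the truncated support valid
  # (theta + 4*lambda > 0 with theta = xbar*(1 - lambda)).
  lo <- -1 + eps
  if (xmax > xbar) lo <- max(lo, -xbar / (xmax - xbar) + eps)
  if (xbar < 4)    lo <- max(lo, -xbar / (4 - xbar) + eps)
  hi <- 1 - eps

  f_lo <- gp_score(lo, vals, wts, xbar, n)
  f_hi <- gp_score(hi, vals, wts, xbar, n)
  if (is.finite(f_lo) && is.finite(f_hi) && f_lo * f_hi < 0) {
    root <- stats::uniroot(gp_score, c(lo, hi), vals = vals, wts = wts,
                           xbar = xbar, n = n, tol = tol)
    lambda_hat <- root$root
    converged  <- TRUE
  } else {
    # no interior root: maximize the likelihood over the admissible range
    opt <- stats::optimize(function(l) {
      th <- xbar * (1 - l)
      if (th <= 0) return(-Inf)
      pars <- tryCatch(gp_params(th, l), error = function(e) NULL)
      if (is.null(pars)) return(-Inf)
      gp_loglik(counts, pars)
    }, interval = c(lo, hi), maximum = TRUE, tol = tol)
    lambda_hat <- opt$maximum
    converged  <- FALSE
  }
  lambda_hat <- min(lambda_hat, 1 - 1e-6)
  theta_hat  <- xbar * (1 - lambda_hat)
  out <- gp_params(theta_hat, lambda_hat)
  out$n     <- n
  out$xbar  <- xbar
  out$converged <- converged
  out$score <- gp_score(lambda_hat, vals, wts, xbar, n)
  out
}

#' Random draws from the generalized Poisson distribution
#'
#' For `0 <= lambda < 1` uses the exact Lagrangian (branching-process)
#' representation: a Poisson(`theta`) number of ancestors, each spawning a
#' Poisson(`lambda`) branching cascade; the total progeny count is GP
#' distributed.  For `lambda < 0` samples by inversion of the renormalized
#' truncated pmf over `0..q`.
#'
#' @param params a [gp_params()] object.
#' @param size number of draws (positive integer).
#' @param seed optional integer seed for reproducibility.
#' @return Integer vector of `size` i.i.d. GP draws.
#' @examples
#' x <- rgp(gp_params(2, 0.5), 1000, seed = 42)
#' mean(x)  # ~ 4  = theta / (1 - lambda)
#' @export
rgp <- function(params, size, seed = NULL) {
  p <- as_gp_params(params)
  if (!is.numeric(size) || length(size) != 1L || size <= 0 || size != floor(size))
    stop("size must be a positive integer")
  if (!is.null(seed)) set.seed(seed)
  if (p$lambda >= 0) {
    if (p$lambda >= 1) stop("sampling requires lambda < 1")
    total <- gen <- stats::rpois(size, p$theta)
    active <- which(gen > 0L)
    while (length(active)) {
      offspring <- stats::rpois(length(active), p$lambda * gen[active])
      total[active] <- total[active] + offspring
      gen[active] <- offspring
      active <- active[offspring > 0L]
    }
    total
  } else {
    support <- 0:p$q
    pmf <- dgp(support, p)
    pmf <- pmf / sum(pmf)
    sample(support, size, replace = TRUE, prob = pmf)
  }
}
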