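#' Multivariate Gaussian log-likelihood specification
#'
#' Bundles a simulated vector `x`, an observation mean vector `mu` and an
#' error covariance `Sigma` for one term of the calibration objective. Under
#' the annual-independence assumption `Sigma` is diagonal; a full symmetric
#' positive-definite matrix is also accepted.
#'
#' @param x Simulated vector (length d, one entry per jointly calibrated
#'   year).
#' @param mu Observation mean vector (length d).
#' @param Sigma Covariance: a length-d vector of variances (taken as the
#'   diagonal) or a d x d symmetric positive-definite matrix.
#' @return An object of class `likelihood_spec`.
#' @export
likelihood_spec <- function(x, mu, Sigma) {
  x <- as.numeric(x); mu <- as.numeric(mu)
  d <- length(x)
  if (length(mu) != d)
    stop("x and mu must have the same length", call. = FALSE)
  if (is.matrix(Sigma)) {
    if (nrow(Sigma) != d || ncol(Sigma) != d)
      stop("Sigma must be d x d", call. = FALSE)
    if (max(abs(Sigma - t(Sigma))) > 1e-8)
      stop("Sigma must be symmetric", call. = FALSE)
  } else {
    if (length(Sigma) == 1) Sigma <- rep(Sigma, d)
    if (length(Sigma) != d)
      stop("diagonal Sigma must have length d", call. = FALSE)
    Sigma <- diag(Sigma, nrow = d)
  }
  structure(list(x = x, mu = mu, Sigma = Sigma, d = d),
            class = "likelihood_spec")
}

#' Gaussian log-likelihood of one calibration term
#'
#' Evaluates -1/2 [d log(2 pi) + log|Sigma| + MD^2] where MD is the
#' Mahalanobis distance of `x` from `mu` under `Sigma`.
#'
#' @param spec A [likelihood_spec()].
#' @return The scalar log-likelihood.
#' @export
log_likelihood_term <- function(spec) {
  stopifnot(inherits(spec, "likelihood_spec"))
  ch <- tryCatch(chol(spec$Sigma), error = function(e) NULL)
  if (is.null(ch))
    stop("covariance error: Sigma is not positive definite", call. = FALSE)
  logdet <- 2 * sum(log(diag(ch)))
  r <- backsolve(ch, spec$x - spec$mu, transpose = TRUE)
  md2 <- sum(r^2)
  -0.5 * (spec$d * log(2 * pi) + logdet + md2)
}

#' Combined calibration log-likelihood
#'
#' Sums the maximum-LAI, yield (TWSO) and AGB log-likelihood terms. In the
#' calibration layer the LAI term uses the station-climatology prior (mean
#' 6.5, SD 1.5 per year) and the TWSO/AGB terms use county statistics with a
#' standard deviation of 10% of each statistical value, diagonal covariance.
#'
#' @param lai_spec,twso_spec,agb_spec [likelihood_spec()] objects sharing the
#'   same dimension d.
#' @return The scalar total log-likelihood.
#' @export
total_log_likelihood <- function(lai_spec, twso_spec, agb_spec) {
  d <- lai_spec$d
  if (twso_spec$d != d || agb_spec$d != d)
    stop("specification error: all three terms must share d", call. = FALSE)
  log_likelihood_term(lai_spec) + log_likelihood_term(twso_spec) +
    log_likelihood_term(agb_spec)
}
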