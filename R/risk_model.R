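# Two-Gaussian PRS mixture and the Gaussian absolute-risk transform.
#
# The PRS distribution in a population with prevalence pi is modelled as
#   phi(PRS) = (1 - pi) N(mu0, sigma) + pi N(mu1, sigma),
# which by Bayes' rule gives the absolute risk
#   r(PRS) = 1 / (1 + (1-pi)/pi * exp[((PRS-mu1)^2 - (PRS-mu0)^2) / (2 sigma^2)]).
# With equal variances the log-odds are linear in the PRS, which is the
# numerically stable form used here.

#' Fit the two-Gaussian PRS mixture parameters
#'
#' Estimates the control mean \eqn{\mu_0}, case mean \eqn{\mu_1}, and a
#' pooled standard deviation \eqn{\sigma} (square root of the sample-size
#' weighted average of the two group variances) from labelled PRS.  The
#' case/control SD ratio is reported as a diagnostic — the equal-variance
#' model is adequate when it is close to 1, and unequal variances can
#' produce unrealistic tail behaviour.
#'
#' @param prs numeric vector of polygenic scores.
#' @param status 0/1 case indicators (NA dropped together with the score).
#' @param pi optional externally supplied prevalence for the risk model;
#'   defaults to the sample case fraction.
#' @param disease optional label used in error messages.
#' @return an object of class \code{"risk_model_params"}: list with
#'   \code{mu0}, \code{mu1}, \code{sigma}, \code{pi}, \code{sd_ratio}
#'   (case SD / control SD), \code{sigma0}, \code{sigma1}, \code{n0},
#'   \code{n1}, \code{pi_sample}.
#' @export
fit_gaussian_params <- function(prs, status, pi = NULL, disease = NULL) {
  keep <- !is.na(status) & !is.na(prs)
  prs <- prs[keep]; status <- status[keep]
  if (!all(status %in% c(0, 1))) stop("status must be 0/1")
  if (any(!is.finite(prs))) stop("PRS must be finite")
  n1 <- sum(status == 1); n0 <- sum(status == 0)
  label <- if (is.null(disease)) "" else paste0(" for disease ", disease)
  if (n1 < 2 || n0 < 2)
    stop("need at least 2 cases and 2 controls to fit the PRS mixture",
         label, " (got ", n1, " cases, ", n0, " controls)")
  x0 <- prs[status == 0]; x1 <- prs[status == 1]
  v0 <- var(x0); v1 <- var(x1)
  pi_sample <- n1 / (n0 + n1)
  params <- list(
    mu0 = mean(x0), mu1 = mean(x1),
    sigma = sqrt((n0 * v0 + n1 * v1) / (n0 + n1)),
    sigma0 = sqrt(v0), sigma1 = sqrt(v1),
    sd_ratio = sqrt(v1 / v0),
    pi = if (is.null(pi)) pi_sample else pi,
    pi_sample = pi_sample, n0 = n0, n1 = n1
  )
  class(params) <- "risk_model_params"
  params
}

#' @export
print.risk_model_params <- function(x, ...) {
  cat(sprintf(
    "Gaussian risk model: mu0 = %.4f, mu1 = %.4f, sigma = %.4f, pi = %.4g\n",
    x$mu0, x$mu1, x$sigma, x$pi))
  cat(sprintf("  case/control SD ratio = %.3f (n1 = %d, n0 = %d)\n",
              x$sd_ratio, x$n1, x$n0))
  invisible(x)
}

#' Absolute disease risk from a PRS
#'
#' Evaluates the Gaussian risk model.  With equal variances (the default)
#' the computation uses the equivalent log-odds form
#' \deqn{\mathrm{logit}\, r = \mathrm{logit}\, \pi +
#'   \frac{\mu_1 - \mu_0}{\sigma^2}\Big(x - \frac{\mu_0 + \mu_1}{2}\Big),}
#' so extreme scores approach risk 0 or 1 smoothly without overflow.
#' An unequal-variance variant (using the fitted per-stratum SDs) is
#' available for diagnostics only.
#'
#' @param prs numeric vector of scores.
#' @param params a \code{\link{fit_gaussian_params}} result, or any list with
#'   \code{mu0}, \code{mu1}, \code{sigma}, \code{pi}.
#' @param pi optional prevalence override (e.g. a configured lifetime risk
#'   instead of the sample case fraction).
#' @param equal_variances if \code{FALSE}, use the per-stratum SDs
#'   \code{sigma0}, \code{sigma1} from \code{params}.
#' @return numeric vector of risks in (0, 1).
#' @export
#' @examples
#' p <- list(mu0 = 0, mu1 = 0.5, sigma = 1, pi = 0.2)
#' absolute_risk(0.25, p)  # midpoint of the means: exactly pi
absolute_risk <- function(prs, params, pi = NULL, equal_variances = TRUE) {
  if (params$sigma <= 0) stop("sigma must be > 0")
  pi <- if (is.null(pi)) params$pi else pi
  if (pi <= 0 || pi >= 1) stop("pi must lie strictly in (0, 1)")
  if (equal_variances) {
    logit <- qlogis(pi) +
      (params$mu1 - params$mu0) / params$sigma^2 *
      (prs - (params$mu0 + params$mu1) / 2)
  } else {
    if (is.null(params$sigma0) || is.null(params$sigma1))
      stop("unequal-variance model requires sigma0 and sigma1")
    logit <- qlogis(pi) + log(params$sigma0 / params$sigma1) +
      (prs - params$mu0)^2 / (2 * params$sigma0^2) -
      (prs - params$mu1)^2 / (2 * params$sigma1^2)
  }
  plogis(logit)
}

#' Density of the fitted two-component PRS mixture
#'
#' @param x numeric vector.
#' @param params as in \code{\link{absolute_risk}}.
#' @return mixture density values.
#' @export
mixture_density <- function(x, params) {
  (1 - params$pi) * dnorm(x, params$mu0, params$sigma) +
    params$pi * dnorm(x, params$mu1, params$sigma)
}
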