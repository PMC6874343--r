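# m-AFC psychometric function on the d-prime axis.
#
# The internal-response model: the correct alternative elicits a response
# x_C ~ N(d', 1) and each of the m-1 incorrect alternatives an independent
# x_I ~ N(0, 1); the largest internal response determines the choice.
# Probability correct is therefore
#   p(C) = \int phi(x - d') [Phi(x)]^(m-1) dx
# which reduces to Phi(d'/sqrt(2)) at m = 2 and to chance 1/m at d' = 0.

# Gauss-Hermite rule, cached after first use.  Order 64 gives < 1e-10
# absolute error against adaptive quadrature for |d'| <= 6, m <= 8 (the
# integrand is a Gaussian times a bounded monotone factor once centred).
.gh_rule <- local({
  cache <- NULL
  function(order = 64L) {
    if (is.null(cache)) cache <<- pracma::gaussHermite(order)
    cache
  }
})

.check_m <- function(m) {
  if (length(m) != 1L || !is.finite(m) || m < 2 || m != round(m))
    stop_sdtl("invalid_argument", "`m` must be a single integer >= 2, got ",
              deparse(m))
  as.integer(m)
}

#' Probability correct in an m-AFC task at a given d-prime
#'
#' Evaluates the m-alternative forced-choice psychometric function
#' \deqn{p(C) = \int_{-\infty}^{\infty} \varphi(x - d') \, \Phi(x)^{m-1} dx,}
#' the probability that the correct alternative produces the largest of
#' \eqn{m} internal responses when the correct-response distribution is
#' \eqn{N(d', 1)} and each incorrect one is \eqn{N(0, 1)}.
#'
#' The integral is evaluated by fixed-order Gauss--Hermite quadrature after
#' centring at \code{dprime}, which is deterministic and accurate to well
#' below \code{1e-9} over the working range of the package.
#'
#' @param dprime numeric vector of separations \eqn{d' = \theta - b} in
#'   d-prime units; must be finite.
#' @param m single integer \eqn{\ge 2}, the number of response alternatives.
#' @return numeric vector of probabilities in \eqn{(0, 1)}, strictly
#'   increasing in \code{dprime} and strictly decreasing in \code{m}.
#'   \code{pc_mafc(0, m)} equals chance \eqn{1/m}.
#' @seealso [dprime_mafc()] for the inverse, [mc_pc()] for the mechanistic
#'   Monte-Carlo counterpart.
#' @examples
#' pc_mafc(0, 2)                  # chance, 0.5
#' pc_mafc(2.4626, 2)             # ~ 47/49
#' pc_mafc(c(-1, 0, 1), 3)
#' @export
pc_mafc <- function(dprime, m) {
  m <- .check_m(m)
  if (!is.numeric(dprime) || anyNA(dprime) || any(!is.finite(dprime)))
    stop_sdtl("invalid_argument", "`dprime` must be finite numeric")
  gh <- .gh_rule()
  # x = dprime + sqrt(2) t turns the integral into a Hermite form
  z <- outer(dprime, sqrt(2) * gh$x, "+")
  as.vector(pnorm(z)^(m - 1L) %*% gh$w) / sqrt(pi)
}

#' d-prime achieving a given probability correct in an m-AFC task
#'
#' Inverts [pc_mafc()]: finds the unique \eqn{d'} with
#' \code{pc_mafc(dprime, m) == p}.  The root is bracketed on an expanding
#' interval (starting at \eqn{[-10, 10]}) and refined with
#' [stats::uniroot()] to a residual below \code{1e-10} in probability.
#'
#' @param p numeric vector of probabilities, each strictly inside
#'   \eqn{(0, 1)}.  Degenerate observed proportions (0 or 1) must be
#'   adjusted by the caller before inversion; see [calibrate_items()].
#' @inheritParams pc_mafc
#' @return numeric vector of d-prime values; \code{dprime_mafc(1/m, m)} is 0.
#' @examples
#' dprime_mafc(0.5, 2)            # 0
#' dprime_mafc(47/49, 2)          # 2.4626 = sqrt(2) * qnorm(47/49)
#' @export
dprime_mafc <- function(p, m) {
  m <- .check_m(m)
  if (!is.numeric(p) || anyNA(p) || any(p <= 0) || any(p >= 1))
    stop_sdtl("domain_error",
              "`p` must lie strictly inside (0, 1); adjust degenerate scores first")
  vapply(p, function(pi) {
    f <- function(d) pc_mafc(d, m) - pi
    lo <- -10; hi <- 10
    while (f(lo) > 0) {
      lo <- lo * 2
      if (lo < -1e6) stop_sdtl("domain_error", "probability too extreme to invert")
    }
    while (f(hi) < 0) {
      hi <- hi * 2
      if (hi > 1e6) stop_sdtl("domain_error", "probability too extreme to invert")
    }
    uniroot(f, c(lo, hi), tol = 1e-12)$root
  }, numeric(1))
}

# Generalised form of the choice integral, for model-comparison checks.
# The correct-alternative density may be the standard normal centred at
# dprime or a point mass at dprime; the incorrect-alternative CDF may be
# normal or logistic.  With a point mass the sifting property collapses the
# integral to cdf(dprime)^(m-1); with logistic cdf and m = 2 that is exactly
# the dichotomous Rasch probability 1/(1 + exp(-dprime)).  Continuous cases
# use adaptive quadrature (this path is diagnostic, not performance-critical).
pc_mafc_general <- function(dprime, m,
                            correct_density = c("normal", "pointmass"),
                            alternative_cdf = c("normal", "logistic")) {
  m <- .check_m(m)
  correct_density <- match.arg(correct_density)
  alternative_cdf <- match.arg(alternative_cdf)
  cdf <- switch(alternative_cdf, normal = pnorm, logistic = plogis)
  if (correct_density == "pointmass") {
    return(cdf(dprime)^(m - 1L))
  }
  vapply(dprime, function(d) {
    integrate(function(x) dnorm(x - d) * cdf(x)^(m - 1L),
              -Inf, Inf, rel.tol = 1e-12)$value
  }, numeric(1))
}
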