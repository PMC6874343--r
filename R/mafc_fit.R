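#' Fit latent item and person measures to m-AFC responses
#'
#' The main model-fitting interface.  Both methods place items and persons
#' on a common d-prime axis on which the probability of a correct response
#' by person \eqn{i} to an m-alternative item \eqn{h} is
#' \eqn{L_m(\theta_i - b_h)}, the m-AFC psychometric function ([pc_mafc()]).
#'
#' \describe{
#'   \item{\code{method = "approx"}}{Two-stage approximation: items are
#'     calibrated against the "average" person anchored at \eqn{\theta = 0}
#'     ([calibrate_items()], with Wilson confidence intervals mapped into
#'     d-prime units), then each person measure is estimated by an
#'     independent 1-D MLE ([fit_all_persons()]).}
#'   \item{\code{method = "em"}}{Alternating local MLE initialised at the
#'     two-stage solution: item measures are re-estimated given the current
#'     person measures, person measures given the current item measures,
#'     until the largest absolute parameter change falls below \code{tol}.
#'     Because the likelihood depends only on differences
#'     \eqn{\theta - b}, the origin is re-anchored after every cycle by
#'     subtracting the mean person measure from all \eqn{\theta} and all
#'     \eqn{b}, keeping the average person at \eqn{\theta = 0} without
#'     changing the likelihood.  Each half-step is an exact coordinate
#'     maximisation, so the total log-likelihood is non-decreasing along
#'     the trace.}
#' }
#'
#' @param responses a response table (see [validate_responses()]): columns
#'   \code{person_id}, \code{item_id}, \code{m}, \code{score}.
#' @param method \code{"approx"} (two-stage, the default) or \code{"em"}.
#' @param conf confidence level for item intervals; default 0.95.
#' @param tol EM stopping threshold on the maximum absolute parameter
#'   change, in d-prime units; default \code{1e-4}.
#' @param max_iter maximum number of EM cycles; default 100.  If reached
#'   without convergence the fit is returned with \code{converged = FALSE}.
#' @return an object of class \code{"mafc_fit"}: a list with components
#'   \code{items} (item-measure data frame), \code{persons} (person-measure
#'   data frame), \code{method}, \code{conf}, \code{n_iterations},
#'   \code{converged}, \code{trace} (data frame \code{iteration},
#'   \code{max_abs_change}, \code{loglik}), \code{logLik},
#'   \code{responses}, \code{call}.  Methods: \code{print}, \code{summary},
#'   \code{coef}, \code{predict}, \code{fitted}, \code{residuals},
#'   \code{simulate}, \code{logLik}, \code{nobs}, \code{plot}.
#' @examples
#' truth <- simulate_truth(n_persons = 20, n_items = 24, design = "complete",
#'                         seed = 7)
#' resp <- simulate_responses(truth)
#' fit <- mafc_fit(resp)
#' fit
#' head(coef(fit, "items"))
#' @export
mafc_fit <- function(responses, method = c("approx", "em"), conf = 0.95,
                     tol = 1e-4, max_iter = 100L) {
  method <- match.arg(method)
  responses <- validate_responses(responses)
  if (tol <= 0) stop_sdtl("invalid_argument", "`tol` must be positive")
  if (max_iter < 1) stop_sdtl("invalid_argument", "`max_iter` must be >= 1")
  items <- calibrate_items(responses, conf = conf)
  persons <- fit_all_persons(responses, items)
  ll0 <- .table_loglik(responses, persons$theta, items$b,
                       persons$person_id, items$item_id)
  if (method == "approx") {
    fit <- list(items = items, persons = persons, method = "approx",
                conf = conf, n_iterations = 0L, converged = TRUE,
                trace = data.frame(iteration = 0L, max_abs_change = NA_real_,
                                   loglik = ll0),
                logLik = ll0, responses = responses, call = match.call())
  } else {
    fit <- .fit_em(responses, items, persons, conf = conf, tol = tol,
                   max_iter = as.integer(max_iter), ll0 = ll0)
    fit$call <- match.call()
  }
  class(fit) <- "mafc_fit"
  fit
}

# Alternating item/person maximisation (local MLE), initialised at the
# two-stage solution.  Coordinate steps are exact 1-D maximisations on
# [-10, 10]; degenerate coordinates (no correct or no incorrect responses)
# sit at the bound and are flagged.
.fit_em <- function(responses, items0, persons0, conf, tol, max_iter, ll0) {
  item_ids <- items0$item_id
  person_ids <- persons0$person_id
  item_m <- items0$m
  pi_idx <- match(responses$person_id, person_ids)
  it_idx <- match(responses$item_id, item_ids)
  rows_by_item <- split(seq_len(nrow(responses)), factor(it_idx, seq_along(item_ids)))
  rows_by_person <- split(seq_len(nrow(responses)), factor(pi_idx, seq_along(person_ids)))

  theta <- persons0$theta
  b <- items0$b
  # anchor the initial state so successive parameter vectors are comparable
  shift <- mean(theta); theta <- theta - shift; b <- b - shift

  trace <- data.frame(iteration = 0L, max_abs_change = NA_real_, loglik = ll0)
  converged <- FALSE
  item_flag <- logical(length(item_ids))
  person_flag <- logical(length(person_ids))
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    prev <- c(theta, b)
    # item step: b_h maximises the likelihood of item h given current thetas
    for (h in seq_along(item_ids)) {
      r <- rows_by_item[[h]]
      s <- responses$score[r] == 1L
      thA <- theta[pi_idx[r]][s]; thB <- theta[pi_idx[r]][!s]
      g <- item_m[h]
      if (!length(thB)) { b[h] <- -.SEARCH_BOUND; item_flag[h] <- TRUE; next }
      if (!length(thA)) { b[h] <- .SEARCH_BOUND; item_flag[h] <- TRUE; next }
      ll <- function(bh) .item_loglik(bh, thA, thB, g)
      res <- .max_1d(ll)
      b[h] <- res$estimate; item_flag[h] <- res$at_bound
    }
    # person step: theta_i given current item measures
    for (i in seq_along(person_ids)) {
      r <- rows_by_person[[i]]
      groups <- .split_by_m(b[it_idx[r]], responses$m[r], responses$score[r])
      res <- .max_1d(function(th) .person_loglik(th, groups))
      theta[i] <- res$estimate; person_flag[i] <- res$at_bound
    }
    # re-anchor: mean person measure back to 0 (likelihood-invariant)
    shift <- mean(theta); theta <- theta - shift; b <- b - shift
    delta <- max(abs(c(theta, b) - prev))
    ll <- .table_loglik(responses, theta, b, person_ids, item_ids)
    trace <- rbind(trace, data.frame(iteration = iter, max_abs_change = delta,
                                     loglik = ll))
    if (delta < tol) { converged <- TRUE; break }
  }

  items <- items0
  items$b <- b
  items$degenerate_flag <- items0$degenerate_flag | item_flag
  # Wald intervals from the item-step curvature (the Wilson mapping assumes
  # all persons at theta = 0, which no longer holds after refinement)
  z <- qnorm(1 - (1 - conf) / 2)
  h_step <- 1e-3
  for (h in seq_along(item_ids)) {
    r <- rows_by_item[[h]]
    s <- responses$score[r] == 1L
    thA <- theta[pi_idx[r]][s]; thB <- theta[pi_idx[r]][!s]
    g <- item_m[h]
    if (!length(thA) || !length(thB) || item_flag[h]) {
      items$ci_low[h] <- NA_real_; items$ci_high[h] <- NA_real_; next
    }
    ll <- function(bh) .item_loglik(bh, thA, thB, g)
    info <- -(ll(b[h] + h_step) - 2 * ll(b[h]) + ll(b[h] - h_step)) / h_step^2
    se <- if (is.finite(info) && info > 0) 1 / sqrt(info) else NA_real_
    items$ci_low[h] <- b[h] - z * se
    items$ci_high[h] <- b[h] + z * se
  }
  persons <- persons0
  persons$theta <- theta
  persons$degenerate_flag <- person_flag
  for (i in seq_along(person_ids)) {
    r <- rows_by_person[[i]]
    groups <- .split_by_m(b[it_idx[r]], responses$m[r], responses$score[r])
    llf <- function(th) .person_loglik(th, groups)
    info <- -(llf(theta[i] + h_step) - 2 * llf(theta[i]) + llf(theta[i] - h_step)) /
      h_step^2
    persons$se[i] <- if (!person_flag[i] && is.finite(info) && info > 0)
      1 / sqrt(info) else NA_real_
  }
  list(items = items, persons = persons, method = "em", conf = conf,
       n_iterations = iter, converged = converged, trace = trace,
       logLik = trace$loglik[nrow(trace)], responses = responses)
}

.item_loglik <- function(bh, theta_correct, theta_incorrect, m) {
  ll <- 0
  if (length(theta_correct)) {
    p <- pc_mafc(theta_correct - bh, m)
    ll <- ll + sum(log(pmax(p, .P_EPS)))
  }
  if (length(theta_incorrect)) {
    p <- pc_mafc(theta_incorrect - bh, m)
    ll <- ll + sum(log(pmax(1 - p, .P_EPS)))
  }
  ll
}

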