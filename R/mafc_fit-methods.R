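# S3 methods for "mafc_fit" objects.

#' @export
print.mafc_fit <- function(x, ...) {
  cat("m-AFC latent-measure fit, method = \"", x$method, "\"\n", sep = "")
  cat(sprintf("  %d items, %d persons, %d responses\n",
              nrow(x$items), nrow(x$persons), nrow(x$responses)))
  cat(sprintf("  log-likelihood: %.4f\n", x$logLik))
  if (x$method == "em")
    cat(sprintf("  EM: %d iteration(s), %s (final max change %.2g)\n",
                x$n_iterations,
                if (x$converged) "converged" else "NOT converged",
                x$trace$max_abs_change[nrow(x$trace)]))
  invisible(x)
}

#' Summarise an m-AFC latent-measure fit
#'
#' @param object a \code{"mafc_fit"} object.
#' @param ... unused.
#' @return an object of class \code{"summary.mafc_fit"} with measure ranges,
#'   degenerate counts and convergence information.
#' @export
summary.mafc_fit <- function(object, ...) {
  s <- list(
    method = object$method,
    n_items = nrow(object$items),
    n_persons = nrow(object$persons),
    n_responses = nrow(object$responses),
    m_values = sort(unique(object$items$m)),
    item_range = range(object$items$b),
    person_range = range(object$persons$theta),
    mean_person_se = mean(object$persons$se, na.rm = TRUE),
    degenerate_items = sum(object$items$degenerate_flag),
    degenerate_persons = sum(object$persons$degenerate_flag),
    logLik = object$logLik,
    n_iterations = object$n_iterations,
    converged = object$converged
  )
  class(s) <- "summary.mafc_fit"
  s
}

#' @export
print.summary.mafc_fit <- function(x, ...) {
  cat("m-AFC latent-measure fit, method = \"", x$method, "\"\n", sep = "")
  cat(sprintf("  responses: %d (%d items with m in {%s}, %d persons)\n",
              x$n_responses, x$n_items, paste(x$m_values, collapse = ", "),
              x$n_persons))
  cat(sprintf("  item measures b:   [%.3f, %.3f] d' (%d degenerate)\n",
              x$item_range[1], x$item_range[2], x$degenerate_items))
  cat(sprintf("  person measures:   [%.3f, %.3f] d' (%d degenerate)\n",
              x$person_range[1], x$person_range[2], x$degenerate_persons))
  cat(sprintf("  mean person SE:    %.3f d'\n", x$mean_person_se))
  cat(sprintf("  log-likelihood:    %.4f\n", x$logLik))
  if (x$method == "em")
    cat(sprintf("  EM iterations:     %d (%s)\n", x$n_iterations,
                if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Extract measures from an m-AFC fit
#'
#' @param object a \code{"mafc_fit"} object.
#' @param what \code{"items"}, \code{"persons"} or \code{"both"} (default);
#'   items are \eqn{b} in d-prime units, persons \eqn{\theta}.
#' @param ... unused.
#' @return a named numeric vector, or a list of two for \code{"both"}.
#' @export
coef.mafc_fit <- function(object, what = c("both", "items", "persons"), ...) {
  what <- match.arg(what)
  items <- stats::setNames(object$items$b, object$items$item_id)
  persons <- stats::setNames(object$persons$theta, object$persons$person_id)
  switch(what, items = items, persons = persons,
         both = list(items = items, persons = persons))
}

#' @export
logLik.mafc_fit <- function(object, ...) {
  structure(object$logLik,
            df = nrow(object$items) + nrow(object$persons) - 1L,
            nobs = nrow(object$responses), class = "logLik")
}

#' @export
nobs.mafc_fit <- function(object, ...) nrow(object$responses)

#' Predicted probability correct from an m-AFC fit
#'
#' @param object a \code{"mafc_fit"} object.
#' @param newdata data frame with columns \code{person_id} and
#'   \code{item_id} (ids must be known to the fit); defaults to the
#'   training responses.
#' @param ... unused.
#' @return numeric vector of probabilities \eqn{L_m(\hat\theta_i - \hat b_h)}.
#' @export
predict.mafc_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$responses
  ii <- match(newdata$item_id, object$items$item_id)
  pi <- match(newdata$person_id, object$persons$person_id)
  if (anyNA(ii))
    stop_sdtl("reference_error", "unknown item_id: ",
              paste(unique(newdata$item_id[is.na(ii)]), collapse = ", "))
  if (anyNA(pi))
    stop_sdtl("reference_error", "unknown person_id: ",
              paste(unique(newdata$person_id[is.na(pi)]), collapse = ", "))
  d <- object$persons$theta[pi] - object$items$b[ii]
  m <- object$items$m[ii]
  p <- numeric(length(d))
  for (g in unique(m)) p[m == g] <- pc_mafc(d[m == g], g)
  p
}

#' @export
fitted.mafc_fit <- function(object, ...) predict(object)

#' Residuals of an m-AFC fit
#'
#' @param object a \code{"mafc_fit"} object.
#' @param type \code{"response"} (score minus fitted probability),
#'   \code{"pearson"} or \code{"deviance"}.
#' @param ... unused.
#' @return numeric vector, one element per training response.
#' @export
residuals.mafc_fit <- function(object,
                               type = c("response", "pearson", "deviance"),
                               ...) {
  type <- match.arg(type)
  p <- pmin(pmax(fitted(object), .P_EPS), 1 - .P_EPS)
  s <- object$responses$score
  switch(type,
         response = s - p,
         pearson = (s - p) / sqrt(p * (1 - p)),
         deviance = sign(s - p) * sqrt(-2 * (s * log(p) + (1 - s) * log(1 - p))))
}

#' Simulate response tables from a fitted model
#'
#' Draws Bernoulli scores at the fitted probabilities for the training
#' (person, item) pairs, in the style of [stats::simulate()].
#'
#' @param object a \code{"mafc_fit"} object.
#' @param nsim number of replicate tables.
#' @param seed integer seed (RNG state is restored on exit as in
#'   \code{stats::simulate}); \code{NULL} uses the current state.
#' @param ... unused.
#' @return data frame of \code{nsim} score columns \code{sim_1, ...}, with
#'   the (person, item, m) layout of the training table as attributes-free
#'   companion columns available via \code{object$responses}.
#' @export
simulate.mafc_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      set.seed(NULL)
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  p <- fitted(object)
  out <- as.data.frame(lapply(seq_len(nsim), function(k)
    stats::rbinom(length(p), 1L, p)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot an m-AFC latent-measure fit
#'
#' Two base-graphics panels: item measures in rank order with their
#' confidence intervals, and person measures with one-standard-error bars.
#' Both share the d-prime axis, so item difficulty and person ability are
#' directly comparable (more negative items are easier; \eqn{b = 0} is
#' chance for the average person).
#'
#' @param x a \code{"mafc_fit"} object.
#' @param ... passed on to [graphics::plot()].
#' @return \code{x}, invisibly.
#' @export
plot.mafc_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  it <- x$items[order(x$items$b), ]
  graphics::plot(it$b, seq_len(nrow(it)), pch = 16, cex = 0.6,
                 xlab = "item measure b (d')", ylab = "item rank",
                 main = "Items", ...)
  graphics::segments(it$ci_low, seq_len(nrow(it)), it$ci_high)
  graphics::abline(v = 0, lty = 3)
  pe <- x$persons[order(x$persons$theta), ]
  graphics::plot(pe$theta, seq_len(nrow(pe)), pch = 16, cex = 0.6,
                 xlab = expression(paste("person measure ", theta, " (d')")),
                 ylab = "person rank", main = "Persons", ...)
  graphics::segments(pe$theta - pe$se, seq_len(nrow(pe)),
                     pe$theta + pe$se)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}
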