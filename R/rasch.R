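# Dichotomous Rasch comparator.  The Rasch model is the special case of the
# m-AFC choice integral in which the correct-alternative density is a point
# mass (Dirac delta) at theta - b and the alternative CDF is logistic: by
# the sifting property the integral collapses to 1/(1 + exp(-(theta - b))).
# Fitting here is joint maximum likelihood (JMLE): alternating damped
# Newton blocks for persons and items, mean item measure anchored at zero.

#' Dichotomous Rasch response probability
#'
#' \deqn{p(R \mid \theta, b) = \frac{e^{(\theta - b) R}}{1 + e^{\theta - b}}}
#' for a binary score \eqn{R \in \{0, 1\}}, with \eqn{\theta} and \eqn{b}
#' in logits.
#'
#' @param theta person measure (logits); recycled with \code{b}.
#' @param b item measure (logits).
#' @param score 0 or 1 (default 1).
#' @return numeric vector of probabilities.
#' @examples
#' rasch_probability(0, 0)        # 0.5
#' rasch_probability(2, 0)        # 1 / (1 + exp(-2))
#' @export
rasch_probability <- function(theta, b, score = 1) {
  if (anyNA(theta) || anyNA(b) || any(!is.finite(theta)) || any(!is.finite(b)))
    stop_sdtl("invalid_argument", "`theta` and `b` must be finite")
  if (!all(score %in% c(0, 1)))
    stop_sdtl("invalid_argument", "`score` must be 0 or 1")
  p1 <- plogis(theta - b)
  ifelse(rep_len(score, length(p1)) == 1, p1, 1 - p1)
}

#' Fit the dichotomous Rasch model by joint maximum likelihood
#'
#' Alternates damped Newton updates of all person measures (items fixed)
#' and all item measures (persons fixed) on the logistic log-likelihood;
#' each block update is step-halved until the total log-likelihood does not
#' decrease, so the likelihood is non-decreasing across iterations.  After
#' every cycle the origin is re-anchored to the conventional mean item
#' measure of zero (a likelihood-invariant translation).
#'
#' Persons and items with extreme raw scores (all correct or all incorrect)
#' have no finite MLE and are excluded, iteratively, before estimation;
#' their ids are reported in the result.
#'
#' @param responses a response table (see [validate_responses()]); the
#'   \code{m} column is ignored by the Rasch model, which conditions only
#'   on the binary scores.
#' @param tol convergence threshold on the maximum absolute parameter
#'   change in logits; default \code{1e-5}.
#' @param max_iter maximum JMLE cycles; default 500.
#' @return an object of class \code{"rasch_fit"}: list with
#'   \code{item_measures} and \code{person_measures} (named numeric, logits),
#'   \code{excluded_items}, \code{excluded_persons}, \code{anchoring}
#'   (\code{"mean-item-zero"}), \code{converged}, \code{n_iterations},
#'   \code{trace} (log-likelihood per iteration).
#' @export
rasch_fit <- function(responses, tol = 1e-5, max_iter = 500L) {
  responses <- validate_responses(responses)
  df <- responses
  excluded_persons <- character(0)
  excluded_items <- character(0)
  repeat {
    pr <- tapply(df$score, df$person_id, mean)
    bad_p <- names(pr)[pr %in% c(0, 1)]
    ir <- tapply(df$score, df$item_id, mean)
    bad_i <- names(ir)[ir %in% c(0, 1)]
    if (!length(bad_p) && !length(bad_i)) break
    excluded_persons <- c(excluded_persons, bad_p)
    excluded_items <- c(excluded_items, bad_i)
    df <- df[!(df$person_id %in% bad_p) & !(df$item_id %in% bad_i), ,
             drop = FALSE]
    if (nrow(df) == 0L)
      stop_sdtl("validation_error",
                "no estimable responses left after removing extreme scores")
  }
  person_ids <- sort(unique(df$person_id))
  item_ids <- sort(unique(df$item_id))
  pi <- match(df$person_id, person_ids)
  ii <- match(df$item_id, item_ids)
  s <- df$score
  theta <- numeric(length(person_ids))
  b <- numeric(length(item_ids))
  loglik <- function(theta, b) {
    eta <- theta[pi] - b[ii]
    sum(s * eta - log1p(exp(eta)))
  }
  ll <- loglik(theta, b)
  trace <- ll
  converged <- FALSE
  n_iter <- 0L
  for (iter in seq_len(max_iter)) {
    n_iter <- iter
    prev <- c(theta, b)
    # person block (separable, concave per coordinate)
    p <- plogis(theta[pi] - b[ii])
    grad <- as.vector(rowsum(s - p, factor(pi, seq_along(person_ids))))
    info <- as.vector(rowsum(p * (1 - p), factor(pi, seq_along(person_ids))))
    step <- pmax(pmin(grad / info, 5), -5)
    sfac <- 1
    repeat {
      cand <- theta + sfac * step
      ll_new <- loglik(cand, b)
      if (ll_new >= ll - 1e-12 || sfac < 1e-8) break
      sfac <- sfac / 2
    }
    theta <- cand; ll <- max(ll_new, ll)
    # item block
    p <- plogis(theta[pi] - b[ii])
    grad <- as.vector(rowsum(s - p, factor(ii, seq_along(item_ids))))
    info <- as.vector(rowsum(p * (1 - p), factor(ii, seq_along(item_ids))))
    step <- pmax(pmin(-grad / info, 5), -5)
    sfac <- 1
    repeat {
      cand <- b + sfac * step
      ll_new <- loglik(theta, cand)
      if (ll_new >= ll - 1e-12 || sfac < 1e-8) break
      sfac <- sfac / 2
    }
    b <- cand; ll <- max(ll_new, ll)
    # anchor: mean item measure at 0 (translation leaves likelihood fixed)
    shift <- mean(b); b <- b - shift; theta <- theta - shift
    trace <- c(trace, ll)
    if (max(abs(c(theta, b) - prev)) < tol) { converged <- TRUE; break }
  }
  structure(list(item_measures = stats::setNames(b, item_ids),
                 person_measures = stats::setNames(theta, person_ids),
                 excluded_items = unique(excluded_items),
                 excluded_persons = unique(excluded_persons),
                 anchoring = "mean-item-zero",
                 converged = converged, n_iterations = n_iter,
                 trace = trace),
            class = "rasch_fit")
}

#' @export
print.rasch_fit <- function(x, ...) {
  cat("Dichotomous Rasch fit (JMLE, mean-item-zero anchoring)\n")
  cat(sprintf("  %d items, %d persons; %s in %d iteration(s)\n",
              length(x$item_measures), length(x$person_measures),
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations))
  if (length(x$excluded_persons) || length(x$excluded_items))
    cat(sprintf("  excluded extreme scores: %d person(s), %d item(s)\n",
                length(x$excluded_persons), length(x$excluded_items)))
  invisible(x)
}

#' Linear relation between Rasch and m-AFC SDT item measures
#'
#' Regresses Rasch item measures (logits) on SDT item measures (d-prime),
#' separately within each group of items sharing the same number of
#' alternatives \eqn{m}.  Within an \eqn{m} group the two scales are close
#' to linearly related; the intercepts differ across \eqn{m} because SDT
#' anchors chance at \eqn{d' = 0} for every \eqn{m} while the Rasch logit of
#' chance depends on \eqn{m}.
#'
#' @param sdt_items item-measure table from [calibrate_items()] or
#'   [mafc_fit()] (columns \code{item_id}, \code{m}, \code{b}).
#' @param rasch a \code{"rasch_fit"} object sharing item ids.
#' @param min_items smallest group size for a reported line; default 3.
#'   Smaller groups are skipped with a warning.
#' @return data frame with one row per fitted \eqn{m} group:
#'   \code{m}, \code{slope} (logits per d-prime), \code{intercept} (logits),
#'   \code{r2}, \code{n_items}.
#' @export
compare_rasch_sdt <- function(sdt_items, rasch, min_items = 3L) {
  if (!inherits(rasch, "rasch_fit"))
    stop_sdtl("invalid_argument", "`rasch` must be a rasch_fit object")
  common <- intersect(sdt_items$item_id, names(rasch$item_measures))
  if (!length(common))
    stop_sdtl("reference_error", "no shared item ids between the two fits")
  sdt <- sdt_items[match(common, sdt_items$item_id), ]
  y <- rasch$item_measures[common]
  out <- list()
  for (g in sort(unique(sdt$m))) {
    sel <- sdt$m == g
    if (sum(sel) < min_items) {
      warning(sprintf("skipping m = %d group: only %d item(s)", g, sum(sel)),
              call. = FALSE)
      next
    }
    fit <- stats::lm(y[sel] ~ sdt$b[sel])
    out[[length(out) + 1L]] <- data.frame(
      m = as.integer(g),
      slope = unname(coef(fit)[2L]),
      intercept = unname(coef(fit)[1L]),
      r2 = suppressWarnings(summary(fit)$r.squared),
      n_items = sum(sel))
  }
  if (!length(out))
    stop_sdtl("invalid_argument", "no m group has >= ", min_items, " items")
  do.call(rbind, out)
}
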