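# Two-stage estimation: item calibration against the "average" person
# (theta = 0), then independent per-person maximum likelihood.  Both stages
# share the 1-D log-likelihood machinery also used by the EM refinement.

.SEARCH_BOUND <- 10       # d-prime search interval is [-10, 10]
.OPT_TOL <- 1e-6          # 1-D optimiser tolerance (d-prime units)
.P_EPS <- 1e-16           # likelihood clamp keeping log() finite

#' Wilson score confidence interval for a binomial proportion
#'
#' The Wilson method inverts the score test; unlike the Wald interval its
#' endpoints remain inside \eqn{(0, 1)} and behave well at extreme counts.
#' Exact endpoint values of 0 or 1 (which arise only at \code{n_correct = 0}
#' or \code{= n_total}) are nudged inward by machine epsilon so the interval
#' can always be mapped onto the d-prime axis.
#'
#' @param n_correct number of successes (0..n_total).
#' @param n_total number of trials (>= 1).
#' @param conf confidence level in (0, 1); default 0.95.
#' @return numeric vector \code{c(lower, upper)}, both strictly inside
#'   \eqn{(0, 1)} and containing \code{n_correct / n_total}.
#' @examples
#' wilson_ci(47, 49)
#' wilson_ci(0, 10)   # lower endpoint is 0-adjacent but positive
#' @export
wilson_ci <- function(n_correct, n_total, conf = 0.95) {
  if (length(n_total) != 1L || !is.finite(n_total) || n_total < 1 ||
      n_total != round(n_total))
    stop_sdtl("invalid_argument", "`n_total` must be a positive integer")
  if (length(n_correct) != 1L || !is.finite(n_correct) || n_correct < 0 ||
      n_correct > n_total || n_correct != round(n_correct))
    stop_sdtl("invalid_argument", "`n_correct` must be an integer in [0, n_total]")
  if (length(conf) != 1L || !is.finite(conf) || conf <= 0 || conf >= 1)
    stop_sdtl("invalid_argument", "`conf` must lie in (0, 1)")
  z <- qnorm(1 - (1 - conf) / 2)
  phat <- n_correct / n_total
  denom <- 1 + z^2 / n_total
  centre <- (phat + z^2 / (2 * n_total)) / denom
  half <- (z / denom) * sqrt(phat * (1 - phat) / n_total + z^2 / (4 * n_total^2))
  eps <- .Machine$double.eps
  c(max(centre - half, eps), min(centre + half, 1 - eps))
}

#' Calibrate item measures against the average person
#'
#' Treats all responses to an item as repeated measures from a single
#' "average" person anchored at \eqn{\theta = 0}, so the observed proportion
#' correct \eqn{\hat p_h} determines the item measure through
#' \eqn{\hat b_h = -d'} with \code{pc_mafc(d', m) = } \eqn{\hat p_h}.
#' Negative \eqn{b} means an easier item; \eqn{b = 0} is chance performance.
#' Wilson interval endpoints are mapped through the same inverse (the order
#' flips because \eqn{b = -d'}).
#'
#' Items with a degenerate score (0 or all correct) are given the adjusted
#' proportion \eqn{(n_c + 0.5) / (n + 1)} and flagged, keeping \eqn{b}
#' finite and ordinally consistent with neighbouring items.
#'
#' @param responses a response table: data frame with columns
#'   \code{person_id}, \code{item_id}, \code{m}, \code{score} (0/1), one row
#'   per trial, each person at most once per item.
#' @param conf confidence level for the Wilson interval; default 0.95.
#' @return data frame with one row per item (sorted by \code{item_id}):
#'   \code{item_id}, \code{m}, \code{n_correct}, \code{n_total}, \code{b},
#'   \code{ci_low}, \code{ci_high}, \code{degenerate_flag}.
#' @examples
#' r <- data.frame(person_id = paste0("P", 1:49), item_id = "I1",
#'                 m = 2, score = rep(c(1, 0), c(47, 2)))
#' calibrate_items(r)   # b = -2.4626
#' @export
calibrate_items <- function(responses, conf = 0.95) {
  responses <- validate_responses(responses)
  ids <- sort(unique(responses$item_id))
  n_correct <- as.vector(rowsum(responses$score,
                                factor(responses$item_id, levels = ids)))
  n_total <- as.vector(table(factor(responses$item_id, levels = ids)))
  m <- responses$m[match(ids, responses$item_id)]
  degenerate <- n_correct == 0L | n_correct == n_total
  p_use <- ifelse(degenerate, (n_correct + 0.5) / (n_total + 1),
                  n_correct / n_total)
  b <- numeric(length(ids))
  ci_low <- numeric(length(ids))
  ci_high <- numeric(length(ids))
  for (g in unique(m)) {
    sel <- m == g
    b[sel] <- -dprime_mafc(p_use[sel], g)
    w <- vapply(which(sel), function(i) wilson_ci(n_correct[i], n_total[i], conf),
                numeric(2))
    ci_low[sel] <- -dprime_mafc(w[2L, ], g)   # upper p -> lower b
    ci_high[sel] <- -dprime_mafc(w[1L, ], g)
  }
  data.frame(item_id = ids, m = as.integer(m),
             n_correct = as.integer(n_correct), n_total = as.integer(n_total),
             b = b, ci_low = ci_low, ci_high = ci_high,
             degenerate_flag = degenerate,
             stringsAsFactors = FALSE, row.names = NULL)
}

# Person log-likelihood at ability theta, given item measures split by m.
# groups: list of list(m=, b_correct=, b_incorrect=).
.person_loglik <- function(theta, groups) {
  ll <- 0
  for (g in groups) {
    if (length(g$b_correct)) {
      p <- pc_mafc(theta - g$b_correct, g$m)
      ll <- ll + sum(log(pmax(p, .P_EPS)))
    }
    if (length(g$b_incorrect)) {
      p <- pc_mafc(theta - g$b_incorrect, g$m)
      ll <- ll + sum(log(pmax(1 - p, .P_EPS)))
    }
  }
  ll
}

.split_by_m <- function(b, m, score) {
  lapply(unique(m), function(g) {
    sel <- m == g
    list(m = g, b_correct = b[sel & score == 1L], b_incorrect = b[sel & score == 0L])
  })
}

# Maximise a 1-D log-likelihood on [-bound, bound]; returns estimate, SE from
# a central second difference of the log-likelihood, and a boundary flag.
.max_1d <- function(loglik, bound = .SEARCH_BOUND) {
  opt <- optimize(loglik, c(-bound, bound), maximum = TRUE, tol = .OPT_TOL)
  est <- opt$maximum
  at_bound <- bound - abs(est) < 1e-3
  if (at_bound) est <- sign(est) * bound
  h <- 1e-3
  info <- -(loglik(est + h) - 2 * loglik(est) + loglik(est - h)) / h^2
  se <- if (!at_bound && is.finite(info) && info > 0) 1 / sqrt(info) else NA_real_
  list(estimate = est, se = se, at_bound = at_bound)
}

#' Maximum-likelihood person measure from scored items
#'
#' Given calibrated item measures for the items a person answered correctly
#' and incorrectly, finds the ability \eqn{\hat\theta} maximising
#' \deqn{\sum_m \Big[\sum_{b \in A_m} \log L_m(\theta - b) +
#'       \sum_{b \in B_m} \log(1 - L_m(\theta - b))\Big]}
#' where \eqn{L_m} is the m-AFC psychometric function.  The standard error
#' is \eqn{(-\ell''(\hat\theta))^{-1/2}} from a central second difference of
#' the log-likelihood (the observed-information convention).
#'
#' A person with all responses correct (or all incorrect) has no finite MLE;
#' the estimate is clamped to the search bound (\eqn{\pm 10} d-prime) and
#' flagged.
#'
#' @param correct data frame (or NULL) with columns \code{b} and \code{m}
#'   for correctly answered items.
#' @param incorrect same, for incorrectly answered items.
#' @param person_id optional identifier carried into the result.
#' @return one-row data frame: \code{person_id}, \code{n_items},
#'   \code{theta}, \code{se}, \code{degenerate_flag}.
#' @examples
#' fit_person(correct = data.frame(b = 0, m = 2),
#'            incorrect = data.frame(b = 0, m = 2))  # theta = 0
#' @export
fit_person <- function(correct = NULL, incorrect = NULL, person_id = NA_character_) {
  as_bm <- function(x) {
    if (is.null(x) || NROW(x) == 0L)
      return(data.frame(b = numeric(0), m = integer(0)))
    if (!all(c("b", "m") %in% names(x)))
      stop_sdtl("invalid_argument", "item sets need columns `b` and `m`")
    if (anyNA(x$b) || any(!is.finite(x$b)))
      stop_sdtl("invalid_argument", "item measures must be finite")
    x
  }
  correct <- as_bm(correct); incorrect <- as_bm(incorrect)
  n_items <- nrow(correct) + nrow(incorrect)
  if (n_items == 0L)
    stop_sdtl("invalid_argument", "at least one scored item is required")
  # a person with only correct (or only incorrect) responses has a likelihood
  # monotone in theta: no finite MLE exists
  if (nrow(incorrect) == 0L || nrow(correct) == 0L) {
    return(data.frame(person_id = person_id, n_items = n_items,
                      theta = if (nrow(incorrect) == 0L) .SEARCH_BOUND else -.SEARCH_BOUND,
                      se = NA_real_, degenerate_flag = TRUE,
                      stringsAsFactors = FALSE, row.names = NULL))
  }
  b <- c(correct$b, incorrect$b)
  m <- as.integer(c(correct$m, incorrect$m))
  score <- rep(c(1L, 0L), c(nrow(correct), nrow(incorrect)))
  groups <- .split_by_m(b, m, score)
  res <- .max_1d(function(theta) .person_loglik(theta, groups))
  data.frame(person_id = person_id, n_items = n_items,
             theta = res$estimate, se = res$se,
             degenerate_flag = res$at_bound,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Person measures for every person in a response table
#'
#' Applies [fit_person()] independently to each person, looking item
#' measures up in \code{items}.  Persons are independent given the item
#' measures, so the row order of \code{responses} is irrelevant.
#'
#' @inheritParams calibrate_items
#' @param items item-measure table as returned by [calibrate_items()]
#'   (columns \code{item_id}, \code{b}, \code{m}); every \code{item_id} in
#'   \code{responses} must be present.
#' @return data frame with one row per person (sorted by \code{person_id}):
#'   \code{person_id}, \code{n_items}, \code{theta}, \code{se},
#'   \code{degenerate_flag}.
#' @export
fit_all_persons <- function(responses, items) {
  responses <- validate_responses(responses)
  idx <- match(responses$item_id, items$item_id)
  if (anyNA(idx)) {
    missing <- unique(responses$item_id[is.na(idx)])
    stop_sdtl("reference_error", "no item measure for item(s): ",
              paste(missing, collapse = ", "))
  }
  b <- items$b[idx]
  pid <- factor(responses$person_id)
  rows <- split(seq_len(nrow(responses)), pid)
  out <- lapply(names(rows), function(p) {
    r <- rows[[p]]
    s <- responses$score[r] == 1L
    fit_person(correct = data.frame(b = b[r][s], m = responses$m[r][s]),
               incorrect = data.frame(b = b[r][!s], m = responses$m[r][!s]),
               person_id = p)
  })
  do.call(rbind, out)
}

#' Paired condition effect on person measures
#'
#' Mean within-person difference in ability between two matched sets of
#' person estimates (for example the two arms of a paired intervention),
#' with a normal-approximation confidence interval.
#'
#' @param persons_a,persons_b person-measure tables ([fit_all_persons()]
#'   output) covering identical \code{person_id} sets; the difference is
#'   \code{b - a}.
#' @param conf confidence level; default 0.95.
#' @return list with \code{mean} (mean \eqn{\Delta\theta}), \code{se},
#'   \code{ci_low}, \code{ci_high}, \code{n}, \code{conf}.
#' @export
summarize_paired_effect <- function(persons_a, persons_b, conf = 0.95) {
  if (anyDuplicated(persons_a$person_id) || anyDuplicated(persons_b$person_id))
    stop_sdtl("reference_error", "duplicated person_id in input")
  if (!setequal(persons_a$person_id, persons_b$person_id))
    stop_sdtl("reference_error", "person_id sets do not match")
  d <- persons_b$theta[match(persons_a$person_id, persons_b$person_id)] -
    persons_a$theta
  n <- length(d)
  se <- if (n > 1) sd(d) / sqrt(n) else NA_real_
  z <- qnorm(1 - (1 - conf) / 2)
  list(mean = mean(d), se = se,
       ci_low = mean(d) - z * se, ci_high = mean(d) + z * se,
       n = n, conf = conf)
}

# Total log-likelihood of a response table under given measures.
.table_loglik <- function(responses, theta, b, person_ids, item_ids) {
  th <- theta[match(responses$person_id, person_ids)]
  bb <- b[match(responses$item_id, item_ids)]
  d <- th - bb
  ll <- 0
  for (g in unique(responses$m)) {
    sel <- responses$m == g
    p <- pmin(pmax(pc_mafc(d[sel], g), .P_EPS), 1 - .P_EPS)
    s <- responses$score[sel]
    ll <- ll + sum(s * log(p) + (1L - s) * log(1 - p))
  }
  ll
}
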