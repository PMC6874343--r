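# Seeded generative simulator emulating the motivating study design:
# ~100 "persons" (each subject appearing once per condition of a paired
# two-condition intervention), ~192 items that are a mix of 2-AFC and 3-AFC
# tasks, and trials grouped into blocks whose parity determines which
# condition a subject sees them under.

#' Generate the latent truth behind a synthetic m-AFC study
#'
#' Persons come in matched pairs: each underlying subject contributes a
#' \code{"control"} person with ability \eqn{\theta = a_s} and a
#' \code{"treatment"} person with \eqn{\theta = a_s + } \code{condition_effect},
#' where \eqn{a_s \sim N(0, \code{theta_sd})}.  Item measures are drawn
#' \eqn{b \sim N(\code{b_mean}, \code{b_sd})} (items mostly easier than the
#' average person, as in typical clinical m-AFC batteries) and assigned a
#' number of alternatives by cycling through \code{m_levels}, so the default
#' gives one 2-AFC item for every two 3-AFC items.
#'
#' Items are partitioned into \code{n_blocks} consecutive blocks.  Under the
#' \code{"blocked"} design each subject is randomised to a block parity:
#' their treatment person responds to all odd-parity (or all even-parity)
#' blocks and their control person to the complementary blocks, so each
#' person sees exactly half the blocks and disjoint groups of persons
#' respond to disjoint item sets.  Under \code{"complete"} every person
#' responds to every item.
#'
#' @param n_persons total number of persons (2 per subject; must be even).
#'   Default 100.
#' @param n_items number of items; default 192.
#' @param design \code{"blocked"} (default) or \code{"complete"}.
#' @param m_levels integer vector cycled over items to assign the number of
#'   response alternatives; default \code{c(2, 3, 3)}.
#' @param theta_sd standard deviation of subject abilities (d-prime);
#'   default 0.8.
#' @param b_mean,b_sd mean and SD of item measures (d-prime); defaults -1
#'   and 1.
#' @param condition_effect ability shift of the treatment condition
#'   (d-prime); default 0.552.
#' @param n_blocks number of item blocks (even); default 8.
#' @param seed integer seed; the same seed reproduces the truth exactly.
#' @return an object of class \code{"simulation_truth"}: list with
#'   \code{persons} (person_id, subject_id, condition, theta),
#'   \code{items} (item_id, m, block, b), \code{condition_effect},
#'   \code{design}, \code{n_blocks}, \code{seed}.
#' @examples
#' truth <- simulate_truth(n_persons = 10, n_items = 24, seed = 1)
#' head(truth$items)
#' @export
simulate_truth <- function(n_persons = 100L, n_items = 192L,
                           design = c("blocked", "complete"),
                           m_levels = c(2L, 3L, 3L),
                           theta_sd = 0.8, b_mean = -1, b_sd = 1,
                           condition_effect = 0.552,
                           n_blocks = 8L, seed = 1L) {
  design <- match.arg(design)
  if (n_persons < 2 || n_persons %% 2 != 0)
    stop_sdtl("invalid_argument", "`n_persons` must be even (two per subject)")
  if (n_blocks < 2 || n_blocks %% 2 != 0)
    stop_sdtl("invalid_argument", "`n_blocks` must be even")
  if (n_items < n_blocks)
    stop_sdtl("invalid_argument", "need at least one item per block")
  if (any(m_levels < 2) || any(m_levels != round(m_levels)))
    stop_sdtl("invalid_argument", "`m_levels` must be integers >= 2")
  set.seed(seed)
  n_subjects <- n_persons %/% 2L
  subject_id <- sprintf("S%03d", seq_len(n_subjects))
  ability <- rnorm(n_subjects, 0, theta_sd)
  persons <- data.frame(
    person_id = c(paste0(subject_id, "_control"), paste0(subject_id, "_treatment")),
    subject_id = rep(subject_id, 2L),
    condition = rep(c("control", "treatment"), each = n_subjects),
    theta = c(ability, ability + condition_effect),
    stringsAsFactors = FALSE)
  items <- data.frame(
    item_id = sprintf("I%03d", seq_len(n_items)),
    m = as.integer(rep_len(m_levels, n_items)),
    block = rep(seq_len(n_blocks), each = ceiling(n_items / n_blocks))[seq_len(n_items)],
    b = rnorm(n_items, b_mean, b_sd),
    stringsAsFactors = FALSE)
  parity <- sample(c("odd", "even"), n_subjects, replace = TRUE)
  structure(list(persons = persons, items = items,
                 condition_effect = condition_effect, design = design,
                 n_blocks = as.integer(n_blocks),
                 treatment_parity = stats::setNames(parity, subject_id),
                 seed = as.integer(seed)),
            class = "simulation_truth")
}

# (person, item) pairs observed under the truth's design.
.design_pairs <- function(truth) {
  np <- nrow(truth$persons); ni <- nrow(truth$items)
  if (truth$design == "complete") {
    return(data.frame(p = rep(seq_len(np), each = ni),
                      i = rep(seq_len(ni), times = np)))
  }
  odd_blocks <- which(truth$items$block %% 2 == 1)
  out <- vector("list", np)
  for (p in seq_len(np)) {
    par <- truth$treatment_parity[[truth$persons$subject_id[p]]]
    # treatment persons see their subject's randomised parity; control the other
    if (truth$persons$condition[p] == "control")
      par <- if (par == "odd") "even" else "odd"
    sel <- if (par == "odd") truth$items$block %% 2 == 1 else
      truth$items$block %% 2 == 0
    out[[p]] <- data.frame(p = p, i = which(sel))
  }
  do.call(rbind, out)
}

#' Draw a synthetic response table from a simulation truth
#'
#' Two equivalent-by-construction generators:
#' \describe{
#'   \item{\code{mode = "model"}}{scores are Bernoulli draws at the model
#'     probability \code{pc_mafc(theta - b, m)};}
#'   \item{\code{mode = "mechanistic"}}{the internal-response mechanism is
#'     simulated directly: one draw \eqn{x_C \sim N(\theta - b, 1)} for the
#'     correct alternative and \eqn{m - 1} independent \eqn{N(0, 1)} draws
#'     for the incorrect ones, scoring 1 when \eqn{x_C} exceeds them all.}
#' }
#' The two modes agree in distribution, which makes the mechanistic mode an
#' independent oracle for the quadrature behind [pc_mafc()].
#'
#' @param truth a \code{"simulation_truth"} object.
#' @param mode \code{"model"} (default) or \code{"mechanistic"}.
#' @param seed integer seed for the response draws; defaults to
#'   \code{truth$seed}.  Identical truth, mode and seed give a bit-identical
#'   table.
#' @return a validated response table (columns \code{person_id},
#'   \code{item_id}, \code{m}, \code{score}).
#' @examples
#' truth <- simulate_truth(n_persons = 10, n_items = 24, seed = 1)
#' resp <- simulate_responses(truth)
#' head(resp)
#' @export
simulate_responses <- function(truth, mode = c("model", "mechanistic"),
                               seed = truth$seed) {
  if (!inherits(truth, "simulation_truth"))
    stop_sdtl("invalid_argument", "`truth` must come from simulate_truth()")
  mode <- match.arg(mode)
  pairs <- .design_pairs(truth)
  d <- truth$persons$theta[pairs$p] - truth$items$b[pairs$i]
  m <- truth$items$m[pairs$i]
  score <- integer(nrow(pairs))
  set.seed(seed)
  # draw group-by-group in a fixed group order so results are reproducible
  for (g in sort(unique(m))) {
    sel <- which(m == g)
    if (mode == "model") {
      score[sel] <- rbinom(length(sel), 1L, pc_mafc(d[sel], g))
    } else {
      xc <- rnorm(length(sel), d[sel])
      xmax <- rnorm(length(sel))
      if (g > 2L) for (k in seq_len(g - 2L)) xmax <- pmax(xmax, rnorm(length(sel)))
      score[sel] <- as.integer(xc > xmax)
    }
  }
  data.frame(person_id = truth$persons$person_id[pairs$p],
             item_id = truth$items$item_id[pairs$i],
             m = m, score = score, stringsAsFactors = FALSE)
}

#' Monte-Carlo probability correct from the internal-response mechanism
#'
#' Direct mechanistic estimate of the m-AFC psychometric function: the
#' fraction of \code{n} simulated trials in which the correct alternative's
#' internal response \eqn{N(d', 1)} exceeds all \eqn{m - 1} incorrect
#' \eqn{N(0, 1)} responses.  Serves as an independent sampling oracle for
#' the quadrature in [pc_mafc()].
#'
#' @param dprime separation in d-prime units.
#' @param m number of alternatives (integer >= 2).
#' @param n number of simulated trials.
#' @param seed integer seed; same inputs reproduce the estimate exactly.
#' @return the fraction correct, a single number in \eqn{[0, 1]}.
#' @examples
#' mc_pc(0, 2, 1e4, seed = 1)   # ~ 0.5
#' @export
mc_pc <- function(dprime, m, n, seed = 1L) {
  m <- .check_m(m)
  if (length(n) != 1L || n < 1 || n != round(n))
    stop_sdtl("invalid_argument", "`n` must be a positive integer")
  set.seed(seed)
  xc <- rnorm(n, dprime)
  xmax <- rnorm(n)
  if (m > 2L) for (k in seq_len(m - 2L)) xmax <- pmax(xmax, rnorm(n))
  mean(xc > xmax)
}

#' Write the latent truth tables of a simulation to CSV
#'
#' Produces two files: \code{<stem>_persons.csv} (person_id, subject_id,
#' condition, theta) and \code{<stem>_items.csv} (item_id, m, block, b),
#' each carrying the design, condition effect and seed in \code{#} comment
#' header lines.
#'
#' @param truth a \code{"simulation_truth"} object.
#' @param stem path stem for the two files.
#' @return character vector of the two paths, invisibly.
#' @export
write_truth <- function(truth, stem) {
  if (!inherits(truth, "simulation_truth"))
    stop_sdtl("invalid_argument", "`truth` must come from simulate_truth()")
  hdr <- sprintf("# design=%s condition_effect=%g n_blocks=%d seed=%d",
                 truth$design, truth$condition_effect, truth$n_blocks,
                 truth$seed)
  pp <- paste0(stem, "_persons.csv")
  ip <- paste0(stem, "_items.csv")
  for (x in list(list(df = truth$persons, path = pp),
                 list(df = truth$items, path = ip))) {
    con <- file(x$path, "w")
    writeLines(hdr, con)
    utils::write.csv(x$df, con, row.names = FALSE, quote = FALSE)
    close(con)
  }
  invisible(c(pp, ip))
}
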