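# Dichotomous Rasch comparator: probability, JMLE fit, SDT comparison.

test_that("rasch_probability is the logistic of theta - b", {
  expect_identical(rasch_probability(0, 0, 1), 0.5)
  expect_equal(rasch_probability(2, 0, 1), 1 / (1 + exp(-2)), tolerance = 1e-15)
  th <- c(-1, 0.5, 2); b <- c(0, 1, -1)
  expect_equal(rasch_probability(th, b, 1) + rasch_probability(th, b, 0),
               rep(1, 3), tolerance = 1e-15)
  expect_error(rasch_probability(Inf, 0), class = "sdtl_invalid_argument")
})

test_that("Rasch equals the choice model with a point-mass density and logistic CDF", {
  d <- seq(-8, 8, by = 0.4)
  lhs <- rasch_probability(d, 0, 1)
  rhs <- sdtlatent:::pc_mafc_general(d, 2, "pointmass", "logistic")
  expect_lt(max(abs(lhs - rhs)), 1e-12)
})

test_that("a fully symmetric pattern gives item measures symmetric about zero", {
  tab <- data.frame(person_id = c("P1", "P1", "P2", "P2"),
                    item_id = c("A", "B", "A", "B"),
                    m = 2L, score = c(1L, 0L, 0L, 1L))
  fit <- rasch_fit(tab)
  expect_lt(abs(sum(fit$item_measures)), 1e-8)
  expect_equal(unname(fit$item_measures["A"]), -unname(fit$item_measures["B"]),
               tolerance = 1e-8)
})

test_that("JMLE recovers Rasch-generated item measures", {
  set.seed(21)
  np <- 500; ni <- 40
  theta <- rnorm(np); b <- rnorm(ni)
  tab <- data.frame(person_id = rep(sprintf("P%03d", 1:np), each = ni),
                    item_id = rep(sprintf("I%02d", 1:ni), np),
                    m = 2L,
                    score = rbinom(np * ni, 1, plogis(rep(theta, each = ni) -
                                                        rep(b, np))))
  fit <- rasch_fit(tab)
  expect_true(fit$converged)
  est <- fit$item_measures[sprintf("I%02d", 1:ni)]
  keep <- !is.na(est)
  expect_gt(cor(est[keep], b[keep]), 0.95)
  # anchoring and likelihood contracts
  expect_lt(abs(mean(fit$item_measures)), 1e-8)
  expect_true(all(diff(fit$trace) >= -1e-9))
  # person order is exchangeable
  fit2 <- rasch_fit(tab[sample(nrow(tab)), ])
  expect_equal(fit2$item_measures, fit$item_measures, tolerance = 1e-10)
})

test_that("extreme raw scores are excluded and reported", {
  s <- small_sim(n_persons = 10, n_items = 12)
  tab <- s$responses
  extra <- data.frame(person_id = "ACE", item_id = unique(tab$item_id),
                      m = tab$m[match(unique(tab$item_id), tab$item_id)],
                      score = 1L)
  fit <- rasch_fit(rbind(tab, extra))
  expect_true("ACE" %in% fit$excluded_persons)
  expect_false("ACE" %in% names(fit$person_measures))
})

test_that("comparison lines share slopes but not intercepts by construction", {
  b2 <- seq(-2, 1, length.out = 6)
  b3 <- seq(-2, 1, length.out = 8)
  sdt_items <- data.frame(item_id = sprintf("I%02d", 1:14),
                          m = rep(c(2L, 3L), c(6, 8)),
                          b = c(b2, b3 + 0.8))
  rasch <- structure(list(item_measures = setNames(
    c(1.3 * b2 + 0.2, 1.3 * b3 + 0.2), sdt_items$item_id)),
    class = "rasch_fit")
  # the m = 3 group's SDT values are shifted by a constant, so slopes match
  # and intercepts differ by slope * shift
  cmp <- compare_rasch_sdt(sdt_items, rasch)
  expect_identical(cmp$m, c(2L, 3L))
  expect_equal(cmp$slope[1], cmp$slope[2], tolerance = 1e-10)
  expect_equal(cmp$intercept[1] - cmp$intercept[2], 1.3 * 0.8,
               tolerance = 1e-10)
  expect_true(all(cmp$r2 > 0.999999))
  # groups below the minimum size are skipped with a warning
  expect_warning(cmp2 <- compare_rasch_sdt(sdt_items, rasch, min_items = 7L),
                 "skipping")
  expect_identical(cmp2$m, 3L)
})

test_that("SDT and Rasch item measures are linearly related on 2-AFC data", {
  truth <- simulate_truth(n_persons = 150, n_items = 64, design = "complete",
                          m_levels = 2L, b_mean = 0, b_sd = 0.8,
                          condition_effect = 0, seed = 31)
  resp <- simulate_responses(truth)
  sdt <- mafc_fit(resp)
  rasch <- rasch_fit(resp)
  cmp <- compare_rasch_sdt(sdt$items, rasch)
  # logistic-vs-normal scaling: ~1.7 logits per probit unit, and the 2-AFC
  # psychometric function compresses d' by sqrt(2), so ~1.7/sqrt(2) = 1.202
  expect_equal(cmp$slope, 1.7 / sqrt(2), tolerance = 0.15)
  expect_gt(cmp$r2, 0.98)
})

test_that("mixed-m data separate the Rasch intercepts across m groups", {
  s <- small_sim(n_persons = 60, n_items = 48, seed = 17)
  sdt <- mafc_fit(s$responses)
  rasch <- rasch_fit(s$responses)
  cmp <- compare_rasch_sdt(sdt$items, rasch)
  expect_identical(cmp$m, c(2L, 3L))
  # SDT anchors chance at d' = 0 for all m; Rasch places chance at a logit
  # that depends on m, so the intercepts must differ
  expect_gt(abs(cmp$intercept[1] - cmp$intercept[2]), 0.2)
})
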