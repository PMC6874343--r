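# Item calibration, person MLE and the paired-effect summary.

test_that("wilson_ci matches the score-test oracle and stays inside (0,1)", {
  # independent oracle: prop.test without continuity correction
  for (case in list(c(47, 49), c(3, 7), c(1, 12), c(30, 60))) {
    got <- wilson_ci(case[1], case[2], 0.95)
    ref <- suppressWarnings(prop.test(case[1], case[2], correct = FALSE)$conf.int)
    expect_equal(got, as.numeric(ref), tolerance = 1e-10)
    expect_true(got[1] < case[1] / case[2] && case[1] / case[2] < got[2])
  }
  # symmetry at phat = 0.5
  ci <- wilson_ci(5, 10)
  expect_equal(ci[1] + ci[2], 1, tolerance = 1e-12)
  # degenerate counts: endpoints nudged strictly inside (0, 1)
  lo0 <- wilson_ci(0, 10)
  expect_gt(lo0[1], 0)
  expect_lt(lo0[1], 1e-10)
  expect_lt(lo0[2], 0.5)
  hi1 <- wilson_ci(10, 10)
  expect_lt(hi1[2], 1)
  expect_error(wilson_ci(5, 0), class = "sdtl_invalid_argument")
  expect_error(wilson_ci(11, 10), class = "sdtl_invalid_argument")
  expect_error(wilson_ci(5, 10, 1), class = "sdtl_invalid_argument")
})

test_that("item calibration maps observed proportions onto the d' axis", {
  tab <- scores_table(n_correct = c(47, 44, 25, 17),
                      n_total = c(49, 46, 50, 51),
                      m = c(2, 2, 2, 3))
  items <- calibrate_items(tab)
  # closed-form oracle at m = 2: b = -sqrt(2) * qnorm(p)
  expect_equal(items$b[items$item_id == "I01"], -sqrt(2) * qnorm(47 / 49),
               tolerance = 1e-5)
  expect_equal(items$b[items$item_id == "I02"], -sqrt(2) * qnorm(44 / 46),
               tolerance = 1e-5)
  # a chance-level score maps to b = 0 for any m
  expect_equal(items$b[items$item_id == "I03"], 0, tolerance = 1e-6)
  expect_equal(items$b[items$item_id == "I04"], 0, tolerance = 1e-6)
  # interval order flips through b = -d': ci_low < b < ci_high
  expect_true(all(items$ci_low < items$b & items$b < items$ci_high))
  expect_false(any(items$degenerate_flag))
})

test_that("higher proportion correct gives a more negative item measure", {
  tab <- scores_table(n_correct = c(10, 20, 30, 39),
                      n_total = rep(40, 4), m = rep(3, 4))
  items <- calibrate_items(tab)
  expect_true(all(diff(items$b[match(sprintf("I%02d", 1:4), items$item_id)]) < 0))
})

test_that("degenerate item scores stay finite and are flagged", {
  tab <- scores_table(n_correct = c(20, 0, 19), n_total = c(20, 20, 20),
                      m = c(2, 2, 2))
  items <- calibrate_items(tab)
  expect_identical(items$degenerate_flag,
                   items$n_correct %in% c(0L, items$n_total))
  expect_true(all(is.finite(items$b)))
  # the adjusted perfect score stays ordinally below (easier than) 19/20
  expect_lt(items$b[items$item_id == "I01"], items$b[items$item_id == "I03"])
})

test_that("person MLE solves the symmetric case and flags perfect scores", {
  # one correct and one incorrect response to identical 2-AFC items: the
  # likelihood is symmetric about 0
  p <- fit_person(correct = data.frame(b = 0, m = 2),
                  incorrect = data.frame(b = 0, m = 2))
  expect_equal(p$theta, 0, tolerance = 1e-4)
  expect_false(p$degenerate_flag)
  expect_gt(p$se, 0)
  # all-correct person: likelihood increases monotonically in theta
  pc <- fit_person(correct = data.frame(b = c(0, 0.5), m = c(2, 3)))
  expect_true(pc$degenerate_flag)
  expect_equal(pc$theta, 10)
  expect_error(fit_person(), class = "sdtl_invalid_argument")
})

test_that("person MLE agrees with a dense grid-search oracle and recovers truth", {
  set.seed(11)
  n <- 50
  b <- rnorm(n)
  theta_true <- 1.0
  score <- rbinom(n, 1, pc_mafc(theta_true - b, 2))
  est <- fit_person(correct = data.frame(b = b[score == 1], m = 2),
                    incorrect = data.frame(b = b[score == 0], m = 2))
  # oracle: exhaustive grid over theta in [-6, 6], step 1e-3
  grid <- seq(-6, 6, by = 1e-3)
  ll <- vapply(grid, function(th)
    sum(log(pc_mafc(th - b[score == 1], 2))) +
      sum(log(1 - pc_mafc(th - b[score == 0], 2))), numeric(1))
  expect_lt(abs(est$theta - grid[which.max(ll)]), 2e-3)
  expect_lt(abs(est$theta - theta_true), 3 * est$se)
})

test_that("fit_all_persons is order-invariant and validates references", {
  s <- small_sim(n_persons = 10, n_items = 12)
  items <- calibrate_items(s$responses)
  persons <- fit_all_persons(s$responses, items)
  expect_identical(nrow(persons), 10L)
  expect_setequal(persons$person_id, unique(s$responses$person_id))
  shuffled <- s$responses[sample(nrow(s$responses)), ]
  expect_equal(fit_all_persons(shuffled, items), persons)
  expect_error(fit_all_persons(s$responses, items[-1, ]),
               class = "sdtl_reference_error")
  # a person whose only response is correct is degenerate
  one <- data.frame(person_id = "solo", item_id = items$item_id[1],
                    m = items$m[1], score = 1L)
  pd <- fit_all_persons(one, items)
  expect_true(pd$degenerate_flag)
})

test_that("paired effect summary recovers exact shifts", {
  s <- small_sim(n_persons = 10, n_items = 12)
  items <- calibrate_items(s$responses)
  persons <- fit_all_persons(s$responses, items)
  same <- summarize_paired_effect(persons, persons)
  expect_identical(same$mean, 0)
  shifted <- persons
  shifted$theta <- persons$theta + 0.5
  eff <- summarize_paired_effect(persons, shifted)
  expect_equal(eff$mean, 0.5, tolerance = 1e-12)
  expect_identical(eff$n, nrow(persons))
  other <- persons
  other$person_id[1] <- "someone_else"
  expect_error(summarize_paired_effect(persons, other),
               class = "sdtl_reference_error")
})

test_that("the joint likelihood is translation-invariant", {
  s <- small_sim(n_persons = 8, n_items = 10)
  items <- calibrate_items(s$responses)
  persons <- fit_all_persons(s$responses, items)
  ll <- sdtlatent:::.table_loglik(s$responses, persons$theta, items$b,
                                  persons$person_id, items$item_id)
  for (shift in c(-2, 0.37, 5)) {
    ll_shift <- sdtlatent:::.table_loglik(s$responses, persons$theta + shift,
                                          items$b + shift,
                                          persons$person_id, items$item_id)
    expect_equal(ll_shift, ll, tolerance = 1e-10)
  }
})
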