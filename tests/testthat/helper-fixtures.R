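# Programmatic fixtures shared across test files.

# Response rows realising an exact n_correct / n_total score for one item,
# answered by distinct persons.
item_score_rows <- function(item_id, n_correct, n_total, m,
                            person_prefix = item_id) {
  data.frame(person_id = sprintf("%s_P%03d", person_prefix, seq_len(n_total)),
             item_id = item_id, m = as.integer(m),
             score = rep(c(1L, 0L), c(n_correct, n_total - n_correct)),
             stringsAsFactors = FALSE)
}

# Table realising several (n_correct, n_total, m) item scores at once.
scores_table <- function(n_correct, n_total, m) {
  do.call(rbind, lapply(seq_along(n_correct), function(i)
    item_score_rows(sprintf("I%02d", i), n_correct[i], n_total[i], m[i])))
}

# A small complete-design response table with known latent truth.
small_sim <- function(n_persons = 30, n_items = 40, seed = 3, ...) {
  truth <- simulate_truth(n_persons = n_persons, n_items = n_items,
                          design = "complete", seed = seed, ...)
  list(truth = truth, responses = simulate_responses(truth))
}
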