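# CSV schemas.  Responses are long format, one row per scored trial:
#   person_id,item_id,m,score
# Measure tables mirror calibrate_items()/fit_all_persons() output.
# Missing responses are simply absent rows; the likelihoods only ever sum
# over observed trials.

.RESP_HEADER <- c("person_id", "item_id", "m", "score")

#' Validate a response table
#'
#' Checks the structural invariants every estimator relies on: required
#' columns, integer \code{m >= 2}, binary \code{score}, at most one response
#' per (person, item) pair, and a single \code{m} per item.
#'
#' @param responses data frame with columns \code{person_id},
#'   \code{item_id}, \code{m}, \code{score}.
#' @return the validated table, with \code{m} and \code{score} as integers
#'   and ids as character.
#' @export
validate_responses <- function(responses) {
  if (!is.data.frame(responses) || !all(.RESP_HEADER %in% names(responses)))
    stop_sdtl("validation_error", "responses need columns ",
              paste(.RESP_HEADER, collapse = ", "))
  df <- data.frame(person_id = as.character(responses$person_id),
                   item_id = as.character(responses$item_id),
                   m = responses$m, score = responses$score,
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0L)
    stop_sdtl("validation_error", "response table is empty")
  if (anyNA(df))
    stop_sdtl("validation_error", "response table contains missing values")
  if (any(df$m != round(df$m)) || any(df$m < 2))
    stop_sdtl("validation_error", "`m` must be an integer >= 2 in every row")
  if (!all(df$score %in% c(0, 1)))
    stop_sdtl("validation_error", "`score` must be 0 or 1 in every row")
  df$m <- as.integer(df$m)
  df$score <- as.integer(df$score)
  key <- paste(df$person_id, df$item_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key), , drop = FALSE][1L, ]
    stop_sdtl("validation_error", "duplicate response for pair (",
              dup$person_id, ", ", dup$item_id, ")")
  }
  mm <- tapply(df$m, df$item_id, function(x) length(unique(x)))
  if (any(mm > 1L))
    stop_sdtl("validation_error", "inconsistent `m` for item(s): ",
              paste(names(mm)[mm > 1L], collapse = ", "))
  df
}

#' Read a response table from CSV
#'
#' Expects the exact header \code{person_id,item_id,m,score}.  Malformed
#' rows are reported with their file line number; duplicate (person, item)
#' pairs and items with inconsistent \code{m} are rejected.
#'
#' @param path path to a comma-delimited UTF-8 file.
#' @return validated response table (see [validate_responses()]).
#' @export
read_responses <- function(path) {
  if (!file.exists(path))
    stop_sdtl("parse_error", "file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (!identical(names(df), .RESP_HEADER))
    stop_sdtl("parse_error", "header must be exactly: ",
              paste(.RESP_HEADER, collapse = ","), " in ", path)
  m <- suppressWarnings(as.numeric(df$m))
  score <- suppressWarnings(as.numeric(df$score))
  bad <- which(is.na(m) | m != round(m) | m < 2 |
                 is.na(score) | !(score %in% c(0, 1)) |
                 !nzchar(df$person_id) | !nzchar(df$item_id))
  if (length(bad))
    stop_sdtl("parse_error", "malformed row at line ", bad[1L] + 1L,
              " of ", path)
  df$m <- as.integer(m)
  df$score <- as.integer(score)
  validate_responses(df)
}

#' Write a response table to CSV
#'
#' Inverse of [read_responses()]: a write followed by a read reproduces the
#' table exactly (identifiers must not contain commas or quotes).
#'
#' @param responses validated response table.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_responses <- function(responses, path) {
  responses <- validate_responses(responses)
  utils::write.csv(responses, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Format a measure table for CSV output: numeric measure columns fixed to
# 6 decimals (locale-independent), flags as TRUE/FALSE.
.write_measures <- function(df, num_cols, path) {
  out <- df
  for (cn in num_cols) out[[cn]] <- sprintf("%.6f", df[[cn]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write item measures to CSV
#'
#' Columns: \code{item_id,m,n_correct,n_total,b,ci_low,ci_high,degenerate_flag},
#' measures printed to 6 decimals.
#' @param items item-measure table ([calibrate_items()] output).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_item_measures <- function(items, path) {
  .write_measures(items[, c("item_id", "m", "n_correct", "n_total",
                            "b", "ci_low", "ci_high", "degenerate_flag")],
                  c("b", "ci_low", "ci_high"), path)
}

#' Write person measures to CSV
#'
#' Columns: \code{person_id,n_items,theta,se,degenerate_flag}, measures
#' printed to 6 decimals.
#' @param persons person-measure table ([fit_all_persons()] output).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_person_measures <- function(persons, path) {
  .write_measures(persons[, c("person_id", "n_items", "theta", "se",
                              "degenerate_flag")],
                  c("theta", "se"), path)
}
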