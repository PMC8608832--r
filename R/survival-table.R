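#' Build a survival cohort table
#'
#' A cohort table is a tibble with one row per subject holding the
#' right-censored follow-up: `subject_id`, `time` (years, > 0), `event_code`
#' (0 = censored, 1 = primary event, 2 = competing death) and any number of
#' numeric covariate columns. The outcome the table is analysed for is
#' carried as an attribute so downstream event mapping (see
#' [event_indicator()]) is unambiguous.
#'
#' @param data a data frame with columns `subject_id`, `time`, `event_code`;
#'   all other columns are treated as covariates and must be numeric and
#'   finite.
#' @param outcome_label one of `"VA"`, `"hf_death"`, `"all_cause_death"`.
#' @return A tibble of class `cohort_table` with attribute `outcome_label`.
#' @export
cohort_table <- function(data, outcome_label = c("VA", "hf_death", "all_cause_death")) {
  outcome_label <- match.arg(outcome_label)
  data <- tibble::as_tibble(data)
  need <- c("subject_id", "time", "event_code")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(data) == 0) stop("cohort table must be non-empty", call. = FALSE)
  if (anyDuplicated(data$subject_id)) {
    stop("duplicate subject_id: ",
         paste(unique(data$subject_id[duplicated(data$subject_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(data$time)) || any(data$time <= 0)) {
    stop("`time` must be positive and finite for every subject", call. = FALSE)
  }
  if (!all(data$event_code %in% c(0L, 1L, 2L))) {
    stop("`event_code` must be 0 (censored), 1 (primary event) or 2 (competing death)",
         call. = FALSE)
  }
  covars <- setdiff(names(data), need)
  for (cv in covars) {
    if (!is.numeric(data[[cv]]) || any(!is.finite(data[[cv]]))) {
      stop("covariate `", cv, "` must be numeric and finite", call. = FALSE)
    }
  }
  data$subject_id <- as.character(data$subject_id)
  data$event_code <- as.integer(data$event_code)
  out <- data[, c(need, covars)]
  attr(out, "outcome_label") <- outcome_label
  class(out) <- c("cohort_table", class(out))
  out
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> outcome %s: %d subjects, %d primary events, %d competing deaths\n",
              attr(x, "outcome_label"), nrow(x),
              sum(x$event_code == 1L), sum(x$event_code == 2L)))
  NextMethod()
}

#' Read a survival table from delimited text
#'
#' Comma-delimited UTF-8 with a header; required columns `subject_id`,
#' `time`, `event_code`, any further columns become covariates.
#'
#' @param path path to a CSV file.
#' @inheritParams cohort_table
#' @return A [cohort_table()].
#' @export
read_survival_table <- function(path, outcome_label = "VA") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  cohort_table(df, outcome_label)
}

#' Write a survival table as delimited text
#'
#' @param cohort a [cohort_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_survival_table <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_table"))
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' Map event codes to a 0/1 event indicator for an outcome
#'
#' Ventricular arrhythmia (`"VA"`) treats code 1 as the event and codes 0
#' and 2 as censoring; `"all_cause_death"` treats codes 1 and 2 as events
#' (any terminal event counts); `"hf_death"` treats the death code 2 as the
#' event and code 1 as censoring.
#'
#' @param event_code integer vector in `{0, 1, 2}`.
#' @param outcome_label one of `"VA"`, `"hf_death"`, `"all_cause_death"`.
#' @return Integer 0/1 vector of the same length.
#' @export
event_indicator <- function(event_code,
                            outcome_label = c("VA", "hf_death", "all_cause_death")) {
  outcome_label <- match.arg(outcome_label)
  stopifnot(all(event_code %in% 0:2))
  switch(outcome_label,
         VA = as.integer(event_code == 1L),
         hf_death = as.integer(event_code == 2L),
         all_cause_death = as.integer(event_code %in% c(1L, 2L)))
}
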