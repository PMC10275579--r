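#' Validate a trial-level cohort table
#'
#' A cohort is a tidy tibble with one row per subject x session x trial and
#' columns `subject`, `session` (1 or 2), `trial` (1-based, consecutive),
#' `deck` (1-4 or letters A-D), `gain` (>= 0) and `loss` (<= 0). Every
#' subject must have session 1; session 2 may be absent (dropout). Offending
#' rows are named in validation errors.
#'
#' @param cohort a data frame of trials.
#' @return The validated cohort as a tibble, with `deck` normalized to
#'   integers 1-4 and rows sorted by subject, session, trial.
#' @export
validate_cohort <- function(cohort) {
  cohort <- tibble::as_tibble(cohort)
  need <- c("subject", "session", "trial", "deck", "gain", "loss")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols) > 0)
    abort(paste0("cohort is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  cohort$deck <- deck_index(cohort$deck)
  cohort$session <- as.integer(cohort$session)
  cohort$trial <- as.integer(cohort$trial)
  if (!all(cohort$session %in% c(1L, 2L)))
    abort("session must be 1 or 2")
  if (any(cohort$gain < 0)) abort("gain must be >= 0")
  if (any(cohort$loss > 0)) abort("loss must be <= 0")

  cohort <- dplyr::arrange(cohort, .data$subject, .data$session, .data$trial)

  key <- paste(cohort$subject, cohort$session, cohort$trial)
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    abort(paste0("duplicated (subject, session, trial) keys: ",
                 paste(head(dup, 5), collapse = "; ")))
  }

  bad <- cohort |>
    dplyr::group_by(.data$subject, .data$session) |>
    dplyr::summarise(
      ok = all(.data$trial == seq_along(.data$trial)),
      first_gap = if (all(.data$trial == seq_along(.data$trial))) NA_integer_
                  else seq_along(.data$trial)[.data$trial !=
                                              seq_along(.data$trial)][1],
      .groups = "drop"
    ) |>
    dplyr::filter(!.data$ok)
  if (nrow(bad) > 0)
    abort(paste0(
      "trial indices must be consecutive from 1; first gap at subject ",
      bad$subject[1], ", session ", bad$session[1], ", position ",
      bad$first_gap[1]))

  by_subj <- split(cohort$session, cohort$subject)
  no_s1 <- names(by_subj)[!vapply(by_subj, function(s) 1L %in% s, logical(1))]
  if (length(no_s1) > 0)
    abort(paste0("session 1 is required for every subject; missing for: ",
                 paste(head(no_s1, 5), collapse = ", ")))
  cohort
}

#' Read / write trial-level cohort data
#'
#' The on-disk dialect is a UTF-8 comma-separated file with header
#' `subject,session,trial,deck,gain,loss`. Decks may be written as 1-4 or
#' letters A-D; they are always written back as 1-4, with rows sorted by
#' subject, session, trial, so a write/read round trip is lossless.
#'
#' @param path file path.
#' @return `read_cohort()` returns a validated cohort tibble.
#' @export
read_cohort <- function(path) {
  cohort <- readr::read_csv(path, show_col_types = FALSE,
                            col_types = readr::cols(
                              subject = readr::col_character(),
                              session = readr::col_integer(),
                              trial = readr::col_integer(),
                              deck = readr::col_character(),
                              gain = readr::col_double(),
                              loss = readr::col_double()))
  validate_cohort(cohort)
}

#' @param cohort a cohort tibble (see [validate_cohort()]).
#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  cohort <- validate_cohort(cohort)
  readr::write_csv(cohort, path)
  invisible(path)
}

#' Good-deck summary scores
#'
#' The traditional IGT summary score: the proportion of trials on which an
#' advantageous ("good") deck was selected, per subject and session.
#'
#' @param cohort a cohort tibble.
#' @param good_decks decks counted as good (default C and D).
#' @return Tibble with columns `subject`, `session`, `n_trials`, `score`.
#' @export
summary_scores <- function(cohort, good_decks = c("C", "D")) {
  cohort <- validate_cohort(cohort)
  good <- deck_index(good_decks)
  cohort |>
    dplyr::group_by(.data$subject, .data$session) |>
    dplyr::summarise(n_trials = dplyr::n(),
                     score = mean(.data$deck %in% good),
                     .groups = "drop")
}

#' @param session_trials trials of a single subject-session (tibble with a
#'   `deck` column, or a deck vector).
#' @rdname summary_scores
#' @export
summary_score <- function(session_trials, good_decks = c("C", "D")) {
  deck <- if (is.data.frame(session_trials)) session_trials$deck
          else session_trials
  if (length(deck) == 0) abort("empty session: no trials")
  mean(deck_index(deck) %in% deck_index(good_decks))
}

# complete-pairs wide table of a per-subject-session metric
retest_pairs <- function(scores, value_col = "score") {
  wide <- scores |>
    dplyr::select(dplyr::all_of(c("subject", "session", value_col))) |>
    tidyr::pivot_wider(names_from = "session", values_from =
                         dplyr::all_of(value_col), names_prefix = "s") |>
    dplyr::filter(!is.na(.data$s1), !is.na(.data$s2))
  wide
}
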