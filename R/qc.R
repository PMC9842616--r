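# Participant-level quality control: the study's exclusion rules.

#' Apply the exclusion rules to a trial dataset
#'
#' Excludes participants who (1) failed the comprehension check (two or
#' more of the four questions wrong), (2) responded constantly (identical
#' response on every own-choice trial of a session), or (3) failed an
#' attention check. QC is a pure filter: retained rows are unaltered and
#' applying it twice equals applying it once.
#'
#' @param trials Long trial tibble.
#' @param comprehension_flags Tibble with `participant_id` and logical
#'   correctness columns `q1`..`q4` covering every participant in `trials`.
#' @param attention_flags Optional tibble with `participant_id` and logical
#'   `passed`; participants absent from it are treated as passed.
#' @param constant_scope `"own"` (default) checks constancy over own-choice
#'   trials per session; `"all"` widens the rule to guessing trials too.
#' @return List with `trials` (filtered) and `report`, an
#'   `exclusion_report` with counts `n_input`, `n_failed_comprehension`,
#'   `n_constant_response`, `n_failed_attention`, `n_retained` and a
#'   per-participant `flags` tibble.
#' @export
apply_exclusions <- function(trials, comprehension_flags,
                             attention_flags = NULL,
                             constant_scope = c("own", "all")) {
  constant_scope <- match.arg(constant_scope)
  ids <- unique(trials$participant_id)

  qcols <- c("q1", "q2", "q3", "q4")
  if (!all(c("participant_id", qcols) %in% names(comprehension_flags))) {
    stop("`comprehension_flags` needs columns participant_id, q1..q4.",
         call. = FALSE)
  }
  unknown <- setdiff(ids, comprehension_flags$participant_id)
  if (length(unknown) > 0) {
    stop(sprintf("Records reference participants without comprehension flags: %s.",
                 paste(utils::head(unknown, 5), collapse = ", ")),
         call. = FALSE)
  }

  comp <- comprehension_flags[match(ids, comprehension_flags$participant_id), ]
  n_wrong <- rowSums(!as.matrix(comp[, qcols]))
  failed_comprehension <- n_wrong >= 2

  scope <- if (constant_scope == "own") {
    trials[trials$response_type == "own", ]
  } else {
    trials
  }
  const_by_session <- scope |>
    dplyr::group_by(.data$participant_id, .data$session) |>
    dplyr::summarise(constant = dplyr::n_distinct(.data$response) == 1L,
                     .groups = "drop") |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(constant = any(.data$constant), .groups = "drop")
  constant_response <- ids %in%
    const_by_session$participant_id[const_by_session$constant]

  failed_attention <- if (is.null(attention_flags)) {
    rep(FALSE, length(ids))
  } else {
    passed <- attention_flags$passed[match(ids, attention_flags$participant_id)]
    !is.na(passed) & !passed
  }

  flags <- tibble::tibble(
    participant_id = ids,
    failed_comprehension = failed_comprehension,
    constant_response = constant_response,
    failed_attention = failed_attention,
    excluded = failed_comprehension | constant_response | failed_attention
  )
  keep <- flags$participant_id[!flags$excluded]

  report <- structure(list(
    n_input = length(ids),
    n_failed_comprehension = sum(failed_comprehension),
    n_constant_response = sum(constant_response),
    n_failed_attention = sum(failed_attention),
    n_retained = length(keep),
    flags = flags
  ), class = "exclusion_report")

  list(trials = trials[trials$participant_id %in% keep, ], report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat(sprintf(paste0(
    "Exclusion report: %d participants in\n",
    "  failed comprehension (>= 2 of 4 wrong): %d\n",
    "  constant responders:                    %d\n",
    "  failed attention checks:                %d\n",
    "  retained:                               %d\n"),
    x$n_input, x$n_failed_comprehension, x$n_constant_response,
    x$n_failed_attention, x$n_retained))
  invisible(x)
}
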