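# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a reproducible child seed from a master seed
#'
#' Deterministic integer hash used to give every participant (and every
#' phase within a participant) its own random substream while keeping the
#' whole simulation a pure function of one master seed. Values stay below
#' 2^31 - 1 so they are always valid R integer seeds.
#'
#' @param seed Master integer seed.
#' @param index Non-negative integer stream index.
#' @return A single integer seed.
#' @keywords internal
derive_seed <- function(seed, index) {
  m <- 2147483647
  s <- (as.double(seed) %% m) + 1
  for (k in as.double(index)) {
    s <- (s * 48271 + (k + 1) * 10007) %% m
  }
  as.integer(s)
}

# Consistent factor coding used by the models and metrics.
frame_levels <- function() c("gain", "loss")
norm_levels <- function() c("risk_averse", "risk_seeking")
domain_levels <- function() c("moral", "monetary")
phase_levels <- function() c("baseline", "learning", "ownD0", "ownD3", "othersD3")
response_levels <- function() c("certain", "gamble")

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a single finite number in [%s, %s].",
                 name, format(lower), format(upper)), call. = FALSE)
  }
  invisible(x)
}

assert_choice <- function(x, name, choices) {
  if (!is.character(x) || length(x) != 1L || !(x %in% choices)) {
    stop(sprintf("`%s` must be one of: %s (got %s).",
                 name, paste(choices, collapse = ", "),
                 paste(utils::head(as.character(x), 3), collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}
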