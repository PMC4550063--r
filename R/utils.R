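# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Presentation rounding used when printing percentages and interval bounds.
#' Unlike [base::round()], which rounds half to even (so 15.5 -> 16 but
#' 16.5 -> 16), this rounds ties upward in magnitude: 15.5 -> 16, -2.5 -> -3.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(c(15.5, 16.5, -2.63))
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Deterministic per-stage sub-seed derived from one global seed, so that
# cohort generation and pathway simulation can be re-run independently.
# Kept below 2^31 - 1 (R integers are 32-bit).
substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(as.numeric(seed)) * 48271 + h * 10007) %% 2147483647L)
}

cdss_abort <- function(msg, class) {
  stop(structure(
    class = c(class, "cdss_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Parse a semicolon-separated multi-valued CSV field into a character set.
split_multi <- function(x) {
  out <- strsplit(ifelse(is.na(x) | x == "", NA_character_, x), ";", fixed = TRUE)
  lapply(out, function(v) if (length(v) == 1L && is.na(v)) character(0) else unique(v))
}

join_multi <- function(lst) {
  vapply(lst, function(v) paste(sort(v), collapse = ";"), character(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
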