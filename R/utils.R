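# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @noRd
uns_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "uns_error")))
}

# round half-up, the convention used for all printed percentages and for
# fixture evidence planting (round(0.5) in base R rounds to even)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == as.integer(x)
}

# one scalar string, non-NA
is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
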