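# internal helpers shared across modules

#' Round half away from zero
#'
#' Base `round()` rounds half to even; survey reports and trend tables here
#' round halves away from zero (so 2.135 prints as 2.14, -2.135 as -2.14).
#'
#' @param x numeric vector.
#' @param digits integer, decimal places (default 2).
#' @return numeric vector rounded half-away-from-zero.
#' @export
#' @examples
#' round_half_out(c(0.125, -0.125), 2)
round_half_out <- function(x, digits = 2) {
  stopifnot(is.numeric(x), length(digits) == 1L, digits >= 0)
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

# Deterministic 31-bit sub-seed from a base seed plus string tags, so that
# per-(participant, week, game) streams do not depend on simulation call order.
# FNV-1a style hash; collisions are harmless (streams merely coincide).
derive_seed <- function(seed, ...) {
  tags <- paste(c(seed, ...), collapse = "\r")
  h <- 2166136261 %% 2147483647
  for (b in utf8ToInt(tags)) {
    h <- bitwXor(as.integer(h), as.integer(b))
    h <- (h * 16777619) %% 2147483647
  }
  as.integer(h %% 2147483646) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_input <- function(msg) stop(msg, call. = FALSE)

assert_cols <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort_input(sprintf("%s is missing required column(s): %s",
                        what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}
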