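# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic substream seed from a master seed and string labels.
# Polynomial hash over the master seed's digits and the labels' UTF-8 bytes,
# reduced modulo a prime below 2^31 so each (tract, feature) pair owns an RNG
# substream independent of list order. Every intermediate stays below
# 31 * 2^31 << 2^53, so the arithmetic is exact in doubles.
substream_seed <- function(master_seed, ...) {
  labels <- paste(c(...), collapse = "\r")
  h <- as.numeric(master_seed) %% 2147483629
  for (b in utf8ToInt(paste0("\a", labels))) {
    h <- (h * 31 + b) %% 2147483629
  }
  as.integer(h)
}

#' Percentage of a count with explicit rounding convention
#'
#' Computes `100 * count / total` and rounds it under an explicit convention.
#' `"half_up"` rounds halves away from zero at the requested number of decimal
#' digits (unlike [round()], which rounds halves to even); `"truncate"` drops
#' the digits beyond the requested precision without rounding.
#'
#' @param count Numerator count (non-negative).
#' @param total Denominator count (positive).
#' @param digits Decimal digits to keep (default 1).
#' @param method `"half_up"` (default) or `"truncate"`.
#' @return A numeric percentage on the 0-100 scale.
#' @examples
#' percentage(9, 441, digits = 0)              # 2
#' percentage(1, 343, digits = 2)              # 0.29
#' percentage(8, 98, digits = 1, method = "truncate")  # 8.1
#' @export
percentage <- function(count, total, digits = 1,
                       method = c("half_up", "truncate")) {
  method <- match.arg(method)
  stopifnot(is.numeric(count), is.numeric(total), all(total > 0))
  x <- 100 * count / total
  f <- 10^digits
  switch(method,
    half_up  = sign(x) * floor(abs(x) * f + 0.5) / f,
    truncate = trunc(x * f) / f
  )
}
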