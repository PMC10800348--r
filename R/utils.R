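# Internal helpers shared across modules.

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded sections do not disturb
#' the caller's RNG stream. Every stochastic component of the package draws
#' from a named sub-stream derived with [substream_seed()] so components can
#' be regenerated independently.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a named sub-stream seed from a master seed; stays below 2^31.
substream_seed <- function(seed, component) {
  h <- fnv1a32(paste0(component, ":", as.integer(seed)))
  as.integer(h %% 2147483647)
}

# FNV-1a 32-bit hash of a character string, returned as a double in [0, 2^32).
# Used for sub-stream seed derivation and run-manifest config hashes. All
# arithmetic is done in doubles with a split multiply so nothing exceeds 2^53.
fnv1a32 <- function(s) {
  bytes <- utf8ToInt(enc2utf8(paste(s, collapse = "\n")))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    h1 <- floor(h / 65536); h0 <- h %% 65536
    h <- (h0 * p + ((h1 * p) %% 65536) * 65536) %% 4294967296
  }
  h
}

config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = 12, force = TRUE)
  h <- fnv1a32(as.character(s))
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

#' Signed percent change between two values
#'
#' `100 * (comparison - reference) / reference`. This is the quantity behind
#' statements like "deforestation fell from 27.8 to 11.7 thousand km2, a 58%
#' reduction": the reported magnitude is `round_half_away(abs(...))`.
#'
#' @param reference baseline value, must be nonzero.
#' @param comparison new value.
#' @return signed percent change (not rounded).
#' @seealso [report_percent()] for the integer presentation rule.
#' @export
#' @examples
#' percent_change(27.8, 11.7)   # about -57.9
percent_change <- function(reference, comparison) {
  if (!is.numeric(reference) || !is.numeric(comparison))
    stop("percent_change() needs numeric inputs", call. = FALSE)
  if (any(reference == 0))
    stop("percent_change() undefined for a zero reference", call. = FALSE)
  100 * (comparison - reference) / reference
}

#' Round to integer percent, half away from zero
#'
#' Presentation rule for reported percentages: 57.5 -> 58, -57.5 -> -58.
#'
#' @param x numeric vector of percentages.
#' @return integer-valued numeric vector.
#' @export
report_percent <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Trailing moving average: value at i is mean(x[(i-window+1):i]); NA until the
# window is full or when any member is NA.
moving_average <- function(x, window = 4L) {
  n <- length(x)
  out <- rep(NA_real_, n)
  if (window < 1L) stop("window must be >= 1", call. = FALSE)
  for (i in seq_len(n)) {
    if (i >= window) {
      w <- x[(i - window + 1L):i]
      if (!anyNA(w)) out[i] <- mean(w)
    }
  }
  out
}

# Exact binomial central interval for a proportion: c(lo, hi) on the
# proportion scale, mass alpha/2 in each tail.
binom_interval <- function(n, p, alpha = 0.01) {
  stats::qbinom(c(alpha / 2, 1 - alpha / 2), size = n, prob = p) / n
}

`%||%` <- function(a, b) if (is.null(a)) b else a
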