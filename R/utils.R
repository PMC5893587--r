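#' @importFrom rlang .data abort warn inform %||%
#' @import dplyr
#' @importFrom tibble tibble as_tibble
NULL

# Run code under a fixed RNG seed, restoring the caller's RNG state afterwards.
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Centered moving average used throughout; exported wrapper lives in series.R.
ma_truncated <- function(x, window) {
  n <- length(x)
  h <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    xs <- x[max(1L, i - h):min(n, i + h)]
    if (all(is.na(xs))) NA_real_ else mean(xs, na.rm = TRUE)
  }, numeric(1))
}

check_window <- function(window) {
  if (length(window) != 1L || is.na(window) || window < 1 || window %% 2 == 0) {
    abort("`window` must be a single odd integer >= 1.")
  }
  as.integer(window)
}

# Significance stars matching the usual P < 0.05 / 0.01 / 0.001 convention.
p_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return("")
    if (pi < 0.001) "***" else if (pi < 0.01) "**" else if (pi < 0.05) "*" else ""
  }, character(1))
}
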