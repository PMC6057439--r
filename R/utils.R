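# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Classed error constructor so callers can distinguish failure modes
# (format, contract, geometry, ...) with expect_error(class = ...).
stop_tm <- function(msg, class, call. = FALSE) {
  cond <- structure(
    class = c(paste0("tendonmech_", class), "tendonmech_error",
              "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  )
  stop(cond)
}

warn_tm <- function(msg, class) {
  cond <- structure(
    class = c(paste0("tendonmech_", class), "tendonmech_warning",
              "warning", "condition"),
    list(message = msg, call = NULL)
  )
  warning(cond)
}

# Evaluate `code` under a fixed RNG state without disturbing the caller's
# stream. All stochastic operations in the package go through this so that
# every generator/fit is a pure function of its seed.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop_tm("`seed` must be a single integer", "contract")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# SEM over a vector; NA (missing) for n < 2 rather than an error, matching
# how single-replicate groups are reported in the deposited sheets.
sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# Full-precision numeric formatting for text round trips.
fmt_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) "NA" else format(v, digits = 17, scientific = TRUE)
  }, character(1))
}
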