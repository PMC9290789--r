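# Classed error conditions so callers and tests can discriminate failure modes.

stop_ciflow <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "ciflow_error"), call = call))
}

stop_invalid_parameter <- function(msg) stop_ciflow(msg, "ciflow_invalid_parameter")
stop_empty_input       <- function(msg) stop_ciflow(msg, "ciflow_empty_input")
stop_undefined_statistic <- function(msg) stop_ciflow(msg, "ciflow_undefined_statistic")
stop_no_threshold      <- function(msg) stop_ciflow(msg, "ciflow_no_threshold")
stop_missing_input     <- function(msg) stop_ciflow(msg, "ciflow_missing_input")
stop_schema            <- function(msg) stop_ciflow(msg, "ciflow_schema_error")
stop_parse             <- function(msg) stop_ciflow(msg, "ciflow_parse_error")
stop_validation        <- function(msg) stop_ciflow(msg, "ciflow_validation_error")
stop_numerical         <- function(msg) stop_ciflow(msg, "ciflow_numerical_error")

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop_invalid_parameter("`seed` must be a single non-missing number")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == floor(x)
}

is_proportion <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
}

`%||%` <- function(a, b) if (is.null(a)) b else a
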