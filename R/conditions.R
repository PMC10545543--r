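## Classed error conditions used across the package so callers (and tests)
## can distinguish error families without string matching.

stop_cnscreen <- function(class, msg, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "cnscreen_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

stop_invalid_design <- function(msg) stop_cnscreen("cnscreen_invalid_design", msg)
stop_config         <- function(msg) stop_cnscreen("cnscreen_config_error", msg)
stop_parse          <- function(msg) stop_cnscreen("cnscreen_parse_error", msg)
stop_format         <- function(msg) stop_cnscreen("cnscreen_format_error", msg)
stop_normalization  <- function(msg) stop_cnscreen("cnscreen_normalization_error", msg)
stop_null_build     <- function(msg) stop_cnscreen("cnscreen_null_error", msg)
stop_calling        <- function(msg) stop_cnscreen("cnscreen_calling_error", msg)
stop_degenerate     <- function(msg) stop_cnscreen("cnscreen_degenerate_input", msg)
stop_undefined_cor  <- function(msg) stop_cnscreen("cnscreen_undefined_correlation", msg)
stop_io             <- function(msg) stop_cnscreen("cnscreen_io_error", msg)

## Derive stage seeds from one master seed: hash the label into an offset so
## every stochastic stage is reproducible yet decoupled from call order.
## Kept below 2^31 - 1 so the result is a valid R integer seed.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}
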