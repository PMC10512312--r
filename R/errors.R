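# Typed condition helpers. Every malformed input raises a classed error so
# callers (and tests) can distinguish validation, format, configuration and
# I/O failures without parsing message strings.

stop_bgcrank <- function(class, message, ...) {
  cond <- structure(
    class = c(class, "bgcrank_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

stop_validation <- function(message, ...) {
  stop_bgcrank("bgcrank_validation_error", message, ...)
}

stop_format <- function(message, ...) {
  stop_bgcrank("bgcrank_format_error", message, ...)
}

stop_config <- function(message, ...) {
  stop_bgcrank("bgcrank_config_error", message, ...)
}

stop_io <- function(message, ...) {
  stop_bgcrank("bgcrank_io_error", message, ...)
}

# Re-raise a condition with the pipeline stage attached to the message.
with_stage <- function(stage, expr) {
  tryCatch(expr, bgcrank_error = function(e) {
    e$message <- sprintf("[stage %s] %s", stage, conditionMessage(e))
    e$stage <- stage
    stop(e)
  }, error = function(e) {
    stop_bgcrank("bgcrank_stage_error",
                 sprintf("[stage %s] %s", stage, conditionMessage(e)),
                 stage = stage, parent = e)
  })
}
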