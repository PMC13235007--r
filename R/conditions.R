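# Classed conditions so callers can branch on failure mode rather than
# matching message text. All inherit from "ith_error".

ith_error <- function(subclass, message, ...) {
  cond <- structure(
    class = c(subclass, "ith_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

ith_format_error      <- function(msg, ...) ith_error("ith_format_error", msg, ...)
ith_io_error          <- function(msg, ...) ith_error("ith_io_error", msg, ...)
ith_parameter_error   <- function(msg, ...) ith_error("ith_parameter_error", msg, ...)
ith_empty_roi_error   <- function(msg, ...) ith_error("ith_empty_roi_error", msg, ...)
ith_degenerate_roi_error <- function(msg, ...) ith_error("ith_degenerate_roi_error", msg, ...)
ith_integrity_error   <- function(msg, ...) ith_error("ith_integrity_error", msg, ...)
ith_degenerate_input_error  <- function(msg, ...) ith_error("ith_degenerate_input_error", msg, ...)
ith_degenerate_labels_error <- function(msg, ...) ith_error("ith_degenerate_labels_error", msg, ...)
ith_usage_error       <- function(msg, ...) ith_error("ith_usage_error", msg, ...)
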