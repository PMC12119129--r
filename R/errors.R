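# Condition classes used across the package. Every user-facing failure is a
# classed condition so the HTTP layer can map it to a status code without
# string-matching messages.
#
#   tf_invalid_input   - bad pixel data / shapes            -> 400
#   tf_bad_request     - malformed client request           -> 400
#   tf_not_found       - unknown image / tile out of range  -> 404
#   tf_store_error     - malformed or inconsistent store    -> 500
#   tf_io_error        - filesystem problems                -> 500

tf_stop <- function(message, class, ...) {
  stop(errorCondition(message, ..., class = c(class, "tf_error")))
}

stop_invalid_input <- function(message, ...) tf_stop(message, "tf_invalid_input", ...)
stop_bad_request   <- function(message, ...) tf_stop(message, "tf_bad_request", ...)
stop_not_found     <- function(message, ...) tf_stop(message, "tf_not_found", ...)
stop_store_error   <- function(message, ...) tf_stop(message, "tf_store_error", ...)
stop_io_error      <- function(message, ...) tf_stop(message, "tf_io_error", ...)

# integer coercion that refuses non-integral input
as_count <- function(x, what) {
  if (length(x) != 1L || is.na(x) || !is.numeric(x) || x != floor(x))
    stop_invalid_input(sprintf("%s must be a single integer, got %s", what,
                               paste(format(x), collapse = ",")))
  as.integer(x)
}
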