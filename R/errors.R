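# Structured condition helpers. Every user-facing failure carries a condition
# class that the HTTP facade maps onto a status code, so library use and
# protocol use fail the same way.

ehrest_error_classes <- c(
  parse_error      = 400L,
  bad_request      = 400L,
  validation_error = 400L,
  not_found        = 404L,
  conflict         = 409L,
  precondition     = 412L,
  not_acceptable   = 406L,
  method_not_allowed = 405L,
  internal         = 500L
)

stop_ehrest <- function(class, message, ...) {
  stopifnot(class %in% names(ehrest_error_classes))
  cond <- structure(
    class = c(paste0("ehrest_", class), "ehrest_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

#' HTTP status code for a condition raised by this package
#'
#' @param cond A condition object.
#' @return An integer HTTP status (500 for conditions not raised by ehrest).
#' @keywords internal
ehrest_status <- function(cond) {
  for (cl in names(ehrest_error_classes)) {
    if (inherits(cond, paste0("ehrest_", cl))) return(ehrest_error_classes[[cl]])
  }
  500L
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
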