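#' @noRd
gc_abort <- function(message, class, call = sys.call(-1)) {
  cnd <- structure(
    class = c(class, "gcorient_error", "error", "condition"),
    list(message = message, call = call)
  )
  stop(cnd)
}

#' @noRd
degenerate_geometry_error <- function(message) {
  gc_abort(message, "gcorient_degenerate_geometry")
}

#' @noRd
validation_error <- function(message) {
  gc_abort(message, "gcorient_validation_error")
}
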