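#' Condition vocabulary of the knockdown design
#'
#' The five transfection conditions of the time-course design: non-transfected
#' cells (\code{NT}), control siRNA (\code{siCTR}), the two single knockdowns
#' (\code{siCBP}, \code{siP300}) and the double knockdown
#' (\code{siCBP_P300}).
#'
#' @return Character vector of condition labels.
#' @export
kd_conditions <- function() {
  c("NT", "siCTR", "siCBP", "siP300", "siCBP_P300")
}

#' Default time-point vocabulary (transfection clock)
#'
#' Hours post transfection at which arrays were collected; \code{T0} precedes
#' the induction of differentiation. The vocabulary is configuration: every
#' reader accepts an alternative ordered set.
#'
#' @return Ordered character vector of time-point labels.
#' @export
default_timepoints <- function() {
  c("T0", "T48", "T72", "T96")
}

# classed conditions so callers can distinguish failure modes
kdtc_stop <- function(class, ..., call. = FALSE) {
  stop(errorCondition(paste0(...), class = c(class, "kdtc_error", "error")))
}

kdtc_warn <- function(class, ...) {
  warning(warningCondition(paste0(...), class = c(class, "kdtc_warning", "warning")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
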