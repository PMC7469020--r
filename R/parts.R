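#' The seven parts of the daily time-use composition
#'
#' Returns the canonical, fixed ordering of the seven activity parts used
#' throughout the package: personal care, sleep, eating, physical activity,
#' leisure screen time, work (paid and unpaid, including foodwork), and
#' socialising & hobbies. Every composition, basis and result in the
#' pipeline uses this order; the pivot ilr coordinates are defined relative
#' to it, so it must never be permuted downstream.
#'
#' @return Character vector of length 7.
#' @export
#' @examples
#' time_use_parts()
time_use_parts <- function() {
  c("personal_care", "sleep", "eating", "physical_activity",
    "screen_time", "work", "social_hobbies")
}

#' Minutes in a diary day
#' @return 1440.
#' @export
day_total <- function() 1440

# internal: check a parts vector/matrix has the canonical columns in order
check_part_names <- function(x, what = "composition") {
  nm <- if (is.matrix(x)) colnames(x) else names(x)
  if (!is.null(nm) && !identical(nm, time_use_parts())) {
    stop(what, " must use the fixed part order: ",
         paste(time_use_parts(), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

# internal: coerce vector input to a 1-row matrix, remembering shape
as_comp_matrix <- function(x) {
  if (is.matrix(x)) {
    storage.mode(x) <- "double"
    return(x)
  }
  matrix(as.numeric(x), nrow = 1, dimnames = list(NULL, names(x)))
}
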