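#' Within-trial clock of the ankle dorsiflexion paradigm
#'
#' One trial of the motor task consists of a preparation cue, a dynamic
#' dorsiflexion movement, a static hold, and rest. The default durations
#' (1, 2.5, 3, 5 seconds; 11.5 s total) are the paradigm the rest of the
#' package assumes: movement onset (t = 0 for all epoch windows) is the end
#' of the preparation phase.
#'
#' @param prep_s,dynamic_s,static_s,rest_s Phase durations in seconds; all
#'   must be strictly positive.
#' @return An object of class `trial_timing` with fields `prep_s`,
#'   `dynamic_s`, `static_s`, `rest_s`.
#' @examples
#' tm <- trial_timing()
#' timing_total(tm)  # 11.5
#' @export
trial_timing <- function(prep_s = 1, dynamic_s = 2.5, static_s = 3, rest_s = 5) {
  d <- c(prep_s = prep_s, dynamic_s = dynamic_s, static_s = static_s,
         rest_s = rest_s)
  if (!is.numeric(d) || any(!is.finite(d)) || any(d <= 0))
    stop("all trial phase durations must be finite and > 0", call. = FALSE)
  structure(as.list(d), class = "trial_timing")
}

#' Total duration of one trial
#' @param timing A [trial_timing()] object.
#' @return Total trial duration in seconds.
#' @export
timing_total <- function(timing) {
  stopifnot(inherits(timing, "trial_timing"))
  timing$prep_s + timing$dynamic_s + timing$static_s + timing$rest_s
}

#' @export
print.trial_timing <- function(x, ...) {
  cat(sprintf("<trial_timing> prep %g s | dynamic %g s | static %g s | rest %g s (total %g s)\n",
              x$prep_s, x$dynamic_s, x$static_s, x$rest_s, timing_total(x)))
  invisible(x)
}
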