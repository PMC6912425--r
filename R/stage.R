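#' Differentiation stage labels, in temporal order
#'
#' @export
STAGES <- c("non", "early", "late")

#' Assign a differentiation stage to a time point
#'
#' Samples from an MDI-induced 3T3-L1 time course are partitioned into three
#' stages by time relative to induction: `non` for 0 h and before, `early`
#' for times after 0 up to and including 48 h, and `late` for times after
#' 48 h up to the end of the protocol at 260 h. The boundaries are closed on
#' the right, so 0 h is `non` and 48 h is `early`.
#'
#' @param time_h numeric vector of time points in hours relative to
#'   induction; negative values denote pre-induction samples.
#' @return character vector of stage labels (`"non"`, `"early"`, `"late"`).
#' @examples
#' assign_stage(c(-48, 0, 4, 48, 240))
#' @export
assign_stage <- function(time_h) {
  if (!is.numeric(time_h)) stop("time_h must be numeric")
  if (anyNA(time_h)) stop("time_h contains missing values")
  if (any(time_h > 260)) {
    stop("time point(s) beyond the 260 h differentiation protocol: ",
         paste(time_h[time_h > 260], collapse = ", "))
  }
  ifelse(time_h <= 0, "non", ifelse(time_h <= 48, "early", "late"))
}
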