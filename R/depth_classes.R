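#' Canonical depth classes
#'
#' Macrophyte transects are surveyed in four fixed depth classes below the
#' water surface. Each class is represented downstream by the signed midpoint
#' of its limits (negative metres, downward), so that "0-1 m" becomes -0.5 m
#' and the open-ended ">4 m" class is placed at -5.0 m.
#'
#' @return A data.frame with columns `label` (the four canonical class labels,
#'   shallow to deep) and `midpoint` (signed depth in m).
#' @examples
#' depth_classes()
#' @export
depth_classes <- function() {
  data.frame(
    label = c("0-1", "1-2", "2-4", ">4"),
    midpoint = c(-0.5, -1.5, -3.0, -5.0),
    stringsAsFactors = FALSE
  )
}

#' Convert a depth-class label to its signed midpoint
#'
#' @param label character vector of canonical depth-class labels.
#' @return numeric vector of signed depths in metres (negative downward).
#' @examples
#' depth_midpoint(c("0-1", ">4"))
#' @export
depth_midpoint <- function(label) {
  dc <- depth_classes()
  idx <- match(label, dc$label)
  if (anyNA(idx)) {
    bad <- unique(label[is.na(idx)])
    stop("unknown depth class label(s): ", paste(bad, collapse = ", "))
  }
  dc$midpoint[idx]
}

#' Signed midpoints of the four depth classes, shallow to deep
#' @return numeric vector of length 4.
#' @export
depth_midpoints <- function() depth_classes()$midpoint
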