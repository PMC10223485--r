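#' Event class labels
#'
#' The pipeline classifies fixed-width sensor blocks into three events:
#' `NON_FALL` (activities of daily living), `PRE_FALL` (the transition from a
#' controlled to a dangerous state that may end in a fall), and `FALL` (the
#' fall itself, through ground impact). The integer codes 0/1/2 are fixed:
#' they index ensemble sub-models and per-class metric rows throughout the
#' package.
#'
#' @format Integer scalars 0, 1, 2.
#' @name class-labels
NULL

#' @rdname class-labels
#' @export
NON_FALL <- 0L

#' @rdname class-labels
#' @export
PRE_FALL <- 1L

#' @rdname class-labels
#' @export
FALL <- 2L

#' All class labels as a named integer vector
#'
#' @return Named integer vector `c(non_fall = 0L, pre_fall = 1L, fall = 2L)`.
#' @export
class_labels <- function() {
  c(non_fall = NON_FALL, pre_fall = PRE_FALL, fall = FALL)
}

#' Human-readable name of a class label
#'
#' @param label Integer label code (0, 1, or 2), vectorized.
#' @return Character vector of label names.
#' @export
label_name <- function(label) {
  nm <- names(class_labels())
  stopifnot(all(label %in% class_labels()))
  nm[label + 1L]
}

#' Default tie-break priority for block labeling and score fusion
#'
#' Severity ordering: a missed fall is costlier than a false alarm, so ties
#' resolve towards the more dangerous event.
#'
#' @return Integer vector `c(FALL, PRE_FALL, NON_FALL)`.
#' @export
default_tie_break <- function() c(FALL, PRE_FALL, NON_FALL)

validate_labels <- function(labels, what = "labels") {
  if (!is.numeric(labels) || any(is.na(labels))) {
    stop(what, " must be numeric and free of NA", call. = FALSE)
  }
  bad <- which(!(labels %in% class_labels()))
  if (length(bad) > 0L) {
    stop(
      what, " contain value(s) outside {0, 1, 2}: first offender ",
      labels[bad[1L]], " at position ", bad[1L],
      call. = FALSE
    )
  }
  as.integer(labels)
}

# Argmax over per-class values with priority-ordered tie breaking.
# `values` is indexed by class code + 1; returns a class code.
argmax_with_priority <- function(values, priority = default_tie_break()) {
  if (anyNA(values)) stop("scores contain NA/NaN", call. = FALSE)
  m <- max(values)
  tied <- which(values == m) - 1L
  if (length(tied) == 1L) return(tied)
  for (p in priority) {
    if (p %in% tied) return(as.integer(p))
  }
  tied[1L]
}
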