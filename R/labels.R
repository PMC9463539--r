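#' WHO-style radiograph class labels
#'
#' The five categories of the WHO standardized methodology for interpreting
#' paediatric chest radiographs, in the canonical order used throughout the
#' package: confusion-matrix axes, softmax output order, and argmax
#' tie-breaking all follow this order.
#'
#' @return Character vector of the five class names:
#'   `consolidation`, `other_infiltrate`, `both`, `normal`, `uninterpretable`.
#' @export
#' @examples
#' class_labels()
class_labels <- function() {
  c("consolidation", "other_infiltrate", "both", "normal", "uninterpretable")
}

N_CLASSES <- 5L

#' Coerce labels to the canonical class factor
#'
#' Accepts class names, a factor, or integer codes 0-4 (in canonical order)
#' and returns a factor with the canonical level order. Unknown labels are an
#' error; the offending values are named in the message.
#'
#' @param x character, factor, or integer vector of labels.
#' @return factor with levels `class_labels()`.
#' @export
as_class_label <- function(x) {
  lv <- class_labels()
  if (is.factor(x)) x <- as.character(x)
  if (is.numeric(x)) {
    if (any(x < 0 | x > 4 | x != floor(x), na.rm = TRUE))
      stop("integer class codes must be whole numbers in 0..4")
    return(factor(lv[x + 1L], levels = lv))
  }
  bad <- setdiff(unique(x[!is.na(x)]), lv)
  if (length(bad))
    stop("unknown class label(s): ", paste(bad, collapse = ", "))
  factor(x, levels = lv)
}

#' Integer code of a class label
#'
#' @param x labels in any form accepted by [as_class_label()].
#' @return integer codes 0-4 in canonical order.
#' @export
label_code <- function(x) as.integer(as_class_label(x)) - 1L

# internal: 1-based index
label_index <- function(x) as.integer(as_class_label(x))
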