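# round half away from zero to `digits` decimals (95.45 -> 95.5), unlike
# base round()'s round-half-even
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Confusion counts with the pure-as-positive convention
#'
#' One-class screening convention: the pure (target) class is positive.
#' `TP` = pure accepted, `FN` = pure rejected, `TN` = adulterated rejected,
#' `FP` = adulterated accepted.
#'
#' @param decisions data.frame with `specimen_id` and `decision`
#'   (`"accepted"`/`"rejected"`), as from [ddsimca_classify()].
#' @param labels `"pure"`/`"adulterated"` per specimen: a vector aligned with
#'   `decisions`, a named vector, or a data.frame with `specimen_id`, `label`.
#' @return List of class `confusion_counts` with `TP`, `FP`, `FN`, `TN`.
#' @export
confusion <- function(decisions, labels) {
  if (nrow(decisions) == 0) stop("empty decision set")
  if (is.data.frame(labels)) {
    labels <- stats::setNames(labels$label, labels$specimen_id)
  }
  if (!is.null(names(labels))) {
    miss <- setdiff(decisions$specimen_id, names(labels))
    if (length(miss) > 0) {
      stop("unlabeled specimen(s): ", paste(utils::head(miss, 5), collapse = ", "))
    }
    labels <- labels[decisions$specimen_id]
  } else if (length(labels) != nrow(decisions)) {
    stop("labels must align with decisions")
  }
  if (!all(labels %in% c("pure", "adulterated"))) {
    stop('labels must be "pure" or "adulterated"')
  }
  acc <- decisions$decision == "accepted"
  pure <- labels == "pure"
  structure(list(TP = sum(pure & acc), FN = sum(pure & !acc),
                 TN = sum(!pure & !acc), FP = sum(!pure & acc)),
            class = "confusion_counts")
}

#' Sensitivity, specificity and accuracy (percent)
#'
#' Sensitivity = detected pure / total pure; specificity = detected
#' adulterated / total adulterated; accuracy = correct / total. Each is
#' `100 x` the ratio, rounded half-up to one decimal. An empty denominator
#' gives `NA`.
#'
#' @param c a [confusion()] result (or list with `TP`, `FP`, `FN`, `TN`).
#' @return Percent value (one decimal) or `NA`.
#' @export
sensitivity <- function(c) {
  if (c$TP + c$FN == 0) return(NA_real_)
  round_half_up(100 * c$TP / (c$TP + c$FN), 1L)
}

#' @rdname sensitivity
#' @export
specificity <- function(c) {
  if (c$FP + c$TN == 0) return(NA_real_)
  round_half_up(100 * c$TN / (c$FP + c$TN), 1L)
}

#' @rdname sensitivity
#' @export
accuracy <- function(c) {
  tot <- c$TP + c$FP + c$FN + c$TN
  if (tot == 0) return(NA_real_)
  round_half_up(100 * (c$TP + c$TN) / tot, 1L)
}

#' Descriptive statistics of a concentration design
#'
#' @param x vector of concentration labels (%), length >= 2.
#' @return List with `n`, `min`, `max`, `mean`, `sd` (sample SD, `n - 1`),
#'   the statistics rounded to 2 decimals for reporting.
#' @export
summarize_concentrations <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 2L) stop("need at least 2 concentration labels")
  list(n = length(x),
       min = round_half_up(min(x), 2L),
       max = round_half_up(max(x), 2L),
       mean = round_half_up(mean(x), 2L),
       sd = round_half_up(stats::sd(x), 2L))
}
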