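#' Confusion-matrix accuracy statistics
#'
#' @param tp,fp,fn,tn confusion-matrix counts: a positive survey in a
#'   simulated-infested cell is a true positive, a negative survey in a
#'   simulated-infested cell a false positive, and so on.
#' @return an object of class `slf_accuracy` with fields `accuracy`,
#'   `precision`, `recall`, `specificity` (each in \[0, 1\], or `NA` when its
#'   denominator is zero), `counts`, and `undefined` naming the statistics
#'   whose denominators were zero. Undefined ratios are flagged, never
#'   silently reported as 0.
#' @export
accuracy_stats <- function(tp, fp, fn, tn) {
  total <- tp + fp + fn + tn
  if (total == 0) stop("empty confusion table")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  out <- list(accuracy = (tp + tn) / total,
              precision = ratio(tp, tp + fp),
              recall = ratio(tp, tp + fn),
              specificity = ratio(tn, tn + fp),
              counts = c(tp = tp, fp = fp, fn = fn, tn = tn))
  out$undefined <- names(which(vapply(out[1:4], is.na, TRUE)))
  structure(out, class = "slf_accuracy")
}

#' @export
print.slf_accuracy <- function(x, ...) {
  cat(sprintf("accuracy %.4f | precision %.4f | recall %.4f | specificity %.4f\n",
              x$accuracy, x$precision, x$recall, x$specificity))
  if (length(x$undefined))
    cat("undefined (zero denominator):", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' Score a simulated run against presence/absence surveys
#'
#' Each survey record is matched to its grid cell and to the simulated state
#' of the year it was collected; records across all surveyed years are pooled
#' into a single confusion matrix for the period.
#'
#' @param run an `slf_run`.
#' @param observations an `slf_observations` data frame (columns x, y, year,
#'   status); years must lie within the simulated span.
#' @param landscape the `slf_landscape` the run was simulated on.
#' @return an `slf_accuracy`.
#' @export
score_run <- function(run, observations, landscape) {
  if (nrow(observations) == 0L) stop("empty observation set")
  yrs <- unique(observations$year)
  if (!all(yrs %in% run$years))
    stop("observation years outside the simulated span")
  rc <- cell_of(observations$x, observations$y, landscape)
  sim_pos <- logical(nrow(observations))
  for (y in yrs) {
    sel <- observations$year == y
    inf <- run$infested[[as.character(y)]]
    sim_pos[sel] <- inf[rc[sel, , drop = FALSE]]
  }
  obs_pos <- observations$status == "positive"
  accuracy_stats(tp = sum(obs_pos & sim_pos), fp = sum(!obs_pos & sim_pos),
                 fn = sum(obs_pos & !sim_pos), tn = sum(!obs_pos & !sim_pos))
}
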