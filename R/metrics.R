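#' Confusion matrix over the three defect classes
#'
#' Entry `(t, p)` counts items with truth `t` predicted `p`, over the
#' fixed alphabet `+1/2`, `none`, `-1/2`. Winding-number `other` outcomes
#' (|k| >= 1 etc.) are mapped to `none` before counting, so comparisons
#' between methods are always three-class.
#'
#' @param truth,pred label vectors (character or factor) of equal length.
#' @return 3x3 integer matrix, rows = truth, columns = predicted.
#' @export
defect_confusion <- function(truth, pred) {
  truth <- map_other(truth)
  pred <- map_other(pred)
  if (length(truth) != length(pred))
    stop_nemadef("`truth` and `pred` must have equal length", "nemadef_invalid_input")
  cls <- defect_classes()
  bad <- setdiff(unique(c(as.character(truth), as.character(pred))), cls)
  if (length(bad))
    stop_nemadef(paste0("unknown label(s): ", paste(bad, collapse = ", ")),
                 "nemadef_invalid_input")
  table(truth = factor(truth, levels = cls),
        pred = factor(pred, levels = cls))
}

map_other <- function(lab) {
  lab <- as.character(lab)
  lab[lab == "other"] <- "none"
  lab
}

#' Precision, sensitivity and F1 score per class
#'
#' One-vs-rest scores from a confusion matrix:
#' `P = TP / (TP + FP)`, `Sens = TP / (TP + FN)`, and the harmonic mean
#' `F1 = 2 P Sens / (P + Sens)`. Precision measures what proportion of
#' detections are correct (the cost of false positives); sensitivity what
#' proportion of true defects is found (false negatives). Zero
#' denominators yield `NaN` with a warning rather than a silent 0, so
#' degenerate classes cannot bias comparisons.
#'
#' @param confusion a 3x3 matrix from [defect_confusion()].
#' @param class one of the three class labels, or `NULL` for all classes.
#' @return for one class a named numeric vector `(precision, sensitivity,
#'   f1)`; for all classes a data.frame with one row per class plus the
#'   class sizes.
#' @export
precision_sensitivity_f1 <- function(confusion, class = NULL) {
  cls <- defect_classes()
  stopifnot(all(dim(confusion) == c(3L, 3L)))
  one <- function(c0) {
    i <- match(c0, cls)
    tp <- confusion[i, i]
    fp <- sum(confusion[-i, i])
    fn <- sum(confusion[i, -i])
    p <- if (tp + fp == 0) { warning(sprintf("precision undefined for class %s (no detections)", c0)); NaN } else tp / (tp + fp)
    s <- if (tp + fn == 0) { warning(sprintf("sensitivity undefined for class %s (no true items)", c0)); NaN } else tp / (tp + fn)
    f1 <- if (!is.nan(p) && !is.nan(s) && p + s > 0) 2 * p * s / (p + s) else NaN
    c(precision = p, sensitivity = s, f1 = f1)
  }
  if (!is.null(class)) return(one(match.arg(class, cls)))
  out <- as.data.frame(t(vapply(cls, one, numeric(3))))
  out$class <- cls
  out$size <- as.integer(rowSums(confusion))
  out[, c("class", "precision", "sensitivity", "f1", "size")]
}

#' F1 score from precision and sensitivity
#'
#' The harmonic mean `F1 = 2 P S / (P + S)`; lies between `min(P, S)` and
#' `max(P, S)`.
#'
#' @param precision,sensitivity scores in `[0, 1]`.
#' @return scalar F1.
#' @export
f1_score <- function(precision, sensitivity) {
  2 * precision * sensitivity / (precision + sensitivity)
}

#' Class-size-weighted average of per-class scores
#'
#' Weighted mean with weights proportional to class sizes. `NaN` scores
#' (undefined metrics from empty classes) are excluded with a warning and
#' the remaining weights renormalized.
#'
#' @param values per-class scores.
#' @param sizes class sizes, same length.
#' @return scalar.
#' @export
weighted_average <- function(values, sizes) {
  if (length(values) != length(sizes) || sum(sizes) <= 0)
    stop_nemadef("`sizes` must match `values` and sum to > 0",
                 "nemadef_parameter_error")
  keep <- !is.nan(values) & !is.na(values)
  if (!all(keep)) {
    warning("undefined per-class values excluded from weighted average")
    if (!any(keep) || sum(sizes[keep]) == 0)
      stop_nemadef("no defined values to average", "nemadef_parameter_error")
  }
  sum(values[keep] * sizes[keep]) / sum(sizes[keep])
}

#' Per-class and overall classification report
#'
#' The standard per-method scoring layout: precision, sensitivity and F1
#' for each class, and totals weighted by class size. Overall accuracy
#' equals the class-size-weighted sensitivity.
#'
#' @param truth,pred label vectors.
#' @param method optional method tag carried into the output.
#' @return an object of class `defect_metrics`: list with `confusion`,
#'   `per_class` (data.frame), `weighted` (named vector with `precision`,
#'   `sensitivity`, `f1`), `accuracy`, `n`, `method`.
#' @export
classification_report <- function(truth, pred, method = NA_character_) {
  cm <- defect_confusion(truth, pred)
  pc <- precision_sensitivity_f1(cm)
  w <- c(precision = weighted_average(pc$precision, pc$size),
         sensitivity = weighted_average(pc$sensitivity, pc$size),
         f1 = weighted_average(pc$f1, pc$size))
  structure(list(confusion = cm, per_class = pc, weighted = w,
                 accuracy = sum(diag(cm)) / sum(cm), n = sum(cm),
                 method = method),
            class = "defect_metrics")
}

#' @export
print.defect_metrics <- function(x, digits = 3L, ...) {
  cat(sprintf("<defect_metrics>%s n = %d, accuracy = %.3f\n",
              if (!is.na(x$method)) paste0(" [", x$method, "]") else "",
              x$n, x$accuracy))
  pc <- x$per_class
  pc[, 2:4] <- round(pc[, 2:4], digits)
  print(pc, row.names = FALSE)
  cat(sprintf("weighted: P = %.3f, Sens = %.3f, F1 = %.3f\n",
              x$weighted["precision"], x$weighted["sensitivity"],
              x$weighted["f1"]))
  invisible(x)
}

#' Write metrics as a scoreboard CSV (one row per method) and JSON
#'
#' @param reports list of `defect_metrics` objects.
#' @param csv,json output paths (either may be `NULL`).
#' @return the scoreboard data.frame, invisibly.
#' @export
write_metrics <- function(reports, csv = NULL, json = NULL) {
  rows <- lapply(reports, function(r) {
    pc <- r$per_class
    out <- data.frame(method = r$method, n = r$n, accuracy = r$accuracy)
    for (i in seq_len(nrow(pc))) {
      cls <- gsub("[+/]", "", pc$class[i])
      out[[paste0("P_", cls)]] <- pc$precision[i]
      out[[paste0("S_", cls)]] <- pc$sensitivity[i]
      out[[paste0("F1_", cls)]] <- pc$f1[i]
    }
    out$P_weighted <- r$weighted["precision"]
    out$S_weighted <- r$weighted["sensitivity"]
    out$F1_weighted <- r$weighted["f1"]
    out
  })
  tab <- do.call(rbind, rows)
  if (!is.null(csv)) utils::write.csv(tab, csv, row.names = FALSE)
  if (!is.null(json)) {
    jsonlite::write_json(lapply(reports, function(r) {
      list(method = r$method, n = r$n, accuracy = r$accuracy,
           per_class = r$per_class,
           weighted = as.list(r$weighted),
           confusion = unclass(r$confusion))
    }), json, digits = NA, auto_unbox = TRUE)
  }
  invisible(tab)
}
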