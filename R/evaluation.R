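#' Confusion counts between predicted and true timelines
#'
#' Per-bin 2x2 tally on the 0.16 s subframe grid, with "swallow" as the
#' positive class. Both timelines must share bin width and length.
#'
#' @param pred A [timeline()] (confidences are thresholded at `threshold`)
#'   or binary vector.
#' @param truth A binary [timeline()] or vector of the same length.
#' @param threshold Decision threshold applied to `pred` (strict `>`).
#' @return A list of class `confusion_counts` with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(pred, truth, threshold = 0.5) {
  pv <- if (inherits(pred, "timeline")) pred$values else as.numeric(pred)
  tv <- if (inherits(truth, "timeline")) truth$values else as.numeric(truth)
  if (inherits(pred, "timeline") && inherits(truth, "timeline") &&
      abs(pred$bin_width - truth$bin_width) > 1e-9)
    stop("prediction and truth are on different bin grids")
  if (length(pv) != length(tv))
    stop("prediction and truth have different lengths (",
         length(pv), " vs ", length(tv), ")")
  p <- pv > threshold
  t <- tv > threshold
  structure(list(tp = sum(p & t), fp = sum(p & !t),
                 tn = sum(!p & !t), fn = sum(!p & t)),
            class = "confusion_counts")
}

#' Bundle raw counts into a `confusion_counts` object
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @return A `confusion_counts` object.
#' @export
as_confusion_counts <- function(tp, fp, tn, fn) {
  if (any(c(tp, fp, tn, fn) < 0)) stop("counts must be non-negative")
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d FP=%d TN=%d FN=%d\n",
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Swap the class orientation of confusion counts
#'
#' Exchanges `tp <-> tn` and `fp <-> fn`, turning swallow-positive counts
#' into non-swallow-positive counts. `class_flip(class_flip(c))` is the
#' identity and accuracy is invariant.
#'
#' @param counts A `confusion_counts` object.
#' @return The flipped `confusion_counts`.
#' @export
class_flip <- function(counts) {
  as_confusion_counts(tp = counts$tn, fp = counts$fn,
                      tn = counts$tp, fn = counts$fp)
}

#' Diagnostic test accuracy metrics from confusion counts
#'
#' Computes accuracy `(TP+TN)/total`, sensitivity (recall) `TP/(TP+FN)`,
#' specificity `TN/(TN+FP)`, positive predictive value (precision)
#' `TP/(TP+FP)`, negative predictive value `TN/(TN+FN)`, and the F1 score
#' (harmonic mean of precision and recall). A zero denominator yields `NA`
#' (undefined), never an error.
#'
#' @param counts A `confusion_counts` object with positive total.
#' @return A list of class `metrics_report` with fields `accuracy`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `f1` and the counts.
#' @export
compute_metrics <- function(counts) {
  total <- counts$tp + counts$fp + counts$tn + counts$fn
  if (total <= 0) stop("cannot compute metrics from zero counts")
  div <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- div(counts$tp, counts$tp + counts$fn)
  ppv <- div(counts$tp, counts$tp + counts$fp)
  f1 <- if (is.na(sens) || is.na(ppv) || (ppv + sens) == 0) NA_real_ else
    2 * ppv * sens / (ppv + sens)
  structure(list(
    accuracy = (counts$tp + counts$tn) / total,
    sensitivity = sens,
    specificity = div(counts$tn, counts$tn + counts$fp),
    ppv = ppv,
    npv = div(counts$tn, counts$tn + counts$fn),
    f1 = f1,
    counts = counts
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 2, ...) {
  v <- unlist(x[c("ppv", "npv", "specificity", "sensitivity", "f1")])
  cat(sprintf("accuracy %.2f | PPV %.2f  NPV %.2f  Spec %.2f  Sens %.2f  F1 %.2f\n",
              x$accuracy, v[1], v[2], v[3], v[4], v[5]))
  invisible(x)
}

#' F1 score from precision and recall
#'
#' The harmonic mean `2 P R / (P + R)`; `NA` when both are zero.
#'
#' @param precision,recall Values in `[0, 1]`.
#' @return The F1 score.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall == 0, NA_real_,
         2 * precision * recall / (precision + recall))
}

#' Two-orientation metrics table
#'
#' Metrics with "swallow" as the positive class and, via [class_flip()],
#' with "non-swallow" as the positive class — the two rows of a standard
#' diagnostic accuracy table.
#'
#' @param counts A `confusion_counts` object (swallow-positive orientation).
#' @return A list of class `class_metrics` with `swallow`, `non_swallow`
#'   ([compute_metrics()] reports) and `accuracy`.
#' @export
metrics_by_class <- function(counts) {
  sw <- compute_metrics(counts)
  ns <- compute_metrics(class_flip(counts))
  structure(list(swallow = sw, non_swallow = ns, accuracy = sw$accuracy),
            class = "class_metrics")
}

#' @export
print.class_metrics <- function(x, ...) {
  cat(sprintf("Total accuracy = %.2f\n", x$accuracy))
  fmt <- function(m) sprintf("%.2f  %.2f  %.2f  %.2f  %.2f",
                             m$ppv, m$npv, m$specificity, m$sensitivity, m$f1)
  cat("                 PPV   NPV   Spec  Sens  F1\n")
  cat("Non-swallow (0) ", fmt(x$non_swallow), "\n")
  cat("Swallow (1)     ", fmt(x$swallow), "\n")
  invisible(x)
}

#' Stratified evaluation by feeding type
#'
#' Pools per-recording confusion counts within each feeding-type stratum
#' (micro-averaging) and computes two-orientation metrics for the pooled
#' "all" stratum plus each non-empty feeding-type stratum. Recordings with
#' unknown feeding type contribute to "all" only, with a warning.
#'
#' @param counts_by_recording Named list of `confusion_counts`, one per
#'   recording.
#' @param metadata Data frame with columns `recording_id` and
#'   `feeding_type` (`"bottle"`, `"breast"`, `"unknown"`).
#' @return Named list of [metrics_by_class()] reports (`all`, and `bottle`/
#'   `breast` where non-empty), each carrying its stratum name.
#' @export
stratified_evaluate <- function(counts_by_recording, metadata) {
  ids <- names(counts_by_recording)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("counts_by_recording must be a named list keyed by recording_id")
  miss <- setdiff(ids, metadata$recording_id)
  if (length(miss))
    stop("recordings missing from metadata: ", paste(miss, collapse = ", "))
  ft <- metadata$feeding_type[match(ids, metadata$recording_id)]
  if (any(!ft %in% c("bottle", "breast")))
    warning("recordings with unknown feeding type contribute to 'all' only: ",
            paste(ids[!ft %in% c("bottle", "breast")], collapse = ", "))
  pool <- function(sel) {
    cs <- counts_by_recording[sel]
    as_confusion_counts(tp = sum(vapply(cs, `[[`, 0, "tp")),
                        fp = sum(vapply(cs, `[[`, 0, "fp")),
                        tn = sum(vapply(cs, `[[`, 0, "tn")),
                        fn = sum(vapply(cs, `[[`, 0, "fn")))
  }
  out <- list(all = metrics_by_class(pool(seq_along(ids))))
  for (stratum in c("bottle", "breast")) {
    sel <- which(ft == stratum)
    if (!length(sel)) {
      warning("stratum '", stratum, "' is empty; omitted")
      next
    }
    out[[stratum]] <- metrics_by_class(pool(sel))
  }
  for (nm in names(out)) attr(out[[nm]], "stratum") <- nm
  out
}

#' Event-level overlap metrics (supplementary)
#'
#' Counts whole events rather than 0.16 s bins: a truth interval is a hit
#' when at least one predicted interval overlaps it, and a predicted
#' interval is a true detection when it overlaps some truth interval.
#' This is a supplementary diagnostic — the package's headline metrics are
#' the subframe-level (per-bin) tallies of [confusion_counts()].
#'
#' @param pred,truth [annotation_set()]s of predicted and true intervals.
#' @return List with `event_recall` (truth intervals hit), `event_precision`
#'   (predictions that hit), `f1`, and the raw counts.
#' @export
event_overlap_metrics <- function(pred, truth) {
  overlaps <- function(a, b)
    vapply(seq_len(nrow(a)), function(i)
      any(a$onset[i] < b$offset & a$offset[i] > b$onset), logical(1))
  n_truth <- nrow(truth); n_pred <- nrow(pred)
  hit_truth <- if (n_truth && n_pred) sum(overlaps(truth, pred)) else 0L
  hit_pred <- if (n_truth && n_pred) sum(overlaps(pred, truth)) else 0L
  rec <- if (n_truth > 0) hit_truth / n_truth else NA_real_
  prec <- if (n_pred > 0) hit_pred / n_pred else NA_real_
  list(event_recall = rec, event_precision = prec,
       f1 = f1_score(prec, rec),
       n_truth = n_truth, n_pred = n_pred,
       truth_hit = hit_truth, pred_hit = hit_pred)
}

#' Write a metrics report set to JSON and CSV
#'
#' Full precision goes to JSON; the CSV table is rounded to 2 decimals,
#' mirroring conventional diagnostic accuracy tables.
#'
#' @param reports Result of [stratified_evaluate()] (or a single
#'   `class_metrics`).
#' @param json_path,csv_path Output paths (either may be `NULL`).
#' @return The report data frame, invisibly.
#' @export
write_metrics_report <- function(reports, json_path = NULL, csv_path = NULL) {
  if (inherits(reports, "class_metrics")) reports <- list(all = reports)
  rows <- list()
  for (stratum in names(reports)) {
    r <- reports[[stratum]]
    for (cls in c("non_swallow", "swallow")) {
      m <- r[[cls]]
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = stratum, class = cls,
        ppv = m$ppv, npv = m$npv, specificity = m$specificity,
        sensitivity = m$sensitivity, f1 = m$f1, accuracy = r$accuracy)
    }
  }
  df <- do.call(rbind, rows)
  if (!is.null(json_path))
    jsonlite::write_json(df, json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(csv_path)) {
    rounded <- df
    num <- vapply(rounded, is.numeric, TRUE)
    rounded[num] <- lapply(rounded[num], round, 2)
    write.csv(rounded, csv_path, row.names = FALSE)
  }
  invisible(df)
}
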