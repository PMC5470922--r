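#' Pixel-wise confusion counts against ground truth
#'
#' Tallies true/false positives/negatives between a predicted foreground mask
#' and a ground-truth mask. Pixels flagged in `ignore` contribute to no
#' bucket (useful when a ground-truth set marks unknown regions; with no
#' ignore mask every pixel is counted).
#'
#' @param mask Logical (or 0/255) matrix, TRUE/255 = foreground.
#' @param truth Ground-truth matrix, same encoding and shape.
#' @param ignore Optional logical matrix; TRUE pixels are excluded.
#' @return Object of class `"confusion_counts"`: integers `tp`, `fp`, `tn`,
#'   `fn` summing to the number of evaluated pixels.
#' @examples
#' confusion(matrix(c(TRUE, FALSE), 2, 2), matrix(c(TRUE, TRUE), 2, 2))
#' @export
confusion <- function(mask, truth, ignore = NULL) {
  if (!is.matrix(mask) || !is.matrix(truth) || !identical(dim(mask), dim(truth)))
    stop("mask and truth must be matrices of the same shape")
  m <- mask != 0
  g <- truth != 0
  keep <- if (is.null(ignore)) TRUE else {
    if (!is.matrix(ignore) || !identical(dim(ignore), dim(mask)))
      stop("ignore mask shape must match")
    !(ignore != 0)
  }
  structure(list(tp = sum(m & g & keep), fp = sum(m & !g & keep),
                 tn = sum(!m & !g & keep), fn = sum(!m & g & keep)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion counts: TP=%d FP=%d TN=%d FN=%d (PWC=%.3f%%)\n",
              x$tp, x$fp, x$tn, x$fn, pwc(x)))
  invisible(x)
}

#' Percentage of wrong classifications
#'
#' `PWC = 100 * (FN + FP) / (TP + TN + FP + FN)`, the fraction of
#' misclassified pixels expressed as a percentage. Lower is better; 0 is a
#' perfect segmentation and 100 total disagreement.
#'
#' @param counts A `"confusion_counts"` object (or a named list with `tp`,
#'   `fp`, `tn`, `fn`).
#' @return A single numeric value in `[0, 100]`.
#' @examples
#' pwc(list(tp = 90, tn = 880, fp = 10, fn = 20))  # 3.0
#' @export
pwc <- function(counts) {
  total <- counts$tp + counts$fp + counts$tn + counts$fn
  if (total == 0) stop("PWC is undefined on zero evaluated pixels")
  100 * (counts$fn + counts$fp) / total
}

#' Mean PWC over a sequence
#'
#' @param per_frame Non-empty numeric vector of per-frame PWC values.
#' @return Their arithmetic mean.
#' @export
mean_pwc <- function(per_frame) {
  if (length(per_frame) == 0) stop("per-frame PWC list must be non-empty")
  mean(per_frame)
}

#' Evaluate a segmentation against ground truth
#'
#' Computes per-frame confusion counts and PWC for every frame that has a
#' ground-truth mask.
#'
#' @param seg A `"segmentation"` object, or a list of logical masks.
#' @param truth An `rgbd_sequence` whose frames carry `gt` masks, or a list
#'   of ground-truth matrices aligned with the masks.
#' @param ignore Optional list of ignore masks (or a single matrix recycled
#'   over frames).
#' @return A data.frame with columns `frame_index`, `tp`, `fp`, `tn`, `fn`,
#'   `pwc`, with the sequence mean PWC attached as attribute `"mean_pwc"`.
#' @export
evaluate_segmentation <- function(seg, truth, ignore = NULL) {
  masks <- if (inherits(seg, "segmentation")) seg$masks else seg
  truths <- if (inherits(truth, "rgbd_sequence")) lapply(truth, `[[`, "gt") else truth
  if (length(masks) != length(truths))
    stop("mask and ground-truth sequences must align")
  have <- !vapply(truths, is.null, logical(1))
  rows <- lapply(which(have), function(t) {
    ig <- if (is.null(ignore)) NULL
          else if (is.matrix(ignore)) ignore else ignore[[t]]
    cc <- confusion(masks[[t]], truths[[t]], ig)
    data.frame(frame_index = t, tp = cc$tp, fp = cc$fp, tn = cc$tn, fn = cc$fn,
               pwc = pwc(cc))
  })
  if (length(rows) == 0) stop("no ground-truth masks to evaluate against")
  df <- do.call(rbind, rows)
  attr(df, "mean_pwc") <- mean_pwc(df$pwc)
  df
}

#' Write per-frame metrics as CSV
#'
#' Emits `frame_index, tp, fp, tn, fn, pwc` rows followed by one trailing
#' `mean` row carrying the sequence mean PWC.
#'
#' @param metrics Data.frame from [evaluate_segmentation()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(metrics, path) {
  out <- metrics
  out$frame_index <- as.character(out$frame_index)
  out <- rbind(out, data.frame(frame_index = "mean", tp = NA, fp = NA, tn = NA,
                               fn = NA, pwc = attr(metrics, "mean_pwc")))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
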