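# Evaluation metrics: Dice similarity coefficient, sensitivity,
# specificity, and the (full, symmetric) Hausdorff distance between
# boundary point sets, reported per class and aggregated over a test set.

.as_mask <- function(x) {
  if (is.logical(x)) x <- x * 1L
  x
}

#' Dice similarity coefficient
#'
#' `2 |S ∩ G| / (|S| + |G|)` between a predicted and a ground-truth binary
#' mask. Defined as 1 when both masks are empty (correctly predicting
#' absence).
#'
#' @param S,G binary masks (logical or 0/1) of equal shape.
#' @return value in `[0, 1]`.
#' @export
dsc <- function(S, G) {
  S <- .as_mask(S); G <- .as_mask(G)
  if (!identical(dim(S), dim(G))) stop("masks have different shapes")
  s <- sum(S); g <- sum(G)
  if (s + g == 0) return(1)
  2 * sum(S * G) / (s + g)
}

#' Sensitivity and specificity
#'
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (TN + FP)` of a
#' predicted mask `S` against ground truth `G`. An empty denominator (no
#' positives for sensitivity, no negatives for specificity) returns 1.
#'
#' @inheritParams dsc
#' @return value in `[0, 1]`.
#' @export
sensitivity <- function(S, G) {
  S <- .as_mask(S); G <- .as_mask(G)
  if (!identical(dim(S), dim(G))) stop("masks have different shapes")
  tp <- sum(S * G); fn <- sum((1 - S) * G)
  if (tp + fn == 0) return(1)
  tp / (tp + fn)
}

#' @rdname sensitivity
#' @export
specificity <- function(S, G) {
  S <- .as_mask(S); G <- .as_mask(G)
  if (!identical(dim(S), dim(G))) stop("masks have different shapes")
  tn <- sum((1 - S) * (1 - G)); fp <- sum(S * (1 - G))
  if (tn + fp == 0) return(1)
  tn / (tn + fp)
}

# boundary pixels: foreground pixels with at least one 4-neighbor outside
# the mask (or on the image border)
.boundary_points <- function(M) {
  M <- .as_mask(M)
  H <- nrow(M); W <- ncol(M)
  pad <- matrix(0L, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- M
  inner <- pad[2:(H + 1L), 2:(W + 1L)] == 1 &
    pad[1:H, 2:(W + 1L)] == 1 & pad[3:(H + 2L), 2:(W + 1L)] == 1 &
    pad[2:(H + 1L), 1:W] == 1 & pad[2:(H + 1L), 3:(W + 2L)] == 1
  which(M == 1 & !inner, arr.ind = TRUE)
}

#' Hausdorff distance between mask boundaries
#'
#' Maximum of the two directed Hausdorff distances between the boundary
#' point sets of the masks, in Euclidean pixel units (multiply by the pixel
#' spacing for physical units).
#'
#' @inheritParams dsc
#' @param spacing isotropic pixel spacing multiplier (default 1 = pixels).
#' @return non-negative scalar; error if either mask is empty.
#' @export
hausdorff <- function(S, G, spacing = 1) {
  S <- .as_mask(S); G <- .as_mask(G)
  if (!identical(dim(S), dim(G))) stop("masks have different shapes")
  if (sum(S) == 0 || sum(G) == 0)
    stop("Hausdorff distance is undefined for an empty mask")
  a <- .boundary_points(S)
  b <- .boundary_points(G)
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  h <- max(sqrt(apply(d2, 1, min)), sqrt(apply(d2, 2, min)))
  h * spacing
}

#' Evaluate predictions against ground truth
#'
#' Computes per-class DSC, sensitivity, specificity and Hausdorff distance
#' for each case and aggregates per-class means over the test set. Cases
#' whose ground truth lacks a class are excluded from that class's
#' averages.
#'
#' @param predictions list of predicted label maps.
#' @param ground_truths list of ground-truth label maps, same length and
#'   shapes.
#' @param classes integer class indices to evaluate (default `1:3`).
#' @param class_names names used in the report.
#' @param csv optional path; when given, the per-case table is written as
#'   CSV.
#' @return object of class `bws_metrics_report`: list with `per_case`
#'   (data frame `case`, `class`, `dsc`, `sen`, `spe`, `hd`, `gt_pixels`)
#'   and `summary` (per-class means plus a foreground-mean row).
#' @export
evaluate <- function(predictions, ground_truths, classes = 1:3,
                     class_names = c("urine", "wall", "tumor"),
                     csv = NULL) {
  if (length(predictions) != length(ground_truths))
    stop("predictions and ground truths must be paired")
  rows <- list()
  for (i in seq_along(predictions)) {
    p <- predictions[[i]]; g <- ground_truths[[i]]
    if (!identical(dim(p), dim(g)))
      stop("case ", i, ": prediction and ground truth shapes differ")
    for (k in seq_along(classes)) {
      cl <- classes[k]
      gm <- g == cl
      if (!any(gm)) next
      pm <- p == cl
      hd <- if (any(pm)) hausdorff(pm, gm) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        case = i, class = class_names[k], dsc = dsc(pm, gm),
        sen = sensitivity(pm, gm), spe = specificity(pm, gm), hd = hd,
        gt_pixels = sum(gm))
    }
  }
  per_case <- do.call(rbind, rows)
  agg <- stats::aggregate(per_case[, c("dsc", "sen", "spe", "hd")],
                          by = list(class = per_case$class), FUN = mean,
                          na.rm = TRUE)
  fg <- data.frame(class = "foreground_mean",
                   t(colMeans(agg[, c("dsc", "sen", "spe", "hd")],
                              na.rm = TRUE)))
  summary <- rbind(agg, fg)
  if (!is.null(csv)) utils::write.csv(per_case, csv, row.names = FALSE)
  structure(list(per_case = per_case, summary = summary),
            class = "bws_metrics_report")
}

#' @export
print.bws_metrics_report <- function(x, ...) {
  cat("Segmentation evaluation (per-class means over cases)\n")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
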