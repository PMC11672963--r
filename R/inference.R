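# Inference-time machinery: multi-view test-time augmentation with exact
# inverse transforms, probability merging, and segmentation correction
# enforcing the anatomical prior of a single, hole-free bladder region.

#' Argmax label map from a probability map
#'
#' Per-pixel argmax over channels; ties are broken toward the lower class
#' index.
#'
#' @param prob `(H, W, K)` probability array.
#' @return integer matrix with values in `0..K-1`.
#' @export
label_from_prob <- function(prob) {
  d <- dim(prob)
  m <- matrix(prob, nrow = d[1] * d[2])
  matrix(max.col(m, ties.method = "first") - 1L, d[1], d[2])
}

# exact grid transforms (square inputs for rotations)
.tta_ops <- list(
  identity = list(f = function(x) x, i = function(x) x),
  hflip = list(f = function(x) x[, ncol(x):1, drop = FALSE],
               i = function(x) x[, ncol(x):1, drop = FALSE]),
  vflip = list(f = function(x) x[nrow(x):1, , drop = FALSE],
               i = function(x) x[nrow(x):1, , drop = FALSE]),
  rot90 = list(f = function(x) t(x[nrow(x):1, , drop = FALSE]),
               i = function(x) t(x)[nrow(x):1, , drop = FALSE]),
  rot180 = list(f = function(x) x[nrow(x):1, ncol(x):1, drop = FALSE],
                i = function(x) x[nrow(x):1, ncol(x):1, drop = FALSE]),
  rot270 = list(f = function(x) t(x)[nrow(x):1, , drop = FALSE],
                i = function(x) t(x[nrow(x):1, , drop = FALSE])))

#' Test-time augmentation transforms
#'
#' The weak augmentation set: horizontal/vertical flips and rotations by
#' multiples of 90 degrees. All are exactly invertible on the pixel grid,
#' so `inverse(forward(x))` is bitwise identical to `x` -- a requirement
#' checked at registration time; interpolating transforms are rejected.
#'
#' @param names subset of `"identity"`, `"hflip"`, `"vflip"`, `"rot90"`,
#'   `"rot180"`, `"rot270"`.
#' @return list of transforms, each with `name`, `forward`, `inverse`.
#' @export
tta_transforms <- function(names = c("identity", "hflip", "vflip",
                                     "rot90", "rot180", "rot270")) {
  unknown <- setdiff(names, names(.tta_ops))
  if (length(unknown))
    stop("unknown transforms: ", paste(unknown, collapse = ", "))
  lapply(names, function(nm) {
    tr <- list(name = nm, forward = .tta_ops[[nm]]$f,
               inverse = .tta_ops[[nm]]$i)
    register_tta_transform(tr)
  })
}

#' Register (validate) a test-time augmentation transform
#'
#' Checks on an integer test grid that the transform's inverse undoes its
#' forward map exactly; transforms without an exact inverse are rejected,
#' since label and probability fields must return to the original image
#' space without interpolation.
#'
#' @param transform list with `name`, `forward`, `inverse`.
#' @return the transform, invisibly validated.
#' @export
register_tta_transform <- function(transform) {
  probe <- matrix(seq_len(16L * 16L), 16L, 16L)
  back <- transform$inverse(transform$forward(probe))
  if (!identical(back, probe))
    stop("transform '", transform$name,
         "' has no exact inverse on the pixel grid")
  transform
}

.apply_tr_prob <- function(prob, fn) {
  d <- dim(prob)
  out <- NULL
  for (k in seq_len(d[3])) {
    m <- fn(prob[, , k])
    if (is.null(out)) out <- array(0, dim = c(dim(m), d[3]))
    out[, , k] <- m
  }
  out
}

#' Segmentation prediction with test-time augmentation
#'
#' Runs the model on each transformed copy of the image, inverse-transforms
#' the probability maps back to the original space, and merges them
#' (per-pixel mean by default, or per-pixel majority vote of the argmax
#' labels).
#'
#' @param model a `bws_seg_model` or a segmentation `bws_net`.
#' @param image numeric matrix in `[0, 1]`.
#' @param transforms list from [tta_transforms()]; must be non-empty.
#' @param merge `"mean"` or `"vote"`.
#' @return for `merge = "mean"` an `(H, W, K)` probability map; for
#'   `"vote"` the merged map is the vote-frequency map over classes.
#' @export
tta_predict <- function(model, image, transforms = tta_transforms(),
                        merge = c("mean", "vote")) {
  merge <- match.arg(merge)
  if (!length(transforms)) stop("transform list must be non-empty")
  net <- if (inherits(model, "bws_seg_model")) model$net else model
  acc <- NULL
  for (tr in transforms) {
    xt <- tr$forward(image)
    prob <- segment_forward(xt, net)$prob
    prob <- .apply_tr_prob(prob, tr$inverse)
    if (merge == "vote") {
      lab <- label_from_prob(prob)
      prob <- .one_hot(lab, dim(prob)[3])
      dim(prob) <- dim(prob)[1:3]
    }
    acc <- if (is.null(acc)) prob else acc + prob
  }
  acc / length(transforms)
}

#' Keep the largest foreground component
#'
#' Connected components are computed on the union of the foreground
#' classes (urine, wall, tumor); every component except the largest is
#' relabeled to background, preserving class identities inside the kept
#' component. Ties go to the component first encountered in row-major
#' order.
#'
#' @param label integer label map.
#' @param connectivity 4 or 8 (default 8).
#' @return corrected label map; attribute `removed` counts dropped
#'   components, attribute `no_foreground` flags an all-background input
#'   (returned unchanged with a warning).
#' @export
largest_component <- function(label, connectivity = 8L) {
  fg <- matrix(as.integer(label > 0), nrow(label))
  if (!any(fg > 0)) {
    warning("label map has no foreground; returned unchanged")
    attr(label, "no_foreground") <- TRUE
    attr(label, "removed") <- 0L
    return(label)
  }
  comp <- cpp_label_components(fg, as.integer(connectivity))
  sizes <- tabulate(comp[comp > 0])
  keep <- which.max(sizes)  # ties: lowest id = first encountered
  out <- label
  out[comp != keep & comp > 0] <- 0L
  attr(out, "removed") <- length(sizes) - 1L
  out
}

#' Fill interior holes of the segmentation
#'
#' Background regions not connected to the image border (4-connectivity)
#' are holes inside the bladder region and are filled. Each filled pixel
#' takes the majority class among its 8-neighborhood foreground pixels,
#' iterating inward from the hole boundary; existing foreground pixels are
#' never altered.
#'
#' @param label integer label map.
#' @return label map with holes filled; attribute `filled` counts filled
#'   pixels.
#' @export
fill_holes <- function(label) {
  H <- nrow(label); W <- ncol(label)
  bg <- matrix(as.integer(label == 0L), H)
  comp <- cpp_label_components(bg, 4L)
  border_ids <- unique(c(comp[1, ], comp[H, ], comp[, 1], comp[, W]))
  border_ids <- border_ids[border_ids > 0]
  hole <- comp > 0 & !(comp %in% border_ids)
  out <- label
  n_filled <- sum(hole)
  while (any(hole)) {
    idx <- which(hole, arr.ind = TRUE)
    changed <- FALSE
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1]; j <- idx[r, 2]
      ii <- max(1, i - 1):min(H, i + 1)
      jj <- max(1, j - 1):min(W, j + 1)
      nb <- out[ii, jj]
      nb <- nb[nb > 0]
      if (!length(nb)) next
      tab <- tabulate(nb, nbins = 3L)
      out[i, j] <- which.max(tab)  # majority; ties to the lower class
      hole[i, j] <- FALSE
      changed <- TRUE
    }
    if (!changed) break  # isolated hole with no foreground anywhere
  }
  attr(out, "filled") <- n_filled
  out
}

#' Correct a segmentation to a single hole-free region
#'
#' Applies [largest_component()] then [fill_holes()], enforcing the
#' anatomical prior that exactly one bladder structure, with no interior
#' holes, is present per image. Idempotent.
#'
#' @param label integer label map.
#' @param connectivity component connectivity (default 8).
#' @return list with `label` (corrected map) and `report` (class
#'   `bws_correction_report`: `components_removed`, `hole_pixels_filled`,
#'   `changed_pixel_fraction`).
#' @export
correct_segmentation <- function(label, connectivity = 8L) {
  lc <- largest_component(label, connectivity)
  fh <- fill_holes(lc)
  out <- fh
  attributes(out) <- list(dim = dim(label))
  report <- structure(list(
    components_removed = attr(lc, "removed"),
    hole_pixels_filled = attr(fh, "filled"),
    changed_pixel_fraction = mean(out != label)),
    class = "bws_correction_report")
  list(label = out, report = report)
}

#' @export
print.bws_correction_report <- function(x, ...) {
  cat(sprintf(
    "<correction> components removed: %d, hole pixels filled: %d, changed: %.4f\n",
    x$components_removed, x$hole_pixels_filled, x$changed_pixel_fraction))
  invisible(x)
}

#' Predict a label map for an image
#'
#' Full inference path: test-time augmentation (optional), per-pixel
#' argmax, then segmentation correction (optional).
#'
#' @param object a `bws_seg_model`.
#' @param image numeric matrix in `[0, 1]`, or a list of such matrices.
#' @param tta apply test-time augmentation (default TRUE).
#' @param correct apply segmentation correction (default TRUE).
#' @param merge `"mean"` or `"vote"`.
#' @param transforms transform list used when `tta = TRUE`.
#' @param connectivity component connectivity for the correction.
#' @param ... unused.
#' @return integer label map (or list of maps) with attribute `report`
#'   (a `bws_correction_report`) when `correct = TRUE`.
#' @export
predict.bws_seg_model <- function(object, image, tta = TRUE, correct = TRUE,
                                  merge = c("mean", "vote"),
                                  transforms = tta_transforms(),
                                  connectivity = 8L, ...) {
  merge <- match.arg(merge)
  if (is.list(image))
    return(lapply(image, function(im)
      predict.bws_seg_model(object, im, tta = tta, correct = correct,
                            merge = merge, transforms = transforms,
                            connectivity = connectivity)))
  prob <- if (tta) tta_predict(object, image, transforms, merge)
  else segment_forward(image, object$net)$prob
  lab <- label_from_prob(prob)
  if (correct) {
    cs <- correct_segmentation(lab, connectivity)
    lab <- cs$label
    attr(lab, "report") <- cs$report
  }
  lab
}

#' @export
print.bws_seg_model <- function(x, ...) {
  cat(sprintf(
    "<bws_seg_model> %s, n_labeled = %d, beta = %.3g, best val DSC = %.4f\n",
    if (x$pretrained) "pre-trained trunk" else "scratch init",
    x$policy$n_labeled, x$policy$beta, x$best_val_dsc))
  invisible(x)
}

#' @export
summary.bws_seg_model <- function(object, ...) {
  h <- object$history
  cat("Semi-supervised segmentation model\n")
  print(object)
  cat(sprintf("  epochs: %d, final DFL %.4f, final VAE loss %.4f\n",
              nrow(h), h$dfl[nrow(h)], h$val_loss[nrow(h)]))
  tr <- table(object$transfer$group)
  cat(sprintf("  parameter groups: %s\n",
              paste(names(tr), tr, sep = "=", collapse = ", ")))
  invisible(object)
}

#' @export
plot.bws_seg_model <- function(x, ...) {
  h <- x$history
  graphics::par(mfrow = c(1, 2))
  graphics::plot(h$epoch, h$dfl, type = "l", xlab = "epoch",
                 ylab = "Dice-focal loss", main = "training loss")
  graphics::plot(h$epoch, h$val_dsc, type = "l", xlab = "epoch",
                 ylab = "validation DSC", main = "validation Dice")
  invisible(x)
}

#' @export
print.bws_pretrain_model <- function(x, ...) {
  cat(sprintf(
    "<bws_pretrain_model> %d epochs, best validation loss %.5f\n",
    nrow(x$history), x$best_val_loss))
  invisible(x)
}
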