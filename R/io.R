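# Image and label I/O plus pipeline configuration.  Images are 8-bit
# grayscale PNG in [0,1]; label maps are PNGs whose pixel value is the
# class index {0,1,2,3} so the round trip through disk is exact.  NIfTI
# export (single-slice volume, identity affine) is available when RNifti
# is installed.

#' Write a grayscale image as 8-bit PNG
#' @param image numeric matrix in `[0, 1]`.
#' @param path output file path.
#' @export
write_image_png <- function(image, path) {
  stopifnot(is.matrix(image))
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' Read a grayscale PNG as an image matrix
#' @param path PNG file path.
#' @return numeric matrix in `[0, 1]`.
#' @export
read_image_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1L]
  x
}

#' Write a label map as integer-valued PNG
#' @param label integer matrix with values in `0..255` (class indices).
#' @param path output file path.
#' @export
write_label_png <- function(label, path) {
  stopifnot(is.matrix(label), all(label >= 0), all(label <= 255))
  png::writePNG(matrix(as.integer(label), nrow(label)) / 255, path)
  invisible(path)
}

#' Read a label map written by [write_label_png()]
#' @param path PNG file path.
#' @return integer matrix of class indices.
#' @export
read_label_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1L]
  matrix(as.integer(round(x * 255)), nrow(x))
}

#' Export an image or label map as single-slice NIfTI
#'
#' Writes a `H x W x 1` volume with an identity affine. Requires the
#' RNifti package.
#'
#' @param x numeric or integer matrix.
#' @param path output path (`.nii` or `.nii.gz`).
#' @export
write_nifti <- function(x, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("NIfTI export requires the RNifti package")
  vol <- array(x, dim = c(dim(x), 1L))
  RNifti::writeNifti(RNifti::asNifti(vol), path)
  invisible(path)
}

# --- pipeline configuration -------------------------------------------------

#' Default pipeline configuration
#'
#' Nested list of defaults for every stage: phantom generation, masking,
#' network architecture, loss weights, the two training stages, and
#' inference options. A configuration echoed to disk with
#' [write_config()] reproduces the run.
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 0L,
    phantom = list(image_size = 96L,
                   lumen_radius_range = c(0.18, 0.30),
                   wall_thickness_range = c(4, 7),
                   tumor_radius_range = c(6, 12),
                   intensity_means = c(background = 0.10, urine = 0.85,
                                       wall = 0.25, tumor = 0.45),
                   noise_sigma = 0.04, blur_sigma = 1.0,
                   tumor_probability = 0.9),
    data = list(n_labeled = 42L, n_unlabeled = 54L, n_test = 10L),
    mask = list(holes_min = 5L, holes_max = 10L, side_min = 15L,
                side_max = 20L, noise = "uniform", crop_size = 64L),
    network = list(in_channels = 1L, base_width = 8L, leaky_slope = 0.01,
                   num_classes = 4L, latent_dim = 16L),
    loss = list(alpha_background = 0.1, alpha_urine = 0.1, alpha_wall = 0.6,
                alpha_tumor = 0.8, gamma = 2, epsilon = 1e-6,
                reduction = "mean"),
    pretrain = list(optimizer = "adam", lr = 1e-3, epochs = 20L,
                    batch_size = 8L, val_fraction = 0.2),
    train = list(optimizer = "adamw", lr1 = 1e-3, epochs = 40L,
                 batch_size = 8L, val_fraction = 0.2, n_labeled = "auto",
                 weight_decay = 0.01),
    inference = list(tta = TRUE, correct = TRUE, merge = "mean",
                     connectivity = 8L))
}

.merge_config <- function(base, override, path = "") {
  for (nm in names(override)) {
    key <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(base))
      stop("unknown configuration key: ", key)
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      if (!is.list(override[[nm]]))
        stop("configuration key ", key, " must be a section")
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]], key)
    } else {
      v <- override[[nm]]
      if (is.list(v)) v <- unlist(v)
      if (!is.null(names(base[[nm]]))) {
        if (is.null(names(v)) && length(v) == length(base[[nm]]))
          names(v) <- names(base[[nm]])
        else if (!is.null(names(v)))
          v <- v[names(base[[nm]])]
      }
      base[[nm]] <- v
    }
  }
  base
}

#' Read a YAML pipeline configuration
#'
#' Missing keys fall back to [default_config()]; unknown keys are an error
#' naming the offending key.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return full configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- .merge_config(cfg, user)
  }
  cfg
}

#' Write a pipeline configuration as YAML
#' @param config configuration list.
#' @param path output file path.
#' @export
write_config <- function(config, path) {
  # named atomic vectors must become maps, or YAML drops the names
  namify <- function(x) {
    if (is.list(x)) lapply(x, namify)
    else if (!is.null(names(x))) as.list(x)
    else x
  }
  yaml::write_yaml(namify(config), path)
  invisible(path)
}

# build typed sub-configs from the plain list
.phantom_config_of <- function(cfg) {
  p <- cfg$phantom
  phantom_config(image_size = p$image_size,
                 lumen_radius_range = p$lumen_radius_range,
                 wall_thickness_range = p$wall_thickness_range,
                 tumor_radius_range = p$tumor_radius_range,
                 intensity_means = unlist(p$intensity_means),
                 noise_sigma = p$noise_sigma, blur_sigma = p$blur_sigma,
                 tumor_probability = p$tumor_probability)
}

.net_config_of <- function(cfg) {
  n <- cfg$network
  net_config(in_channels = n$in_channels, base_width = n$base_width,
             leaky_slope = n$leaky_slope, num_classes = n$num_classes,
             latent_dim = n$latent_dim)
}

.loss_weights_of <- function(cfg) {
  l <- cfg$loss
  loss_weights(alpha = c(background = l$alpha_background,
                         urine = l$alpha_urine, wall = l$alpha_wall,
                         tumor = l$alpha_tumor),
               gamma = l$gamma, epsilon = l$epsilon)
}
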