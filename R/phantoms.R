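# Synthetic bladder phantoms.  Each phantom is one bladder per image: a
# bright elliptical lumen (urine), a thin dark wall ring around it, and --
# with some probability -- a wall-attached tumor blob whose intensity lies
# between wall and urine, so that wall/tumor discrimination is nontrivial.
# Boundary blur and additive Gaussian noise emulate the soft, partially
# ambiguous boundaries that motivate the segmentation method.

#' Phantom generator configuration
#'
#' Geometry and intensity parameters of the synthetic bladder phantoms.
#' Class intensity means are ordered urine > tumor > wall, mirroring
#' T2-weighted contrast where the lumen is bright, the muscular wall dark,
#' and tumors intermediate and easily confused with the wall.
#'
#' @param image_size pixels per side (square image), >= 32.
#' @param lumen_radius_range lumen semi-axis range as a fraction of
#'   `image_size`.
#' @param wall_thickness_range wall ring thickness range in pixels.
#' @param tumor_radius_range tumor blob radius range in pixels.
#' @param intensity_means named per-class mean intensities in `[0, 1]`.
#' @param noise_sigma additive Gaussian noise scale.
#' @param blur_sigma Gaussian boundary-smoothing scale in pixels.
#' @param tumor_probability fraction of phantoms carrying a tumor.
#' @return object of class `bws_phantom_config`.
#' @export
phantom_config <- function(image_size = 96L,
                           lumen_radius_range = c(0.18, 0.30),
                           wall_thickness_range = c(4, 7),
                           tumor_radius_range = c(6, 12),
                           intensity_means = c(background = 0.10,
                                               urine = 0.85,
                                               wall = 0.25,
                                               tumor = 0.45),
                           noise_sigma = 0.04,
                           blur_sigma = 1.0,
                           tumor_probability = 0.9) {
  stopifnot(image_size >= 32,
            diff(lumen_radius_range) >= 0, lumen_radius_range[1] > 0,
            diff(wall_thickness_range) >= 0, wall_thickness_range[1] >= 1,
            diff(tumor_radius_range) >= 0, tumor_radius_range[1] >= 1,
            noise_sigma >= 0, blur_sigma >= 0,
            tumor_probability >= 0, tumor_probability <= 1)
  im <- intensity_means[c("background", "urine", "wall", "tumor")]
  if (anyNA(im) || any(im < 0) || any(im > 1))
    stop("intensity_means must name background, urine, wall, tumor in [0,1]")
  if (!(im["urine"] > im["tumor"] && im["tumor"] > im["wall"]))
    stop("intensity means must satisfy urine > tumor > wall")
  if (wall_thickness_range[2] >= lumen_radius_range[1] * image_size)
    stop(sprintf(
      "wall thickness (up to %g px) must be smaller than the minimum lumen radius (%g px)",
      wall_thickness_range[2], lumen_radius_range[1] * image_size))
  structure(list(image_size = as.integer(image_size),
                 lumen_radius_range = lumen_radius_range,
                 wall_thickness_range = wall_thickness_range,
                 tumor_radius_range = tumor_radius_range,
                 intensity_means = im,
                 noise_sigma = noise_sigma,
                 blur_sigma = blur_sigma,
                 tumor_probability = tumor_probability),
            class = "bws_phantom_config")
}

# deterministic per-item seed within 32-bit range
.derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1000003 + k) %% 2147483629)
}

# separable Gaussian blur with replicate-edge normalization, via two banded
# matrix products
.gauss_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  n <- nrow(x)
  B <- matrix(0, n, n)
  for (d in (-r):r) {
    i <- seq_len(n)
    j <- i + d
    ok <- j >= 1 & j <= n
    B[cbind(i[ok], j[ok])] <- k[d + r + 1]
  }
  B <- B / rowSums(B)
  B %*% x %*% t(B)
}

#' Generate one synthetic bladder phantom
#'
#' Builds the label map first (elliptical lumen, morphological wall ring,
#' optional tumor blob grown from a random wall pixel, replacing the wall
#' and lumen pixels it covers), then renders the image from per-class
#' intensity means, blurs boundaries, and adds clipped Gaussian noise.
#'
#' @param config a [phantom_config()].
#' @param seed integer seed; the sample is a deterministic function of
#'   `(config, seed)`.
#' @return object of class `bws_phantom`: list with `image` (matrix in
#'   `[0, 1]`), `label` (integer matrix, 0 background / 1 urine / 2 wall /
#'   3 tumor), `has_tumor`, and `seed`.
#' @export
generate_phantom <- function(config = phantom_config(), seed = 1L) {
  stopifnot(inherits(config, "bws_phantom_config"))
  set.seed(as.integer(seed))
  n <- config$image_size

  # lumen: random ellipse comfortably inside the image
  rr <- config$lumen_radius_range * n
  a <- stats::runif(1, rr[1], rr[2])
  b <- stats::runif(1, rr[1], rr[2])
  th <- stats::runif(1, 0, pi)
  tw <- stats::runif(1, config$wall_thickness_range[1],
                     config$wall_thickness_range[2])
  margin <- max(a, b) + tw + max(config$tumor_radius_range) / 2 + 2
  cx <- n / 2 + stats::runif(1, -1, 1) * max(0, n / 2 - margin) * 0.5
  cy <- n / 2 + stats::runif(1, -1, 1) * max(0, n / 2 - margin) * 0.5

  gx <- matrix(rep(seq_len(n), n), n) - cx
  gy <- matrix(rep(seq_len(n), each = n), n) - cy
  u <- gx * cos(th) + gy * sin(th)
  v <- -gx * sin(th) + gy * cos(th)
  # normalized elliptical radius: 1 on the lumen boundary
  er <- sqrt((u / a)^2 + (v / b)^2)
  lumen <- er <= 1
  # wall ring: same ellipse dilated by the wall thickness (closed by
  # construction)
  wall <- !lumen & (sqrt((u / (a + tw))^2 + (v / (b + tw))^2) <= 1)

  label <- matrix(0L, n, n)
  label[wall] <- 2L
  label[lumen] <- 1L

  has_tumor <- stats::runif(1) < config$tumor_probability
  if (has_tumor) {
    wi <- which(wall)
    pick <- wi[sample.int(length(wi), 1L)]
    pr <- stats::runif(1, config$tumor_radius_range[1],
                       config$tumor_radius_range[2])
    ti <- ((pick - 1L) %% n) + 1L
    tj <- ((pick - 1L) %/% n) + 1L
    dx <- matrix(rep(seq_len(n), n), n) - ti
    dy <- matrix(rep(seq_len(n), each = n), n) - tj
    ang <- atan2(dy, dx)
    # perturbed disk: radius modulated by a smooth angular harmonic
    ph <- stats::runif(2, 0, 2 * pi)
    amp <- stats::runif(2, 0, 0.25)
    rad <- pr * (1 + amp[1] * sin(2 * ang + ph[1]) +
                   amp[2] * sin(3 * ang + ph[2]))
    tumor <- sqrt(dx^2 + dy^2) <= rad
    # keep the phantom inside the frame
    tumor[c(1L, n), ] <- FALSE
    tumor[, c(1L, n)] <- FALSE
    label[tumor] <- 3L
    has_tumor <- any(label == 3L)
  }

  means <- config$intensity_means
  img <- matrix(means["background"], n, n)
  img[label == 1L] <- means["urine"]
  img[label == 2L] <- means["wall"]
  img[label == 3L] <- means["tumor"]
  img <- .gauss_blur(img, config$blur_sigma)
  if (config$noise_sigma > 0)
    img <- img + matrix(stats::rnorm(n * n, 0, config$noise_sigma), n, n)
  img <- pmin(pmax(img, 0), 1)

  structure(list(image = img, label = label, has_tumor = has_tumor,
                 seed = as.integer(seed)),
            class = "bws_phantom")
}

#' Generate a phantom dataset on disk
#'
#' Writes labeled, unlabeled and test splits as 8-bit grayscale PNG images
#' (labels as integer-valued PNGs) plus a JSON manifest listing split
#' membership. Each sample uses its own seed derived deterministically from
#' the dataset seed, so splits are disjoint and reproducible.
#'
#' @param n_labeled,n_unlabeled,n_test split sizes (>= 0).
#' @param config a [phantom_config()].
#' @param seed integer dataset seed.
#' @param out_dir output directory; refuses to write into a non-empty
#'   directory unless `overwrite = TRUE`.
#' @param overwrite allow writing into a non-empty directory.
#' @return the manifest (invisibly a list), with entries `labeled`,
#'   `unlabeled`, `test`; labeled/test entries carry image and label paths.
#' @export
generate_dataset <- function(n_labeled, n_unlabeled, n_test,
                             config = phantom_config(), seed = 0L,
                             out_dir, overwrite = FALSE) {
  stopifnot(n_labeled >= 0, n_unlabeled >= 0, n_test >= 0)
  if (dir.exists(out_dir) && length(dir(out_dir, all.files = FALSE)) > 0 &&
      !overwrite)
    stop("output directory ", out_dir,
         " is not empty; use overwrite = TRUE to replace it")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  manifest <- list(seed = as.integer(seed),
                   image_size = config$image_size,
                   labeled = list(), unlabeled = list(), test = list())
  counts <- c(labeled = n_labeled, unlabeled = n_unlabeled, test = n_test)
  offset <- 0L
  for (sp in names(counts)) {
    dir.create(file.path(out_dir, sp), showWarnings = FALSE)
    for (i in seq_len(counts[[sp]])) {
      s <- .derive_seed(seed, offset + i)
      ph <- generate_phantom(config, seed = s)
      img_path <- file.path(sp, sprintf("%s_%03d.png", sp, i))
      write_image_png(ph$image, file.path(out_dir, img_path))
      entry <- list(image = img_path, seed = s, has_tumor = ph$has_tumor)
      if (sp != "unlabeled") {
        lab_path <- file.path(sp, sprintf("%s_%03d_label.png", sp, i))
        write_label_png(ph$label, file.path(out_dir, lab_path))
        entry$label <- lab_path
      }
      manifest[[sp]][[i]] <- entry
    }
    offset <- offset + counts[[sp]]
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a dataset manifest
#'
#' @param dir dataset directory written by [generate_dataset()].
#' @return manifest list with absolute paths resolved against `dir`.
#' @export
read_manifest <- function(dir) {
  path <- file.path(dir, "manifest.json")
  if (!file.exists(path)) stop("no manifest.json in ", dir)
  m <- jsonlite::read_json(path)
  m$dir <- dir
  m
}

# load all images (and labels where present) of one split as lists
.load_split <- function(manifest, split) {
  entries <- manifest[[split]]
  images <- lapply(entries, function(e)
    read_image_png(file.path(manifest$dir, e$image)))
  labels <- lapply(entries, function(e)
    if (!is.null(e$label)) read_label_png(file.path(manifest$dir, e$label)))
  list(images = images, labels = labels)
}

#' @export
print.bws_phantom <- function(x, ...) {
  cat(sprintf("<bws_phantom> %d x %d, classes {%s}, tumor: %s, seed %d\n",
              nrow(x$image), ncol(x$image),
              paste(sort(unique(as.vector(x$label))), collapse = ","),
              x$has_tumor, x$seed))
  invisible(x)
}
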