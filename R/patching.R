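# Masked-patch preparation for self-supervised pre-training: random square
# crops and "hole" masking, where square regions of the patch are replaced
# by noise.  Two independently masked views of the same patch form one
# pre-training pair.

#' Random square crop
#'
#' Crops a `size x size` window at an offset drawn uniformly over all valid
#' positions, deterministically for a given seed.
#'
#' @param image numeric matrix.
#' @param size crop side in pixels; must not exceed either image dimension.
#' @param seed integer seed.
#' @return `size x size` matrix with attribute `offset` (top-left corner,
#'   1-based `c(row, col)`).
#' @export
random_crop <- function(image, size, seed = 1L) {
  d <- dim(image)
  if (size > d[1] || size > d[2])
    stop(sprintf("crop size %d exceeds image size %d x %d", size,
                 d[1], d[2]))
  set.seed(as.integer(seed))
  i <- sample.int(d[1] - size + 1L, 1L)
  j <- sample.int(d[2] - size + 1L, 1L)
  out <- image[i:(i + size - 1L), j:(j + size - 1L)]
  attr(out, "offset") <- c(i, j)
  out
}

#' Sample square masking holes
#'
#' Draws a uniform number of holes in `[n_min, n_max]`, each an axis-aligned
#' square with side uniform in `[s_min, s_max]`, placed uniformly so that
#' every hole lies fully inside the patch. Holes may overlap.
#'
#' @param n_min,n_max hole-count range (defaults 5-10).
#' @param s_min,s_max hole-side range in pixels (defaults 15-20).
#' @param patch_size patch side in pixels; must exceed `s_max`.
#' @param seed integer seed.
#' @return data frame with columns `row`, `col` (1-based top-left corner)
#'   and `side`.
#' @export
sample_holes <- function(n_min = 5L, n_max = 10L, s_min = 15L, s_max = 20L,
                         patch_size, seed = 1L) {
  stopifnot(n_min >= 0, n_max >= n_min, s_min >= 1, s_max >= s_min)
  if (s_max >= patch_size)
    stop(sprintf("maximum hole side (%d) must be smaller than patch size (%d)",
                 s_max, patch_size))
  set.seed(as.integer(seed))
  n <- if (n_max > n_min) sample(n_min:n_max, 1L) else n_min
  if (n == 0L)
    return(data.frame(row = integer(), col = integer(), side = integer()))
  side <- if (s_max > s_min) sample(s_min:s_max, n, replace = TRUE) else
    rep(as.integer(s_min), n)
  row <- vapply(side, function(s) sample.int(patch_size - s + 1L, 1L), 1L)
  col <- vapply(side, function(s) sample.int(patch_size - s + 1L, 1L), 1L)
  data.frame(row = row, col = col, side = side)
}

#' Replace hole regions by noise
#'
#' Pixels inside the given holes are replaced by random noise (uniform on
#' `[0, 1]` by default, or clipped Gaussian around 0.5); all other pixels
#' are untouched.
#'
#' @param patch numeric matrix in `[0, 1]`.
#' @param holes data frame from [sample_holes()].
#' @param seed integer seed for the noise fill.
#' @param noise `"uniform"` or `"gaussian"`.
#' @return masked patch, same shape, values in `[0, 1]`.
#' @export
apply_mask <- function(patch, holes, seed = 1L,
                       noise = c("uniform", "gaussian")) {
  noise <- match.arg(noise)
  d <- dim(patch)
  if (nrow(holes) == 0L) return(patch)
  if (any(holes$row < 1 | holes$col < 1 |
            holes$row + holes$side - 1L > d[1] |
            holes$col + holes$side - 1L > d[2]))
    stop("holes must lie fully inside the patch")
  set.seed(as.integer(seed))
  out <- patch
  for (h in seq_len(nrow(holes))) {
    s <- holes$side[h]
    fill <- if (noise == "uniform") stats::runif(s * s) else
      pmin(pmax(stats::rnorm(s * s, 0.5, 0.25), 0), 1)
    out[holes$row[h]:(holes$row[h] + s - 1L),
        holes$col[h]:(holes$col[h] + s - 1L)] <- matrix(fill, s, s)
  }
  out
}

#' Build a pre-training pair of masked views
#'
#' Applies two independent hole samplings and noise fills to copies of the
#' same patch. The two views are the inputs whose reconstructions the
#' contrast consistency loss compares.
#'
#' @param patch numeric matrix (already cropped to working size).
#' @param mask_config list with `holes_min`, `holes_max`, `side_min`,
#'   `side_max`, `noise`.
#' @param seed integer seed; the two views use seeds derived from it.
#' @return object of class `bws_pretrain_pair`: list with `original`,
#'   `view1`, `view2`, `holes1`, `holes2`.
#' @export
make_pretrain_pair <- function(patch,
                               mask_config = list(holes_min = 5L,
                                                  holes_max = 10L,
                                                  side_min = 15L,
                                                  side_max = 20L,
                                                  noise = "uniform"),
                               seed = 1L) {
  m <- mask_config
  seed <- as.integer(seed)
  mk <- function(s) {
    h <- sample_holes(m$holes_min, m$holes_max, m$side_min, m$side_max,
                      patch_size = min(dim(patch)), seed = s)
    list(view = apply_mask(patch, h, seed = .derive_seed(s, 1L),
                           noise = m$noise),
         holes = h)
  }
  v1 <- mk(.derive_seed(seed, 11L))
  v2 <- mk(.derive_seed(seed, 12L))
  structure(list(original = patch, view1 = v1$view, view2 = v2$view,
                 holes1 = v1$holes, holes2 = v2$holes),
            class = "bws_pretrain_pair")
}
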