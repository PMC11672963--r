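# Independent brute-force oracles used across test files.  These are
# deliberately naive re-implementations (loops, set arithmetic) kept
# separate from the package's own code paths.

# connected-component count by repeated flood fill over an explicit stack
oracle_components <- function(mask, connectivity = 8) {
  H <- nrow(mask); W <- ncol(mask)
  seen <- matrix(FALSE, H, W)
  nb <- if (connectivity == 8)
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  count <- 0L
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (!mask[i, j] || seen[i, j]) next
    count <- count + 1L
    stack <- list(c(i, j)); seen[i, j] <- TRUE
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (s in seq_len(nrow(nb))) {
        ii <- p[1] + nb[s, 1]; jj <- p[2] + nb[s, 2]
        if (ii < 1 || ii > H || jj < 1 || jj > W) next
        if (mask[ii, jj] && !seen[ii, jj]) {
          seen[ii, jj] <- TRUE
          stack[[length(stack) + 1L]] <- c(ii, jj)
        }
      }
    }
  }
  count
}

# number of interior background holes of a foreground mask (4-connected
# background regions not touching the border)
oracle_holes <- function(fg) {
  H <- nrow(fg); W <- ncol(fg)
  bg <- !fg
  seen <- matrix(FALSE, H, W)
  holes <- 0L
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (!bg[i, j] || seen[i, j]) next
    stack <- list(c(i, j)); seen[i, j] <- TRUE
    touches <- FALSE
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      if (p[1] == 1 || p[1] == H || p[2] == 1 || p[2] == W) touches <- TRUE
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        ii <- p[1] + d[1]; jj <- p[2] + d[2]
        if (ii < 1 || ii > H || jj < 1 || jj > W) next
        if (bg[ii, jj] && !seen[ii, jj]) {
          seen[ii, jj] <- TRUE
          stack[[length(stack) + 1L]] <- c(ii, jj)
        }
      }
    }
    if (!touches) holes <- holes + 1L
  }
  holes
}

# random blobby label map with several components and holes, for
# post-processing property tests
random_noisy_label <- function(seed, size = 32L) {
  set.seed(seed)
  lab <- matrix(0L, size, size)
  nblob <- sample(2:4, 1)
  for (b in seq_len(nblob)) {
    ci <- sample(5:(size - 5), 1); cj <- sample(5:(size - 5), 1)
    r <- sample(3:7, 1)
    d2 <- outer(seq_len(size), rep(1, size)) * 0
    ii <- matrix(rep(seq_len(size), size), size)
    jj <- matrix(rep(seq_len(size), each = size), size)
    m <- (ii - ci)^2 + (jj - cj)^2 <= r^2
    lab[m] <- sample(1:3, 1)
  }
  # punch a few interior holes and sprinkle speckle
  for (h in seq_len(sample(1:3, 1))) {
    ci <- sample(3:(size - 2), 1); cj <- sample(3:(size - 2), 1)
    if (lab[ci, cj] > 0) lab[ci + (-1:0), cj + (-1:0)] <- 0L
  }
  sp <- sample(size^2, 8)
  lab[sp] <- sample(0:3, 8, replace = TRUE)
  lab
}

tiny_train_config <- function(seed = 1L, epochs = 2L) {
  cfg <- default_config()
  cfg$seed <- as.integer(seed)
  cfg$phantom$image_size <- 32L
  cfg$phantom$lumen_radius_range <- c(0.22, 0.3)
  cfg$phantom$wall_thickness_range <- c(3, 4)
  cfg$phantom$tumor_radius_range <- c(4, 6)
  cfg$network$base_width <- 2L
  cfg$network$latent_dim <- 4L
  cfg$mask$crop_size <- 32L
  cfg$mask$side_min <- 4L
  cfg$mask$side_max <- 6L
  cfg$pretrain$epochs <- as.integer(epochs)
  cfg$pretrain$batch_size <- 2L
  cfg$train$epochs <- as.integer(epochs)
  cfg$train$batch_size <- 4L
  cfg
}

tiny_phantoms <- function(n, cfg, seed0 = 100L) {
  pc <- bladderseg:::.phantom_config_of(cfg)
  lapply(seq_len(n), function(i) generate_phantom(pc, seed = seed0 + i))
}
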