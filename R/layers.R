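# Differentiable layer primitives on (H, W, C, N) arrays.  Each *_fwd
# returns the output plus whatever the matching *_bwd needs; backward
# functions return the input gradient and parameter gradients.  The
# architecture graphs live in networks.R / training.R.

#' Leaky rectified linear unit
#'
#' Elementwise activation: `x` for `x >= 0`, `a * x` for `x < 0`. The small
#' negative slope keeps gradient flowing through inactive units so they can
#' recover during training.
#'
#' @param x numeric vector, matrix or array.
#' @param a positive negative-branch slope (default 0.01).
#' @return object of the same shape as `x`.
#' @export
#' @examples
#' leaky_relu(c(-2, 0, 5), a = 0.01)
leaky_relu <- function(x, a = 0.01) {
  stopifnot(is.numeric(a), length(a) == 1L, a > 0)
  neg <- x < 0
  x[neg] <- a * x[neg]
  x
}

lrelu_fwd <- function(x, a = 0.01) {
  neg <- x < 0
  y <- x
  y[neg] <- a * x[neg]
  list(y = y, neg = neg, a = a)
}

lrelu_bwd <- function(dy, cache) {
  dy[cache$neg] <- cache$a * dy[cache$neg]
  dy
}

# --- batch normalization (per channel over H, W, N) -------------------------

.channel_stat <- function(x, d) {
  # x: (H,W,C,N) -> per-channel aggregate over H*W and N
  m <- matrix(colMeans(matrix(x, nrow = d[1] * d[2])), nrow = d[3])
  rowMeans(m)
}

bn_fwd <- function(x, gamma, beta, state, train, momentum = 0.1,
                   eps = 1e-5) {
  d <- dim(x)
  hw <- d[1] * d[2]
  if (train) {
    mu <- .channel_stat(x, d)
    xc <- x - rep(mu, each = hw)
    v <- .channel_stat(xc * xc, d)
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * v
  } else {
    mu <- state$mean
    v <- state$var
    xc <- x - rep(mu, each = hw)
  }
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- xc * rep(inv_sd, each = hw)
  y <- xhat * rep(gamma, each = hw) + rep(beta, each = hw)
  list(y = y, xhat = xhat, inv_sd = inv_sd, gamma = gamma, state = state,
       train = train)
}

bn_bwd <- function(dy, cache) {
  d <- dim(dy)
  hw <- d[1] * d[2]
  xhat <- cache$xhat
  dgamma <- .channel_stat(dy * xhat, d) * (hw * d[4])
  dbeta <- .channel_stat(dy, d) * (hw * d[4])
  g <- rep(cache$gamma * cache$inv_sd, each = hw)
  if (!cache$train) {
    return(list(dx = dy * g, dgamma = dgamma, dbeta = dbeta))
  }
  m_dy <- .channel_stat(dy, d)
  m_dyx <- .channel_stat(dy * xhat, d)
  dx <- g * (dy - rep(m_dy, each = hw) - xhat * rep(m_dyx, each = hw))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# --- convolution wrappers ---------------------------------------------------

conv_fwd <- function(x, w, b) {
  y <- cpp_conv2d_fwd(x, w, b)
  list(y = y, x = x, w = w)
}

conv_bwd <- function(dy, cache) {
  cpp_conv2d_bwd(cache$x, cache$w, dy)
}

# conv 3x3 -> BN -> leaky ReLU, the basic block of both networks.  The BN
# and activation are fused in C++; the plain-R bn_fwd/bn_bwd above serve as
# the independent reference implementation.
block_fwd <- function(x, p, s, name, train, slope, momentum = 0.1) {
  cv <- conv_fwd(x, p[[paste0(name, ".w")]], p[[paste0(name, ".b")]])
  g <- p[[paste0(name, ".g")]]
  st <- s[[name]]
  out <- if (train)
    cpp_bn_lrelu_fwd(cv$y, g, p[[paste0(name, ".be")]], numeric(0),
                     numeric(0), slope, 1e-5)
  else
    cpp_bn_lrelu_fwd(cv$y, g, p[[paste0(name, ".be")]], st$mean, st$var,
                     slope, 1e-5)
  if (train) {
    st$mean <- (1 - momentum) * st$mean + momentum * out$mean
    st$var <- (1 - momentum) * st$var + momentum * out$var
    s[[name]] <- st
  }
  list(y = out$y, cv = cv, xhat = out$xhat, inv_sd = out$inv_sd,
       gamma = g, slope = slope, train = train, state = s)
}

block_bwd <- function(dy, cache, name, grads) {
  bb <- cpp_bn_lrelu_bwd(dy, cache$y, cache$xhat, cache$gamma,
                         cache$inv_sd, cache$slope, cache$train)
  cb <- conv_bwd(bb$dx, cache$cv)
  grads[[paste0(name, ".w")]] <- cb$dw
  grads[[paste0(name, ".b")]] <- cb$db
  grads[[paste0(name, ".g")]] <- bb$dgamma
  grads[[paste0(name, ".be")]] <- bb$dbeta
  list(dx = cb$dx, grads = grads)
}

# --- pooling ----------------------------------------------------------------

#' 2x2 max pooling with argmax indices
#'
#' Pools with a 2x2 window and stride 2 and records, for every window, the
#' position of its maximum so that [max_unpool()] can later reinsert each
#' retained value at its original location. Ties take the first maximal
#' element in row-major window order.
#'
#' @param x array `(H, W, C, N)` or a plain `H x W` matrix; spatial dims must
#'   be even.
#' @return list with `y` (pooled values) and `idx` (integer codes
#'   `di + 2*dj` of the argmax offset within each window), both of spatial
#'   size `H/2 x W/2`.
#' @seealso [max_unpool()]
#' @export
max_pool_with_indices <- function(x) {
  was_mat <- is.matrix(x)
  if (was_mat) dim(x) <- c(dim(x), 1L, 1L)
  out <- cpp_maxpool2_fwd(x)
  if (was_mat) {
    out$y <- out$y[, , 1L, 1L, drop = TRUE]
    out$idx <- out$idx[, , 1L, 1L, drop = TRUE]
    dim(out$y) <- dim(x)[1:2] / 2L
    dim(out$idx) <- dim(x)[1:2] / 2L
  }
  out
}

#' Index-preserving max unpooling
#'
#' Inverse of [max_pool_with_indices()]: each pooled value is written back at
#' the recorded argmax position of its window; every other output pixel is
#' zero.
#'
#' @param pooled pooled values, `(H/2, W/2, C, N)` array or matrix.
#' @param idx argmax codes from [max_pool_with_indices()], same shape.
#' @param out_size integer vector `c(H, W)` of the unpooled spatial size.
#' @return array (or matrix) of spatial size `out_size`.
#' @export
max_unpool <- function(pooled, idx, out_size) {
  stopifnot(length(out_size) == 2L)
  was_mat <- is.matrix(pooled)
  if (was_mat) {
    dim(pooled) <- c(dim(pooled), 1L, 1L)
    idx <- as.integer(idx)
    dim(idx) <- dim(pooled)
  }
  if (!identical(dim(pooled), dim(idx)))
    stop("pooled values and index map have different shapes")
  y <- cpp_maxunpool_fwd(pooled, idx, as.integer(out_size[1]),
                         as.integer(out_size[2]))
  if (was_mat) {
    y <- y[, , 1L, 1L, drop = TRUE]
    dim(y) <- as.integer(out_size)
  }
  y
}

# --- dense / misc -----------------------------------------------------------

# x: (F, N) feature matrix
affine_fwd <- function(x, w, b) {
  list(y = w %*% x + b, x = x, w = w)
}

affine_bwd <- function(dy, cache) {
  list(dx = t(cache$w) %*% dy, dw = dy %*% t(cache$x), db = rowSums(dy))
}

# global average pool (H,W,C,N) -> (C,N)
gap_fwd <- function(x) {
  d <- dim(x)
  y <- matrix(colMeans(matrix(x, nrow = d[1] * d[2])), nrow = d[3])
  list(y = y, d = d)
}

gap_bwd <- function(dy, cache) {
  d <- cache$d
  array(rep(as.vector(dy), each = d[1] * d[2]) / (d[1] * d[2]), dim = d)
}

sigmoid_fwd <- function(x) {
  y <- 1 / (1 + exp(-x))
  list(y = y)
}

sigmoid_bwd <- function(dy, cache) dy * cache$y * (1 - cache$y)

# softmax over the channel dimension of (H,W,C,N)
softmax_fwd <- function(x) {
  d <- dim(x)
  hw <- d[1] * d[2]
  m <- matrix(aperm(x, c(3, 1, 2, 4)), nrow = d[3])
  m <- exp(sweep(m, 2, apply(m, 2, max)))
  m <- sweep(m, 2, colSums(m), "/")
  p <- aperm(array(m, dim = d[c(3, 1, 2, 4)]), c(2, 3, 1, 4))
  list(y = p)
}

# dy is dL/dp; returns dL/dlogits
softmax_bwd <- function(dy, p) {
  d <- dim(p)
  pm <- matrix(aperm(p, c(3, 1, 2, 4)), nrow = d[3])
  dm <- matrix(aperm(dy, c(3, 1, 2, 4)), nrow = d[3])
  sm <- pm * sweep(dm, 2, colSums(dm * pm))
  aperm(array(sm, dim = d[c(3, 1, 2, 4)]), c(2, 3, 1, 4))
}
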