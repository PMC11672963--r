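# Encoder-decoder networks.  Both stages share one trunk: an encoder of nine
# 3x3 conv blocks (conv -> BN -> leaky ReLU) arranged 3-3-3 between three
# 2x2 max-pooling layers that record argmax indices, and a decoder of four
# conv blocks interleaved 1-1-2 with three index-preserving unpooling
# layers.  The reconstruction network caps the trunk with a 1x1 conv +
# sigmoid; the segmentation network caps it with a 1x1 conv + softmax over
# the four classes and attaches a small variational branch at the
# bottleneck.

#' Network configuration
#'
#' Architecture hyper-parameters shared by the reconstruction and
#' segmentation networks. Channel widths double at each pooling stage
#' (`base_width`, `2*base_width`, `4*base_width`), so the feature map
#' shrinks spatially while the channel count grows.
#'
#' @param in_channels number of input channels (grayscale: 1).
#' @param base_width channels of the first encoder stage; stages use
#'   `base_width * c(1, 2, 4)`.
#' @param leaky_slope negative slope of the leaky ReLU.
#' @param num_classes segmentation classes (background, urine, wall, tumor).
#' @param latent_dim size of the variational branch's Gaussian latent.
#' @return object of class `bws_net_config`.
#' @export
net_config <- function(in_channels = 1L, base_width = 8L,
                       leaky_slope = 0.01, num_classes = 4L,
                       latent_dim = 16L) {
  stopifnot(base_width >= 1, latent_dim >= 1, leaky_slope > 0)
  cfg <- list(
    in_channels = as.integer(in_channels),
    base_width = as.integer(base_width),
    widths = as.integer(base_width * c(1L, 2L, 4L)),
    encoder_blocks = 9L, pool_stages = 3L,
    decoder_blocks = 4L, upsample_stages = 3L,
    leaky_slope = leaky_slope,
    num_classes = as.integer(num_classes),
    latent_dim = as.integer(latent_dim))
  class(cfg) <- "bws_net_config"
  cfg
}

# block name -> c(cin, cout) for the trunk
.trunk_plan <- function(cfg) {
  w <- cfg$widths
  list(
    e1 = c(cfg$in_channels, w[1]), e2 = c(w[1], w[1]), e3 = c(w[1], w[1]),
    e4 = c(w[1], w[2]), e5 = c(w[2], w[2]), e6 = c(w[2], w[2]),
    e7 = c(w[2], w[3]), e8 = c(w[3], w[3]), e9 = c(w[3], w[3]),
    d1 = c(w[3], w[2]), d2 = c(w[2], w[1]), d3 = c(w[1], w[1]),
    d4 = c(w[1], w[1]))
}

.he_init <- function(k, cin, cout) {
  array(stats::rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
        dim = c(k, k, cin, cout))
}

.new_block <- function(p, s, name, cin, cout, k = 3L) {
  p[[paste0(name, ".w")]] <- .he_init(k, cin, cout)
  p[[paste0(name, ".b")]] <- numeric(cout)
  p[[paste0(name, ".g")]] <- rep(1, cout)
  p[[paste0(name, ".be")]] <- numeric(cout)
  s[[name]] <- list(mean = numeric(cout), var = rep(1, cout))
  list(p = p, s = s)
}

.init_head <- function(p, cfg, head) {
  w1 <- cfg$widths[1]
  if (head == "recon") {
    p[["rh.w"]] <- .he_init(1L, w1, 1L)
    p[["rh.b"]] <- numeric(1)
  } else {
    p[["sh.w"]] <- .he_init(1L, w1, cfg$num_classes)
    p[["sh.b"]] <- numeric(cfg$num_classes)
  }
  p
}

#' Build an untrained network
#'
#' @param config a [net_config()].
#' @param head `"recon"` for the reconstruction network or `"seg"` for the
#'   segmentation network (softmax head plus variational branch).
#' @param seed integer seed for the random initialization.
#' @return object of class `bws_net` holding parameters, batch-norm running
#'   statistics and the configuration.
#' @export
build_net <- function(config = net_config(), head = c("seg", "recon"),
                      seed = 1L) {
  head <- match.arg(head)
  set.seed(as.integer(seed))
  p <- list(); s <- list()
  plan <- .trunk_plan(config)
  for (nm in names(plan)) {
    bl <- .new_block(p, s, nm, plan[[nm]][1], plan[[nm]][2])
    p <- bl$p; s <- bl$s
  }
  p <- .init_head(p, config, head)
  if (head == "seg") {
    w3 <- config$widths[3]; L <- config$latent_dim
    p[["vmu.w"]] <- matrix(stats::rnorm(L * w3, 0, sqrt(1 / w3)), L, w3)
    p[["vmu.b"]] <- numeric(L)
    p[["vlv.w"]] <- matrix(stats::rnorm(L * w3, 0, sqrt(1 / w3)), L, w3)
    p[["vlv.b"]] <- numeric(L)
    p[["vfc.w"]] <- matrix(stats::rnorm(w3 * L, 0, sqrt(1 / L)), w3, L)
    p[["vfc.b"]] <- numeric(w3)
    bl <- .new_block(p, s, "v1", w3, w3)
    p <- bl$p; s <- bl$s
    p[["v2.w"]] <- .he_init(3L, w3, w3)
    p[["v2.b"]] <- numeric(w3)
  }
  structure(list(params = p, bn_state = s, config = config, head = head),
            class = "bws_net")
}

.trunk_param_names <- function() {
  blocks <- c(paste0("e", 1:9), paste0("d", 1:4))
  as.vector(t(outer(blocks, c(".w", ".b", ".g", ".be"), paste0)))
}

.check_input_size <- function(x, cfg) {
  d <- dim(x)
  div <- 2^cfg$pool_stages
  if (d[1] %% div != 0 || d[2] %% div != 0)
    stop(sprintf(
      "input spatial size %d x %d must be divisible by %d (2^pool_stages)",
      d[1], d[2], div))
}

.as_batch <- function(image, cfg) {
  if (is.matrix(image)) dim(image) <- c(dim(image), 1L, 1L)
  if (length(dim(image)) == 3L) dim(image) <- c(dim(image), 1L)
  stopifnot(length(dim(image)) == 4L, dim(image)[3] == cfg$in_channels)
  image
}

# Encoder: blocks e1..e9 with pools after e3, e6, e9.  Returns bottleneck
# features plus the pooling-index stack and pre-pool sizes (the
# EncoderState) and per-block caches for backprop.
encoder_fwd <- function(x, p, s, cfg, train) {
  caches <- list(); idxs <- list(); sizes <- list()
  a <- cfg$leaky_slope
  for (stage in 1:3) {
    for (b in 1:3) {
      nm <- paste0("e", (stage - 1) * 3 + b)
      bl <- block_fwd(x, p, s, nm, train, a)
      s <- bl$state
      caches[[nm]] <- bl
      x <- bl$y
    }
    sizes[[stage]] <- dim(x)[1:2]
    pl <- cpp_maxpool2_fwd(x)
    idxs[[stage]] <- pl$idx
    x <- pl$y
  }
  list(bottleneck = x, pool_indices = idxs, pre_pool_sizes = sizes,
       caches = caches, state = s)
}

encoder_bwd <- function(dbott, enc, p, grads) {
  dx <- dbott
  for (stage in 3:1) {
    dx <- cpp_maxpool2_bwd(dx, enc$pool_indices[[stage]],
                           as.integer(enc$pre_pool_sizes[[stage]][1]),
                           as.integer(enc$pre_pool_sizes[[stage]][2]))
    for (b in 3:1) {
      nm <- paste0("e", (stage - 1) * 3 + b)
      bb <- block_bwd(dx, enc$caches[[nm]], nm, grads)
      grads <- bb$grads
      dx <- bb$dx
    }
  }
  list(dx = dx, grads = grads)
}

# Decoder: unpool3 -> d1 -> unpool2 -> d2 -> unpool1 -> d3 -> d4
decoder_fwd <- function(bott, enc, p, s, cfg, train) {
  caches <- list()
  a <- cfg$leaky_slope
  x <- bott
  for (stage in 3:1) {
    x <- cpp_maxunpool_fwd(x, enc$pool_indices[[stage]],
                           as.integer(enc$pre_pool_sizes[[stage]][1]),
                           as.integer(enc$pre_pool_sizes[[stage]][2]))
    nm <- paste0("d", 4 - stage)
    bl <- block_fwd(x, p, s, nm, train, a)
    s <- bl$state
    caches[[nm]] <- bl
    x <- bl$y
  }
  bl <- block_fwd(x, p, s, "d4", train, a)
  s <- bl$state
  caches[["d4"]] <- bl
  list(y = bl$y, caches = caches, state = s)
}

decoder_bwd <- function(dy, dec, enc, grads) {
  bb <- block_bwd(dy, dec$caches[["d4"]], "d4", grads)
  grads <- bb$grads
  dx <- bb$dx
  for (stage in 1:3) {
    nm <- paste0("d", 4 - stage)
    bb <- block_bwd(dx, dec$caches[[nm]], nm, grads)
    grads <- bb$grads
    dx <- cpp_maxunpool_bwd(bb$dx, enc$pool_indices[[stage]])
  }
  list(dbott = dx, grads = grads)
}

# Full reconstruction-network pass with caches (training) ------------------

recon_fwd <- function(x, net, train) {
  p <- net$params; cfg <- net$config
  enc <- encoder_fwd(x, p, net$bn_state, cfg, train)
  dec <- decoder_fwd(enc$bottleneck, enc, p, enc$state, cfg, train)
  hd <- conv_fwd(dec$y, p[["rh.w"]], p[["rh.b"]])
  sg <- sigmoid_fwd(hd$y)
  list(y = sg$y, enc = enc, dec = dec, hd = hd, sg = sg,
       state = dec$state)
}

recon_bwd <- function(dy, fw, net) {
  grads <- list()
  dy <- sigmoid_bwd(dy, fw$sg)
  cb <- conv_bwd(dy, fw$hd)
  grads[["rh.w"]] <- cb$dw; grads[["rh.b"]] <- cb$db
  db <- decoder_bwd(cb$dx, fw$dec, fw$enc, grads)
  eb <- encoder_bwd(db$dbott, fw$enc, net$params, db$grads)
  eb$grads
}

# Full segmentation-network pass.  eps is the (latent_dim x N) standard
# normal draw for the reparameterized sample; NULL uses the posterior mean
# (deterministic, used at inference).
seg_fwd <- function(x, net, train, eps = NULL) {
  p <- net$params; cfg <- net$config
  enc <- encoder_fwd(x, p, net$bn_state, cfg, train)
  dec <- decoder_fwd(enc$bottleneck, enc, p, enc$state, cfg, train)
  hd <- conv_fwd(dec$y, p[["sh.w"]], p[["sh.b"]])
  sm <- softmax_fwd(hd$y)

  # variational branch from the bottleneck
  gp <- gap_fwd(enc$bottleneck)
  mu <- affine_fwd(gp$y, p[["vmu.w"]], p[["vmu.b"]])
  lv <- affine_fwd(gp$y, p[["vlv.w"]], p[["vlv.b"]])
  if (is.null(eps)) eps <- matrix(0, nrow(mu$y), ncol(mu$y))
  z <- mu$y + exp(lv$y / 2) * eps
  fc <- affine_fwd(z, p[["vfc.w"]], p[["vfc.b"]])
  bd <- dim(enc$bottleneck)
  # broadcast the decoded vector over the bottleneck's spatial grid
  br <- array(rep(as.vector(fc$y), each = bd[1] * bd[2]), dim = bd)
  v1 <- block_fwd(br, p, dec$state, "v1", train, cfg$leaky_slope)
  v2 <- conv_fwd(v1$y, p[["v2.w"]], p[["v2.b"]])

  list(prob = sm$y, mu = mu$y, log_var = lv$y, vae_recon = v2$y,
       bottleneck = enc$bottleneck,
       enc = enc, dec = dec, hd = hd, sm = sm, gp = gp, mu_c = mu,
       lv_c = lv, eps = eps, fc = fc, v1 = v1, v2 = v2, bd = bd,
       state = v1$state)
}

# dprob: dL/dprob; dmu, dlv: grads of the KL term; dvrec: dL/d vae_recon;
# dbott_mse: dL/d bottleneck coming from the (detached-target) MSE term.
seg_bwd <- function(fw, net, dprob, dmu, dlv, dvrec) {
  p <- net$params
  grads <- list()

  # variational branch
  cb2 <- conv_bwd(dvrec, fw$v2)
  grads[["v2.w"]] <- cb2$dw; grads[["v2.b"]] <- cb2$db
  bb1 <- block_bwd(cb2$dx, fw$v1, "v1", grads)
  grads <- bb1$grads
  bd <- fw$bd
  dfc <- matrix(colSums(matrix(bb1$dx, nrow = bd[1] * bd[2])), nrow = bd[3])
  ab <- affine_bwd(dfc, fw$fc)
  grads[["vfc.w"]] <- ab$dw; grads[["vfc.b"]] <- ab$db
  dz <- ab$dx
  dmu_t <- dmu + dz
  dlv_t <- dlv + dz * fw$eps * exp(fw$lv_c$y / 2) / 2
  amu <- affine_bwd(dmu_t, fw$mu_c)
  alv <- affine_bwd(dlv_t, fw$lv_c)
  grads[["vmu.w"]] <- amu$dw; grads[["vmu.b"]] <- amu$db
  grads[["vlv.w"]] <- alv$dw; grads[["vlv.b"]] <- alv$db
  dgap <- amu$dx + alv$dx
  dbott_vae <- gap_bwd(dgap, fw$gp)

  # softmax head and decoder
  dlog <- softmax_bwd(dprob, fw$sm$y)
  cbh <- conv_bwd(dlog, fw$hd)
  grads[["sh.w"]] <- cbh$dw; grads[["sh.b"]] <- cbh$db
  db <- decoder_bwd(cbh$dx, fw$dec, fw$enc, grads)
  eb <- encoder_bwd(db$dbott + dbott_vae, fw$enc, p, db$grads)
  eb$grads
}

# --- user-facing forward passes -------------------------------------------

#' Reconstruction-network forward pass
#'
#' Runs an image through the encoder-decoder reconstruction network in
#' evaluation mode (batch-norm running statistics, no sampling). The output
#' has the same spatial size as the input and values in `[0, 1]` from the
#' final sigmoid.
#'
#' @param image numeric matrix in `[0, 1]`, or an `(H, W, 1, N)` array.
#'   Spatial size must be divisible by `2^pool_stages` (8 by default).
#' @param net a `bws_net` with `head = "recon"`.
#' @return reconstruction of the same spatial size as `image`.
#' @export
reconstruct_forward <- function(image, net) {
  stopifnot(inherits(net, "bws_net"), net$head == "recon")
  x <- .as_batch(image, net$config)
  .check_input_size(x, net$config)
  y <- recon_fwd(x, net, train = FALSE)$y
  if (is.matrix(image)) {
    y <- y[, , 1L, 1L]
    dim(y) <- dim(image)
  }
  y
}

#' Segmentation-network forward pass
#'
#' Runs an image through the segmentation network in evaluation mode and
#' returns the per-pixel class-probability map together with the
#' variational branch's posterior parameters and its reconstruction of the
#' bottleneck feature field.
#'
#' @inheritParams reconstruct_forward
#' @param net a `bws_net` with `head = "seg"`.
#' @return list with `prob` (`H x W x num_classes x N`, channels sum to 1
#'   per pixel), `latent` (list `mu`, `log_var`), and `vae_recon`.
#' @export
segment_forward <- function(image, net) {
  stopifnot(inherits(net, "bws_net"), net$head == "seg")
  x <- .as_batch(image, net$config)
  .check_input_size(x, net$config)
  fw <- seg_fwd(x, net, train = FALSE, eps = NULL)
  prob <- fw$prob
  if (is.matrix(image)) prob <- prob[, , , 1L, drop = TRUE]
  list(prob = prob, latent = list(mu = fw$mu, log_var = fw$log_var),
       vae_recon = fw$vae_recon)
}

#' Transfer pre-trained trunk weights into a segmentation network
#'
#' Copies every encoder/decoder trunk parameter (convolution weights and
#' biases, batch-norm scale/shift and running statistics) from a pre-trained
#' reconstruction network into a segmentation network. The classification
#' head and the variational branch keep their random initialization and are
#' trained at their own learning rate (see [build_param_groups()]).
#'
#' @param pretrained_net `bws_net` with `head = "recon"` (or another
#'   `"seg"` net with a matching trunk).
#' @param seg_net `bws_net` with `head = "seg"`.
#' @return `seg_net` with trunk weights replaced; the attached
#'   `"transfer_report"` attribute is a data frame listing every parameter
#'   group as `transferred` or `random`.
#' @export
transfer_weights <- function(pretrained_net, seg_net) {
  stopifnot(inherits(pretrained_net, "bws_net"), inherits(seg_net, "bws_net"),
            seg_net$head == "seg")
  trunk <- .trunk_param_names()
  for (nm in trunk) {
    src <- pretrained_net$params[[nm]]
    dst <- seg_net$params[[nm]]
    if (is.null(src)) stop("pretrained network lacks parameter ", nm)
    if (!identical(dim(src), dim(dst)) || length(src) != length(dst))
      stop(sprintf("shape mismatch at layer %s: pretrained %s vs target %s",
                   nm, paste(dim(src), collapse = "x"),
                   paste(dim(dst), collapse = "x")))
    seg_net$params[[nm]] <- src
  }
  for (nm in c(paste0("e", 1:9), paste0("d", 1:4)))
    seg_net$bn_state[[nm]] <- pretrained_net$bn_state[[nm]]
  all_nm <- names(seg_net$params)
  report <- data.frame(
    param = all_nm,
    group = ifelse(all_nm %in% trunk, "transferred", "random"),
    stringsAsFactors = FALSE)
  attr(seg_net, "transfer_report") <- report
  seg_net
}

#' @export
print.bws_net <- function(x, ...) {
  np <- sum(vapply(x$params, length, 1L))
  cat(sprintf(
    "<bws_net> %s head, widths %s, latent %d, %d parameters\n",
    x$head, paste(x$config$widths, collapse = "-"),
    x$config$latent_dim, np))
  invisible(x)
}

.count_params <- function(net, names = NULL) {
  if (is.null(names)) names <- names(net$params)
  sum(vapply(net$params[names], length, 1L))
}
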