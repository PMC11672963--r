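# Training objectives.  The self-supervised stage minimizes a contrast
# consistency term (L1 between the reconstructions of two differently
# masked views) plus a reconstruction observation term (L1 of each view's
# reconstruction against the unmasked original).  The segmentation stage
# minimizes a Dice-focal loss on labeled pixels plus a variational loss
# (bottleneck-feature MSE + KL against a standard normal) on all samples.
#
# All pixel sums are implemented as means over pixels so the loss scale is
# independent of patch size; `reduction = "sum"` restores literal sums.

.clamp_p <- 1e-7

#' Loss weights for the Dice-focal objective
#'
#' Per-class focal weights reflect how hard each class is: urine and
#' background are large, bright/dark, easy regions (0.1); the thin wall
#' (0.6) and the wall-attached tumor (0.8) are the classes the loss should
#' concentrate on.
#'
#' @param alpha named numeric vector of per-class focal weights in `(0, 1]`,
#'   names `background`, `urine`, `wall`, `tumor`.
#' @param gamma focal exponent (>= 0); higher values down-weight
#'   well-classified pixels more aggressively.
#' @param epsilon Dice smoothing term (> 0).
#' @return object of class `bws_loss_weights`.
#' @export
loss_weights <- function(alpha = c(background = 0.1, urine = 0.1,
                                   wall = 0.6, tumor = 0.8),
                         gamma = 2, epsilon = 1e-6) {
  stopifnot(all(alpha > 0), all(alpha <= 1), gamma >= 0, epsilon > 0,
            setequal(names(alpha),
                     c("background", "urine", "wall", "tumor")))
  structure(list(alpha = alpha[c("background", "urine", "wall", "tumor")],
                 gamma = gamma, epsilon = epsilon),
            class = "bws_loss_weights")
}

.reduce <- function(x, reduction) {
  if (reduction == "mean") mean(x) else sum(x)
}

#' Contrast consistency loss
#'
#' L1 discrepancy between the reconstructions of two differently masked
#' views of the same patch. Pulling the two reconstructions together makes
#' the network infer masked content consistently rather than copying
#' whichever pixels happen to be visible.
#'
#' @param r1,r2 reconstructions of equal shape.
#' @param reduction `"mean"` (default) or `"sum"` over pixels.
#' @return non-negative scalar, symmetric in its arguments.
#' @export
contrast_consistency_loss <- function(r1, r2, reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  if (!identical(dim(r1), dim(r2)) || length(r1) != length(r2))
    stop("reconstructions have different shapes")
  .reduce(abs(r1 - r2), reduction)
}

#' Reconstruction observation loss
#'
#' Sum of the L1 errors of both masked-view reconstructions against the
#' unmasked original patch.
#'
#' @param r1,r2 reconstructions.
#' @param x the unmasked original patch.
#' @inheritParams contrast_consistency_loss
#' @return non-negative scalar.
#' @export
reconstruction_observation_loss <- function(r1, r2, x,
                                            reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  if (!identical(dim(r1), dim(x)) || !identical(dim(r2), dim(x)))
    stop("reconstructions and original have different shapes")
  .reduce(abs(r1 - x), reduction) + .reduce(abs(r2 - x), reduction)
}

#' Total self-supervised pre-training loss
#'
#' Contrast consistency plus reconstruction observation loss.
#'
#' @param pair a [make_pretrain_pair()] result (only `$original` is used).
#' @param r1,r2 reconstructions of the pair's two views.
#' @inheritParams contrast_consistency_loss
#' @return non-negative scalar.
#' @export
self_supervised_loss <- function(pair, r1, r2, reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  contrast_consistency_loss(r1, r2, reduction) +
    reconstruction_observation_loss(r1, r2, pair$original, reduction)
}

# one-hot (H,W,K[,N]) from integer labels (H,W[,N]) in 0..K-1
.one_hot <- function(label, K = 4L) {
  d <- dim(label)
  if (length(d) == 2L) d <- c(d, 1L)
  lab <- array(as.integer(label), dim = d)
  oh <- array(0, dim = c(d[1], d[2], K, d[3]))
  for (k in 0:(K - 1L)) oh[, , k + 1L, ] <- (lab == k) * 1
  oh
}

.prob_4d <- function(prob) {
  if (length(dim(prob)) == 3L) dim(prob) <- c(dim(prob), 1L)
  prob
}

#' Focal loss
#'
#' Mean over pixels of `-alpha_c (1 - p_c)^gamma log(p_c)` where `c` is the
#' true class of each pixel and `p_c` its predicted probability. The
#' modulating factor `(1 - p_c)^gamma` down-weights easy pixels so training
#' concentrates on the hard wall/tumor boundary pixels.
#'
#' @param prob probability map `(H, W, 4[, N])`, channels summing to 1.
#' @param label integer label map `(H, W[, N])` with values in `0..3`.
#' @param w a [loss_weights()].
#' @return non-negative scalar.
#' @export
focal_loss <- function(prob, label, w = loss_weights()) {
  prob <- .prob_4d(prob)
  oh <- .one_hot(label, dim(prob)[3])
  if (!identical(dim(oh), dim(prob)))
    stop("probability map and label map have inconsistent shapes")
  d <- dim(prob)
  m <- matrix(aperm(prob * oh, c(3, 1, 2, 4)), nrow = d[3])
  pt <- pmax(colSums(m), .clamp_p)
  at <- w$alpha[as.integer(label) + 1L]
  mean(-at * (1 - pt)^w$gamma * log(pt))
}

# gradient of focal_loss w.r.t. prob (same shape as prob)
.focal_grad <- function(prob, label, w) {
  prob <- .prob_4d(prob)
  d <- dim(prob)
  oh <- .one_hot(label, d[3])
  npix <- d[1] * d[2] * d[4]
  lab1 <- as.integer(label) + 1L
  at <- array(w$alpha[lab1], dim = d[c(1, 2, 4)])
  g <- array(0, d)
  for (k in seq_len(d[3])) {
    sel <- oh[, , k, , drop = FALSE]
    dim(sel) <- d[c(1, 2, 4)]
    p <- pmax(prob[, , k, , drop = FALSE], .clamp_p)
    dim(p) <- d[c(1, 2, 4)]
    gk <- -at * ((1 - p)^w$gamma / p -
                   w$gamma * (1 - p)^(w$gamma - 1) * log(p)) * sel
    g[, , k, ] <- gk / npix
  }
  g
}

#' Soft Dice loss
#'
#' Per-class soft Dice loss `1 - (2|x∩y| + e) / (|x| + |y| + e)` with a
#' probability-weighted intersection, averaged over the foreground classes
#' (urine, wall, tumor) present in the ground truth. Zero when the
#' prediction matches the label exactly; approaches 1 for disjoint masks as
#' `e -> 0`.
#'
#' @param pred probability map `(H, W, 4[, N])` or an integer label/binary
#'   mask of the same shape as `label` (converted to one-hot).
#' @param label integer label map (or binary mask).
#' @param epsilon smoothing term added to numerator and denominator.
#' @param classes class indices included in the average (default `1:3`,
#'   the foreground classes).
#' @return scalar in `[0, 1]`.
#' @export
dice_loss <- function(pred, label, epsilon = 1e-6, classes = 1:3) {
  K <- if (length(dim(pred)) >= 3L) dim(pred)[3] else
    max(2L, max(as.integer(label)) + 1L, max(as.integer(pred)) + 1L)
  p <- if (length(dim(pred)) >= 3L) .prob_4d(pred) else .one_hot(pred, K)
  y <- .one_hot(label, K)
  if (!identical(dim(p), dim(y)))
    stop("prediction and label have inconsistent shapes")
  classes <- classes[classes < K]
  present <- classes[vapply(classes, function(k) any(y[, , k + 1L, ] > 0),
                            TRUE)]
  if (!length(present))
    present <- classes[vapply(classes, function(k) any(p[, , k + 1L, ] > 0),
                              TRUE)]
  if (!length(present)) return(0)
  ls <- vapply(present, function(k) {
    pk <- p[, , k + 1L, ]; yk <- y[, , k + 1L, ]
    1 - (2 * sum(pk * yk) + epsilon) / (sum(pk) + sum(yk) + epsilon)
  }, 1.0)
  mean(ls)
}

# gradient of dice_loss w.r.t. prob
.dice_grad <- function(prob, label, epsilon = 1e-6, classes = 1:3) {
  p <- .prob_4d(prob)
  d <- dim(p)
  y <- .one_hot(label, d[3])
  present <- classes[vapply(classes, function(k) any(y[, , k + 1L, ] > 0),
                            TRUE)]
  g <- array(0, d)
  if (!length(present)) return(g)
  for (k in present) {
    pk <- p[, , k + 1L, , drop = FALSE]
    yk <- y[, , k + 1L, , drop = FALSE]
    num <- 2 * sum(pk * yk) + epsilon
    den <- sum(pk) + sum(yk) + epsilon
    g[, , k + 1L, ] <- -(2 * yk * den - num) / den^2 / length(present)
  }
  g
}

#' Dice-focal loss
#'
#' Exact sum of [focal_loss()] and [dice_loss()]; the focal term drives
#' per-pixel classification of hard pixels while the Dice term aligns
#' region overlap, countering the extreme class imbalance between
#' background and the thin wall.
#'
#' @inheritParams focal_loss
#' @return non-negative scalar.
#' @export
dice_focal_loss <- function(prob, label, w = loss_weights()) {
  focal_loss(prob, label, w) + dice_loss(prob, label, w$epsilon)
}

#' KL divergence of a diagonal Gaussian from the standard normal
#'
#' Closed form `0.5 * sum(mu^2 + sigma^2 - log sigma^2 - 1)` over latent
#' dimensions, averaged over the batch.
#'
#' @param lat list with `mu` and `log_var`, each `latent_dim x N` (vectors
#'   are treated as one sample).
#' @return non-negative scalar.
#' @export
kl_standard_normal <- function(lat) {
  mu <- as.matrix(lat$mu); lv <- as.matrix(lat$log_var)
  stopifnot(all(is.finite(mu)), all(is.finite(lv)))
  mean(colSums(0.5 * (mu^2 + exp(lv) - lv - 1)))
}

.kl_grad <- function(lat) {
  mu <- as.matrix(lat$mu); lv <- as.matrix(lat$log_var)
  n <- ncol(mu)
  list(dmu = mu / n, dlv = 0.5 * (exp(lv) - 1) / n)
}

#' Variational loss
#'
#' Mean squared reconstruction error plus [kl_standard_normal()]. Both
#' labeled and unlabeled images contribute to this term, which is how
#' unlabeled data shapes the encoder's representation.
#'
#' @param target reconstruction target (bottleneck feature field by
#'   default; see the methods vignette).
#' @param reconstruction variational branch output, same shape as `target`.
#' @param lat list with `mu` and `log_var`.
#' @return non-negative scalar.
#' @export
vae_loss <- function(target, reconstruction, lat) {
  if (!identical(dim(target), dim(reconstruction)))
    stop("target and reconstruction have different shapes")
  mean((target - reconstruction)^2) + kl_standard_normal(lat)
}

#' Total semi-supervised loss
#'
#' Dice-focal loss over the labeled samples of a batch plus the variational
#' loss over all samples. A fully unlabeled batch contributes only the
#' variational term.
#'
#' @param batch list with `labels` (integer `(H, W, N)` array, slices for
#'   unlabeled samples ignored) and `labeled` (logical vector of length N).
#' @param outputs list with `prob`, `vae_target`, `vae_recon`, `mu`,
#'   `log_var` as produced by the segmentation forward pass.
#' @param w a [loss_weights()].
#' @return non-negative scalar.
#' @export
semi_loss <- function(batch, outputs, w = loss_weights()) {
  n <- length(batch$labeled)
  if (n == 0L) stop("empty batch")
  val <- vae_loss(outputs$vae_target, outputs$vae_recon,
                  list(mu = outputs$mu, log_var = outputs$log_var))
  if (!any(batch$labeled)) return(val)
  sel <- which(batch$labeled)
  prob <- .prob_4d(outputs$prob)[, , , sel, drop = FALSE]
  labs <- batch$labels
  if (length(dim(labs)) == 2L) dim(labs) <- c(dim(labs), 1L)
  labs <- labs[, , sel, drop = FALSE]
  dice_focal_loss(prob, labs, w) + val
}
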