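# Training orchestration: self-supervised pre-training of the
# reconstruction network, and semi-supervised fine-tuning of the
# segmentation network with the label-count-adaptive two-group learning
# rate.

#' Adaptive learning-rate ratio
#'
#' Ratio `beta = LR2 / LR1` between the learning rate of randomly
#' initialized layers (classification head, variational branch) and that of
#' pre-trained trunk layers, as a function of the number of annotated
#' training samples `n`. The anchor table is
#' `beta = (20, 10, 2, 0.2, 0.02)` at `n = (1, 4, 12, 21, 42)`; between
#' anchors the ratio is interpolated log-linearly in `(log n, log beta)`,
#' and outside the anchor range it clamps to the nearest endpoint.
#'
#' @param n number of annotated training samples (>= 1).
#' @param table data frame with columns `n` and `beta`.
#' @return the ratio `beta`.
#' @export
#' @examples
#' beta_for_n(42) # 0.02
#' beta_for_n(1)  # 20
beta_for_n <- function(n, table = beta_table()) {
  if (length(n) != 1L || !is.finite(n) || n < 1)
    stop("n must be a single count >= 1")
  tb <- table[order(table$n), ]
  if (n <= tb$n[1]) return(tb$beta[1])
  if (n >= tb$n[nrow(tb)]) return(tb$beta[nrow(tb)])
  hit <- which(tb$n == n)
  if (length(hit)) return(tb$beta[hit])
  hi <- which(tb$n > n)[1]
  lo <- hi - 1L
  t <- (log(n) - log(tb$n[lo])) / (log(tb$n[hi]) - log(tb$n[lo]))
  exp((1 - t) * log(tb$beta[lo]) + t * log(tb$beta[hi]))
}

#' Anchor table for [beta_for_n()]
#' @return data frame with columns `n`, `beta`.
#' @export
beta_table <- function() {
  data.frame(n = c(42, 21, 12, 4, 1), beta = c(0.02, 0.2, 2, 10, 20))
}

#' Two-group learning-rate policy
#'
#' @param lr1 base learning rate of pre-trained-initialized layers.
#' @param n_labeled number of annotated training samples.
#' @param table anchor table, see [beta_table()].
#' @return object of class `bws_lr_policy` with fields `lr1`, `n_labeled`,
#'   `beta`, `lr2 = beta * lr1`.
#' @export
lr_policy <- function(lr1 = 1e-4, n_labeled, table = beta_table()) {
  beta <- beta_for_n(n_labeled, table)
  structure(list(lr1 = lr1, n_labeled = as.integer(n_labeled),
                 beta_table = table, beta = beta, lr2 = beta * lr1),
            class = "bws_lr_policy")
}

#' Assign per-parameter learning rates
#'
#' Transferred trunk parameters train at `lr1`; randomly initialized
#' parameters (head, variational branch) at `lr2 = beta * lr1`. Every
#' parameter belongs to exactly one group.
#'
#' @param seg_net segmentation `bws_net`.
#' @param policy a [lr_policy()].
#' @param report transfer report from [transfer_weights()] (data frame
#'   `param`, `group`).
#' @return data frame with columns `param`, `group`, `lr`.
#' @export
build_param_groups <- function(seg_net, policy, report) {
  nms <- names(seg_net$params)
  missing <- setdiff(nms, report$param)
  if (length(missing))
    stop("parameters missing from transfer report: ",
         paste(missing, collapse = ", "))
  report <- report[match(nms, report$param), ]
  report$lr <- ifelse(report$group == "transferred", policy$lr1, policy$lr2)
  report
}

# --- optimizers -------------------------------------------------------------

.opt_new <- function(params, lrs, kind = c("adam", "adamw"),
                     weight_decay = 0.01) {
  kind <- match.arg(kind)
  zeros <- lapply(params, function(p) p * 0)
  list(kind = kind, m = zeros, v = zeros, t = 0L, lrs = lrs,
       beta1 = 0.9, beta2 = 0.999, eps = 1e-8, wd = weight_decay)
}

.opt_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  c1 <- 1 - b1^opt$t; c2 <- 1 - b2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * g
    opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * g * g
    step <- (opt$m[[nm]] / c1) / (sqrt(opt$v[[nm]] / c2) + opt$eps)
    lr <- opt$lrs[[nm]]
    p <- params[[nm]] - lr * step
    # decoupled weight decay on convolution/affine weights only
    if (opt$kind == "adamw" && endsWith(nm, ".w"))
      p <- p - lr * opt$wd * params[[nm]]
    params[[nm]] <- p
  }
  list(opt = opt, params = params)
}

# assemble (H,W,1,N) batch from a list of matrices
.stack_batch <- function(images) {
  d <- dim(images[[1]])
  x <- array(0, dim = c(d[1], d[2], 1L, length(images)))
  for (i in seq_along(images)) x[, , 1L, i] <- images[[i]]
  x
}

#' Self-supervised pre-training
#'
#' Trains the reconstruction network on masked patch pairs: every epoch,
#' each training image yields a random crop and two independently
#' hole-masked views; the network minimizes the contrast consistency plus
#' reconstruction observation loss with Adam. The checkpoint with the best
#' validation loss is kept.
#'
#' @param images a dataset directory, a manifest from [read_manifest()], or
#'   a list of image matrices. For a manifest, the labeled and unlabeled
#'   splits are pooled (labels are not needed at this stage).
#' @param config pipeline configuration ([default_config()] shape); the
#'   `mask`, `network` and `pretrain` sections are used.
#' @param net optionally a pre-built `bws_net` with `head = "recon"`.
#' @return object of class `bws_pretrain_model`: best network, per-epoch
#'   `history`, and the configuration.
#' @export
pretrain <- function(images, config = default_config(), net = NULL) {
  if (is.character(images)) images <- read_manifest(images)
  if (is.list(images) && !is.null(images$labeled)) {
    m <- images
    images <- c(.load_split(m, "labeled")$images,
                .load_split(m, "unlabeled")$images)
  }
  if (!length(images)) stop("pre-training requires at least one image")
  pc <- config$pretrain; mc <- config$mask
  seed <- as.integer(config$seed)
  if (is.null(net)) net <- build_net(.net_config_of(config), head = "recon",
                                     seed = .derive_seed(seed, 77L))
  stopifnot(net$head == "recon")

  crop <- min(mc$crop_size, min(vapply(images, nrow, 1L)))
  n <- length(images)
  set.seed(.derive_seed(seed, 1L))
  ord <- sample.int(n)
  n_val <- if (n >= 5) max(1L, round(pc$val_fraction * n)) else 0L
  val_idx <- if (n_val) ord[seq_len(n_val)] else integer()
  tr_idx <- setdiff(ord, val_idx)
  if (!length(tr_idx)) { tr_idx <- val_idx; val_idx <- integer() }

  mkpair <- function(i, s) {
    patch <- random_crop(images[[i]], crop, seed = s)
    make_pretrain_pair(patch, list(holes_min = mc$holes_min,
                                   holes_max = mc$holes_max,
                                   side_min = mc$side_min,
                                   side_max = mc$side_max,
                                   noise = mc$noise), seed = s + 1L)
  }
  # fixed validation pairs
  val_pairs <- lapply(seq_along(val_idx), function(k)
    mkpair(val_idx[k], .derive_seed(seed, 5000L + k)))

  opt <- .opt_new(net$params,
                  lrs = stats::setNames(as.list(rep(pc$lr,
                                                    length(net$params))),
                                        names(net$params)),
                  kind = "adam")
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best <- list(loss = Inf, params = net$params, bn = net$bn_state)

  pair_loss_grad <- function(pairs, train) {
    x <- .stack_batch(lapply(pairs, `[[`, "original"))
    x1 <- .stack_batch(lapply(pairs, `[[`, "view1"))
    x2 <- .stack_batch(lapply(pairs, `[[`, "view2"))
    f1 <- recon_fwd(x1, net, train)
    if (train) net$bn_state <<- f1$state
    f2 <- recon_fwd(x2, net, train)
    if (train) net$bn_state <<- f2$state
    r1 <- f1$y; r2 <- f2$y
    loss <- mean(abs(r1 - r2)) + mean(abs(r1 - x)) + mean(abs(r2 - x))
    if (!train) return(list(loss = loss))
    N <- length(r1)
    d1 <- (sign(r1 - r2) + sign(r1 - x)) / N
    d2 <- (sign(r2 - r1) + sign(r2 - x)) / N
    g1 <- recon_bwd(d1, f1, net)
    g2 <- recon_bwd(d2, f2, net)
    g <- g1
    for (nm in names(g2)) g[[nm]] <- g[[nm]] + g2[[nm]]
    list(loss = loss, grads = g)
  }

  bs <- pc$batch_size
  for (epoch in seq_len(pc$epochs)) {
    set.seed(.derive_seed(seed, 100L + epoch))
    idx <- sample(tr_idx)
    losses <- c()
    nb <- ceiling(length(idx) / bs)
    for (b in seq_len(nb)) {
      take <- idx[((b - 1L) * bs + 1L):min(b * bs, length(idx))]
      pairs <- lapply(seq_along(take), function(k)
        mkpair(take[k], .derive_seed(seed, epoch * 10000L + b * 100L + k)))
      lg <- pair_loss_grad(pairs, train = TRUE)
      st <- .opt_step(opt, net$params, lg$grads)
      opt <- st$opt
      net$params <- st$params
      losses <- c(losses, lg$loss)
    }
    vl <- if (length(val_pairs))
      pair_loss_grad(val_pairs, train = FALSE)$loss else mean(losses)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = mean(losses),
                                         val_loss = vl))
    if (vl <= best$loss)
      best <- list(loss = vl, params = net$params, bn = net$bn_state)
  }
  net$params <- best$params
  net$bn_state <- best$bn
  structure(list(net = net, history = history, config = config,
                 best_val_loss = best$loss),
            class = "bws_pretrain_model")
}

#' Save / load a model checkpoint
#'
#' Checkpoints contain the parameters, batch-norm state, configuration and
#' (for segmentation models) the transfer report and training history.
#'
#' @param model a `bws_pretrain_model`, `bws_seg_model` or `bws_net`.
#' @param path file path.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("cannot load checkpoint: ", path,
                               " does not exist")
  readRDS(path)
}

# mean foreground DSC of argmax predictions against labels
.mean_fg_dsc <- function(prob, labels) {
  n <- dim(prob)[4]
  vals <- c()
  for (i in seq_len(n)) {
    pred <- label_from_prob(prob[, , , i, drop = TRUE])
    g <- labels[[i]]
    for (k in 1:3) {
      if (!any(g == k)) next
      vals <- c(vals, dsc(pred == k, g == k))
    }
  }
  if (length(vals)) mean(vals) else NA_real_
}

#' Semi-supervised segmentation training
#'
#' Fine-tunes the segmentation network with AdamW on mixed batches drawn
#' half from the labeled pool and half from the unlabeled pool. Labeled
#' samples contribute the Dice-focal loss; all samples contribute the
#' variational loss. Transferred trunk layers train at `lr1` and randomly
#' initialized layers at `lr2 = beta(n) * lr1`. The epoch with the best
#' mean foreground Dice on the held-out validation fraction of the labeled
#' data is kept.
#'
#' @param labeled list with `images` and `labels` (parallel lists), or a
#'   manifest/directory whose labeled split is used.
#' @param unlabeled list of image matrices (may be empty), or `NULL` to
#'   take the manifest's unlabeled split.
#' @param checkpoint a `bws_pretrain_model` (or reconstruction `bws_net`)
#'   whose trunk initializes the model, or `NULL` to train from scratch
#'   (the no-pre-training baseline arm).
#' @param config pipeline configuration; the `network`, `loss` and `train`
#'   sections are used.
#' @param policy optional [lr_policy()]; by default built from
#'   `config$train$lr1` and the labeled-sample count.
#' @return object of class `bws_seg_model` with the best network, `history`
#'   (per-epoch losses and validation Dice), the `transfer` report and the
#'   policy.
#' @export
train_semisupervised <- function(labeled, unlabeled = NULL,
                                 checkpoint = NULL,
                                 config = default_config(),
                                 policy = NULL) {
  if (is.character(labeled)) labeled <- read_manifest(labeled)
  if (is.list(labeled) && !is.null(labeled$labeled)) {
    m <- labeled
    sp <- .load_split(m, "labeled")
    labeled <- list(images = sp$images, labels = sp$labels)
    if (is.null(unlabeled)) unlabeled <- .load_split(m, "unlabeled")$images
  }
  if (is.null(unlabeled)) unlabeled <- list()
  n_lab <- length(labeled$images)
  if (n_lab < 1) stop("semi-supervised training requires >= 1 labeled sample")

  tc <- config$train
  seed <- as.integer(config$seed)
  w <- .loss_weights_of(config)
  net <- build_net(.net_config_of(config), head = "seg",
                   seed = .derive_seed(seed, 88L))

  if (!is.null(checkpoint)) {
    src <- if (inherits(checkpoint, "bws_pretrain_model")) checkpoint$net
    else checkpoint
    net <- transfer_weights(src, net)
    report <- attr(net, "transfer_report")
  } else {
    report <- data.frame(param = names(net$params), group = "transferred",
                         stringsAsFactors = FALSE)
  }
  if (is.null(policy)) {
    nl <- tc$n_labeled
    if (identical(nl, "auto") || is.null(nl)) nl <- n_lab
    policy <- lr_policy(lr1 = tc$lr1, n_labeled = nl)
  }
  groups <- build_param_groups(net, policy, report)
  lrs <- stats::setNames(as.list(groups$lr), groups$param)
  opt <- .opt_new(net$params, lrs, kind = "adamw",
                  weight_decay = tc$weight_decay)

  # validation split of the labeled data
  set.seed(.derive_seed(seed, 2L))
  ord <- sample.int(n_lab)
  n_val <- if (n_lab >= 2) max(1L, round(tc$val_fraction * n_lab)) else 0L
  val_idx <- if (n_val) ord[seq_len(n_val)] else integer()
  tr_idx <- setdiff(ord, val_idx)
  val_x <- if (n_val) .stack_batch(labeled$images[val_idx])
  half <- max(1L, tc$batch_size %/% 2L)

  run_batch <- function(img_list, lab_list, labeled_mask, eps_seed) {
    x <- .stack_batch(img_list)
    nb <- length(img_list)
    L <- net$config$latent_dim
    set.seed(eps_seed)
    eps <- matrix(stats::rnorm(L * nb), L, nb)
    fw <- seg_fwd(x, net, train = TRUE, eps = eps)
    net$bn_state <<- fw$state
    target <- fw$bottleneck  # detached: constant w.r.t. the MSE gradient
    mse <- mean((target - fw$vae_recon)^2)
    kl <- kl_standard_normal(list(mu = fw$mu, log_var = fw$log_var))
    dvrec <- 2 * (fw$vae_recon - target) / length(target)
    kg <- .kl_grad(list(mu = fw$mu, log_var = fw$log_var))

    dprob <- array(0, dim(fw$prob))
    dfl <- 0
    if (any(labeled_mask)) {
      sel <- which(labeled_mask)
      probl <- fw$prob[, , , sel, drop = FALSE]
      labs <- array(0L, dim = c(dim(x)[1], dim(x)[2], length(sel)))
      for (k in seq_along(sel)) labs[, , k] <- lab_list[[sel[k]]]
      dfl <- dice_focal_loss(probl, labs, w)
      dsub <- .focal_grad(probl, labs, w) + .dice_grad(probl, labs,
                                                       w$epsilon)
      dprob[, , , sel] <- dsub
    }
    grads <- seg_bwd(fw, net, dprob, kg$dmu, kg$dlv, dvrec)
    list(loss_dfl = dfl, loss_val = mse + kl, grads = grads)
  }

  history <- data.frame(epoch = integer(), dfl = numeric(),
                        val_loss = numeric(), val_dsc = numeric())
  best <- list(dsc = -Inf, params = net$params, bn = net$bn_state)
  # an epoch covers the full semi-supervised pool: the larger of the
  # labeled and unlabeled sets, with the smaller pool recycled
  steps <- max(1L, ceiling(max(length(tr_idx), length(unlabeled)) / half))

  for (epoch in seq_len(tc$epochs)) {
    set.seed(.derive_seed(seed, 300L + epoch))
    lab_order <- sample(rep(tr_idx, length.out = steps * half))
    e_dfl <- c(); e_val <- c()
    for (st in seq_len(steps)) {
      li <- lab_order[((st - 1L) * half + 1L):(st * half)]
      imgs <- labeled$images[li]
      labs <- labeled$labels[li]
      mask <- rep(TRUE, length(li))
      if (length(unlabeled)) {
        ui <- sample.int(length(unlabeled), half, replace = TRUE)
        imgs <- c(imgs, unlabeled[ui])
        labs <- c(labs, vector("list", length(ui)))
        mask <- c(mask, rep(FALSE, length(ui)))
      }
      out <- run_batch(imgs, labs, mask,
                       .derive_seed(seed, epoch * 100000L + st))
      stp <- .opt_step(opt, net$params, out$grads)
      opt <- stp$opt
      net$params <- stp$params
      e_dfl <- c(e_dfl, out$loss_dfl)
      e_val <- c(e_val, out$loss_val)
    }
    vd <- if (n_val) {
      fwv <- seg_fwd(val_x, net, train = FALSE, eps = NULL)
      .mean_fg_dsc(fwv$prob, labeled$labels[val_idx])
    } else -mean(e_dfl)
    history <- rbind(history, data.frame(
      epoch = epoch, dfl = mean(e_dfl), val_loss = mean(e_val),
      val_dsc = if (n_val) vd else NA_real_))
    if (vd >= best$dsc)
      best <- list(dsc = vd, params = net$params, bn = net$bn_state)
  }
  net$params <- best$params
  net$bn_state <- best$bn
  attr(net, "transfer_report") <- NULL
  structure(list(net = net, history = history, transfer = report,
                 policy = policy, config = config,
                 best_val_dsc = if (n_val) best$dsc else NA_real_,
                 pretrained = !is.null(checkpoint)),
            class = "bws_seg_model")
}
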