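test_that("leaky ReLU follows its two branches", {
  expect_identical(leaky_relu(5), 5)
  expect_identical(leaky_relu(0), 0)
  expect_equal(leaky_relu(-2, a = 0.01), -0.02)
  expect_equal(leaky_relu(c(-1, 2), a = 0.2), c(-0.2, 2))
})

test_that("max pooling records per-window argmax and breaks ties row-major", {
  x <- matrix(c(1, 3, 2, 4), 2, 2)  # column-major: [[1,2],[3,4]]
  pl <- max_pool_with_indices(x)
  expect_equal(pl$y[1, 1], 4)
  expect_equal(pl$idx[1, 1], 3L)  # bottom-right: di=1, dj=1 -> 1 + 2

  # constant field: first element in row-major window order wins
  pc <- max_pool_with_indices(matrix(7, 4, 4))
  expect_true(all(pc$y == 7))
  expect_true(all(pc$idx == 0L))

  expect_error(max_pool_with_indices(array(0, c(5, 6, 1, 1))), "even")
})

test_that("max unpooling places values at recorded positions, zero elsewhere", {
  up <- max_unpool(matrix(4, 1, 1), matrix(3L, 1, 1), c(2, 2))
  expect_equal(up, matrix(c(0, 0, 0, 4), 2, 2))
  expect_equal(max_unpool(matrix(0, 2, 2), matrix(0L, 2, 2), c(4, 4)),
               matrix(0, 4, 4))
})

test_that("pool/unpool round trip matches brute-force window enumeration", {
  for (s in 1:20) {
    set.seed(s)
    x <- matrix(rnorm(8 * 8), 8)
    pl <- max_pool_with_indices(x)
    up <- max_unpool(pl$y, pl$idx, c(8, 8))
    for (i in 1:4) for (j in 1:4) {
      win <- x[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)]
      uwin <- up[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)]
      expect_equal(pl$y[i, j], max(win))
      nz <- which(uwin != 0)
      if (max(win) != 0) {
        expect_length(nz, 1L)
        expect_equal(uwin[nz], max(win))
        # the value sits at an argmax position of the window
        expect_equal(win[nz], max(win))
      } else {
        expect_true(all(uwin == 0))
      }
    }
  }
})

test_that("both networks preserve spatial size across input sizes", {
  cfg <- net_config(base_width = 2L, latent_dim = 3L)
  rn <- build_net(cfg, head = "recon", seed = 1)
  sn <- build_net(cfg, head = "seg", seed = 2)
  for (sz in c(64L, 96L, 128L)) {
    x <- matrix(runif(sz * sz), sz)
    y <- reconstruct_forward(x, rn)
    expect_identical(dim(y), c(sz, sz))
    expect_true(all(y >= 0 & y <= 1))
    p <- segment_forward(x, sn)$prob
    expect_identical(dim(p)[1:2], c(sz, sz))
  }
  expect_error(reconstruct_forward(matrix(0, 30, 30), rn), "divisible")
})

test_that("probability maps are valid distributions over the four classes", {
  cfg <- net_config(base_width = 2L, latent_dim = 3L)
  sn <- build_net(cfg, head = "seg", seed = 3)
  x <- matrix(runif(32 * 32), 32)
  out <- segment_forward(x, sn)
  expect_identical(dim(out$prob)[3], 4L)
  sums <- apply(out$prob, c(1, 2), sum)
  expect_true(all(abs(sums - 1) < 1e-5))
  lab <- label_from_prob(out$prob)
  expect_true(all(lab %in% 0:3))
  expect_length(out$latent$mu, 3L)
  expect_length(out$latent$log_var, 3L)
})

test_that("untrained forward passes are deterministic", {
  cfg <- net_config(base_width = 2L)
  rn <- build_net(cfg, head = "recon", seed = 9)
  x <- matrix(runif(32 * 32), 32)
  expect_identical(reconstruct_forward(x, rn), reconstruct_forward(x, rn))
})

test_that("weight transfer copies the trunk exactly and reports all groups", {
  cfg <- net_config(base_width = 2L, latent_dim = 3L)
  rn <- build_net(cfg, head = "recon", seed = 4)
  sn <- build_net(cfg, head = "seg", seed = 5)
  sh_before <- sn$params[["sh.w"]]
  st <- transfer_weights(rn, sn)
  rep <- attr(st, "transfer_report")

  trunk <- rep$param[rep$group == "transferred"]
  for (nm in trunk) expect_identical(st$params[[nm]], rn$params[[nm]])
  expect_identical(st$params[["sh.w"]], sh_before)

  # transferred and random sets partition the parameters
  expect_setequal(rep$param, names(st$params))
  expect_identical(anyDuplicated(rep$param), 0L)

  # idempotence
  st2 <- transfer_weights(rn, st)
  expect_identical(st2$params, st$params)

  # shape mismatch names the layer
  rn_bad <- build_net(net_config(base_width = 4L), head = "recon", seed = 6)
  expect_error(transfer_weights(rn_bad, sn), "e1")
})

test_that("segmentation trunk has the same parameter count as the reconstruction trunk", {
  cfg <- net_config(base_width = 2L, latent_dim = 3L)
  rn <- build_net(cfg, head = "recon", seed = 1)
  sn <- build_net(cfg, head = "seg", seed = 2)
  trunk <- bladderseg:::.trunk_param_names()
  expect_identical(bladderseg:::.count_params(rn, trunk),
                   bladderseg:::.count_params(sn, trunk))
})

test_that("fused batch-norm/activation matches the plain-R reference", {
  ns <- asNamespace("bladderseg")
  set.seed(8)
  x <- array(rnorm(6 * 6 * 3 * 2), c(6, 6, 3, 2))
  gamma <- runif(3, 0.5, 1.5); beta <- rnorm(3)
  state <- list(mean = numeric(3), var = rep(1, 3))
  ref_bn <- ns$bn_fwd(x, gamma, beta, state, train = TRUE)
  ref <- ns$lrelu_fwd(ref_bn$y, 0.01)
  fused <- ns$cpp_bn_lrelu_fwd(x, gamma, beta, numeric(0), numeric(0),
                               0.01, 1e-5)
  expect_equal(fused$y, ref$y, tolerance = 1e-12)

  dy <- array(rnorm(length(x)), dim(x))
  ref_b <- ns$bn_bwd(ns$lrelu_bwd(dy, ref), ref_bn)
  fus_b <- ns$cpp_bn_lrelu_bwd(dy, fused$y, fused$xhat, gamma,
                               fused$inv_sd, 0.01, TRUE)
  expect_equal(fus_b$dx, ref_b$dx, tolerance = 1e-10)
  expect_equal(fus_b$dgamma, ref_b$dgamma, tolerance = 1e-10)
  expect_equal(fus_b$dbeta, ref_b$dbeta, tolerance = 1e-10)
})

test_that("analytic network gradients agree with finite differences", {
  ns <- asNamespace("bladderseg")
  cfg <- net_config(base_width = 2L, latent_dim = 3L)
  net <- build_net(cfg, head = "seg", seed = 5)
  set.seed(3)
  x <- array(runif(8 * 8 * 1 * 2), c(8, 8, 1, 2))
  lab <- array(sample(0:3, 8 * 8 * 2, TRUE), c(8, 8, 2))
  w <- loss_weights()
  eps_mat <- matrix(rnorm(3 * 2), 3, 2)
  base_fw <- ns$seg_fwd(x, net, train = TRUE, eps = eps_mat)
  target <- base_fw$bottleneck
  loss_of <- function(p) {
    n2 <- net; n2$params <- p
    fw <- ns$seg_fwd(x, n2, train = TRUE, eps = eps_mat)
    dice_focal_loss(fw$prob, lab, w) +
      mean((target - fw$vae_recon)^2) +
      kl_standard_normal(list(mu = fw$mu, log_var = fw$log_var))
  }
  dvrec <- 2 * (base_fw$vae_recon - target) / length(target)
  kg <- ns$.kl_grad(list(mu = base_fw$mu, log_var = base_fw$log_var))
  dprob <- ns$.focal_grad(base_fw$prob, lab, w) +
    ns$.dice_grad(base_fw$prob, lab, w$epsilon)
  g <- ns$seg_bwd(base_fw, net, dprob, kg$dmu, kg$dlv, dvrec)

  set.seed(99)
  for (nm in c("e1.w", "e5.g", "d2.b", "sh.w", "vmu.w", "vfc.b", "v2.w")) {
    arr <- net$params[[nm]]
    i <- sample(length(arr), 1)
    h <- 1e-5
    p1 <- net$params; p1[[nm]][i] <- arr[i] + h
    p2 <- net$params; p2[[nm]][i] <- arr[i] - h
    numg <- (loss_of(p1) - loss_of(p2)) / (2 * h)
    expect_equal(g[[nm]][i], numg, tolerance = 1e-4,
                 label = paste("gradient of", nm))
  }
})
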