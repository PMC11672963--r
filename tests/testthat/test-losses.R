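test_that("self-supervised loss terms evaluate and decompose correctly", {
  set.seed(1)
  x <- matrix(runif(16 * 16), 16)
  r1 <- matrix(runif(16 * 16), 16)
  r2 <- matrix(runif(16 * 16), 16)

  expect_equal(contrast_consistency_loss(r1, r1), 0)
  expect_equal(contrast_consistency_loss(matrix(1, 4, 4), matrix(0, 4, 4)),
               1)
  expect_equal(contrast_consistency_loss(r1, r2),
               contrast_consistency_loss(r2, r1))

  expect_equal(reconstruction_observation_loss(x, x, x), 0)
  expect_equal(reconstruction_observation_loss(x, x + 0.5, x), 0.5)
  expect_equal(reconstruction_observation_loss(r1, r2, x),
               reconstruction_observation_loss(r2, r1, x))

  pair <- list(original = x)
  expect_equal(self_supervised_loss(pair, r1, r2),
               contrast_consistency_loss(r1, r2) +
                 reconstruction_observation_loss(r1, r2, x),
               tolerance = 1e-12)
  expect_equal(self_supervised_loss(pair, x, x), 0)
  expect_gte(self_supervised_loss(pair, r1, r2), 0)

  # sum reduction restores the literal pixel sums
  expect_equal(contrast_consistency_loss(r1, r2, reduction = "sum"),
               sum(abs(r1 - r2)))
  expect_error(contrast_consistency_loss(r1, matrix(0, 4, 4)), "shape")
})

test_that("focal loss matches its closed form", {
  w <- loss_weights()
  # perfect one-hot prediction has zero loss
  lab <- matrix(c(0L, 1L, 2L, 3L), 2, 2)
  oh <- bladderseg:::.one_hot(lab, 4L)
  expect_equal(focal_loss(oh, lab, w), 0)

  # single wall pixel at p = 0.5, gamma = 2, alpha = 0.6
  p <- array(0, c(1, 1, 4))
  p[1, 1, ] <- c(0.5 / 3, 0.5 / 3, 0.5, 0.5 / 3)
  l <- matrix(2L, 1, 1)
  expect_equal(focal_loss(p, l, w), 0.6 * 0.25 * log(2), tolerance = 1e-12)

  # linear in alpha: doubling one class's weight doubles its contribution
  w2 <- loss_weights(alpha = c(background = 0.1, urine = 0.1, wall = 0.6,
                               tumor = 0.8), gamma = 2)
  base <- focal_loss(p, l, w2)
  # scale the wall alpha by 2 via manual construction
  w3 <- w2; w3$alpha["wall"] <- 2 * w3$alpha["wall"]
  expect_equal(focal_loss(p, l, w3), 2 * base, tolerance = 1e-12)

  # gamma = 0, all alpha = 1 reduces to mean cross-entropy
  w4 <- loss_weights(alpha = c(background = 1, urine = 1, wall = 1,
                               tumor = 1), gamma = 0)
  set.seed(4)
  pr <- array(runif(6 * 6 * 4), c(6, 6, 4))
  s <- apply(pr, c(1, 2), sum)
  for (k in 1:4) pr[, , k] <- pr[, , k] / s
  labs <- matrix(sample(0:3, 36, TRUE), 6)
  ce <- mean(-log(vapply(seq_len(36), function(i) {
    ij <- arrayInd(i, c(6, 6))
    pr[ij[1], ij[2], labs[i] + 1]
  }, 1.0)))
  expect_equal(focal_loss(pr, labs, w4), ce, tolerance = 1e-10)
})

test_that("Dice loss hits its endpoints and intermediate values", {
  # identical masks -> 0
  m <- matrix(0L, 8, 8); m[3:5, 3:5] <- 1L
  expect_equal(dice_loss(m, m, epsilon = 1e-9), 0)

  # disjoint masks -> 1 as e -> 0
  a <- matrix(0L, 8, 8); a[1:2, 1:2] <- 1L
  b <- matrix(0L, 8, 8); b[6:8, 6:8] <- 1L
  expect_equal(dice_loss(a, b, epsilon = 1e-9), 1, tolerance = 1e-6)

  # half overlap on 2-pixel masks: 1 - 2*1/4 = 0.5
  s <- matrix(0L, 4, 4); s[1, 1:2] <- 1L
  g <- matrix(0L, 4, 4); g[1, 2:3] <- 1L
  expect_equal(dice_loss(s, g, epsilon = 1e-12), 0.5, tolerance = 1e-9)
})

test_that("Dice loss equals 1 - DSC on binary masks as e -> 0", {
  for (s in 1:200) {
    set.seed(s)
    a <- matrix(rbinom(64, 1, 0.4), 8)
    b <- matrix(rbinom(64, 1, 0.4), 8)
    if (sum(a) + sum(b) == 0) next
    expect_equal(dice_loss(a, b, epsilon = 1e-12), 1 - dsc(a, b),
                 tolerance = 1e-8)
  }
})

test_that("Dice-focal loss is the exact sum of its parts", {
  w <- loss_weights()
  set.seed(5)
  pr <- array(runif(4 * 4 * 4), c(4, 4, 4))
  s <- apply(pr, c(1, 2), sum)
  for (k in 1:4) pr[, , k] <- pr[, , k] / s
  lab <- matrix(sample(0:3, 16, TRUE), 4)
  expect_equal(dice_focal_loss(pr, lab, w),
               focal_loss(pr, lab, w) + dice_loss(pr, lab, w$epsilon),
               tolerance = 1e-12)
  oh <- bladderseg:::.one_hot(lab, 4L)
  expect_equal(dice_focal_loss(oh, lab, w), 0)
})

test_that("KL against the standard normal matches the closed form and MC", {
  expect_equal(kl_standard_normal(list(mu = 0, log_var = 0)), 0)
  expect_equal(kl_standard_normal(list(mu = 1, log_var = 0)), 0.5)
  # Monte-Carlo cross-check of the KL integral for mu=1, sigma^2=1
  set.seed(10)
  z <- rnorm(2e5, mean = 1, sd = 1)
  mc <- mean(dnorm(z, 1, 1, log = TRUE) - dnorm(z, 0, 1, log = TRUE))
  expect_equal(mc, 0.5, tolerance = 0.01)

  for (s in 1:20) {
    set.seed(s)
    lat <- list(mu = rnorm(5), log_var = rnorm(5))
    expect_gte(kl_standard_normal(lat), 0)
  }
})

test_that("VAE loss decomposes into MSE plus KL", {
  set.seed(6)
  t <- array(rnorm(24), c(2, 3, 4))
  r <- array(rnorm(24), c(2, 3, 4))
  lat <- list(mu = rnorm(3), log_var = rnorm(3))
  expect_equal(vae_loss(t, r, lat),
               mean((t - r)^2) + kl_standard_normal(lat),
               tolerance = 1e-12)
  expect_equal(vae_loss(t, t, list(mu = c(0, 0), log_var = c(0, 0))), 0)
  expect_error(vae_loss(t, array(0, c(3, 2, 4)), lat), "shape")
})

test_that("semi-supervised loss handles labeled, unlabeled and empty batches", {
  set.seed(7)
  H <- 4L
  pr <- array(runif(H * H * 4 * 2), c(H, H, 4, 2))
  s <- apply(pr, c(1, 2, 4), sum)
  for (k in 1:4) pr[, , k, ] <- pr[, , k, ] / s
  labs <- array(sample(0:3, H * H * 2, TRUE), c(H, H, 2))
  outputs <- list(prob = pr,
                  vae_target = array(rnorm(8), c(2, 2, 2)),
                  vae_recon = array(rnorm(8), c(2, 2, 2)),
                  mu = matrix(rnorm(4), 2), log_var = matrix(rnorm(4), 2))
  w <- loss_weights()
  val <- vae_loss(outputs$vae_target, outputs$vae_recon,
                  list(mu = outputs$mu, log_var = outputs$log_var))

  all_lab <- semi_loss(list(labels = labs, labeled = c(TRUE, TRUE)),
                       outputs, w)
  expect_equal(all_lab, dice_focal_loss(pr, labs, w) + val,
               tolerance = 1e-12)

  none <- semi_loss(list(labels = labs, labeled = c(FALSE, FALSE)),
                    outputs, w)
  expect_equal(none, val, tolerance = 1e-12)

  expect_error(semi_loss(list(labels = labs, labeled = logical(0)),
                         outputs, w), "empty")
})

test_that("probability clamping keeps the focal loss finite", {
  w <- loss_weights()
  p <- array(0, c(1, 1, 4)); p[1, 1, 1] <- 1  # true class has probability 0
  l <- matrix(2L, 1, 1)
  v <- focal_loss(p, l, w)
  expect_true(is.finite(v))
  expect_gt(v, 0)
})
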