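test_that("every registered transform has an exact bitwise inverse", {
  for (tr in tta_transforms()) {
    set.seed(42)
    lab <- matrix(sample(0:3, 24 * 24, TRUE), 24)
    expect_identical(tr$inverse(tr$forward(lab)), lab,
                     label = paste("inverse of", tr$name))
    pr <- matrix(runif(24 * 24), 24)
    expect_identical(tr$inverse(tr$forward(pr)), pr)
  }
  bad <- list(name = "shift", forward = function(x) x + 1,
              inverse = function(x) x)
  expect_error(register_tta_transform(bad), "exact inverse")
})

test_that("identity-only TTA equals a plain forward pass", {
  cfg <- net_config(base_width = 2L, latent_dim = 3L)
  sn <- build_net(cfg, head = "seg", seed = 1)
  x <- matrix(runif(32 * 32), 32)
  plain <- segment_forward(x, sn)$prob
  one <- tta_predict(sn, x, tta_transforms("identity"))
  expect_equal(one, plain, tolerance = 1e-12)
  two <- tta_predict(sn, x, tta_transforms(c("identity", "identity")))
  expect_equal(two, plain, tolerance = 1e-12)
})

test_that("TTA merging is permutation-invariant and probability-valid", {
  cfg <- net_config(base_width = 2L, latent_dim = 3L)
  sn <- build_net(cfg, head = "seg", seed = 2)
  x <- matrix(runif(32 * 32), 32)
  a <- tta_predict(sn, x, tta_transforms(c("identity", "hflip", "rot180")))
  b <- tta_predict(sn, x, tta_transforms(c("rot180", "identity", "hflip")))
  expect_equal(a, b, tolerance = 1e-12)
  sums <- apply(a, c(1, 2), sum)
  expect_true(all(abs(sums - 1) < 1e-6))
  expect_error(tta_predict(sn, x, list()), "non-empty")
})

test_that("flip TTA of a mirror-symmetric input yields a mirror-symmetric map", {
  cfg <- net_config(base_width = 2L, latent_dim = 3L)
  sn <- build_net(cfg, head = "seg", seed = 3)
  half <- matrix(runif(32 * 16), 32)
  x <- cbind(half, half[, 16:1])  # left-right symmetric
  merged <- tta_predict(sn, x, tta_transforms(c("identity", "hflip")))
  flipped <- merged[, 32:1, ]
  expect_equal(merged, flipped, tolerance = 1e-10)
})

test_that("largest_component keeps only the biggest foreground blob", {
  lab <- matrix(0L, 16, 16)
  lab[2:9, 2:9] <- 1L           # ~64 px blob
  lab[13:14, 13:14] <- 2L       # 4 px blob
  out <- largest_component(lab)
  expect_true(all(out[13:14, 13:14] == 0L))
  expect_identical(out[2:9, 2:9], lab[2:9, 2:9])
  expect_identical(attr(out, "removed"), 1L)

  # single-component map unchanged
  one <- matrix(0L, 8, 8); one[3:5, 3:5] <- 2L
  out1 <- largest_component(one)
  expect_identical(as.vector(out1), as.vector(one))

  # all-background input returns unchanged with a warning
  expect_warning(out0 <- largest_component(matrix(0L, 4, 4)),
                 "no foreground")
  expect_true(attr(out0, "no_foreground"))
})

test_that("fill_holes fills interior background with the surrounding class", {
  lab <- matrix(0L, 12, 12)
  lab[3:9, 3:9] <- 1L
  lab[5:6, 5:6] <- 0L  # interior hole inside urine
  out <- fill_holes(lab)
  expect_true(all(out[5:6, 5:6] == 1L))
  expect_identical(attr(out, "filled"), 4L)

  # hole-free map unchanged; border background never filled
  clean <- matrix(0L, 8, 8); clean[3:5, 3:5] <- 2L
  outc <- fill_holes(clean)
  expect_identical(as.vector(outc), as.vector(clean))
  expect_identical(attr(outc, "filled"), 0L)
})

test_that("correct_segmentation enforces one hole-free component and is idempotent", {
  for (s in 1:50) {
    lab <- random_noisy_label(s)
    cs <- correct_segmentation(lab)
    fg <- cs$label > 0L
    if (!any(fg)) next
    expect_identical(oracle_components(fg, 8), 1L)
    expect_identical(oracle_holes(fg), 0L)
    again <- correct_segmentation(cs$label)
    expect_identical(again$label, cs$label)
    expect_identical(again$report$components_removed, 0L)
    expect_identical(again$report$hole_pixels_filled, 0L)
  }

  # clean phantom label passes through untouched
  ph <- generate_phantom(phantom_config(), seed = 3)
  cs <- correct_segmentation(ph$label)
  expect_identical(cs$label, ph$label)
  expect_equal(cs$report$changed_pixel_fraction, 0)
})

test_that("correction never increases component or hole counts", {
  for (s in 51:120) {
    lab <- random_noisy_label(s)
    before_c <- oracle_components(lab > 0L, 8)
    cs <- correct_segmentation(lab)
    after_c <- oracle_components(cs$label > 0L, 8)
    expect_lte(after_c, max(before_c, 1L))
    expect_identical(oracle_holes(cs$label > 0L), 0L)
  }
})

test_that("argmax ties break toward the lower class index", {
  p <- array(0.25, c(2, 2, 4))
  expect_true(all(label_from_prob(p) == 0L))
  p[1, 1, ] <- c(0.1, 0.4, 0.4, 0.1)
  expect_identical(label_from_prob(p)[1, 1], 1L)
})

test_that("predict options toggle TTA and correction independently", {
  cfg <- net_config(base_width = 2L, latent_dim = 3L)
  model <- structure(list(net = build_net(cfg, head = "seg", seed = 4),
                          policy = lr_policy(n_labeled = 1),
                          pretrained = FALSE, best_val_dsc = NA_real_),
                     class = "bws_seg_model")
  x <- matrix(runif(32 * 32), 32)
  plain <- predict(model, x, tta = FALSE, correct = FALSE)
  expect_identical(as.vector(plain),
                   as.vector(label_from_prob(segment_forward(x, model$net)$prob)))
  corr <- predict(model, x, tta = FALSE, correct = TRUE)
  expect_s3_class(attr(corr, "report"), "bws_correction_report")
  fg <- corr > 0L
  if (any(fg)) {
    expect_identical(oracle_components(fg, 8), 1L)
    expect_identical(oracle_holes(fg), 0L)
  }
  # vote merge is also a valid option
  voted <- predict(model, x, tta = TRUE, correct = FALSE, merge = "vote")
  expect_true(all(voted %in% 0:3))
})
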