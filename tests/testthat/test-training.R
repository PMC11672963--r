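test_that("beta reproduces the anchor table and interpolates log-linearly", {
  tb <- beta_table()
  expect_equal(beta_for_n(42), 0.02)
  expect_equal(beta_for_n(21), 0.2)
  expect_equal(beta_for_n(12), 2)
  expect_equal(beta_for_n(4), 10)
  expect_equal(beta_for_n(1), 20)

  # clamping beyond the anchors
  expect_equal(beta_for_n(100), 0.02)
  expect_equal(beta_for_n(1), beta_for_n(1, tb))

  # independent re-derivation of the log-linear interpolant at n = 3
  t <- (log(3) - log(1)) / (log(4) - log(1))
  expect_equal(beta_for_n(3), exp((1 - t) * log(20) + t * log(10)),
               tolerance = 1e-12)

  expect_error(beta_for_n(0), ">= 1")
})

test_that("beta is monotone non-increasing over n in [1, 42]", {
  vals <- vapply(1:42, beta_for_n, 1.0)
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("parameter groups assign lr1 to the trunk and beta*lr1 to the rest", {
  cfg <- net_config(base_width = 2L, latent_dim = 3L)
  rn <- build_net(cfg, head = "recon", seed = 1)
  sn <- transfer_weights(rn, build_net(cfg, head = "seg", seed = 2))
  rep <- attr(sn, "transfer_report")

  pol <- lr_policy(lr1 = 1e-4, n_labeled = 42)
  groups <- build_param_groups(sn, pol, rep)
  expect_equal(unique(groups$lr[groups$group == "transferred"]), 1e-4)
  expect_equal(unique(groups$lr[groups$group == "random"]), 2e-6)

  pol1 <- lr_policy(lr1 = 1e-4, n_labeled = 1)
  g1 <- build_param_groups(sn, pol1, rep)
  expect_equal(unique(g1$lr[g1$group == "random"]), 20 * 1e-4)

  # groups partition the parameter set
  expect_setequal(groups$param, names(sn$params))
  expect_identical(anyDuplicated(groups$param), 0L)

  # a report missing parameters is an error
  expect_error(build_param_groups(sn, pol, rep[-1, ]), "missing")
})

test_that("pre-training reduces the self-supervised loss and checkpoints round-trip", {
  cfg <- tiny_train_config(seed = 5, epochs = 6L)
  imgs <- lapply(tiny_phantoms(6, cfg), `[[`, "image")
  pm <- pretrain(imgs, cfg)
  h <- pm$history
  expect_identical(nrow(h), 6L)
  # smoothed, non-strict improvement over training
  expect_lte(mean(tail(h$train_loss, 2)), mean(head(h$train_loss, 2)))

  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(pm, f)
  pm2 <- load_checkpoint(f)
  expect_identical(pm2$net$params, pm$net$params)
  expect_identical(pm2$best_val_loss, pm$best_val_loss)
  expect_error(load_checkpoint(file.path(tempdir(), "nope.rds")),
               "does not exist")

  expect_error(pretrain(list(), cfg), "at least one image")
})

test_that("pre-trained reconstruction beats the all-zero baseline on held-out phantoms", {
  cfg <- tiny_train_config(seed = 11, epochs = 12L)
  cfg$network$base_width <- 4L
  imgs <- lapply(tiny_phantoms(8, cfg), `[[`, "image")
  pm <- pretrain(imgs, cfg)
  held <- generate_phantom(bladderseg:::.phantom_config_of(cfg),
                           seed = 999L)$image
  rec <- reconstruct_forward(held, pm$net)
  expect_lt(mean(abs(rec - held)), mean(abs(held)))
})

test_that("zero-hole masking reduces pre-training to plain reconstruction", {
  cfg <- tiny_train_config(seed = 6, epochs = 1L)
  cfg$mask$holes_min <- 0L
  cfg$mask$holes_max <- 0L
  imgs <- lapply(tiny_phantoms(3, cfg), `[[`, "image")
  # with identical views the contrast term must vanish: loss = 2 * L1(r, x)
  pm <- pretrain(imgs, cfg)
  net <- pm$net
  x <- imgs[[1]]
  r <- reconstruct_forward(x, net)
  pair <- make_pretrain_pair(x, list(holes_min = 0L, holes_max = 0L,
                                     side_min = 2L, side_max = 3L,
                                     noise = "uniform"), seed = 1)
  expect_equal(self_supervised_loss(pair, r, r),
               2 * mean(abs(r - x)), tolerance = 1e-12)
})

test_that("semi-supervised training runs, improves and is seed-deterministic", {
  cfg <- tiny_train_config(seed = 7, epochs = 3L)
  phs <- tiny_phantoms(5, cfg)
  labeled <- list(images = lapply(phs[1:3], `[[`, "image"),
                  labels = lapply(phs[1:3], `[[`, "label"))
  unlabeled <- lapply(phs[4:5], `[[`, "image")

  sm <- train_semisupervised(labeled, unlabeled, checkpoint = NULL,
                             config = cfg)
  expect_s3_class(sm, "bws_seg_model")
  expect_identical(nrow(sm$history), 3L)
  expect_true(all(is.finite(sm$history$dfl)))
  expect_true(all(c("dfl", "val_loss", "val_dsc") %in% names(sm$history)))

  # determinism of the full history under a fixed seed
  sm2 <- train_semisupervised(labeled, unlabeled, checkpoint = NULL,
                              config = cfg)
  expect_equal(sm$history, sm2$history, tolerance = 1e-12)
  expect_equal(sm$net$params, sm2$net$params, tolerance = 1e-12)

  # no unlabeled data: pure supervised + VAE still runs
  sm3 <- train_semisupervised(labeled, list(), checkpoint = NULL,
                              config = cfg)
  expect_identical(nrow(sm3$history), 3L)

  expect_error(train_semisupervised(list(images = list(), labels = list()),
                                    list(), NULL, cfg), "labeled")
})

test_that("pretrained initialization transfers into the fine-tuned model", {
  cfg <- tiny_train_config(seed = 8, epochs = 1L)
  phs <- tiny_phantoms(4, cfg)
  imgs <- lapply(phs, `[[`, "image")
  pm <- pretrain(imgs, cfg)
  labeled <- list(images = lapply(phs[1:2], `[[`, "image"),
                  labels = lapply(phs[1:2], `[[`, "label"))
  sm <- train_semisupervised(labeled, imgs[3:4], checkpoint = pm,
                             config = cfg)
  expect_true(sm$pretrained)
  expect_identical(sort(unique(sm$transfer$group)),
                   c("random", "transferred"))
  # beta from the labeled count (n = 2)
  expect_equal(sm$policy$beta, beta_for_n(2))
})
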