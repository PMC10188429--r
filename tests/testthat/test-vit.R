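test_that("patchify produces the expected patch grid and reassembles exactly", {
  cfg <- vit_config_desk()
  set.seed(10)
  px <- matrix(runif(64 * 64), 64, 64)
  P <- patchify(px, cfg)
  expect_identical(dim(P), c(64L, 64L))   # (64/8)^2 patches of 8^2 pixels
  # row-major reassembly inverts patchify
  rebuilt <- matrix(0, 64, 64)
  k <- 0
  for (pr in 1:8) for (pc in 1:8) {
    k <- k + 1
    rebuilt[(pr - 1) * 8 + 1:8, (pc - 1) * 8 + 1:8] <-
      matrix(P[k, ], 8, 8, byrow = TRUE)
  }
  expect_identical(rebuilt, px)
  big <- vit_config_full()
  expect_identical(nrow(patchify(matrix(0, 224, 224), big)), 196L)
  expect_identical(ncol(patchify(matrix(0, 224, 224), big)), 256L)
  expect_error(patchify(matrix(0, 32, 32), cfg), "side")
})

test_that("forward pass yields normalized probabilities and attention rows", {
  cfg <- micro_vit()
  params <- vit_init(cfg)
  set.seed(11)
  imgs <- lapply(1:5, function(i) matrix(runif(32 * 32), 32, 32))
  probs <- vit_forward(params, imgs, cfg, return_attention = TRUE)
  expect_identical(dim(probs), c(5L, 2L))
  expect_true(all(probs >= 0 & probs <= 1))
  expect_equal(rowSums(probs), rep(1, 5), tolerance = 1e-6)
  att <- attr(probs, "attention")
  for (blk in att) for (im in blk) for (head in im) {
    expect_equal(rowSums(head), rep(1, nrow(head)), tolerance = 1e-6)
  }
  # inference is deterministic
  expect_identical(unclass(vit_forward(params, imgs, cfg)),
                   unclass(vit_forward(params, imgs, cfg)))
})

test_that("parameter count matches the closed form for both presets", {
  for (cfg in list(micro_vit(), vit_config_desk(), vit_config_full())) {
    params <- vit_init(cfg)
    expect_identical(sum(vapply(params, length, 0L)), as.integer(vit_param_count(cfg)))
  }
  # desk preset against an independent hand computation:
  # patch 64*64+64, cls 64, pos 65*64, blocks 2*(128+4*4160+128+8320+8256),
  # final LN 128, head 130
  expect_identical(vit_param_count(vit_config_desk()), 75586)
})

test_that("initial loss sits at the binary-cross-entropy chance level", {
  cfg <- micro_vit()
  params <- vit_init(cfg)
  set.seed(12)
  imgs <- lapply(1:40, function(i) matrix(runif(32 * 32), 32, 32))
  probs <- vit_forward(params, imgs, cfg)
  y <- rep(c(0, 1), 20)
  loss <- -mean(log(probs[cbind(1:40, y + 1)]))
  expect_equal(loss, log(2), tolerance = 0.1)
})

test_that("gradients agree with finite differences on a tiny model", {
  cfg <- vit_config(image_side = 16, patch_side = 8, embed_dim = 8, depth = 1,
                    heads = 2, mlp_ratio = 2, batch_size = 2, epochs = 1,
                    seed = 5)
  params <- vit_init(cfg)
  set.seed(13)
  imgs <- list(matrix(runif(256), 16, 16), matrix(runif(256), 16, 16))
  y <- c(0L, 1L)
  Y <- matrix(0, 2, 2); Y[cbind(1:2, y + 1)] <- 1
  Xp <- eegvit:::stack_patches(imgs, cfg)
  loss_at <- function(p) {
    fwd <- eegvit:::vit_forward_core(p, Xp, 2, cfg)
    -mean(log(fwd$probs[cbind(1:2, y + 1)]))
  }
  fwd <- eegvit:::vit_forward_core(params, Xp, 2, cfg, keep_cache = TRUE)
  gr <- eegvit:::vit_backward_core(params, fwd, Y, cfg)
  h <- 1e-6
  for (nm in c("patch_w", "cls", "pos", "b1.wq", "b1.wo", "b1.w1", "b1.ln1_g",
               "lnf_g", "head_w", "head_b")) {
    for (j in c(1L, length(params[[nm]]))) {
      pp <- params; pp[[nm]][j] <- pp[[nm]][j] + h
      pm <- params; pm[[nm]][j] <- pm[[nm]][j] - h
      num <- (loss_at(pp) - loss_at(pm)) / (2 * h)
      expect_equal(gr[[nm]][j], num, tolerance = 1e-4,
                   label = sprintf("analytic grad %s[%d]", nm, j))
    }
  }
})

test_that("training fits a linearly separable toy task and is reproducible", {
  bright <- lapply(1:10, function(i) make_test_image(matrix(0.9, 64, 64), "delirium"))
  dark <- lapply(1:10, function(i) make_test_image(matrix(0.1, 64, 64), "control"))
  imgs <- c(bright, dark)
  fit <- vit_train(imgs, vit_config_desk(seed = 3))
  expect_equal(utils::tail(fit$trace$train_accuracy, 1), 1.0)
  expect_identical(nrow(fit$trace), 5L)
  pred <- vit_predict(fit, imgs)
  expect_identical(pred$labels, rep(c(1L, 0L), each = 10))
  # bit-identical rerun
  fit2 <- vit_train(imgs, vit_config_desk(seed = 3))
  expect_identical(fit$params, fit2$params)
  expect_error(vit_train(bright, vit_config_desk()), "both classes")
})

test_that("prediction ties break toward the control class with a flag", {
  cfg <- micro_vit()
  params <- vit_init(cfg)
  # force an exact tie by zeroing the classification head
  params$head_w[] <- 0; params$head_b[] <- 0
  img <- list(matrix(0.5, 32, 32))
  expect_message(pred <- vit_predict(params, img, cfg), "tied")
  expect_identical(pred$labels, 0L)
  expect_true(pred$tie[1])
})

test_that("without positional embeddings the class output is patch-permutation invariant", {
  cfg <- micro_vit()
  params <- vit_init(cfg)
  set.seed(14)
  img <- matrix(runif(32 * 32), 32, 32)
  Xp <- eegvit:::stack_patches(list(img), cfg)
  perm <- sample.int(nrow(Xp))
  with_pos <- eegvit:::vit_forward_core(params, Xp, 1, cfg)$probs
  with_pos_perm <- eegvit:::vit_forward_core(params, Xp[perm, ], 1, cfg)$probs
  expect_gt(max(abs(with_pos - with_pos_perm)), 1e-8)  # positions matter
  no_pos <- eegvit:::vit_forward_core(params, Xp, 1, cfg, pos_scale = 0)$probs
  no_pos_perm <- eegvit:::vit_forward_core(params, Xp[perm, ], 1, cfg,
                                           pos_scale = 0)$probs
  expect_equal(no_pos, no_pos_perm, tolerance = 1e-10)
})

test_that("a trained model round-trips through serialization", {
  imgs <- c(lapply(1:4, function(i) make_test_image(matrix(0.9, 32, 32), "delirium")),
            lapply(1:4, function(i) make_test_image(matrix(0.1, 32, 32), "control")))
  fit <- vit_train(imgs, micro_vit())
  d <- withr::local_tempdir()
  path <- file.path(d, "model.rds")
  vit_save(fit, path)
  back <- vit_load(path)
  expect_equal(back$params, fit$params)
  expect_equal(back$cfg$embed_dim, fit$cfg$embed_dim)
  expect_identical(unclass(vit_forward(back$params, imgs[1:2], back$cfg)),
                   unclass(vit_forward(fit$params, imgs[1:2], fit$cfg)))
})
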