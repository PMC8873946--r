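test_that("hyperparameter and policy validation", {
  expect_error(hyperparams(learning_rate = 0), class = "pc_spec_error")
  expect_error(hyperparams(class_weights = c(1, -1, 1)),
               class = "pc_spec_error")
  expect_error(hyperparams(max_epochs = 0), class = "pc_spec_error")
  expect_error(augmentation_policy(hflip = 1.5), class = "pc_spec_error")
  expect_error(augmentation_policy(brightness = c(-1, 1)),
               class = "pc_spec_error")
})

test_that("augment applies paired geometric transforms", {
  withr::with_seed(21, {
    img <- array(runif(48 * 48 * 3, 0, 255), dim = c(48, 48, 3))
  })
  pts <- data.frame(x = c(10, 30), y = c(5, 40), class = c("neg", "pos"))
  lbl <- encode_labels(pts, c(48, 48))

  # identity draw leaves the pair unchanged
  id <- augment(img, lbl, NULL)
  expect_identical(id$image, img)
  expect_equal(id$labels, lbl)

  # hflip moves a label at (x, y) to (W-1-x, y)
  hf <- augment(img, lbl, list(hflip = TRUE, vflip = FALSE, angle = 0,
                               brightness = 1))
  expect_equal(hf$labels[5 + 1, 48 - 1 - 10 + 1], 1L)
  expect_equal(hf$labels[40 + 1, 48 - 1 - 30 + 1], 2L)
  expect_identical(hf$image[, 48:1, ], img)

  # four 90-degree rotations compose to the identity exactly
  cur <- list(image = img, labels = lbl)
  for (i in 1:4)
    cur <- augment(cur$image, cur$labels,
                   list(hflip = FALSE, vflip = FALSE, angle = 90,
                        brightness = 1))
  expect_identical(cur$image, img)
  expect_equal(cur$labels, lbl)

  # brightness touches the image only and preserves the label value set
  br <- augment(img, lbl, list(hflip = FALSE, vflip = FALSE, angle = 0,
                               brightness = 1.2))
  expect_equal(br$labels, lbl)
  expect_equal(br$image, clip(img * 1.2, 0, 255), tolerance = 1e-12)

  # arbitrary-angle rotation preserves the label value set
  rot <- augment(img, lbl, list(hflip = FALSE, vflip = FALSE, angle = 37,
                                brightness = 1))
  expect_true(all(rot$labels %in% c(0L, 1L, 2L)))
  expect_equal(dim(rot$image), dim(img))
})

test_that("class-weight rescaling leaves loss and gradient unchanged", {
  withr::with_seed(33, {
    logits <- array(rnorm(16 * 16 * 3), dim = c(16, 16, 3))
    lbl <- matrix(sample(0:2, 256, TRUE), 16, 16)
  })
  a <- plasmacount:::weighted_ce(logits, lbl, c(1, 5, 9))
  b <- plasmacount:::weighted_ce(logits, lbl, 7 * c(1, 5, 9))
  expect_equal(a$loss, b$loss, tolerance = 1e-12)
  expect_equal(a$dlogits, b$dlogits, tolerance = 1e-12)
})

test_that("training is reproducible and rejects bad configurations", {
  s <- make_patch_samples(2, 600, tiny_spec)
  hp <- hyperparams(learning_rate = 0.05, max_epochs = 3, seed = 4)
  r1 <- train(s, s[1], hp)
  r2 <- train(s, s[1], hp)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$checkpoint$network$layers, r2$checkpoint$network$layers)
  expect_equal(nrow(r1$history), 3)
  expect_true(all(c("epoch", "loss", "val_macro_f1") %in% names(r1$history)))

  expect_error(train(list(), s, hp), class = "pc_spec_error")
  # a divergent learning rate aborts with a training error
  expect_error(train(s, s[1], hyperparams(learning_rate = 1e160,
                                          max_epochs = 3, seed = 4)),
               class = "pc_training_error")
})

test_that("train_val_split is seeded and at tile level", {
  s <- make_patch_samples(5, 700, tiny_spec)
  sp1 <- train_val_split(s, 0.2, seed = 9)
  sp2 <- train_val_split(s, 0.2, seed = 9)
  expect_equal(length(sp1$val), 1)
  expect_equal(length(sp1$train), 4)
  expect_identical(sp1$val[[1]]$points, sp2$val[[1]]$points)
})

test_that("grid search selects the best cell and survives failures", {
  s <- make_patch_samples(2, 800, tiny_spec)
  hp0 <- hyperparams(max_epochs = 2, seed = 3)

  # 1-point grid returns that point
  g1 <- grid_search(s, s[1], learning_rates = 0.05,
                    class_weights = list(c(1, 10, 10)), hp_base = hp0)
  expect_equal(g1$best_hp$learning_rate, 0.05)
  expect_equal(nrow(g1$table), 1)

  # a divergent cell is marked failed and never selected; the returned
  # cell has the max recorded score
  g <- grid_search(s, s[1], learning_rates = c(1e160, 0.05),
                   class_weights = list(c(1, 10, 10)), hp_base = hp0)
  expect_true(g$table$failed[1])
  expect_false(g$table$failed[2])
  expect_equal(g$best_hp$learning_rate, 0.05)
  expect_equal(g$best$checkpoint$meta$val_macro_f1,
               max(g$table$val_macro_f1, na.rm = TRUE))
})
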