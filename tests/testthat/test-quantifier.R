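test_that("build_quantifier realizes the configured architecture", {
  cfg <- quantifier_config(seed = 5)
  m <- build_quantifier(cfg)
  expect_equal(cfg$latent_dim, 2)
  # encoder: 4 hidden layers of 1321 nodes, then linear map to the latent
  expect_equal(vapply(m$encoder$W, ncol, integer(1)), c(rep(1321, 4), 2))
  expect_equal(vapply(m$decoder$W, nrow, integer(1)), c(2, rep(1321, 4)))
  expect_equal(dim(m$head$W[[1]]), c(2, 3))
  expect_equal(m$encoder$acts, c(rep("relu", 4), "linear"))
  expect_equal(m$decoder$acts[5], "sigmoid")
  # identical seed -> identical initial parameters
  m2 <- build_quantifier(cfg)
  expect_identical(m$encoder$W, m2$encoder$W)
  m3 <- build_quantifier(quantifier_config(seed = 6))
  expect_false(identical(m$encoder$W[[1]], m3$encoder$W[[1]]))
})

test_that("total loss decomposes exactly as reconstruction + lambda * prediction", {
  # tiny hand-specified network, checked against explicit arithmetic
  cfg <- quantifier_config(input_dim = 3, hidden_layers = 1, hidden_width = 2,
                           latent_dim = 1, loss_weight_lambda = 0.5, seed = 2)
  m <- build_quantifier(cfg, metabolites = "uric_acid")
  m$encoder$W <- list(matrix(c(1, 0, -1, 0.5, 0.5, 0), 3, 2),
                      matrix(c(1, -1), 2, 1))
  m$encoder$b <- list(c(0.1, -0.2), 0)
  m$decoder$W <- list(matrix(c(0.5, -0.5), 1, 2),
                      matrix(c(1, 0, 0, 1, 0.5, 0.5), 2, 3))
  m$decoder$b <- list(c(0, 0), c(0, 0, 0))
  m$head$W <- list(matrix(2, 1, 1)); m$head$b <- list(0.5)
  X <- rbind(c(0.2, 0.8, 0.4), c(1, 0, 0.6))
  Y <- rbind(0.3, 0.9)
  # forward, written out longhand
  relu <- function(z) pmax(z, 0); sig <- function(z) 1 / (1 + exp(-z))
  H <- relu(X %*% m$encoder$W[[1]] + rep(1, 2) %o% m$encoder$b[[1]])
  Z <- H %*% m$encoder$W[[2]]
  D <- relu(Z %*% m$decoder$W[[1]])
  Xhat <- sig(D %*% m$decoder$W[[2]])
  Yhat <- sig(Z * 2 + 0.5)
  recon <- sum((Xhat - X)^2) / 6
  pred <- sum((Yhat - Y)^2) / 2
  got <- total_loss(m, X, Y)
  expect_equal(got$reconstruction, recon)
  expect_equal(got$prediction, pred)
  expect_equal(got$total, recon + 0.5 * pred)
  # lambda = 0: total equals reconstruction
  m$config$loss_weight_lambda <- 0
  expect_equal(total_loss(m, X, Y)$total, total_loss(m, X, Y)$reconstruction)
  expect_error(total_loss(m, X, rbind(1.4, 0)), "\\[0, 1\\]")
})

test_that("analytic gradients match finite differences", {
  cfg <- quantifier_config(input_dim = 7, hidden_layers = 2, hidden_width = 5,
                           latent_dim = 2, seed = 9)
  m <- build_quantifier(cfg, metabolites = c("a", "b"))
  set.seed(1)
  X <- matrix(stats::runif(4 * 7), 4, 7)
  Y <- matrix(stats::runif(4 * 2), 4, 2)
  g <- sersquant:::quantifier_grads(m, X, Y)
  eps <- 1e-6
  worst <- 0
  for (part in c("encoder", "decoder", "head")) {
    for (l in seq_along(m[[part]]$W)) {
      for (k in sample(length(m[[part]]$W[[l]]), 4)) {
        m2 <- m
        m2[[part]]$W[[l]][k] <- m2[[part]]$W[[l]][k] + eps
        num <- (total_loss(m2, X, Y)$total - total_loss(m, X, Y)$total) / eps
        worst <- max(worst, abs(num - g[[part]]$dW[[l]][k]) /
                       max(abs(num), 1e-8))
      }
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("training follows the schedule, stops early and keeps the best epoch", {
  g <- desk_grid(120)
  set <- generate_dataset(default_library(),
                          default_design(replicates = 3), noise_model(seed = 3), g)
  set <- minmax_normalize(set)
  cfg <- quantifier_config(input_dim = 120, hidden_layers = 2,
                           hidden_width = 32, latent_dim = 2, batch_size = 16,
                           max_epochs = 60, lr_initial = 1e-3, lr_late = 1e-4,
                           weight_decay_initial = 1e-5, weight_decay_late = 1e-6,
                           schedule_epoch = 50, early_stop_patience = 60,
                           seed = 4)
  m <- build_quantifier(cfg)
  m <- train_quantifier(m, set[1:90], set[91:123])
  h <- m$history
  # learning rate and weight decay drop exactly at epoch 51
  expect_equal(unique(h$lr[h$epoch <= 50]), 1e-3)
  expect_equal(unique(h$lr[h$epoch >= 51]), 1e-4)
  expect_equal(unique(h$weight_decay[h$epoch >= 51]), 1e-6)
  best <- attr(h, "best_epoch")
  expect_lte(h$val_total[best], h$val_total[1])
  expect_equal(min(h$val_total), h$val_total[best])
  expect_error(train_quantifier(build_quantifier(cfg), set[0], set[1:5]),
               "empty|labels")
})

test_that("training is deterministic given the seed", {
  g <- desk_grid(120)
  set <- minmax_normalize(generate_dataset(
    default_library(), default_design(replicates = 2), noise_model(seed = 5), g))
  cfg <- tiny_config(seed = 11)
  m1 <- train_quantifier(build_quantifier(cfg), set[1:60], set[61:82])
  m2 <- train_quantifier(build_quantifier(cfg), set[1:60], set[61:82])
  expect_identical(m1$encoder$W, m2$encoder$W)
  expect_identical(m1$history, m2$history)
  expect_identical(predict(m1, set[61:82]), predict(m2, set[61:82]))
})

test_that("predictions are bounded by the training concentration range", {
  g <- desk_grid(120)
  set <- minmax_normalize(generate_dataset(
    default_library(), default_design(replicates = 3), noise_model(seed = 6), g))
  m <- train_quantifier(build_quantifier(tiny_config(seed = 2)),
                        set[1:90], set[91:123])
  ph <- predict(m, set)
  lv <- metabolite_levels()
  for (met in names(lv)) {
    expect_true(all(ph[[met]] >= 0))
    expect_true(all(ph[[met]] <= max(lv[[met]])))
  }
  expect_error(predict(m, matrix(0.5, 2, 77)), "length 77")
  expect_error(predict(build_quantifier(tiny_config()), set), "untrained")
})

test_that("noiseless single-analyte ramps are recovered and monotone", {
  g <- desk_grid(200)
  lib <- default_library()
  des <- single_analyte_design("uric_acid", replicates = 2)
  set <- minmax_normalize(generate_dataset(lib, des, zero_noise(seed = 1), g,
                                           label_analytes = "uric_acid"))
  cfg <- desk_config(latent_dim = 1, seed = 3, input_dim = 200)
  # zero-noise replicates are identical; use replicate 1 to train,
  # replicate 2 as validation
  tr <- which(set$meta$replicate == 1)
  m <- train_quantifier(build_quantifier(cfg, metabolites = "uric_acid"),
                        set[tr], set[-tr])
  ph <- predict(m, set[tr])$uric_acid
  truth <- set$labels$uric_acid[tr]
  # the zero-concentration class is predicted near zero
  expect_lt(abs(ph[truth == 0]), 2)
  # predictions along the ramp are non-decreasing
  ord <- order(truth)
  expect_true(all(diff(ph[ord]) > -0.5))
  expect_gt(r_squared(ph, truth), 0.95)
})

test_that("latent embedding separates concentration classes", {
  g <- desk_grid(120)
  set <- minmax_normalize(generate_dataset(
    default_library(), default_design(replicates = 3), noise_model(seed = 8), g))
  m <- train_quantifier(build_quantifier(tiny_config(seed = 5)),
                        set[1:90], set[91:123])
  emb <- embed_spectra(m, set)
  expect_equal(nrow(emb), nrow(set$spectra))
  expect_true(all(c("z1", "z2", "uric_acid") %in% names(emb)))
  # identical spectra map to identical points
  two <- set$spectra[c(1, 1), ]
  ez <- embed_spectra(m, two)
  expect_identical(ez[1, ], ez[2, ], ignore_attr = TRUE)
  # lowest vs highest uric-acid classes: between-class distance exceeds
  # within-class spread
  lo <- emb[set$labels$uric_acid == 0, c("z1", "z2")]
  hi <- emb[set$labels$uric_acid == 40, c("z1", "z2")]
  between <- sqrt(sum((colMeans(lo) - colMeans(hi))^2))
  spread <- mean(c(apply(lo, 2, stats::sd), apply(hi, 2, stats::sd)))
  expect_gt(between, spread)
})

test_that("cross-validation produces per-repeat metric distributions", {
  g <- desk_grid(120)
  set <- generate_dataset(default_library(), default_design(replicates = 3),
                          noise_model(seed = 9), g)
  cv <- cross_validate(set, tiny_config(seed = 1), n_repeats = 2)
  expect_equal(nrow(cv$metrics), 2 * 3)
  expect_equal(sort(unique(cv$metrics$repeat_id)), 1:2)
  # held-out size: round(0.25 * n) predictions per repeat
  n <- nrow(set$spectra)
  expect_equal(sum(cv$predictions$repeat_id == 1), n - round(0.75 * n))
  expect_true(all(c("true_uric_acid", "pred_tyrosine") %in%
                    names(cv$predictions)))
  expect_error(cross_validate(set[1:3], tiny_config(), 2), "too small")
  # deterministic
  cv2 <- cross_validate(set, tiny_config(seed = 1), n_repeats = 2)
  expect_identical(cv$metrics, cv2$metrics)
})

test_that("ordinal and per-metabolite head variants train and predict", {
  g <- desk_grid(120)
  set <- minmax_normalize(generate_dataset(
    default_library(), default_design(replicates = 3), noise_model(seed = 10), g))
  lv <- metabolite_levels()
  cfg <- tiny_config(seed = 3, head_type = "ordinal")
  m <- build_quantifier(cfg, levels = lv)
  m <- train_quantifier(m, set[1:90], set[91:123])
  ph <- predict(m, set[91:123])
  # expectation over softmax stays inside the level hull
  for (met in names(lv)) {
    expect_true(all(ph[[met]] >= min(lv[[met]]) - 1e-9))
    expect_true(all(ph[[met]] <= max(lv[[met]]) + 1e-9))
  }
  cfgp <- tiny_config(seed = 4, per_metabolite = TRUE)
  mp <- train_quantifier(build_quantifier(cfgp), set[1:90], set[91:123])
  php <- predict(mp, set[91:123])
  expect_equal(names(php), c("uric_acid", "lactate", "tyrosine"))
  expect_equal(nrow(php), 33)
})
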