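#' Configuration of the autoencoder quantifier
#'
#' Defaults reproduce the reference architecture and schedule: a symmetric
#' encoder/decoder with four 1321-node layers around a 2-D latent, Adam with
#' learning rate 1e-4 and weight decay 1e-5 (dropped to 1e-5 / 1e-6 after
#' epoch 50), batch size 32, at most 150 epochs with early stopping on the
#' validation total loss.
#'
#' @param input_dim spectrum length (grid points).
#' @param hidden_layers hidden layers per side of the bottleneck.
#' @param hidden_width nodes per hidden layer.
#' @param latent_dim bottleneck size (2 reproduces the reference model).
#' @param batch_size minibatch size.
#' @param max_epochs training-epoch cap.
#' @param lr_initial,lr_late Adam learning rate before/after `schedule_epoch`.
#' @param weight_decay_initial,weight_decay_late L2 weight decay
#'   before/after `schedule_epoch`.
#' @param schedule_epoch last epoch of the initial rate (the late rates
#'   apply from `schedule_epoch + 1` on).
#' @param early_stop_patience epochs without validation improvement before
#'   stopping; the best-validation parameters are restored.
#' @param loss_weight_lambda weight of the prediction loss in the total.
#' @param head_type `"logistic"` (one linear+sigmoid unit per metabolite on
#'   the latent, regressing the min-max-scaled concentration) or
#'   `"ordinal"` (softmax over the discrete concentration levels; the
#'   prediction is the expected level).
#' @param per_metabolite train one single-metabolite model per analyte
#'   instead of a shared autoencoder with three heads.
#' @param seed integer seed controlling initialization and batch order.
#' @return An object of class `quantifier_config`.
#' @export
quantifier_config <- function(input_dim = 1321, hidden_layers = 4,
                              hidden_width = 1321, latent_dim = 2,
                              batch_size = 32, max_epochs = 150,
                              lr_initial = 1e-4, lr_late = 1e-5,
                              weight_decay_initial = 1e-5,
                              weight_decay_late = 1e-6,
                              schedule_epoch = 50, early_stop_patience = 15,
                              loss_weight_lambda = 1,
                              head_type = c("logistic", "ordinal"),
                              per_metabolite = FALSE, seed = 1L) {
  head_type <- match.arg(head_type)
  counts <- c(input_dim, hidden_layers, hidden_width, latent_dim,
              batch_size, max_epochs, schedule_epoch, early_stop_patience)
  if (any(counts < 1)) stop("quantifier_config: counts must be >= 1")
  rates <- c(lr_initial, lr_late, weight_decay_initial, weight_decay_late)
  if (any(rates <= 0)) stop("quantifier_config: rates must be > 0")
  if (loss_weight_lambda < 0) stop("quantifier_config: lambda must be >= 0")
  structure(list(
    input_dim = as.integer(input_dim), hidden_layers = as.integer(hidden_layers),
    hidden_width = as.integer(hidden_width), latent_dim = as.integer(latent_dim),
    batch_size = as.integer(batch_size), max_epochs = as.integer(max_epochs),
    lr_initial = lr_initial, lr_late = lr_late,
    weight_decay_initial = weight_decay_initial,
    weight_decay_late = weight_decay_late,
    schedule_epoch = as.integer(schedule_epoch),
    early_stop_patience = as.integer(early_stop_patience),
    loss_weight_lambda = loss_weight_lambda, head_type = head_type,
    per_metabolite = isTRUE(per_metabolite), seed = as.integer(seed)),
    class = "quantifier_config")
}

#' Build an untrained quantifier
#'
#' Architecture: encoder = `hidden_layers` fully connected ReLU layers of
#' `hidden_width` nodes followed by a linear map to the latent; decoder
#' mirrors it with a sigmoid output (inputs are min-max normalized to
#' \[0,1\]); prediction head = one logistic (linear + sigmoid) unit per
#' metabolite on the latent coordinates, so each head's weight vector is
#' that metabolite's "concentration axis" in latent space.
#'
#' @param config a `quantifier_config`.
#' @param metabolites label columns the head predicts.
#' @param levels named list of level vectors, required for the ordinal head.
#' @return An object of class `sers_quantifier` (untrained).
#' @export
build_quantifier <- function(config,
                             metabolites = c("uric_acid", "lactate", "tyrosine"),
                             levels = NULL) {
  stopifnot(inherits(config, "quantifier_config"))
  if (config$head_type == "ordinal") {
    if (is.null(levels) || !all(metabolites %in% names(levels)))
      stop("build_quantifier: ordinal head needs 'levels' for every metabolite")
  }
  with_seed(config$seed, {
    enc_dims <- c(config$input_dim, rep(config$hidden_width, config$hidden_layers),
                  config$latent_dim)
    enc_acts <- c(rep("relu", config$hidden_layers), "linear")
    encoder <- nn_new(enc_dims, enc_acts)
    dec_dims <- rev(enc_dims)
    dec_acts <- c(rep("relu", config$hidden_layers), "sigmoid")
    decoder <- nn_new(dec_dims, dec_acts)
    head <- if (config$head_type == "logistic") {
      nn_new(c(config$latent_dim, length(metabolites)), "sigmoid")
    } else {
      lapply(metabolites, function(m)
        nn_new(c(config$latent_dim, length(levels[[m]])), "linear"))
    }
    structure(list(encoder = encoder, decoder = decoder, head = head,
                   metabolites = metabolites, levels = levels,
                   config = config, label_scale = NULL,
                   history = NULL, trained = FALSE),
              class = "sers_quantifier")
  })
}

#' @export
print.sers_quantifier <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<sers_quantifier> %strained; %d-%s-%d latent, %s head for %s\n",
    if (x$trained) "" else "un", cfg$input_dim,
    paste(rep(cfg$hidden_width, cfg$hidden_layers), collapse = "-"),
    cfg$latent_dim, cfg$head_type, paste(x$metabolites, collapse = ", ")))
  if (x$trained && !is.null(x$history))
    cat(sprintf("  best epoch %d of %d; val total loss %.3g\n",
                attr(x$history, "best_epoch"), nrow(x$history),
                min(x$history$val_total)))
  invisible(x)
}

# resolve input matrix (+ optional labels) from spectrum_set or matrix
as_model_input <- function(x, model = NULL) {
  if (inherits(x, "spectrum_set")) {
    x <- minmax_normalize(x)
    list(X = x$spectra, labels = x$labels)
  } else {
    list(X = as.matrix(x), labels = NULL)
  }
}

check_input_dim <- function(X, model) {
  if (ncol(X) != model$config$input_dim)
    stop(sprintf("spectra have length %d but the model expects %d",
                 ncol(X), model$config$input_dim))
}

scale_labels <- function(labels, metabolites, scale = NULL) {
  Y <- as.matrix(labels[, metabolites, drop = FALSE])
  if (is.null(scale)) {
    lo <- apply(Y, 2, min); hi <- apply(Y, 2, max)
    if (any(hi - lo <= 0))
      stop(sprintf("constant training label(s): %s",
                   paste(metabolites[hi - lo <= 0], collapse = ", ")))
    scale <- list(min = lo, max = hi)
  }
  Ys <- sweep(sweep(Y, 2, scale$min), 2, scale$max - scale$min, `/`)
  list(Y = Ys, scale = scale)
}

unscale_labels <- function(Ys, scale) {
  sweep(sweep(Ys, 2, scale$max - scale$min, `*`), 2, scale$min, `+`)
}

# ordinal helpers: one-hot targets and softmax
onehot_levels <- function(y, levels) {
  idx <- match(round(y, 8), round(levels, 8))
  if (anyNA(idx)) stop("ordinal head: label not among the declared levels")
  out <- matrix(0, length(y), length(levels))
  out[cbind(seq_along(y), idx)] <- 1
  out
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# forward through encoder + heads (+ decoder if wanted)
quantifier_forward <- function(model, X, cache = FALSE) {
  enc <- nn_forward(model$encoder, X, cache = cache)
  Z <- enc$out
  dec <- nn_forward(model$decoder, Z, cache = cache)
  if (model$config$head_type == "logistic") {
    hd <- nn_forward(model$head, Z, cache = cache)
    list(enc = enc, dec = dec, head = hd, Z = Z,
         Xhat = dec$out, Yhat = hd$out)
  } else {
    hd <- lapply(model$head, function(h) nn_forward(h, Z, cache = cache))
    P <- lapply(hd, function(h) softmax_rows(h$out))
    Yhat <- do.call(cbind, lapply(seq_along(P), function(i) {
      lv <- model$levels[[model$metabolites[i]]]
      drop(P[[i]] %*% lv)
    }))
    list(enc = enc, dec = dec, head = hd, P = P, Z = Z,
         Xhat = dec$out, Yhat = Yhat)
  }
}

#' Training objective: reconstruction + weighted prediction loss
#'
#' `reconstruction` is the mean squared error between the decoded and input
#' spectra; `prediction` the mean squared error between the head outputs and
#' the min-max-scaled labels (for the ordinal head, the mean cross-entropy);
#' `total = reconstruction + lambda * prediction`.
#'
#' @param model a `sers_quantifier`.
#' @param X normalized spectra matrix (rows in \[0,1\]).
#' @param Y_scaled labels scaled to \[0,1\] per metabolite (logistic head)
#'   or raw level labels (ordinal head).
#' @return List with `reconstruction`, `prediction`, `total`.
#' @export
total_loss <- function(model, X, Y_scaled) {
  X <- as.matrix(X)
  Y_scaled <- as.matrix(Y_scaled)
  fw <- quantifier_forward(model, X)
  recon <- mean((fw$Xhat - X)^2)
  if (model$config$head_type == "logistic") {
    if (any(Y_scaled < -1e-9) || any(Y_scaled > 1 + 1e-9))
      stop("total_loss: labels must be scaled to [0, 1]")
    pred <- mean((fw$Yhat - Y_scaled)^2)
  } else {
    ce <- 0
    for (i in seq_along(model$metabolites)) {
      Tm <- onehot_levels(Y_scaled[, i], model$levels[[model$metabolites[i]]])
      ce <- ce + -mean(rowSums(Tm * log(pmax(fw$P[[i]], 1e-12))))
    }
    pred <- ce / length(model$metabolites)
  }
  list(reconstruction = recon, prediction = pred,
       total = recon + model$config$loss_weight_lambda * pred)
}

# one batch: losses + gradients for encoder/decoder/head
quantifier_grads <- function(model, X, Y) {
  lambda <- model$config$loss_weight_lambda
  fw <- quantifier_forward(model, X, cache = TRUE)
  n <- nrow(X); p <- ncol(X); m <- length(model$metabolites)
  dXhat <- 2 * (fw$Xhat - X) / (n * p)
  bdec <- nn_backward(model$decoder, fw$dec, dXhat)
  if (model$config$head_type == "logistic") {
    dYhat <- lambda * 2 * (fw$Yhat - Y) / (n * m)
    bhead <- nn_backward(model$head, fw$head, dYhat)
    dZ <- bdec$dX + bhead$dX
    head_grads <- list(dW = bhead$dW, db = bhead$db)
  } else {
    dZ <- bdec$dX
    head_grads <- vector("list", m)
    for (i in seq_len(m)) {
      Tm <- onehot_levels(Y[, i], model$levels[[model$metabolites[i]]])
      dLogit <- lambda * (fw$P[[i]] - Tm) / (n * m)
      bh <- nn_backward(model$head[[i]], fw$head[[i]], dLogit)
      head_grads[[i]] <- list(dW = bh$dW, db = bh$db)
      dZ <- dZ + bh$dX
    }
  }
  benc <- nn_backward(model$encoder, fw$enc, dZ)
  list(encoder = list(dW = benc$dW, db = benc$db),
       decoder = list(dW = bdec$dW, db = bdec$db),
       head = head_grads)
}

#' Train the quantifier
#'
#' Minibatch Adam on `total = reconstruction + lambda * prediction`, with
#' the scheduled learning-rate / weight-decay drop after
#' `config$schedule_epoch` and early stopping on the validation total loss
#' (patience `early_stop_patience`, best-validation parameters restored).
#' Label scaling (per-metabolite min-max over the training labels) is
#' fitted here and stored in the model for inverse scaling at prediction.
#'
#' @param model an untrained (or trained) `sers_quantifier`.
#' @param train_set,val_set disjoint `spectrum_set`s with labels for every
#'   metabolite the head predicts.
#' @param verbose print per-epoch losses.
#' @return The trained `sers_quantifier`, with `$history` (a data.frame of
#'   per-epoch losses and rates, `best_epoch` attribute) and `$label_scale`.
#' @export
train_quantifier <- function(model, train_set, val_set, verbose = FALSE) {
  stopifnot(inherits(model, "sers_quantifier"))
  cfg <- model$config
  if (cfg$per_metabolite && length(model$metabolites) > 1L)
    return(train_per_metabolite(model, train_set, val_set, verbose))
  tr <- as_model_input(train_set)
  va <- as_model_input(val_set)
  if (is.null(tr$labels) || is.null(va$labels))
    stop("train_quantifier: train and validation sets need labels")
  if (nrow(tr$X) < 1L || nrow(va$X) < 1L)
    stop("train_quantifier: empty training or validation set")
  check_input_dim(tr$X, model)
  ordinal <- cfg$head_type == "ordinal"
  if (ordinal) {
    Ytr <- as.matrix(tr$labels[, model$metabolites, drop = FALSE])
    Yva <- as.matrix(va$labels[, model$metabolites, drop = FALSE])
    sc <- scale_labels(tr$labels, model$metabolites)  # kept for inverse use
  } else {
    sc <- scale_labels(tr$labels, model$metabolites)
    Ytr <- sc$Y
    Yva <- scale_labels(va$labels, model$metabolites, sc$scale)$Y
  }
  model$label_scale <- sc$scale
  st <- list(encoder = adam_new(model$encoder),
             decoder = adam_new(model$decoder))
  st$head <- if (ordinal) lapply(model$head, adam_new) else adam_new(model$head)
  n <- nrow(tr$X)
  hist <- vector("list", cfg$max_epochs)
  best <- list(val = Inf, epoch = 0L, nets = NULL)
  t_adam <- 0L
  with_seed((cfg$seed %% 100000000L) + 77003L, {
    for (epoch in seq_len(cfg$max_epochs)) {
      late <- epoch > cfg$schedule_epoch
      lr <- if (late) cfg$lr_late else cfg$lr_initial
      wd <- if (late) cfg$weight_decay_late else cfg$weight_decay_initial
      ord <- sample.int(n)
      starts <- seq(1L, n, by = cfg$batch_size)
      for (s in starts) {
        bi <- ord[s:min(s + cfg$batch_size - 1L, n)]
        g <- quantifier_grads(model, tr$X[bi, , drop = FALSE],
                              Ytr[bi, , drop = FALSE])
        t_adam <- t_adam + 1L
        up <- adam_step(model$encoder, g$encoder, st$encoder, t_adam, lr, wd)
        model$encoder <- up$net; st$encoder <- up$state
        up <- adam_step(model$decoder, g$decoder, st$decoder, t_adam, lr, wd)
        model$decoder <- up$net; st$decoder <- up$state
        if (ordinal) {
          for (i in seq_along(model$head)) {
            up <- adam_step(model$head[[i]], g$head[[i]], st$head[[i]],
                            t_adam, lr, wd)
            model$head[[i]] <- up$net; st$head[[i]] <- up$state
          }
        } else {
          up <- adam_step(model$head, g$head, st$head, t_adam, lr, wd)
          model$head <- up$net; st$head <- up$state
        }
      }
      ltr <- total_loss(model, tr$X, Ytr)
      lva <- total_loss(model, va$X, Yva)
      hist[[epoch]] <- data.frame(
        epoch = epoch, lr = lr, weight_decay = wd,
        train_recon = ltr$reconstruction, train_pred = ltr$prediction,
        train_total = ltr$total, val_recon = lva$reconstruction,
        val_pred = lva$prediction, val_total = lva$total)
      if (verbose)
        message(sprintf("epoch %3d  train %.5f  val %.5f", epoch,
                        ltr$total, lva$total))
      if (lva$total < best$val - 1e-12) {
        best$val <- lva$total; best$epoch <- epoch
        best$nets <- list(encoder = model$encoder, decoder = model$decoder,
                          head = model$head)
      } else if (epoch - best$epoch >= cfg$early_stop_patience) {
        break
      }
    }
  })
  model$encoder <- best$nets$encoder
  model$decoder <- best$nets$decoder
  model$head <- best$nets$head
  model$history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
  attr(model$history, "best_epoch") <- best$epoch
  model$trained <- TRUE
  model
}

# per-metabolite option: one independent single-head model per analyte
train_per_metabolite <- function(model, train_set, val_set, verbose) {
  fits <- lapply(seq_along(model$metabolites), function(i) {
    m <- model$metabolites[i]
    cfg <- model$config
    cfg$per_metabolite <- FALSE
    cfg$seed <- cfg$seed + i
    sub <- build_quantifier(cfg, metabolites = m,
                            levels = model$levels[m])
    train_quantifier(sub, train_set, val_set, verbose)
  })
  names(fits) <- model$metabolites
  structure(list(models = fits, metabolites = model$metabolites,
                 config = model$config, trained = TRUE),
            class = c("sers_quantifier_multi"))
}

#' Predict metabolite concentrations
#'
#' Head outputs are inverse-scaled to physical units. With the logistic
#' head, predictions are bounded by the training concentration range
#' (sigmoid codomain), so they are never negative and never exceed the
#' training maximum -- a documented saturation behavior.
#'
#' @param object a trained `sers_quantifier`.
#' @param newdata `spectrum_set` (normalized on the fly if needed) or a
#'   matrix of normalized spectra with `input_dim` columns.
#' @param ... unused.
#' @return data.frame with one concentration column per metabolite.
#' @export
predict.sers_quantifier <- function(object, newdata, ...) {
  if (!object$trained) stop("predict: model is untrained")
  inp <- as_model_input(newdata)
  check_input_dim(inp$X, object)
  fw <- quantifier_forward(object, inp$X)
  out <- if (object$config$head_type == "logistic")
    unscale_labels(fw$Yhat, object$label_scale)
  else fw$Yhat
  out <- as.data.frame(out)
  names(out) <- object$metabolites
  out
}

#' @export
predict.sers_quantifier_multi <- function(object, newdata, ...) {
  out <- lapply(object$models, function(m) predict(m, newdata)[[1L]])
  as.data.frame(out)
}

#' Latent-space embedding of spectra
#'
#' Encoder outputs, one `latent_dim`-dimensional point per spectrum, with
#' labels attached for plotting. On well-trained models, concentration
#' classes align along the heads' weight directions ("concentration axes").
#'
#' @param model a trained `sers_quantifier`.
#' @param spectra `spectrum_set` or normalized matrix.
#' @return data.frame with columns `z1..zk` plus any label columns.
#' @export
embed_spectra <- function(model, spectra) {
  if (!model$trained) stop("embed_spectra: model is untrained")
  inp <- as_model_input(spectra)
  check_input_dim(inp$X, model)
  Z <- nn_forward(model$encoder, inp$X)$out
  out <- as.data.frame(Z)
  names(out) <- paste0("z", seq_len(ncol(Z)))
  if (!is.null(inp$labels)) out <- cbind(out, inp$labels)
  out
}

#' Repeated random-subsampling cross-validation
#'
#' For each repeat: a fresh random 75/25 split, a freshly initialized and
#' trained model (the held-out quarter doubles as the early-stopping
#' validation set), and per-metabolite R-squared and RMSE on the held-out
#' spectra in physical units.
#'
#' @param dataset a labeled `spectrum_set`.
#' @param config a `quantifier_config`.
#' @param n_repeats number of random splits (default 10).
#' @param train_fraction fraction used for training (default 0.75).
#' @param metabolites label columns to model.
#' @return An object of class `cv_result`: `$metrics` (data.frame with
#'   columns `repeat_id`, `metabolite`, `r2`, `rmse`), `$predictions`
#'   (per-repeat data.frames of held-out true/predicted values).
#' @export
cross_validate <- function(dataset, config, n_repeats = 10,
                           train_fraction = 0.75,
                           metabolites = c("uric_acid", "lactate", "tyrosine")) {
  stopifnot(inherits(dataset, "spectrum_set"),
            inherits(config, "quantifier_config"))
  if (!all(metabolites %in% names(dataset$labels)))
    stop("cross_validate: dataset lacks labels for every metabolite")
  dataset <- minmax_normalize(dataset)
  n <- nrow(dataset$spectra)
  n_train <- round(train_fraction * n)
  if (n_train < 2L || n - n_train < 2L)
    stop("cross_validate: dataset too small to split")
  metrics <- vector("list", n_repeats)
  preds <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    idx <- with_seed(config$seed + 13L * r, sample.int(n, n_train))
    cfg_r <- config
    cfg_r$seed <- config$seed + 1000L + r
    model <- build_quantifier(cfg_r, metabolites = metabolites,
                              levels = if (config$head_type == "ordinal")
                                lapply(dataset$labels[metabolites], function(v)
                                  sort(unique(v))) else NULL)
    model <- train_quantifier(model, dataset[idx], dataset[-idx])
    ph <- predict(model, dataset[-idx])
    truth <- dataset$labels[-idx, metabolites, drop = FALSE]
    metrics[[r]] <- do.call(rbind, lapply(metabolites, function(m)
      data.frame(repeat_id = r, metabolite = m,
                 r2 = r_squared(ph[[m]], truth[[m]]),
                 rmse = rmse(ph[[m]], truth[[m]]))))
    pr <- cbind(repeat_id = r, truth)
    names(pr)[-1] <- paste0("true_", metabolites)
    for (m in metabolites) pr[[paste0("pred_", m)]] <- ph[[m]]
    preds[[r]] <- pr
  }
  structure(list(metrics = do.call(rbind, metrics),
                 predictions = do.call(rbind, preds),
                 config = config, metabolites = metabolites),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d repeats\n", max(x$metrics$repeat_id)))
  for (m in x$metabolites) {
    mm <- x$metrics[x$metrics$metabolite == m, ]
    cat(sprintf("  %-10s R2 %.2f-%.2f (mean %.2f), RMSE mean %.3g\n", m,
                min(mm$r2), max(mm$r2), mean(mm$r2), mean(mm$rmse)))
  }
  invisible(x)
}
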