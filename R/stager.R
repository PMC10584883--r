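#' Sequence-classifier configuration
#'
#' Defaults are the full-scale selected hyperparameters: three biLSTM layers
#' of 128 hidden units per direction, dropout 0.2 after every biLSTM layer,
#' initial learning rate 1e-2 dropped to one-hundredth every 50 training
#' epochs, L2 regularization 0.1, global L2 gradient clipping at 2, at most
#' 5000 training epochs, and early stopping with patience 50 on the
#' validation loss. The mini-batch policy is "longest sequence": one batch
#' holding every training sequence, zero-padded at the end to the longest
#' after sorting by length.
#'
#' `fast_stager_config()` is the documented desk-scale profile (1 layer,
#' 32 units, 200 max epochs, L2 1e-4) used by the scaled-down experiments
#' and continuous tests; everything else matches the full configuration.
#'
#' @param n_bilstm_layers,hidden_units,dropout_rate,n_classes network shape
#' @param initial_lr,lr_drop_factor,lr_drop_every learning-rate schedule:
#'   `lr = initial_lr * lr_drop_factor^floor((epoch - 1) / lr_drop_every)`
#' @param l2_regularization L2 penalty coefficient added to weight-matrix
#'   gradients (biases exempt)
#' @param grad_clip_l2 global L2-norm gradient threshold
#' @param max_epochs hard cap on training epochs
#' @param early_stop_patience epochs without validation-loss improvement
#'   (`> 1e-5`) before stopping
#' @param seed seed for weight initialization and dropout
#' @return a list with class `"stager_config"`
#' @export
stager_config <- function(n_bilstm_layers = 3, hidden_units = 128,
                          dropout_rate = 0.2, n_classes = 6,
                          initial_lr = 1e-2, lr_drop_factor = 0.01,
                          lr_drop_every = 50, l2_regularization = 0.1,
                          grad_clip_l2 = 2.0, max_epochs = 5000,
                          early_stop_patience = 50, seed = 1L) {
  stopifnot(n_bilstm_layers >= 1, hidden_units >= 1,
            dropout_rate >= 0, dropout_rate < 1,
            initial_lr > 0, max_epochs >= 1, early_stop_patience >= 1)
  if (n_classes != 6)
    stop("the default label set requires n_classes = 6 (five stages + LV)")
  structure(list(n_bilstm_layers = as.integer(n_bilstm_layers),
                 hidden_units = as.integer(hidden_units),
                 dropout_rate = dropout_rate, n_classes = as.integer(n_classes),
                 initial_lr = initial_lr, lr_drop_factor = lr_drop_factor,
                 lr_drop_every = as.integer(lr_drop_every),
                 l2_regularization = l2_regularization,
                 grad_clip_l2 = grad_clip_l2,
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 seed = as.integer(seed)),
            class = "stager_config")
}

#' @rdname stager_config
#' @export
fast_stager_config <- function(seed = 1L, max_epochs = 200) {
  stager_config(n_bilstm_layers = 1, hidden_units = 32,
                max_epochs = max_epochs, l2_regularization = 1e-4,
                seed = seed)
}

#' Build an (untrained) biLSTM sleep stager
#'
#' Network: 4-feature sequence input -> `[biLSTM(hidden_units per
#' direction) -> dropout]` x `n_bilstm_layers` -> fully-connected layer with
#' 6 outputs -> softmax over the class order `N1, N2, N3, REM, WK, LV`.
#' Weights are initialized uniform within +/- `1/sqrt(fan_in)` (forget-gate
#' biases at 1), seeded by `config$seed`.
#'
#' @param config a [stager_config()]
#' @param n_features input features per epoch (default 4: HR, RR, lambda, BMF)
#' @return a list with class `"stager"`
#' @export
build_stager <- function(config, n_features = 4) {
  params <- with_seed(config$seed,
    init_lstm_params(n_features, config$hidden_units,
                     config$n_bilstm_layers, config$n_classes))
  structure(list(params = params, config = config,
                 class_order = CLASS_ORDER,
                 n_features = n_features,
                 mu = rep(0, n_features), sd = rep(1, n_features),
                 history = NULL),
            class = "stager")
}

# encode hypnogram labels as integer class indices in CLASS_ORDER
encode_classes <- function(labels) {
  idx <- match(as.character(labels), CLASS_ORDER)
  if (anyNA(idx)) stop("unknown stage label in sequence")
  idx
}

#' Categorical cross-entropy loss
#'
#' `CEL = -(1/N) sum_i sum_c 1[true_i = c] * ln(p_ic)` with a probability
#' floor of 1e-12; `N` counts the unmasked epochs.
#'
#' @param probs `T x 6` matrix of class probabilities (columns in the order
#'   `N1, N2, N3, REM, WK, LV`)
#' @param labels a [hypnogram()] (or character vector) of length `T`
#' @param mask optional logical vector; `FALSE` positions (padding) are
#'   excluded
#' @return scalar loss
#' @export
cross_entropy_loss <- function(probs, labels, mask = NULL) {
  labels <- as.character(labels)
  stopifnot(nrow(probs) == length(labels))
  idx <- encode_classes(labels)
  p <- pmax(probs[cbind(seq_along(idx), idx)], 1e-12)
  ll <- -log(p)
  if (!is.null(mask)) ll <- ll[mask]
  mean(ll)
}

# features argument -> plain T x n_features matrix
as_feature_matrix <- function(features, n_features = 4) {
  if (is.data.frame(features)) {
    cols <- intersect(c("hr", "rr", "lam", "bmf"), names(features))
    if (length(cols) != 4) stop("feature data.frame must have hr, rr, lam, bmf")
    features <- as.matrix(features[, cols])
  }
  features <- as.matrix(features)
  if (ncol(features) != n_features)
    stop(sprintf("expected %d feature columns, got %d", n_features, ncol(features)))
  storage.mode(features) <- "double"
  features
}

# pack a list of T_i x D matrices into a zero-padded (B, T, D) batch
pack_batch <- function(seq_list, n_features) {
  B <- length(seq_list)
  lens <- vapply(seq_list, nrow, integer(1))
  T_ <- max(lens)
  X <- array(0, c(B, T_, n_features))
  mask <- matrix(FALSE, B, T_)
  for (b in seq_len(B)) {
    X[b, seq_len(lens[b]), ] <- seq_list[[b]]
    mask[b, seq_len(lens[b])] <- TRUE
  }
  list(X = X, mask = mask, lens = lens)
}

batch_loss_grad <- function(probs, Y, mask) {
  B <- dim(probs)[1]; T_ <- dim(probs)[2]; C <- dim(probs)[3]
  nvalid <- sum(mask)
  pf <- probs; dim(pf) <- c(B * T_, C)
  yf <- Y; dim(yf) <- c(B * T_, C)
  mf <- as.numeric(mask)
  ptrue <- pmax(rowSums(pf * yf), 1e-12)
  loss <- -sum(log(ptrue) * mf) / nvalid
  dlog <- (pf - yf) * mf / nvalid
  list(loss = loss, dlogits = dlog)
}

masked_accuracy <- function(probs, Y, mask) {
  B <- dim(probs)[1]; T_ <- dim(probs)[2]; C <- dim(probs)[3]
  pf <- probs; dim(pf) <- c(B * T_, C)
  yf <- Y; dim(yf) <- c(B * T_, C)
  pred <- max.col(pf, ties.method = "first")
  truth <- max.col(yf, ties.method = "first")
  mean((pred == truth)[as.logical(mask)])
}

#' Train the biLSTM stager
#'
#' Full-batch ("longest sequence" mini-batch policy) Adam optimization of
#' the masked categorical cross-entropy over all six classes, with the
#' stepped learning-rate schedule, L2 weight regularization, global L2-norm
#' gradient clipping, and early stopping on the validation loss. Features
#' are z-scored per column using training-set statistics (zero padding rows
#' excluded from the statistics but transformed like any other input). The
#' weights returned are those of the best validation loss. Training history
#' (`epoch, lr, train_loss, val_loss, val_acc, grad_norm`) is stored on the
#' model.
#'
#' @param train_features list of per-subject feature tables/matrices
#'   (each `T_i x 4`), already LV-padded via [pad_lv()]
#' @param train_labels list of matching [hypnogram()]s
#' @param config a [stager_config()]
#' @param val_features,val_labels validation sequences in the same form
#' @param standardize z-score features with training-fold statistics
#'   (default TRUE)
#' @return a trained `"stager"`
#' @export
train_stager <- function(train_features, train_labels, config,
                         val_features, val_labels, standardize = TRUE) {
  if (length(train_features) < 2) stop("need at least 2 training subjects")
  stopifnot(length(train_features) == length(train_labels),
            length(val_features) == length(val_labels))
  n_features <- 4L
  xs <- lapply(train_features, as_feature_matrix, n_features = n_features)
  vs <- lapply(val_features, as_feature_matrix, n_features = n_features)

  # sort training sequences by length (longest first) before padding
  ord <- order(vapply(xs, nrow, integer(1)), decreasing = TRUE)
  xs <- xs[ord]
  ys <- lapply(train_labels[ord], encode_classes)
  yv <- lapply(val_labels, encode_classes)

  all_rows <- do.call(rbind, xs)
  mu <- if (standardize) colMeans(all_rows) else rep(0, n_features)
  sdv <- if (standardize) apply(all_rows, 2, stats::sd) else rep(1, n_features)
  sdv[!is.finite(sdv) | sdv < 1e-8] <- 1
  zs <- lapply(xs, function(m) sweep(sweep(m, 2, mu), 2, sdv, "/"))
  zv <- lapply(vs, function(m) sweep(sweep(m, 2, mu), 2, sdv, "/"))

  tb <- pack_batch(zs, n_features)
  vb <- pack_batch(zv, n_features)
  C <- config$n_classes
  onehot <- function(batch, enc) {
    Y <- array(0, c(dim(batch$X)[1], dim(batch$X)[2], C))
    for (b in seq_along(enc))
      Y[cbind(b, seq_along(enc[[b]]), enc[[b]])] <- 1
    Y
  }
  Yt <- onehot(tb, ys)
  Yv <- onehot(vb, yv)

  model <- build_stager(config, n_features)
  model$mu <- mu; model$sd <- sdv
  params <- model$params
  madam <- lapply(params, function(p) p * 0)
  vadam <- madam
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  best_loss <- Inf; best_params <- params; wait <- 0L; step <- 0L
  hist <- vector("list", config$max_epochs)
  keep <- 1 - config$dropout_rate
  l2_keys <- grep("\\.(W|U)$", names(params), value = TRUE)

  with_seed(derive_seed(config$seed, "train"), {
    for (epoch in seq_len(config$max_epochs)) {
      lr <- config$initial_lr *
        config$lr_drop_factor^((epoch - 1) %/% config$lr_drop_every)
      masks <- NULL
      if (config$dropout_rate > 0) {
        masks <- lapply(seq_len(config$n_bilstm_layers), function(l) {
          dmn <- c(dim(tb$X)[1], dim(tb$X)[2], 2 * config$hidden_units)
          array((stats::runif(prod(dmn)) < keep) / keep, dmn)
        })
      }
      fwd <- network_forward(params, tb$X, config, train = TRUE,
                             dropout_masks = masks)
      lg <- batch_loss_grad(fwd$probs, Yt, tb$mask)
      if (!is.finite(lg$loss))
        stop(sprintf("training aborted: non-finite loss at epoch %d", epoch))
      grads <- network_backward(params, config, fwd, lg$dlogits,
                                dropout_masks = masks)
      if (config$l2_regularization > 0) {
        for (k in l2_keys)
          grads[[k]] <- grads[[k]] + config$l2_regularization * params[[k]]
      }
      cl <- clip_gradients(grads, config$grad_clip_l2)
      grads <- cl$grads
      step <- step + 1L
      for (k in names(params)) {
        madam[[k]] <- beta1 * madam[[k]] + (1 - beta1) * grads[[k]]
        vadam[[k]] <- beta2 * vadam[[k]] + (1 - beta2) * grads[[k]]^2
        mhat <- madam[[k]] / (1 - beta1^step)
        vhat <- vadam[[k]] / (1 - beta2^step)
        params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
      }
      vfwd <- network_forward(params, vb$X, config, train = FALSE)
      vl <- batch_loss_grad(vfwd$probs, Yv, vb$mask)$loss
      vacc <- masked_accuracy(vfwd$probs, Yv, vb$mask)
      hist[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                                  train_loss = lg$loss, val_loss = vl,
                                  val_acc = vacc, grad_norm = cl$norm)
      if (best_loss - vl > 1e-5) {
        best_loss <- vl; best_params <- params; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$early_stop_patience) break
      }
    }
  })
  model$params <- best_params
  model$history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
  model
}

#' Predict a hypnogram from an epoch feature sequence
#'
#' Forward pass (dropout off) followed by a per-epoch argmax of the softmax
#' probabilities; ties break toward the lower class index in the order
#' `N1, N2, N3, REM, WK, LV`.
#'
#' @param model a trained `"stager"`
#' @param features `T x 4` feature table/matrix
#' @return `list(hypnogram, probs)` with `probs` a `T x 6` matrix whose
#'   columns follow `model$class_order`
#' @export
predict_stages <- function(model, features) {
  x <- as_feature_matrix(features, model$n_features)
  z <- sweep(sweep(x, 2, model$mu), 2, model$sd, "/")
  X <- array(z, c(1, nrow(z), ncol(z)))
  fwd <- network_forward(model$params, X, model$config, train = FALSE)
  probs <- matrix(fwd$probs, nrow(z), model$config$n_classes)
  colnames(probs) <- model$class_order
  pred <- model$class_order[max.col(probs, ties.method = "first")]
  list(hypnogram = hypnogram(pred), probs = probs)
}

#' Leave-one-subject-out cross-validation
#'
#' For each subject, trains on all other subjects with the held-out subject
#' serving as the early-stopping validation set (the single-holdout scheme;
#' note this makes the stopping criterion see the evaluation subject, an
#' optimism-prone but faithful protocol) and predicts the held-out night.
#' Per-subject seeds derive from the subject id, so results do not depend
#' on subject order.
#'
#' @param features_list named list of per-subject feature tables (LV-padded)
#' @param labels_list matching named list of [hypnogram()]s
#' @param config a [stager_config()]
#' @return named list of `list(id, true, pred, probs, model)` per subject
#' @export
loocv <- function(features_list, labels_list, config) {
  n <- length(features_list)
  if (n < 3) stop("leave-one-out cross-validation needs at least 3 subjects")
  ids <- names(features_list) %||% sprintf("S%03d", seq_len(n))
  if (is.null(names(features_list))) {
    names(features_list) <- ids
    names(labels_list) <- ids
  }
  ids <- sort(ids)
  out <- vector("list", n)
  names(out) <- ids
  for (id in ids) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, id)
    rest <- setdiff(ids, id)
    model <- train_stager(features_list[rest], labels_list[rest], cfg,
                          features_list[id], labels_list[id])
    pr <- predict_stages(model, features_list[[id]])
    out[[id]] <- list(id = id, true = labels_list[[id]],
                      pred = pr$hypnogram, probs = pr$probs, model = model)
  }
  out
}

#' Save / load a trained stager as a JSON checkpoint
#'
#' Plain-text archive: configuration echoed as JSON alongside all weight
#' matrices and the feature-standardization statistics.
#'
#' @param model a `"stager"`
#' @param path file path
#' @export
save_stager <- function(model, path) {
  obj <- list(config = unclass(model$config),
              class_order = model$class_order,
              n_features = model$n_features,
              mu = model$mu, sd = model$sd,
              params = lapply(model$params, function(p) {
                if (is.matrix(p)) list(dim = dim(p), data = as.numeric(p))
                else list(dim = NULL, data = as.numeric(p))
              }))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_stager
#' @export
load_stager <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(stager_config, obj$config[setdiff(names(obj$config), NULL)])
  params <- lapply(obj$params, function(p) {
    if (!is.null(p$dim) && length(p$dim) == 2) matrix(p$data, p$dim[1], p$dim[2])
    else as.numeric(p$data)
  })
  structure(list(params = params, config = cfg,
                 class_order = obj$class_order,
                 n_features = obj$n_features,
                 mu = obj$mu, sd = obj$sd, history = NULL),
            class = "stager")
}
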