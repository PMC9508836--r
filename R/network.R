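## Per-variant-type convolutional classifier: configuration, parameter
## initialization, training loop (Adam/AdamW, stepwise LR decay, early
## stopping, best-epoch checkpointing) and prediction. The heavy forward/
## backward passes live in compiled code (src/cnn.cpp).

#' Network architecture configuration
#'
#' Defaults follow the published architecture: nine same-padded 3x3
#' convolutional layers with 96 filters and ReLU, batch normalization plus
#' a squeeze-and-excitation block after every third layer, and a head that
#' concatenates global max and global average pooling into a single
#' sigmoid unit with an L1 penalty. Smaller settings train much faster on
#' CPU and are used throughout the test suite.
#'
#' @param conv_layers number of conv layers (divisible by `se_every`).
#' @param filters filters per conv layer.
#' @param se_every apply BN + SE after every this-many conv layers.
#' @param se_ratio SE bottleneck reduction ratio (bottleneck width is
#'   `max(1, filters / se_ratio)`).
#' @param l1 L1 coefficient on the sigmoid layer weights.
#' @param input_shape `c(rows, cols, channels)` of the input images.
#' @return a `model_config`.
#' @export
model_config <- function(conv_layers = 9L, filters = 96L, se_every = 3L,
                         se_ratio = 16L, l1 = 1e-6,
                         input_shape = c(IMAGE_ROWS, IMAGE_COLS, 3L)) {
  conv_layers <- as.integer(conv_layers)
  se_every <- as.integer(se_every)
  if (conv_layers <= 0L || filters <= 0L || se_ratio <= 0L) {
    stop2("conv_layers, filters and se_ratio must be positive")
  }
  if (conv_layers %% se_every != 0L) {
    stop2("conv_layers must be divisible by se_every")
  }
  structure(list(
    conv_layers = conv_layers, filters = as.integer(filters),
    kernel = c(3L, 3L), se_every = se_every, se_ratio = as.integer(se_ratio),
    l1 = l1, rows = as.integer(input_shape[1]),
    cols = as.integer(input_shape[2]), channels = as.integer(input_shape[3])
  ), class = "model_config")
}

#' Training configuration
#'
#' Defaults mirror the published schedule: up to 100 epochs with early
#' stopping after 40 epochs without validation improvement, binary
#' cross-entropy loss, Adam (substitution model) or AdamW (indel models,
#' warm-started from the substitution weights), and a stepwise learning
#' rate decay of 0.5 every 10 epochs.
#'
#' @param max_epochs maximum training epochs.
#' @param patience early-stopping patience (epochs without validation
#'   improvement; must be < `max_epochs`).
#' @param optimizer `"adam"` or `"adamw"`.
#' @param learning_rate initial learning rate.
#' @param weight_decay decoupled weight decay (AdamW only).
#' @param batch_size mini-batch size.
#' @param lr_decay,lr_every stepwise decay factor and period (epochs).
#' @param seed RNG seed for shuffling.
#' @param verbose print per-epoch progress?
#' @return a `training_config`.
#' @export
training_config <- function(max_epochs = 100L, patience = 40L,
                            optimizer = c("adam", "adamw"),
                            learning_rate = 1e-3, weight_decay = 1e-4,
                            batch_size = 32L, lr_decay = 0.5,
                            lr_every = 10L, seed = 1L, verbose = FALSE) {
  optimizer <- match.arg(optimizer)
  if (patience >= max_epochs) stop2("patience must be < max_epochs")
  if (learning_rate <= 0) stop2("learning_rate must be positive")
  structure(list(max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), optimizer = optimizer,
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size), lr_decay = lr_decay,
                 lr_every = as.integer(lr_every), seed = as.integer(seed),
                 verbose = verbose),
            class = "training_config")
}

#' Stepwise learning-rate schedule
#'
#' @param epoch 0-based epoch index.
#' @param lr0 initial learning rate.
#' @param decay multiplicative factor applied every `every` epochs.
#' @param every decay period in epochs.
#' @return the learning rate in effect at `epoch`.
#' @export
lr_schedule <- function(epoch, lr0, decay = 0.5, every = 10L) {
  lr0 * decay^(epoch %/% every)
}

TRAINABLE <- c("conv_W", "conv_b", "bn_gamma", "bn_beta",
               "se_W1", "se_b1", "se_W2", "se_b2", "head_w", "head_b")

#' Build an untrained classifier
#'
#' Convolutional and SE weights use He-normal initialization; BN scales
#' start at 1 and running statistics at (0, 1); the head starts near zero.
#' Two builds with the same seed are parameter-identical.
#'
#' @param config a [model_config()].
#' @param seed RNG seed for the initial weights.
#' @return a `dnm_cnn` model (untrained).
#' @export
build_network <- function(config = model_config(), seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  set.seed(seed)
  L <- config$conv_layers
  F_ <- config$filters
  r <- max(1L, F_ %/% config$se_ratio)
  nbn <- L %/% config$se_every
  he <- function(nrow, ncol) {
    matrix(stats::rnorm(nrow * ncol, 0, sqrt(2 / ncol)), nrow, ncol)
  }
  conv_W <- vector("list", L)
  conv_b <- vector("list", L)
  for (l in seq_len(L)) {
    cin <- if (l == 1L) config$channels else F_
    conv_W[[l]] <- he(F_, cin * 9L)
    conv_b[[l]] <- numeric(F_)
  }
  params <- list(
    conv_W = conv_W, conv_b = conv_b,
    bn_gamma = replicate(nbn, rep(1, F_), simplify = FALSE),
    bn_beta = replicate(nbn, numeric(F_), simplify = FALSE),
    bn_rmean = replicate(nbn, numeric(F_), simplify = FALSE),
    bn_rvar = replicate(nbn, rep(1, F_), simplify = FALSE),
    se_W1 = replicate(nbn, he(r, F_), simplify = FALSE),
    se_b1 = replicate(nbn, numeric(r), simplify = FALSE),
    se_W2 = replicate(nbn, he(F_, r), simplify = FALSE),
    se_b2 = replicate(nbn, numeric(F_), simplify = FALSE),
    head_w = stats::rnorm(2L * F_, 0, sqrt(1 / (2 * F_))),
    head_b = 0
  )
  structure(list(config = config, params = params, history = NULL,
                 trained = FALSE),
            class = "dnm_cnn")
}

#' @export
print.dnm_cnn <- function(x, ...) {
  n <- sum(lengths(lapply(unlist(x$params[TRAINABLE],
                                 recursive = FALSE), as.numeric)))
  cat(sprintf(paste0(
    "<dnm_cnn> %d conv layers x %d filters, SE every %d (ratio %d)\n",
    "  input %dx%dx%d, %d trainable parameters, %s\n"),
    x$config$conv_layers, x$config$filters, x$config$se_every,
    x$config$se_ratio, x$config$rows, x$config$cols, x$config$channels,
    n, if (isTRUE(x$trained)) "trained" else "untrained"))
  invisible(x)
}

#' Squeeze-and-excitation block (reference implementation)
#'
#' Squeeze: per-channel global average. Excitation: bottleneck dense layer
#' (ReLU) followed by an expansion dense layer with sigmoid gates in
#' `[0, 1]` that rescale each channel. Output shape equals input shape.
#'
#' @param x feature maps, array `rows x cols x channels`.
#' @param W1,b1 bottleneck weights (`r x channels`) and bias.
#' @param W2,b2 expansion weights (`channels x r`) and bias.
#' @return list with `output` (same shape as `x`) and `gates`.
#' @export
se_block <- function(x, W1, b1, W2, b2) {
  stopifnot(length(dim(x)) == 3L)
  s <- apply(x, 3, mean)
  z1 <- pmax(as.vector(W1 %*% s + b1), 0)
  gates <- stats::plogis(as.vector(W2 %*% z1 + b2))
  list(output = sweep(x, 3, gates, `*`), gates = gates)
}

as_image_batch <- function(x) {
  d <- dim(x)
  if (is.null(d) || !(length(d) %in% c(3L, 4L))) {
    stop2("images must be a rows x cols x channels (x n) array")
  }
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  if (!is.double(x)) storage.mode(x) <- "double"
  x
}

cnn_config_list <- function(model) {
  c <- model$config
  list(rows = c$rows, cols = c$cols, channels = c$channels,
       conv_layers = c$conv_layers, filters = c$filters,
       se_every = c$se_every, se_ratio = c$se_ratio)
}

#' Forward pass: probability of the de novo class
#'
#' @param object a `dnm_cnn` model.
#' @param images array `rows x cols x channels [x n]`.
#' @param ... unused.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
predict.dnm_cnn <- function(object, images, ...) {
  .cnn_predict(object$params, cnn_config_list(object),
               as_image_batch(images))
}

bce <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Train the classifier
#'
#' Mini-batch training with binary cross-entropy, Adam or AdamW, the
#' stepwise LR schedule of [lr_schedule()], early stopping, and
#' best-validation-epoch checkpointing: the returned model carries the
#' parameters of the epoch with the lowest validation loss.
#'
#' @param model a `dnm_cnn` from [build_network()] (or a warm-started one).
#' @param train_x,train_y training images (`rows x cols x channels x n`)
#'   and 0/1 labels (1 = de novo).
#' @param val_x,val_y validation images and labels (disjoint from
#'   training).
#' @param config a [training_config()].
#' @return the trained `dnm_cnn`, with `$history` (one row per epoch:
#'   epoch, lr, train_loss, val_loss, val_acc), `$best_epoch` and
#'   `$stopped_epoch`.
#' @export
train_cnn <- function(model, train_x, train_y, val_x, val_y,
                      config = training_config()) {
  stopifnot(inherits(model, "dnm_cnn"), inherits(config, "training_config"))
  train_x <- as_image_batch(train_x)
  val_x <- as_image_batch(val_x)
  n <- dim(train_x)[4]
  if (n == 0L || length(train_y) != n) stop2("empty or mismatched dataset")
  cfg <- cnn_config_list(model)
  params <- model$params
  skeleton <- params[TRAINABLE]
  theta <- unlist(skeleton, use.names = FALSE)
  m <- numeric(length(theta))
  v <- numeric(length(theta))
  tstep <- 0L
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  momentum <- 0.9   # running-statistics momentum for batch norm
  set.seed(config$seed)
  history <- NULL
  best_loss <- Inf
  best_params <- params
  best_epoch <- NA_integer_
  stopped <- config$max_epochs
  for (epoch in seq_len(config$max_epochs)) {
    lr <- lr_schedule(epoch - 1L, config$learning_rate,
                      config$lr_decay, config$lr_every)
    idx <- sample.int(n)
    batches <- split(idx, ceiling(seq_along(idx) / config$batch_size))
    epoch_loss <- 0
    for (b in batches) {
      xb <- train_x[, , , b, drop = FALSE]
      res <- .cnn_batch_grad(params, cfg, xb, as.numeric(train_y[b]),
                             model$config$l1)
      if (!is.finite(res$loss)) {
        stop2("training diverged (non-finite loss) at epoch ", epoch,
              "; lower the learning rate")
      }
      epoch_loss <- epoch_loss + res$loss * length(b)
      g <- unlist(res$grads, use.names = FALSE)
      tstep <- tstep + 1L
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      mhat <- m / (1 - beta1^tstep)
      vhat <- v / (1 - beta2^tstep)
      theta <- theta - lr * mhat / (sqrt(vhat) + eps)
      if (config$optimizer == "adamw") {
        theta <- theta - lr * config$weight_decay * theta
      }
      params[TRAINABLE] <- utils::relist(theta, skeleton)
      for (s in seq_along(res$bn_mean)) {
        params$bn_rmean[[s]] <- momentum * params$bn_rmean[[s]] +
          (1 - momentum) * res$bn_mean[[s]]
        params$bn_rvar[[s]] <- momentum * params$bn_rvar[[s]] +
          (1 - momentum) * res$bn_var[[s]]
      }
    }
    epoch_loss <- epoch_loss / n
    val_p <- .cnn_predict(params, cfg, val_x)
    val_loss <- bce(val_p, val_y)
    val_acc <- mean((val_p >= 0.5) == (val_y == 1))
    history <- rbind(history, data.frame(
      epoch = epoch, lr = lr, train_loss = epoch_loss,
      val_loss = val_loss, val_acc = val_acc))
    if (config$verbose) {
      message(sprintf(
        "epoch %3d  lr %.2e  train %.4f  val %.4f  acc %.3f",
        epoch, lr, epoch_loss, val_loss, val_acc))
    }
    if (val_loss < best_loss) {
      best_loss <- val_loss
      best_params <- params
      best_epoch <- epoch
    }
    if (epoch - best_epoch >= config$patience) {
      stopped <- epoch
      break
    }
  }
  model$params <- best_params
  model$history <- history
  model$best_epoch <- best_epoch
  model$stopped_epoch <- stopped
  model$trained <- TRUE
  model
}

#' Warm-start one model from another
#'
#' Copies all parameters from `source` into `model` (shapes must match);
#' used to initialize the insertion/deletion models from the trained
#' substitution model.
#'
#' @param model target `dnm_cnn`.
#' @param source trained `dnm_cnn` with an identical configuration.
#' @return `model` with `source`'s parameters.
#' @export
warm_start <- function(model, source) {
  stopifnot(inherits(model, "dnm_cnn"), inherits(source, "dnm_cnn"))
  shapes <- function(p) lapply(p, function(x)
    if (is.list(x)) lapply(x, dim_or_len) else dim_or_len(x))
  dim_or_len <- function(x) dim(x) %||% length(x)
  if (!identical(shapes(model$params), shapes(source$params))) {
    stop2("parameter shapes differ; models must share a configuration")
  }
  model$params <- source$params
  model$trained <- FALSE
  model
}

#' Classify one encoded candidate with a per-type model bank
#'
#' The candidate is routed to the model matching its variant type and
#' labelled `"DNM"` when the de novo probability is at least `threshold`
#' (inclusive at the default 0.5), else `"IV"`.
#'
#' @param model_bank named list of `dnm_cnn` models, one per variant type
#'   (`substitution`, `insertion`, `deletion`).
#' @param image a `dnm_image` with a `variant_type` attribute.
#' @param threshold de novo probability threshold (default 0.5).
#' @return data.frame with `p_dnm`, `label`, `model_used`.
#' @export
classify_dnm <- function(model_bank, image, threshold = 0.5) {
  vt <- attr(image, "variant_type")
  if (is.null(vt) || !vt %in% names(model_bank)) {
    stop2("no model available for variant type '", vt %||% "?", "'")
  }
  p <- predict(model_bank[[vt]], unclass(image))
  data.frame(p_dnm = p, label = ifelse(p >= threshold, "DNM", "IV"),
             model_used = vt, stringsAsFactors = FALSE)
}

#' Hyperparameter search space
#'
#' Discrete choices for filters and batch size; log-uniform segments for
#' the L1 coefficient, learning rate and weight decay.
#'
#' @return a `search_space` list of bounds/choices.
#' @export
search_space <- function() {
  structure(list(
    filters = c(32L, 64L, 96L, 128L),
    batch_size = c(32L, 64L),
    l1 = c(1e-10, 0.1),
    learning_rate = c(1e-8, 0.01),
    weight_decay = c(1e-8, 0.01)
  ), class = "search_space")
}

#' Sample configurations from the search space
#'
#' Discrete fields are sampled uniformly; continuous fields are sampled
#' log-uniformly within their segments.
#'
#' @param space a [search_space()].
#' @param n number of draws.
#' @param seed RNG seed.
#' @return data.frame with one sampled configuration per row.
#' @export
sample_search_space <- function(space, n, seed = 1L) {
  set.seed(seed)
  logu <- function(n, lo, hi) exp(stats::runif(n, log(lo), log(hi)))
  data.frame(
    filters = sample(space$filters, n, replace = TRUE),
    batch_size = sample(space$batch_size, n, replace = TRUE),
    l1 = logu(n, space$l1[1], space$l1[2]),
    learning_rate = logu(n, space$learning_rate[1],
                         space$learning_rate[2]),
    weight_decay = logu(n, space$weight_decay[1], space$weight_decay[2])
  )
}

#' Seeded random hyperparameter search
#'
#' Draws `budget` configurations from the space and returns the one with
#' the lowest validation cross-entropy as measured by `eval_fn`.
#'
#' @param space a [search_space()].
#' @param budget number of trials (>= 1).
#' @param eval_fn function taking one sampled configuration (a one-row
#'   data.frame) and returning its validation cross-entropy loss. See
#'   [make_cnn_eval_fn()] for the standard trainer-backed evaluator.
#' @param seed RNG seed.
#' @return list with `best` (configuration row, with its loss) and
#'   `results` (all trials).
#' @export
hyperparameter_search <- function(space, budget, eval_fn, seed = 1L) {
  if (budget < 1L) stop2("budget must be >= 1")
  draws <- sample_search_space(space, budget, seed = seed)
  losses <- vapply(seq_len(budget),
                   function(i) eval_fn(draws[i, , drop = FALSE]),
                   numeric(1))
  draws$val_loss <- losses
  list(best = draws[which.min(losses), , drop = FALSE], results = draws)
}

#' Trainer-backed evaluator for [hyperparameter_search()]
#'
#' @param train_x,train_y,val_x,val_y datasets as in [train_cnn()].
#' @param base_config a [model_config()] whose filters/l1 fields are
#'   overridden by each sampled configuration.
#' @param epochs training epochs per trial.
#' @param seed weight-init/shuffling seed.
#' @return a function usable as `eval_fn`.
#' @export
make_cnn_eval_fn <- function(train_x, train_y, val_x, val_y,
                             base_config, epochs = 5L, seed = 1L) {
  function(draw) {
    cfg <- base_config
    cfg$filters <- as.integer(draw$filters)
    cfg$l1 <- draw$l1
    model <- build_network(cfg, seed = seed)
    tc <- training_config(
      max_epochs = epochs, patience = max(1L, epochs - 1L),
      learning_rate = draw$learning_rate,
      weight_decay = draw$weight_decay,
      batch_size = as.integer(draw$batch_size), seed = seed)
    fit <- train_cnn(model, train_x, train_y, val_x, val_y, tc)
    min(fit$history$val_loss)
  }
}
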