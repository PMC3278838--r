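sigmoid <- function(z) 1 / (1 + exp(-z))

PM_BLOCKS <- list(
  PM1 = "BPC",
  PM2 = "ATOM",
  PM3 = c("BPC", "AC"),
  PM4 = c("BPC", "ATOM"),
  PM5 = c("BPC", "AC", "ATOM")
)

#' Canonical prediction-model configurations PM1-PM5
#'
#' The five feature-block combinations evaluated by the architecture, each
#' classified by a two-layer feed-forward network (one hidden layer of
#' sigmoid units, one sigmoid output):
#' * `PM1` - 40 BPC property means (40 features);
#' * `PM2` - atomic composition alone (5 features);
#' * `PM3` - 40 BPC plus their 25 autocorrelation values (65 features);
#' * `PM4` - 40 BPC plus 5 atomic values (45 features);
#' * `PM5` - all three blocks (70 features).
#'
#' @param pm_id One of `"PM1"` .. `"PM5"`.
#' @param bpc The 40 selected property accessions (required for all but
#'   PM2).
#' @param ac The 5 accessions whose autocorrelation functions are computed
#'   (required for PM3 and PM5).
#' @param hidden_units Hidden-layer size (default 23).
#' @param fractions Train/validation/test split fractions, summing to 1
#'   (default 0.6/0.2/0.2).
#' @param max_epochs,learning_rate,lr_decay,momentum,patience Training
#'   hyperparameters of [train_ann()].
#' @param seed Seed for weight initialization.
#' @return A `pm_config` with the matching [encoding_config()] in
#'   `$encoding` and `$expected_dim` of 40, 5, 65, 45 or 70.
#' @examples
#' idx <- synthesize_indices(45, seed = 1)
#' cfg <- pm_config("PM3", bpc = idx$accession[1:40], ac = idx$accession[41:45])
#' cfg$expected_dim # 65
#' @export
pm_config <- function(pm_id = c("PM1", "PM2", "PM3", "PM4", "PM5"),
                      bpc = character(), ac = character(),
                      hidden_units = 23L,
                      fractions = c(train = 0.6, validation = 0.2,
                                    test = 0.2),
                      max_epochs = 2000L, learning_rate = 0.1,
                      lr_decay = 0.999, momentum = 0.9,
                      patience = 100L, seed = 1L) {
  pm_id <- match.arg(pm_id)
  blocks <- PM_BLOCKS[[pm_id]]
  if ("BPC" %in% blocks && length(bpc) != 40L) {
    abort(sprintf("%s needs exactly 40 BPC accessions (got %d).",
                  pm_id, length(bpc)))
  }
  if ("AC" %in% blocks && length(ac) != 5L) {
    abort(sprintf("%s needs exactly 5 AC accessions (got %d).",
                  pm_id, length(ac)))
  }
  if (abs(sum(fractions) - 1) > 1e-8) abort("`fractions` must sum to 1.")
  encoding <- encoding_config(
    bpc = if ("BPC" %in% blocks) bpc else character(),
    ac = if ("AC" %in% blocks) ac else character(),
    blocks = blocks)
  structure(
    list(pm_id = pm_id, encoding = encoding,
         expected_dim = n_features(encoding),
         hidden_units = as.integer(hidden_units), fractions = fractions,
         max_epochs = as.integer(max_epochs),
         learning_rate = learning_rate, lr_decay = lr_decay,
         momentum = momentum, patience = as.integer(patience),
         seed = as.integer(seed)),
    class = "pm_config")
}

#' @export
print.pm_config <- function(x, ...) {
  cat(sprintf("<pm_config> %s: blocks %s, %d features, %d hidden units\n",
              x$pm_id, paste(x$encoding$blocks, collapse = "+"),
              x$expected_dim, x$hidden_units))
  invisible(x)
}

#' Stratified train/validation/test split
#'
#' Splits a labeled dataset at the given fractions (default 60/20/20),
#' stratified by class with a seeded shuffle. A non-empty validation
#' partition is required because network training stops early on validation
#' loss.
#'
#' @param data Tibble with a `label` column.
#' @param fractions Numeric vector of three fractions summing to 1.
#' @param seed Seed for the shuffle.
#' @return Named list of tibbles `train`, `validation`, `test`; partitions
#'   are disjoint and exhaustive, and each contains both classes.
#' @export
split_data <- function(data, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  stopifnot("label" %in% names(data), length(fractions) == 3L)
  if (abs(sum(fractions) - 1) > 1e-8) abort("`fractions` must sum to 1.")
  if (any(fractions[1:2] <= 0)) {
    abort(paste("Train and validation fractions must be positive:",
                "early stopping requires a validation partition."))
  }
  assignment <- integer(nrow(data))
  with_seed(seed, {
    for (cl in unique(data$label)) {
      idx <- sample(which(data$label == cl))
      n <- length(idx)
      bounds <- floor(cumsum(fractions) * n + 1e-9)
      counts <- diff(c(0L, bounds))
      assignment[idx] <- rep(1:3, times = counts)
    }
  })
  parts <- map(1:3, function(k) data[assignment == k, , drop = FALSE])
  names(parts) <- c("train", "validation", "test")
  check <- map(parts[c("train", "validation")], function(p) {
    if (length(unique(p$label)) < 2L) {
      abort(paste("A partition lost one of the classes;",
                  "provide more data or different fractions."))
    }
  })
  if (fractions[3] > 0 && length(unique(parts$test$label)) < 2L) {
    abort("Test partition lost a class; provide more data.")
  }
  parts
}

#' Train the two-layer feed-forward prediction network
#'
#' A single hidden layer of sigmoid units and one sigmoid output unit
#' (target 1 = amyloidogenic, 0 = non-amyloidogenic), trained by full-batch
#' backpropagation on the cross-entropy loss with momentum and a
#' geometrically decaying learning rate. Min-max normalization is fitted on
#' the training partition only and stored with the model; training stops
#' early when the validation loss has not improved for `patience` epochs,
#' restoring the best weights. Fully deterministic given the seed.
#'
#' @param train,validation Tibbles with `label` and identical raw (not yet
#'   normalized) feature columns.
#' @param config A [pm_config()], or `NULL` to accept any feature
#'   dimension with default hyperparameters.
#' @return An `amyhex_ann` model: weights, the stored `minmax_params`,
#'   the feature-name manifest, the per-epoch loss history, and the epoch
#'   whose weights were kept.
#' @seealso [predict_scores()], [classify_scores()]
#' @export
train_ann <- function(train, validation, config = NULL) {
  stopifnot("label" %in% names(train), "label" %in% names(validation))
  feats <- feature_columns(train)
  if (!identical(feats, feature_columns(validation))) {
    abort("Train and validation must share the same feature columns.")
  }
  if (!is.null(config) && inherits(config, "pm_config") &&
      length(feats) != config$expected_dim) {
    abort(sprintf("%s expects %d features, got %d.",
                  config$pm_id, config$expected_dim, length(feats)))
  }
  hp <- if (is.null(config)) {
    list(hidden_units = 23L, max_epochs = 2000L, learning_rate = 0.1,
         lr_decay = 0.999, momentum = 0.9, patience = 100L, seed = 1L)
  } else {
    config
  }

  norm <- fit_minmax(train)
  x <- as.matrix(apply_minmax(train, norm)[feats])
  y <- as.numeric(train$label)
  xv <- as.matrix(apply_minmax(validation, norm)[feats])
  yv <- as.numeric(validation$label)

  p <- ncol(x)
  H <- hp$hidden_units
  w <- with_seed(hp$seed, list(
    W1 = matrix(runif(p * H, -0.5, 0.5), p, H),
    b1 = runif(H, -0.5, 0.5),
    W2 = matrix(runif(H, -0.5, 0.5), H, 1),
    b2 = runif(1, -0.5, 0.5)))
  vel <- map(w, function(m) m * 0)

  forward <- function(w, x) {
    a1 <- sigmoid(sweep(x %*% w$W1, 2, w$b1, "+"))
    list(a1 = a1, a2 = drop(sigmoid(a1 %*% w$W2 + w$b2)))
  }
  xent <- function(yhat, y) {
    eps <- 1e-12
    -mean(y * log(yhat + eps) + (1 - y) * log(1 - yhat + eps))
  }

  n <- nrow(x)
  lr <- hp$learning_rate
  best <- list(loss = Inf, w = w, epoch = 0L)
  history <- vector("list", hp$max_epochs)
  stale <- 0L
  epoch <- 0L
  while (epoch < hp$max_epochs) {
    epoch <- epoch + 1L
    fw <- forward(w, x)
    train_loss <- xent(fw$a2, y)
    if (!is.finite(train_loss)) {
      abort(sprintf(
        "Training diverged at epoch %d (non-finite loss); lower the learning rate (%.3g).",
        epoch, lr))
    }
    dz2 <- matrix((fw$a2 - y) / n, ncol = 1)
    grad <- list(
      W1 = crossprod(x, (dz2 %*% t(w$W2)) * fw$a1 * (1 - fw$a1)),
      b1 = colSums((dz2 %*% t(w$W2)) * fw$a1 * (1 - fw$a1)),
      W2 = crossprod(fw$a1, dz2),
      b2 = sum(dz2))
    vel <- map2(vel, grad, function(v, g) hp$momentum * v - lr * g)
    w <- map2(w, vel, `+`)
    lr <- lr * hp$lr_decay

    val_loss <- xent(forward(w, xv)$a2, yv)
    history[[epoch]] <- tibble(epoch = epoch, train_loss = train_loss,
                               val_loss = val_loss)
    if (val_loss < best$loss - 1e-9) {
      best <- list(loss = val_loss, w = w, epoch = epoch)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= hp$patience) break
    }
  }

  structure(
    list(weights = best$w, normalization = norm, manifest = feats,
         hidden_units = H, config = config,
         history = bind_rows(history[!map_lgl_null(history)]),
         stop_epoch = best$epoch, seed = hp$seed),
    class = "amyhex_ann")
}

map_lgl_null <- function(x) vapply(x, is.null, logical(1))

#' Score samples with a trained prediction network
#'
#' Applies the model's stored min-max normalization to the raw feature
#' columns and runs the forward pass; scores are sigmoid outputs in (0, 1),
#' in input row order.
#'
#' @param model An `amyhex_ann` from [train_ann()].
#' @param data Tibble whose feature columns exactly match the model's
#'   manifest.
#' @return Numeric vector of scores.
#' @export
predict_scores <- function(model, data) {
  stopifnot(inherits(model, "amyhex_ann"))
  feats <- feature_columns(data)
  missing_f <- setdiff(model$manifest, feats)
  extra_f <- setdiff(feats, model$manifest)
  if (length(missing_f) || length(extra_f)) {
    abort(sprintf(
      "Feature manifest mismatch. Missing: %s. Unexpected: %s.",
      paste(c(missing_f, "none")[1], collapse = ", "),
      paste(c(extra_f, "none")[1], collapse = ", ")))
  }
  x <- as.matrix(apply_minmax(data, model$normalization)[model$manifest])
  w <- model$weights
  a1 <- sigmoid(sweep(x %*% w$W1, 2, w$b1, "+"))
  drop(sigmoid(a1 %*% w$W2 + w$b2))
}

#' @export
#' @param object An `amyhex_ann`.
#' @param newdata Tibble of raw features.
#' @param type `"score"` for sigmoid outputs, `"class"` for 0/1 labels.
#' @param threshold Decision threshold for `type = "class"`.
#' @param ... Unused.
#' @rdname predict_scores
predict.amyhex_ann <- function(object, newdata, type = c("score", "class"),
                               threshold = 0.5, ...) {
  type <- match.arg(type)
  scores <- predict_scores(object, newdata)
  if (type == "score") scores else classify_scores(scores, threshold)
}

#' Threshold scores into binary labels
#'
#' A sample is called positive when its score is greater than or equal to
#' the threshold (ties go to the positive class, matching the target coding
#' 1 = amyloidogenic). Thresholds are clamped to `[0, 1]`.
#'
#' @param scores Numeric scores in `[0, 1]`.
#' @param threshold Decision threshold (default 0.5).
#' @return Integer vector of 0/1 labels.
#' @export
classify_scores <- function(scores, threshold = 0.5) {
  threshold <- min(max(threshold, 0), 1)
  as.integer(scores >= threshold)
}

#' @export
print.amyhex_ann <- function(x, ...) {
  cat(sprintf(
    "<amyhex_ann> %d-%d-1 sigmoid network%s | stopped at epoch %d (val loss %.4f)\n",
    length(x$manifest), x$hidden_units,
    if (!is.null(x$config)) paste0(" [", x$config$pm_id, "]") else "",
    x$stop_epoch, min(x$history$val_loss)))
  invisible(x)
}

#' @describeIn train_ann Per-epoch training history
#'   (`epoch`, `train_loss`, `val_loss`).
#' @param x An `amyhex_ann`.
#' @param ... Unused.
#' @method tidy amyhex_ann
#' @export
tidy.amyhex_ann <- function(x, ...) {
  x$history
}

#' @describeIn train_ann One-row model summary.
#' @method glance amyhex_ann
#' @export
glance.amyhex_ann <- function(x, ...) {
  tibble(n_features = length(x$manifest), hidden_units = x$hidden_units,
         pm_id = if (!is.null(x$config)) x$config$pm_id else NA_character_,
         stop_epoch = x$stop_epoch,
         best_val_loss = min(x$history$val_loss),
         epochs_run = nrow(x$history))
}

#' @describeIn train_ann Training and validation loss curves.
#' @param object An `amyhex_ann`.
#' @method autoplot amyhex_ann
#' @export
autoplot.amyhex_ann <- function(object, ...) {
  hist_long <- tidyr::pivot_longer(object$history,
                                   c("train_loss", "val_loss"),
                                   names_to = "partition",
                                   values_to = "loss")
  ggplot2::ggplot(hist_long,
                  ggplot2::aes(x = .data$epoch, y = .data$loss,
                               colour = .data$partition)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$stop_epoch, linetype = 2) +
    ggplot2::labs(x = "Epoch", y = "Cross-entropy loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Serialize a trained network as JSON
#'
#' @param model An `amyhex_ann`.
#' @param file Path.
#' @return [write_ann()]: `file`, invisibly; [read_ann()]: the model.
#' @export
write_ann <- function(model, file) {
  payload <- list(
    weights = map(model$weights, function(m) {
      if (is.matrix(m)) list(dim = dim(m), values = as.numeric(m))
      else list(dim = NULL, values = as.numeric(m))
    }),
    normalization = as.data.frame(model$normalization),
    manifest = model$manifest, hidden_units = model$hidden_units,
    pm_id = if (!is.null(model$config)) model$config$pm_id else NULL,
    stop_epoch = model$stop_epoch, seed = model$seed)
  jsonlite::write_json(payload, file, digits = NA, auto_unbox = TRUE)
  invisible(file)
}

#' @rdname write_ann
#' @export
read_ann <- function(file) {
  payload <- jsonlite::read_json(file, simplifyVector = TRUE)
  weights <- map(payload$weights, function(wl) {
    if (length(wl$dim) == 2L) matrix(wl$values, wl$dim[1], wl$dim[2])
    else as.numeric(wl$values)
  })
  norm <- as_tibble(payload$normalization)
  class(norm) <- c("minmax_params", class(norm))
  structure(
    list(weights = weights, normalization = norm,
         manifest = payload$manifest, hidden_units = payload$hidden_units,
         config = NULL, history = tibble(epoch = integer(),
                                         train_loss = numeric(),
                                         val_loss = numeric()),
         stop_epoch = payload$stop_epoch, seed = payload$seed),
    class = "amyhex_ann")
}
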