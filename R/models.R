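#' Model architecture specification
#'
#' Defines the layer stack: a first convolution (3 kernels, stride 40,
#' width 40 by default, so a 1000-sample window becomes 25 timesteps of 3
#' channels), a stack of 5 LSTM layers, attention pooling over the top
#' layer's per-timestep outputs, a second convolution integrating the
#' attention-weighted sequence, then flatten, a fully connected ReLU
#' layer with dropout, and a 2-class softmax output.
#'
#' @param input_len Window length in samples (default 1000 = 10 s at
#'   100 Hz).
#' @param conv1_kernels,conv1_width,conv1_stride First convolution:
#'   number of kernels, kernel width and stride (samples).
#' @param lstm_layers Number of stacked LSTM layers.
#' @param lstm_hidden Hidden units per LSTM layer.
#' @param attn_width Hidden width of the feedforward alignment model.
#' @param conv2_kernels,conv2_width,conv2_stride Second convolution over
#'   the attention-weighted timestep sequence.
#' @param dense_width Fully connected layer width.
#' @param dropout Dropout rate on the dense layer during training.
#' @param n_classes Number of output classes.
#' @return A `model_spec` object.
#' @export
model_spec <- function(input_len = 1000L,
                       conv1_kernels = 3L, conv1_width = 40L,
                       conv1_stride = 40L,
                       lstm_layers = 5L, lstm_hidden = 64L,
                       attn_width = 32L,
                       conv2_kernels = 8L, conv2_width = 5L,
                       conv2_stride = 5L,
                       dense_width = 32L, dropout = 0.5,
                       n_classes = 2L) {
  spec <- structure(
    list(input_len = as.integer(input_len),
         conv1_kernels = as.integer(conv1_kernels),
         conv1_width = as.integer(conv1_width),
         conv1_stride = as.integer(conv1_stride),
         lstm_layers = as.integer(lstm_layers),
         lstm_hidden = as.integer(lstm_hidden),
         attn_width = as.integer(attn_width),
         conv2_kernels = as.integer(conv2_kernels),
         conv2_width = as.integer(conv2_width),
         conv2_stride = as.integer(conv2_stride),
         dense_width = as.integer(dense_width),
         dropout = dropout, n_classes = as.integer(n_classes)),
    class = "model_spec")
  T1 <- (spec$input_len - spec$conv1_width) %/% spec$conv1_stride + 1L
  if (T1 < spec$conv2_width)
    stop("model_spec: conv2 width exceeds the post-conv1 sequence length")
  spec
}

#' Training configuration
#'
#' @param learn_rate Adam learning rate (default 0.001).
#' @param batch_size Minibatch size (default 256).
#' @param num_epochs Training epochs (default 500).
#' @param n_seed_repeats Number of random-seed repetitions for
#'   [train_multiseed()] (default 5).
#' @param fractions Named train/test/validation split fractions; must sum
#'   to 1 (default 0.7/0.2/0.1).
#' @param rng_seed Seed controlling initialisation, shuffling and
#'   dropout.
#' @param verbose Print per-epoch progress.
#' @return A `train_config` object.
#' @export
train_config <- function(learn_rate = 0.001, batch_size = 256L,
                         num_epochs = 500L, n_seed_repeats = 5L,
                         fractions = c(train = 0.7, test = 0.2,
                                       validation = 0.1),
                         rng_seed = 1L, verbose = FALSE) {
  if (abs(sum(fractions) - 1) > 1e-8)
    stop("train_config: split fractions must sum to 1")
  structure(list(learn_rate = learn_rate, batch_size = as.integer(batch_size),
                 num_epochs = as.integer(num_epochs),
                 n_seed_repeats = as.integer(n_seed_repeats),
                 fractions = fractions, rng_seed = as.integer(rng_seed),
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

#' One LSTM cell step
#'
#' Standard LSTM recurrence by default: gate activations
#' \eqn{i_t, f_t, o_t = \sigma(W [x_t, h_{t-1}] + b)}, candidate
#' \eqn{g_t = \tanh(\cdot)}, cell update
#' \eqn{C_t = f_t \odot C_{t-1} + i_t \odot g_t}, output
#' \eqn{h_t = o_t \odot \tanh(C_t)}. With `printed_variant = TRUE` the
#' nonstandard printed variant is computed instead: the gates also see
#' \eqn{C_{t-1}} in their input, the forget-gate bias multiplies
#' \eqn{C_{t-1}} elementwise, the cell update is
#' \eqn{C_t = f_t + i_t \odot g_t} (no \eqn{f_t \odot C_{t-1}} product),
#' and the output gate sees the new \eqn{C_t}.
#'
#' @param x Input vector (length D) or (n x D) matrix.
#' @param h_prev,c_prev Previous hidden/cell state, length H vectors or
#'   (n x H) matrices.
#' @param weights List with `Wx` (D x 4H), `Wh` (H x 4H), `b` (4H), and —
#'   for the literal variant — `Wc` (H x 4H). Gate block order is
#'   i, f, g, o.
#' @param printed_variant Use the printed nonstandard equations.
#' @return List with `h`, `c` and gate activations `i`, `f`, `o` (all
#'   (n x H) matrices).
#' @export
lstm_step <- function(x, h_prev, c_prev, weights, printed_variant = FALSE) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  if (is.vector(h_prev)) h_prev <- matrix(h_prev, nrow = 1L)
  if (is.vector(c_prev)) c_prev <- matrix(c_prev, nrow = 1L)
  H <- ncol(h_prev)
  if (ncol(weights$Wx) != 4L * H || nrow(weights$Wx) != ncol(x) ||
      nrow(weights$Wh) != H)
    stop("lstm_step: weight shapes inconsistent with the inputs")
  z <- x %*% weights$Wx + h_prev %*% weights$Wh
  if (printed_variant) {
    if (is.null(weights$Wc))
      stop("lstm_step: printed_variant needs weights$Wc")
    z <- z + c_prev %*% weights$Wc
  }
  z <- sweep(z, 2L, weights$b, "+")
  i <- sigmoid(z[, 1:H, drop = FALSE])
  g <- tanh(z[, (2L * H + 1L):(3L * H), drop = FALSE])
  if (printed_variant) {
    bf <- weights$b[(H + 1L):(2L * H)]
    zf <- x %*% weights$Wx[, (H + 1L):(2L * H), drop = FALSE] +
      h_prev %*% weights$Wh[, (H + 1L):(2L * H), drop = FALSE] +
      c_prev %*% weights$Wc[, (H + 1L):(2L * H), drop = FALSE] +
      sweep(c_prev, 2L, bf, "*")
    f <- sigmoid(zf)
    c_new <- f + i * g
    zo <- x %*% weights$Wx[, (3L * H + 1L):(4L * H), drop = FALSE] +
      h_prev %*% weights$Wh[, (3L * H + 1L):(4L * H), drop = FALSE] +
      c_new %*% weights$Wc[, (3L * H + 1L):(4L * H), drop = FALSE]
    zo <- sweep(zo, 2L, weights$b[(3L * H + 1L):(4L * H)], "+")
    o <- sigmoid(zo)
  } else {
    f <- sigmoid(z[, (H + 1L):(2L * H), drop = FALSE])
    o <- sigmoid(z[, (3L * H + 1L):(4L * H), drop = FALSE])
    c_new <- f * c_prev + i * g
  }
  list(h = o * tanh(c_new), c = c_new, i = i, f = f, o = o)
}

#' Attention layer over encoder outputs
#'
#' Bahdanau-style content attention: each encoder hidden vector
#' \eqn{h_j} is scored by a feedforward alignment model
#' \eqn{a_j = v^\top \tanh(W [s; h_j] + b)} (with optional decoder/query
#' state \eqn{s}), the scores are softmax-normalised into weights
#' \eqn{\alpha_j \ge 0, \sum_j \alpha_j = 1}, and the context is
#' \eqn{C = \sum_j \alpha_j h_j}.
#'
#' @param enc (T x H) matrix of encoder hidden vectors, one row per
#'   position.
#' @param params List with `W` ((H + Q) x A or H x A), `b` (A), `v`
#'   (A x 1); created with random Glorot values when omitted.
#' @param query Optional query/decoder state vector (length Q).
#' @param seed Seed for the default random parameters.
#' @return List with `context` (length H), `weights` (length T, sums to
#'   1) and `scores` (pre-softmax alignments).
#' @export
attention_layer <- function(enc, params = NULL, query = NULL, seed = 1L) {
  if (is.vector(enc)) enc <- matrix(enc, nrow = 1L)
  Tn <- nrow(enc)
  if (Tn < 1L) stop("attention_layer: need at least one encoder output")
  H <- ncol(enc)
  Q <- if (is.null(query)) 0L else length(query)
  if (is.null(params)) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    A <- max(4L, H)
    params <- list(W = glorot(H + Q, A), b = numeric(A), v = glorot(A, 1L))
  }
  inp <- if (Q > 0L) cbind(matrix(query, Tn, Q, byrow = TRUE), enc) else enc
  s <- tanh(sweep(inp %*% params$W, 2L, params$b, "+"))
  scores <- as.numeric(s %*% params$v)
  w <- exp(scores - max(scores))
  w <- w / sum(w)
  list(context = as.numeric(crossprod(w, enc)), weights = w, scores = scores)
}

#' Build a sequence classifier
#'
#' @param kind `"lstm_attention"` (conv, 5-layer LSTM, attention pooling,
#'   conv, dense, softmax), `"lstm"` (same trunk, last hidden state in
#'   place of attention + conv2) or `"bilstm"` (forward and backward LSTM
#'   stacks, concatenated last hidden states).
#' @param spec A [model_spec()].
#' @param seed Seed for parameter initialisation; identical seeds give
#'   identical models.
#' @return A `ppg_model`: `kind`, `spec`, `params`.
#' @export
build_model <- function(kind = c("lstm_attention", "lstm", "bilstm"),
                        spec = model_spec(), seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(inherits(spec, "model_spec"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  structure(list(kind = kind, spec = spec,
                 params = init_params(kind, spec)),
            class = "ppg_model")
}

#' @export
print.ppg_model <- function(x, ...) {
  np <- length(flatten_params(x$params))
  cat(sprintf("<ppg_model> %s: %d LSTM layers x %d units, %d parameters\n",
              x$kind, x$spec$lstm_layers, x$spec$lstm_hidden, np))
  invisible(x)
}

#' Number of trainable parameters
#' @param model A `ppg_model`.
#' @return Integer count.
#' @export
n_parameters <- function(model) length(flatten_params(model$params))

standardize_windows <- function(X) {
  mu <- rowMeans(X)
  sd_ <- apply(X, 1L, stats::sd)
  sd_[sd_ < .Machine$double.eps] <- 1
  (X - mu) / sd_
}

#' Predict class probabilities for windows
#'
#' Windows are z-scored per row before the forward pass, so amplitude
#' offsets and scale do not affect predictions.
#'
#' @param model A trained (or freshly built) `ppg_model`.
#' @param X (n x input_len) matrix of windows.
#' @return (n x n_classes) matrix of probabilities; columns ordered as
#'   `model$classes` when the model has been trained.
#' @export
predict_proba <- function(model, X) {
  stopifnot(inherits(model, "ppg_model"))
  if (is.vector(X)) X <- matrix(X, nrow = 1L)
  if (ncol(X) != model$spec$input_len)
    stop("predict_proba: window length does not match spec$input_len")
  nn_forward(model, standardize_windows(X))$probs
}

#' Build a window dataset from a cohort
#'
#' Optionally preprocesses every record, then segments them into
#' fixed-length windows, producing the matrix form the classifiers
#' consume.
#'
#' @param cohort A `ppg_cohort`.
#' @param window_s Window length (s).
#' @param preprocess Run [preprocess_record()] first.
#' @return A `window_dataset`: `X` (n x window samples), `label`
#'   (character), `subject_id`, `session`, `window_index`.
#' @export
build_window_dataset <- function(cohort, window_s = 10, preprocess = TRUE) {
  stopifnot(inherits(cohort, "ppg_cohort"))
  rows <- list(); meta <- list()
  for (res in cohort$records) {
    rec <- if (preprocess) preprocess_record(res$record) else res$record
    for (w in segment_windows(rec, window_s)) {
      rows[[length(rows) + 1L]] <- w$samples
      meta[[length(meta) + 1L]] <- data.frame(
        subject_id = w$subject_id, label = w$label, session = w$session,
        window_index = w$window_index, stringsAsFactors = FALSE)
    }
  }
  md <- do.call(rbind, meta)
  structure(list(X = do.call(rbind, rows), label = md$label,
                 subject_id = md$subject_id, session = md$session,
                 window_index = md$window_index),
            class = "window_dataset")
}

#' Split a window dataset into train/test/validation
#'
#' Stratified by class. With `unit = "window"` individual windows are
#' assigned (the protocol used for the main results, which lets windows
#' of one subject appear in several splits); `unit = "subject"` assigns
#' whole subjects, for leakage-free evaluation.
#'
#' @param dataset A `window_dataset`.
#' @param fractions Named fractions summing to 1, default 0.7 train /
#'   0.2 test / 0.1 validation.
#' @param unit `"window"` or `"subject"`.
#' @param seed RNG seed; identical seeds give identical assignments.
#' @return Character vector of split names, one per window.
#' @export
split_dataset <- function(dataset,
                          fractions = c(train = 0.7, test = 0.2,
                                        validation = 0.1),
                          unit = c("window", "subject"), seed = 1L) {
  unit <- match.arg(unit)
  if (abs(sum(fractions) - 1) > 1e-8)
    stop("split_dataset: fractions must sum to 1")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n <- length(dataset$label)
  assign_group <- function(idx) {
    k <- length(idx)
    counts <- floor(fractions * k)
    rem <- k - sum(counts)
    if (rem > 0) {
      # spend remainders on empty splits first, then largest remainder
      prio <- order(counts == 0, fractions * k - counts,
                    decreasing = TRUE)[seq_len(rem)]
      counts[prio] <- counts[prio] + 1L
    }
    if (any(counts == 0))
      stop("split_dataset: a split would be empty")
    rep(names(fractions), counts)[sample.int(k)]
  }
  out <- character(n)
  if (unit == "window") {
    for (cl in unique(dataset$label)) {
      idx <- which(dataset$label == cl)
      out[idx] <- assign_group(idx)
    }
  } else {
    subj <- unique(data.frame(subject_id = dataset$subject_id,
                              label = dataset$label))
    subj$split <- NA_character_
    for (cl in unique(subj$label)) {
      idx <- which(subj$label == cl)
      subj$split[idx] <- assign_group(idx)
    }
    out <- subj$split[match(dataset$subject_id, subj$subject_id)]
  }
  out
}

label_to_onehot <- function(label, classes) {
  Y <- matrix(0, length(label), length(classes))
  Y[cbind(seq_along(label), match(label, classes))] <- 1
  Y
}

#' Train a sequence classifier
#'
#' Minimises the cross-entropy loss with Adam, with dropout on the dense
#' layer, recording per-epoch training and validation loss/accuracy.
#' Training aborts with a diagnostic if the loss turns non-finite.
#'
#' @param kind Model kind, see [build_model()].
#' @param dataset A `window_dataset`.
#' @param split Split assignment from [split_dataset()]; windows labelled
#'   `"train"` are optimised on, `"validation"` tracked per epoch.
#' @param spec A [model_spec()].
#' @param config A [train_config()].
#' @return List with the trained `model` (which carries `classes`) and
#'   `history` (data frame: epoch, train_loss, train_acc, val_loss,
#'   val_acc).
#' @export
train_model <- function(kind, dataset, split, spec = model_spec(),
                        config = train_config()) {
  stopifnot(inherits(dataset, "window_dataset"))
  classes <- sort(unique(dataset$label))
  model <- build_model(kind, spec, seed = config$rng_seed)
  model$classes <- classes

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$rng_seed + 1L)

  Xtr <- standardize_windows(dataset$X[split == "train", , drop = FALSE])
  ytr <- dataset$label[split == "train"]
  Ytr <- label_to_onehot(ytr, classes)
  has_val <- any(split == "validation")
  if (has_val) {
    Xva <- standardize_windows(dataset$X[split == "validation", , drop = FALSE])
    yva <- dataset$label[split == "validation"]
  }

  st <- adam_init(model$params)
  ntr <- nrow(Xtr)
  hist <- vector("list", config$num_epochs)
  for (ep in seq_len(config$num_epochs)) {
    ord <- sample.int(ntr)
    ep_loss <- 0; ep_correct <- 0
    for (b0 in seq(1L, ntr, by = config$batch_size)) {
      idx <- ord[b0:min(b0 + config$batch_size - 1L, ntr)]
      Xb <- Xtr[idx, , drop = FALSE]
      Yb <- Ytr[idx, , drop = FALSE]
      fw <- nn_forward(model, Xb, training = TRUE)
      loss <- cross_entropy(fw$probs, Yb)
      if (!is.finite(loss))
        stop(sprintf("train_model: divergent (non-finite) loss at epoch %d", ep))
      g <- nn_backward(model, Xb, Yb, fw)
      upd <- adam_step(model$params, g, st, config$learn_rate)
      model$params <- upd$params
      st <- upd$state
      ep_loss <- ep_loss + loss * length(idx)
      ep_correct <- ep_correct +
        sum(max.col(fw$probs) == max.col(Yb, ties.method = "first"))
    }
    row <- data.frame(epoch = ep, train_loss = ep_loss / ntr,
                      train_acc = ep_correct / ntr,
                      val_loss = NA_real_, val_acc = NA_real_)
    if (has_val) {
      pv <- nn_forward(model, Xva)$probs
      row$val_loss <- cross_entropy(pv, match(yva, classes))
      row$val_acc <- mean(classes[max.col(pv)] == yva)
    }
    hist[[ep]] <- row
    if (config$verbose)
      message(sprintf("epoch %3d  loss %.4f  acc %.3f  val_acc %s", ep,
                      row$train_loss, row$train_acc,
                      ifelse(has_val, sprintf("%.3f", row$val_acc), "-")))
  }
  list(model = model, history = do.call(rbind, hist))
}

#' Train across several seeds and aggregate
#'
#' Repeats [train_model()] with different seeds and reports per-seed test
#' metrics, their mean, and metrics of the seed-averaged predicted
#' probabilities.
#'
#' @inheritParams train_model
#' @param seeds Integer vector of seeds; defaults to
#'   `config$rng_seed + 0:(config$n_seed_repeats - 1)`.
#' @param positive Positive class for the metrics.
#' @return List with `per_seed` (data frame), `mean_metrics`,
#'   `prob_averaged` (metrics of the averaged probabilities) and
#'   `models`.
#' @export
train_multiseed <- function(kind, dataset, split, spec = model_spec(),
                            config = train_config(), seeds = NULL,
                            positive = "hypertensive") {
  if (is.null(seeds))
    seeds <- config$rng_seed + seq_len(config$n_seed_repeats) - 1L
  Xte <- dataset$X[split == "test", , drop = FALSE]
  yte <- dataset$label[split == "test"]
  per <- list(); probs_sum <- NULL; models <- list()
  for (s in seeds) {
    cfg <- config; cfg$rng_seed <- as.integer(s)
    tr <- train_model(kind, dataset, split, spec, cfg)
    pp <- predict_proba(tr$model, Xte)
    pred <- tr$model$classes[max.col(pp)]
    rep_ <- evaluation_report(pred, yte, positive = positive, protocol = "test")
    per[[length(per) + 1L]] <- data.frame(seed = s,
                                          accuracy = rep_$accuracy,
                                          precision = rep_$precision,
                                          recall = rep_$recall, f1 = rep_$f1)
    probs_sum <- if (is.null(probs_sum)) pp else probs_sum + pp
    models[[length(models) + 1L]] <- tr$model
  }
  per <- do.call(rbind, per)
  pavg <- probs_sum / length(seeds)
  pred_avg <- models[[1L]]$classes[max.col(pavg)]
  list(per_seed = per,
       mean_metrics = colMeans(per[, -1L, drop = FALSE]),
       prob_averaged = evaluation_report(pred_avg, yte, positive = positive,
                                         protocol = "test"),
       models = models)
}

#' Fit a classical feature-based classifier
#'
#' SVM (RBF kernel) or k-nearest neighbours on the 20-dimensional
#' pulse-wave feature vectors. Features are z-scored with the training
#' statistics, which are stored for prediction.
#'
#' @param features Data frame from [build_feature_table()] (must contain
#'   the 20 feature columns and `label`).
#' @param kind `"svm"` or `"knn"`.
#' @param k Neighbours for KNN.
#' @param cost,gamma SVM hyperparameters (gamma defaults to 1/20).
#' @return A `classical_model` with a `predict` method.
#' @export
fit_classical <- function(features, kind = c("svm", "knn"), k = 5L,
                          cost = 1, gamma = NULL) {
  kind <- match.arg(kind)
  if (length(unique(features$label)) < 2L)
    stop("fit_classical: need at least 2 classes")
  X <- as.matrix(features[, feature_names, drop = FALSE])
  mu <- colMeans(X); sd_ <- apply(X, 2L, stats::sd)
  sd_[sd_ < .Machine$double.eps] <- 1
  Xs <- sweep(sweep(X, 2L, mu), 2L, sd_, "/")
  y <- factor(features$label)
  fit <- if (kind == "svm") {
    if (is.null(gamma)) gamma <- 1 / ncol(Xs)
    e1071::svm(Xs, y, kernel = "radial", cost = cost, gamma = gamma)
  } else NULL
  structure(list(kind = kind, fit = fit, train_X = Xs, train_y = y,
                 k = as.integer(k), center = mu, scale = sd_),
            class = "classical_model")
}

#' @param object A `classical_model`.
#' @param newdata Data frame with the 20 feature columns.
#' @param ... Unused.
#' @rdname fit_classical
#' @export
predict.classical_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, feature_names, drop = FALSE])
  Xs <- sweep(sweep(X, 2L, object$center), 2L, object$scale, "/")
  if (object$kind == "svm") {
    as.character(stats::predict(object$fit, Xs))
  } else {
    as.character(class::knn(object$train_X, Xs, object$train_y,
                            k = object$k))
  }
}
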