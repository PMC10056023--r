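make_step_weights <- function(D, H, seed = 1, zero = FALSE, with_c = FALSE) {
  set.seed(seed)
  mk <- function(nr, nc) if (zero) matrix(0, nr, nc)
    else matrix(rnorm(nr * nc, sd = 0.5), nr, nc)
  w <- list(Wx = mk(D, 4 * H), Wh = mk(H, 4 * H),
            b = if (zero) numeric(4 * H) else rnorm(4 * H, sd = 0.5))
  if (with_c) w$Wc <- mk(H, 4 * H)
  w
}

test_that("all-zero weights give gate activations of exactly 1/2", {
  w <- make_step_weights(2, 3, zero = TRUE)
  st <- lstm_step(c(1, -1), rep(0.2, 3), rep(0.4, 3), w)
  expect_equal(as.numeric(st$i), rep(0.5, 3))
  expect_equal(as.numeric(st$f), rep(0.5, 3))
  expect_equal(as.numeric(st$o), rep(0.5, 3))
  # cell update driven only by those constants: c = 0.5*c_prev + 0.5*tanh(0)
  expect_equal(as.numeric(st$c), rep(0.2, 3))
  expect_equal(as.numeric(st$h), as.numeric(0.5 * tanh(st$c)))
})

test_that("gate outputs stay in (0,1) and hidden outputs in (-1,1) on fuzzed inputs", {
  for (s in 1:20) {
    set.seed(s)
    w <- make_step_weights(4, 5, seed = s)
    st <- lstm_step(rnorm(4, sd = 3), rnorm(5), rnorm(5), w)
    expect_true(all(st$i > 0 & st$i < 1))
    expect_true(all(st$f > 0 & st$f < 1))
    expect_true(all(st$o > 0 & st$o < 1))
    expect_true(all(abs(st$h) < 1))
  }
})

test_that("lstm_step matches an independent scalar recurrence on a 2-unit cell", {
  D <- 3; H <- 2
  w <- make_step_weights(D, H, seed = 42)
  x <- c(0.3, -1.2, 0.7); h0 <- c(0.1, -0.2); c0 <- c(0.5, 0.05)
  # brute-force scalar oracle, gate by gate, unit by unit
  sig <- function(z) 1 / (1 + exp(-z))
  oracle_h <- numeric(H); oracle_c <- numeric(H)
  for (u in 1:H) {
    zi <- sum(x * w$Wx[, u]) + sum(h0 * w$Wh[, u]) + w$b[u]
    zf <- sum(x * w$Wx[, H + u]) + sum(h0 * w$Wh[, H + u]) + w$b[H + u]
    zg <- sum(x * w$Wx[, 2 * H + u]) + sum(h0 * w$Wh[, 2 * H + u]) + w$b[2 * H + u]
    zo <- sum(x * w$Wx[, 3 * H + u]) + sum(h0 * w$Wh[, 3 * H + u]) + w$b[3 * H + u]
    oracle_c[u] <- sig(zf) * c0[u] + sig(zi) * tanh(zg)
    oracle_h[u] <- sig(zo) * tanh(oracle_c[u])
  }
  st <- lstm_step(x, h0, c0, w)
  expect_equal(as.numeric(st$c), oracle_c, tolerance = 1e-6)
  expect_equal(as.numeric(st$h), oracle_h, tolerance = 1e-6)
})

test_that("the literal printed cell variant follows its stated equations", {
  D <- 2; H <- 2
  w <- make_step_weights(D, H, seed = 7, with_c = TRUE)
  x <- c(0.5, -0.5); h0 <- c(0.2, 0.1); c0 <- c(0.3, -0.4)
  st <- lstm_step(x, h0, c0, w, printed_variant = TRUE)
  sig <- function(z) 1 / (1 + exp(-z))
  for (u in 1:H) {
    zf <- sum(x * w$Wx[, H + u]) + sum(h0 * w$Wh[, H + u]) +
      sum(c0 * w$Wc[, H + u]) + w$b[H + u] * c0[u]
    f <- sig(zf)
    zi <- sum(x * w$Wx[, u]) + sum(h0 * w$Wh[, u]) +
      sum(c0 * w$Wc[, u]) + w$b[u]
    zg <- sum(x * w$Wx[, 2 * H + u]) + sum(h0 * w$Wh[, 2 * H + u]) +
      sum(c0 * w$Wc[, 2 * H + u]) + w$b[2 * H + u]
    cc <- f + sig(zi) * tanh(zg)
    expect_equal(st$c[1, u], cc, tolerance = 1e-9)
  }
  expect_error(lstm_step(x, h0, c0, make_step_weights(2, 2),
                         printed_variant = TRUE), "Wc")
  expect_error(lstm_step(c(1, 2, 3), h0, c0, w), "shapes")
})

test_that("attention weights are a proper distribution and T=1 passes through", {
  enc <- matrix(rnorm(40), 8, 5)
  # constant encoder rows give identical scores, so uniform weights
  enc_const <- matrix(1, 6, 5)
  a <- attention_layer(enc_const, seed = 2)
  expect_equal(a$weights, rep(1 / 6, 6), tolerance = 1e-12)
  for (s in 1:20) {
    set.seed(s)
    e <- matrix(rnorm(40, sd = 2), 8, 5)
    a <- attention_layer(e, seed = s)
    expect_true(all(a$weights >= 0))
    expect_equal(sum(a$weights), 1, tolerance = 1e-9)
    expect_equal(a$context, as.numeric(crossprod(a$weights, e)),
                 tolerance = 1e-12)
  }
  one <- attention_layer(matrix(c(1, 2, 3), 1, 3), seed = 1)
  expect_equal(one$weights, 1)
  expect_equal(one$context, c(1, 2, 3))
  expect_error(attention_layer(matrix(numeric(0), 0, 3)), "at least one")
})

test_that("context is the weight-averaged encoder state, query included", {
  set.seed(5)
  enc <- matrix(rnorm(30), 6, 5)
  a <- attention_layer(enc, seed = 5, query = c(0.3, -0.2))
  expect_equal(a$context, as.numeric(crossprod(a$weights, enc)),
               tolerance = 1e-12)
  expect_equal(sum(a$weights), 1, tolerance = 1e-9)
})

test_that("built models map windows to normalised probabilities deterministically", {
  spec <- tiny_spec()
  set.seed(1)
  X <- matrix(rnorm(5 * 80), 5, 80)
  for (kind in c("lstm_attention", "lstm", "bilstm")) {
    m <- build_model(kind, spec, seed = 3)
    p <- predict_proba(m, X)
    expect_equal(dim(p), c(5L, 2L))
    expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-6)
    expect_true(all(p >= 0))
    m2 <- build_model(kind, spec, seed = 3)
    expect_identical(predict_proba(m2, X), p)
  }
  expect_gt(n_parameters(build_model("lstm_attention", spec)),
            n_parameters(build_model("lstm", spec)))
  expect_error(build_model("cnn", spec), "arg")
})

test_that("analytic gradients agree with central differences on a tiny model", {
  spec <- tiny_spec()
  set.seed(11)
  X <- matrix(rnorm(3 * 80), 3, 80)
  Y <- ppgscreen:::label_to_onehot(c("a", "b", "a"), c("a", "b"))
  m <- build_model("lstm_attention", spec, seed = 7)
  m$params$attn_v <- matrix(rnorm(3) * 0.1, 3, 1)
  fw <- ppgscreen:::nn_forward(m, X)
  g <- ppgscreen:::nn_backward(m, X, Y, fw)
  eps <- 1e-5
  for (nm in c("conv1_K", "attn_W", "attn_v", "conv2_K", "dense_W", "out_b")) {
    for (i in unique(round(seq(1, length(m$params[[nm]]), length.out = 4)))) {
      m2 <- m
      m2$params[[nm]][i] <- m$params[[nm]][i] + eps
      lp <- cross_entropy(ppgscreen:::nn_forward(m2, X)$probs, Y)
      m2$params[[nm]][i] <- m$params[[nm]][i] - eps
      lm <- cross_entropy(ppgscreen:::nn_forward(m2, X)$probs, Y)
      num <- (lp - lm) / (2 * eps)
      expect_lt(abs(num - g[[nm]][i]) / max(1e-7, abs(num) + abs(g[[nm]][i])),
                1e-3)
    }
  }
  for (l in 1:2) for (nm in c("Wx", "Wh", "b")) {
    for (i in unique(round(seq(1, length(m$params$lstm[[l]][[nm]]),
                               length.out = 3)))) {
      m2 <- m
      m2$params$lstm[[l]][[nm]][i] <- m$params$lstm[[l]][[nm]][i] + eps
      lp <- cross_entropy(ppgscreen:::nn_forward(m2, X)$probs, Y)
      m2$params$lstm[[l]][[nm]][i] <- m$params$lstm[[l]][[nm]][i] - eps
      lm <- cross_entropy(ppgscreen:::nn_forward(m2, X)$probs, Y)
      num <- (lp - lm) / (2 * eps)
      ana <- g$lstm[[l]][[nm]][i]
      expect_lt(abs(num - ana) / max(1e-7, abs(num) + abs(ana)), 1e-3)
    }
  }
})

test_that("splits honour fractions, stratification and determinism", {
  ds <- structure(list(label = rep(c("healthy", "hypertensive"), each = 50),
                       subject_id = rep(sprintf("S%02d", 1:10), each = 10)),
                  class = "window_dataset")
  sp <- split_dataset(ds, seed = 1)
  expect_equal(as.integer(table(sp)[c("train", "test", "validation")]),
               c(70L, 20L, 10L))
  tab <- table(sp, ds$label)
  expect_true(all(abs(tab[, 1] - tab[, 2]) <= 1))
  expect_identical(split_dataset(ds, seed = 1), sp)
  expect_false(identical(split_dataset(ds, seed = 2), sp))
  sps <- split_dataset(ds, unit = "subject", seed = 3)
  sub_splits <- tapply(sps, ds$subject_id, function(x) length(unique(x)))
  expect_true(all(sub_splits == 1L))
  expect_error(split_dataset(ds, fractions = c(train = 0.99, test = 0.005,
                                               validation = 0.005), seed = 1),
               "empty")
  expect_error(split_dataset(ds, fractions = c(train = 0.7, test = 0.2,
                                               validation = 0.2)), "sum to 1")
})

test_that("training reduces the loss and is bit-reproducible for a fixed seed", {
  # tiny learnable task: class differs by a strong low-frequency pattern
  set.seed(8)
  n <- 40
  t <- seq(0, 0.79, by = 0.01)
  X <- t(replicate(n, rnorm(80, sd = 0.3)))
  y <- rep(c("a", "b"), each = n / 2)
  X[y == "b", ] <- X[y == "b", ] + 2 * sin(2 * pi * 2.5 * t)
  ds <- structure(list(X = X, label = y,
                       subject_id = rep(c("s1", "s2", "s3", "s4"), n / 4)),
                  class = "window_dataset")
  sp <- rep(c("train", "test", "validation"), c(28, 8, 4))[sample.int(n)]
  cfg <- train_config(learn_rate = 0.01, batch_size = 8, num_epochs = 15,
                      rng_seed = 2)
  tr <- train_model("lstm_attention", ds, sp, tiny_spec(), cfg)
  expect_lt(tail(tr$history$train_loss, 1), tr$history$train_loss[1])
  expect_equal(nrow(tr$history), 15L)
  expect_true(all(c("train_loss", "val_acc") %in% names(tr$history)))
  tr2 <- train_model("lstm_attention", ds, sp, tiny_spec(), cfg)
  expect_identical(tr$history, tr2$history)
  expect_identical(tr$model$params, tr2$model$params)
})

test_that("multi-seed training aggregates per-seed metrics and averaged probabilities", {
  set.seed(8)
  n <- 40
  t <- seq(0, 0.79, by = 0.01)
  X <- t(replicate(n, rnorm(80, sd = 0.3)))
  y <- rep(c("a", "b"), each = n / 2)
  X[y == "b", ] <- X[y == "b", ] + 2 * sin(2 * pi * 2.5 * t)
  ds <- structure(list(X = X, label = y), class = "window_dataset")
  sp <- rep(c("train", "test", "validation"), c(28, 8, 4))[sample.int(n)]
  cfg <- train_config(learn_rate = 0.01, batch_size = 8, num_epochs = 10,
                      rng_seed = 1, n_seed_repeats = 2)
  ms <- train_multiseed("lstm_attention", ds, sp, tiny_spec(), cfg,
                        positive = "b")
  expect_equal(nrow(ms$per_seed), 2L)
  expect_equal(unname(ms$mean_metrics["accuracy"]),
               mean(ms$per_seed$accuracy))
  expect_s3_class(ms$prob_averaged, "evaluation_report")
})

test_that("classical models separate obvious clusters and reject degenerate input", {
  set.seed(31)
  mk_features <- function(n, shift) {
    m <- matrix(rnorm(n * 20), n, 20) + shift
    df <- as.data.frame(m)
    names(df) <- ppg_feature_names()
    df
  }
  tr <- rbind(cbind(mk_features(40, 0), label = "healthy"),
              cbind(mk_features(40, 10), label = "hypertensive"))
  te <- rbind(cbind(mk_features(20, 0), label = "healthy"),
              cbind(mk_features(20, 10), label = "hypertensive"))
  for (kind in c("svm", "knn")) {
    fit <- fit_classical(tr, kind)
    expect_equal(mean(predict(fit, te) == te$label), 1.0)
  }
  # KNN with k = 1 classifies its own training set perfectly
  fit1 <- fit_classical(tr, "knn", k = 1)
  expect_equal(mean(predict(fit1, tr) == tr$label), 1.0)
  expect_error(fit_classical(tr[tr$label == "healthy", ], "svm"),
               "2 classes")
})

test_that("label-permuted features give chance-level accuracy", {
  set.seed(77)
  accs <- replicate(20, {
    m <- matrix(rnorm(60 * 20), 60, 20)
    df <- as.data.frame(m); names(df) <- ppg_feature_names()
    df$label <- sample(rep(c("healthy", "hypertensive"), 30))
    fit <- fit_classical(df[1:40, ], "knn")
    mean(predict(fit, df[41:60, ]) == df$label[41:60])
  })
  expect_lt(abs(mean(accs) - 0.5), 0.1)
})

test_that("predictions are invariant to window offset and scale", {
  m <- std_trained("lstm_attention", 1L)$model
  ds <- std_dataset()
  X <- ds$X[1:5, , drop = FALSE]
  p0 <- predict_proba(m, X)
  expect_equal(predict_proba(m, X + 100), p0, tolerance = 1e-8)
  expect_equal(predict_proba(m, X * 7), p0, tolerance = 1e-8)
})

test_that("attention pooling beats the plain LSTM on the standard cohort", {
  wins <- 0L
  seeds <- 1:5
  for (s in seeds) {
    acc_att <- test_accuracy_of(std_trained("lstm_attention", s)$model)
    acc_lstm <- test_accuracy_of(std_trained("lstm", s)$model)
    if (acc_att >= acc_lstm) wins <- wins + 1L
  }
  expect_gte(wins, 4L)
})
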