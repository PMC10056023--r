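# Native neural-network core: batched forward and backward passes for the
# conv -> stacked LSTM -> attention -> conv -> dense -> softmax classifier
# and its plain/bidirectional LSTM ablations, trained with Adam.
# Everything operates on plain matrices; a batch is one (n x L) matrix of
# z-scored windows.

sigmoid <- function(z) 1 / (1 + exp(-z))
relu <- function(z) z * (z > 0)

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

orthogonal_init <- function(h) {
  qr.Q(qr(matrix(stats::rnorm(h * h), h, h)))
}

# one packed LSTM layer parameter set; gate order i, f, g, o.
# Recurrent blocks start orthogonal (norm-preserving through time) and
# the forget gate starts open, both standard for deep LSTM stacks.
init_lstm_layer <- function(d_in, h) {
  b <- numeric(4L * h)
  b[(h + 1L):(2L * h)] <- 1
  Wh <- do.call(cbind, lapply(1:4, function(i) orthogonal_init(h)))
  list(Wx = glorot(d_in, 4L * h), Wh = Wh, b = b)
}

init_params <- function(kind, spec) {
  L <- spec$input_len
  k1 <- spec$conv1_kernels; w1 <- spec$conv1_width; s1 <- spec$conv1_stride
  T1 <- (L - w1) %/% s1 + 1L
  H <- spec$lstm_hidden
  p <- list(conv1_K = glorot(w1, k1), conv1_b = rep(0.01, k1))
  mk_stack <- function() {
    st <- vector("list", spec$lstm_layers)
    d <- k1
    for (l in seq_len(spec$lstm_layers)) {
      st[[l]] <- init_lstm_layer(d, H)
      d <- H
    }
    st
  }
  if (kind == "bilstm") {
    p$lstm_f <- mk_stack(); p$lstm_b <- mk_stack()
    head_in <- 2L * H
  } else {
    p$lstm <- mk_stack()
    head_in <- H
  }
  if (kind == "lstm_attention") {
    A <- spec$attn_width
    p$attn_W <- glorot(H, A); p$attn_b <- numeric(A)
    p$attn_v <- matrix(0, A, 1L)   # uniform attention at the start
    k2 <- spec$conv2_kernels; w2 <- spec$conv2_width; s2 <- spec$conv2_stride
    T2 <- (T1 - w2) %/% s2 + 1L
    p$conv2_K <- glorot(w2 * H, k2); p$conv2_b <- rep(0.01, k2)
    head_in <- T2 * k2
  }
  p$dense_W <- glorot(head_in, spec$dense_width)
  p$dense_b <- numeric(spec$dense_width)
  p$out_W <- glorot(spec$dense_width, spec$n_classes)
  p$out_b <- numeric(spec$n_classes)
  p
}

conv1d_forward <- function(X, K, b, width, stride) {
  L <- ncol(X)
  T_out <- (L - width) %/% stride + 1L
  Zpre <- vector("list", T_out)
  A <- vector("list", T_out)
  for (t in seq_len(T_out)) {
    cols <- ((t - 1L) * stride + 1L):((t - 1L) * stride + width)
    z <- X[, cols, drop = FALSE] %*% K
    z <- sweep(z, 2L, b, "+")
    Zpre[[t]] <- z
    A[[t]] <- relu(z)
  }
  list(Zpre = Zpre, A = A, T_out = T_out)
}

# inputs: list over time of (n x d_in); returns per-time hidden outputs
# plus the caches backprop needs
lstm_layer_forward <- function(inputs, par) {
  Tn <- length(inputs)
  n <- nrow(inputs[[1L]])
  H <- nrow(par$Wh)
  h <- matrix(0, n, H)
  cc <- matrix(0, n, H)
  hs <- vector("list", Tn)
  cache <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    z <- inputs[[t]] %*% par$Wx + h %*% par$Wh
    z <- sweep(z, 2L, par$b, "+")
    i <- sigmoid(z[, 1:H, drop = FALSE])
    f <- sigmoid(z[, (H + 1L):(2L * H), drop = FALSE])
    g <- tanh(z[, (2L * H + 1L):(3L * H), drop = FALSE])
    o <- sigmoid(z[, (3L * H + 1L):(4L * H), drop = FALSE])
    c_new <- f * cc + i * g
    tc <- tanh(c_new)
    h_new <- o * tc
    cache[[t]] <- list(i = i, f = f, g = g, o = o, tc = tc,
                       c_prev = cc, h_prev = h)
    h <- h_new
    cc <- c_new
    hs[[t]] <- h
  }
  list(hs = hs, cache = cache)
}

# dhs: list over time of gradients w.r.t. the layer's hidden outputs
# (zero matrices where no gradient flows in). Returns gradients for the
# layer parameters and for its inputs.
lstm_layer_backward <- function(inputs, fwd, par, dhs) {
  Tn <- length(inputs)
  n <- nrow(inputs[[1L]])
  H <- nrow(par$Wh)
  dWx <- matrix(0, nrow(par$Wx), ncol(par$Wx))
  dWh <- matrix(0, H, 4L * H)
  db <- numeric(4L * H)
  dinputs <- vector("list", Tn)
  dh_next <- matrix(0, n, H)
  dc_next <- matrix(0, n, H)
  for (t in rev(seq_len(Tn))) {
    ch <- fwd$cache[[t]]
    dh <- dhs[[t]] + dh_next
    dtc <- dh * ch$o
    dc <- dtc * (1 - ch$tc^2) + dc_next
    do_ <- dh * ch$tc
    df <- dc * ch$c_prev
    di <- dc * ch$g
    dg <- dc * ch$i
    dc_next <- dc * ch$f
    dz <- cbind(di * ch$i * (1 - ch$i),
                df * ch$f * (1 - ch$f),
                dg * (1 - ch$g^2),
                do_ * ch$o * (1 - ch$o))
    dWx <- dWx + crossprod(inputs[[t]], dz)
    dWh <- dWh + crossprod(ch$h_prev, dz)
    db <- db + colSums(dz)
    dinputs[[t]] <- dz %*% t(par$Wx)
    dh_next <- dz %*% t(par$Wh)
  }
  list(dWx = dWx, dWh = dWh, db = db, dinputs = dinputs)
}

# Attention pooling over the top LSTM layer's per-timestep outputs:
# alignment scores from a one-hidden-layer feedforward net with a learned
# query (a_j = v' tanh(W h_j + b)), softmax weights, and the
# alpha-weighted sequence passed on to the second convolution.
attention_forward <- function(hs, W, b, v) {
  Tn <- length(hs)
  n <- nrow(hs[[1L]])
  s <- vector("list", Tn)
  amat <- matrix(0, n, Tn)
  for (t in seq_len(Tn)) {
    st <- tanh(sweep(hs[[t]] %*% W, 2L, b, "+"))
    s[[t]] <- st
    amat[, t] <- st %*% v
  }
  alpha <- softmax_rows(amat)
  # the weighted sequence is scaled by T so its entries stay O(h) rather
  # than O(h/T); the weights themselves still sum to 1
  U <- vector("list", Tn)
  for (t in seq_len(Tn)) U[[t]] <- Tn * alpha[, t] * hs[[t]]
  list(s = s, alpha = alpha, U = U)
}

attention_backward <- function(hs, att, W, b, v, dU) {
  Tn <- length(hs)
  n <- nrow(hs[[1L]])
  H <- ncol(hs[[1L]])
  dalpha <- matrix(0, n, Tn)
  dhs <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    dalpha[, t] <- Tn * rowSums(dU[[t]] * hs[[t]])
    dhs[[t]] <- Tn * att$alpha[, t] * dU[[t]]
  }
  # softmax backward (rowwise)
  da <- att$alpha * (dalpha - rowSums(dalpha * att$alpha))
  dW <- matrix(0, H, ncol(W))
  db <- numeric(ncol(W))
  dv <- matrix(0, ncol(W), 1L)
  for (t in seq_len(Tn)) {
    st <- att$s[[t]]
    dv <- dv + crossprod(st, da[, t, drop = FALSE])
    ds <- da[, t] %*% t(v) * (1 - st^2)
    dW <- dW + crossprod(hs[[t]], ds)
    db <- db + colSums(ds)
    dhs[[t]] <- dhs[[t]] + ds %*% t(W)
  }
  list(dW = dW, db = db, dv = dv, dhs = dhs)
}

# Full forward pass. Returns class probabilities and (optionally) the
# cache needed by nn_backward. `drop_mask` is NULL outside training.
nn_forward <- function(model, X, training = FALSE, drop_mask = NULL) {
  p <- model$params; spec <- model$spec; kind <- model$kind
  c1 <- conv1d_forward(X, p$conv1_K, p$conv1_b,
                       spec$conv1_width, spec$conv1_stride)
  cache <- list(c1 = c1)
  if (kind == "bilstm") {
    fwd_f <- run_stack(c1$A, p$lstm_f)
    fwd_b <- run_stack(rev(c1$A), p$lstm_b)
    Tn <- c1$T_out
    head_in <- cbind(fwd_f$layers[[spec$lstm_layers]]$hs[[Tn]],
                     fwd_b$layers[[spec$lstm_layers]]$hs[[Tn]])
    cache$stack_f <- fwd_f; cache$stack_b <- fwd_b
  } else {
    stk <- run_stack(c1$A, p$lstm)
    cache$stack <- stk
    top <- stk$layers[[spec$lstm_layers]]$hs
    if (kind == "lstm_attention") {
      att <- attention_forward(top, p$attn_W, p$attn_b, p$attn_v)
      cache$att <- att
      c2 <- conv2d_seq_forward(att$U, p$conv2_K, p$conv2_b,
                               spec$conv2_width, spec$conv2_stride)
      cache$c2 <- c2
      head_in <- do.call(cbind, c2$A)
    } else {
      head_in <- top[[c1$T_out]]
    }
  }
  cache$head_in <- head_in
  Gpre <- sweep(head_in %*% p$dense_W, 2L, p$dense_b, "+")
  G <- relu(Gpre)
  if (training && spec$dropout > 0) {
    if (is.null(drop_mask))
      drop_mask <- matrix(stats::runif(length(G)) >= spec$dropout,
                          nrow(G), ncol(G)) / (1 - spec$dropout)
    G <- G * drop_mask
  }
  logits <- sweep(G %*% p$out_W, 2L, p$out_b, "+")
  probs <- softmax_rows(logits)
  cache$Gpre <- Gpre; cache$G <- G; cache$drop_mask <- drop_mask
  list(probs = probs, cache = cache)
}

run_stack <- function(inputs, stack) {
  layers <- vector("list", length(stack))
  cur <- inputs
  for (l in seq_along(stack)) {
    layers[[l]] <- lstm_layer_forward(cur, stack[[l]])
    cur <- layers[[l]]$hs
  }
  list(layers = layers, inputs = inputs)
}

# sequence convolution over a list of (n x H) frames
conv2d_seq_forward <- function(U, K, b, width, stride) {
  Tn <- length(U)
  T_out <- (Tn - width) %/% stride + 1L
  Zpre <- vector("list", T_out); A <- vector("list", T_out)
  for (tt in seq_len(T_out)) {
    j0 <- (tt - 1L) * stride
    Q <- do.call(cbind, U[(j0 + 1L):(j0 + width)])
    z <- sweep(Q %*% K, 2L, b, "+")
    Zpre[[tt]] <- z
    A[[tt]] <- relu(z)
  }
  list(Zpre = Zpre, A = A, T_out = T_out)
}

zero_like <- function(p) {
  if (is.list(p)) lapply(p, zero_like)
  else if (is.matrix(p)) matrix(0, nrow(p), ncol(p))
  else numeric(length(p))
}

# mean cross-entropy loss and gradients of every parameter.
# Y is an (n x n_classes) one-hot matrix.
nn_backward <- function(model, X, Y, fw) {
  p <- model$params; spec <- model$spec; kind <- model$kind
  n <- nrow(X)
  g <- zero_like(p)
  cache <- fw$cache
  dlogits <- (fw$probs - Y) / n
  g$out_W <- crossprod(cache$G, dlogits)
  g$out_b <- colSums(dlogits)
  dG <- dlogits %*% t(p$out_W)
  if (!is.null(cache$drop_mask)) dG <- dG * cache$drop_mask
  dGpre <- dG * (cache$Gpre > 0)
  g$dense_W <- crossprod(cache$head_in, dGpre)
  g$dense_b <- colSums(dGpre)
  dhead <- dGpre %*% t(p$dense_W)

  T1 <- cache$c1$T_out
  H <- spec$lstm_hidden
  if (kind == "lstm_attention") {
    # un-flatten into conv2 outputs, then back through conv2
    k2 <- spec$conv2_kernels; w2 <- spec$conv2_width; s2 <- spec$conv2_stride
    T2 <- cache$c2$T_out
    dU <- rep(list(matrix(0, n, H)), T1)
    for (tt in seq_len(T2)) {
      dA2 <- dhead[, ((tt - 1L) * k2 + 1L):(tt * k2), drop = FALSE]
      dZ2 <- dA2 * (cache$c2$Zpre[[tt]] > 0)
      j0 <- (tt - 1L) * s2
      Q <- do.call(cbind, cache$att$U[(j0 + 1L):(j0 + w2)])
      g$conv2_K <- g$conv2_K + crossprod(Q, dZ2)
      g$conv2_b <- g$conv2_b + colSums(dZ2)
      dQ <- dZ2 %*% t(p$conv2_K)
      for (j in seq_len(w2)) {
        dU[[j0 + j]] <- dU[[j0 + j]] +
          dQ[, ((j - 1L) * H + 1L):(j * H), drop = FALSE]
      }
    }
    top_hs <- cache$stack$layers[[spec$lstm_layers]]$hs
    ab <- attention_backward(top_hs, cache$att, p$attn_W, p$attn_b,
                             p$attn_v, dU)
    g$attn_W <- ab$dW; g$attn_b <- ab$db; g$attn_v <- ab$dv
    dtop <- ab$dhs
    bk <- backprop_stack(cache$stack, p$lstm, dtop)
    g$lstm <- bk$grads
    dA1 <- bk$dinputs
  } else if (kind == "lstm") {
    dtop <- rep(list(matrix(0, n, H)), T1)
    dtop[[T1]] <- dhead
    bk <- backprop_stack(cache$stack, p$lstm, dtop)
    g$lstm <- bk$grads
    dA1 <- bk$dinputs
  } else { # bilstm
    dtop_f <- rep(list(matrix(0, n, H)), T1)
    dtop_b <- rep(list(matrix(0, n, H)), T1)
    dtop_f[[T1]] <- dhead[, 1:H, drop = FALSE]
    dtop_b[[T1]] <- dhead[, (H + 1L):(2L * H), drop = FALSE]
    bk_f <- backprop_stack(cache$stack_f, p$lstm_f, dtop_f)
    bk_b <- backprop_stack(cache$stack_b, p$lstm_b, dtop_b)
    g$lstm_f <- bk_f$grads; g$lstm_b <- bk_b$grads
    dA1 <- mapply(function(a, b) a + b, bk_f$dinputs, rev(bk_b$dinputs),
                  SIMPLIFY = FALSE)
  }

  # conv1 backward
  w1 <- spec$conv1_width; s1 <- spec$conv1_stride
  for (t in seq_len(T1)) {
    dZ1 <- dA1[[t]] * (cache$c1$Zpre[[t]] > 0)
    cols <- ((t - 1L) * s1 + 1L):((t - 1L) * s1 + w1)
    g$conv1_K <- g$conv1_K + crossprod(X[, cols, drop = FALSE], dZ1)
    g$conv1_b <- g$conv1_b + colSums(dZ1)
  }
  g
}

backprop_stack <- function(stk, stack_par, dtop) {
  nl <- length(stack_par)
  grads <- vector("list", nl)
  dcur <- dtop
  for (l in rev(seq_len(nl))) {
    inputs <- if (l == 1L) stk$inputs else stk$layers[[l - 1L]]$hs
    bk <- lstm_layer_backward(inputs, stk$layers[[l]], stack_par[[l]], dcur)
    grads[[l]] <- list(Wx = bk$dWx, Wh = bk$dWh, b = bk$db)
    dcur <- bk$dinputs
  }
  list(grads = grads, dinputs = dcur)
}

# flatten/unflatten parameter trees for Adam and for numerical checks
flatten_params <- function(p) {
  unlist(p, use.names = FALSE)
}

adam_init <- function(p) list(m = zero_like(p), v = zero_like(p), t = 0L)

adam_step <- function(p, g, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  walk <- function(pp, gg, mm, vv) {
    if (is.list(pp)) {
      out_p <- pp; out_m <- mm; out_v <- vv
      for (k in seq_along(pp)) {
        r <- walk(pp[[k]], gg[[k]], mm[[k]], vv[[k]])
        out_p[[k]] <- r$p; out_m[[k]] <- r$m; out_v[[k]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else {
      m <- beta1 * mm + (1 - beta1) * gg
      v <- beta2 * vv + (1 - beta2) * gg^2
      mhat <- m / (1 - beta1^st$t)
      vhat <- v / (1 - beta2^st$t)
      list(p = pp - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
    }
  }
  r <- walk(p, g, st$m, st$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = st$t))
}

#' Mean cross-entropy loss
#'
#' Mean negative log-probability assigned to the true class. Zero (or
#' numerically tiny) probabilities for a true class are clipped to
#' `clip`, with a warning that logs the clip value, so the loss stays
#' finite.
#'
#' @param probs Matrix (n x classes) of predicted probability vectors,
#'   or a vector for a single prediction.
#' @param labels Integer class indices (1-based) or an one-hot matrix.
#' @param clip Lower clip for the true-class probability.
#' @return Scalar loss (nats).
#' @export
cross_entropy <- function(probs, labels, clip = 1e-12) {
  if (is.vector(probs)) probs <- matrix(probs, nrow = 1L)
  if (is.matrix(labels)) labels <- max.col(labels, ties.method = "first")
  stopifnot(length(labels) == nrow(probs))
  pt <- probs[cbind(seq_len(nrow(probs)), labels)]
  if (any(pt < clip)) {
    warning(sprintf("cross_entropy: %d true-class probabilities below %g clipped",
                    sum(pt < clip), clip))
    pt <- pmax(pt, clip)
  }
  -mean(log(pt))
}
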