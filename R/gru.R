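# Stacked bidirectional GRU with feed-forward attention, implemented in
# plain matrix code with analytic backpropagation-through-time. The batch
# layout is row-major: activations are (batch x dim) matrices and an input
# sequence is a list of T such matrices.

sigmoid <- function(x) 1 / (1 + exp(-x))

# Row-broadcast a bias vector onto a (n x d) matrix.
add_bias <- function(m, b) sweep(m, 2L, b, "+")

# Input weights: uniform at 1/sqrt(fan-in). Recurrent weights: random
# orthogonal (QR sign-fixed), which preserves hidden-state norm through the
# recurrence and speeds up early training.
new_gru_layer_params <- function(input_dim, hidden) {
  s_in <- 1 / sqrt(input_dim)
  rw <- function(nr, nc, s) matrix(stats::runif(nr * nc, -s, s), nr, nc)
  ortho <- function(d) {
    qr_ <- qr(matrix(stats::rnorm(d * d), d, d))
    q <- qr.Q(qr_)
    q * sign(diag(qr.R(qr_)))[col(q)]
  }
  list(
    Wz = rw(input_dim, hidden, s_in), Uz = ortho(hidden), bz = rep(0, hidden),
    Wr = rw(input_dim, hidden, s_in), Ur = ortho(hidden), br = rep(0, hidden),
    Wh = rw(input_dim, hidden, s_in), Uh = ortho(hidden), bh = rep(0, hidden)
  )
}

#' One gated-recurrent-unit step
#'
#' Advances a GRU hidden state by one position using the gate equations
#' \deqn{z_t = \sigma(W_z x_t + U_z h_{t-1} + b_z)}
#' \deqn{r_t = \sigma(W_r x_t + U_r h_{t-1} + b_r)}
#' \deqn{h_t = (1 - z_t) \circ h_{t-1} + z_t \circ
#'       \tanh(W_h x_t + U_h (r_t \circ h_{t-1}) + b_h)}
#' with \eqn{\sigma} the logistic sigmoid and \eqn{\circ} the elementwise
#' product. Note the update gate multiplies the candidate state, so a
#' closed gate (\eqn{z_t = 0}) copies the previous hidden state unchanged.
#'
#' @param x_t Input vector (or `n x input_dim` matrix for a batch).
#' @param h_prev Previous hidden state, vector or `n x hidden` matrix.
#' @param p Layer parameter list with `Wz, Uz, bz, Wr, Ur, br, Wh, Uh, bh`.
#' @return The new hidden state, same shape as `h_prev`.
#' @export
gru_step <- function(x_t, h_prev, p) {
  vec_in <- is.null(dim(x_t))
  if (vec_in) {
    x_t <- matrix(x_t, nrow = 1L)
    h_prev <- matrix(h_prev, nrow = 1L)
  }
  if (ncol(x_t) != nrow(p$Wz) || ncol(h_prev) != nrow(p$Uz)) {
    rlang::abort("gru_step: input/hidden dimensions inconsistent with parameters")
  }
  z <- sigmoid(add_bias(x_t %*% p$Wz + h_prev %*% p$Uz, p$bz))
  r <- sigmoid(add_bias(x_t %*% p$Wr + h_prev %*% p$Ur, p$br))
  hc <- tanh(add_bias(x_t %*% p$Wh + (r * h_prev) %*% p$Uh, p$bh))
  h <- (1 - z) * h_prev + z * hc
  if (vec_in) drop(h) else h
}

# Forward pass over a full sequence (list of n x in matrices), caching the
# per-step intermediates needed by BPTT. The input projections for all
# gates and all timesteps are hoisted out of the recurrence into one large
# matrix product; only the hidden-to-hidden products remain in the loop.
gru_seq_forward <- function(xs, p, keep_cache = FALSE) {
  T_ <- length(xs)
  n <- nrow(xs[[1L]])
  hidden <- nrow(p$Uz)
  X_all <- do.call(rbind, xs)
  P_all <- X_all %*% cbind(p$Wz, p$Wr, p$Wh)
  P_all <- sweep(P_all, 2L, c(p$bz, p$br, p$bh), "+")
  Uzr <- cbind(p$Uz, p$Ur)
  iz <- seq_len(hidden)
  ir <- hidden + iz
  ic <- 2L * hidden + iz
  h <- matrix(0, n, hidden)
  hs <- vector("list", T_)
  cache <- if (keep_cache) vector("list", T_) else NULL
  for (t in seq_len(T_)) {
    rows <- ((t - 1L) * n + 1L):(t * n)
    HU <- h %*% Uzr
    z <- sigmoid(P_all[rows, iz, drop = FALSE] + HU[, iz, drop = FALSE])
    r <- sigmoid(P_all[rows, ir, drop = FALSE] + HU[, ir, drop = FALSE])
    rh <- r * h
    hc <- tanh(P_all[rows, ic, drop = FALSE] + rh %*% p$Uh)
    h_new <- (1 - z) * h + z * hc
    if (keep_cache) cache[[t]] <- list(h_prev = h, z = z, r = r, rh = rh, hc = hc)
    h <- h_new
    hs[[t]] <- h
  }
  if (keep_cache) attr(cache, "X_all") <- X_all
  list(hs = hs, cache = cache)
}

# BPTT for one direction. dhs: list of T (n x hidden) gradients w.r.t. the
# emitted hidden states. The recurrence accumulates the per-step gate
# deltas; all weight gradients and input gradients are then single stacked
# matrix products.
gru_seq_backward <- function(dhs, cache, p) {
  T_ <- length(cache)
  n <- nrow(dhs[[1L]])
  hidden <- nrow(p$Uz)
  Uzr_t <- t(cbind(p$Uz, p$Ur))
  Uh_t <- t(p$Uh)
  D_all <- matrix(0, T_ * n, 3L * hidden)
  iz <- seq_len(hidden)
  ir <- hidden + iz
  ic <- 2L * hidden + iz
  dh_run <- 0
  for (t in rev(seq_len(T_))) {
    cc <- cache[[t]]
    dh <- dhs[[t]] + dh_run
    dz <- dh * (cc$hc - cc$h_prev)
    dhc <- dh * cc$z
    dh_prev <- dh * (1 - cc$z)
    dac <- dhc * (1 - cc$hc^2)
    dRH <- dac %*% Uh_t
    dr <- dRH * cc$h_prev
    dh_prev <- dh_prev + dRH * cc$r
    daz <- dz * cc$z * (1 - cc$z)
    dar <- dr * cc$r * (1 - cc$r)
    dh_prev <- dh_prev + cbind(daz, dar) %*% Uzr_t
    rows <- ((t - 1L) * n + 1L):(t * n)
    D_all[rows, ] <- cbind(daz, dar, dac)
    dh_run <- dh_prev
  }
  X_all <- attr(cache, "X_all")
  H_prev_all <- do.call(rbind, lapply(cache, `[[`, "h_prev"))
  RH_all <- do.call(rbind, lapply(cache, `[[`, "rh"))
  WG <- crossprod(X_all, D_all)
  UG <- crossprod(H_prev_all, D_all[, c(iz, ir), drop = FALSE])
  bg <- colSums(D_all)
  g <- list(
    Wz = WG[, iz, drop = FALSE], Uz = UG[, iz, drop = FALSE], bz = bg[iz],
    Wr = WG[, ir, drop = FALSE], Ur = UG[, hidden + iz, drop = FALSE], br = bg[ir],
    Wh = WG[, ic, drop = FALSE], Uh = crossprod(RH_all, D_all[, ic, drop = FALSE]),
    bh = bg[ic]
  )
  dX_all <- D_all %*% t(cbind(p$Wz, p$Wr, p$Wh))
  dxs <- lapply(seq_len(T_), function(t) {
    dX_all[((t - 1L) * n + 1L):(t * n), , drop = FALSE]
  })
  list(dxs = dxs, grads = g)
}

#' Bidirectional GRU layer over a sequence
#'
#' Runs one GRU left-to-right and an independent GRU right-to-left over the
#' input sequence and concatenates, at each position, the forward state with
#' the backward state. The output length equals the input length and its
#' width is twice the hidden size.
#'
#' @param inputs A `T x input_dim` matrix, one row per sequence position.
#' @param fwd,bwd Parameter lists for the two directions (see [gru_step()]).
#' @return A `T x (2*hidden)` matrix of concatenated hidden states.
#' @export
bigru_layer <- function(inputs, fwd, bwd) {
  if (is.null(dim(inputs)) || nrow(inputs) == 0L) {
    rlang::abort("bigru_layer: inputs must be a nonempty matrix of row vectors")
  }
  T_ <- nrow(inputs)
  xs <- lapply(seq_len(T_), function(t) inputs[t, , drop = FALSE])
  hf <- gru_seq_forward(xs, fwd)$hs
  hb <- gru_seq_forward(rev(xs), bwd)$hs
  out <- matrix(0, T_, ncol(hf[[1L]]) + ncol(hb[[1L]]))
  for (t in seq_len(T_)) {
    out[t, ] <- c(hf[[t]], hb[[T_ - t + 1L]])
  }
  out
}

new_attention_params <- function(dim) {
  s <- 1 / sqrt(dim)
  list(w = stats::runif(dim, -s, s), b = 0)
}

#' Attention pooling of a hidden-state sequence
#'
#' Computes a scalar relevance score for each position,
#' \eqn{e_t = \sigma_a(h_t)} with \eqn{\sigma_a(h) = \tanh(w \cdot h + b)},
#' converts the scores to weights with a softmax
#' \eqn{\alpha_t = \exp(e_t) / \sum_k \exp(e_k)}, and returns the context
#' vector \eqn{c = \sum_t \alpha_t h_t}, the attention-weighted mean of the
#' state sequence. The softmax subtracts the maximum score before
#' exponentiating for numerical stability.
#'
#' @param states A `T x dim` matrix of hidden states, one row per position.
#' @param a Attention parameters: list with weight vector `w` and scalar `b`.
#' @return A list with `context` (length-`dim` vector) and `weights`
#'   (length-`T`, nonnegative, summing to 1).
#' @export
attention_pool <- function(states, a) {
  if (is.null(dim(states)) || nrow(states) == 0L) {
    rlang::abort("attention_pool: states must be a nonempty matrix")
  }
  e <- tanh(drop(states %*% a$w) + a$b)
  w <- exp(e - max(e))
  alpha <- w / sum(w)
  list(context = drop(crossprod(states, alpha)), weights = alpha)
}

# ---- full network ----------------------------------------------------------

#' Initialize the stacked BiGRU-attention network
#'
#' Creates the full parameter set of the classifier: three stacked
#' bidirectional GRU layers, a feed-forward attention head, and an affine
#' output unit with logistic sigmoid producing a score in (0, 1).
#'
#' @param input_dim Width of each one-hot input row (21).
#' @param hidden Hidden units per direction per layer.
#' @param layers Number of stacked bidirectional layers.
#' @param seed Integer seed for the parameter initialization.
#' @return An object of class `hla_network`.
#' @export
new_network <- function(input_dim = 21L, hidden = 64L, layers = 3L, seed = 1L) {
  withr::local_seed(seed)
  lays <- vector("list", layers)
  d_in <- input_dim
  for (l in seq_len(layers)) {
    lays[[l]] <- list(fwd = new_gru_layer_params(d_in, hidden),
                      bwd = new_gru_layer_params(d_in, hidden))
    d_in <- 2L * hidden
  }
  out_dim <- 2L * hidden
  structure(
    list(
      layers = lays,
      attn = new_attention_params(out_dim),
      out = list(w = stats::runif(out_dim, -1, 1) / sqrt(out_dim), b = 0),
      dims = list(input_dim = input_dim, hidden = hidden, layers = layers)
    ),
    class = "hla_network"
  )
}

# Batched forward pass. x: [n, T, input_dim] array. Returns predicted
# probabilities; with keep_cache = TRUE also every intermediate needed for
# backprop. Dropout (inverted scaling) is applied to each BiGRU layer's
# output only when training = TRUE.
network_forward <- function(x, net, dropout = 0, training = FALSE,
                            keep_cache = FALSE) {
  n <- dim(x)[1L]
  T_ <- dim(x)[2L]
  xs <- lapply(seq_len(T_), function(t) matrix(x[, t, ], nrow = n))
  layer_caches <- if (keep_cache) vector("list", length(net$layers)) else NULL
  for (l in seq_along(net$layers)) {
    lay <- net$layers[[l]]
    f <- gru_seq_forward(xs, lay$fwd, keep_cache = keep_cache)
    b <- gru_seq_forward(rev(xs), lay$bwd, keep_cache = keep_cache)
    hb_aligned <- rev(b$hs)
    out <- vector("list", T_)
    masks <- NULL
    use_drop <- training && dropout > 0
    if (use_drop) masks <- vector("list", T_)
    for (t in seq_len(T_)) {
      o <- cbind(f$hs[[t]], hb_aligned[[t]])
      if (use_drop) {
        m <- matrix(stats::rbinom(length(o), 1L, 1 - dropout), nrow(o)) / (1 - dropout)
        masks[[t]] <- m
        o <- o * m
      }
      out[[t]] <- o
    }
    if (keep_cache) {
      layer_caches[[l]] <- list(fwd = f$cache, bwd = b$cache, masks = masks)
    }
    xs <- out
  }
  hidden_w <- ncol(xs[[1L]])
  # attention over the top layer's states, batched across samples
  E <- matrix(0, n, T_)
  for (t in seq_len(T_)) E[, t] <- tanh(drop(xs[[t]] %*% net$attn$w) + net$attn$b)
  Em <- E - apply(E, 1L, max)
  W <- exp(Em)
  A <- W / rowSums(W)
  C <- matrix(0, n, hidden_w)
  for (t in seq_len(T_)) C <- C + A[, t] * xs[[t]]
  logits <- drop(C %*% net$out$w) + net$out$b
  p <- sigmoid(logits)
  if (!keep_cache) return(list(p = p))
  list(p = p, cache = list(xs_top = xs, E = E, A = A, C = C,
                           layer_caches = layer_caches, n = n, T_ = T_))
}

# Backward pass from dlogits (gradient of loss w.r.t. the pre-sigmoid
# output, length n). Returns gradients in the same nested shape as net.
network_backward <- function(dlogits, fwd_out, net, dropout = 0,
                             training = FALSE) {
  cache <- fwd_out$cache
  n <- cache$n
  T_ <- cache$T_
  xs <- cache$xs_top
  A <- cache$A
  E <- cache$E
  g <- list(layers = vector("list", length(net$layers)),
            attn = list(w = net$attn$w * 0, b = 0),
            out = list(w = net$out$w * 0, b = 0))
  # output unit
  dC <- outer(dlogits, net$out$w)
  g$out$w <- drop(crossprod(cache$C, dlogits))
  g$out$b <- sum(dlogits)
  # attention: dA and dH from the context sum, then softmax and tanh score
  dA <- matrix(0, n, T_)
  dH <- vector("list", T_)
  for (t in seq_len(T_)) {
    dA[, t] <- rowSums(dC * xs[[t]])
    dH[[t]] <- A[, t] * dC
  }
  dE <- A * (dA - rowSums(A * dA))
  dS <- dE * (1 - E^2)
  for (t in seq_len(T_)) {
    g$attn$w <- g$attn$w + drop(crossprod(xs[[t]], dS[, t]))
    dH[[t]] <- dH[[t]] + outer(dS[, t], net$attn$w)
  }
  g$attn$b <- sum(dS)
  # stacked BiGRU layers, top down
  for (l in rev(seq_along(net$layers))) {
    lay <- net$layers[[l]]
    lc <- cache$layer_caches[[l]]
    hidden <- ncol(lc$fwd[[1L]]$z)
    if (!is.null(lc$masks)) {
      for (t in seq_len(T_)) dH[[t]] <- dH[[t]] * lc$masks[[t]]
    }
    dhf <- lapply(dH, function(m) m[, seq_len(hidden), drop = FALSE])
    dhb <- lapply(dH, function(m) m[, hidden + seq_len(hidden), drop = FALSE])
    bf <- gru_seq_backward(dhf, lc$fwd, lay$fwd)
    bb <- gru_seq_backward(rev(dhb), lc$bwd, lay$bwd)
    dxb <- rev(bb$dxs)
    dH <- lapply(seq_len(T_), function(t) bf$dxs[[t]] + dxb[[t]])
    g$layers[[l]] <- list(fwd = bf$grads, bwd = bb$grads)
  }
  g
}

#' Score an encoded pair with a network
#'
#' Deterministic inference: three stacked bidirectional GRU passes,
#' attention pooling, and an affine map through the logistic sigmoid.
#' Dropout is disabled.
#'
#' @param e A 49 x 21 one-hot matrix from [encode_pair()], or an
#'   `[n, 49, 21]` array of them.
#' @param net An `hla_network`.
#' @return A numeric score (or vector of scores) strictly in (0, 1).
#' @export
network_score <- function(e, net) {
  if (length(dim(e)) == 2L) {
    x <- array(e, dim = c(1L, dim(e)))
    return(network_forward(x, net)$p[1L])
  }
  network_forward(e, net)$p
}

# ---- optimizer -------------------------------------------------------------

# Apply f elementwise over two parameter trees of identical shape.
tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    out
  } else {
    f(a, b)
  }
}

tree_map <- function(f, a) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map(f, a[[i]])
    out
  } else {
    f(a)
  }
}

adam_init <- function(params) {
  list(m = tree_map(function(a) a * 0, params),
       v = tree_map(function(a) a * 0, params),
       t = 0L)
}

adam_update <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  mh <- tree_map(function(m) m / bc1, state$m)
  vh <- tree_map(function(v) v / bc2, state$v)
  step <- tree_map2(function(m, v) lr * m / (sqrt(v) + eps), mh, vh)
  params <- tree_map2(`-`, params, step)
  list(params = params, state = state)
}

bce_loss <- function(p, y, eps = 1e-12) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}
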