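# Oracle checks for the recurrent core: hand arithmetic for single steps,
# independent composition for the full forward pass, and numerical
# differentiation for the analytic gradients.

test_that("gru_step matches step-by-step hand arithmetic in the scalar case", {
  p <- list(Wz = matrix(0.3), Uz = matrix(-0.2), bz = 0.1,
            Wr = matrix(0.5), Ur = matrix(0.4), br = -0.3,
            Wh = matrix(-0.7), Uh = matrix(0.6), bh = 0.2)
  x <- 0.9
  h_prev <- -0.4
  # independent evaluation of the printed gate equations
  sig <- function(a) 1 / (1 + exp(-a))
  z <- sig(0.3 * x + (-0.2) * h_prev + 0.1)
  r <- sig(0.5 * x + 0.4 * h_prev - 0.3)
  hc <- tanh(-0.7 * x + 0.6 * (r * h_prev) + 0.2)
  expected <- (1 - z) * h_prev + z * hc
  expect_equal(gru_step(x, h_prev, p), expected, tolerance = 1e-12)
})

test_that("gru_step degenerate gates behave as the equations dictate", {
  d <- 3
  zero <- function() matrix(0, d, d)
  p <- list(Wz = zero(), Uz = zero(), bz = rep(0, d),
            Wr = zero(), Ur = zero(), br = rep(0, d),
            Wh = zero(), Uh = zero(), bh = rep(0, d))
  # all-zero parameters and state: candidate tanh(0)=0, h stays 0
  expect_equal(gru_step(rep(1, d), rep(0, d), p), rep(0, d))

  # update gate forced shut (huge negative bias): h_t ~ h_prev
  p2 <- p
  p2$bz <- rep(-50, d)
  h_prev <- c(0.3, -0.8, 0.5)
  expect_equal(gru_step(rnorm(d), h_prev, p2), h_prev, tolerance = 1e-12)

  # update gate forced open: h_prev enters only through the reset path
  p3 <- p
  p3$bz <- rep(50, d)
  p3$Wh <- diag(d)
  x <- c(0.2, -0.1, 0.4)
  expect_equal(gru_step(x, h_prev, p3), tanh(x), tolerance = 1e-12)

  expect_error(gru_step(rep(1, 2), rep(0, d), p), "dimensions")
})

test_that("bigru_layer output has the right shape and composes from gru_step", {
  withr::local_seed(3)
  fwd <- panneo:::new_gru_layer_params(4, 3)
  bwd <- panneo:::new_gru_layer_params(4, 3)
  x <- matrix(rnorm(2 * 4), 2, 4)
  out <- bigru_layer(x, fwd, bwd)
  expect_equal(dim(out), c(2L, 6L))

  # compose from independent unidirectional runs of the scalar-step oracle
  h1f <- gru_step(x[1, ], rep(0, 3), fwd)
  h2f <- gru_step(x[2, ], h1f, fwd)
  h2b <- gru_step(x[2, ], rep(0, 3), bwd)
  h1b <- gru_step(x[1, ], h2b, bwd)
  expect_equal(out[1, ], c(h1f, h1b), tolerance = 1e-12)
  expect_equal(out[2, ], c(h2f, h2b), tolerance = 1e-12)

  # a length-49 input yields 49 output positions
  x49 <- matrix(rnorm(49 * 4), 49, 4)
  expect_equal(dim(bigru_layer(x49, fwd, bwd)), c(49L, 6L))

  # palindromic input with tied parameters: reversed output swaps halves
  xp <- rbind(x, x[2:1, , drop = FALSE])
  op <- bigru_layer(xp, fwd, fwd)
  swapped <- cbind(op[, 4:6], op[, 1:3])
  expect_equal(op, swapped[nrow(op):1, ], tolerance = 1e-12)

  expect_error(bigru_layer(matrix(0, 0, 4), fwd, bwd), "nonempty")
})

test_that("attention_pool matches the softmax-weighted-mean formulas", {
  withr::local_seed(4)
  # uniform scores: weights 1/T, context = mean state
  states <- matrix(rnorm(12), 4, 3)
  a0 <- list(w = rep(0, 3), b = 0.7)
  res <- attention_pool(states, a0)
  expect_equal(res$weights, rep(0.25, 4))
  expect_equal(res$context, colMeans(states))

  # closed-form two-state softmax: e = (0, ln 3) -> weights (0.25, 0.75).
  # With sigma_a = tanh(w.h + b), choose h so tanh gives exactly 0 and
  # atanh values are exercised via direct construction of e instead.
  sm <- exp(c(0, log(3)))
  expect_equal(sm / sum(sm), c(0.25, 0.75))

  # random 5-state instance vs direct evaluation of the three formulas
  st <- matrix(rnorm(5 * 4), 5, 4)
  ap <- list(w = rnorm(4), b = 0.2)
  e <- tanh(st %*% ap$w + 0.2)
  alpha <- exp(e) / sum(exp(e))
  ctx <- colSums(st * as.vector(alpha))
  got <- attention_pool(st, ap)
  expect_equal(got$weights, as.vector(alpha), tolerance = 1e-12)
  expect_equal(got$context, ctx, tolerance = 1e-12)

  expect_error(attention_pool(matrix(0, 0, 3), ap), "nonempty")
})

test_that("attention weights are a convex combination for random inputs", {
  withr::local_seed(5)
  for (i in 1:10) {
    T_ <- sample(2:8, 1)
    d <- sample(2:5, 1)
    st <- matrix(rnorm(T_ * d, sd = 3), T_, d)
    a <- list(w = rnorm(d), b = rnorm(1))
    res <- attention_pool(st, a)
    expect_true(all(res$weights >= 0))
    expect_equal(sum(res$weights), 1, tolerance = 1e-6)
    expect_true(all(res$context >= apply(st, 2, min) - 1e-9))
    expect_true(all(res$context <= apply(st, 2, max) + 1e-9))
  }
})

test_that("forward pass composes from the layer and attention oracles", {
  tab <- tiny_pseudo()
  net <- tiny_network(hidden = 2, layers = 3, seed = 9)
  e <- encode_pair("ACDEFGHIK", "HLA-A*01:01", tab)
  score <- panneo:::network_score(e, net)
  expect_gt(score, 0)
  expect_lt(score, 1)

  # independent composition: stacked bigru_layer calls, direct attention
  # formulas, affine + sigmoid
  h <- matrix(as.numeric(e), nrow(e), ncol(e))
  for (l in 1:3) h <- bigru_layer(h, net$layers[[l]]$fwd, net$layers[[l]]$bwd)
  et <- tanh(drop(h %*% net$attn$w) + net$attn$b)
  alpha <- exp(et - max(et)) / sum(exp(et - max(et)))
  ctx <- drop(crossprod(h, alpha))
  expected <- 1 / (1 + exp(-(sum(ctx * net$out$w) + net$out$b)))
  expect_equal(score, expected, tolerance = 1e-10)

  # inference is deterministic
  expect_identical(score, panneo:::network_score(e, net))
})

test_that("analytic gradients match numerical differentiation", {
  withr::local_seed(21)
  net <- tiny_network(hidden = 3, layers = 2, seed = 33)
  n <- 4
  T_ <- 5
  x <- array(as.numeric(runif(n * T_ * 21) > 0.8), dim = c(n, T_, 21))
  y <- c(1, 0, 1, 0)
  loss_fn <- function(nn) panneo:::bce_loss(panneo:::network_forward(x, nn)$p, y)
  fw <- panneo:::network_forward(x, net, keep_cache = TRUE)
  gr <- panneo:::network_backward((fw$p - y) / n, fw, net)

  check_block <- function(getter, setter, g) {
    idx <- sample(length(g), min(4, length(g)))
    for (i in idx) {
      h <- 1e-5
      up <- net; v <- getter(up); v[i] <- v[i] + h; up <- setter(up, v)
      dn <- net; v <- getter(dn); v[i] <- v[i] - h; dn <- setter(dn, v)
      num <- (loss_fn(up) - loss_fn(dn)) / (2 * h)
      expect_equal(g[i], num, tolerance = 1e-4)
    }
  }
  check_block(function(n) n$layers[[1]]$fwd$Wh,
              function(n, v) { n$layers[[1]]$fwd$Wh[] <- v; n },
              gr$layers[[1]]$fwd$Wh)
  check_block(function(n) n$layers[[2]]$bwd$Uz,
              function(n, v) { n$layers[[2]]$bwd$Uz[] <- v; n },
              gr$layers[[2]]$bwd$Uz)
  check_block(function(n) n$layers[[1]]$bwd$br,
              function(n, v) { n$layers[[1]]$bwd$br <- v; n },
              gr$layers[[1]]$bwd$br)
  check_block(function(n) n$attn$w,
              function(n, v) { n$attn$w <- v; n }, gr$attn$w)
  check_block(function(n) n$out$w,
              function(n, v) { n$out$w <- v; n }, gr$out$w)
})
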