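zero_gru <- function(H, X) {
  list(w_xr = matrix(0, H, X), w_hr = matrix(0, H, H),
       w_xz = matrix(0, H, X), w_hz = matrix(0, H, H),
       w_xh = matrix(0, H, X), w_hh = matrix(0, H, H),
       b_r = rep(0, H), b_z = rep(0, H), b_h = rep(0, H))
}

test_that("GRU cell step has the correct fixed points and limits", {
  H <- 4; X <- 2
  p <- zero_gru(H, X)
  h_prev <- c(0.3, -0.5, 0.9, 0)
  # z = 0.5 and candidate 0: h = 0.5 h_prev
  expect_equal(gru_cell_step(rnorm(X), h_prev, p), 0.5 * h_prev)
  # saturated update gate: pure memory
  p$b_z <- rep(50, H)
  expect_equal(gru_cell_step(rnorm(X), h_prev, p), h_prev, tolerance = 1e-12)
})

test_that("GRU cell step matches the scalar loop oracle on random cells", {
  withr::with_seed(41, {
    for (i in 1:1000) {
      H <- sample(1:8, 1); X <- sample(1:4, 1)
      p <- gru_cell_params(X, H)
      x <- rnorm(X); h <- runif(H, -1, 1)
      expect_equal(gru_cell_step(x, h, p), oracle_gru_step(x, h, p),
                   tolerance = 1e-10)
    }
  })
})

test_that("GRU hidden state stays in [-1, 1] when initialized there", {
  withr::with_seed(42, {
    for (i in 1:50) {
      H <- sample(2:6, 1)
      p <- gru_cell_params(3, H)
      h <- runif(H, -1, 1)
      for (t in 1:20) {
        h <- gru_cell_step(rnorm(3, sd = 2), h, p)
        expect_true(all(h >= -1 & h <= 1))
      }
    }
  })
})

test_that("attention weights form a distribution and respect score structure", {
  withr::with_seed(43, {
    p <- attention_params(3, 3)
  })
  # all hidden states identical: uniform weights, context = projected value
  H_same <- matrix(rep(c(0.2, -0.4, 0.7), each = 5), 5, 3)
  out <- attention(H_same, p)
  expect_equal(out$weights, rep(0.2, 5), tolerance = 1e-12)
  expect_equal(out$context, drop(p$W_V %*% c(0.2, -0.4, 0.7)),
               tolerance = 1e-12)

  # a dominating key saturates the softmax to one-hot
  p_id <- list(W_Q = diag(2), W_K = diag(2), W_V = diag(2))
  H_dom <- rbind(c(1, 0), c(0, 1), c(30, 0))
  out2 <- attention(H_dom, p_id)
  expect_equal(out2$weights[3], 1, tolerance = 1e-6)
  expect_equal(out2$context, c(30, 0), tolerance = 1e-4)

  expect_error(attention(numeric(0), p))
})

test_that("attention matches the explicit-summation oracle and softmax shift invariance holds", {
  withr::with_seed(44, {
    for (i in 1:1000) {
      T_steps <- sample(2:6, 1); H <- sample(2:5, 1); d <- sample(2:5, 1)
      p <- attention_params(H, d)
      Hmat <- matrix(rnorm(T_steps * H), T_steps, H)
      got <- attention(Hmat, p)
      want <- oracle_attention(Hmat, p)
      expect_equal(got$weights, want$weights, tolerance = 1e-10)
      expect_equal(got$context, want$context, tolerance = 1e-10)
      expect_true(all(got$weights >= 0))
      expect_equal(sum(got$weights), 1, tolerance = 1e-9)
    }
    # softmax shift invariance on the internal row-softmax
    s <- matrix(rnorm(8), 2, 4)
    expect_equal(ripecast:::softmax_rows(s), ripecast:::softmax_rows(s + 3.7),
                 tolerance = 1e-12)
  })
})

test_that("gruat_forward composes GRU, attention and the heads", {
  cfg <- maturity_config(hidden = 4, att_dim = 3, fc = 3, T_steps = 5,
                         x_dim = 6, seed = 9)
  m <- build_maturity_model(cfg)
  w <- withr::with_seed(10, matrix(rnorm(5 * 6, sd = 0.3), 5, 6))

  # oracle composition: scalar GRU steps -> attention -> ReLU FC -> linear
  p <- m$params
  gru_p <- list(w_xr = p$w_xr, w_hr = p$w_hr, w_xz = p$w_xz, w_hz = p$w_hz,
                w_xh = p$w_xh, w_hh = p$w_hh, b_r = p$b_r, b_z = p$b_z,
                b_h = p$b_h)
  h <- rep(0, 4)
  H_all <- matrix(0, 5, 4)
  for (t in 1:5) {
    h <- oracle_gru_step(w[t, ], h, gru_p)
    H_all[t, ] <- h
  }
  att <- oracle_attention(H_all, list(W_Q = p$W_Q, W_K = p$W_K, W_V = p$W_V))
  fc <- pmax(drop(p$fc_W %*% att$context) + p$fc_b, 0)
  raw <- drop(p$out_W %*% fc) + p$out_b
  expected <- pmin(pmax(raw, 0), 1)
  expected <- if (sum(expected) > 0) expected / sum(expected) else rep(1 / 3, 3)

  got <- gruat_forward(m, w)
  expect_equal(unlist(got, use.names = FALSE), expected, tolerance = 1e-9)
  # deterministic
  expect_identical(gruat_forward(m, w), gruat_forward(m, w))
})

test_that("a zero-weight network outputs its simplex-projected output bias", {
  cfg <- maturity_config(hidden = 3, att_dim = 2, fc = 2, T_steps = 4,
                         x_dim = 6, seed = 1)
  m <- build_maturity_model(cfg)
  m$params <- lapply(m$params, function(p) p * 0)
  m$params$out_b <- c(0.6, 0.3, 0.3)
  got <- gruat_forward(m, matrix(rnorm(24), 4, 6))
  expect_equal(unlist(got, use.names = FALSE), c(0.5, 0.25, 0.25),
               tolerance = 1e-12)
})

test_that("predictions lie on the 3-simplex for arbitrary windows", {
  cfg <- maturity_config(hidden = 6, att_dim = 4, fc = 4, T_steps = 6,
                         x_dim = 6, seed = 12)
  m <- build_maturity_model(cfg)
  withr::with_seed(13, {
    w <- array(rnorm(20 * 6 * 6, sd = 2), c(20, 6, 6))
  })
  pred <- predict_maturity(m, w)
  expect_true(all(as.matrix(pred) >= 0))
  expect_equal(rowSums(as.matrix(pred)), rep(1, 20), tolerance = 1e-9)
})

test_that("ripeness training is seeded and a zero-epoch call is the identity", {
  withr::with_seed(14, {
    w <- array(runif(40 * 6 * 6), c(40, 6, 6))
    y <- matrix(runif(40 * 3), 40, 3)
    y <- y / rowSums(y)
  })
  data <- list(windows = w, targets = y)
  cfg <- maturity_config(hidden = 5, att_dim = 3, fc = 3, T_steps = 6,
                         x_dim = 6, epochs = 4, seed = 15)
  m0 <- build_maturity_model(cfg)
  expect_identical(train_maturity(m0, data, epochs = 0)$params, m0$params)
  m1 <- train_maturity(build_maturity_model(cfg), data)
  m2 <- train_maturity(build_maturity_model(cfg), data)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
  expect_equal(nrow(m1$history), 4L)
})
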