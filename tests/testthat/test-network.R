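test_that("the LSTM cell reproduces hand evaluations of the gate formulas", {
  d <- 1; d_h <- 1
  p <- akinet_params(d, d_h, d_a = 1, seed = 1)
  for (nm in names(p)) p[[nm]][] <- 0

  # all-zero parameters and state: the origin is a fixed point
  st <- lstm_step(0.7, NULL, p)
  expect_equal(st$h, 0)
  expect_equal(st$c, 0)

  # large candidate bias: c' = sigmoid(0) * tanh(b_c) ~ 0.5, h' = 0.5 tanh(c')
  p$b_c <- 20
  st2 <- lstm_step(0, NULL, p)
  expect_equal(st2$c, 0.5, tolerance = 1e-8)
  expect_equal(st2$h, 0.5 * tanh(0.5), tolerance = 1e-8)

  # gates are strictly inside (0, 1) for any finite input
  set.seed(2)
  p3 <- akinet_params(4, 6, 3, seed = 2)
  st3 <- lstm_step(rnorm(4, 0, 10), NULL, p3)
  expect_true(all(st3$i > 0 & st3$i < 1))
  expect_true(all(st3$f > 0 & st3$f < 1))
  expect_true(all(st3$o > 0 & st3$o < 1))
  expect_true(all(st3$g > -1 & st3$g < 1))
  expect_error(lstm_step(c(NA, 1, 2, 3), NULL, p3), "non-finite")
})

test_that("sequence encoding matches stepwise evaluation and is deterministic", {
  ri <- random_instance(5)
  H <- encode_sequence(ri$batch, ri$params)
  # T = 1 equals one cell update from zeros
  b1 <- ri$batch
  b1$inputs <- ri$batch$inputs[, 1, , drop = FALSE]
  b1$pad_mask <- ri$batch$pad_mask[, 1, drop = FALSE]
  H1 <- encode_sequence(b1, ri$params)
  st <- lstm_step(ri$batch$inputs[1, 1, ], NULL, ri$params)
  expect_equal(H1[1, 1, ], st$h, tolerance = 1e-12)
  # identical rows in, identical rows out
  b2 <- ri$batch
  b2$inputs[2, , ] <- b2$inputs[1, , ]
  b2$pad_mask[2, ] <- b2$pad_mask[1, ]
  H2 <- encode_sequence(b2, ri$params)
  expect_identical(H2[1, , ], H2[2, , ])
})

test_that("a masked prefix never changes real-step outputs", {
  ri <- random_instance(6, B = 2, T_len = 6)
  H <- encode_sequence(ri$batch, ri$params)
  pre <- 3
  bp <- ri$batch
  bp$inputs <- array(0, dim(ri$batch$inputs) + c(0, pre, 0))
  bp$inputs[, (pre + 1):(pre + 6), ] <- ri$batch$inputs
  bp$inputs[, 1:pre, ] <- rnorm(2 * pre * 3)   # garbage under the mask
  bp$pad_mask <- cbind(matrix(FALSE, 2, pre), ri$batch$pad_mask)
  Hp <- encode_sequence(bp, ri$params)
  expect_equal(Hp[, (pre + 1):(pre + 6), ], H, tolerance = 1e-12)
})

test_that("risk heads apply the logistic map to hand-set weights", {
  p <- akinet_params(2, 3, 2, seed = 3)
  expect_equal(step_risk(c(1, 2, 3), p), 0.5)      # zero-initialised head
  p$w_out <- c(1, 0, 0)
  expect_equal(step_risk(c(log(3), 5, -2), p), 0.75)
  p$b_out <- 1e3
  expect_gt(step_risk(c(0, 0, 0), p), 1 - 1e-10)
  p$w_pool <- c(1, 0, 0)
  expect_equal(pooled_risk(c(log(3), 0, 0), p), 0.75)
})

test_that("attention weights form a simplex and match hand softmax", {
  p <- akinet_params(2, d_h = 3, d_a = 2, seed = 4)
  H1 <- matrix(rnorm(3), 1, 3)
  expect_equal(attention_weights(H1, p), 1)

  Hsame <- matrix(rep(rnorm(3), 4), 4, 3, byrow = TRUE)
  expect_equal(attention_weights(Hsame, p), rep(0.25, 4))

  # scores (ln 2, 0, 0) -> (0.5, 0.25, 0.25); engineer via a linear probe
  p2 <- p
  p2$W_h <- matrix(c(1e-8, 0, 0, 0, 0, 0), 2, 3)  # tanh ~ identity at small x
  p2$b_h <- c(0, 0)
  p2$v <- c(1e8, 0)
  Hs <- matrix(0, 3, 3); Hs[1, 1] <- log(2)
  expect_equal(attention_weights(Hs, p2), c(0.5, 0.25, 0.25), tolerance = 1e-6)

  # normalisation to 1e-10 on random inputs, with and without padding
  set.seed(9)
  for (k in 1:5) {
    H <- matrix(rnorm(18), 6, 3)
    mask <- c(TRUE, TRUE, TRUE, TRUE, k > 2, k > 4)
    a <- attention_weights(H, p, mask = mask)
    expect_lt(abs(sum(a) - 1), 1e-10)
    expect_true(all(a >= 0))
    expect_true(all(a[!mask] == 0))
  }
  expect_error(attention_weights(matrix(rnorm(6), 2, 3), p,
                                 mask = c(FALSE, FALSE)), "undefined")
})

test_that("the context vector is the attention-weighted combination", {
  set.seed(10)
  H <- matrix(rnorm(6), 3, 2)
  expect_equal(context_vector(H, c(0, 1, 0)), H[2, ])
  expect_equal(context_vector(H[1:2, ], c(0.5, 0.5)), colMeans(H[1:2, ]))
  a <- runif(3); a <- a / sum(a)
  expect_equal(context_vector(H, a),
               a[1] * H[1, ] + a[2] * H[2, ] + a[3] * H[3, ])
})

test_that("attention entropy is maximal exactly at uniform weights", {
  T_len <- 6
  expect_equal(attention_entropy_term(rep(1 / T_len, T_len), 1, "concentration"),
               log(T_len))
  a <- c(0.5, rep(0.5 / 5, 5))
  expect_lt(attention_entropy_term(a, 1, "concentration"), log(T_len))
})

test_that("task heads are independent and match manual affine evaluation", {
  p <- akinet_params(2, d_h = 2, d_a = 2, seed = 11)
  expect_equal(unname(multitask_forward(c(1, -1), p)), rep(0.5, 3))
  p$A_task <- rbind(c(1, 0), c(0, 2), c(-1, 0))
  p$b_task <- c(0, 0.5, 0)
  s <- c(0.3, -0.7)
  manual <- plogis(c(0.3, 0.5 + 2 * -0.7, -0.3))
  expect_equal(unname(multitask_forward(s, p)), manual)
  # perturbing head k only moves output k
  p2 <- p
  p2$A_task[2, ] <- p2$A_task[2, ] + 1
  out1 <- multitask_forward(s, p)
  out2 <- multitask_forward(s, p2)
  expect_equal(out2[c(1, 3)], out1[c(1, 3)])
  expect_false(out2[2] == out1[2])
})

test_that("checkpoints round-trip bit-exactly", {
  p <- akinet_params(5, 8, 4, p_static = 2, seed = 12)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(p, path, config = list(d_h = 8))
  back <- load_checkpoint(path)
  expect_identical(back$params, p)
  expect_true(nzchar(back$config_hash))
  unlink(path)
})
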