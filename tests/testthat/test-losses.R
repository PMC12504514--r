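test_that("sequence cross-entropy matches hand arithmetic and masking", {
  expect_equal(bce_sequence(rep(1, 4), rep(0.5, 4)), 4 * log(2))
  # near-perfect predictions cost at most T |log(1 - eps)|
  expect_lt(bce_sequence(c(1, 0, 1), c(1, 0, 1)), 3 * abs(log(1 - 1e-7)) + 1e-12)
  # matrix form averages per-patient sums
  y <- rbind(c(1, 0), c(0, 0))
  p <- rbind(c(0.8, 0.3), c(0.2, 0.4))
  manual <- mean(c(-log(0.8) - log(0.7), -log(0.8) - log(0.6)))
  expect_equal(bce_sequence(y, p), manual)
})

test_that("weighted cross-entropy reduces, scales, and matches hand sums", {
  set.seed(20)
  y <- rbinom(6, 1, 0.5)
  p <- runif(6, 0.1, 0.9)
  expect_equal(weighted_bce(y, p, rep(1, 6)),
               mean(-(y * log(p) + (1 - y) * log(1 - p))))
  w <- runif(6, 0.5, 3)
  expect_equal(weighted_bce(y, p, 2 * w), 2 * weighted_bce(y, p, w))
  # two instances with the inverse-frequency weights of a 3,812/27,963 cohort
  y2 <- c(1, 0); p2 <- c(0.7, 0.2); w2 <- c(3.668, 0.579)
  expect_equal(weighted_bce(y2, p2, w2),
               (-3.668 * log(0.7) - 0.579 * log(0.8)) / 2)
  expect_error(weighted_bce(y2, p2, c(1, -1)), "strictly positive")
})

test_that("inverse class frequency balances aggregate class contributions", {
  expect_equal(inverse_class_weights(c(50, 50)), c(1, 1))
  w <- inverse_class_weights(c(27963 - 3812, 3812))
  expect_equal(w[2], 27963 / 7624, tolerance = 1e-12)
  expect_equal(round(w[2], 4), 3.6678)
  expect_equal(round(w[1], 4), 0.5789)
  for (k in 1:5) {
    set.seed(k)
    counts <- sample(10:500, 2)
    expect_equal(sum(counts * inverse_class_weights(counts)), sum(counts))
  }
  expect_error(inverse_class_weights(c(10, 0)), "non-empty")
})

test_that("dynamic weights decrease with class accuracy through a sigmoid", {
  expect_equal(dynamic_weight_update(0.5, 2), 0.5)
  expect_equal(dynamic_weight_update(0.5, 17), 0.5)
  expect_equal(dynamic_weight_update(0.25, 2), plogis(0.5))
  expect_equal(round(dynamic_weight_update(0.25, 2), 4), 0.6225)
  expect_lt(dynamic_weight_update(1, 50), 1e-10)
  acc <- seq(0, 1, by = 0.1)
  expect_true(all(diff(dynamic_weight_update(acc, 3)) < 0))
})

test_that("focal loss reduces to cross-entropy and matches hand values", {
  set.seed(21)
  y <- rbinom(8, 1, 0.4); p <- runif(8, 0.1, 0.9)
  expect_equal(focal_loss(y, p, alpha = 1, gamma = 0),
               mean(-(y * log(p) + (1 - y) * log(1 - p))))
  expect_equal(focal_loss(1, 0.9, 1, 2), 0.01 * -log(0.9))
  expect_equal(round(focal_loss(1, 0.9, 1, 2), 7), round(1.0536052e-3, 7))
  expect_lt(focal_loss(1, 1 - 1e-9, 1, 2), 1e-12)
  # printed (positive-only) form ignores negatives entirely
  expect_equal(focal_loss(0, 0.99, 1, 2, symmetric = FALSE), 0)
  expect_gt(focal_loss(0, 0.99, 1, 2, symmetric = TRUE), 0)
  expect_error(focal_loss(y, p, 1, -1), "non-negative")
})

test_that("smoothness penalty sums squared consecutive real-step differences", {
  expect_equal(smoothness_penalty(rep(0.4, 9), gamma = 3), 0)
  expect_equal(smoothness_penalty(c(0, 1), gamma = 1), 1)
  expect_equal(smoothness_penalty(c(0.2, 0.5, 0.4), gamma = 2),
               2 * (0.09 + 0.01))
  # masked steps do not pair with real ones
  p <- c(0.2, 0.9, 0.3)
  expect_equal(smoothness_penalty(p, c(TRUE, FALSE, TRUE), 1), 0)
  expect_equal(smoothness_penalty(0.7, gamma = 5), 0)   # T = 1
})

test_that("entropy term hits its extremes and respects the sign convention", {
  expect_equal(attention_entropy_term(c(0, 1, 0), 2, "concentration"), 0)
  expect_equal(attention_entropy_term(rep(0.25, 4), 1, "concentration"), log(4))
  expect_equal(attention_entropy_term(rep(0.25, 4), 1, "diversity"), -log(4))
  expect_equal(attention_entropy_term(c(0.5, 0.25, 0.25), 1, "concentration"),
               1.5 * log(2))
  expect_equal(round(attention_entropy_term(c(0.5, 0.25, 0.25), 1,
                                            "concentration"), 4), 1.0397)
})

test_that("the composite total is the exact sum of its recorded terms", {
  p <- akinet_params(3, 4, 2, seed = 22)
  for (nm in names(p)) p[[nm]][] <- rnorm(length(p[[nm]]), 0, 0.3)
  cfg <- loss_config(l2_lambda = 0.07, task_lambdas = c(1, 0.5, 0.2))
  bd <- total_loss(1.23, cfg, params = p, smooth_term = 0.4,
                   entropy_term = -0.1, task_losses = c(1, 2, 3))
  expect_equal(bd$total,
               bd$data_term + bd$l2_term + bd$smooth_term + bd$entropy_term +
                 bd$multitask_term, tolerance = 1e-12)
  expect_equal(bd$l2_term, 0.07 * l2_penalty(p))
  expect_equal(bd$multitask_term, 1 + 0.5 * 2 + 0.2 * 3)
  # zero strengths collapse to the data term
  bd0 <- total_loss(1.23, loss_config(), params = p)
  expect_equal(bd0$total, 1.23)
  # zero parameters give a zero penalty
  p0 <- p; for (nm in names(p0)) p0[[nm]][] <- 0
  expect_equal(total_loss(1, loss_config(l2_lambda = 5), params = p0)$l2_term, 0)
})

test_that("L2 covers weight matrices but not biases or log-uncertainties", {
  p <- akinet_params(2, 3, 2, seed = 23)
  base <- l2_penalty(p)
  p$b_i <- p$b_i + 10
  p$log_sigma <- p$log_sigma + 10
  expect_equal(l2_penalty(p), base)
  p$W_i <- p$W_i + 1
  expect_gt(l2_penalty(p), base)
})

test_that("multi-task combination covers fixed and uncertainty modes", {
  L <- c(1, 2, 3)
  expect_equal(multitask_loss(L, loss_config(task_lambdas = c(1, 0, 0))), 1)
  expect_equal(multitask_loss(L, loss_config(use_uncertainty = TRUE),
                              log_sigma = c(0, 0, 0)), sum(L) / 2)
  val <- multitask_loss(L, loss_config(use_uncertainty = TRUE),
                        log_sigma = log(c(1, 2, 1)))
  expect_equal(val, 0.5 + 2 / 8 + log(2) + 1.5)
  expect_equal(round(val, 4), 2.9431)
})
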