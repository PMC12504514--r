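test_that("learning rate decays by the configured factor on schedule", {
  expect_equal(lr_schedule(0), 0.001)
  expect_equal(lr_schedule(9), 0.001)
  expect_equal(lr_schedule(10), 1e-4)
  expect_equal(lr_schedule(25), 1e-5)
  expect_equal(lr_schedule(7, lr0 = 0.5, decay_factor = 2, decay_every = 3),
               0.5 / 4)
})

test_that("splits are disjoint and match the fractions to within one patient", {
  for (n in c(57, 200)) {
    sp <- split_cohort(n, c(0.8, 0.1, 0.1), seed = 4)
    all_idx <- c(sp$train, sp$val, sp$test)
    expect_equal(sort(all_idx), seq_len(n))
    expect_lte(abs(length(sp$train) - 0.8 * n), 1)
    expect_lte(abs(length(sp$val) - 0.1 * n), 1)
  }
  expect_identical(split_cohort(100, seed = 7), split_cohort(100, seed = 7))
})

test_that("AUC by ranks equals brute-force pair enumeration", {
  expect_equal(auc_rank(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0)), 0.75)
  expect_equal(auc_rank(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc_rank(rep(0.3, 10), c(1, 1, 1, 0, 0, 0, 0, 1, 0, 0)), 0.5)
  expect_true(is.na(auc_rank(runif(5), rep(1, 5))))
  brute <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (a in pos) for (b in neg)
      tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(pos) * length(neg))
  }
  set.seed(40)
  for (k in 1:5) {
    y <- rbinom(200, 1, 0.3)
    s <- round(runif(200), 2)   # rounded scores force ties
    expect_equal(auc_rank(s, y), brute(s, y))
  }
})

test_that("the metrics report matches hand-counted confusion quantities", {
  m <- evaluate_predictions(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0))
  expect_equal(m$recall, 0.5)
  expect_equal(m$accuracy, 0.5)
  expect_equal(m$auc, 0.75)
  expect_equal(unname(m$confusion), c(1L, 1L, 1L, 1L))
  perfect <- evaluate_predictions(c(0.99, 0.98, 0.01), c(1, 1, 0))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$auc, 1)
  # F1 consistent with the precision/recall identity
  expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall))
})

test_that("training is deterministic given the seed and frozen at zero rate", {
  co <- simulate_cohort(sim_config(n_patients = 60, seed = 71))
  tr <- train_config(epochs = 2, d_h = 6, d_a = 3, batch_size = 16, seed = 5)
  f1 <- akinet(co, "sequence", train = tr)
  f2 <- akinet(co, "sequence", train = tr)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$logs, f2$logs)

  tr0 <- train_config(lr0 = 0, epochs = 2, d_h = 6, d_a = 3, seed = 5)
  f0 <- akinet(co, "sequence", train = tr0)
  init <- akinet_params(co$d, 6L, 3L,
                        p_static = ncol(akinet:::profile_matrix(co$profiles)),
                        seed = 5)
  expect_identical(f0$final_params, init)
})

test_that("one SGD step moves parameters by exactly minus lr times gradient", {
  ri <- random_instance(55)
  cfg <- loss_config(smooth_gamma = 0.2, l2_lambda = 0.01)
  res <- akinet_loss_grad(ri$params, ri$batch, cfg, "sequence")
  lr <- 0.05
  stepped <- akinet:::params_axpy(ri$params, res$grads, -lr)
  for (nm in names(ri$params))
    expect_equal(stepped[[nm]], ri$params[[nm]] - lr * res$grads[[nm]],
                 tolerance = 1e-14)
  # and the step decreases the smooth composite objective
  after <- akinet_loss_grad(stepped, ri$batch, cfg, "sequence")
  expect_lt(after$breakdown$total, res$breakdown$total)
})

test_that("predict returns consistent per-step, patient and task outputs", {
  co <- simulate_cohort(sim_config(n_patients = 50, seed = 73))
  fit <- akinet(co, "sequence", train = train_config(epochs = 2, d_h = 6,
                                                     d_a = 3, seed = 6))
  te <- cohort_subset(fit$cohort, fit$splits$test)
  steps <- predict(fit, te, type = "step")
  pat <- predict(fit, te, type = "patient")
  expect_equal(length(steps), te$n)
  # patient score is the final-step risk
  expect_equal(pat, vapply(steps, function(p) p[length(p)], 1.0))
  tk <- predict(fit, te, type = "tasks")
  expect_equal(dim(tk), c(te$n, 3L))
  expect_true(all(tk > 0 & tk < 1))
  r <- residuals(fit, te)
  truth <- vapply(te$profiles, function(p) p$outcome_aki, 1L)
  expect_equal(r, truth - pat)
})

test_that("dynamic evaluation limits: zero rate is static, infinite anchor pins", {
  co <- simulate_cohort(sim_config(n_patients = 60, seed = 75))
  fit <- akinet(co, "sequence", train = train_config(epochs = 2, d_h = 6,
                                                     d_a = 3, seed = 7))
  stream <- lapply(split(1:20, rep(1:4, each = 5)),
                   function(ix) cohort_subset(fit$cohort, ix))
  static <- dynamic_evaluate(fit, stream, eta = 0)
  expect_identical(static$params, fit$params)
  pinned <- dynamic_evaluate(fit, stream, eta = 0.01, elastic_lambda = Inf)
  expect_identical(pinned$params, fit$params)
  expect_equal(pinned$logloss, static$logloss)
  # one unanchored window step equals the hand gradient update
  one <- dynamic_evaluate(fit, stream[1], eta = 0.01, elastic_lambda = 0)
  batch <- akinet:::prepare_batch(fit, stream[[1]])
  g <- akinet_loss_grad(fit$params, batch, loss_config(), "sequence")$grads
  manual <- akinet:::params_axpy(fit$params, g, -0.01)
  expect_equal(one$params, manual, tolerance = 1e-12)
})

test_that("ablation rejects unknown switches and reproduces the baseline", {
  co <- simulate_window_task(80, T_len = 12, effect = 1.5,
                             windows = list(c(5, 9)), seed = 8)
  expect_error(ablate(co, switches = "no_lstm"), "unknown ablation switch")
  tr <- train_config(epochs = 2, d_h = 4, d_a = 2, seed = 9,
                     split = c(0.7, 0.15, 0.15))
  tab <- ablate(co, switches = "no_attention", mode = "pooled", train = tr,
                filter = FALSE)
  expect_equal(tab$config, c("baseline", "no_attention"))
  expect_true(all(is.finite(tab$auc)))
  # the no-attention fit predicts from the final hidden state
  fit0 <- akinet(co, "pooled", train = tr, filter = FALSE, attention = FALSE)
  te <- cohort_subset(fit0$cohort, fit0$splits$test)
  pb <- akinet:::prepare_batch(fit0, te)
  H <- encode_sequence(pb, fit0$params)
  hT <- t(vapply(seq_len(te$n), function(b) H[b, pb$lengths[b], ],
                 numeric(attr(fit0$params, "dims")$d_h)))
  expect_equal(predict(fit0, te, type = "patient"),
               drop(plogis(hT %*% fit0$params$w_pool + fit0$params$b_pool)),
               tolerance = 1e-12)
})
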