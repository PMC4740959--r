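test_that("state update has the documented fixed points and closed forms", {
  w <- build_topology(topology_spec("hybrid", N = 8, seed = 2))
  st <- esn_state(8)
  out <- esn_step(st, 0, w, alpha = 1)
  expect_identical(out$X, numeric(8))       # activation(0) = 0 fixed point
  # single hybrid neuron, only the input weight active: X = tanh(W_in u)
  m1 <- manual_hybrid_1(w_in = 1)
  out1 <- esn_step(esn_state(1), 0.1, m1, alpha = 1)
  expect_equal(out1$X, tanh(0.1), tolerance = 1e-12)
  expect_equal(out1$X, 0.0997, tolerance = 1e-3)
})

test_that("the ring rotates the state by one neuron per step", {
  spec <- topology_spec("one_way_ring", N = 4, seed = 1)
  w <- build_topology(spec)
  w$W_in[] <- 0
  w$W_ring[] <- 1
  st <- esn_state(4)
  st$X <- c(1, 2, 3, 4)
  out <- esn_step(st, 0, w, alpha = 1, activation = "identity")
  expect_equal(out$X, c(4, 1, 2, 3))
  out2 <- esn_step(out, 0, w, alpha = 1, activation = "identity")
  expect_equal(out2$X, c(3, 4, 1, 2))
})

test_that("harvest keeps T - washout columns and reaches fixed points", {
  w <- build_topology(topology_spec("hybrid", N = 6, seed = 3))
  sig <- matrix(rnorm(10), 1, 10)
  expect_identical(esn_harvest(sig, w)$T_kept, 10L)
  expect_identical(esn_harvest(sig, w, washout = 4)$T_kept, 6L)
  expect_error(esn_harvest(matrix(numeric(0), 1, 0), w), "matrix")
  expect_error(esn_harvest(sig, w, washout = 10), "washout")
  # small weights + constant input: successive states converge
  w$W_ring <- w$W_ring * 0.1
  w$W_up <- w$W_up * 0.1
  w$W_down <- w$W_down * 0.1
  const <- matrix(0.3, 1, 200)
  sm <- esn_harvest(const, w, alpha = 1)
  d_late <- sqrt(sum((sm$X_all[, 200] - sm$X_all[, 199])^2))
  d_early <- sqrt(sum((sm$X_all[, 2] - sm$X_all[, 1])^2))
  expect_lt(d_late, 1e-10)
  expect_lt(d_late, d_early)
})

test_that("normal-equation readout recovers exact and oracle solutions", {
  set.seed(10)
  X <- matrix(rnorm(25), 5, 5)
  W_true <- matrix(rnorm(10), 2, 5)
  tr <- train_readout(X, W_true %*% X, ridge = 0)
  expect_equal(tr$W_out, W_true, tolerance = 1e-9)
  expect_identical(train_readout(X, matrix(0, 2, 5), ridge = 0)$W_out,
                   matrix(0, 2, 5))
  # oracle equivalence on a well-conditioned rectangular system
  X2 <- matrix(rnorm(200), 5, 40)
  Y2 <- matrix(rnorm(80), 2, 40)
  expect_equal(train_readout(X2, Y2, ridge = 0)$W_out, ls_oracle(X2, Y2),
               tolerance = 1e-10)
  # singular system advises ridge
  Xs <- matrix(1, 3, 10)
  expect_error(train_readout(Xs, matrix(1, 1, 10), ridge = 0), "ridge")
  expect_silent(train_readout(Xs, matrix(1, 1, 10), ridge = 1e-6))
})

test_that("readout output is the plain linear map", {
  X <- matrix(rnorm(30), 3, 10)
  expect_equal(readout_output(diag(3), X), X)
  expect_equal(readout_output(matrix(1, 1, 3), X), t(colSums(X)),
               ignore_attr = TRUE)
  W_true <- matrix(rnorm(6), 2, 3)
  tr <- train_readout(X, W_true %*% X, ridge = 0)
  expect_equal(readout_output(tr, X), W_true %*% X, tolerance = 1e-8)
  expect_error(readout_output(matrix(1, 1, 4), X), "columns")
})

test_that("threshold classification counts time steps correctly", {
  ref <- c(0, 1, 1, 1)
  expect_equal(classify_threshold(ref, 0.5, ref)$accuracy, 1)
  expect_equal(classify_threshold(rep(0, 4), 0.5, rep(1, 4))$accuracy, 0)
  r <- classify_threshold(c(0.2, 0.7, 0.4, 0.9), 0.5, ref)
  expect_identical(r$labels, c(0L, 1L, 0L, 1L))
  expect_equal(r$accuracy, 0.75)
})

test_that("winner-take-all picks the largest mean output, ties low", {
  y <- matrix(0, 3, 6)
  y[cbind(c(3, 1, 2), c(1, 3, 5))] <- 1   # one-hot per 2-step segment
  y[cbind(c(3, 1, 2), c(2, 4, 6))] <- 1
  r <- classify_wta(y, c(2, 2, 2), reference = c(3L, 1L, 2L))
  expect_identical(r$labels, c(3L, 1L, 2L))
  expect_equal(r$accuracy, 1)
  ytie <- matrix(1, 2, 4)
  expect_identical(classify_wta(ytie, c(2, 2))$labels, c(1L, 1L))
  expect_error(classify_wta(y, c(2, 2, 0, 2)), "segment")
})

test_that("tanh reservoirs stay bounded for arbitrary bounded input", {
  for (kind in c("hybrid", "random")) {
    w <- build_topology(topology_spec(kind, N = 20, seed = 8,
                                      connectivity = 0.3))
    sig <- matrix(runif(300, -5, 5), 1, 300)
    sm <- esn_harvest(sig, w, alpha = 0.7)
    expect_true(all(abs(sm$X_all) <= 1))
  }
})

test_that("compiled harvest path equals the reference implementation", {
  for (kind in c("one_way_ring", "two_way_ring", "center", "hybrid",
                 "random")) {
    for (seed in 1:2) {
      w <- build_topology(topology_spec(kind, N = 9, K = 2, seed = seed,
                                        connectivity = 0.5))
      sig <- matrix(rnorm(2 * 40), 2, 40)
      ref <- esn_harvest(sig, w, alpha = 0.6, "tanh", washout = 5)
      fast <- hybridesn:::harvest_fast(sig, w, 0.6, "tanh", 5L,
                                       return_states = TRUE)
      expect_equal(fast$X_all, ref$X_all, tolerance = 1e-12)
      expect_equal(fast$XXt, tcrossprod(ref$X_all), tolerance = 1e-10)
      expect_equal(fast$state_sum, rowSums(ref$X_all), tolerance = 1e-10)
    }
  }
})

test_that("a hybrid reservoir separates the synthetic two-class stream", {
  ds <- gen_eeg_like(30, seed = 101)
  sp <- train_test_split(ds, 24, 6, seed = 201)
  fit <- esn(sp$train, N = 100, alpha = 0.2, seed = 301)
  p <- predict(fit, sp$test)
  expect_gte(p$accuracy, 0.95)
})

test_that("esn objects expose the standard modelling methods", {
  ds <- gen_eeg_like(6, duration_s = 2, fs = 173.61, seed = 5)
  fit <- esn(ds, N = 20, seed = 6)
  expect_s3_class(fit, "esn")
  expect_identical(dim(coef(fit)), c(1L, 20L))
  expect_identical(dim(residuals(fit)), c(1L, 12L))
  s <- summary(fit)
  expect_s3_class(s, "summary.esn")
  expect_true(s$train_segment_accuracy >= 0.5)
  expect_output(print(fit), "hybrid")
  expect_output(print(s), "training accuracy")
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_silent(plot(fit))
  p <- predict(fit, ds)
  expect_length(p$labels, 12L)
  expect_true(all(p$labels %in% c("0", "1")))
})
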