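test_that("subthreshold neuron transfer saturates below I_max", {
  p <- process_params()
  expect_identical(neuron_transfer(0, p), 0)
  expect_equal(neuron_transfer(1, p), p$I_max, tolerance = 1e-6)
  i1 <- 2 * p$n * p$V_T / p$R_in      # drives the tanh argument to 1
  expect_equal(neuron_transfer(i1, p), p$I_max * tanh(1), tolerance = 1e-12)
  expect_equal(neuron_transfer(i1, p), 0.7616e-9, tolerance = 1e-4)
  i_s <- seq(-5, 5, length.out = 101) * 1e-9
  expect_true(all(abs(neuron_transfer(i_s, p)) < p$I_max))
  expect_equal(neuron_transfer(-i_s, p), -neuron_transfer(i_s, p))
})

test_that("mismatch weights are lognormal with the analytic spread", {
  p <- process_params()
  expect_equal(round(mismatch_sigma(p), 2), 2.85)
  s <- sample_mismatch_synapses(10000, p, seed = 42)
  expect_true(all(s$w1 > 0) && all(s$w2 > 0))
  emp <- sd(log(s$w1))
  expect_lt(abs(emp - mismatch_sigma(p)) / mismatch_sigma(p), 0.05)
  # goodness of fit of |w| against lognormal(ln r1 - ln 2, sigma^2)
  ks <- stats::ks.test(log(s$w), "pnorm", mean = -log(2),
                       sd = mismatch_sigma(p))
  expect_gt(ks$p.value, 0.01)
  # very large devices have vanishing mismatch
  big <- process_params(W_nm = 45e3, L_nm = 45e3)
  sb <- sample_mismatch_synapses(500, big, seed = 1)
  expect_lt(sd(log(sb$w1)), 0.01)
  expect_equal(median(sb$w1), 1, tolerance = 0.01)
})

test_that("log-weight spread scales as the inverse square root of area", {
  base <- mismatch_sigma(process_params())
  # scaling W and L together by s multiplies the area by s^2, so the
  # log-weight spread shrinks by s; doubling both halves sigma
  for (s in c(2, 4, 8, 16)) {
    p <- process_params(W_nm = 45 * s, L_nm = 45 * s)
    expect_equal(mismatch_sigma(p), base / s, tolerance = 1e-12)
  }
  p2 <- process_params(W_nm = 90, L_nm = 90)
  expect_equal(mismatch_sigma(p2), base / 2, tolerance = 1e-12)
})

test_that("synapse output satisfies both printed forms", {
  p <- process_params()
  s <- data.frame(w1 = 1, w2 = 1, w = 0.5, b = 0.5, sign = 1)
  expect_equal(synapse_output(p$I_max / 2, p$I_max / 2, s, p), p$I_max / 2)
  # differential-plus-bias form agrees with the mirror-current form
  smp <- sample_mismatch_synapses(1000, p, seed = 7)
  ixm <- runif(1000) * p$I_max
  ixp <- p$I_max - ixm
  direct <- synapse_output(ixp, ixm, smp, p)
  recast <- (ixp - ixm) * smp$w1 / 2 + p$I_max * smp$b
  expect_equal(direct, recast, tolerance = 1e-12)
  expect_error(synapse_output(p$I_max, p$I_max, s, p), "complementary")
})

test_that("baseline synapse area follows the gcd expectation", {
  p <- process_params()
  Am <- p$A_match_nm2
  expect_equal(baseline_synapse_area(baseline_weight_spec(1), p), 2 * Am)
  # exhaustive oracle at w_res = 1/8
  spec8 <- baseline_weight_spec(1 / 8)
  k <- 1:8
  gcds <- sapply(k, function(ki) {
    a <- 8; b <- ki
    while (b != 0) { t <- b; b <- a %% b; a <- t }
    a
  })
  oracle <- 2 * Am * mean(k / gcds)
  expect_equal(baseline_synapse_area(spec8, p), oracle)
  for (d in c("uniform_pm1", "normal", "lognormal")) {
    a <- baseline_synapse_area(baseline_weight_spec(1 / 100, d), p)
    expect_gte(a, 2 * Am)
  }
  expect_error(baseline_weight_spec(0.3), "unit fraction")
})

test_that("area model reproduces the closed-form block areas", {
  p <- process_params()
  Am <- p$A_match_nm2
  expect_equal(Am, 20250)                       # 10x minimal 45 nm sizing
  spec <- topology_spec("hybrid", N = 30, K = 1, M = 1)
  ar <- area_report(spec, p)
  expect_equal(ar$area_nm2[ar$block == "neurons"], 31 * 5 * Am)
  expect_equal(ar$area_nm2[ar$block == "synapses"] /
                 sum(hybridesn:::synapse_count(spec)), 6 * Am)  # a = 1
  expect_equal(ar$area_nm2[ar$block == "output"], (30 * 1 + 9) * Am)
  # half-area mirrors shrink the synapse block
  ph <- process_params(a = 0.5)
  arh <- area_report(spec, ph)
  expect_equal(arh$area_nm2[arh$block == "synapses"] /
                 sum(hybridesn:::synapse_count(spec)), 4 * Am)
  # degenerate empty reservoir leaves only the opamp in the output block
  spec0 <- structure(list(kind = "one_way_ring", N = 0L, K = 1L, M = 1L,
                          connectivity = 0.5), class = "topology_spec")
  expect_equal(area_report(spec0, p)$area_nm2[3], 9 * Am)
})

test_that("power model reproduces the closed-form block powers", {
  p <- process_params()
  spec <- topology_spec("one_way_ring", N = 2, K = 1, M = 1)
  pw <- power_report(spec, p)
  expect_equal(pw$power_W[pw$block == "neurons"] / 2, 0.55e-9)  # per neuron
  n_syn <- sum(hybridesn:::synapse_count(spec))
  expect_equal(pw$power_W[pw$block == "synapses"] / n_syn, 2.475e-9)
  expect_equal(pw$power_W[pw$block == "output"],
               p$eta * 2 * 1 * p$I_max * p$V_DD + 2 * p$I_bias * p$V_DD)
  # per-sample mode uses the drawn gains
  smp <- sample_mismatch_synapses(n_syn, p, seed = 3)
  ps <- power_report(spec, p, samples = smp, mode = "per_sample")
  expect_equal(ps$power_W[ps$block == "synapses"],
               sum(p$V_DD * p$I_max * (2 * p$eta + p$eta * smp$w1 +
                                         smp$w2 + 2)))
  expect_error(power_report(spec, p, mode = "per_sample"), "samples")
  # power scales linearly with the drive currents
  tiny <- process_params(I_max = 1e-15, I_bias = 1e-13)
  expect_lt(power_report(spec, tiny)$power_W[4], 1e-12)
})

test_that("median-mode power is affine in N for rings, quadratic for random", {
  p <- process_params()
  Ns <- c(10L, 20L, 40L, 80L, 160L)
  for (kind in c("one_way_ring", "two_way_ring", "hybrid")) {
    tot <- sapply(Ns, function(N) power_report(
      topology_spec(kind, N = N), p)$power_W[4])
    fit <- lm(tot ~ Ns)
    expect_lt(max(abs(residuals(fit))), 1e-20)
  }
  tot_r <- sapply(Ns, function(N) power_report(
    topology_spec("random", N = N, connectivity = 0.5), p)$power_W[4])
  qfit <- lm(tot_r ~ Ns + I(Ns^2))
  expect_lt(max(abs(residuals(qfit))), 1e-20)
  expect_gt(coef(qfit)[["I(Ns^2)"]], 0)
  lfit <- lm(tot_r ~ Ns)
  expect_gt(max(abs(residuals(lfit))), 1e-12)   # not explained linearly
})

test_that("physical parameters must be positive", {
  expect_error(process_params(I_max = 0), "positive")
  expect_error(process_params(W_nm = -1), "positive")
  expect_error(process_params(a = 2), "<= 1")
})
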