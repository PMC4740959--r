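#' Subthreshold process and circuit parameters
#'
#' Device constants for the analog (subthreshold mixed-signal) realization.
#' Defaults follow a 45 nm low-power predictive technology model: maximum
#' differential-pair current `I_max` = 1 nA, thermal voltage `V_T` = 26 mV,
#' subthreshold slope factor `n` = 1.2, Pelgrom threshold-mismatch
#' coefficient `A_Vth` = 4 mV.um, minimal device dimensions W = L = 45 nm,
#' matched-device area `A_match` = 10 x minimal sizing = 20250 nm^2, supply
#' `V_DD` = 0.55 V (with `V_SS = V_DD`), neuron activity factor `eta` = 0.5,
#' and output-opamp bias `I_bias` = 0.1 uA.
#'
#' @param I_max Maximum neuron output current (A).
#' @param V_T Thermal voltage (V).
#' @param n Subthreshold slope constant (dimensionless).
#' @param A_Vth Pelgrom mismatch coefficient (mV.um).
#' @param W_nm,L_nm Current-mirror device width/length (nm).
#' @param A_match_nm2 Matched-device area (nm^2); default 10 x `W_nm * L_nm`.
#' @param V_DD Supply voltage (V); `V_SS` is assumed equal.
#' @param eta Pre-synaptic neuron activity factor in \[0, 1\].
#' @param I_bias Output opamp bias current (A).
#' @param R_in Neuron input resistance (ohm); default `2 n V_T / I_max`, so
#'   a full-scale input current drives the tanh argument to 1.
#' @param a Area ratio `A_var / A_match` in (0, 1] for the mismatch synapse.
#' @return An object of class `"process_params"`.
#' @export
process_params <- function(I_max = 1e-9, V_T = 0.026, n = 1.2, A_Vth = 4,
                           W_nm = 45, L_nm = 45,
                           A_match_nm2 = 10 * W_nm * L_nm,
                           V_DD = 0.55, eta = 0.5, I_bias = 1e-7,
                           R_in = 2 * n * V_T / I_max, a = 1) {
  vals <- c(I_max = I_max, V_T = V_T, n = n, A_Vth = A_Vth, W_nm = W_nm,
            L_nm = L_nm, A_match_nm2 = A_match_nm2, V_DD = V_DD,
            I_bias = I_bias, R_in = R_in, a = a)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("process_params: all physical quantities must be strictly ",
         "positive and finite")
  if (eta < 0 || eta > 1) stop("process_params: 'eta' must lie in [0, 1]")
  if (a > 1) stop("process_params: 'a' = A_var/A_match must be <= 1")
  structure(list(I_max = I_max, V_T = V_T, n = n, A_Vth = A_Vth,
                 W_nm = W_nm, L_nm = L_nm, A_match_nm2 = A_match_nm2,
                 V_DD = V_DD, eta = eta, I_bias = I_bias, R_in = R_in,
                 a = a), class = "process_params")
}

#' @export
print.process_params <- function(x, ...) {
  cat("Subthreshold process parameters\n")
  cat(sprintf("  I_max = %.3g nA, V_DD = %.3g V, V_T = %.3g V, n = %.3g\n",
              x$I_max * 1e9, x$V_DD, x$V_T, x$n))
  cat(sprintf("  A_Vth = %.3g mV.um, W = L = %g nm, A_match = %g nm^2\n",
              x$A_Vth, x$W_nm, x$A_match_nm2))
  cat(sprintf("  eta = %.3g, I_bias = %.3g uA, R_in = %.3g Mohm, a = %.3g\n",
              x$eta, x$I_bias * 1e6, x$R_in * 1e-6, x$a))
  invisible(x)
}

#' Standard deviation of log mismatch weights
#'
#' The lognormal spread of a mismatch-based synapse weight:
#' `sigma = (A_Vth / sqrt(W L)) / (n V_T)`. At the defaults (A_Vth = 4
#' mV.um, W = L = 45 nm, n = 1.2, V_T = 26 mV) this evaluates to about 2.85.
#'
#' @param p A [process_params()].
#' @return The standard deviation of `ln |w|` (dimensionless).
#' @export
mismatch_sigma <- function(p = process_params()) {
  sigma_V <- p$A_Vth * 1e-3 / sqrt((p$W_nm * 1e-3) * (p$L_nm * 1e-3))  # V
  sigma_V / (p$n * p$V_T)
}

#' Subthreshold neuron transfer function
#'
#' Differential output current of the weak-inversion differential pair:
#' `i_x = I_max * tanh(i_s R_in / (2 n V_T))`. The magnitude stays strictly
#' below `I_max` for any finite input current.
#'
#' @param i_s Input (synaptic) current, A.
#' @param p A [process_params()].
#' @return Differential output current `i_x+ - i_x-` (A).
#' @export
neuron_transfer <- function(i_s, p = process_params()) {
  p$I_max * tanh(i_s * p$R_in / (2 * p$n * p$V_T))
}

#' Sample mismatch-based random synapses
#'
#' Draws synapse weights as produced by threshold-voltage mismatch in the
#' two current mirrors of the bipolar-input synapse: each mirror's gain is
#' `r1 * exp(dVth / (n V_T))` (similarly `r2`) with
#' `dVth ~ N(0, (A_Vth/sqrt(W L))^2)`, so the
#' gains `w1` (NMOS) and `w2` (PMOS) are lognormal with log-sd
#' [mismatch_sigma()]. The effective signed weight is `w = w1 / 2` with a
#' random +/-1 polarity (each synapse is wired to the positive or negative
#' neuron output with equal probability), and the bias is `b = w2 - w1/2`.
#'
#' @param count Number of synapses to sample.
#' @param p A [process_params()].
#' @param seed Optional integer seed.
#' @param r1,r2 Nominal mirror gain ratios (default 1, minimal sizing).
#' @return A data frame with columns `w1`, `w2`, `w`, `b`, `sign`.
#' @export
sample_mismatch_synapses <- function(count, p = process_params(),
                                     seed = NULL, r1 = 1, r2 = 1) {
  if (count < 1) stop("sample_mismatch_synapses: 'count' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  sigma <- mismatch_sigma(p)
  w1 <- r1 * exp(stats::rnorm(count, 0, sigma))
  w2 <- r2 * exp(stats::rnorm(count, 0, sigma))
  data.frame(w1 = w1, w2 = w2, w = w1 / 2, b = w2 - 0.5 * w1,
             sign = sample(c(-1, 1), count, replace = TRUE))
}

#' Output current of a mismatch synapse
#'
#' Evaluates `i_s = w2 I_max - w1 ix_minus`, the single-ended synapse output
#' given the complementary pre-synaptic pair currents (`ix_plus + ix_minus`
#' must equal `I_max`). Algebraically this equals
#' `(ix_plus - ix_minus) w1/2 + I_max b`.
#'
#' @param ix_plus,ix_minus Complementary pre-synaptic currents (A).
#' @param s One row of [sample_mismatch_synapses()] (fields `w1`, `w2`).
#' @param p A [process_params()].
#' @return Synaptic output current (A).
#' @export
synapse_output <- function(ix_plus, ix_minus, s, p = process_params()) {
  if (any(abs(ix_plus + ix_minus - p$I_max) > 1e-6 * p$I_max))
    stop("synapse_output: ix_plus + ix_minus must equal I_max ",
         "(complementary differential pair)")
  s$w2 * p$I_max - s$w1 * ix_minus
}

gcd_int <- function(a, b) {
  while (b != 0) { t <- b; b <- a %% b; a <- t }
  a
}

#' Baseline-weight specification for the deterministic synapse
#'
#' The deterministic (geometry-ratio) synapse realizes discrete weights
#' `w = k * w_res`, `k` a positive integer, by sizing its two current
#' mirrors; its area grows with the irreducible ratio `k / gcd(1/w_res, k)`.
#'
#' @param w_res Weight resolution; `1/w_res` must be a positive integer.
#' @param distribution `"uniform_pm1"`, `"normal"` (sd 0.1) or
#'   `"lognormal"` (log-sd 2.85).
#' @param sd,sdlog Spread parameters for the normal/lognormal laws.
#' @return An object of class `"baseline_weight_spec"`.
#' @export
baseline_weight_spec <- function(w_res = 1 / 100,
                                 distribution = c("uniform_pm1", "normal",
                                                  "lognormal"),
                                 sd = 0.1, sdlog = 2.85) {
  distribution <- match.arg(distribution)
  Q <- 1 / w_res
  if (!isTRUE(all.equal(Q, round(Q))) || Q < 1)
    stop("baseline_weight_spec: 'w_res' must be a unit fraction 1/Q")
  structure(list(w_res = w_res, Q = as.integer(round(Q)),
                 distribution = distribution, sd = sd, sdlog = sdlog),
            class = "baseline_weight_spec")
}

#' Expected area of the deterministic baseline synapse
#'
#' Evaluates `E[A] = 2 A_match E[k / gcd(1/w_res, k)]` over the weight
#' distribution at the given resolution. For the uniform law the expectation
#' is enumerated exactly over `k = 1..1/w_res`; for continuous laws it is a
#' seeded Monte Carlo average with `k = max(1, round(|w| / w_res))`. The
#' result is never below `2 A_match` (two matched MOSFETs).
#'
#' @param spec A [baseline_weight_spec()].
#' @param p A [process_params()].
#' @param nsim Monte Carlo draws for continuous distributions.
#' @param seed Seed for the Monte Carlo path.
#' @return Expected synapse area in nm^2.
#' @export
baseline_synapse_area <- function(spec = baseline_weight_spec(),
                                  p = process_params(), nsim = 10000L,
                                  seed = 1L) {
  Q <- spec$Q
  reduced <- function(k) k / vapply(k, gcd_int, numeric(1), b = Q)
  Ek <- switch(spec$distribution,
    uniform_pm1 = mean(reduced(seq_len(Q))),
    {
      set.seed(seed)
      w <- if (spec$distribution == "normal")
        stats::rnorm(nsim, 0, spec$sd)
      else stats::rlnorm(nsim, 0, spec$sdlog) *
        sample(c(-1, 1), nsim, replace = TRUE)
      k <- pmax(1, round(abs(w) / spec$w_res))
      mean(reduced(k))
    })
  2 * p$A_match_nm2 * Ek
}

# Synapse counts per topology: every neuron has an input synapse per channel
# plus the recurrent links of its kind; center-bearing kinds add the up and
# down links. Random kind uses the expected count at the spec's connectivity
# (self-loops excluded).
synapse_count <- function(spec) {
  N <- spec$N
  rec <- switch(spec$kind,
                one_way_ring = N, two_way_ring = 2 * N, center = 2 * N,
                hybrid = 3 * N, random = spec$connectivity * N * (N - 1))
  c(input = N * spec$K, recurrent = rec)
}

neuron_count <- function(spec) {
  spec$N + as.integer(spec$kind %in% c("center", "hybrid"))
}

#' Area report for the analog realization
#'
#' Per-block and total silicon area: `5 A_match` per neuron,
#' `A_match (2 + 4a)` per mismatch synapse, and `(N M + 9) A_match` for the
#' memristor-crossbar output layer (crossbar plus a seven-transistor opamp).
#'
#' @param spec A [topology_spec()].
#' @param p A [process_params()].
#' @return An object of class `"area_report"`: data frame with one row per
#'   block (`neurons`, `synapses`, `output`, `total`), areas in nm^2 and in
#'   `A_match` units.
#' @export
area_report <- function(spec, p = process_params()) {
  Am <- p$A_match_nm2
  n_neu <- neuron_count(spec)
  n_syn <- sum(synapse_count(spec))
  a_neu <- n_neu * 5 * Am
  a_syn <- n_syn * Am * (2 + 4 * p$a)
  a_out <- (spec$N * spec$M + 9) * Am
  df <- data.frame(
    block = c("neurons", "synapses", "output", "total"),
    count = c(n_neu, n_syn, spec$M, NA),
    area_nm2 = c(a_neu, a_syn, a_out, a_neu + a_syn + a_out))
  df$area_Amatch <- df$area_nm2 / Am
  structure(df, class = c("area_report", "data.frame"))
}

#' Power report for the analog realization
#'
#' Per-block and total static power: `I_max V_DD` per neuron, per-synapse
#' power `V_DD I_max (2 eta + eta w1 + w2 + 2)`, and output-layer power
#' `eta N M I_max V_DD + 2 M I_bias V_DD`. In `"median"` mode every synapse
#' uses the nominal (distribution-median) gains `w1 = w2 = 1`; in
#' `"per_sample"` mode one sampled synapse per physical synapse exposes the
#' mismatch-induced spread.
#'
#' @param spec A [topology_spec()].
#' @param p A [process_params()].
#' @param samples Data frame from [sample_mismatch_synapses()]; required in
#'   `"per_sample"` mode with at least one row per synapse.
#' @param mode `"median"` or `"per_sample"`.
#' @return An object of class `"power_report"`: data frame with one row per
#'   block, power in watts and nW.
#' @export
power_report <- function(spec, p = process_params(), samples = NULL,
                         mode = c("median", "per_sample")) {
  mode <- match.arg(mode)
  n_neu <- neuron_count(spec)
  n_syn <- sum(synapse_count(spec))
  p_neu <- n_neu * p$I_max * p$V_DD
  syn_power <- function(w1, w2)
    p$V_DD * p$I_max * (2 * p$eta + p$eta * w1 + w2 + 2)
  p_syn <- if (mode == "median") n_syn * syn_power(1, 1) else {
    if (is.null(samples) || nrow(samples) < n_syn)
      stop("power_report: per_sample mode needs >= ", n_syn,
           " synapse samples, got ", if (is.null(samples)) 0
           else nrow(samples))
    sum(syn_power(samples$w1[seq_len(n_syn)], samples$w2[seq_len(n_syn)]))
  }
  p_out <- p$eta * spec$N * spec$M * p$I_max * p$V_DD +
    2 * spec$M * p$I_bias * p$V_DD
  df <- data.frame(
    block = c("neurons", "synapses", "output", "total"),
    count = c(n_neu, n_syn, spec$M, NA),
    power_W = c(p_neu, p_syn, p_out, p_neu + p_syn + p_out))
  df$power_nW <- df$power_W * 1e9
  attr(df, "mode") <- mode
  structure(df, class = c("power_report", "data.frame"))
}

#' @export
print.area_report <- function(x, ...) {
  cat("Analog area report\n")
  print.data.frame(x, row.names = FALSE, digits = 6)
  invisible(x)
}

#' @export
print.power_report <- function(x, ...) {
  cat("Analog power report (", attr(x, "mode"), " mode)\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 6)
  invisible(x)
}
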