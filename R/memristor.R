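#' Memristor device parameters
#'
#' Parameters of the semi-empirical tunneling memristor model: an
#' exponential (sinh) I-V branch per voltage polarity, a threshold-gated
#' state-change rate, and a window function confining the state variable
#' `gamma` to \[0, 1\]. The `xi` fitting constants of the cited
#' W/Ag-chalcogenide device are not published; the defaults here are
#' documented placeholders chosen for smooth, monotone incremental
#' switching, and every value is configurable.
#'
#' @param G_moff Off-state conductance (S).
#' @param g On/off conductance ratio (the conductance interpolates from
#'   `G_moff` at `gamma = 0` to `g * G_moff` at `gamma = 1`).
#' @param xi1p,xi1n Conduction fitting constants (positive/negative branch).
#' @param xi2p,xi2n,xi3p,xi3n Window-function fitting constants.
#' @param xi4p,xi4n,xi5p,xi5n,xi6p,xi6n State-change rate fitting constants.
#' @param V_tp Positive write threshold (> 0, V).
#' @param V_tn Negative write threshold (< 0, V).
#' @return An object of class `"memristor_params"`.
#' @export
memristor_params <- function(G_moff = 1e-6, g = 100,
                             xi1p = 1, xi1n = 1,
                             xi2p = 1, xi2n = 1, xi3p = 0.5, xi3n = 0.5,
                             xi4p = 1, xi4n = 1, xi5p = 2, xi5n = 2,
                             xi6p = 2, xi6n = 2,
                             V_tp = 1, V_tn = -1) {
  if (V_tp <= 0 || V_tn >= 0)
    stop("memristor_params: need V_tp > 0 and V_tn < 0")
  if (G_moff <= 0 || g <= 0 || any(c(xi1p, xi1n, xi2p, xi2n, xi3p, xi3n,
                                     xi4p, xi4n, xi5p, xi5n, xi6p,
                                     xi6n) <= 0))
    stop("memristor_params: conductance and fitting parameters must be ",
         "positive")
  structure(list(G_moff = G_moff, g = g, xi1p = xi1p, xi1n = xi1n,
                 xi2p = xi2p, xi2n = xi2n, xi3p = xi3p, xi3n = xi3n,
                 xi4p = xi4p, xi4n = xi4n, xi5p = xi5p, xi5n = xi5n,
                 xi6p = xi6p, xi6n = xi6n, V_tp = V_tp, V_tn = V_tn),
            class = "memristor_params")
}

#' Memristor state
#'
#' @param gamma State variable in \[0, 1\] (0 = fully off, 1 = fully on).
#' @return An object of class `"memristor_state"`.
#' @export
memristor_state <- function(gamma = 0) {
  if (gamma < 0 || gamma > 1)
    stop("memristor_state: 'gamma' must lie in [0, 1]")
  structure(list(gamma = gamma), class = "memristor_state")
}

#' Memristor read current
#'
#' Tunneling I-V relationship with a state-dependent prefactor:
#' `i = (1 - gamma + g gamma) G_moff xi1 sinh(v xi1)`, with the branch
#' constant `xi1+` for `v >= 0` and `xi1-` for `v < 0`. Zero voltage gives
#' zero current.
#'
#' @param v_m Applied voltage (V); vectorized.
#' @param st A [memristor_state()] (or a plain gamma value).
#' @param p A [memristor_params()].
#' @return Device current (A).
#' @export
device_current <- function(v_m, st, p = memristor_params()) {
  gamma <- if (inherits(st, "memristor_state")) st$gamma else st
  pref <- (1 - gamma + p$g * gamma) * p$G_moff
  ifelse(v_m >= 0,
         pref * p$xi1p * sinh(v_m * p$xi1p),
         pref * p$xi1n * sinh(v_m * p$xi1n))
}

mem_window <- function(gamma, v_m, p) {
  if (v_m >= 0) {
    if (gamma >= p$xi3p)
      exp(-p$xi2p * (gamma - p$xi3p)) * (1 - gamma) / (1 - p$xi3p)
    else 1
  } else {
    if (gamma <= p$xi3n)
      exp(p$xi2n * (gamma - p$xi3n)) * gamma / p$xi3n
    else 1
  }
}

#' Update the memristor state for one pulse interval
#'
#' Forward-Euler step of the threshold-gated rate equation: the state rate
#' is zero for voltages between the thresholds, and
#' `xi4 sinh(xi5 v - xi6 V_tp)` times the boundary window beyond them. The
#' window vanishes as `gamma` approaches 1 (positive branch) or 0 (negative
#' branch), and the result is clipped to \[0, 1\].
#'
#' @param st A [memristor_state()].
#' @param v_m Applied voltage (V).
#' @param dt Pulse duration (s); must be positive.
#' @param p A [memristor_params()].
#' @return The updated [memristor_state()].
#' @export
device_update <- function(st, v_m, dt, p = memristor_params()) {
  if (dt <= 0) stop("device_update: 'dt' must be positive")
  gamma <- if (inherits(st, "memristor_state")) st$gamma else st
  chi <- if (v_m > p$V_tp)
    p$xi4p * sinh(p$xi5p * v_m - p$xi6p * p$V_tp) * mem_window(gamma, v_m, p)
  else if (v_m < p$V_tn)
    p$xi4n * sinh(p$xi5n * v_m - p$xi6n * p$V_tp) * mem_window(gamma, v_m, p)
  else 0
  memristor_state(min(1, max(0, gamma + dt * chi)))
}

# Read conductance at state gamma: the Eq.-style prefactor, a linear
# interpolation between the off and on conductances.
mem_conductance <- function(gamma, p) (1 - gamma + p$g * gamma) * p$G_moff

#' Signed weight encoded by a crossbar column pair
#'
#' Each reservoir output drives two memristors, one exciting and one
#' inhibiting the output opamp; the effective signed weight is
#' `w = R (G_plus - G_minus) / (G_plus + G_minus)`, whose magnitude is
#' strictly below `R`.
#'
#' @param G_plus,G_minus Conductances of the excitatory/inhibitory devices
#'   (S, strictly positive); vectorized.
#' @param R Feedback resistance (ohm); `R1 = R2 = R`.
#' @return Signed weight(s).
#' @export
crossbar_weight <- function(G_plus, G_minus, R = 1) {
  if (any(G_plus <= 0) || any(G_minus <= 0))
    stop("crossbar_weight: conductances must be strictly positive")
  (G_plus - G_minus) / (G_plus + G_minus) * R
}

#' Create a memristor crossbar readout column set
#'
#' One crossbar output: a pair of memristors per reservoir neuron. Device
#' states start at mid-range with a small seeded spread so that initial
#' weights are near zero but not exactly symmetric.
#'
#' @param N Number of reservoir outputs feeding the crossbar.
#' @param p A [memristor_params()].
#' @param R Feedback resistance (ohm).
#' @param gamma_init Initial state level in (0, 1).
#' @param spread Half-width of the uniform initial-state jitter.
#' @param seed Optional integer seed for the jitter.
#' @return An object of class `"crossbar_readout"` with state vectors
#'   `gamma_plus`, `gamma_minus`.
#' @export
crossbar_readout <- function(N, p = memristor_params(), R = 1,
                             gamma_init = 0.5, spread = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  jitter <- function() stats::runif(N, -spread, spread)
  gp <- pmin(1, pmax(0, gamma_init + jitter()))
  gm <- pmin(1, pmax(0, gamma_init + jitter()))
  structure(list(gamma_plus = gp, gamma_minus = gm, params = p, R = R),
            class = "crossbar_readout")
}

#' Weights currently stored in a crossbar readout
#'
#' @param cb A [crossbar_readout()].
#' @return Length-N vector of signed weights.
#' @export
crossbar_weights <- function(cb) {
  crossbar_weight(mem_conductance(cb$gamma_plus, cb$params),
                  mem_conductance(cb$gamma_minus, cb$params), cb$R)
}

#' Crossbar readout voltage
#'
#' Output of one crossbar column set for a vector of reservoir output
#' currents: the weighted sum `v = sum_j ix_j w_j` with the weights of
#' [crossbar_weights()]. The crossbar is an exactly linear map, so this
#' agrees with a dense readout using `W_out = crossbar_weights(cb)`.
#'
#' @param ix Length-N vector of reservoir outputs.
#' @param cb A [crossbar_readout()].
#' @return Scalar output voltage.
#' @export
readout_voltage <- function(ix, cb) {
  w <- crossbar_weights(cb)
  if (length(ix) != length(w))
    stop("readout_voltage: input length ", length(ix),
         " does not match crossbar width ", length(w))
  sum(ix * w)
}

#' Train a crossbar readout with stochastic pulse updates
#'
#' Stochastic least-mean-squares-style training: for each presented state
#' vector the signed output error selects the crossbar row to write — the
#' excitatory (`G_plus`) row for positive errors, the inhibitory
#' (`G_minus`) row for negative ones — and each active column of that row
#' receives a supra-threshold write pulse whose polarity follows the
#' column's input sign, so every update moves the output toward the target.
#' Pulses are stochastically gated with probability proportional to the
#' error magnitude (clipped to 1). Device states evolve only through
#' [device_update()], so every conductance trajectory respects the device
#' physics and stays in \[0, 1\].
#'
#' @param sm A `"state_matrix"` or N x T matrix of training states.
#' @param targets Length-T target vector for the single output.
#' @param cb A [crossbar_readout()] with N column pairs.
#' @param pulse_amplitude Write-pulse voltage; must exceed both thresholds
#'   in magnitude.
#' @param epochs Passes over the training columns.
#' @param dt Pulse duration handed to [device_update()].
#' @param err_scale Error magnitude mapping to pulse probability 1.
#' @param seed Integer seed for the stochastic gating.
#' @return The trained `"crossbar_readout"`, with an `epoch_loss` attribute
#'   (mean squared error after each epoch).
#' @export
pulse_train_readout <- function(sm, targets, cb, pulse_amplitude = 1.3,
                                epochs = 5L, dt = 0.05, err_scale = 1,
                                seed = 1L) {
  X <- if (inherits(sm, "state_matrix")) sm$X_all else sm
  if (ncol(X) != length(targets))
    stop("pulse_train_readout: ", ncol(X), " states but ",
         length(targets), " targets")
  p <- cb$params
  if (pulse_amplitude <= p$V_tp || -pulse_amplitude >= p$V_tn)
    stop("pulse_train_readout: 'pulse_amplitude' must exceed |V_tp| and ",
         "|V_tn|")
  set.seed(seed)
  N <- length(cb$gamma_plus)
  losses <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    for (t in sample.int(ncol(X))) {
      x <- X[, t]
      v <- readout_voltage(x, cb)
      e <- targets[t] - v
      if (!is.finite(e))
        stop("pulse_train_readout: non-finite training error at sample ",
             t, "; training aborted")
      if (stats::runif(1) >= min(1, abs(e) / err_scale)) next
      # error sign selects the row; input sign sets the pulse polarity
      for (j in which(x != 0)) {
        v_w <- sign(x[j]) * pulse_amplitude
        if (e > 0)
          cb$gamma_plus[j] <- device_update(cb$gamma_plus[j], v_w, dt,
                                            p)$gamma
        else
          cb$gamma_minus[j] <- device_update(cb$gamma_minus[j], v_w, dt,
                                             p)$gamma
      }
    }
    w <- crossbar_weights(cb)
    losses[ep] <- mean((targets - drop(crossprod(X, w)))^2)
  }
  attr(cb, "epoch_loss") <- losses
  cb
}
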