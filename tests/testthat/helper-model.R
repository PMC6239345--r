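# Shared fixtures: the calibrated channel set and frequently used operating
# points, built once per test run.

.fixt <- new.env(parent = emptyenv())

calibrated_channels <- function() {
  if (is.null(.fixt$channels))
    .fixt$channels <- build_channel_set(g_max = gbar_default())
  .fixt$channels
}

dark_op <- function() {
  if (is.null(.fixt$dark)) .fixt$dark <- find_dark_rest(calibrated_channels())
  .fixt$dark
}

op_at <- function(V) {
  key <- paste0("op", V)
  if (is.null(.fixt[[key]]))
    .fixt[[key]] <- solve_balance_at_voltage(V, calibrated_channels())
  .fixt[[key]]
}

test_grid <- function() c(dark_op()$V, -59, -52, -44, -41, -36)

# Pulse response predicted from the analytic impedance by inverse FFT of the
# pulse current spectrum (the linearisation route, independent of the ODE
# solver).
predict_pulse_lin <- function(op, protocol, freeze = freeze_none()) {
  p <- protocol
  total <- p$pre_ms + p$duration_ms + p$post_ms
  n <- round(total / p$dt_ms)
  t_ms <- (0:(n - 1)) * p$dt_ms
  i_pA <- ifelse(t_ms >= p$pre_ms & t_ms < p$pre_ms + p$duration_ms,
                 p$amplitude_nA * 1000, 0)
  T_s <- total * 1e-3
  k <- 0:(n - 1)
  f <- ifelse(k <= n / 2, k, k - n) / T_s
  zf <- membrane_impedance(op, freeze, f = 1)$zfun
  Zk <- zf(f)                      # GOhm; zfun(-f) = Conj(zfun(f))
  dv <- Re(stats::fft(stats::fft(i_pA) * Zk, inverse = TRUE)) / n
  list(t_ms = t_ms, dV_mV = dv)
}
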