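# Gating curves, time constants, composite inactivation and modulation edits.

test_that("steady-state midpoints and time-constant values match the closed forms", {
  ch <- build_channel_set(g_max = c(shaker = 1, shab = 1, novel = 1))
  # activation midpoints before the exponent: m_inf = (1/2)^(1/gamma)
  expect_equal(gating_value(ch$shaker$activation, -23.7), 0.5^(1 / 3),
               tolerance = 1e-12)
  expect_equal(gating_value(ch$shab$activation, -1), 0.5^(1 / 2),
               tolerance = 1e-12)
  expect_equal(gating_value(ch$novel$activation, -1), 0.5^(1 / 2),
               tolerance = 1e-12)
  # inactivation midpoint of Shab (both modes share the curve)
  expect_equal(gating_value(ch$shab$components[[1]]$h, -25.7), 0.5,
               tolerance = 1e-12)
  expect_equal(gating_value(ch$shab$components[[2]]$h, -25.7), 0.5,
               tolerance = 1e-12)
  # printed time-constant values
  expect_equal(gating_tau(ch$shab$components[[2]]$h, -120), 3000)
  expect_equal(gating_tau(ch$shab$components[[2]]$h, 40), 3000)
  expect_equal(gating_tau(ch$shab$components[[1]]$h, 0), 335 + 73.2,
               tolerance = 1e-12)
  expect_equal(gating_tau(ch$novel$activation, -19.4), 13 + 165,
               tolerance = 1e-12)
})

test_that("modulation edits the right curves and composes", {
  ser <- build_channel_set(modulation_state(serotonin = TRUE),
                           g_max = c(shaker = 1, shab = 1, novel = 1))
  # serotonin-shifted midpoints
  expect_equal(gating_value(ser$shaker$activation, 11.7), 0.5^(1 / 3),
               tolerance = 1e-12)
  expect_equal(gating_value(ser$shab$activation, 12.7), 0.5^(1 / 2),
               tolerance = 1e-12)
  expect_equal(gating_value(ser$shab$components[[1]]$h, -15.7), 0.5,
               tolerance = 1e-12)
  # serotonin time constants are rigid shifts of the unmodulated curves
  un <- build_channel_set(g_max = c(shaker = 1, shab = 1, novel = 1))
  V <- seq(-80, -20, by = 7)
  expect_equal(gating_tau(ser$shaker$activation, V),
               gating_tau(un$shaker$activation, V - 31.4), tolerance = 1e-12)
  expect_equal(gating_tau(ser$shaker$components[[2]]$h, V),
               gating_tau(un$shaker$components[[2]]$h, V - 25), tolerance = 1e-12)
  expect_equal(gating_tau(ser$shab$activation, V),
               gating_tau(un$shab$activation, V - 13.7), tolerance = 1e-12)
  expect_equal(gating_tau(ser$shab$components[[1]]$h, V),
               gating_tau(un$shab$components[[1]]$h, V - 10), tolerance = 1e-12)
  # PIP2 depletion: 10 mV leftward shift of Shab activation only
  pip <- build_channel_set(modulation_state(pip2_depleted = TRUE),
                           g_max = c(shaker = 1, shab = 1, novel = 1))
  expect_equal(gating_value(pip$shab$activation, -11), 0.5^(1 / 2),
               tolerance = 1e-12)
  expect_equal(gating_tau(pip$shab$activation, V),
               gating_tau(un$shab$activation, V), tolerance = 1e-12)
  expect_equal(gating_value(pip$shab$components[[1]]$h, V),
               gating_value(un$shab$components[[1]]$h, V), tolerance = 1e-12)
  # Novel untouched by either modulator
  expect_equal(gating_value(ser$novel$activation, V),
               gating_value(un$novel$activation, V), tolerance = 1e-12)
  # both modulators compose: serotonin Shab activation midpoint moves 10 mV left
  both <- build_channel_set(modulation_state(serotonin = TRUE, pip2_depleted = TRUE),
                            g_max = c(shaker = 1, shab = 1, novel = 1))
  expect_equal(gating_value(both$shab$activation, 12.7 - 10), 0.5^(1 / 2),
               tolerance = 1e-12)
  # calmodulin scaling multiplies Shab g_max only, curves unchanged
  half <- build_channel_set(modulation_state(shab_scale = 0.5),
                            g_max = c(shaker = 1, shab = 2, novel = 1))
  expect_equal(half$shab$g_max, 1)
  expect_equal(half$shaker$g_max, 1)
  expect_equal(gating_value(half$shab$activation, V),
               gating_value(un$shab$activation, V), tolerance = 1e-12)
})

test_that("activation curves rise and inactivation curves fall monotonically", {
  for (mod in list(modulation_state(), modulation_state(serotonin = TRUE),
                   modulation_state(pip2_depleted = TRUE))) {
    ch <- build_channel_set(mod, g_max = c(shaker = 1, shab = 1, novel = 1))
    V <- seq(-120, 60, by = 1)
    for (nm in names(ch)) {
      m <- gating_value(ch[[nm]]$activation, V)
      expect_true(all(diff(m) > 0), info = paste(nm, "activation"))
      expect_true(all(m > 0 & m < 1))
      expect_true(all(gating_tau(ch[[nm]]$activation, V) > 0))
      for (cc in ch[[nm]]$components) {
        if (is.null(cc$h)) next
        h <- gating_value(cc$h, V)
        expect_true(all(diff(h) < 0), info = paste(nm, "inactivation"))
        expect_true(all(h > 0 & h < 1))
      }
    }
  }
})

test_that("steady-state slopes agree with central finite differences", {
  ch <- build_channel_set(g_max = c(shaker = 1, shab = 1, novel = 1))
  V <- seq(-90, -20, by = 3.7)
  dh <- 1e-3
  schemes <- list(ch$shaker$activation, ch$shaker$components[[2]]$h,
                  ch$shab$activation, ch$shab$components[[1]]$h,
                  ch$novel$activation)
  for (s in schemes) {
    fd <- (gating_value(s, V + dh) - gating_value(s, V - dh)) / (2 * dh)
    expect_equal(gating_slope(s, V), fd, tolerance = 1e-5)
  }
})

test_that("time-constant formulas are continuous through their singular voltages", {
  ch <- build_channel_set(g_max = c(shaker = 1, shab = 1, novel = 1))
  sing <- list(list(ch$shaker$activation, -59.6),
               list(ch$shaker$components[[2]]$h, 13.5),
               list(ch$shab$activation, -23.8))
  for (s in sing) {
    t0 <- gating_tau(s[[1]], s[[2]])
    expect_true(is.finite(t0) && t0 > 0)
    expect_lt(abs(gating_tau(s[[1]], s[[2]] + 1e-6) - t0), 1e-6 * t0)
    expect_lt(abs(gating_tau(s[[1]], s[[2]] - 1e-6) - t0), 1e-6 * t0)
  }
})

test_that("composite inactivation equals the fraction-weighted component sum", {
  ch <- build_channel_set(g_max = c(shaker = 5, shab = 7, novel = 3))
  set.seed(42)
  for (i in 1:1000) {
    V <- stats::runif(1, -90, -20)
    m <- stats::runif(1); h1 <- stats::runif(1); h2 <- stats::runif(1)
    # Shaker: h = 0.13 + 0.87 h1
    g_split <- channel_conductance(ch$shaker, list(m = m, h = c(1, h1)))
    g_direct <- ch$shaker$g_max * (0.13 + 0.87 * h1) * m^3
    expect_equal(g_split, g_direct, tolerance = 1e-12)
    # Shab: h = 0.7 h1 + 0.3 h2
    g_split <- channel_conductance(ch$shab, list(m = m, h = c(h1, h2)))
    g_direct <- ch$shab$g_max * (0.7 * h1 + 0.3 * h2) * m^2
    expect_equal(g_split, g_direct, tolerance = 1e-12)
  }
})

test_that("conductance respects gate bounds and rejects bad input", {
  ch <- build_channel_set(g_max = c(shaker = 2, shab = 2, novel = 2))
  # fully open Shab equals g_max; m = 0 closes any channel
  expect_equal(channel_conductance(ch$shab, list(m = 1, h = c(1, 1))), 2)
  expect_equal(channel_conductance(ch$shaker, list(m = 0, h = c(1, 1))), 0)
  # Shaker with h1 = 0 retains the non-inactivating fraction
  expect_equal(channel_conductance(ch$shaker, list(m = 1, h = c(1, 0))),
               0.13 * 2, tolerance = 1e-12)
  expect_error(channel_conductance(ch$shaker, list(m = 1.2, h = c(1, 1))),
               "gate")
  expect_error(channel_conductance(ch$shaker, list(m = 0.5, h = c(1, -0.1))),
               "gate")
  expect_error(build_channel_set(g_max = c(shaker = -1, shab = 1, novel = 1)),
               "non-negative")
  expect_error(modulation_state(shab_scale = 0), "shab_scale")
})

test_that("channel configs round-trip losslessly through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  g <- c(shaker = 16.123456789, shab = 53.987654321, novel = 0.000123456789)
  mod <- modulation_state(serotonin = TRUE, shab_scale = 0.5)
  write_channel_config(path, g_max = g, modulation = mod)
  back <- read_channel_config(path)
  expect_identical(back$g_max, g)
  expect_identical(unclass(back$modulation), unclass(mod))
  V <- seq(-80, -30, by = 11)
  orig <- build_channel_set(mod, g_max = g)
  for (nm in names(orig))
    expect_equal(gating_value(back$channels[[nm]]$activation, V),
                 gating_value(orig[[nm]]$activation, V), tolerance = 1e-15)
})
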