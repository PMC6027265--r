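test_that("segmentation finds the organic-acid onset and the aeration stop", {
  tr <- simulate_fermentation(noise_free_scenario())
  seg <- segment_phases(tr)
  truth <- attr(tr, "truth")
  ## onset near 6 h of cultivation, consistent with the generating model
  expect_lt(abs(seg$aerobic[2] - truth$t_micro), 0.25)
  expect_gt(seg$aerobic[2], 5)
  expect_lt(seg$aerobic[2], 6.5)
  expect_equal(seg$anaerobic[1], 11)
  expect_equal(seg$microaerobic[1], seg$aerobic[2])
})

test_that("traces without detectable products get an empty microaerobic window", {
  pp <- default_phase_params()
  pp[, c("Y_PS_lactate", "Y_PS_succinate", "Y_PS_acetate")] <- 0
  ## without fermentation products all carbon goes through biomass:
  ## a larger glucose supply keeps the run substrate-replete
  tr <- simulate_fermentation(noise_free_scenario(
    phase_params = pp, S0 = 100, sampling_grid = seq(0, 12, 0.5)))
  expect_warning(seg <- segment_phases(tr), "microaerobic")
  expect_null(seg$microaerobic)
  expect_equal(seg$aerobic[2], 11)

  ## a threshold above the maximal product concentration behaves the same
  tr2 <- simulate_fermentation(noise_free_scenario())
  expect_warning(seg2 <- segment_phases(tr2, product_threshold = 1e3),
                 "microaerobic")
  expect_null(seg2$microaerobic)
})

test_that("a missing aeration-stop event demands an explicit anaerobic time", {
  tr <- fermentation_trace(time = 0:5, biomass = exp(0.2 * (0:5)),
                           glucose = 60 - (0:5))
  expect_error(segment_phases(tr), "t_anaer")
  expect_warning(seg <- segment_phases(tr, t_anaer = 3), "microaerobic")
  expect_equal(seg$anaerobic, c(3, 5))
})

test_that("growth-rate regression is exact on noise-free exponentials", {
  tr <- simulate_fermentation(noise_free_scenario())
  seg <- segment_phases(tr)
  est <- fit_growth_rate(tr, c(seg$microaerobic[1], 10.99))
  expect_equal(est$value, 0.21, tolerance = 1e-9)
  expect_equal(est$r_squared, 1, tolerance = 1e-12)
  expect_equal(est$stderr, 0, tolerance = 1e-9)

  ## both window-search variants agree on clean data
  est2 <- fit_growth_rate(tr, c(seg$microaerobic[1], 10.99),
                          method = "exhaustive")
  expect_equal(est2$value, est$value, tolerance = 1e-9)
})

test_that("two points give the slope identity at min_points = 2", {
  tr <- fermentation_trace(time = c(0, 1), biomass = c(1, exp(1)),
                           glucose = c(10, 9))
  est <- fit_growth_rate(tr, c(0, 1), min_points = 2)
  expect_equal(est$value, 1, tolerance = 1e-12)
})

test_that("the window search trims away a non-exponential region", {
  ## exponential growth at 0.4 for 5 h, then an abrupt stationary phase
  tt <- seq(0, 10, 0.5)
  X <- ifelse(tt <= 5, 0.4 * exp(0.4 * tt), 0.4 * exp(2))
  tr <- fermentation_trace(time = tt, biomass = X, glucose = 60 - tt)
  est <- fit_growth_rate(tr, c(0, 10))
  expect_equal(est$value, 0.4, tolerance = 1e-9)
  expect_lte(est$fit_window[2], 5.5)
})

test_that("growth-rate recovery from noisy traces is unbiased", {
  mus <- vapply(1:20, function(s) {
    tr <- simulate_fermentation(process_scenario(seed = 100 + s))
    seg <- segment_phases(tr)
    fit_growth_rate(tr, c(0, seg$aerobic[2] - 1e-9))$value
  }, numeric(1))
  ## the printed uncertainty of the aerobic growth rate is +-0.01
  expect_lt(abs(mean(mus) - 0.40), 0.01)
})

test_that("R2 window choice and slope are invariant to biomass rescaling", {
  tr <- simulate_fermentation(process_scenario(seed = 77))
  est1 <- fit_growth_rate(tr, c(0, 5))
  tr2 <- tr
  tr2$biomass_gDCW_L <- tr$biomass_gDCW_L * (0.30 / 0.22)  # alpha change
  est2 <- fit_growth_rate(tr2, c(0, 5))
  expect_equal(est2$value, est1$value, tolerance = 1e-12)
  expect_equal(est2$fit_window, est1$fit_window)
  expect_equal(est2$r_squared, est1$r_squared, tolerance = 1e-12)
})

test_that("yield regression reproduces hand arithmetic and edge cases", {
  ## slope = 10.4 / 20 on an exact line
  tr <- fermentation_trace(time = 0:2, biomass = c(0.4, 5.6, 10.8),
                           glucose = c(60, 50, 40))
  est <- fit_yield(tr, c(0, 2), "biomass")
  expect_equal(est$value, 0.52, tolerance = 1e-12)
  expect_equal(est$r_squared, 1, tolerance = 1e-12)

  ## constant biomass while glucose falls: yield exactly 0
  tr0 <- fermentation_trace(time = 0:3, biomass = rep(2, 4),
                            glucose = c(40, 30, 20, 10))
  expect_equal(fit_yield(tr0, c(0, 3), "biomass")$value, 0)

  ## degenerate inputs
  trc <- fermentation_trace(time = 0:3, biomass = 1:4, glucose = rep(10, 4))
  expect_error(fit_yield(trc, c(0, 3), "biomass"), "constant")
  expect_error(fit_yield(tr, c(0, 0.5), "biomass"), ">= 3")
  expect_error(fit_yield(tr, c(0, 2), "product", "butanol"), "product_name")
})

test_that("noise-free phase windows return the generating yields", {
  tr <- simulate_fermentation(noise_free_scenario())
  seg <- segment_phases(tr)
  win <- c(seg$microaerobic[1], 10.99)
  est <- fit_yield(tr, win, "product", "lactate")
  expect_equal(est$value, 0.49, tolerance = 1e-6)
  expect_equal(fit_yield(tr, win, "biomass")$value, 0.29, tolerance = 1e-6)
})

test_that("q_S error propagation reproduces the reference phase table", {
  rows <- list(list(mu = c(0.40, 0.01), y = c(0.52, 0.04), q = c(0.77, 0.06)),
               list(mu = c(0.21, 0.00), y = c(0.29, 0.02), q = c(0.72, 0.05)),
               list(mu = c(0.09, 0.01), y = c(0.16, 0.01), q = c(0.56, 0.07)))
  for (r in rows) {
    qs <- compute_qs(r$mu, r$y)
    expect_equal(oxyshift:::.round_half_up(qs$value, 2), r$q[1])
    expect_equal(oxyshift:::.round_half_up(qs$stderr, 2), r$q[2])
  }
  ## degenerate cases
  q0 <- compute_qs(c(0, 0), c(0.5, 0.1))
  expect_equal(q0$value, 0)
  expect_equal(q0$stderr, 0)
  expect_error(compute_qs(c(0.4, 0.01), c(0, 0)), "Y_X/S")
})

test_that("every noise-free estimate matches its generating parameter", {
  tr <- simulate_fermentation(noise_free_scenario())
  co <- coef(fit_phase_kinetics(tr))
  pp <- default_phase_params()
  for (i in 1:3) {
    ph <- pp$phase[i]
    expect_equal(co[ph, "mu"], pp$mu[i], tolerance = 1e-6)
    expect_equal(co[ph, "Y_XS"], pp$Y_XS[i], tolerance = 1e-6)
    for (p in c("lactate", "succinate", "acetate")) {
      nm <- paste0("Y_PS_", p)
      if (pp[[nm]][i] > 0)
        expect_equal(co[ph, nm], pp[[nm]][i], tolerance = 1e-6)
    }
    expect_equal(co[ph, "q_S"], pp$mu[i] / pp$Y_XS[i], tolerance = 1e-6)
  }
})

test_that("phase_kinetics methods are coherent", {
  tr <- simulate_fermentation(noise_free_scenario())
  fit <- fit_phase_kinetics(tr)

  ## predictions reproduce the noise-free observations
  res <- residuals(fit)
  expect_lt(max(abs(res$biomass_gDCW_L)), 1e-6)
  expect_lt(max(abs(res$glucose_g_L)), 1e-4)

  ## summary applies the 2-decimal report convention
  sm <- summary(fit)
  expect_equal(sm$q_S, c(0.77, 0.72, 0.56))

  ## simulate() round-trips through a scenario built from the fit
  sims <- simulate(fit, nsim = 2, seed = 4, cv = 0)
  expect_length(sims, 2)
  expect_equal(sims[[1]]$biomass_gDCW_L, tr$biomass_gDCW_L, tolerance = 1e-3)
})
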