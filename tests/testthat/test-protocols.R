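r_opt <- optimized_rate_params()

test_that("multi-input responses track fold changes, not absolute steps", {
  # 20 nM at 0, +20 nM at 2 h, +40 nM at 3 h: both perturbations are
  # two-fold steps and elicit similar responses
  cfg <- circuit_config(50, 150)
  sch <- input_schedule(c(0, 120, 180), "A", c(20, 20, 40))
  rep <- run_multi_input(r_opt, cfg, sch,
                         options = sim_options(t_end = 400, dt = 0.25))
  expect_equal(nrow(rep), 2)
  expect_lt(abs(rep$amplitude[2] / rep$amplitude[1] - 1), 0.5)
  expect_equal(rep$u_after, c(40, 80))
})

test_that("negative input gives an undershoot that recovers", {
  # start from the settled 40 nM steady state, then add 20 nM inhibitor
  cfg <- circuit_config(100, 100)
  dr <- derived_rates(cfg, r_opt)
  eq <- equilibrium_simple(dr, r_opt$k, 40)
  r_nb <- r_opt; r_nb$B <- 0
  sch <- input_schedule(c(0, 120), c("A", "I"), c(40, 20))
  rep <- run_multi_input(r_nb, cfg, sch,
                         init = c(x = eq$x_bar, y = eq$y_bar, z = eq$z_bar),
                         options = sim_options(t_end = 1500, dt = 0.5))
  expect_equal(rep$species, "I")
  expect_gt(rep$undershoot, 0)
  expect_true(rep$recovered)   # adapts back to the prior steady level
  # empty post-baseline schedule: nothing to report, flat output
  rep0 <- run_multi_input(r_opt, cfg, input_schedule(0, "A", 20),
                          init = NULL,
                          options = sim_options(t_end = 200, dt = 1))
  expect_equal(nrow(rep0), 0)
})

test_that("template-ratio sweep is proportional to the ratio", {
  ratios <- c(0.1, 0.5, 1, 2, 3)
  rep <- run_condition_sweep("ratio", ratios, r_opt, circuit_config(50, 150),
                             options = sim_options(t_end = 2500, dt = 1))
  # closed form is exactly linear in the ratio; simulated steady states
  # land on it (R^2 > 0.99)
  expect_rel_equal(rep$steady_y, rep$steady_y_closed, 1e-4)
  fitq <- stats::lm(rep$steady_y ~ ratios)
  expect_gt(summary(fitq)$r.squared, 0.99)
  expect_true(attr(rep, "trends")[["steady"]])
})

test_that("enzyme sweeps reproduce the expected response table", {
  base <- circuit_config(50, 150)
  opts <- sim_options(t_end = 2500, dt = 1)
  rnaser <- run_condition_sweep("rnaser", c(50, 75, 100), r_opt, base,
                                schedule = input_schedule(0, "A", 10),
                                options = opts)
  expect_true(all(diff(rnaser$steady_y) > 0))       # steady rMG up
  expect_true(all(diff(rnaser$peak_time) > 0))      # response slower
  expect_true(all(attr(rnaser, "trends")))

  rnap <- run_condition_sweep("rnap", c(120, 171, 220), r_opt, base,
                              options = opts)
  expect_lt(diff(range(rnap$steady_y)) / mean(rnap$steady_y), 1e-4)
  expect_true(all(diff(rnap$peak_time) < 0))        # response faster
  expect_true(all(attr(rnap, "trends")))

  ratio <- run_condition_sweep("ratio", c(0.5, 1, 2), r_opt, base,
                               options = opts)
  expect_true(all(diff(ratio$steady_y) > 0))
  expect_true(all(diff(ratio$peak_time) > 0))
  expect_true(all(diff(ratio$settle_time) > 0))

  single <- run_condition_sweep("rnap", 171, r_opt, base, options = opts)
  expect_equal(nrow(single), 1)
  expect_true(all(is.na(attr(single, "trends"))))
})

test_that("fold-change protocol segments and rates the pulses", {
  # the scale-invariant limit model: every doubling gives the same pulse
  sch <- input_schedule(time = c(0, 20, 40, 60, 80), species = "A",
                        amount = c(1, 1, 2, 4, 8))
  rep_lim <- run_fold_change(model = "fcd_limit", schedule = sch,
                             options = sim_options(t_end = 100, dt = 0.01))
  expect_equal(nrow(rep_lim), 4)
  expect_rel_equal(rep_lim$ratio, 1, 1e-6)
  expect_equal(attr(rep_lim, "n_within_tol"), 4)

  # non-dimensional circuit at the bench condition: amplitudes grow toward
  # the limit as the accumulated input raises the effective p2
  rep_nd <- run_fold_change(p = nondim_params(0.19, 0.93, 0.61))
  expect_equal(nrow(rep_nd), 4)
  expect_true(all(diff(rep_nd$amplitude) > 0))
  expect_true(rep_nd$within_tol[1])
  expect_true(all(rep_nd$ratio < 2.5))
})

test_that("protocol metrics are stable under grid refinement", {
  p <- nondim_params(0.19, 0.93, 0.61)
  sch <- input_schedule(time = c(0, 10, 20), species = "A",
                        amount = c(1, 1, 2))
  coarse <- run_fold_change(p = p, schedule = sch,
                            options = sim_options(t_end = 30, dt = 0.02))
  fine <- run_fold_change(p = p, schedule = sch,
                          options = sim_options(t_end = 30, dt = 0.004))
  expect_rel_equal(coarse$amplitude, fine$amplitude, 0.005)
})
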