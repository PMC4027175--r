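r_opt <- optimized_rate_params()

test_that("background correction recovers the bleaching curve", {
  mm0 <- measurement_model(bleach_amp = 0, noise_sd = 0)
  g0 <- gen_binding_assay(c0 = 10, k = 0.005, mm = mm0)
  cb0 <- correct_background(g0$raw)
  expect_equal(cb0$trace$signal, g0$raw$signal, tolerance = 1e-8)

  mm <- measurement_model(bleach_rate = 0.006, bleach_amp = 4, noise_sd = 0)
  g <- gen_binding_assay(c0 = 10, k = 0.005, mm = mm)
  cb <- correct_background(g$raw)
  expect_rel_equal(cb$fit$estimates[["amp"]], 4, 1e-6)
  expect_rel_equal(cb$fit$estimates[["rate"]], 0.006, 1e-6)
  expect_rel_equal(cb$trace$signal + 1e-9, g$truth$rmg + 1e-9, 1e-6)

  # 2% noise: parameters recovered within 10%
  mmn <- measurement_model(bleach_rate = 0.006, bleach_amp = 4,
                           noise_sd = 0.2, seed = 5)
  gn <- gen_binding_assay(c0 = 10, k = 0.005, mm = mmn)
  cbn <- correct_background(gn$raw)
  expect_rel_equal(cbn$fit$estimates[["amp"]], 4, 0.1)
  expect_rel_equal(cbn$fit$estimates[["rate"]], 0.006, 0.1)

  # a pre-enzyme window can replace the blank series
  raw_nb <- gn$raw[c("t", "signal")]
  expect_error(correct_background(raw_nb), "blank")
})

test_that("calibration is a linear map through the origin", {
  tr <- data.frame(t = 0:10, signal = (0:10) * 2)
  cal <- calibrate(tr, data.frame(nM = 10, au = 10))
  expect_equal(attr(cal, "fluor_per_nM"), 1)
  expect_equal(cal$signal, tr$signal)
  # two collinear standards give the same slope
  cal2 <- calibrate(tr, data.frame(nM = c(5, 10), au = c(10, 20)))
  expect_equal(attr(cal2, "fluor_per_nM"), 2)
  expect_equal(cal2$signal, tr$signal / 2)
  expect_error(calibrate(tr, data.frame(nM = 10, au = -1)), "slope")
})

test_that("binding fit recovers k and respects the intercept", {
  mm0 <- measurement_model(bleach_amp = 0, noise_sd = 0)
  g <- gen_binding_assay(c0 = 10, k = 0.005, mm = mm0)
  fit <- fit_binding(g$raw[c("t", "signal")], c0 = 10)
  expect_rel_equal(fit$estimates[["k"]], 0.005, 1e-6)
  # fitted curve passes through c0 at t = 0
  expect_equal(1 / (fit$estimates[["k"]] * 0 + 1 / 10), 10)
  # with the intercept freed, it lands on 1/c0
  fit2 <- fit_binding(g$raw[c("t", "signal")], c0 = 10,
                      fit_intercept = TRUE)
  expect_rel_equal(fit2$estimates[["b"]], 0.1, 1e-6)
  # 2% noise: k within 10% at fixed seed
  mmn <- measurement_model(bleach_amp = 0, noise_sd = 0.2, seed = 9)
  gn <- gen_binding_assay(c0 = 10, k = 0.005, mm = mmn)
  fitn <- fit_binding(gn$raw[c("t", "signal")], c0 = 10)
  expect_rel_equal(fitn$estimates[["k"]], 0.005, 0.1)
})

test_that("transcription fit recovers the shared rate and burst", {
  cfg <- circuit_config(50, 0)
  mm0 <- measurement_model(bleach_amp = 0, noise_sd = 0)
  g <- gen_transcription_assay(c(20, 40), r_opt, cfg, mm = mm0,
                               t_end = 300)
  traces <- lapply(g$raw, function(x) x[c("t", "signal")])
  fit <- fit_transcription(traces, c(20, 40), cfg)
  expect_rel_equal(fit$estimates[["kp2"]], r_opt$kp2, 1e-4)
  expect_rel_equal(fit$estimates[["B"]], r_opt$B, 1e-3)
  expect_rel_equal(fit$estimates[["tau_b"]], r_opt$tau_b, 1e-3)
  # burst-free data with B fixed at zero: kp2 equals the slope weighting
  r0 <- r_opt; r0$B <- 0
  g0 <- gen_transcription_assay(c(20, 40), r0, cfg, mm = mm0)
  fit0 <- fit_transcription(lapply(g0$raw, function(x) x[c("t", "signal")]),
                            c(20, 40), cfg, fit_burst = FALSE)
  expect_rel_equal(fit0$estimates[["kp2"]], r_opt$kp2, 1e-9)
  expect_error(fit_transcription(traces[1], 20, cfg), "length")
})

test_that("degradation fit identifies beta1 and gamma1", {
  mm0 <- measurement_model(bleach_amp = 0, noise_sd = 0)
  g <- gen_degradation_assay(rmg0 = 1000, img0 = 100, rnase_r = 75,
                             rates = r_opt, mm = mm0, t_end = 400)
  fit <- fit_degradation(g$raw[c("t", "signal")], rmg0 = 1000, img0 = 100,
                         k = r_opt$k)
  expect_rel_equal(fit$estimates[["beta1"]], r_opt$beta1, 0.01)
  expect_rel_equal(fit$estimates[["gamma1"]], r_opt$gamma1, 0.01)
  expect_error(fit_degradation(g$raw, rmg0 = 1000, img0 = 0, k = r_opt$k),
               "identifiable")
  flat <- data.frame(t = 0:50, signal = rep(1000, 51))
  expect_error(fit_degradation(flat, 1000, 100, k = r_opt$k), "flat")
})

test_that("global refinement from the truth stays at the truth", {
  cfg <- circuit_config(50, 150)
  sch <- input_schedule(0, "A", 20)
  mm0 <- measurement_model(bleach_amp = 0, noise_sd = 0)
  g <- gen_circuit_assay(r_opt, cfg, sch, mm0,
                         options = sim_options(t_end = 240))
  fit <- refine_global(list(g$raw[c("t", "signal")]),
                       list(list(config = cfg, schedule = sch)),
                       init = r_opt, n_starts = 1)
  expect_true(fit$converged)
  expect_lt(fit$residual_ss, 1e-8)
  expect_rel_equal(unlist(fit$estimates),
                   unlist(r_opt[names(fit$estimates)]), 1e-3)
  # objective is nonincreasing along the optimizer path
  expect_true(all(diff(fit$info$deviance_path) <= 1e-12))
})

test_that("bounds excluding the truth pin the estimate at a bound", {
  cfg <- circuit_config(50, 150)
  sch <- input_schedule(0, "A", 20)
  mm0 <- measurement_model(bleach_amp = 0, noise_sd = 0)
  g <- gen_circuit_assay(r_opt, cfg, sch, mm0,
                         options = sim_options(t_end = 240))
  pn <- c("kp1", "kp2", "B", "tau_b", "k", "beta1", "gamma1")
  truth <- unlist(r_opt[pn])
  lower <- truth * 0.999; upper <- truth * 1.001
  lower["k"] <- truth[["k"]] * 2   # exclude the true binding rate
  upper["k"] <- truth[["k"]] * 4
  fit <- refine_global(list(g$raw[c("t", "signal")]),
                       list(list(config = cfg, schedule = sch)),
                       init = r_opt, n_starts = 1,
                       bounds = list(lower = lower, upper = upper))
  expect_true("k" %in% fit$info$at_bounds)
  expect_equal(fit$estimates[["k"]], lower[["k"]], tolerance = 1e-6)
})

test_that("refinement is deterministic given data, init and bounds", {
  cfg <- circuit_config(50, 150)
  sch <- input_schedule(0, "A", 20)
  mm <- measurement_model(seed = 21)
  g <- gen_circuit_assay(r_opt, cfg, sch, mm,
                         options = sim_options(t_end = 180))
  args <- list(list(g$raw[c("t", "signal")]),
               list(list(config = cfg, schedule = sch)))
  f1 <- refine_global(args[[1]], args[[2]], init = default_rate_params(),
                      n_starts = 2, seed = 4)
  f2 <- refine_global(args[[1]], args[[2]], init = default_rate_params(),
                      n_starts = 2, seed = 4)
  expect_identical(f1$estimates, f2$estimates)
})
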