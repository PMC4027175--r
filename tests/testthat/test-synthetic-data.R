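r_opt <- optimized_rate_params()
cfg <- circuit_config(50, 150)
sch20 <- input_schedule(0, "A", 20)

test_that("noiseless unit-slope measurement returns the model output", {
  mm0 <- measurement_model(fluor_per_nM = 1, bleach_amp = 0, noise_sd = 0)
  g <- gen_circuit_assay(r_opt, cfg, sch20, mm0,
                         options = sim_options(t_end = 120))
  expect_equal(g$raw$signal, g$truth$y)
  expect_equal(g$raw$t, g$truth$t)
})

test_that("generation is reproducible for a fixed seed", {
  mm <- measurement_model(seed = 11)
  g1 <- gen_circuit_assay(r_opt, cfg, sch20, mm,
                          options = sim_options(t_end = 60))
  g2 <- gen_circuit_assay(r_opt, cfg, sch20, mm,
                          options = sim_options(t_end = 60))
  expect_identical(g1$raw$signal, g2$raw$signal)
  expect_identical(g1$raw$blank, g2$raw$blank)
  # a different seed gives a different noise draw
  mm2 <- measurement_model(seed = 12)
  g3 <- gen_circuit_assay(r_opt, cfg, sch20, mm2,
                          options = sim_options(t_end = 60))
  expect_false(identical(g1$raw$signal, g3$raw$signal))
})

test_that("bleaching background halves at ln(2)/rate", {
  mm <- measurement_model(bleach_rate = 0.01, bleach_amp = 8, noise_sd = 0)
  g <- gen_binding_assay(c0 = 10, k = 0, mm = mm, t_end = 240)
  bg <- g$raw$signal - g$truth$rmg * mm$fluor_per_nM
  t_half <- log(2) / 0.01
  i <- which.min(abs(g$raw$t - t_half))
  # nearest sample to the half-life (1-min sampling)
  expect_equal(bg[i] / bg[1], exp(-0.01 * g$raw$t[i]), tolerance = 1e-9)
  expect_equal(bg[i] / bg[1], 0.5, tolerance = 0.005)
})

test_that("binding assay follows the second-order closed form", {
  g <- gen_binding_assay(c0 = 10, k = 0.005,
                         mm = measurement_model(bleach_amp = 0, noise_sd = 0))
  # reciprocal concentration is linear with intercept 1/c0 = 0.1
  rec <- 1 / g$truth$rmg
  fitc <- stats::coef(stats::lm(rec ~ g$truth$t))
  expect_equal(unname(fitc[1]), 0.1, tolerance = 1e-12)
  expect_equal(unname(fitc[2]), 0.005, tolerance = 1e-12)
  expect_equal(g$truth$rmg[1], 10)
  # k = 0: nothing decays
  g0 <- gen_binding_assay(c0 = 10, k = 0,
                          mm = measurement_model(bleach_amp = 0,
                                                 noise_sd = 0))
  expect_equal(g0$truth$rmg, rep(10, nrow(g0$truth)))
})

test_that("transcription assay is linear in activator with an early burst", {
  g <- gen_transcription_assay(c(20, 40), r_opt, circuit_config(50, 0),
                               mm = measurement_model(bleach_amp = 0,
                                                      noise_sd = 0),
                               t_end = 600)
  tr20 <- g$truth[["A_20"]]; tr40 <- g$truth[["A_40"]]
  late <- function(tr) {          # slope after the burst has decayed
    n <- nrow(tr)
    (tr$rmg[n] - tr$rmg[n - 10]) / (tr$t[n] - tr$t[n - 10])
  }
  expect_equal(late(tr40) / late(tr20), 2, tolerance = 1e-6)
  # initial slope exceeds the late slope by the burst factor (1 + B)
  early <- (tr20$rmg[2] - tr20$rmg[1]) / (tr20$t[2] - tr20$t[1])
  dr <- derived_rates(circuit_config(50, 0), r_opt)
  expect_equal(early / (dr$alpha2 * 20), 1 + r_opt$B, tolerance = 0.05)
  # B = 0: straight line through the origin
  r0 <- r_opt; r0$B <- 0
  g0 <- gen_transcription_assay(30, r0, circuit_config(50, 0),
                                mm = measurement_model(bleach_amp = 0,
                                                       noise_sd = 0))
  tr <- g0$truth[[1]]
  expect_rel_equal(tr$rmg[-1], dr$alpha2 * 30 * tr$t[-1], 1e-9)
  expect_error(gen_transcription_assay(100, r_opt, circuit_config(50, 0)),
               "exceed")
})

test_that("degradation assay shows catalytic rMG turnover", {
  mm0 <- measurement_model(bleach_amp = 0, noise_sd = 0)
  g <- gen_degradation_assay(rmg0 = 1000, img0 = 100, rnase_r = 75,
                             rates = r_opt, mm = mm0, t_end = 2000)
  # with gamma1 > 0 and beta2 = 0, total rMG degraded exceeds the iMG dose
  expect_gt(max(g$truth$degraded), 100)
  # without iMG nothing happens to rMG
  g0 <- gen_degradation_assay(rmg0 = 1000, img0 = 0, rnase_r = 75,
                              rates = r_opt, mm = mm0, t_end = 200)
  expect_rel_equal(g0$truth$rmg, 1000, 1e-9)
  # without binding nothing degrades
  rk0 <- r_opt; rk0$k <- 0
  gk0 <- gen_degradation_assay(rmg0 = 1000, img0 = 100, rnase_r = 75,
                               rates = rk0, mm = mm0, t_end = 200)
  expect_rel_equal(gk0$truth$rmg, 1000, 1e-9)
})

test_that("noise lives on the fluorescence scale only", {
  mm <- measurement_model(noise_sd = 5, seed = 3)
  g <- gen_circuit_assay(r_opt, cfg, sch20, mm,
                         options = sim_options(t_end = 60))
  expect_false(any(is.na(g$truth$y)))
  # truth is smooth; raw is not
  expect_lt(stats::sd(diff(g$truth$y, differences = 2)),
            stats::sd(diff(g$raw$signal, differences = 2)))
})
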