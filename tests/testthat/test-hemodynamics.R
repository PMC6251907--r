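test_that("closure time is the interpolated upward mitral flow crossing", {
  # step record: q_mv jumps from -10 to +5 at t = 0.1
  t <- seq(0, 0.3, by = 0.001)
  rec <- flow_record(t, q_mv = ifelse(t < 0.1, -10, 5),
                     q_av = rep(1, length(t)), systole = c(0, 0.3))
  expect_equal(reference_closure_time(rec), 0.1, tolerance = 5e-3)

  # piecewise-linear crossing: analytic root of the straddling segment
  t <- c(0, 0.05, 0.15, 0.3)
  q <- c(-8, -8, 4, 4)            # crosses at 0.05 + 8/12 * 0.1
  rec <- flow_record(t, q, q_av = rep(1, 4), systole = c(0, 0.3))
  expect_equal(reference_closure_time(rec), 0.05 + 8 / 12 * 0.1,
               tolerance = 1e-9)

  rec_pos <- flow_record(t, q_mv = rep(2, 4), q_av = rep(1, 4),
                         systole = c(0, 0.3))
  expect_error(reference_closure_time(rec_pos), "closure")
})

test_that("regurgitant volume splits into closing and leakage conservatively", {
  t <- seq(0, 0.4, by = 0.001)

  # non-negative mitral flow: all volumes zero
  rec0 <- flow_record(t, q_mv = pmax(sin(20 * t), 0), q_av = rep(1, length(t)),
                      systole = c(0, 0.4))
  v0 <- split_regurgitant_volume(rec0, 0.2)
  expect_equal(unlist(v0), c(closing = 0, leakage = 0, rv_mv = 0))

  # rectangular retrograde pulse of 1.0 ml entirely before t_close
  q <- ifelse(t >= 0.05 & t <= 0.15, -10, 0)
  rec <- flow_record(t, q, q_av = rep(1, length(t)), systole = c(0, 0.4))
  v <- split_regurgitant_volume(rec, 0.3)
  expect_equal(v$closing, 1.0, tolerance = 1e-2)
  expect_equal(v$leakage, 0)
  expect_equal(v$rv_mv, v$closing)

  # conservation: closing + leakage = total retrograde volume, same quadrature
  q2 <- -5 + 3 * sin(17 * t)
  rec2 <- flow_record(t, q2, q_av = rep(1, length(t)), systole = c(0, 0.4))
  for (tc in c(0.1, 0.2234, 0.35)) {
    v <- split_regurgitant_volume(rec2, tc)
    total <- -pracma::trapz(t, pmin(q2, 0))
    expect_equal(v$closing + v$leakage, total, tolerance = 1e-9)
    expect_equal(v$rv_mv, v$closing + v$leakage)
  }
  expect_error(split_regurgitant_volume(rec2, 5), "outside")
})

test_that("aortic volumes integrate forward and backward flow separately", {
  t <- seq(0, 0.5, by = 1e-4)
  q <- ifelse(t <= 0.3, 100, 0)
  rec <- flow_record(t, q_mv = rep(0.1, length(t)), q_av = q)
  av <- aortic_volumes(rec)
  expect_equal(av$sv_av, 30, tolerance = 0.1)
  expect_equal(av$rv_av, 0)

  q2 <- q - ifelse(t > 0.35 & t <= 0.4, 10, 0)
  av2 <- aortic_volumes(flow_record(t, rep(0.1, length(t)), q2))
  expect_equal(av2$rv_av, 0.5, tolerance = 0.01)

  # smooth sin^2 pulse: closed-form volume A * T / 2
  A <- 414; T <- 0.28
  q3 <- ifelse(t <= T, A * sin(pi * t / T)^2, 0)
  av3 <- aortic_volumes(flow_record(t, rep(0.1, length(t)), q3))
  expect_equal(av3$sv_av, A * T / 2, tolerance = A * T / 2 * 1e-3)
})

test_that("regurgitant fraction and grading follow the benchmark rules", {
  expect_equal(regurgitant_fraction(0, 60), 0)
  expect_equal(regurgitant_fraction(24.32, 41.94), 36.70, tolerance = 5e-3)
  expect_equal(regurgitant_fraction(10, 10), 50)
  expect_error(regurgitant_fraction(0, 0), "undefined")

  expect_equal(grade_mr(26.80)$grade, "mild")
  expect_equal(grade_mr(40.04)$grade, "moderate")
  g <- grade_mr(76.13)
  expect_equal(g$grade, "severe")
  expect_equal(g$aha_category, "severe")

  # step-function breakpoints at exactly 30 and 50
  expect_equal(grade_mr(30 - 1e-9)$grade, "mild")
  expect_equal(grade_mr(30)$grade, "moderate")
  expect_equal(grade_mr(50)$grade, "moderate")
  expect_equal(grade_mr(50)$aha_category, "progressive")
  expect_equal(grade_mr(50 + 1e-9)$grade, "severe")
  expect_error(grade_mr(101), "0, 100")

  # rf is monotone in rv_mv and bounded in [0, 100)
  rv <- seq(0, 500, by = 10)
  rf <- vapply(rv, regurgitant_fraction, 0, sv_av = 50)
  expect_true(all(diff(rf) > 0))
  expect_true(all(rf >= 0 & rf < 100))
})

test_that("hemodynamic summary satisfies its volume identities", {
  rec <- gen_waveforms(waveform_config(leak_rate = 20),
                       pressure_config("v_wave"))
  ctrl <- gen_waveforms()
  s <- summarize_hemodynamics(rec, control_record = ctrl)
  expect_equal(s$rv_mv, s$closing_volume + s$leakage_volume, tolerance = 1e-9)
  expect_equal(s$lvsv, s$sv_av + s$rv_mv)
  expect_true(s$rf_mv >= 0 && s$rf_mv <= 100)

  # self-application of the control: leakage small next to closing, mild
  sc <- summarize_hemodynamics(ctrl, control_record = ctrl)
  expect_lt(sc$leakage_volume, sc$closing_volume / 5)
  expect_equal(sc$grade, "mild")

  # no-regurgitation record: rf 0, mild
  clean <- gen_waveforms(waveform_config(leak_rate = 0,
                                         closing_spike_volume = 0,
                                         rebound_volume = 0))
  s0 <- summarize_hemodynamics(clean, t_close = 0.08)
  expect_equal(s0$rf_mv, 0, tolerance = 1e-6)
  expect_equal(s0$grade, "mild")
  expect_error(summarize_hemodynamics(rec), "control")
})

test_that("volumes converge under grid refinement", {
  coarse <- gen_waveforms(waveform_config(leak_rate = 15), dt = 2e-3)
  fine <- gen_waveforms(waveform_config(leak_rate = 15), dt = 1e-3)
  for (f in list(function(r) aortic_volumes(r)$sv_av,
                 function(r) split_regurgitant_volume(r, 0.06)$rv_mv)) {
    expect_lt(abs(f(coarse) - f(fine)) / f(fine), 0.002)
  }
})

test_that("scalar helpers reproduce the textbook identities", {
  expect_equal(ejection_fraction(113, 66), 100 * 66 / 113)
  expect_equal(round(ejection_fraction(113, 66)), 58)
  expect_error(ejection_fraction(100, 120), "sv")
  expect_equal(cardiac_cycle_duration(75), 0.8)
  expect_error(cardiac_cycle_duration(0), "positive")
})

test_that("flow CSV round-trips all channels", {
  rec <- gen_waveforms()
  f <- withr::local_tempfile(fileext = ".csv")
  write_flow_csv(rec, f)
  back <- read_flow_csv(f, systole = rec$systole)
  expect_equal(back$q_mv, rec$q_mv, tolerance = 1e-9)
  expect_equal(back$p_ao, rec$p_ao, tolerance = 1e-9)
  expect_equal(systolic_window(back), systolic_window(rec))
  expect_error(read_flow_csv(system.file("extdata",
                                         "reference_hemodynamics.csv",
                                         package = "chordaemr")),
               "missing required columns")
})
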