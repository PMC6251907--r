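# Synthetic left-heart data generator: one-cycle flow and pressure
# waveforms with a controllable regurgitation severity, and idealized
# pressure-volume loops. Every downstream analysis is testable against the
# generator's injected ground truth.
#
# Shapes are analytic pulses (sin^2 ejection and E/A inflow, a sin^2
# closing spike with a small positive rebound, and a smoothly ramped leak
# plateau), so every injected volume has a closed form.

#' Waveform generator configuration
#'
#' Defaults emulate the control (competent valve) condition: 75 bpm
#' (0.8 s cycle), 58.22 ml forward stroke volume with a 414 ml/s peak
#' aortic ejection, an 8.65 ml mitral closing spike and a sustained
#' systolic leak producing about 0.62 ml of leakage. `leak_rate` is the
#' regurgitation severity knob.
#'
#' @param heart_rate Heart rate, bpm.
#' @param sv_av_target Forward aortic stroke volume, ml.
#' @param peak_av_flow Peak aortic ejection flow, ml/s. Together with
#'   `sv_av_target` this sets the ejection duration
#'   `2 * sv_av_target / peak_av_flow` unless `ejection_duration` is given.
#' @param ejection_duration Optional explicit ejection duration, s.
#' @param e_a_ratio Peak ratio of the early (E) to atrial (A) diastolic
#'   mitral inflow waves.
#' @param closing_spike_volume Retrograde mitral volume of the closing
#'   spike, ml.
#' @param leak_rate Sustained systolic mitral leak rate, ml/s (the default
#'   produces about 0.62 ml of leakage over the control systole).
#' @param rv_av_volume Aortic backflow volume during valve closure, ml.
#' @param rebound_volume Small positive mitral rebound volume right after
#'   the closing spike, ml (gives the control record its mid-systolic
#'   upward flow crossing).
#' @param noise_sd Gaussian noise on both flow channels, ml/s (0 = none).
#' @param seed Integer seed for the noise stream.
#' @return An object of class `waveform_config`.
#' @export
waveform_config <- function(heart_rate = 75, sv_av_target = 58.22,
                            peak_av_flow = 414, ejection_duration = NULL,
                            e_a_ratio = 1.3, closing_spike_volume = 8.65,
                            leak_rate = 3.42, rv_av_volume = 4.27,
                            rebound_volume = 0.15, noise_sd = 0, seed = 1L) {
  stopifnot(heart_rate > 0, sv_av_target > 0, peak_av_flow > 0,
            closing_spike_volume >= 0, leak_rate >= 0, rv_av_volume >= 0,
            rebound_volume >= 0, noise_sd >= 0)
  cycle <- 60 / heart_rate
  t_ej <- if (is.null(ejection_duration)) 2 * sv_av_target / peak_av_flow
  else ejection_duration
  if (t_ej >= 0.6 * cycle)
    stop("waveform_config: ejection occupies too much of the cycle", call. = FALSE)
  structure(list(heart_rate = heart_rate, cycle = cycle,
                 sv_av_target = sv_av_target, peak_av_flow = peak_av_flow,
                 ejection_duration = t_ej, e_a_ratio = e_a_ratio,
                 closing_spike_volume = closing_spike_volume,
                 leak_rate = leak_rate, rv_av_volume = rv_av_volume,
                 rebound_volume = rebound_volume, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "waveform_config")
}

#' Atrial and aortic pressure configuration
#'
#' @param la_mode `"constant"` (competent valve inlet: constant atrial
#'   pressure) or `"v_wave"` (regurgitant conditions: a systolic half-sine
#'   V-wave added to the baseline).
#' @param la_constant Baseline left-atrial pressure, mmHg.
#' @param v_wave_peak Peak atrial pressure of the V-wave, mmHg (must be at
#'   least the baseline).
#' @param aortic_sys,aortic_dia Systolic / diastolic aortic pressure, mmHg.
#' @return An object of class `pressure_config`.
#' @export
pressure_config <- function(la_mode = c("constant", "v_wave"),
                            la_constant = 20, v_wave_peak = 35,
                            aortic_sys = 120, aortic_dia = 80) {
  la_mode <- match.arg(la_mode)
  stopifnot(la_constant > 0, aortic_sys > aortic_dia, aortic_dia > 0)
  if (la_mode == "v_wave" && v_wave_peak < la_constant)
    stop("pressure_config: v_wave_peak must be >= la_constant", call. = FALSE)
  structure(list(la_mode = la_mode, la_constant = la_constant,
                 v_wave_peak = v_wave_peak, aortic_sys = aortic_sys,
                 aortic_dia = aortic_dia),
            class = "pressure_config")
}

# sin^2 pulse of unit area on [a, b], evaluated at t (vectorised)
.sin2_pulse <- function(t, a, b) {
  y <- numeric(length(t))
  sel <- t >= a & t <= b
  y[sel] <- sin(pi * (t[sel] - a) / (b - a))^2 * 2 / (b - a)
  y
}

# unit-height plateau on [a, b] with sin^2 ramps of width w at both ends;
# exact integral is (b - a - w)
.ramped_plateau <- function(t, a, b, w) {
  y <- numeric(length(t))
  sel <- t >= a & t <= b
  tt <- t[sel]
  up <- tt < a + w
  dn <- tt > b - w
  v <- rep(1, length(tt))
  v[up] <- sin(pi * (tt[up] - a) / (2 * w))^2
  v[dn] <- sin(pi * (b - tt[dn]) / (2 * w))^2
  y[sel] <- v
  y
}

# internal timing layout shared by the generator and its ground truth
.waveform_timing <- function(config) {
  t_iso <- 0.02
  t_ej_end <- t_iso + config$ejection_duration
  # the closing spike sits just inside the ejection window, so the closing
  # volume is identical whether the systole markers travel with the record
  # or the window is re-detected from the aortic flow
  spike_on <- 0.025
  spike_off <- 0.08
  reb_off <- spike_off + 0.02
  leak_ramp <- 0.02
  list(t_iso = t_iso, t_ej_end = t_ej_end, t_sys_end = t_ej_end,
       spike_on = spike_on, spike_off = spike_off, reb_off = reb_off,
       leak_on = reb_off, leak_off = t_ej_end, leak_ramp = leak_ramp)
}

#' Leak rate producing a target leakage volume
#'
#' Inverts the generator's leak plateau geometry: the sustained systolic
#' leak at rate `r` injects `r * (leak window - ramp width)` ml of leakage.
#'
#' @param leak_volume Target leakage volume, ml.
#' @param config A [waveform_config()] (fixes the systolic timing).
#' @return Leak rate, ml/s.
#' @export
leak_rate_for_volume <- function(leak_volume, config) {
  tm <- .waveform_timing(config)
  eff <- tm$leak_off - tm$leak_on - tm$leak_ramp
  if (eff <= 0) stop("leak_rate_for_volume: no leak window", call. = FALSE)
  leak_volume / eff
}

#' Generate one cardiac cycle of synthetic flow and pressure waveforms
#'
#' Builds a [flow_record()] over one cycle: a sin^2 aortic ejection pulse
#' integrating exactly to the forward stroke volume, a small aortic
#' backflow pulse at valve closure, a negative mitral closing spike
#' followed by a small positive rebound and a sustained leak plateau over
#' systole, and a biphasic (E/A) diastolic mitral inflow whose volume
#' equals the systolic output (forward plus regurgitant), emulating
#' periodic steady state. Pressure channels follow the configured aortic
#' and atrial profiles; LV volume is the running integral of net inflow.
#' Deterministic for a fixed seed.
#'
#' @param config A [waveform_config()].
#' @param pressures A [pressure_config()].
#' @param dt Sample interval, s; must resolve the cycle with at least 200
#'   samples.
#' @return A [flow_record()] whose `meta$ground_truth` holds the injected
#'   closing, leakage and stroke volumes.
#' @export
gen_waveforms <- function(config = waveform_config(),
                          pressures = pressure_config(), dt = 1e-3) {
  if (dt > config$cycle / 200)
    stop("gen_waveforms: dt too coarse (need >= 200 samples per cycle)",
         call. = FALSE)
  tm <- .waveform_timing(config)
  if (config$leak_rate > 0 && tm$leak_off - tm$leak_on - tm$leak_ramp <= 0)
    stop(paste0("gen_waveforms: systole too short for the leak plateau; ",
                "lengthen the ejection (ejection_duration) or drop leak_rate"),
         call. = FALSE)
  t <- seq(0, config$cycle, by = dt)

  # aortic flow: ejection + closure backflow
  q_av <- config$sv_av_target * .sin2_pulse(t, tm$t_iso, tm$t_ej_end)
  bf_on <- tm$t_ej_end + 0.002
  q_av <- q_av - config$rv_av_volume * .sin2_pulse(t, bf_on, bf_on + 0.04)

  # mitral flow: closing spike, rebound, leak, diastolic E/A inflow
  q_mv <- -config$closing_spike_volume * .sin2_pulse(t, tm$spike_on, tm$spike_off)
  q_mv <- q_mv + config$rebound_volume * .sin2_pulse(t, tm$spike_off, tm$reb_off)
  q_mv <- q_mv - config$leak_rate *
    .ramped_plateau(t, tm$leak_on, tm$leak_off, tm$leak_ramp)
  leakage_gt <- config$leak_rate * (tm$leak_off - tm$leak_on - tm$leak_ramp)
  rv_mv_gt <- config$closing_spike_volume + leakage_gt

  v_in <- config$sv_av_target + rv_mv_gt
  e_on <- tm$t_ej_end + 0.06; e_off <- e_on + 0.22
  a_on <- config$cycle - 0.18; a_off <- config$cycle - 0.03
  if (a_on < e_off) { a_on <- e_off + 0.01; a_off <- min(a_on + 0.15, config$cycle - 0.01) }
  d_e <- e_off - e_on; d_a <- a_off - a_on
  p_a <- 2 * v_in / (config$e_a_ratio * d_e + d_a)
  p_e <- config$e_a_ratio * p_a
  q_mv <- q_mv + (p_e * d_e / 2) * .sin2_pulse(t, e_on, e_off) +
    (p_a * d_a / 2) * .sin2_pulse(t, a_on, a_off)

  if (config$noise_sd > 0) {
    rng <- .seeded_rng(config$seed)
    nz <- stats::qnorm(rng(2 * length(t))) * config$noise_sd
    q_av <- q_av + nz[seq_along(t)]
    q_mv <- q_mv + nz[length(t) + seq_along(t)]
  }

  # pressures
  p_ao <- pressures$aortic_dia +
    (pressures$aortic_sys - pressures$aortic_dia) *
    ifelse(t >= tm$t_iso & t <= tm$t_ej_end,
           sin(pi * (t - tm$t_iso) / (tm$t_ej_end - tm$t_iso))^2, 0) +
    5 * ifelse(t > tm$t_ej_end, exp(-(t - tm$t_ej_end) / 0.12), 0)
  p_la <- rep(pressures$la_constant, length(t))
  if (pressures$la_mode == "v_wave") {
    sel <- t <= tm$t_sys_end
    p_la[sel] <- p_la[sel] + (pressures$v_wave_peak - pressures$la_constant) *
      sin(pi * t[sel] / tm$t_sys_end)
  }
  p_lv <- pmax(8, ifelse(t <= tm$t_ej_end, p_ao + 5 * (t <= tm$t_ej_end), 10) *
                 ifelse(t <= tm$t_iso, t / tm$t_iso, 1))
  v_lv <- 113 + pracma::cumtrapz(t, q_mv - q_av)[, 1]

  flow_record(t, q_mv, q_av, p_ao = p_ao, p_la = p_la, p_lv = p_lv,
              v_lv = v_lv, systole = c(0, tm$t_sys_end),
              meta = list(config = config, pressures = pressures,
                          ground_truth = list(
                            closing = config$closing_spike_volume,
                            leakage = leakage_gt,
                            rv_mv = rv_mv_gt,
                            sv_av = config$sv_av_target,
                            rv_av = config$rv_av_volume,
                            t_close = tm$spike_off)))
}

#' Generate an idealized pressure-volume loop
#'
#' Four-phase loop through filling (low pressure, end-systolic to
#' end-diastolic volume), isovolumetric contraction, ejection with a
#' rounded pressure top, and isovolumetric relaxation. Defaults use an
#' end-diastolic volume of 113 ml and an end-systolic volume of 47 ml
#' (66 ml stroke volume). With `rounded = FALSE` the loop is the exact
#' rectangle spanning diastolic-to-systolic pressure, so its stroke work
#' has a closed form.
#'
#' @param edv End-diastolic volume, ml.
#' @param esv End-systolic volume, ml (`edv > esv > 0`).
#' @param pressures A [pressure_config()].
#' @param n_samples Total number of loop samples.
#' @param rounded Rounded physiologic shape (default) or exact rectangle.
#' @param p_fill Filling pressure bounds, mmHg.
#' @param p_es End-systolic (end-of-ejection) pressure for the rounded
#'   shape, mmHg.
#' @return A [pv_loop()].
#' @export
gen_pv_loop <- function(edv = 113, esv = 47, pressures = pressure_config(),
                        n_samples = 200, rounded = TRUE,
                        p_fill = c(8, 12), p_es = 90) {
  if (!(edv > esv && esv > 0))
    stop("gen_pv_loop: need edv > esv > 0", call. = FALSE)
  n4 <- max(2L, n_samples %/% 4L)
  s <- seq(0, 1, length.out = n4 + 1L)[-(n4 + 1L)]
  dia <- pressures$aortic_dia; sys <- pressures$aortic_sys
  if (rounded) {
    # ejection pressure: quadratic through (0, dia), (0.5, sys), (1, p_es)
    p_ej <- dia * 2 * (s - 0.5) * (s - 1) - sys * 4 * s * (s - 1) +
      p_es * 2 * s * (s - 0.5)
    fill_v <- esv + (edv - esv) * s
    fill_p <- p_fill[1] + (p_fill[2] - p_fill[1]) * s^2
    v <- c(fill_v, rep(edv, n4), edv - (edv - esv) * s, rep(esv, n4))
    p <- c(fill_p, p_fill[2] + (dia - p_fill[2]) * s, p_ej,
           p_es + (p_fill[1] - p_es) * s)
    es_index <- 3L * n4   # last ejection sample, at esv and ~p_es
  } else {
    v <- c(esv + (edv - esv) * s, rep(edv, n4), edv - (edv - esv) * s,
           rep(esv, n4))
    p <- c(rep(dia, n4), dia + (sys - dia) * s, rep(sys, n4),
           sys - (sys - dia) * s)
    es_index <- NULL
  }
  pv_loop(p, v, es_index = es_index)
}

#' Generate a suite of records across regurgitation severities
#'
#' One record per leak rate (sorted ascending severity), sharing the
#' control timing, plus a ground-truth table of the injected volumes for
#' recovery tests. Optional per-record overrides of the closing spike and
#' forward stroke volume emulate conditions where more extensive chordae
#' rupture also raises the closing volume and lowers the forward output;
#' the ejection duration is held at the base configuration's value so that
#' the closure time is common to the suite.
#'
#' @param base A [waveform_config()] for the control condition.
#' @param leak_rates Non-negative leak rates, ml/s, sorted ascending.
#' @param closing_volumes Optional per-record closing spike volumes, ml.
#' @param sv_av_targets Optional per-record forward stroke volumes, ml.
#' @param names Optional record names (default `severity_1`, ...).
#' @param pressures A [pressure_config()]; regurgitant records use a V-wave
#'   atrial profile when `v_wave = TRUE`.
#' @param v_wave Use an elevated V-wave atrial pressure for records with a
#'   nonzero leak.
#' @param dt Sample interval, s.
#' @return List with `records` (named list of [flow_record()]) and
#'   `ground_truth` (data frame of injected volumes).
#' @export
gen_severity_suite <- function(base = waveform_config(), leak_rates,
                               closing_volumes = NULL, sv_av_targets = NULL,
                               names = NULL,
                               pressures = pressure_config(),
                               v_wave = TRUE, dt = 1e-3) {
  stopifnot(all(leak_rates >= 0), !is.unsorted(leak_rates))
  n <- length(leak_rates)
  if (is.null(closing_volumes))
    closing_volumes <- rep(base$closing_spike_volume, n)
  if (is.null(sv_av_targets)) sv_av_targets <- rep(base$sv_av_target, n)
  if (is.null(names)) names <- sprintf("severity_%d", seq_len(n))
  stopifnot(length(closing_volumes) == n, length(sv_av_targets) == n,
            length(names) == n)
  records <- list(); gt <- list()
  for (i in seq_len(n)) {
    cfg <- waveform_config(
      heart_rate = base$heart_rate, sv_av_target = sv_av_targets[i],
      peak_av_flow = 2 * sv_av_targets[i] / base$ejection_duration,
      ejection_duration = base$ejection_duration,
      e_a_ratio = base$e_a_ratio,
      closing_spike_volume = closing_volumes[i],
      leak_rate = leak_rates[i], rv_av_volume = base$rv_av_volume,
      rebound_volume = base$rebound_volume, noise_sd = base$noise_sd,
      seed = base$seed + i)
    pc <- pressures
    if (v_wave && leak_rates[i] > leak_rates[1])
      pc <- pressure_config("v_wave", pressures$la_constant,
                            max(pressures$v_wave_peak, pressures$la_constant),
                            pressures$aortic_sys, pressures$aortic_dia)
    rec <- gen_waveforms(cfg, pc, dt)
    records[[names[i]]] <- rec
    g <- rec$meta$ground_truth
    gt[[i]] <- data.frame(name = names[i], leak_rate = leak_rates[i],
                          closing = g$closing, leakage = g$leakage,
                          rv_mv = g$rv_mv, sv_av = g$sv_av)
  }
  list(records = records, ground_truth = do.call(rbind, gt))
}
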