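# Mitral regurgitation quantification from transvalvular flow waveforms:
# closing/leakage volume split, regurgitant volumes and fraction, and
# severity grading.
#
# Sign convention: forward flow is positive for both valves (mitral LA->LV,
# aortic LV->aorta). Volumes are ml, time is seconds, integrals trapezoidal.

#' Synchronized flow / pressure record over a cardiac cycle
#'
#' Container for time series of transmitral and aortic flow, optional
#' pressures and left-ventricular volume over at least one cardiac cycle.
#'
#' @param time Time samples, s, strictly increasing.
#' @param q_mv Transmitral flow, ml/s, LA-to-LV positive.
#' @param q_av Aortic flow, ml/s, LV-to-aorta positive.
#' @param p_ao,p_la,p_lv Optional pressures, mmHg.
#' @param v_lv Optional LV volume, ml.
#' @param systole Optional length-2 numeric `c(start, end)` marking the
#'   systolic window, s. When absent it is detected from the aortic flow:
#'   from the first positive `q_av` sample until `q_av` returns to <= 0.
#' @param meta Optional list of generator/provenance metadata.
#' @return An object of class `flow_record`.
#' @export
flow_record <- function(time, q_mv, q_av, p_ao = NULL, p_la = NULL,
                        p_lv = NULL, v_lv = NULL, systole = NULL,
                        meta = list()) {
  n <- length(time)
  stopifnot(length(q_mv) == n, length(q_av) == n)
  if (any(diff(time) <= 0))
    stop("flow_record: time must be strictly increasing", call. = FALSE)
  if (any(!is.finite(q_mv)) || any(!is.finite(q_av)))
    stop("flow_record: flows must be finite", call. = FALSE)
  for (ch in list(p_ao = p_ao, p_la = p_la, p_lv = p_lv, v_lv = v_lv))
    if (!is.null(ch)) stopifnot(length(ch) == n)
  if (!is.null(systole)) {
    stopifnot(length(systole) == 2, systole[1] < systole[2])
    if (systole[1] < time[1] || systole[2] > time[n])
      stop("flow_record: systole markers outside the record span", call. = FALSE)
  }
  structure(list(time = as.numeric(time), q_mv = as.numeric(q_mv),
                 q_av = as.numeric(q_av), p_ao = p_ao, p_la = p_la,
                 p_lv = p_lv, v_lv = v_lv, systole = systole, meta = meta),
            class = "flow_record")
}

#' @export
print.flow_record <- function(x, ...) {
  cat(sprintf("Flow/pressure record: %d samples over %.3f s\n",
              length(x$time), diff(range(x$time))))
  sw <- systolic_window(x)
  cat(sprintf("  systole [%.3f, %.3f] s; channels: %s\n", sw[1], sw[2],
              paste(c("q_mv", "q_av",
                      names(Filter(Negate(is.null),
                                   x[c("p_ao", "p_la", "p_lv", "v_lv")]))),
                    collapse = ", ")))
  invisible(x)
}

#' Systolic window of a record
#'
#' Returns the explicit systole markers when present, otherwise detects the
#' window from the aortic flow: from the first strictly positive `q_av`
#' sample to the first time after the ejection peak at which `q_av` returns
#' to <= 0 (record end if it never does).
#'
#' @param record A [flow_record()].
#' @return Length-2 numeric `c(start, end)`, s.
#' @export
systolic_window <- function(record) {
  if (!is.null(record$systole)) return(record$systole)
  pos <- which(record$q_av > 0)
  if (!length(pos))
    stop("systolic_window: no positive aortic flow found", call. = FALSE)
  i0 <- pos[1]
  ipk <- pos[which.max(record$q_av[pos])]
  after <- which(record$q_av <= 0 & seq_along(record$q_av) > ipk)
  i1 <- if (length(after)) after[1] else length(record$time)
  c(record$time[i0], record$time[i1])
}

#' Mitral valve closure time of a control record
#'
#' Locates the first upward zero-crossing of the transmitral flow after the
#' onset of negative systolic mitral flow, by linear interpolation between
#' samples. This control-model crossover defines, for every valve
#' condition, the boundary between closing volume (retrograde flow during
#' leaflet closure) and leakage volume (retrograde flow after closure).
#'
#' @param control_record A [flow_record()] for the control (competent) valve.
#' @return Closure time, s.
#' @export
reference_closure_time <- function(control_record) {
  sw <- systolic_window(control_record)
  t <- control_record$time; q <- control_record$q_mv
  in_sys <- which(t >= sw[1] & t <= sw[2])
  neg <- in_sys[q[in_sys] < 0]
  if (!length(neg))
    stop("reference_closure_time: no negative systolic mitral flow (closure not detectable)",
         call. = FALSE)
  i_on <- neg[1]
  up <- which(q[-1] >= 0 & q[-length(q)] < 0)   # crossing between i and i+1
  up <- up[up >= i_on]
  if (!length(up))
    stop("reference_closure_time: no upward mitral flow crossing after closure onset",
         call. = FALSE)
  i <- up[1]
  if (q[i + 1] == q[i]) return(t[i + 1])
  t[i] + (0 - q[i]) * (t[i + 1] - t[i]) / (q[i + 1] - q[i])
}

#' Split the mitral regurgitant volume into closing and leakage volumes
#'
#' Integrates the retrograde (negative) transmitral flow over systole and
#' splits it at `t_close`: the closing volume accumulates from the onset of
#' negative systolic mitral flow to `t_close`, the leakage volume from
#' `t_close` to the end of systole. Trapezoidal quadrature on the sampled
#' grid with `t_close` inserted as an interpolated sample, so that
#' closing + leakage equals the total retrograde systolic volume exactly.
#'
#' @param record A [flow_record()].
#' @param t_close Closure time, s (e.g. [reference_closure_time()] of the
#'   control record).
#' @return List with `closing`, `leakage` and `rv_mv` (ml).
#' @export
split_regurgitant_volume <- function(record, t_close) {
  sw <- systolic_window(record)
  t <- record$time
  if (t_close < t[1] || t_close > t[length(t)])
    stop("split_regurgitant_volume: t_close outside the record", call. = FALSE)
  # insert t_close into the grid
  if (!t_close %in% t) {
    q_close <- stats::approx(t, record$q_mv, xout = t_close)$y
    ins <- which(t > t_close)[1]
    t <- append(t, t_close, after = ins - 1)
    q <- append(record$q_mv, q_close, after = ins - 1)
  } else q <- record$q_mv
  neg <- pmin(q, 0)
  seg_int <- function(a, b) {
    sel <- t >= a & t <= b
    if (sum(sel) < 2) return(0)
    -.trapz(t[sel], neg[sel])
  }
  closing <- seg_int(sw[1], min(max(t_close, sw[1]), sw[2]))
  leakage <- seg_int(min(max(t_close, sw[1]), sw[2]), sw[2])
  list(closing = closing, leakage = leakage, rv_mv = closing + leakage)
}

#' Forward and regurgitant aortic volumes
#'
#' Trapezoidal integrals of the positive (forward stroke volume) and
#' negative (early-diastolic backflow during aortic valve closure) parts of
#' the aortic flow over the record.
#'
#' @param record A [flow_record()].
#' @return List with `sv_av` and `rv_av` (ml).
#' @export
aortic_volumes <- function(record) {
  list(sv_av = .trapz(record$time, pmax(record$q_av, 0)),
       rv_av = -.trapz(record$time, pmin(record$q_av, 0)))
}

#' Mitral regurgitant fraction
#'
#' `RF = 100 * RV_MV / (SV_AV + RV_MV)`: the regurgitant volume as a
#' percentage of the total LV stroke volume `LVSV = SV_AV + RV_MV`.
#'
#' @param rv_mv Mitral regurgitant volume, ml.
#' @param sv_av Forward (aortic) stroke volume, ml.
#' @return Regurgitant fraction, percent.
#' @export
regurgitant_fraction <- function(rv_mv, sv_av) {
  if (rv_mv < 0 || sv_av < 0)
    stop("regurgitant_fraction: volumes must be non-negative", call. = FALSE)
  if (rv_mv + sv_av == 0)
    stop("regurgitant_fraction: undefined for zero total stroke volume",
         call. = FALSE)
  100 * rv_mv / (sv_av + rv_mv)
}

#' Grade mitral regurgitation severity from the regurgitant fraction
#'
#' Three-level grading: mild for RF < 30%, moderate for 30% <= RF <= 50%,
#' severe for RF > 50%; plus the binary guideline category (severe above
#' 50%, progressive otherwise).
#'
#' @param rf_mv Regurgitant fraction, percent, in `[0, 100]`.
#' @return List with `grade` (`"mild"`, `"moderate"`, `"severe"`) and
#'   `aha_category` (`"progressive"`, `"severe"`).
#' @export
grade_mr <- function(rf_mv) {
  if (rf_mv < 0 || rf_mv > 100)
    stop("grade_mr: rf_mv must lie in [0, 100]", call. = FALSE)
  grade <- if (rf_mv < 30) "mild" else if (rf_mv <= 50) "moderate" else "severe"
  list(grade = grade,
       aha_category = if (rf_mv > 50) "severe" else "progressive")
}

#' Global hemodynamic summary of one valve condition
#'
#' Assembles the full hemodynamic characterisation of a record: aortic
#' forward and regurgitant volumes, the closing/leakage split of the mitral
#' regurgitant volume (split at the control record's closure time), total
#' LV stroke volume, regurgitant fraction and severity grade.
#'
#' @param record A [flow_record()] for the condition of interest.
#' @param control_record A [flow_record()] for the control valve, used only
#'   to fix the closure time. If `NULL`, `t_close` must be given.
#' @param t_close Optional explicit closure time, s.
#' @return An object of class `hemo_summary`: list with `rv_av`,
#'   `closing_volume`, `leakage_volume`, `rv_mv`, `sv_av`, `lvsv`, `rf_mv`,
#'   `grade` and `aha_category`.
#' @export
summarize_hemodynamics <- function(record, control_record = NULL,
                                   t_close = NULL) {
  if (is.null(t_close)) {
    if (is.null(control_record))
      stop("summarize_hemodynamics: provide a control record or t_close",
           call. = FALSE)
    t_close <- reference_closure_time(control_record)
  }
  av <- aortic_volumes(record)
  mv <- split_regurgitant_volume(record, t_close)
  rf <- regurgitant_fraction(mv$rv_mv, av$sv_av)
  gr <- grade_mr(rf)
  structure(list(rv_av = av$rv_av, closing_volume = mv$closing,
                 leakage_volume = mv$leakage, rv_mv = mv$rv_mv,
                 sv_av = av$sv_av, lvsv = av$sv_av + mv$rv_mv,
                 rf_mv = rf, grade = gr$grade,
                 aha_category = gr$aha_category, t_close = t_close),
            class = "hemo_summary")
}

#' @export
print.hemo_summary <- function(x, ...) {
  cat("Global hemodynamic summary\n")
  cat(sprintf("  SV_AV %.2f ml, RV_AV %.2f ml\n", x$sv_av, x$rv_av))
  cat(sprintf("  closing %.2f ml + leakage %.2f ml = RV_MV %.2f ml\n",
              x$closing_volume, x$leakage_volume, x$rv_mv))
  cat(sprintf("  LVSV %.2f ml, RF_MV %.2f%% -> %s MR (%s)\n",
              x$lvsv, x$rf_mv, x$grade, x$aha_category))
  invisible(x)
}

#' Ejection fraction from end-diastolic and stroke volume
#'
#' `EF = 100 * SV / EDV` (percent).
#'
#' @param edv End-diastolic volume, ml.
#' @param sv Stroke volume, ml.
#' @return Ejection fraction, percent.
#' @export
ejection_fraction <- function(edv, sv) {
  if (edv <= 0 || sv < 0 || sv > edv)
    stop("ejection_fraction: need 0 <= sv <= edv, edv > 0", call. = FALSE)
  100 * sv / edv
}

#' Cardiac cycle duration from heart rate
#'
#' @param bpm Heart rate, beats per minute.
#' @return Cycle duration, s.
#' @export
cardiac_cycle_duration <- function(bpm) {
  if (bpm <= 0) stop("cardiac_cycle_duration: bpm must be positive", call. = FALSE)
  60 / bpm
}

#' Read / write a flow record as CSV
#'
#' CSV schema: columns `time_s, q_mv_ml_s, q_av_ml_s` and optional
#' `p_ao_mmHg, p_la_mmHg, p_lv_mmHg, v_lv_ml`; header required. Systole
#' markers, when known, travel in the companion JSON written by the
#' generator.
#'
#' @param record A [flow_record()].
#' @param path File path.
#' @param systole Optional explicit markers used when reading.
#' @return `read_flow_csv` returns a `flow_record`; `write_flow_csv`
#'   returns `path` invisibly.
#' @export
write_flow_csv <- function(record, path) {
  df <- data.frame(time_s = record$time, q_mv_ml_s = record$q_mv,
                   q_av_ml_s = record$q_av)
  if (!is.null(record$p_ao)) df$p_ao_mmHg <- record$p_ao
  if (!is.null(record$p_la)) df$p_la_mmHg <- record$p_la
  if (!is.null(record$p_lv)) df$p_lv_mmHg <- record$p_lv
  if (!is.null(record$v_lv)) df$v_lv_ml <- record$v_lv
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_flow_csv
#' @export
read_flow_csv <- function(path, systole = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("time_s", "q_mv_ml_s", "q_av_ml_s")
  if (!all(need %in% names(df)))
    stop("read_flow_csv: missing required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  grab <- function(col) if (col %in% names(df)) df[[col]] else NULL
  flow_record(df$time_s, df$q_mv_ml_s, df$q_av_ml_s,
              p_ao = grab("p_ao_mmHg"), p_la = grab("p_la_mmHg"),
              p_lv = grab("p_lv_mmHg"), v_lv = grab("v_lv_ml"),
              systole = systole)
}
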