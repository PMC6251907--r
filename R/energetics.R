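# Pressure-volume loop energetics: stroke work, forward stroke work,
# end-systolic potential energy, pressure-volume area and LV efficiency.

# 1 mmHg.ml in joules
MMHG_ML_TO_J <- 1.33322e-4

#' Left-ventricular pressure-volume loop
#'
#' One closed cardiac cycle of LV pressure (mmHg) against LV volume (ml),
#' ordered in time. The loop is closed: first and last samples coincide
#' within `close_tol` (a duplicated closing point is accepted but not
#' required).
#'
#' @param pressure Pressure samples, mmHg.
#' @param volume Volume samples, ml, positive.
#' @param es_index,ed_index Optional indices of the end-systolic and
#'   end-diastolic points. When absent, end-systole is the point maximising
#'   `P / (V - v0)` (see [potential_energy()]) and end-diastole the point of
#'   maximum volume.
#' @param close_tol Closure tolerance, relative to the pressure/volume spans.
#' @return An object of class `pv_loop`.
#' @export
pv_loop <- function(pressure, volume, es_index = NULL, ed_index = NULL,
                    close_tol = 1e-6) {
  stopifnot(length(pressure) == length(volume), length(pressure) >= 3)
  if (any(volume <= 0))
    stop("pv_loop: volumes must be positive", call. = FALSE)
  n <- length(pressure)
  sp <- max(diff(range(pressure)), 1e-12); sv <- max(diff(range(volume)), 1e-12)
  closed <- abs(pressure[1] - pressure[n]) <= close_tol * sp &&
    abs(volume[1] - volume[n]) <= close_tol * sv
  if (closed && n > 3) { pressure <- pressure[-n]; volume <- volume[-n] }
  structure(list(pressure = pressure, volume = volume,
                 es_index = es_index, ed_index = ed_index),
            class = "pv_loop")
}

#' @export
print.pv_loop <- function(x, ...) {
  cat(sprintf("PV loop: %d samples, V in [%.1f, %.1f] ml, P in [%.1f, %.1f] mmHg\n",
              length(x$volume), min(x$volume), max(x$volume),
              min(x$pressure), max(x$pressure)))
  cat(sprintf("  stroke work %.4f J\n", stroke_work(x)))
  invisible(x)
}

# end-systolic point: maximum P/(V - v0), unless fixed by the loop
.es_point <- function(loop, v0 = 0) {
  if (!is.null(loop$es_index)) return(loop$es_index)
  r <- loop$pressure / pmax(loop$volume - v0, 1e-9)
  which.max(r)
}

#' Stroke work: area of the pressure-volume loop
#'
#' Shoelace polygon area of the closed loop in mmHg.ml, converted to joules
#' (1 mmHg.ml = 1.33322e-4 J). The physiologic (counter-clockwise in the
#' V-P plane) orientation yields positive area; a clockwise loop is
#' auto-corrected with a warning.
#'
#' @param loop A [pv_loop()].
#' @return Stroke work, J.
#' @export
stroke_work <- function(loop) {
  v <- loop$volume; p <- loop$pressure
  n <- length(v)
  j <- c(2:n, 1)
  area <- 0.5 * sum(v * p[j] - v[j] * p)   # signed, + for CCW in (V, P)
  if (area < 0) {
    warning("stroke_work: loop traversed clockwise; sign corrected")
    area <- -area
  }
  area * MMHG_ML_TO_J
}

#' Forward stroke work through the aortic valve
#'
#' Time integral over systole of the product of forward aortic flow and
#' aortic pressure, converted to joules: the external work actually
#' delivered to the circulation (regurgitant flow does not contribute).
#'
#' @param record A [flow_record()] carrying `q_av` and `p_ao`.
#' @return Forward stroke work, J.
#' @export
forward_stroke_work <- function(record) {
  if (is.null(record$p_ao))
    stop("forward_stroke_work: record has no aortic pressure channel",
         call. = FALSE)
  sw <- systolic_window(record)
  sel <- record$time >= sw[1] & record$time <= sw[2]
  .trapz(record$time[sel],
         pmax(record$q_av[sel], 0) * record$p_ao[sel]) * MMHG_ML_TO_J
}

#' End-systolic potential energy
#'
#' The mechanical energy stored in the ventricular wall at end-systole that
#' is not converted to external work: the triangular area under the linear
#' end-systolic pressure-volume relation between the volume intercept `v0`
#' and the end-systolic point, `PE = 0.5 * p_es * (v_es - v0)`, converted
#' to joules.
#'
#' @param p_es End-systolic pressure, mmHg.
#' @param v_es End-systolic volume, ml.
#' @param v0 ESPVR volume-axis intercept, ml (default 0).
#' @return Potential energy, J.
#' @export
potential_energy <- function(p_es, v_es, v0 = 0) {
  if (v_es < v0)
    stop("potential_energy: v_es must be >= v0", call. = FALSE)
  0.5 * p_es * (v_es - v0) * MMHG_ML_TO_J
}

#' Left-ventricular efficiency
#'
#' Percentage of the total mechanical energy of contraction (pressure-volume
#' area, `PVA = PE + SW`) converted into forward stroke work:
#' `100 * fSW / PVA`.
#'
#' @param fsw Forward stroke work, J, non-negative.
#' @param pva Pressure-volume area, J, positive.
#' @return Efficiency, percent.
#' @export
lv_efficiency <- function(fsw, pva) {
  if (pva <= 0) stop("lv_efficiency: pva must be positive", call. = FALSE)
  if (fsw < 0) stop("lv_efficiency: fsw must be non-negative", call. = FALSE)
  100 * fsw / pva
}

#' Energetic summary of one valve condition
#'
#' Assembles stroke work (loop area), forward stroke work (aortic flow x
#' pressure integral), end-systolic potential energy, pressure-volume area
#' `PVA = PE + SW` and LV efficiency `100 * fSW / PVA`.
#'
#' @param loop A [pv_loop()].
#' @param record A [flow_record()] with aortic pressure.
#' @param v0 ESPVR volume intercept, ml.
#' @return An object of class `energetics_summary`: list with `sw`, `fsw`,
#'   `pe`, `pva` (J) and `efficiency` (percent).
#' @export
summarize_energetics <- function(loop, record, v0 = 0) {
  sw <- stroke_work(loop)
  fsw <- forward_stroke_work(record)
  ies <- .es_point(loop, v0)
  pe <- potential_energy(loop$pressure[ies], loop$volume[ies], v0)
  pva <- pe + sw
  structure(list(sw = sw, fsw = fsw, pe = pe, pva = pva,
                 efficiency = lv_efficiency(fsw, pva),
                 es_index = ies),
            class = "energetics_summary")
}

#' @export
print.energetics_summary <- function(x, ...) {
  cat("LV energetics\n")
  cat(sprintf("  SW %.4f J, fSW %.4f J, PE %.4f J, PVA %.4f J\n",
              x$sw, x$fsw, x$pe, x$pva))
  cat(sprintf("  LV efficiency %.2f%%\n", x$efficiency))
  invisible(x)
}

#' Read / write a pressure-volume loop as CSV
#'
#' CSV schema: columns `p_mmHg, v_ml` (+ optional `time_s`), header
#' required.
#'
#' @param loop A [pv_loop()].
#' @param path File path.
#' @return `read_pv_csv` returns a `pv_loop`; `write_pv_csv` returns
#'   `path` invisibly.
#' @export
write_pv_csv <- function(loop, path) {
  utils::write.csv(data.frame(p_mmHg = loop$pressure, v_ml = loop$volume),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pv_csv
#' @export
read_pv_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("p_mmHg", "v_ml") %in% names(df)))
    stop("read_pv_csv: need columns p_mmHg and v_ml", call. = FALSE)
  pv_loop(df$p_mmHg, df$v_ml)
}
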