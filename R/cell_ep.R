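# Single-cell atrial action-potential model (Hodgkin-Huxley formalism).
# Six currents: fast sodium I_Na, L-type calcium I_CaL, rapid and slow
# delayed-rectifier potassium I_Kr / I_Ks, inward rectifier I_K1, and a
# background leak. The three conductance scale factors s_Kr, s_Ks, s_CaL
# are the knobs the twin calibration adjusts.

# Flat parameter layout shared with the C++ solver. Order matters.
.cell_param_layout <- c(
  "g_Na", "g_CaL", "g_Kr", "g_Ks", "g_K1", "g_leak",
  "s_Kr", "s_Ks", "s_CaL",
  "E_Na", "E_K", "E_Ca", "E_leak", "C_m",
  "m_vh", "m_k", "m_tau0", "m_tauA", "m_tauV", "m_tauS",
  "h_vh", "h_k", "h_tau0", "h_tauA", "h_tauV", "h_tauK",
  "d_vh", "d_k", "d_tau0", "d_tauA", "d_tauV", "d_tauS",
  "f_vh", "f_k", "f_tau0", "f_tauA", "f_tauV", "f_tauS",
  "xr_vh", "xr_k", "xr_tau0", "xr_tauA", "xr_tauV", "xr_tauS",
  "rkr_vh", "rkr_k",
  "xs_vh", "xs_k", "xs_tau0", "xs_tauA", "xs_tauV", "xs_tauS",
  "k1_k", "k1_vh"
)

#' Default atrial cell parameters
#'
#' Builds the full constant set of the minimal six-current atrial cell:
#' maximal conductances (mS/cm^2), reversal potentials (mV), membrane
#' capacitance (uF/cm^2), gating rate constants per current, and the three
#' dimensionless conductance scale factors \code{s_Kr}, \code{s_Ks},
#' \code{s_CaL} (1 = nominal). Constants are tuned so that at 1 Hz pacing
#' the baseline beat has APD90 near 280 ms and resting potential near
#' -80 mV. Any constant can be overridden by name.
#'
#' @param ... named overrides of individual constants (see
#'   \code{poaftwin:::.cell_param_layout} for the full name list), e.g.
#'   \code{cell_params(s_Kr = 0.8)}.
#' @return An object of class \code{cell_params}: a named numeric vector of
#'   all model constants.
#' @export
cell_params <- function(...) {
  p <- c(
    g_Na = 11, g_CaL = 0.40, g_Kr = 0.12, g_Ks = 0.12, g_K1 = 0.20,
    g_leak = 0.012,
    s_Kr = 1, s_Ks = 1, s_CaL = 1,
    E_Na = 65, E_K = -87, E_Ca = 52, E_leak = -30, C_m = 1,
    m_vh = -40, m_k = 6, m_tau0 = 0.12, m_tauA = 0.40, m_tauV = -40, m_tauS = 25,
    h_vh = -68, h_k = 6.5, h_tau0 = 1.0, h_tauA = 14, h_tauV = -67, h_tauK = 8,
    d_vh = -10, d_k = 6.2, d_tau0 = 1.0, d_tauA = 2.0, d_tauV = -10, d_tauS = 30,
    f_vh = -27, f_k = 7, f_tau0 = 180, f_tauA = 400, f_tauV = -25, f_tauS = 30,
    xr_vh = -14, xr_k = 7, xr_tau0 = 80, xr_tauA = 350, xr_tauV = -20, xr_tauS = 25,
    rkr_vh = -15, rkr_k = 22,
    xs_vh = 4, xs_k = 12, xs_tau0 = 250, xs_tauA = 200, xs_tauV = 10, xs_tauS = 40,
    k1_k = 0.07, k1_vh = -80
  )
  stopifnot(identical(names(p), .cell_param_layout))
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) stop("unknown cell parameter(s): ", paste(bad, collapse = ", "))
    p[names(ov)] <- unlist(ov)
  }
  if (any(p[c("g_Na", "g_CaL", "g_Kr", "g_Ks", "g_K1", "g_leak")] < 0))
    stop("conductances must be >= 0")
  if (any(p[c("s_Kr", "s_Ks", "s_CaL")] < 0)) stop("scale factors must be >= 0")
  if (p[["C_m"]] <= 0) stop("C_m must be > 0")
  class(p) <- "cell_params"
  p
}

#' Load / save cell parameters as YAML
#'
#' @param path file path.
#' @param params a \code{cell_params} object.
#' @return \code{read_cell_params} returns a \code{cell_params} object;
#'   \code{write_cell_params} returns \code{path} invisibly.
#' @export
read_cell_params <- function(path) {
  v <- unlist(yaml::read_yaml(path))
  do.call(cell_params, as.list(v))
}

#' @rdname read_cell_params
#' @export
write_cell_params <- function(params, path) {
  yaml::write_yaml(as.list(unclass(params)), path)
  invisible(path)
}

#' Replace conductance scale factors
#'
#' Returns a copy of \code{params} with the \code{s_Kr}, \code{s_Ks},
#' \code{s_CaL} scale factors replaced; the input is untouched.
#'
#' @param params a \code{cell_params} object.
#' @param s_Kr,s_Ks,s_CaL non-negative dimensionless scales applied to the
#'   corresponding maximal conductances.
#' @return A new \code{cell_params} object.
#' @export
scale_conductances <- function(params, s_Kr = 1, s_Ks = 1, s_CaL = 1) {
  stopifnot(inherits(params, "cell_params"))
  if (any(c(s_Kr, s_Ks, s_CaL) < 0)) stop("scale factors must be >= 0")
  params[["s_Kr"]] <- s_Kr
  params[["s_Ks"]] <- s_Ks
  params[["s_CaL"]] <- s_CaL
  params
}

# Default stimulus: rectangular pulse, 2 ms, amplitude set at roughly
# 1.5x the diastolic threshold of the default cell (see find_stim_threshold).
.default_stim <- list(amp = 23, dur_ms = 2)
.v_init <- -80.8

#' Simulate a paced action-potential train
#'
#' Integrates the six-current cell with classical fourth-order Runge-Kutta
#' at a fixed step. A rectangular stimulus of \code{stim_amp} uA/uF for
#' \code{stim_dur_ms} ms is delivered at the start of each cycle.
#'
#' @param params a \code{cell_params} object.
#' @param cycle_length_ms pacing cycle length (ms); 1000 = 1 Hz.
#' @param n_beats number of paced beats (>= 1); use \code{n_beats = 0} with
#'   a positive \code{duration_ms} for an unstimulated run.
#' @param dt_ms integration step (ms).
#' @param stim_amp,stim_dur_ms stimulus amplitude (uA/uF) and duration (ms).
#' @param duration_ms only for \code{n_beats = 0}: unstimulated duration.
#' @return An \code{ap_trace}: list with \code{time} (ms, uniform grid),
#'   \code{v} (mV), \code{stimulus_times} (ms), \code{cycle_length_ms},
#'   \code{dt_ms}.
#' @export
simulate_ap <- function(params = cell_params(), cycle_length_ms = 1000,
                        n_beats = 3, dt_ms = 0.02,
                        stim_amp = .default_stim$amp,
                        stim_dur_ms = .default_stim$dur, duration_ms = NULL) {
  stopifnot(inherits(params, "cell_params"), dt_ms > 0, n_beats >= 0)
  if (n_beats == 0) {
    if (is.null(duration_ms)) stop("duration_ms required when n_beats = 0")
    m <- .cell_run_cpp(unclass(params), duration_ms, 1, dt_ms, 0, 0, .v_init)
    stim <- numeric(0)
  } else {
    m <- .cell_run_cpp(unclass(params), cycle_length_ms, as.integer(n_beats),
                       dt_ms, stim_amp, stim_dur_ms, .v_init)
    stim <- (seq_len(n_beats) - 1) * cycle_length_ms
  }
  structure(list(time = m[, 1], v = m[, 2], stimulus_times = stim,
                 cycle_length_ms = cycle_length_ms, dt_ms = dt_ms),
            class = "ap_trace")
}

#' Action-potential summary metrics for one beat
#'
#' APD90 is measured from activation (time of maximum upstroke velocity)
#' to 90\% repolarization toward the pre-stimulus diastolic potential, with
#' linear interpolation at the crossing.
#'
#' @param trace an \code{ap_trace} from \code{\link{simulate_ap}}.
#' @param beat_index which paced beat to analyze (default: last).
#' @return List with \code{apd90_ms}, \code{v_rest_mv}, \code{v_peak_mv},
#'   \code{dvdt_max_mv_per_ms}.
#' @export
ap_metrics <- function(trace, beat_index = length(trace$stimulus_times)) {
  stopifnot(inherits(trace, "ap_trace"))
  if (length(trace$stimulus_times) < 1 || beat_index < 1 ||
      beat_index > length(trace$stimulus_times))
    stop("beat_index outside the stimulated beats of the trace")
  t0 <- trace$stimulus_times[beat_index]
  t1 <- t0 + trace$cycle_length_ms
  sel <- trace$time >= t0 & trace$time <= min(t1, max(trace$time))
  tt <- trace$time[sel]
  vv <- trace$v[sel]
  v_dia <- vv[1]
  dvdt <- diff(vv) / diff(tt)
  i_act <- which.max(dvdt)
  if (dvdt[i_act] < 5 || max(vv) < -10) stop("no capture: no upstroke detected in beat window")
  t_act <- tt[i_act]
  v_peak <- max(vv)
  v90 <- v_peak - 0.9 * (v_peak - v_dia)
  i_pk <- which.max(vv)
  post <- seq(i_pk, length(vv))
  cross <- which(vv[post][-length(post)] > v90 & vv[post][-1] <= v90)
  if (!length(cross)) stop("no capture: beat does not repolarize to 90% within window")
  ia <- post[cross[1]]; ib <- ia + 1
  frac <- (vv[ia] - v90) / (vv[ia] - vv[ib])
  t90 <- tt[ia] + frac * (tt[ib] - tt[ia])
  list(apd90_ms = t90 - t_act, v_rest_mv = v_dia, v_peak_mv = v_peak,
       dvdt_max_mv_per_ms = dvdt[i_act])
}

#' Diastolic stimulus threshold by bisection
#'
#' Finds the minimal 2 ms rectangular stimulus amplitude that captures the
#' default beat, by bisection on amplitude.
#'
#' @param params a \code{cell_params} object.
#' @param dt_ms integration step.
#' @param tol amplitude tolerance (uA/uF).
#' @return Threshold amplitude in uA/uF.
#' @export
find_stim_threshold <- function(params = cell_params(), dt_ms = 0.05, tol = 0.25) {
  captures <- function(a) {
    tr <- simulate_ap(params, cycle_length_ms = 500, n_beats = 1, dt_ms = dt_ms,
                      stim_amp = a)
    max(tr$v) > -10
  }
  lo <- 0; hi <- 40
  if (!captures(hi)) stop("no capture even at maximal test amplitude")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (captures(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Export an AP trace as a two-column CSV (time_ms, v_mv)
#'
#' @param trace an \code{ap_trace}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_ap_trace <- function(trace, path) {
  utils::write.csv(data.frame(time_ms = trace$time, v_mv = trace$v),
                   path, row.names = FALSE)
  invisible(path)
}
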