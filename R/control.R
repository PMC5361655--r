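# R-side surface of the spinal controller: gait-event detection on recorded
# contact histories, exact delay-buffer reads, a single-evaluation wrapper of
# the reflex network, and the wiring table that documents which afferent
# drives which muscle in which phase.

#' Detect gait events and phase labels from a contact history
#'
#' Heel strike is the swing-to-contact transition of a foot, toe-off the
#' release of contact; both are timestamped to the history's sampling step.
#' Phase labels per leg: `early_stance` (heel strike until the contralateral
#' toe-off), `late_stance` (double support with this leg trailing, i.e. after
#' the contralateral heel strike), `swing`, and `late_swing` (last 30% of the
#' expected swing time). Stride fraction resets to 0 at each heel strike.
#'
#' @param history Tibble with columns `time`, `contact_l`, `contact_r`
#'   (logical, or numeric loads thresholded at > 0).
#' @return A `gait_phase_state` list: `$events` (time, leg, event) and
#'   `$phases` (time, leg, phase, stride_frac).
#' @export
detect_gait_events <- function(history) {
  stopifnot(all(c("time", "contact_l", "contact_r") %in% names(history)))
  tm <- history$time
  cl <- as.logical(history$contact_l > 0)
  cr <- as.logical(history$contact_r > 0)
  ev <- list()
  for (leg in c("l", "r")) {
    cc <- if (leg == "l") cl else cr
    d <- diff(cc)
    hs <- which(d == 1) + 1
    to <- which(d == -1) + 1
    if (length(hs)) ev[[paste0(leg, "hs")]] <-
      tibble(time = tm[hs], leg = leg, event = "heel_strike")
    if (length(to)) ev[[paste0(leg, "to")]] <-
      tibble(time = tm[to], leg = leg, event = "toe_off")
  }
  events <- if (length(ev)) dplyr::arrange(dplyr::bind_rows(ev), .data$time)
            else tibble(time = numeric(), leg = character(), event = character())
  if (nrow(events) == 0) warn("no contact transitions in window; phase state unchanged")

  phases <- dplyr::bind_rows(lapply(c("l", "r"), function(leg) {
    cc <- if (leg == "l") cl else cr
    oc <- if (leg == "l") cr else cl
    e_own <- events[events$leg == leg, ]
    hs_t <- e_own$time[e_own$event == "heel_strike"]
    to_t <- e_own$time[e_own$event == "toe_off"]
    e_oth <- events[events$leg != leg, ]
    ohs_t <- e_oth$time[e_oth$event == "heel_strike"]
    last_of <- function(tt, t) if (any(tt <= t)) max(tt[tt <= t]) else NA_real_
    stride_T <- if (length(hs_t) >= 2) mean(diff(hs_t)) else NA_real_
    purrr::map_dfr(seq_along(tm), function(i) {
      t <- tm[i]
      lhs <- last_of(hs_t, t); lto <- last_of(to_t, t); lohs <- last_of(ohs_t, t)
      sf <- if (!is.na(lhs) && !is.na(stride_T)) (t - lhs) / stride_T else NA_real_
      ph <- if (cc[i]) {
        trailing <- !is.na(lohs) && (is.na(lhs) || lohs > lhs) && oc[i]
        if (trailing) "late_stance" else "early_stance"
      } else {
        swdur <- if (!is.na(stride_T)) 0.38 * stride_T else Inf
        if (!is.na(lto) && (t - lto) > 0.7 * swdur) "late_swing" else "swing"
      }
      tibble(time = t, leg = leg, phase = ph, stride_frac = sf)
    })
  }))
  structure(list(events = events, phases = phases), class = "gait_phase_state")
}

#' @export
print.gait_phase_state <- function(x, ...) {
  cat(sprintf("<gait_phase_state> %d events over %d samples\n",
              nrow(x$events), nrow(x$phases) / 2))
  invisible(x)
}

#' Read a delayed sample from a signal history
#'
#' Returns the sample recorded at `t - delay`, quantized to the history's
#' (uniform) sampling step — the same convention the simulator's internal
#' ring buffers use for afferent transport delays.
#'
#' @param history Tibble with columns `time` and `value`, uniformly sampled.
#' @param delay Transport delay (s), non-negative.
#' @param t Read time (s).
#' @return The delayed sample value.
#' @export
delay_buffer_read <- function(history, delay, t) {
  stopifnot(delay >= 0, nrow(history) >= 2)
  dt <- history$time[2] - history$time[1]
  idx <- round((t - delay - history$time[1]) / dt) + 1
  if (idx < 1 || t - delay < history$time[1] - dt / 2)
    abort(sprintf(
      "history starts at %.4f s but a read at t = %.4f s with delay %.4f s needs %.4f s; warm up the buffer by %.4f s",
      history$time[1], t, delay, t - delay, history$time[1] - (t - delay)))
  if (idx > nrow(history)) abort("read time is beyond the recorded history")
  history$value[idx]
}

#' One evaluation of the phase-gated reflex network
#'
#' Maps (already delay-read) afferent signals to per-muscle stimulations for
#' both legs, exactly as the simulator does each step. Stimulations are
#' clamped to `[stim_min, 1]`; pathways only contribute in their gated phase
#' (stance weight `w_st`, swing weight `1 - w_st`, trailing-leg double
#' support `ds`).
#'
#' @param afferents 18 x 3 matrix (rows: muscles, left leg then right, in
#'   [muscle_names()] order; columns: force, length, velocity afferents in
#'   normalized units).
#' @param phase List with `w_st`, `ds`, `swing_frac` (each length 2, left,
#'   right), `lean`, `lean_rate`, `load` (length 2), `knee`, `knee_rate`
#'   (length 2).
#' @param params Named reflex-parameter vector.
#' @return Tibble with `muscle`, `leg`, `stimulation`.
#' @export
compute_stimulations <- function(afferents, phase, params = default_reflex_params()) {
  stopifnot(is.matrix(afferents), nrow(afferents) == 18, ncol(afferents) == 3)
  ph <- modifyList(list(w_st = c(1, 1), ds = c(0, 0), swing_frac = c(0, 0),
                        lean = 0.1, lean_rate = 0, load = c(1, 1),
                        knee = c(0.3, 0.3), knee_rate = c(0, 0)), phase)
  s <- rg_control_cpp(afferents, ph$lean, ph$lean_rate, ph$load, ph$w_st,
                      ph$ds, ph$swing_frac, ph$knee, ph$knee_rate, params)
  tibble(muscle = rep(MUSCLES, 2), leg = rep(c("l", "r"), each = 9),
         stimulation = as.numeric(s))
}

#' Reflex wiring table
#'
#' Documents every pathway of the spinal network: which afferent (or postural
#' signal) drives which muscle, in which gait phase, through which gain
#' parameter, and with what sign. The soleus stance pathway carries force
#' feedback only — it has no length- or velocity-afferent term, which is the
#' structural ground truth behind the correlation-confound analysis.
#'
#' @return Tibble with columns `muscle`, `phase`, `source`, `signal`,
#'   `gain_param`, `sign`.
#' @export
reflex_wiring <- function() {
  tibble::tribble(
    ~muscle, ~phase, ~source, ~signal, ~gain_param, ~sign,
    "SOL", "stance", "SOL", "force", "G_SOL", 1,
    "GAS", "stance", "GAS", "force", "G_GAS", 1,
    "VAS", "stance", "VAS", "force", "G_VAS", 1,
    "VAS", "stance", "knee", "angle", "k_ko", -1,
    "VAS", "late_stance", "contralateral_load", "load", "k_dsVAS", -1,
    "TA", "always", "TA", "length", "G_TA", 1,
    "TA", "stance", "SOL", "force", "G_SOLTA", -1,
    "GLU", "stance", "trunk", "lean_pd", "c_GLU_bal", 1,
    "HFL", "stance", "trunk", "lean_pd", "c_HFL_bal", -1,
    "HAM", "stance", "trunk", "lean_pd", "c_HAM_bal", 1,
    "HFL", "late_stance", "phase", "constant", "ds_HFL", 1,
    "GLU", "late_stance", "phase", "constant", "ds_GLU", -1,
    "HFL", "swing", "HFL", "length", "G_HFL", 1,
    "HFL", "swing", "HAM", "length", "G_HAMHFL", -1,
    "HFL", "swing", "trunk", "lean", "k_lean_HFL", 1,
    "HAM", "swing", "HAM", "force", "G_HAM", 1,
    "GLU", "swing", "GLU", "force", "G_GLU_sw", 1,
    "BFSH", "swing", "phase", "constant", "sw_BFSH", 1
  )
}
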