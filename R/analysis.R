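# Response extraction and comparison statistics: per-trial muscle responses,
# condition-indexed trends, band-overlap similarity with exact optimal linear
# scaling, amplitude ratios, proprioceptive-signal change ratios, and the
# correlation-based velocity-feedback attribution.

# default response windows (s after onset) per protocol
.RESP_WINDOWS <- list(mmr = c(0.000, 0.040), tr = c(0.000, 0.040),
                      sr = c(0.010, 0.060), trip = c(0.020, 0.100),
                      slip = c(0.020, 0.150))

#' Default response window of a protocol
#' @param protocol Protocol name.
#' @return Length-2 numeric, seconds after disturbance onset.
#' @export
response_window <- function(protocol) .RESP_WINDOWS[[match.arg(tolower(protocol),
                                                              PROTOCOLS)]]

#' Extract a scalar response from a paired trace
#'
#' The response is the signed peak (default) or mean of the
#' disturbed-minus-undisturbed difference within the response window.
#'
#' @param trace Tibble with columns `time`, `disturbed`, `undisturbed` on a
#'   shared grid.
#' @param onset Disturbance onset time (s).
#' @param window Length-2 window (s after onset).
#' @param stat `"peak"` (signed extremum) or `"mean"`.
#' @return Scalar response.
#' @export
extract_response <- function(trace, onset, window, stat = c("peak", "mean")) {
  stat <- match.arg(stat)
  stopifnot(all(c("time", "disturbed", "undisturbed") %in% names(trace)))
  lo <- onset + window[1]; hi <- onset + window[2]
  if (hi > max(trace$time) + 1e-9 || lo < min(trace$time) - 1e-9)
    abort(sprintf("response window [%.3f, %.3f] s exceeds the trace [%.3f, %.3f] s",
                  lo, hi, min(trace$time), max(trace$time)))
  sel <- trace$time >= lo - 1e-12 & trace$time <= hi + 1e-12
  d <- trace$disturbed[sel] - trace$undisturbed[sel]
  if (!length(d)) return(0)
  if (stat == "mean") return(mean(d))
  d[which.max(abs(d))]
}

#' Width of an evoked activation spike
#'
#' Full width of the contiguous interval, containing the response peak, over
#' which the evoked response (disturbed minus undisturbed activation) stays
#' above `frac` of its peak — the burst-duration convention used for the
#' afferent-stimulation responses.
#'
#' @param trace Tibble with `time`, `disturbed`, `undisturbed`.
#' @param onset Disturbance onset (s).
#' @param search Window after onset in which the spike must lie (s).
#' @param frac Onset/offset threshold as a fraction of the evoked peak.
#' @return Width in seconds.
#' @export
spike_width <- function(trace, onset, search = c(0, 0.1), frac = 0.2) {
  sel <- trace$time >= onset + search[1] & trace$time <= onset + search[2]
  tm <- trace$time[sel]
  d <- trace$disturbed[sel] - trace$undisturbed[sel]
  ipk <- which.max(d)
  if (!length(ipk) || d[ipk] <= 0) return(0)
  thr <- frac * d[ipk]
  above <- d > thr
  lo <- ipk; while (lo > 1 && above[lo - 1]) lo <- lo - 1
  hi <- ipk; while (hi < length(d) && above[hi + 1]) hi <- hi + 1
  tm[hi] - tm[lo]
}

# pull a muscle activation trace pair out of two gait_sims on a shared grid
.act_pair <- function(disturbed, undisturbed, muscle, leg = "r") {
  col <- paste(tolower(muscle), leg, "act", sep = "_")
  n <- min(nrow(disturbed$trajectory), nrow(undisturbed$trajectory))
  tibble(time = disturbed$trajectory$time[seq_len(n)],
         disturbed = disturbed$trajectory[[col]][seq_len(n)],
         undisturbed = undisturbed$trajectory[[col]][seq_len(n)])
}

#' Build condition-indexed response trends from a protocol run
#'
#' For every realizable condition and every requested muscle, extracts the
#' signed peak activation change in the protocol's response window
#' (disturbed minus matched undisturbed trial, both launched from the same
#' limit-cycle snapshot).
#'
#' @param run A [run_protocol()] result.
#' @param muscles Muscle names (default: the six with reference data).
#' @param window Response window override (s after onset).
#' @param stat Passed to [extract_response()].
#' @return A `response_trend` tibble: `muscle`, `condition`, `value`
#'   (condition axis), `response`.
#' @export
response_trend <- function(run, muscles = c("HAM", "RF", "VAS", "GAS", "SOL", "TA"),
                           window = NULL, stat = "peak") {
  stopifnot(inherits(run, "protocol_trials"))
  if (is.null(window)) window <- response_window(run$protocol)
  rows <- list()
  for (i in seq_len(nrow(run$manifest))) {
    m <- run$manifest[i, ]
    if (!isTRUE(m$realizable)) next
    onset <- m$onset
    if (is.na(onset)) next
    if (isTRUE(m$fell) && m$fall_time < onset + window[2]) next
    trial <- run$trials[[i]]
    for (mus in muscles) {
      tr <- .act_pair(trial, run$undisturbed, mus, run$leg)
      resp <- extract_response(tr, onset, window, stat)
      rows[[length(rows) + 1]] <- tibble(
        muscle = mus, condition = m$condition, value = m$value, response = resp)
    }
  }
  out <- dplyr::bind_rows(rows)
  structure(dplyr::arrange(out, .data$muscle, .data$condition),
            class = c("response_trend", class(out)))
}

#' Normalize a reference band to unit peak mean
#'
#' Means are divided by the maximum absolute mean; standard deviations by the
#' same factor, so the band keeps its shape. Idempotent.
#'
#' @param band Tibble with columns `condition`, `mean`, `sd` (raw units), or
#'   two vectors via `mean`/`sd` arguments.
#' @return A `reference_band` tibble (`condition`, `mean`, `sd`), peak
#'   |mean| = 1.
#' @export
normalize_reference <- function(band) {
  stopifnot(all(c("mean", "sd") %in% names(band)))
  peak <- max(abs(band$mean))
  if (peak == 0) abort("all reference means are zero; cannot normalize")
  if (any(band$sd < 0)) abort("reference s.d. must be non-negative")
  out <- band
  out$mean <- band$mean / peak
  out$sd <- band$sd / peak
  if (is.null(out$condition)) out$condition <- seq_len(nrow(out))
  structure(as_tibble(out), class = c("reference_band", class(as_tibble(out))))
}

# exact optimal nonnegative scaling: maximize #conditions with
# |k*m_i - mu_i| <= sd_i; ties broken by minimal sum of squared residuals.
.scale_breakpoints <- function(m, mu, sd) {
  base <- sum(m == 0 & abs(mu) <= sd)
  act <- which(m != 0)
  cnt_at <- function(k)
    sum(abs(k * m[act] - mu[act]) <= sd[act])   # same comparison as an oracle scan
  if (!length(act)) return(list(k = 0, count = base))
  lo <- pmin((mu[act] - sd[act]) / m[act], (mu[act] + sd[act]) / m[act])
  hi <- pmax((mu[act] - sd[act]) / m[act], (mu[act] + sd[act]) / m[act])
  keep <- hi >= 0
  lo <- pmax(lo[keep], 0); hi <- hi[keep]
  khat <- sum(m * mu) / sum(m * m)              # unconstrained SSR minimizer
  if (!length(lo)) return(list(k = max(0, khat), count = base))
  # candidate points: the breakpoints and the midpoints between consecutive
  # ones (every maximal-count region contains one of these)
  bp <- sort(unique(c(0, lo, hi)))
  mids <- if (length(bp) > 1) (head(bp, -1) + tail(bp, -1)) / 2 else numeric()
  cand <- c(bp, mids)
  counts <- vapply(cand, cnt_at, integer(1))
  best <- max(counts)
  # tie-break: among maximizing candidates, move toward the SSR optimum while
  # keeping the count (projection of khat onto each maximizing region)
  winners <- cand[counts == best]
  extra <- numeric()
  for (i in seq_along(mids)) {
    if (counts[length(bp) + i] == best) {
      k_p <- min(max(khat, bp[i]), bp[i + 1])
      if (cnt_at(k_p) == best) extra <- c(extra, k_p)
      else {
        # boundary roundoff: retreat slightly into the open region
        d <- (bp[i + 1] - bp[i]) * 1e-9
        k_p2 <- min(max(khat, bp[i] + d), bp[i + 1] - d)
        if (cnt_at(k_p2) == best) extra <- c(extra, k_p2)
      }
    }
  }
  winners <- c(winners, extra)
  ssr <- vapply(winners, function(k) sum((k * m - mu)^2), numeric(1))
  list(k = max(winners[which.min(ssr)], 0), count = base + best)
}

#' Optimal linear scaling of a model trend into a reference band
#'
#' Finds the single nonnegative factor `k` that maximizes the number of
#' conditions whose scaled model response lies within one standard deviation
#' of the reference mean, by exact sweep over the interval breakpoints
#' `(mean_i +- sd_i) / model_i`; ties are broken by the smallest sum of
#' squared residuals to the mean. Reports the overlap percentage, the
#' similarity statistic of the band comparison.
#'
#' @param model_trend A [response_trend()] for one muscle (or tibble with a
#'   `response` column, or bare numeric vector), one value per condition.
#' @param band A normalized [normalize_reference()] band with matching
#'   condition axis.
#' @param offset Also fit an additive offset (sensitivity analysis only;
#'   responses are baseline-subtracted, so the default maps zero to zero).
#'   The affine fit alternates exact one-dimensional sweeps in scale and
#'   offset.
#' @return A `similarity_result` one-row tibble: `scale`, `offset`,
#'   `n_within`, `n_total`, `percent`.
#' @export
scale_to_band <- function(model_trend, band, offset = FALSE) {
  m <- if (is.numeric(model_trend)) model_trend else model_trend$response
  stopifnot(all(c("mean", "sd") %in% names(band)))
  if (length(m) != nrow(band))
    abort(sprintf("model trend has %d conditions but the band has %d",
                  length(m), nrow(band)))
  b <- 0
  res <- .scale_breakpoints(m, band$mean, band$sd)
  if (offset) {
    for (it in 1:5) {
      res <- .scale_breakpoints(m, band$mean - b, band$sd)
      # exact 1-D offset sweep given the scale: intervals for b
      lo <- band$mean - band$sd - res$k * m
      hi <- band$mean + band$sd - res$k * m
      cand <- c(lo, hi, (lo + hi) / 2)
      cnt <- vapply(cand, function(bb)
        sum(abs(res$k * m + bb - band$mean) <= band$sd), integer(1))
      b <- cand[which.max(cnt)]
    }
    res$count <- sum(abs(res$k * m + b - band$mean) <= band$sd)
  }
  out <- tibble(scale = res$k, offset = b, n_within = res$count,
                n_total = length(m),
                percent = 100 * res$count / length(m))
  structure(out, class = c("similarity_result", class(out)),
            model = m, band = band)
}

#' Response-amplitude ratio of model to reference
#'
#' Both trends are first expressed relative to their own background peak
#' (peak undisturbed activation of the same muscle), then the ratio of peak
#' absolute responses is reported in percent. Amplitudes are only compared
#' for the mechanically replicated whole-joint/whole-body protocols
#' (SR, TRIP, SLIP).
#'
#' @param model_trend,reference_trend Numeric vectors (or tibbles with a
#'   `response`/`mean` column) of responses across conditions.
#' @param model_background,reference_background Peak background activation
#'   used to normalize each side (default 1: trends already normalized).
#' @return Amplitude ratio in percent.
#' @export
amplitude_ratio <- function(model_trend, reference_trend,
                            model_background = 1, reference_background = 1) {
  m <- if (is.numeric(model_trend)) model_trend else model_trend$response
  r <- if (is.numeric(reference_trend)) reference_trend
       else if (!is.null(reference_trend$response)) reference_trend$response
       else reference_trend$mean
  stopifnot(model_background > 0, reference_background > 0)
  pr <- max(abs(r)) / reference_background
  if (pr == 0) abort("reference trend has zero peak; amplitude ratio undefined")
  pm <- max(abs(m)) / model_background
  100 * pm / pr
}

# normalized afferent signals of one muscle from a trajectory
.aff_cols <- function(traj, ms, muscle, leg) {
  p <- function(v) paste(tolower(muscle), leg, v, sep = "_")
  row <- ms[ms$muscle == muscle, ]
  tibble(time = traj$time,
         force = traj[[p("force")]] / row$F_max,
         length = traj[[p("l_ce")]] / row$l_opt,
         velocity = traj[[p("v_ce")]] / (row$v_max * row$l_opt))
}

#' Peak afferent-signal changes caused by a protocol run
#'
#' For each muscle of the target leg and each proprioceptive signal type
#' (normalized force, length, velocity), the peak absolute difference
#' between disturbed and undisturbed trials, maximized over the protocol's
#' realizable conditions.
#'
#' @param run A [run_protocol()] result.
#' @param muscles Muscles to include (default all nine).
#' @param epoch Evaluation epoch after the condition onset (s): only the
#'   immediate response counts, not the later divergence of the recovery
#'   steps.
#' @return Tibble `muscle`, `signal`, `change`.
#' @export
afferent_changes <- function(run, muscles = muscle_names(), epoch = 0.15) {
  stopifnot(inherits(run, "protocol_trials"))
  ms <- muscle_set(run$model)
  leg <- run$leg
  rows <- list()
  for (i in seq_len(nrow(run$manifest))) {
    m <- run$manifest[i, ]
    if (!isTRUE(m$realizable)) next
    # a fall AFTER the analysis epoch does not invalidate the immediate response
    if (isTRUE(m$fell) && (is.na(m$onset) || m$fall_time < m$onset + epoch)) next
    trial <- run$trials[[i]]
    n <- min(nrow(trial$trajectory), nrow(run$undisturbed$trajectory))
    for (mus in muscles) {
      a1 <- .aff_cols(trial$trajectory[seq_len(n), ], ms, mus, leg)
      a0 <- .aff_cols(run$undisturbed$trajectory[seq_len(n), ], ms, mus, leg)
      sel <- if (!is.na(m$onset))
        a1$time >= m$onset & a1$time <= m$onset + epoch else TRUE
      for (sig in c("force", "length", "velocity")) {
        rows[[length(rows) + 1]] <- tibble(
          muscle = mus, signal = sig, condition = m$condition,
          change = max(abs(a1[[sig]][sel] - a0[[sig]][sel])))
      }
    }
  }
  if (!length(rows))
    abort("no usable trials: all conditions were unrealizable or fell within the epoch")
  dplyr::bind_rows(rows) |>
    dplyr::group_by(.data$muscle, .data$signal) |>
    dplyr::summarise(change = max(.data$change), .groups = "drop")
}

#' Ratio of proprioceptive-signal changes: joint perturbation vs whole-body
#'
#' Compares how strongly the imposed ankle stretch (SR) alters the muscles'
#' force, length and velocity afferents relative to the tripping and slipping
#' disturbances, which act on the muscles only through the body's mechanical
#' inertia. Returns the maximum, over muscles and signal types, of the
#' SR-to-TRIP and SR-to-SLIP change ratios; signals with (near-)zero
#' denominator are excluded.
#'
#' @param sr_run,trip_run,slip_run [run_protocol()] results from matched
#'   snapshots.
#' @param muscles Muscles to include.
#' @param min_change Exclusion threshold for denominators (normalized units).
#' @return List: `max_ratio`, and the per-muscle/signal `table`.
#' @export
proprioceptive_change_ratio <- function(sr_run, trip_run, slip_run,
                                        muscles = muscle_names(),
                                        min_change = 1e-6) {
  a_sr <- afferent_changes(sr_run, muscles)
  a_tr <- afferent_changes(trip_run, muscles)
  a_sl <- afferent_changes(slip_run, muscles)
  tab <- a_sr |>
    dplyr::rename(sr = "change") |>
    dplyr::left_join(dplyr::rename(a_tr, trip = "change"), by = c("muscle", "signal")) |>
    dplyr::left_join(dplyr::rename(a_sl, slip = "change"), by = c("muscle", "signal")) |>
    dplyr::mutate(
      ratio_trip = ifelse(.data$trip > min_change, .data$sr / .data$trip, NA_real_),
      ratio_slip = ifelse(.data$slip > min_change, .data$sr / .data$slip, NA_real_))
  ratios <- c(tab$ratio_trip, tab$ratio_slip)
  if (all(is.na(ratios))) abort("all denominators excluded; no ratio defined")
  list(max_ratio = max(ratios, na.rm = TRUE), table = tab)
}

#' Correlation-based velocity-feedback attribution (the confound analysis)
#'
#' Reproduces the classic experimental estimate: regress the soleus response
#' amplitude on the imposed ankle angular-velocity change across
#' stance-phase ankle perturbation trials, then apply the fitted slope to
#' the undisturbed stance dorsiflexion-velocity profile and express the
#' "velocity-attributed" activation as a percentage of the total mean
#' soleus stance activation. In this model the soleus stance pathway has
#' structurally zero velocity gain, so any nonzero attribution demonstrates
#' the confound.
#'
#' @param trials Tibble with one row per perturbation trial: `dvel` (imposed
#'   ankle angular-velocity change, rad/s) and `response` (peak soleus
#'   activation change).
#' @param stance Tibble describing undisturbed stance samples: `ankle_vel`
#'   (rad/s, dorsiflexion positive) and `activation` (soleus).
#' @param rectify Use only dorsiflexion (positive) velocities when projecting
#'   the slope (default TRUE; plantarflexion cannot excite a stretch response).
#' @return List: `percent` (attributed contribution), `slope`
#'   (activation per rad/s), `fit` (the `lm`).
#' @export
velocity_feedback_contribution <- function(trials, stance, rectify = TRUE) {
  stopifnot(all(c("dvel", "response") %in% names(trials)),
            all(c("ankle_vel", "activation") %in% names(stance)))
  if (nrow(trials) < 4) abort("need at least 4 perturbation trials")
  if (sd(trials$dvel) < 1e-9)
    abort("imposed velocity changes are degenerate; cannot regress")
  fit <- lm(response ~ dvel, data = trials)
  slope <- coef(fit)[["dvel"]]
  v <- stance$ankle_vel
  if (rectify) v <- pmax(v, 0)
  attributed <- slope * v
  pct <- 100 * mean(attributed) / mean(stance$activation)
  list(percent = pct, slope = slope, fit = fit)
}

#' Stance-phase ankle-perturbation sweep for the attribution analysis
#'
#' Runs imposed ankle dorsiflexion ramps of varying speed at a fixed stance
#' phase, measures the imposed ankle angular-velocity change and the soleus
#' response per trial, and collects the undisturbed stance profile.
#'
#' @param params,snap,model,ground As in [run_protocol()].
#' @param velocities Ramp speeds (rad/s). The defaults (30-150 deg/s) keep
#'   the perturbation gentle enough that the stance leg stays loaded — a
#'   ramp violent enough to unload the leg gates the stance pathways off and
#'   contaminates the regression; trials where the load gate collapses are
#'   flagged with a warning.
#' @param phase_frac Stride fraction of the onset (stance; default 0.3).
#' @param amp Ramp amplitude (rad, default 8 degrees).
#' @param window Response window (s after onset).
#' @param ... Passed to [run_trial()].
#' @return List of `trials` and `stance` tibbles for
#'   [velocity_feedback_contribution()].
#' @export
velocity_probe <- function(params, snap, model = scale_anthropometry(),
                           ground = ground_model(),
                           velocities = c(30, 60, 90, 120, 150) * pi / 180,
                           phase_frac = 0.3, amp = 8 * pi / 180,
                           window = NULL, ...) {
  if (is.null(window)) window <- response_window("sr")
  t0 <- snap$snapshot$t + phase_frac * snap$stride_period
  dur <- (t0 - snap$snapshot$t) + 0.35
  undist <- run_trial(snap, NULL, params, model, ground, duration = dur, ...)
  leg <- "r"
  vcol <- paste0("dankle_", leg); acol <- paste0("sol_", leg, "_act")
  rows <- list()
  for (vv in velocities) {
    d <- disturbance("sr", t0 = t0, leg = leg, vel = vv, amp = amp)
    tr <- run_trial(snap, d, params, model, ground, duration = dur, ...)
    n <- min(nrow(tr$trajectory), nrow(undist$trajectory))
    tt <- tr$trajectory$time[seq_len(n)]
    dv <- tr$trajectory[[vcol]][seq_len(n)] - undist$trajectory[[vcol]][seq_len(n)]
    sel <- tt >= t0 & tt <= t0 + amp / vv
    dvel <- mean(dv[sel])   # mean imposed velocity change over the ramp
    trace <- .act_pair(tr, undist, "SOL", leg)
    resp <- extract_response(trace, t0, window)
    lsel <- tt >= t0 & tt <= t0 + window[2]
    # the smoothed stance weight is the signal that actually gates the
    # pathways; a collapse there contaminates the regression
    unloaded <- any(tr$trajectory[[paste0("wst_", leg)]][seq_len(n)][lsel] < 0.7)
    if (unloaded)
      warn(sprintf("ramp at %.0f deg/s unloaded the stance leg; regression may be contaminated",
                   vv * 180 / pi))
    rows[[length(rows) + 1]] <- tibble(vel = vv, dvel = dvel, response = resp,
                                       unloaded = unloaded)
  }
  # undisturbed stance profile of the target leg
  u <- undist$trajectory
  st <- u$load_r > 0.1
  stance <- tibble(ankle_vel = u[[vcol]][st], activation = u[[acol]][st])
  list(trials = dplyr::bind_rows(rows), stance = stance, undisturbed = undist)
}
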