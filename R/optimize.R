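# Gait optimization: metabolic cost of a trajectory, the walking cost
# J = C_E + c_v * |v_avg - v_tgt|, and a covariance-matrix-adapting
# evolution strategy over the reflex parameters with a staged objective
# (progress without falling first, then speed, then cost).

#' Metabolic energy of a trajectory
#'
#' Muscle-level energy rate: activation/maintenance heat
#' `alpha_A * a^2 * F_max * l_opt`, shortening and lengthening heat
#' proportional to contractile power, plus positive contractile work.
#' Additive over muscles and time (trapezoidal in time).
#'
#' @param traj A `gait_sim` or its trajectory tibble.
#' @param muscles A [muscle_set()] matching the trajectory's body.
#' @param constants `c(alpha_A, alpha_S, alpha_L)` energy-rate constants
#'   (1/s, -, -).
#' @return Energy in joules.
#' @export
metabolic_energy <- function(traj, muscles = muscle_set(),
                             constants = c(0.5, 0.25, 0.05)) {
  if (inherits(traj, "gait_sim")) traj <- traj$trajectory
  tm <- traj$time
  rate <- rep(0, nrow(traj))
  for (leg in c("l", "r")) for (i in seq_len(nrow(muscles))) {
    mus <- tolower(muscles$muscle[i])
    a <- traj[[paste(mus, leg, "act", sep = "_")]]
    f <- traj[[paste(mus, leg, "force", sep = "_")]]
    v <- traj[[paste(mus, leg, "v_ce", sep = "_")]]
    w <- f * v
    rate <- rate + constants[1] * a^2 * muscles$F_max[i] * muscles$l_opt[i] +
      constants[2] * pmax(w, 0) + constants[3] * pmax(-w, 0) + pmax(w, 0)
  }
  sum(diff(tm) * (head(rate, -1) + tail(rate, -1)) / 2)
}

#' Evaluate the walking cost of a parameter set
#'
#' Runs the model for `transient + window` seconds from a standing start.
#' Without a fall, the cost is exactly `J = C_E + c_v * |v_avg - v_tgt|`
#' with `c_v = 100`, where `C_E` is the metabolic energy over the
#' evaluation window and `v_avg` the average forward speed over it. A fall
#' is scored by a penalty that decreases with the distance walked, so
#' partial progress is rewarded.
#'
#' @param params Reflex parameters.
#' @param v_tgt Target speed (m/s).
#' @param window Evaluation window (s) after the transient; should cover at
#'   least 10 strides.
#' @param transient Discarded settling time (s).
#' @param model,ground,dt As in [simulate_walk()].
#' @param c_v Speed-error weight (J per m/s).
#' @param ... Passed to [simulate_walk()].
#' @return A `cost_terms` one-row tibble: `J`, `C_E`, `c_v`, `v_avg`,
#'   `v_tgt`, `distance`, `fell`, `strides`.
#' @export
evaluate_cost <- function(params, v_tgt, window = 15, transient = 5,
                          model = scale_anthropometry(),
                          ground = ground_model(), dt = 1e-4, c_v = 100, ...) {
  sim <- simulate_walk(params, model = model, ground = ground,
                       duration = transient + window, dt = dt, v0 = v_tgt,
                       record_stride = 100L, ...)
  tr <- sim$trajectory
  if (sim$fall) {
    out <- tibble(J = 1e6 / (1 + max(sim$distance, 0)), C_E = NA_real_,
                  c_v = c_v, v_avg = NA_real_, v_tgt = v_tgt,
                  distance = sim$distance, fell = TRUE, strides = NA_integer_,
                  saturation = NA_real_, stride_period = NA_real_)
  } else {
    win <- tr$time >= sim$t_start + transient
    x <- tr$x[win]; tt <- tr$time[win]; em <- tr$e_met[win]
    v_avg <- (x[length(x)] - x[1]) / (tt[length(tt)] - tt[1])
    C_E <- em[length(em)] - em[1]
    hs <- sim$events$time[sim$events$event == "heel_strike" &
                            sim$events$leg == "r" &
                            sim$events$time >= sim$t_start + transient]
    stim_cols <- grep("_stim$", names(tr), value = TRUE)
    sat <- mean(as.matrix(tr[win, stim_cols]) > 0.95)
    out <- tibble(J = C_E + c_v * abs(v_avg - v_tgt), C_E = C_E, c_v = c_v,
                  v_avg = v_avg, v_tgt = v_tgt, distance = sim$distance,
                  fell = FALSE, strides = length(hs), saturation = sat,
                  stride_period = sim$stride_period)
    if (length(hs) < 10)
      warn(sprintf("evaluation window covers only %d strides (< 10)", length(hs)))
  }
  structure(out, class = c("cost_terms", class(out)), sim = sim)
}

#' Minimal covariance-matrix-adapting evolution strategy
#'
#' Standard (mu/mu_w, lambda) CMA-ES with rank-mu update, used by
#' [optimize_gait()]; exposed for testing against analytic optima.
#'
#' @param fn Objective to minimize (vector in, scalar out).
#' @param x0 Start point.
#' @param sigma0 Initial step size.
#' @param lower,upper Box bounds (candidates clipped).
#' @param lambda Population size (default `4 + floor(3 log n)`).
#' @param budget Maximum objective evaluations.
#' @param seed RNG seed.
#' @return List: `par`, `value`, `evals`, `history` tibble (generation,
#'   best-so-far value).
#' @export
cma_es <- function(fn, x0, sigma0 = 0.3, lower = -Inf, upper = Inf,
                   lambda = NULL, budget = 1000, seed = 1) {
  n <- length(x0)
  if (is.null(lambda)) lambda <- 4 + floor(3 * log(n))
  lower <- rep_len(lower, n); upper <- rep_len(upper, n)
  mu <- floor(lambda / 2)
  w <- log(mu + 0.5) - log(seq_len(mu)); w <- w / sum(w)
  mueff <- 1 / sum(w^2)
  cc <- (4 + mueff / n) / (n + 4 + 2 * mueff / n)
  cs <- (mueff + 2) / (n + mueff + 5)
  c1 <- 2 / ((n + 1.3)^2 + mueff)
  cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((n + 2)^2 + mueff))
  damps <- 1 + 2 * max(0, sqrt((mueff - 1) / (n + 1)) - 1) + cs
  chiN <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))

  with_seed(seed, {
    xmean <- as.numeric(x0); sigma <- sigma0
    pc <- ps <- rep(0, n); C <- diag(n)
    best_x <- xmean; best_f <- Inf; evals <- 0; gen <- 0
    hist <- list()
    # evaluate the initial candidate first so budget = 1 returns it
    best_f <- fn(pmin(pmax(xmean, lower), upper)); evals <- 1
    best_x <- pmin(pmax(xmean, lower), upper)
    hist[[1]] <- tibble(generation = 0L, best = best_f, evals = 1L)
    while (evals < budget) {
      gen <- gen + 1
      eig <- eigen(C, symmetric = TRUE)
      D <- sqrt(pmax(eig$values, 1e-20)); B <- eig$vectors
      nthis <- min(lambda, budget - evals)
      Z <- matrix(rnorm(n * lambda), n, lambda)
      Y <- B %*% (D * Z)
      X <- xmean + sigma * Y
      Xc <- pmin(pmax(X, lower), upper)
      f <- rep(Inf, lambda)
      for (k in seq_len(nthis)) f[k] <- fn(Xc[, k])
      evals <- evals + nthis
      ord <- order(f)
      if (f[ord[1]] < best_f) { best_f <- f[ord[1]]; best_x <- Xc[, ord[1]] }
      hist[[length(hist) + 1]] <- tibble(generation = gen, best = best_f,
                                         evals = as.integer(evals))
      sel <- ord[seq_len(mu)]
      yw <- as.numeric(Y[, sel, drop = FALSE] %*% w)
      xmean <- xmean + sigma * yw
      Cinvsq <- B %*% ((1 / D) * t(B))
      ps <- (1 - cs) * ps + sqrt(cs * (2 - cs) * mueff) * as.numeric(Cinvsq %*% yw)
      hsig <- sqrt(sum(ps^2)) / sqrt(1 - (1 - cs)^(2 * (gen + 1))) / chiN <
        1.4 + 2 / (n + 1)
      pc <- (1 - cc) * pc + hsig * sqrt(cc * (2 - cc) * mueff) * yw
      artmp <- Y[, sel, drop = FALSE]
      C <- (1 - c1 - cmu) * C + c1 * (pc %o% pc + (1 - hsig) * cc * (2 - cc) * C) +
        cmu * artmp %*% (w * t(artmp))
      C <- (C + t(C)) / 2
      sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chiN - 1))
      if (sigma < 1e-12) break
    }
    list(par = best_x, value = best_f, evals = evals,
         history = dplyr::bind_rows(hist))
  })
}

# staged score: falls (penalized by distance) >> wrong speed >> cost.
# Two realism regularizers act within the final stage: a saturation term
# discourages degenerate bang-bang controllers whose stimulations pin at the
# ceiling, and a cadence prior keeps the stride period near the human
# preferred relationship T_pref(v) ~ 1.45 - 0.25 v (s), since long-stride
# low-cadence gaits are energetically admissible here but atypical of
# human walking.
.preferred_stride <- function(v) 1.45 - 0.25 * v

.staged_score <- function(ct, speed_tol = 0.05, sat_weight = 2e4,
                          cadence_weight = 3e4) {
  if (isTRUE(ct$fell)) return(ct$J)            # 1e6 / (1 + distance)
  if (abs(ct$v_avg - ct$v_tgt) > speed_tol)
    return(2e4 + 1e4 * abs(ct$v_avg - ct$v_tgt))
  ct$J + sat_weight * ct$saturation +
    cadence_weight * (ct$stride_period / .preferred_stride(ct$v_tgt) - 1)^2
}

#' Optimize the reflex parameters for one target speed
#'
#' CMA-ES over all reflex gains/offsets in log-scaled coordinates around the
#' initial set, with a staged objective: candidates that fall rank by
#' distance walked, candidates that walk but miss the target speed rank by
#' speed error, and candidates that walk at speed rank by the walking cost
#' `J = C_E + c_v |v_avg - v_tgt|`. Fully reproducible from `seed`.
#'
#' @param v_tgt Target speed (m/s).
#' @param budget Objective evaluations.
#' @param seed RNG seed.
#' @param init Initial parameter vector.
#' @param model,ground As in [simulate_walk()].
#' @param sigma0 Initial CMA step in scaled coordinates.
#' @param window,transient Cost-evaluation horizon (s).
#' @param speed_tol Stage-2 speed gate (m/s).
#' @param ... Passed to [evaluate_cost()].
#' @return A `gait_opt` list: `params` (best), `cost` (its [evaluate_cost()]
#'   terms), `history`, `evals`, `seed`.
#' @export
optimize_gait <- function(v_tgt, budget = 200, seed = 1,
                          init = default_reflex_params(),
                          model = scale_anthropometry(),
                          ground = ground_model(), sigma0 = 0.12,
                          window = 15, transient = 5, speed_tol = 0.05, ...) {
  stopifnot(budget >= 1)
  nm <- names(init)
  x0 <- rep(0, length(init))       # multiplicative log2 offsets
  decode <- function(x) setNames(init * 2^x, nm)
  fn <- function(x) {
    ct <- suppressWarnings(
      evaluate_cost(decode(x), v_tgt, window = window, transient = transient,
                    model = model, ground = ground, ...))
    .staged_score(ct, speed_tol)
  }
  res <- cma_es(fn, x0, sigma0 = sigma0, lower = -2, upper = 2,
                budget = budget, seed = seed)
  best <- decode(res$par)
  ct <- suppressWarnings(
    evaluate_cost(best, v_tgt, window = window, transient = transient,
                  model = model, ground = ground, ...))
  structure(list(params = best, cost = ct, history = res$history,
                 evals = res$evals, seed = seed, v_tgt = v_tgt),
            class = "gait_opt")
}

#' @export
print.gait_opt <- function(x, ...) {
  cat(sprintf("<gait_opt> v_tgt %.2f m/s, %d evals, best J %.1f (fell: %s)\n",
              x$v_tgt, x$evals, x$cost$J, x$cost$fell))
  invisible(x)
}
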