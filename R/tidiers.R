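# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @export
tidy.gait_sim <- function(x, ...) {
  x$trajectory |>
    tidyr::pivot_longer(
      cols = dplyr::matches("^[a-z]+_(l|r)_(act|stim|force|l_ce|v_ce|l_mtu)$"),
      names_to = c("muscle", "leg", "variable"),
      names_pattern = "^([a-z]+)_(l|r)_(act|stim|force|l_ce|v_ce|l_mtu)$",
      values_to = "value") |>
    dplyr::select("time", "muscle", "leg", "variable", "value")
}

#' @export
glance.gait_sim <- function(x, ...) {
  tibble(duration = x$duration_done, distance = x$distance,
         v_avg = ifelse(x$duration_done > 0, x$distance / x$duration_done, NA),
         strides = sum(x$events$event == "heel_strike" & x$events$leg == "r"),
         fell = x$fall, e_met = x$energy,
         stride_period = x$stride_period)
}

#' @export
tidy.similarity_result <- function(x, ...) {
  band <- attr(x, "band"); m <- attr(x, "model")
  b <- if ("offset" %in% names(x)) x$offset[1] else 0
  tibble(condition = band$condition, mean = band$mean, sd = band$sd,
         model_scaled = x$scale[1] * m + b,
         within = abs(x$scale[1] * m + b - band$mean) <= band$sd)
}

#' @export
glance.similarity_result <- function(x, ...) as_tibble(unclass(x))

#' @export
tidy.gait_opt <- function(x, ...) x$history

#' @export
glance.gait_opt <- function(x, ...) {
  dplyr::bind_cols(tibble(v_tgt = x$v_tgt, evals = x$evals, seed = x$seed),
                   as_tibble(x$cost))
}

#' @export
autoplot.gait_sim <- function(object, what = c("joints", "grf", "muscles"), ...) {
  what <- match.arg(what)
  tr <- object$trajectory
  if (what == "joints") {
    df <- tidyr::pivot_longer(tr[, c("time", "hip_l", "knee_l", "ankle_l",
                                     "hip_r", "knee_r", "ankle_r")],
                              -"time", names_to = "joint", values_to = "angle")
    ggplot(df, aes(.data$time, .data$angle * 180 / pi, colour = .data$joint)) +
      geom_line() +
      labs(x = "time [s]", y = "joint angle [deg]") + theme_minimal()
  } else if (what == "grf") {
    df <- tidyr::pivot_longer(tr[, c("time", "grf_y_l", "grf_y_r")],
                              -"time", names_to = "leg", values_to = "force")
    ggplot(df, aes(.data$time, .data$force, colour = .data$leg)) +
      geom_line() + labs(x = "time [s]", y = "vertical GRF [N]") + theme_minimal()
  } else {
    df <- tidy.gait_sim(object) |> dplyr::filter(.data$variable == "act")
    ggplot(df, aes(.data$time, .data$value, colour = .data$leg)) +
      geom_line() + facet_wrap(~ toupper(.data$muscle), scales = "free_y") +
      labs(x = "time [s]", y = "activation") + theme_minimal()
  }
}

#' @export
autoplot.similarity_result <- function(object, ...) {
  df <- tidy.similarity_result(object)
  ggplot(df, aes(.data$condition, .data$mean)) +
    geom_ribbon(aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
                fill = "grey80") +
    geom_line(colour = "grey40") +
    geom_line(aes(y = .data$model_scaled), colour = "black", linewidth = 1) +
    geom_point(aes(y = .data$model_scaled, shape = .data$within), size = 2) +
    scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 4)) +
    labs(x = "condition", y = "normalized response",
         title = sprintf("overlap %.0f%% (k = %.2f)",
                         object$percent[1], object$scale[1])) +
    theme_minimal()
}

#' Plot a response trend against a reference band
#'
#' @param trend A [response_trend()] (one muscle).
#' @param band A normalized reference band.
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_response_trend <- function(trend, band = NULL, ...) {
  if (!is.null(band)) return(autoplot(scale_to_band(trend, band)))
  ggplot(trend, aes(.data$value, .data$response)) +
    geom_line() + geom_point() +
    facet_wrap(~ .data$muscle, scales = "free_y") +
    labs(x = "condition", y = "response (activation change)") + theme_minimal()
}

#' Stick-figure snapshot of the walker
#'
#' @param sim A `gait_sim`.
#' @param times Times at which to draw the model.
#' @param model Body model (defaults to the simulation's).
#' @return A ggplot.
#' @export
plot_stick <- function(sim, times = NULL, model = NULL) {
  if (is.null(model)) model <- sim$model
  tr <- sim$trajectory
  if (is.null(times)) times <- seq(min(tr$time), max(tr$time), length.out = 8)
  segs <- purrr::map_dfr(times, function(tt) {
    i <- which.min(abs(tr$time - tt))
    q <- as.numeric(tr[i, 2:10])
    pts <- segment_positions(model, q)
    pick <- function(p, l) pts[pts$point == p & pts$leg == l, c("x", "y")]
    hip <- pick("hip", "c"); head <- pick("head", "c")
    purrr::map_dfr(c("l", "r"), function(leg) {
      kn <- pick("knee", leg); an <- pick("ankle", leg)
      he <- pick("heel", leg); ba <- pick("ball", leg)
      tibble(t = tt, leg = c("c", leg, leg, leg, leg),
             x = c(hip$x, hip$x, kn$x, an$x, he$x),
             y = c(hip$y, hip$y, kn$y, an$y, he$y),
             xend = c(head$x, kn$x, an$x, he$x, ba$x),
             yend = c(head$y, kn$y, an$y, he$y, ba$y))
    })
  })
  ggplot(segs, aes(.data$x, .data$y, xend = .data$xend, yend = .data$yend,
                   colour = .data$leg)) +
    geom_segment(linewidth = 0.8) + coord_equal() +
    geom_hline(yintercept = 0, colour = "grey70") +
    labs(x = "x [m]", y = "y [m]") + theme_minimal() +
    theme(legend.position = "none")
}
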