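# Hill-type muscle-tendon units: nine muscle groups per leg, each a
# contractile element (force-length and force-velocity surfaces) in series
# with a quadratic-toe elastic tendon and in parallel with passive elastic
# elements. Shortening velocity is positive. Moment arms are either constant
# or cosine-modulated in the spanned joint angle; the signed arm equals
# d(l_mtu)/d(angle) exactly, so torque and length change are energetically
# consistent.

# reference constants at 1.8 m / 80 kg; forces scale with mass, lengths with height
.MUSCLE_REF <- local({
  m <- tibble::tribble(
    ~muscle, ~F_max, ~l_opt, ~v_max, ~l_slack, ~delay,
    "HFL",  2000, 0.11, 12, 0.10, 0.005,
    "GLU",  1500, 0.11, 12, 0.13, 0.005,
    "HAM",  3000, 0.10, 12, 0.31, 0.010,
    "RF",   1200, 0.08, 12, 0.35, 0.010,
    "VAS",  6000, 0.08, 12, 0.23, 0.010,
    "BFSH",  350, 0.12, 12, 0.10, 0.010,
    "GAS",  1500, 0.05, 12, 0.40, 0.020,
    "SOL",  4000, 0.04,  6, 0.26, 0.020,
    "TA",    800, 0.06, 12, 0.24, 0.020
  )
  # per-joint geometry: mode 0 none, 1 constant arm, 2 cosine-modulated arm;
  # r signed so that d(l_mtu)/d(angle) = r (mode 1) or r*cos(angle - th_max) (mode 2)
  g <- tibble::tribble(
    ~muscle, ~hip_mode, ~hip_r, ~hip_thmax, ~hip_thref,
             ~knee_mode, ~knee_r, ~knee_thmax, ~knee_thref,
             ~ankle_mode, ~ankle_r, ~ankle_thmax, ~ankle_thref,
    "HFL",  1, -0.10, 0, 0.30,  0,  0.00, 0, 0,    0,  0.00, 0.0, 0,
    "GLU",  1,  0.10, 0, 0.30,  0,  0.00, 0, 0,    0,  0.00, 0.0, 0,
    "HAM",  1,  0.08, 0, 0.30,  1, -0.05, 0, 0.30, 0,  0.00, 0.0, 0,
    "RF",   1, -0.08, 0, 0.30,  2,  0.06, 1.0, 0.30, 0, 0.00, 0.0, 0,
    "VAS",  0,  0.00, 0, 0,     2,  0.06, 1.0, 0.30, 0, 0.00, 0.0, 0,
    "BFSH", 0,  0.00, 0, 0,     1, -0.04, 0, 0.30, 0,  0.00, 0.0, 0,
    "GAS",  0,  0.00, 0, 0,     1, -0.04, 0, 0.30, 2,  0.05, 0.1, 0,
    "SOL",  0,  0.00, 0, 0,     0,  0.00, 0, 0,    2,  0.05, 0.1, 0,
    "TA",   0,  0.00, 0, 0,     0,  0.00, 0, 0,    2, -0.04, -0.1, 0
  )
  dplyr::left_join(m, g, by = "muscle")
})

#' Muscle-tendon unit constants scaled to a body model
#'
#' Returns the nine muscle-tendon units of one leg with maximum isometric
#' force `F_max` (N), optimum contractile-element length `l_opt` (m),
#' maximum shortening velocity `v_max` (l_opt/s), tendon slack length (m),
#' afferent transport delay (s) and moment-arm geometry per spanned joint.
#' Forces scale with body mass and lengths (including moment arms) with
#' height, relative to the 1.8 m / 80 kg reference.
#'
#' @param model A [scale_anthropometry()] body model.
#' @return A `muscle_set` tibble, one row per muscle in canonical order.
#' @export
muscle_set <- function(model = scale_anthropometry()) {
  stopifnot(inherits(model, "body_model"))
  fm <- attr(model, "mass") / 80
  fl <- attr(model, "height") / 1.8
  out <- .MUSCLE_REF
  out$F_max <- out$F_max * fm
  for (col in c("l_opt", "l_slack", "hip_r", "knee_r", "ankle_r"))
    out[[col]] <- out[[col]] * fl
  structure(out, class = c("muscle_set", class(out)))
}

muscles_to_cfg <- function(ms) {
  par <- as.matrix(ms[, c("F_max", "l_opt", "v_max", "l_slack", "delay")])
  geom <- as.matrix(ms[, c(
    "hip_mode", "hip_r", "hip_thmax", "hip_thref",
    "knee_mode", "knee_r", "knee_thmax", "knee_thref",
    "ankle_mode", "ankle_r", "ankle_thmax", "ankle_thref")])
  list(par = unname(par), geom = unname(geom))
}

.mtu_row <- function(mtu, muscle) {
  stopifnot(is.data.frame(mtu))
  if (!is.null(muscle)) {
    row <- mtu[mtu$muscle == muscle, ]
    if (nrow(row) != 1) abort(paste0("unknown muscle '", muscle, "'"))
    return(row)
  }
  if (nrow(mtu) != 1)
    abort("give a single-row muscle tibble, or a full set plus `muscle`")
  mtu
}

#' Muscle force from the Hill-type contraction model
#'
#' Active force is `activation * F_max * f_l(l_ce) * f_v(v_ce)`, with the
#' force-length curve peaking at `l_opt` and the force-velocity curve
#' reaching zero at the maximum shortening velocity (shortening positive).
#' A parallel elastic element adds passive force beyond `l_opt`; a compressive
#' buffer element supports the contractile element at very short lengths.
#' Out-of-range activations are clamped to `[0, 1]` with a warning.
#'
#' @param activation Muscle activation, fraction in `[0, 1]`.
#' @param l_ce Contractile-element length (m).
#' @param v_ce Contraction velocity in `l_opt`/s, shortening positive.
#' @param mtu A single-row muscle tibble (or a [muscle_set()] with `muscle`).
#' @param muscle Muscle name when `mtu` is a full set.
#' @return A one-row tibble: `force` (N, total), `active`, `passive`, and the
#'   `f_l`, `f_v` factors.
#' @examples
#' ms <- muscle_set()
#' muscle_force(1, ms$l_opt[ms$muscle == "SOL"], 0, ms, "SOL")
#' @export
muscle_force <- function(activation, l_ce, v_ce, mtu, muscle = NULL) {
  row <- .mtu_row(mtu, muscle)
  if (activation < 0 || activation > 1) {
    warn(sprintf("activation %.3g clamped to [0, 1]", activation))
    activation <- min(max(activation, 0), 1)
  }
  vrel <- v_ce / row$v_max
  res <- rg_muscle_force_cpp(activation, l_ce, vrel, row$F_max, row$l_opt, row$v_max)
  tibble(force = res$force, active = res$active, passive = res$passive,
         f_l = res$f_l, f_v = res$f_v)
}

.geom_vec <- function(row) {
  as.numeric(row[, c(
    "hip_mode", "hip_r", "hip_thmax", "hip_thref",
    "knee_mode", "knee_r", "knee_thmax", "knee_thref",
    "ankle_mode", "ankle_r", "ankle_thmax", "ankle_thref")])
}

#' Muscle-tendon unit length, lengthening velocity and moment arms
#'
#' Joint angles follow the walker's conventions: hip flexion, knee flexion
#' and ankle dorsiflexion positive, all zero in the reference posture.
#' The signed moment arm about each joint equals the derivative of MTU
#' length with respect to that joint angle.
#'
#' @param joint_angles Named or positional numeric vector `c(hip, knee, ankle)` (rad).
#' @param mtu A single-row muscle tibble (or a [muscle_set()] plus `muscle`).
#' @param joint_velocities Angular velocities (rad/s), default zero.
#' @param muscle Muscle name when `mtu` is a full set.
#' @return One-row tibble: `length` (m), `velocity` (m/s, lengthening
#'   positive) and moment arms `arm_hip`, `arm_knee`, `arm_ankle` (m).
#' @export
mtu_kinematics <- function(joint_angles, mtu, joint_velocities = c(0, 0, 0),
                           muscle = NULL) {
  row <- .mtu_row(mtu, muscle)
  res <- rg_mtu_geom_cpp(as.numeric(joint_angles), .geom_vec(row),
                         row$l_opt, row$l_slack)
  tibble(length = res$length,
         velocity = sum(res$arms * as.numeric(joint_velocities)),
         arm_hip = res$arms[1], arm_knee = res$arms[2], arm_ankle = res$arms[3])
}
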