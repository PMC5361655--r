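# Anthropometric scaling of the sagittal walker. Segment lengths are
# proportional to stature and segment masses to body mass, using standard
# regression fractions (Winter-style tables); inertias use radius-of-gyration
# fractions of segment length.

# fractions of total body mass / stature
.ANTHRO <- list(
  mass_frac  = c(hat = 0.678, thigh = 0.100, shank = 0.0465, foot = 0.0145),
  len_frac   = c(hat = 0.470, thigh = 0.245, shank = 0.246, foot = 0.152),
  com_frac   = c(hat = 0.438, thigh = 0.433, shank = 0.433),  # from proximal joint
  rgyr_frac  = c(hat = 0.255, thigh = 0.323, shank = 0.302, foot = 0.475),
  ankle_h    = 0.039,   # ankle joint height above sole / stature
  heel_x     = 0.33,    # heel contact point, fraction of foot length behind ankle
  ball_x     = 0.52     # ball contact point, fraction of foot length ahead of ankle
)

#' Build an anthropometrically scaled body model
#'
#' Scales the seven-segment sagittal walker (head-arms-trunk, two thighs,
#' shanks and feet) to a subject's height and mass. Segment lengths scale
#' with height, masses with total mass, and moments of inertia with
#' mass x length^2, following standard anthropometric regression fractions.
#'
#' @param height Standing height in metres, in `[1.4, 2.2]`.
#' @param mass Total body mass in kilograms, in `[40, 120]`.
#' @return A `body_model` object: a tibble with one row per segment
#'   (mass, length, centre-of-mass offset, moment of inertia), carrying
#'   joint limits, foot geometry and totals as attributes.
#' @examples
#' scale_anthropometry(1.8, 80)
#' @export
scale_anthropometry <- function(height = 1.8, mass = 80) {
  if (!is.numeric(height) || length(height) != 1 || height < 1.4 || height > 2.2)
    abort(paste0("`height` must be a single value in [1.4, 2.2] m, got ", height))
  if (!is.numeric(mass) || length(mass) != 1 || mass < 40 || mass > 120)
    abort(paste0("`mass` must be a single value in [40, 120] kg, got ", mass))
  A <- .ANTHRO
  seg <- tibble(
    segment = c("hat", "thigh_l", "thigh_r", "shank_l", "shank_r", "foot_l", "foot_r"),
    mass = unname(mass * A$mass_frac[c("hat", "thigh", "thigh", "shank", "shank", "foot", "foot")]),
    length = unname(height * A$len_frac[c("hat", "thigh", "thigh", "shank", "shank", "foot", "foot")])
  )
  seg$com_offset <- c(
    seg$length[1] * A$com_frac[["hat"]],
    rep(seg$length[2] * A$com_frac[["thigh"]], 2),
    rep(seg$length[4] * A$com_frac[["shank"]], 2),
    rep(0.10 * seg$length[6], 2)   # foot com, forward of ankle along sole
  )
  seg$inertia <- seg$mass * unname(seg$length *
    A$rgyr_frac[c("hat", "thigh", "thigh", "shank", "shank", "foot", "foot")])^2

  foot_len <- seg$length[6]
  structure(
    seg,
    class = c("body_model", class(seg)),
    height = height,
    mass = mass,
    hip_height = height * (A$len_frac[["thigh"]] + A$len_frac[["shank"]] + A$ankle_h),
    ankle_height = height * A$ankle_h,
    foot_pts = c(
      heel_x = -A$heel_x * foot_len, heel_y = -height * A$ankle_h,
      ball_x = A$ball_x * foot_len, ball_y = -height * A$ankle_h
    ),
    joint_limits = rbind(
      hip = c(-0.60, 1.80), knee = c(0.03, 2.40), ankle = c(-0.90, 0.70)
    )
  )
}

#' @export
print.body_model <- function(x, ...) {
  cat(sprintf("<body_model> height %.2f m, mass %.1f kg, hip height %.3f m\n",
              attr(x, "height"), attr(x, "mass"), attr(x, "hip_height")))
  NextMethod()
}

# flatten to the list the C++ core expects
body_to_cfg <- function(model) {
  stopifnot(inherits(model, "body_model"))
  fp <- attr(model, "foot_pts")
  idx <- function(s) which(model$segment == s)
  list(
    m_hat = model$mass[idx("hat")], m_th = model$mass[idx("thigh_l")],
    m_sh = model$mass[idx("shank_l")], m_ft = model$mass[idx("foot_l")],
    l_hat = model$length[idx("hat")], l_th = model$length[idx("thigh_l")],
    l_sh = model$length[idx("shank_l")],
    d_hat = model$com_offset[idx("hat")], d_th = model$com_offset[idx("thigh_l")],
    d_sh = model$com_offset[idx("shank_l")],
    I_hat = model$inertia[idx("hat")], I_th = model$inertia[idx("thigh_l")],
    I_sh = model$inertia[idx("shank_l")], I_ft = model$inertia[idx("foot_l")],
    foot_x_com = 0.10 * model$length[idx("foot_l")],
    foot_y_com = -0.5 * attr(model, "ankle_height"),
    hip0 = attr(model, "hip_height")
  )
}
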