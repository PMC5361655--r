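# Synthetic reference data with known ground truth: smooth bump-mixture
# trends over the condition axis with +-1 s.d. bands of controlled width,
# and EMG-like paired trial traces with injected responses. Everything is
# reproducible from the seed.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification for a synthetic reference band
#'
#' The latent trend is a mixture of smooth bumps over the condition axis
#' (centres, widths, signed heights in `[0, 1]` axis units), mimicking
#' smooth phase-dependent response curves. The band half-width (s.d.) is
#' `sd_rel` per condition (after peak normalization; scalar or vector). A
#' fraction `out_frac` of conditions is displaced out of band (alternating
#' sides) so the best achievable overlap is known by construction;
#' `in_noise` jitters the remaining conditions uniformly within the band.
#'
#' @param n_conditions Number of conditions (5-16 in the emulated studies).
#' @param centers,widths,heights Bump mixture parameters.
#' @param sd_rel Relative band half-width per condition.
#' @param k_star Ground-truth scale: the latent model trend is the
#'   normalized mean divided by `k_star`.
#' @param out_frac Fraction of conditions forced out of band.
#' @param in_noise In-band noise fraction (0 = exactly on the mean).
#' @param out_margin Eligibility margin for out-of-band conditions: only
#'   conditions with |mean| > (1 + out_margin) * sd can be forced out (their
#'   model value is the negated mean, unreachable for any nonnegative scale).
#' @param seed RNG seed.
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(n_conditions = 16,
                       centers = c(0.25, 0.7), widths = c(0.12, 0.18),
                       heights = c(1, 0.6), sd_rel = 0.25,
                       k_star = 1, out_frac = 0, in_noise = 0,
                       out_margin = 0.5, seed = 1) {
  stopifnot(n_conditions >= 2, length(centers) == length(widths),
            length(widths) == length(heights), all(widths > 0),
            all(sd_rel >= 0), k_star > 0, out_frac >= 0, out_frac <= 1)
  if (all(heights == 0)) abort("degenerate trend: all bump heights are zero")
  structure(list(n = n_conditions, centers = centers, widths = widths,
                 heights = heights, sd_rel = sd_rel, k_star = k_star,
                 out_frac = out_frac, in_noise = in_noise,
                 out_margin = out_margin, seed = seed),
            class = "synth_spec")
}

#' Generate a synthetic reference band with known ground truth
#'
#' @param spec A [synth_spec()].
#' @return List: `band` (normalized [normalize_reference()] tibble),
#'   `model_trend` (the matching latent model responses, such that
#'   `k_star * model_trend` best overlaps the band), `k_star`,
#'   `out_idx` (conditions forced out of band), `latent` (unnormalized mean).
#' @export
generate_reference_band <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(spec$seed, {
    x <- (seq_len(spec$n) - 0.5) / spec$n
    latent <- rowSums(vapply(seq_along(spec$centers), function(j)
      spec$heights[j] * exp(-(x - spec$centers[j])^2 / (2 * spec$widths[j]^2)),
      numeric(spec$n)))
    if (max(abs(latent)) == 0) abort("degenerate trend: latent is all zero")
    raw <- tibble(condition = x, mean = latent,
                  sd = rep_len(spec$sd_rel, spec$n) * max(abs(latent)))
    band <- normalize_reference(raw)
    n_out <- round(spec$out_frac * spec$n)
    # out-of-band conditions get the NEGATED mean: for any k >= 0 the scaled
    # model point has the wrong sign (or zero) while the band excludes zero
    # there, so those conditions are unreachable by construction
    eligible <- which(abs(band$mean) > (1 + spec$out_margin) * band$sd)
    if (n_out > length(eligible))
      abort("band too wide to force that many conditions out; lower sd_rel or out_frac")
    out_idx <- if (n_out > 0)
      sort(eligible[sample.int(length(eligible), n_out)]) else integer()
    model <- band$mean
    if (spec$in_noise > 0)
      model <- model + runif(spec$n, -1, 1) * spec$in_noise * band$sd
    if (n_out > 0) model[out_idx] <- -band$mean[out_idx]
    list(band = band, model_trend = model / spec$k_star,
         k_star = spec$k_star, out_idx = out_idx, latent = latent)
  })
}

#' Generate paired EMG-like trial traces with a known injected response
#'
#' Each trial is a pair of traces on a shared grid: a smoothed stochastic
#' background (identical statistics, independent noise) and the same
#' background plus a Gaussian response bump of known height at the onset.
#' With `noise_sd = 0` the extracted response equals `response_height`
#' exactly.
#'
#' @param n_trials Number of trials.
#' @param response_height Injected bump height (activation units).
#' @param onset Bump onset time (s); the bump peaks `bump_delay` later.
#' @param duration,fs Trace length (s) and sampling rate (Hz).
#' @param baseline Background level.
#' @param noise_sd Background noise s.d. before smoothing.
#' @param bump_delay,bump_width Gaussian bump timing (s).
#' @param seed RNG seed.
#' @return Tibble `trial`, `time`, `disturbed`, `undisturbed` with
#'   attributes `onset` and `height`.
#' @export
generate_emg_trials <- function(n_trials = 1, response_height = 0.3,
                                onset = 0.1, duration = 0.4, fs = 1000,
                                baseline = 0.1, noise_sd = 0,
                                bump_delay = 0.02, bump_width = 0.008,
                                seed = 1) {
  stopifnot(n_trials >= 1)
  with_seed(seed, {
    tm <- seq(0, duration, by = 1 / fs)
    bump <- response_height * exp(-(tm - onset - bump_delay)^2 / (2 * bump_width^2))
    smooth_noise <- function() {
      if (noise_sd == 0) return(rep(0, length(tm)))
      as.numeric(stats::filter(rnorm(length(tm), 0, noise_sd),
                               rep(1 / 8, 8), sides = 1, circular = TRUE))
    }
    out <- purrr::map_dfr(seq_len(n_trials), function(k)
      tibble(trial = k, time = tm,
             undisturbed = baseline + smooth_noise(),
             disturbed = baseline + smooth_noise() + bump))
    attr(out, "onset") <- onset
    attr(out, "height") <- response_height
    out
  })
}
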