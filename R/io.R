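# Delimited-text I/O for trajectories, reference bands and parameter sets.

#' Write a trajectory table
#'
#' Tab-separated text with a mandatory header (one row per sample: time,
#' joint angles, ground-reaction forces, per-muscle activation, stimulation,
#' lengths, velocities and forces), or Parquet as a compact binary container
#' for long runs (requires the `arrow` package).
#'
#' @param sim A `gait_sim` or trajectory tibble.
#' @param path Output file.
#' @param format `"tsv"` or `"parquet"`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(sim, path, format = c("tsv", "parquet")) {
  format <- match.arg(format)
  traj <- if (inherits(sim, "gait_sim")) sim$trajectory else sim
  if (format == "tsv") {
    readr::write_tsv(traj, path)
  } else {
    if (!requireNamespace("arrow", quietly = TRUE))
      abort("the 'arrow' package is needed for parquet output")
    arrow::write_parquet(traj, path)
  }
  invisible(path)
}

#' Read a trajectory table written by [write_trajectory()]
#' @param path File path.
#' @return Trajectory tibble.
#' @export
read_trajectory <- function(path) {
  if (grepl("\\.parquet$", path)) {
    if (!requireNamespace("arrow", quietly = TRUE))
      abort("the 'arrow' package is needed for parquet input")
    return(as_tibble(arrow::read_parquet(path)))
  }
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Read / write reference response bands
#'
#' Delimited text with columns `condition`, `mean`, `sd` — one file per
#' muscle and experiment. Reading normalizes the band (peak |mean| = 1)
#' unless `normalize = FALSE`.
#'
#' @param path File path.
#' @param normalize Normalize after reading (default TRUE).
#' @return A `reference_band` tibble.
#' @export
read_reference_band <- function(path, normalize = TRUE) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("condition", "mean", "sd") %in% names(df)))
  if (normalize) normalize_reference(df) else as_tibble(df)
}

#' @rdname read_reference_band
#' @param band Tibble with `condition`, `mean`, `sd`.
#' @export
write_reference_band <- function(band, path) {
  stopifnot(all(c("condition", "mean", "sd") %in% names(band)))
  readr::write_tsv(band[, c("condition", "mean", "sd")], path)
  invisible(path)
}
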