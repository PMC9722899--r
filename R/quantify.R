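#' Correct an apparent axial position for index mismatch
#'
#' Refractive-index mismatch between immersion oil and sample medium
#' stretches apparent axial distances; the measured position is multiplied
#' by the correction ratio (n_oil / n_medium, 1.128 for oil/water).
#'
#' @param z Measured axial position(s), micrometres.
#' @param correction Multiplicative correction factor, or an
#'   [optical_config()] from which `n_oil / n_medium` is taken.
#' @return Corrected axial position(s).
#' @export
axial_position <- function(z, correction = 1.128) {
  if (inherits(correction, "optical_config"))
    correction <- correction$n_oil / correction$n_medium
  z * correction
}

#' Clausius-Mossotti polarizability of a dielectric sphere
#'
#' `alpha = 3 V (n_p^2 - n_m^2) / (n_p^2 + 2 n_m^2)` with
#' `V = (4/3) pi r^3`; the real part of the induced-dipole response in
#' volume units. An index-matched particle (`n_p = n_m`) has zero
#' polarizability.
#'
#' @param radius Particle radius in micrometres.
#' @param n_p Particle refractive index.
#' @param n_m Medium refractive index.
#' @return Polarizability in um^3.
#' @export
reference_polarizability <- function(radius, n_p, n_m = 1.33) {
  if (any(radius <= 0)) abort("radius must be > 0")
  if (any(n_p < 1) || any(n_m < 1)) abort("refractive indices must be >= 1")
  V <- (4 / 3) * pi * radius^3
  3 * V * (n_p^2 - n_m^2) / (n_p^2 + 2 * n_m^2)
}

#' Calibration of the log-scale channel against a known polarizability
#'
#' The scale symmetry constrains only *ratios* of signal strength, so the
#' network's log-scale channel has an arbitrary offset that must be
#' calibrated against one observation of known polarizability.
#'
#' @param reference_log_scale Network log-scale output on the reference
#'   observation.
#' @param reference_polarizability Known polarizability of the reference,
#'   um^3.
#' @param n_medium Medium refractive index (metadata).
#' @return A `polarizability_calibration` object.
#' @export
polarizability_calibration <- function(reference_log_scale,
                                       reference_polarizability,
                                       n_medium = 1.33) {
  if (reference_polarizability <= 0)
    abort("reference polarizability must be > 0")
  structure(list(reference_log_scale = reference_log_scale,
                 reference_polarizability = reference_polarizability,
                 n_medium = n_medium),
            class = "polarizability_calibration")
}

#' @rdname polarizability_calibration
#' @param cal A `polarizability_calibration`.
#' @param path YAML file path.
#' @export
save_calibration <- function(cal, path) {
  yaml::write_yaml(list(reference_log_scale = cal$reference_log_scale,
                        reference_polarizability = cal$reference_polarizability,
                        n_medium = cal$n_medium), path)
  invisible(path)
}

#' @rdname polarizability_calibration
#' @export
load_calibration <- function(path) {
  y <- yaml::read_yaml(path)
  polarizability_calibration(y$reference_log_scale,
                             y$reference_polarizability, y$n_medium)
}

#' Convert log-scale predictions to polarizability
#'
#' `alpha = alpha_ref * exp(log_scale - log_scale_ref)`. For a tibble of
#' detections with a `trace` column, per-trace polarizability is the
#' unweighted mean over the trace's detections.
#'
#' @param pred Numeric log-scale predictions, or a detections tibble with a
#'   `log_scale` column (and optionally `trace`).
#' @param cal A [polarizability_calibration()].
#' @return Numeric polarizabilities, or the tibble with a
#'   `polarizability_um3` column (per-trace mean if `trace` is present).
#' @export
polarizability_from_logscale <- function(pred, cal) {
  conv <- function(ls) cal$reference_polarizability *
    exp(ls - cal$reference_log_scale)
  if (is.numeric(pred)) return(conv(pred))
  pred$polarizability_um3 <- conv(pred$log_scale)
  if ("trace" %in% names(pred)) {
    pred <- dplyr::group_by(pred, .data$trace)
    pred <- dplyr::mutate(pred,
      polarizability_um3 = mean(.data$polarizability_um3))
    pred <- dplyr::ungroup(pred)
  }
  pred
}

#' Classify traces by fluorescence colocalization
#'
#' A detection is colocalized if any fluorescence detection of the same
#' frame lies within `radius`. A trace is labelled `"particle"` if more
#' than `hi_frac` of its detections are colocalized, `"biological"` if
#' fewer than `lo_frac` are, and `"unlabelled"` otherwise.
#'
#' @param traces Detections tibble with `trace`, `frame`, `x`, `y` (px).
#' @param fluo Fluorescence detections tibble with `frame`, `x`, `y` (px,
#'   same coordinates).
#' @param radius Colocalization radius in micrometres (default 0.4).
#' @param hi_frac,lo_frac Classification thresholds (defaults 0.95, 0.05).
#' @param pixel_size Micrometres per px.
#' @return `traces` with logical `colocalized` and per-trace `label`
#'   columns.
#' @export
classify_by_fluorescence <- function(traces, fluo, radius = 0.4,
                                     hi_frac = 0.95, lo_frac = 0.05,
                                     pixel_size = 1) {
  coloc <- logical(nrow(traces))
  for (r in seq_len(nrow(traces))) {
    f <- fluo[fluo$frame == traces$frame[r], , drop = FALSE]
    if (nrow(f) == 0) next
    d <- sqrt((f$x - traces$x[r])^2 + (f$y - traces$y[r])^2) * pixel_size
    coloc[r] <- any(d <= radius)
  }
  traces$colocalized <- coloc
  traces <- dplyr::group_by(traces, .data$trace)
  traces <- dplyr::mutate(traces, label = {
    frac <- mean(.data$colocalized)
    if (frac > hi_frac) "particle"
    else if (frac < lo_frac) "biological"
    else "unlabelled"
  })
  dplyr::ungroup(traces)
}
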