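#' Optical configuration for holographic imaging
#'
#' @param wavelength Illumination wavelength in micrometres (default 633 nm
#'   HeNe line).
#' @param na Numerical aperture of the objective (0 < NA < `n_medium`).
#' @param n_medium Refractive index of the sample medium.
#' @param n_oil Refractive index of the immersion oil.
#' @param pixel_size Object-plane pixel size in micrometres.
#' @return An `optical_config` object.
#' @export
optical_config <- function(wavelength = 0.633, na = 1.3, n_medium = 1.33,
                           n_oil = 1.5, pixel_size = 0.114) {
  if (wavelength <= 0) abort("wavelength must be > 0")
  if (na <= 0 || na >= n_medium) abort("need 0 < NA < n_medium")
  if (pixel_size <= 0) abort("pixel_size must be > 0")
  structure(list(wavelength = wavelength, na = na, n_medium = n_medium,
                 n_oil = n_oil, pixel_size = pixel_size),
            class = "optical_config")
}

fft_freqs <- function(n, d) {
  i <- c(0:(n - n %/% 2 - 1), -(n %/% 2):-1)
  i / (n * d)
}

fft2 <- function(x) fft(x)
ifft2 <- function(x) fft(x, inverse = TRUE) / length(x)

# Angular-spectrum geometry shared by the simulator and the propagator.
# Carrier phase k0 is removed so the background plane wave (the DC
# component) is invariant under propagation.
asm_geometry <- function(h, w, optics) {
  kx <- 2 * pi * fft_freqs(h, optics$pixel_size)
  ky <- 2 * pi * fft_freqs(w, optics$pixel_size)
  k0 <- 2 * pi * optics$n_medium / optics$wavelength
  kcut <- 2 * pi * optics$na / optics$wavelength
  kr2 <- outer(kx^2, ky^2, `+`)
  list(kx = kx, ky = ky, k0 = k0,
       pupil = (kr2 <= kcut^2) + 0,
       kz = sqrt(as.complex(k0^2 - kr2)))
}

new_complex_field <- function(values, optics, background = 1 + 0i, sigma = 0) {
  structure(values, class = c("complex_field", class(values)),
            optics = optics, background = background, sigma = sigma)
}

#' Simulate a weak-scatterer hologram with exact ground truth
#'
#' Each particle contributes a diffraction-limited complex point response
#' (uniform pupil truncated at the NA), phase-shifted to its sub-pixel
#' position, defocused to its axial position by angular-spectrum
#' propagation, and scaled by a factor proportional to its polarizability.
#' The scattered sum rides on a unit background and is corrupted with
#' additive complex Gaussian noise such that
#' `max(|field|) / sqrt(sigma_Re^2 + sigma_Im^2) = snr`.
#'
#' If `truth` carries `radius` and `refractive_index` columns, the signal
#' strength is `signal_per_polarizability` times the Clausius-Mossotti
#' polarizability of each particle (times any `scale` column); otherwise
#' the `scale` column is used directly as the signal strength.
#'
#' @param truth A [scene_truth()] tibble; `z` defaults to 0 (in focus).
#' @param optics An [optical_config()].
#' @param grid A [grid_spec()] (its `pixel_size` is taken from `optics`).
#' @param snr Signal-to-noise ratio, or `NULL`/`Inf` for a noiseless field.
#' @param seed Optional integer seed.
#' @param signal_per_polarizability Field amplitude per unit polarizability
#'   (1/um^3); fixes the arbitrary overall scale of the weak-scatterer
#'   model.
#' @param modulation_offset Optional in-plane offset `(dx, dy)` in
#'   micrometres emulating sample-position-modulated acquisition: each
#'   particle contributes the difference between its response and a copy
#'   displaced by the offset, and the background is suppressed to 0.
#' @return List with `field` (a `complex_field` matrix) and `truth`.
#' @export
simulate_hologram <- function(truth, optics = optical_config(),
                              grid = grid_spec(), snr = NULL, seed = NULL,
                              signal_per_polarizability = 10,
                              modulation_offset = NULL) {
  if (nrow(truth) < 1) abort("scene must contain at least one particle")
  z <- truth[["z"]] %||% rep(0, nrow(truth))
  if (any(abs(z) > 10)) abort("particle z must be within +/- 10 um of focus")
  h <- grid$height; w <- grid$width
  geo <- asm_geometry(h, w, optics)
  norm0 <- sum(geo$pupil) / (h * w)   # in-focus peak of the point response
  acc <- matrix(0 + 0i, h, w)
  scl <- truth[["scale"]] %||% rep(1, nrow(truth))
  for (p in seq_len(nrow(truth))) {
    if (!is.null(truth[["radius"]]) && !is.null(truth[["refractive_index"]])) {
      alpha <- reference_polarizability(truth$radius[p],
                                        truth$refractive_index[p],
                                        optics$n_medium)
      s <- signal_per_polarizability * alpha * scl[p]
    } else {
      s <- scl[p]
    }
    xp <- truth$x[p] * optics$pixel_size
    yp <- truth$y[p] * optics$pixel_size
    ph <- outer(geo$kx * xp, geo$ky * yp, `+`)
    hat <- geo$pupil * exp(-1i * ph) * exp(1i * (geo$kz - geo$k0) * z[p])
    acc <- acc + (1i * s) * hat
  }
  bg <- 1 + 0i
  scatter <- ifft2(acc) / norm0
  if (!is.null(modulation_offset)) {
    ph <- outer(geo$kx * modulation_offset[1], geo$ky * modulation_offset[2], `+`)
    shifted <- ifft2(acc * exp(-1i * ph)) / norm0
    scatter <- scatter - shifted
    bg <- 0 + 0i
  }
  field <- bg + scatter
  sigma <- 0
  if (!is.null(snr) && is.finite(snr)) {
    sigma <- max(Mod(field)) / (snr * sqrt(2))
    noise <- with_seed(seed, complex(real = rnorm(h * w, sd = sigma),
                                     imaginary = rnorm(h * w, sd = sigma)))
    field <- field + matrix(noise, h, w)
  }
  list(field = new_complex_field(field, optics, background = bg, sigma = sigma),
       truth = truth)
}

#' Propagate a complex field along the optical axis
#'
#' Angular-spectrum propagation: the 2D spectrum is multiplied by
#' `exp(i (kz - k0) dz)` on the propagating band (carrier removed, so the
#' uniform background is invariant) while evanescent components decay as
#' `exp(-|Im kz| |dz|)`. The operation is exactly unitary on the
#' propagating band, so propagating by `+dz` then `-dz` restores the field.
#'
#' @param field A `complex_field` (or plain complex matrix with `optics`).
#' @param dz Propagation distance in micrometres (|dz| <= 50).
#' @param optics [optical_config()] override; defaults to the field's own.
#' @return The propagated `complex_field`.
#' @export
propagate_field <- function(field, dz, optics = NULL) {
  optics <- optics %||% attr(field, "optics")
  if (is.null(optics)) abort("field carries no optical_config")
  if (!is.finite(dz) || abs(dz) > 50) abort("dz outside validity range (50 um)")
  geo <- asm_geometry(nrow(field), ncol(field), optics)
  kz <- geo$kz
  kernel <- exp(1i * (Re(kz) - geo$k0) * dz - abs(Im(kz)) * abs(dz))
  out <- ifft2(fft2(unclass(field)) * kernel)
  new_complex_field(out, optics, background = attr(field, "background") %||% (1 + 0i),
                    sigma = attr(field, "sigma") %||% 0)
}

#' Rescale the scattered component of a field
#'
#' Returns `background + s * (field - background)`; the background itself
#' is untouched. Multiplying the scattered field emulates a change of
#' particle polarizability.
#'
#' @param field A `complex_field`.
#' @param s Positive scale factor.
#' @return The rescaled `complex_field`.
#' @export
rescale_scatter <- function(field, s) {
  if (!is.finite(s) || s <= 0) abort("scale factor must be > 0")
  bg <- attr(field, "background") %||% (1 + 0i)
  out <- bg + s * (unclass(field) - bg)
  new_complex_field(out, attr(field, "optics"), background = bg,
                    sigma = attr(field, "sigma") %||% 0)
}

# Network input planes for a complex field: scattered part relative to the
# background level (divided by |background| when non-zero), stacked as
# real/imaginary channels.
field_to_planes <- function(field) {
  bg <- attr(field, "background") %||% (1 + 0i)
  x <- unclass(field) - bg
  if (Mod(bg) > 0) x <- x / Mod(bg)
  out <- array(0, c(nrow(field), ncol(field), 2L))
  out[, , 1L] <- Re(x)
  out[, , 2L] <- Im(x)
  out
}
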