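#' Fisher information for Poisson-limited localization
#'
#' For a pure Poisson detector the Fisher information about parameters
#' `theta = (x, y, orientation)` is
#' `I = sum_k (d nu_k / d theta)^T (d nu_k / d theta) / nu_k`
#' over pixels `k`, where `nu` is the expected photon count. Derivatives
#' are central finite differences of the supersampled, pixel-integrated
#' render.
#'
#' @param render_fn Function `theta -> expected-intensity matrix` with
#'   `theta = c(x, y, orientation)`; must be strictly positive.
#' @param theta Parameter vector at which to evaluate.
#' @param step Finite-difference steps per parameter (px, px, rad);
#'   defaults to one fine-grid pixel (0.1 px) and 0.01 rad.
#' @return Symmetric 3x3 information matrix with dimnames
#'   `(x, y, orientation)`.
#' @export
fisher_information <- function(render_fn, theta = c(0, 0, 0),
                               step = c(0.1, 0.1, 0.01)) {
  nu0 <- render_fn(theta)
  if (any(nu0 <= 0)) abort("expected intensities must be strictly positive")
  derivs <- lapply(seq_along(theta), function(p) {
    tp <- theta; tm <- theta
    tp[p] <- tp[p] + step[p]; tm[p] <- tm[p] - step[p]
    (render_fn(tp) - render_fn(tm)) / (2 * step[p])
  })
  I <- matrix(0, 3, 3, dimnames = list(c("x", "y", "orientation"),
                                       c("x", "y", "orientation")))
  for (a in 1:3) for (b in a:3) {
    I[a, b] <- sum(derivs[[a]] * derivs[[b]] / nu0)
    I[b, a] <- I[a, b]
  }
  I
}

#' Cramer-Rao bound on localization RMSE
#'
#' Inverts the information matrix and returns
#' `sqrt((var_x + var_y) / 2)`, the bound on the root-mean-square position
#' error. For shapes with a rotational symmetry the orientation parameter
#' carries no information; flag them so the singular orientation block is
#' excluded instead of breaking the inversion.
#'
#' @param I 3x3 Fisher information matrix from [fisher_information()].
#' @param rotation_symmetric Is the shape rotationally symmetric (point,
#'   sphere, annulus)?
#' @return Lower bound on localization RMSE in px.
#' @export
rmse_bound <- function(I, rotation_symmetric = FALSE) {
  if (rotation_symmetric) {
    Iinv <- tryCatch(solve(I[1:2, 1:2]),
                     error = function(e) abort("position block is singular"))
    return(sqrt((Iinv[1, 1] + Iinv[2, 2]) / 2))
  }
  rc <- tryCatch(solve(I), error = function(e) {
    d <- diag(I)
    abort(paste0("information matrix is singular; smallest diagonal entry: ",
                 names(which.min(d)),
                 " (flag rotation_symmetric for symmetric shapes)"))
  })
  sqrt((rc[1, 1] + rc[2, 2]) / 2)
}

rotationally_symmetric_shapes <- c("point", "sphere", "annulus")

#' Cramer-Rao bound for a rendered shape at a given SNR
#'
#' Renders the shape with its peak signal set to `snr * sqrt(background)`
#' above background — the same scaling [corrupt_with_noise()] applies —
#' and evaluates the localization bound at the grid center.
#'
#' @param spec A [shape_spec()].
#' @param snr Signal-to-noise ratio(s); vectorized.
#' @param grid A [grid_spec()].
#' @param orientation Shape orientation at which to evaluate.
#' @return Tibble with columns `snr` and `crlb_px`.
#' @export
crlb_for_shape <- function(spec, snr, grid = grid_spec(), orientation = 0) {
  rot_sym <- spec$shape %in% rotationally_symmetric_shapes
  center <- c((grid$height - 1) / 2, (grid$width - 1) / 2)
  purrr::map_dfr(snr, function(s) {
    sp <- spec
    sp$amplitude <- s * sqrt(spec$background)
    fn <- function(theta) render_shape(sp, center + theta[1:2],
                                       orientation + theta[3], grid)
    I <- fisher_information(fn)
    tibble::tibble(snr = s, crlb_px = rmse_bound(I, rotation_symmetric = rot_sym))
  })
}
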