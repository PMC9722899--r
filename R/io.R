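#' Read and write image stacks as TIFF
#'
#' Images are written as 32-bit float multi-page TIFF. TIFF readers (and
#' the underlying `tiff` package) expect samples in `[0, 1]`, so the stack
#' is affinely mapped to that range on write and the mapping is stored in
#' a small YAML sidecar (`<path>.yml`); [read_image_stack()] undoes it
#' when the sidecar is present. Complex fields are stored as a two-page
#' TIFF (real plane, imaginary plane) with the same mechanism.
#'
#' @param images A matrix or list of matrices.
#' @param path Output file path.
#' @export
write_image_stack <- function(images, path) {
  if (is.matrix(images)) images <- list(images)
  lo <- min(vapply(images, min, numeric(1)))
  hi <- max(vapply(images, max, numeric(1)))
  span <- if (hi > lo) hi - lo else 1
  imgs <- lapply(images, function(m) {
    m <- (unclass(m) - lo) / span
    attributes(m) <- list(dim = dim(m))
    m
  })
  tiff::writeTIFF(imgs, path, bits.per.sample = 32L, reduce = FALSE)
  yaml::write_yaml(list(offset = lo, scale = span), paste0(path, ".yml"))
  invisible(path)
}

#' @rdname write_image_stack
#' @return `read_image_stack()` returns a list of matrices.
#' @export
read_image_stack <- function(path) {
  imgs <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(imgs)) imgs <- list(imgs)
  imgs <- lapply(imgs, function(m) if (length(dim(m)) == 3) m[, , 1] else m)
  sidecar <- paste0(path, ".yml")
  if (file.exists(sidecar)) {
    y <- yaml::read_yaml(sidecar)
    imgs <- lapply(imgs, function(m) m * y$scale + y$offset)
  }
  imgs
}

#' @rdname write_image_stack
#' @param field A `complex_field`.
#' @export
write_field_tiff <- function(field, path) {
  write_image_stack(list(Re(unclass(field)), Im(unclass(field))), path)
}

#' @rdname write_image_stack
#' @param optics An [optical_config()] to attach on read.
#' @export
read_field_tiff <- function(path, optics = optical_config()) {
  planes <- read_image_stack(path)
  if (length(planes) != 2) abort("expected a two-page (real, imaginary) TIFF")
  new_complex_field(matrix(complex(real = planes[[1]], imaginary = planes[[2]]),
                           nrow(planes[[1]]), ncol(planes[[1]])),
                    optics)
}
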