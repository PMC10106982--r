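# Synthetic microscopy and plate images. Images are numeric matrices in
# arbitrary intensity units, indexed [row = y, col = x] with pixel centers
# at integer coordinates.

#' Synthesize a spindle-like fluorescence image
#'
#' Renders isotropic 2-D Gaussian spots on a flat background with additive
#' Gaussian noise, the geometry used to emulate kinetochore/spindle
#' fluorescence signals. The ground-truth integrated intensity of each
#' spot, `2 * pi * amplitude * sigma^2`, is attached for parameter-recovery
#' tests. Negative pixel values after noise are clamped to zero (camera
#' counts are non-negative).
#'
#' @param spots Data frame with columns `x`, `y` (pixel coordinates, inside
#'   the image), `amplitude`, `sigma` (px). Zero rows give a flat image.
#' @param background Flat background intensity.
#' @param noise_sd Standard deviation of additive Gaussian noise (0 for
#'   noiseless).
#' @param size `c(width, height)` in pixels.
#' @param seed Integer seed for the noise.
#' @return Numeric matrix with attribute `truth` (the `spots` table plus
#'   `integrated_intensity`).
#' @export
synthesize_spindle_image <- function(spots = data.frame(x = numeric(),
                                                        y = numeric(),
                                                        amplitude = numeric(),
                                                        sigma = numeric()),
                                     background = 100, noise_sd = 0,
                                     size = c(128, 128), seed = 1L) {
  w <- size[1]; h <- size[2]
  spots <- as.data.frame(spots)
  if (nrow(spots) > 0 &&
      any(spots$x < 1 | spots$x > w | spots$y < 1 | spots$y > h))
    stop("spot center outside image bounds")
  xs <- matrix(rep(seq_len(w), each = h), nrow = h)
  ys <- matrix(rep(seq_len(h), times = w), nrow = h)
  img <- matrix(background, nrow = h, ncol = w)
  for (k in seq_len(nrow(spots)))
    img <- img + spots$amplitude[k] *
      exp(-((xs - spots$x[k])^2 + (ys - spots$y[k])^2) / (2 * spots$sigma[k]^2))
  if (noise_sd > 0)
    img <- img + with_seed(derive_seed(seed, "spindle"),
                           matrix(rnorm(h * w, 0, noise_sd), nrow = h))
  img <- pmax(img, 0)
  truth <- spots
  truth$integrated_intensity <- if (nrow(spots)) 2 * pi * spots$amplitude *
    spots$sigma^2 else numeric()
  attr(img, "truth") <- truth
  img
}

#' Synthesize a plate image with colony disks
#'
#' Renders filled disks (colonies) at stated centers on a flat background,
#' with optional additive Gaussian noise. Ground truth (disk count and the
#' covered-area fraction of the frame) is attached.
#'
#' @param disks Data frame with columns `x`, `y`, `r` (px).
#' @param foreground,background Disk and background intensities.
#' @param size `c(width, height)` in pixels.
#' @param noise_sd Additive Gaussian noise sd (default 0).
#' @param seed Integer seed for the noise.
#' @return Numeric matrix with attribute `truth` (list: `n_disks`,
#'   `area_fraction`, `disks`).
#' @export
synthesize_plate_image <- function(disks = data.frame(x = numeric(),
                                                      y = numeric(),
                                                      r = numeric()),
                                   foreground = 200, background = 20,
                                   size = c(256, 256), noise_sd = 0,
                                   seed = 1L) {
  w <- size[1]; h <- size[2]
  disks <- as.data.frame(disks)
  img <- matrix(background, nrow = h, ncol = w)
  xs <- matrix(rep(seq_len(w), each = h), nrow = h)
  ys <- matrix(rep(seq_len(h), times = w), nrow = h)
  covered <- matrix(FALSE, nrow = h, ncol = w)
  for (k in seq_len(nrow(disks)))
    covered <- covered |
      (xs - disks$x[k])^2 + (ys - disks$y[k])^2 <= disks$r[k]^2
  img[covered] <- foreground
  if (noise_sd > 0)
    img <- pmax(img + with_seed(derive_seed(seed, "plate"),
                                matrix(rnorm(h * w, 0, noise_sd), nrow = h)), 0)
  attr(img, "truth") <- list(n_disks = nrow(disks),
                             area_fraction = mean(covered), disks = disks)
  img
}

#' Write a grayscale image as 16-bit TIFF
#'
#' Intensities are stored as 16-bit counts (values are clamped to
#' `[0, 65535]`).
#'
#' @param img Numeric matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(img, path) {
  tiff::writeTIFF(pmin(pmax(img, 0), 65535) / 65535, path,
                  bits.per.sample = 16L)
  invisible(path)
}

#' Read a grayscale TIFF/PNG into an intensity matrix
#'
#' Intensities are returned scaled to the 16-bit count range (0–65535).
#' Multi-channel images are averaged to grayscale.
#'
#' @param path TIFF or PNG path.
#' @return Numeric matrix, `[row = y, col = x]`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  m <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(path, as.is = FALSE)
       else png::readPNG(path)
  if (length(dim(m)) == 3L) m <- apply(m, c(1, 2), mean)
  m * 65535
}
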