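# Quantification of fluorescence and plate images. All functions take
# plain numeric matrices indexed [row = y, col = x], pixel centers at
# integer coordinates.

# Bilinear interpolation at (x, y); coordinates clamped to the frame so
# perpendicular averaging near an edge samples the edge pixel.
bilinear <- function(img, x, y) {
  h <- nrow(img); w <- ncol(img)
  x <- pmin(pmax(x, 1), w)
  y <- pmin(pmax(y, 1), h)
  x0 <- pmin(floor(x), w - 1L); y0 <- pmin(floor(y), h - 1L)
  fx <- x - x0; fy <- y - y0
  img[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
    img[cbind(y0, x0 + 1)] * fx * (1 - fy) +
    img[cbind(y0 + 1, x0)] * (1 - fx) * fy +
    img[cbind(y0 + 1, x0 + 1)] * fx * fy
}

#' Intensity profile along a line, averaged over a perpendicular width
#'
#' Samples the image by bilinear interpolation at `n` evenly spaced points
#' from `p1` to `p2`; at each point, intensities are averaged across
#' `width` parallel lines offset perpendicular to the scan at 1 px
#' spacing. This is the perpendicular line-scan used to profile spindle
#' fluorescence.
#'
#' @param img Numeric matrix.
#' @param p1,p2 Endpoints `c(x, y)` in pixel coordinates; must lie inside
#'   the image.
#' @param width Perpendicular averaging width in px (default 3).
#' @param n Number of samples; default one per pixel of scan length.
#' @return Data frame (class `line_scan_profile`) with columns `position`
#'   (px from `p1`, strictly increasing, uniform spacing) and `intensity`.
#' @export
line_scan <- function(img, p1, p2, width = 3L, n = NULL) {
  h <- nrow(img); w <- ncol(img)
  for (p in list(p1, p2))
    if (p[1] < 1 || p[1] > w || p[2] < 1 || p[2] > h)
      stop("line-scan endpoint outside image")
  len <- sqrt(sum((p2 - p1)^2))
  if (len == 0) stop("line-scan endpoints coincide")
  n <- n %||% (ceiling(len) + 1L)
  u <- (p2 - p1) / len          # unit direction
  v <- c(-u[2], u[1])           # unit perpendicular
  t <- seq(0, len, length.out = n)
  offs <- seq(-(width - 1) / 2, (width - 1) / 2, by = 1)
  acc <- numeric(n)
  for (o in offs) {
    px <- p1[1] + t * u[1] + o * v[1]
    py <- p1[2] + t * u[2] + o * v[2]
    acc <- acc + bilinear(img, px, py)
  }
  structure(data.frame(position = t, intensity = acc / length(offs)),
            class = c("line_scan_profile", "data.frame"))
}

#' Fit a Gaussian to a line-scan profile and integrate it
#'
#' Least-squares fit of `A * exp(-(x - mu)^2 / (2 * sigma^2)) + c` with
#' moment-based initialization; the area under the fitted peak (baseline
#' excluded) is `A * sigma * sqrt(2 * pi)`, the quantity used as a proxy
#' for local protein abundance. Non-convergence is reported via the
#' `converged` flag (with `auc = NA`), never silently.
#'
#' @param profile A [line_scan()] result, or any data frame with
#'   `position` and `intensity` (>= 5 samples).
#' @param sigma_bounds Lower/upper bounds on sigma in px; default
#'   `c(0.5, profile length)`.
#' @return List (class `gaussian_fit`) with `amplitude`, `center`,
#'   `sigma`, `baseline`, `auc`, `converged`.
#' @export
fit_gaussian_auc <- function(profile, sigma_bounds = NULL) {
  x <- profile$position; y <- profile$intensity
  if (length(x) < 5L) stop("need at least 5 profile samples")
  span <- diff(range(x))
  sigma_bounds <- sigma_bounds %||% c(0.5, span)
  # moment initialization: baseline from the profile tails, center and
  # width from the first two moments of the baseline-subtracted signal
  n_tail <- max(2L, length(x) %/% 10L)
  c0 <- median(c(head(y, n_tail), tail(y, n_tail)))
  a0 <- max(max(y) - c0, 1e-6)
  wts <- pmax(y - c0, 0)
  mu0 <- if (sum(wts) > 0) sum(x * wts) / sum(wts) else mean(x)
  s0 <- if (sum(wts) > 0) sqrt(sum(wts * (x - mu0)^2) / sum(wts)) else span / 4
  clamp_s <- function(s) min(max(s, sigma_bounds[1] * 1.01),
                             sigma_bounds[2] * 0.99)
  try_fit <- function(s_init) tryCatch(
    minpack.lm::nlsLM(
      y ~ A * exp(-(x - mu)^2 / (2 * sigma^2)) + c,
      start = list(A = a0, mu = mu0, sigma = clamp_s(s_init), c = c0),
      lower = c(A = 0, mu = min(x), sigma = sigma_bounds[1], c = -Inf),
      upper = c(A = Inf, mu = max(x), sigma = sigma_bounds[2], c = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  # multi-start on the width guards against collapse onto a noise spike
  fits <- Filter(Negate(is.null), lapply(c(1, 0.5, 2), function(f)
    try_fit(s0 * f)))
  fit <- if (length(fits)) fits[[which.min(vapply(fits, function(f)
    sum(residuals(f)^2), numeric(1)))]] else NULL
  if (is.null(fit)) {
    res <- list(amplitude = NA_real_, center = NA_real_, sigma = NA_real_,
                baseline = NA_real_, auc = NA_real_, converged = FALSE)
  } else {
    p <- coef(fit)
    res <- list(amplitude = unname(p["A"]), center = unname(p["mu"]),
                sigma = unname(p["sigma"]), baseline = unname(p["c"]),
                auc = unname(p["A"] * p["sigma"] * sqrt(2 * pi)),
                converged = TRUE)
  }
  structure(res, class = "gaussian_fit")
}

pixel_distances <- function(img, center) {
  xs <- matrix(rep(seq_len(ncol(img)), each = nrow(img)), nrow = nrow(img))
  ys <- matrix(rep(seq_len(nrow(img)), times = ncol(img)), nrow = nrow(img))
  sqrt((xs - center[1])^2 + (ys - center[2])^2)
}

#' Background-corrected integrated intensity in a circle
#'
#' Sums the intensity over the inner disk and subtracts the local
#' background, estimated as the mean per-pixel intensity of the annulus
#' between `r_inner` and `r_outer`, times the inner pixel count. On a
#' uniform image the correction is exact and the result 0. Negative
#' results are reported as-is (truthful noise behavior, not clamped).
#'
#' @param img Numeric matrix.
#' @param center `c(x, y)` circle center.
#' @param r_inner,r_outer Radii in px, `r_outer > r_inner`; the outer
#'   circle must fit inside the image.
#' @return Background-corrected integrated intensity (scalar).
#' @export
circle_intensity <- function(img, center, r_inner, r_outer) {
  if (r_outer <= r_inner) stop("`r_outer` must exceed `r_inner`")
  if (center[1] - r_outer < 1 || center[1] + r_outer > ncol(img) ||
      center[2] - r_outer < 1 || center[2] + r_outer > nrow(img))
    stop("outer circle extends outside the image")
  d <- pixel_distances(img, center)
  inner <- d <= r_inner
  annulus <- d > r_inner & d <= r_outer
  if (!any(annulus)) stop("background annulus contains no pixels")
  sum(img[inner]) - mean(img[annulus]) * sum(inner)
}

#' Percentage of a measurement circle above an intensity threshold
#'
#' The growth readout for spotted serial dilutions: the fraction of
#' pixels inside the circle at or above the binarization threshold,
#' as a percentage.
#'
#' @param img Numeric matrix.
#' @param threshold Intensity threshold (pixels `>= threshold` count as
#'   growth).
#' @param center `c(x, y)` circle center.
#' @param radius Circle radius in px; circle must fit inside the image.
#' @return Percentage in `[0, 100]`.
#' @export
growth_area <- function(img, threshold, center, radius) {
  if (center[1] - radius < 1 || center[1] + radius > ncol(img) ||
      center[2] - radius < 1 || center[2] + radius > nrow(img))
    stop("measurement circle extends outside the image")
  mask <- pixel_distances(img, center) <= radius
  100 * sum(img[mask] >= threshold) / sum(mask)
}

# 8-connected component labelling of a logical mask via a pixel-adjacency
# graph (EBImage's labeller is 4-connected, which splits diagonal bridges).
label_components_8 <- function(mask) {
  idx <- which(mask)
  if (!length(idx)) return(list(n = 0L, sizes = integer()))
  h <- nrow(mask)
  in_mask <- integer(length(mask))
  in_mask[idx] <- seq_along(idx)
  row <- (idx - 1L) %% h + 1L
  edges <- NULL
  for (d in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(-1L, 1L))) {
    nb <- idx + d[1L] + d[2L] * h
    ok <- row + d[1L] >= 1L & row + d[1L] <= h &
      nb >= 1L & nb <= length(mask)
    ok[ok] <- in_mask[nb[ok]] > 0L
    if (any(ok))
      edges <- rbind(edges, cbind(in_mask[idx[ok]], in_mask[nb[ok]]))
  }
  g <- igraph::graph_from_edgelist(
    if (is.null(edges)) matrix(integer(), ncol = 2) else edges,
    directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)
  list(n = comp$no, sizes = as.integer(comp$csize))
}

#' Count colonies on a thresholded plate image
#'
#' Counts 8-connected components of the binarized image (`>= threshold`)
#' whose pixel area lies within `[min_size, max_size]`, the particle
#' analysis used for the minichromosome-loss colony counts.
#'
#' @param img Numeric matrix.
#' @param threshold Binarization threshold.
#' @param min_size,max_size Component-area bounds in px (defaults 5 and
#'   `Inf`).
#' @return Integer colony count.
#' @export
count_colonies <- function(img, threshold, min_size = 5L, max_size = Inf) {
  comp <- label_components_8(img >= threshold)
  sum(comp$sizes >= min_size & comp$sizes <= max_size)
}
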