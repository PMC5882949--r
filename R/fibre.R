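# Actin orientation field, fibre mask, and per-cell order parameters.
#
# The per-pixel orientation is obtained from a second-moment (Hessian-like)
# tensor built from second-order 5x5 Sobel responses. Each tensor component is
# weighted pixelwise by the smoothed actin intensity and Gaussian-blurred
# before the angle is read off with the quadrant-sensitive inverse tangent.

# Second-order 5x5 Sobel kernels: separable products of the 1-D smoothing
# [1 4 6 4 1], second-difference [1 0 -2 0 1] and first-difference
# [-1 -2 0 2 1] stencils. x = column direction, y = row direction.
sobel2_kernels <- function() {
  s <- c(1, 4, 6, 4, 1)
  d2 <- c(1, 0, -2, 0, 1)
  d1 <- c(-1, -2, 0, 2, 1)
  list(
    xx = outer(s, d2) / 16,
    yy = outer(d2, s) / 16,
    xy = outer(d1, d1) / 16
  )
}

#' Per-pixel actin fibre orientation field
#'
#' Computes an axial orientation angle for every pixel of a preprocessed
#' F-actin image. The image is filtered with the three second-order 5x5 Sobel
#' kernels; each response is multiplied pixelwise by the smoothed intensity
#' image and Gaussian-blurred (default sigma 4 px); the local fibre angle is
#' then \code{0.5 * atan2(2 Ixy, Ixx - Iyy)}, calibrated so that a bright
#' ridge texture at angle theta yields phi = theta.
#'
#' @param actin preprocessed F-actin image (matrix in [0, 1]; see
#'   \code{\link{preprocess}}).
#' @param sigma Gaussian blur sigma (pixels) applied to the weighted tensor
#'   components.
#' @return an object of class \code{orientation_field}: list with \code{phi}
#'   (axial angle matrix, radians in [-pi/2, pi/2)), \code{weight} (the
#'   smoothed intensity used in all weighted averages) and \code{low_conf}
#'   (logical matrix flagging degenerate pixels where the tensor carries no
#'   orientation information; phi = 0 there by convention).
#' @export
orientation_field <- function(actin, sigma = 4) {
  stopifnot(is.matrix(actin))
  k <- sobel2_kernels()
  sxx <- conv2r(actin, k$xx)
  syy <- conv2r(actin, k$yy)
  sxy <- conv2r(actin, k$xy)
  ixx <- blur2(sxx * actin, sigma)
  iyy <- blur2(syy * actin, sigma)
  ixy <- blur2(sxy * actin, sigma)
  num <- 2 * ixy
  den <- ixx - iyy
  eps <- 1e-12 * max(abs(num), abs(den), 1e-300)
  low <- abs(num) < eps & abs(den) < eps
  phi <- 0.5 * atan2(num, den)
  phi[low] <- 0
  structure(
    list(phi = wrap_axial(phi), weight = actin, low_conf = low),
    class = "orientation_field"
  )
}

#' @export
print.orientation_field <- function(x, ...) {
  cat(
    "orientation field:", nrow(x$phi), "x", ncol(x$phi), "px;",
    sum(x$low_conf), "low-confidence px\n"
  )
  invisible(x)
}

#' Fibre mask by multi-scale unsharp enhancement
#'
#' Enhances fibrous structures by unsharp masking at Gaussian smoothing
#' degrees 3, 5, 7 and 9 px (\code{img - gaussian(img, sigma)}, negative
#' values clipped to zero), sums the four enhanced images, denoises with a
#' 3x3 median filter, renormalizes to [0, 1] and thresholds at 0.08. Because
#' the threshold is applied on the renormalized image, the mask is invariant
#' to global intensity scaling.
#'
#' @param actin preprocessed F-actin image.
#' @param sigmas unsharp smoothing sigmas in pixels.
#' @param threshold threshold on the normalized enhanced image.
#' @return logical matrix; all \code{FALSE} (with attribute
#'   \code{"no_fibres"}) when the enhanced image is constant.
#' @export
fibre_mask <- function(actin, sigmas = c(3, 5, 7, 9), threshold = 0.08) {
  stopifnot(is.matrix(actin))
  u <- 0
  for (s in sigmas) u <- u + pmax(actin - blur2(actin, s), 0)
  mx <- max(u)
  if (mx <= 0) {
    out <- array(FALSE, dim(actin))
    attr(out, "no_fibres") <- TRUE
    return(out)
  }
  u <- median2(u / mx, 1)
  u <- normalize01(u)
  if (isTRUE(attr(u, "constant"))) {
    out <- array(FALSE, dim(actin))
    attr(out, "no_fibres") <- TRUE
    return(out)
  }
  u > threshold
}

#' Per-cell fibre alignment (nematic order parameter)
#'
#' Intensity-weighted alignment of the axial fibre angles inside a cell: the
#' mean orientation phi0 is taken in doubled-angle space and
#' \eqn{S = \sum w \cos(2(\phi - \phi_0)) / \sum w}. S = 1 for perfectly
#' parallel fibres and 0 for uniformly random orientations.
#'
#' @param field an \code{\link{orientation_field}}.
#' @param fmask fibre mask (logical matrix, see \code{\link{fibre_mask}}).
#' @param cell_mask optional logical matrix restricting the average to one
#'   cell; the fibre mask is intersected with it.
#' @return list with \code{alignment} (S), \code{mean_orientation} (phi0,
#'   radians) and \code{n_px}. When no fibre pixels exist the metrics are
#'   \code{NA} and \code{flag} is \code{"no_fibres"}.
#' @export
fibre_alignment <- function(field, fmask, cell_mask = NULL) {
  stopifnot(inherits(field, "orientation_field"))
  sel <- fmask
  if (!is.null(cell_mask)) sel <- sel & cell_mask
  if (!any(sel)) {
    return(list(alignment = NA_real_, mean_orientation = NA_real_,
                n_px = 0L, flag = "no_fibres"))
  }
  res <- axial_order(field$phi[sel], field$weight[sel])
  list(alignment = res$order, mean_orientation = res$phi0,
       n_px = sum(sel), flag = NA_character_)
}

#' Per-cell radial order of the fibre arrangement
#'
#' Scores how radially the fibres are arranged about the cell centroid. For
#' each fibre pixel the radial direction is \eqn{\psi = atan2(y - y_0, x - x_0)}
#' and the local score is \eqn{s = 0.5 \cos(2(\phi - \psi)) + 0.5}, an
#' axial-consistent form with the anchors 1 (fibre along the radius),
#' 0 (fibre perpendicular to it, i.e. rings) and 0.5 at 45 degrees. The
#' historical single-angle form \eqn{0.5 \cos(\phi - \psi) + 0.5} is available
#' with \code{literal = TRUE}. The cell value is the intensity-weighted mean
#' over the fibre mask; the centroid pixel itself (undefined psi) is excluded.
#'
#' @param field an \code{\link{orientation_field}}.
#' @param fmask fibre mask (logical matrix).
#' @param centroid numeric length-2, centroid (x0, y0) of the cell mask in
#'   pixel coordinates (x = column, y = row).
#' @param cell_mask optional logical matrix restricting to one cell.
#' @param literal use the single-angle cosine form instead of the
#'   doubled-angle form.
#' @return list with \code{radial_order}, \code{n_px}, \code{flag}.
#' @export
radial_order <- function(field, fmask, centroid, cell_mask = NULL,
                         literal = FALSE) {
  stopifnot(inherits(field, "orientation_field"), length(centroid) == 2L)
  sel <- fmask
  if (!is.null(cell_mask)) sel <- sel & cell_mask
  if (!any(sel)) {
    return(list(radial_order = NA_real_, n_px = 0L, flag = "no_fibres"))
  }
  g <- coord_grids(nrow(field$phi), ncol(field$phi))
  dx <- g$x[sel] - centroid[1]
  dy <- g$y[sel] - centroid[2]
  keep <- (dx * dx + dy * dy) > 0.25 # drop the centroid pixel itself
  if (!any(keep)) {
    return(list(radial_order = NA_real_, n_px = 0L, flag = "no_fibres"))
  }
  psi <- atan2(dy[keep], dx[keep])
  phi <- field$phi[sel][keep]
  w <- field$weight[sel][keep]
  s <- if (literal) {
    0.5 * cos(phi - psi) + 0.5
  } else {
    0.5 * cos(2 * (phi - psi)) + 0.5
  }
  sw <- sum(w)
  if (sw <= 0) {
    return(list(radial_order = NA_real_, n_px = 0L, flag = "zero_weight"))
  }
  list(radial_order = sum(s * w) / sw, n_px = sum(keep), flag = NA_character_)
}

#' QC colour overlays for orientation and radial order
#'
#' Renders the orientation field in rainbow colours over [-pi/2, pi/2) and the
#' per-pixel radial order on a blue-white-red scale; pixels outside the fibre
#' mask are black. Deterministic colour mapping.
#'
#' @param field an \code{\link{orientation_field}}.
#' @param fmask fibre mask.
#' @param centroid cell centroid (x0, y0); needed for the radial-order image.
#' @param literal passed to \code{\link{radial_order}}'s per-pixel score.
#' @return list of two rgb arrays (h x w x 3): \code{orientation} and
#'   \code{radial}.
#' @export
render_overlays <- function(field, fmask, centroid, literal = FALSE) {
  d <- dim(field$phi)
  pal <- grDevices::rainbow(256, end = 0.8)
  idx <- pmin(255L, pmax(0L, floor((field$phi / pi + 0.5) * 256))) + 1L
  ori_cols <- pal[idx]
  ori <- array(0, c(d, 3L))
  rgbm <- grDevices::col2rgb(ori_cols) / 255
  for (ch in 1:3) {
    plane <- matrix(rgbm[ch, ], d[1], d[2])
    plane[!fmask] <- 0
    ori[, , ch] <- plane
  }
  g <- coord_grids(d[1], d[2])
  psi <- atan2(g$y - centroid[2], g$x - centroid[1])
  s <- if (literal) {
    0.5 * cos(field$phi - psi) + 0.5
  } else {
    0.5 * cos(2 * (field$phi - psi)) + 0.5
  }
  bwr <- grDevices::colorRampPalette(c("blue", "white", "red"))(256)
  idx2 <- pmin(255L, pmax(0L, floor(s * 256))) + 1L
  rad <- array(0, c(d, 3L))
  rgbm2 <- grDevices::col2rgb(bwr[idx2]) / 255
  for (ch in 1:3) {
    plane <- matrix(rgbm2[ch, ], d[1], d[2])
    plane[!fmask] <- 0
    rad[, , ch] <- plane
  }
  list(orientation = ori, radial = rad)
}
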