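# Internal numeric helpers shared across modules.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap angles to the axial interval [-pi/2, pi/2)
#'
#' Fibre orientations are axial quantities (defined modulo pi): an angle and
#' the same angle plus pi describe the same fibre. All orientation maps in the
#' package live on [-pi/2, pi/2).
#'
#' @param x numeric vector of angles in radians.
#' @return angles wrapped modulo pi into [-pi/2, pi/2).
#' @export
wrap_axial <- function(x) x - pi * floor(x / pi + 0.5)

# wrap to (-pi, pi]
wrap_circ <- function(x) atan2(sin(x), cos(x))

#' Axial mean orientation and nematic order parameter
#'
#' Computes the weighted mean orientation and the alignment order parameter of
#' a set of axial angles in doubled-angle space: the resultant of
#' \eqn{\sum w e^{2 i \phi} / \sum w} has phase \eqn{2\phi_0} and modulus
#' \eqn{S = \sum w \cos(2(\phi - \phi_0)) / \sum w}. S is 1 when all weighted
#' angles coincide (perfect alignment) and tends to 0 for uniformly random
#' orientations.
#'
#' @param phi numeric vector of axial angles (radians).
#' @param w nonnegative weights, recycled to \code{length(phi)}.
#' @return list with \code{phi0} (mean orientation, radians in [-pi/2, pi/2))
#'   and \code{order} (the order parameter S).
#' @export
axial_order <- function(phi, w = 1) {
  w <- rep_len(w, length(phi))
  sw <- sum(w)
  if (length(phi) == 0L || sw <= 0) {
    return(list(phi0 = NA_real_, order = NA_real_))
  }
  z <- sum(w * exp(2i * phi)) / sw
  list(phi0 = wrap_axial(0.5 * Arg(z)), order = Mod(z))
}

# Reflective (mirror) padding of a matrix by n rows/cols on each side.
pad_reflect <- function(x, n) {
  nr <- nrow(x)
  nc <- ncol(x)
  if (n >= nr || n >= nc) stop("padding larger than image")
  ri <- c(rev(seq_len(n) + 1L), seq_len(nr), nr - seq_len(n))
  ci <- c(rev(seq_len(n) + 1L), seq_len(nc), nc - seq_len(n))
  x[ri, ci]
}

# 2-D linear filtering with reflective boundary handling. `k` must have odd
# dimensions. Uses EBImage's FFT filter on the padded image, then crops.
conv2r <- function(x, k) {
  n <- max(dim(k)) %/% 2L
  xp <- pad_reflect(x, n)
  yp <- EBImage::filter2(xp, k, boundary = "circular")
  m <- as.matrix(yp)
  m[(n + 1L):(n + nrow(x)), (n + 1L):(n + ncol(x)), drop = FALSE]
}

gauss_kernel <- function(sigma, radius = ceiling(3.5 * sigma)) {
  g <- stats::dnorm(seq(-radius, radius), sd = sigma)
  k <- outer(g, g)
  k / sum(k)
}

# Gaussian blur with reflective boundaries.
blur2 <- function(x, sigma) conv2r(x, gauss_kernel(sigma))

# Median filter with window (2*half+1)^2; input must lie in [0, 1].
median2 <- function(x, half) {
  as.matrix(EBImage::medianFilter(x, half))
}

# min-max normalization to [0, 1]; constant input maps to zeros with a flag.
normalize01 <- function(x) {
  rng <- range(x)
  if (!is.finite(rng[1]) || !is.finite(rng[2])) stop("non-finite image values")
  if (rng[2] - rng[1] <= 0) {
    out <- array(0, dim(x))
    attr(out, "constant") <- TRUE
    return(out)
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

# cubic smoothstep ramp on [0, 1]
smoothstep <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  t * t * (3 - 2 * t)
}

# raster index grids (x = column, y = row), 1-based
coord_grids <- function(nr, nc) {
  list(
    x = matrix(rep(seq_len(nc), each = nr), nr, nc),
    y = matrix(rep(seq_len(nr), times = nc), nr, nc)
  )
}
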