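# Circumferential vinculin profile, Fourier morphology descriptors,
# classification, and population morphology maps.

#' Circumferential vinculin sector profile
#'
#' Divides the cell mask into \code{n_sectors} angular sectors about the
#' centroid (sector k covers [k*18, (k+1)*18) degrees, counter-clockwise from
#' the +x axis), sums the vinculin intensities per sector, divides by the
#' total and multiplies by \code{n_sectors}. Values above 1 mark directions
#' with stronger-than-average staining; the profile always sums to
#' \code{n_sectors}.
#'
#' @param vinculin vinculin intensity matrix (preprocessed).
#' @param cell_mask logical matrix of the cell.
#' @param centroid numeric (x0, y0) of the cell mask.
#' @param n_sectors number of angular sectors.
#' @return numeric vector of length \code{n_sectors} (mean 1), or all
#'   \code{NA} with attribute \code{"flag" = "zero_intensity"} when the mask
#'   carries no signal.
#' @export
sector_profile <- function(vinculin, cell_mask, centroid, n_sectors = 20) {
  stopifnot(is.matrix(vinculin), is.matrix(cell_mask), length(centroid) == 2L)
  g <- coord_grids(nrow(vinculin), ncol(vinculin))
  sel <- which(cell_mask)
  if (length(sel) == 0L) stop("empty cell mask")
  ang <- atan2(g$y[sel] - centroid[2], g$x[sel] - centroid[1]) %% (2 * pi)
  sec <- pmin(floor(ang / (2 * pi / n_sectors)) + 1L, n_sectors)
  sums <- vapply(seq_len(n_sectors),
                 function(s) sum(vinculin[sel][sec == s]), numeric(1))
  tot <- sum(sums)
  if (tot <= 0) {
    out <- rep(NA_real_, n_sectors)
    attr(out, "flag") <- "zero_intensity"
    return(out)
  }
  sums / tot * n_sectors
}

#' Fourth-order Fourier fit of a sector profile
#'
#' Least-squares fit of
#' \eqn{Y(\alpha) = 1 + \sum_{k=1}^{4} a_k \cos(k\alpha) + b_k \sin(k\alpha)}
#' (constant fixed at 1) at the sector-centre angles. On the uniform sector
#' grid the harmonics are orthogonal, so a profile sampled from a pure
#' harmonic returns its coefficients exactly. The rotation-invariant weights
#' are \eqn{w_k = \sqrt{a_k^2 + b_k^2}}.
#'
#' @param sectors sector profile (length >= 2*n_order + 1, mean ~ 1).
#' @param n_order highest Fourier order fitted.
#' @return object of class \code{fourier_profile}: list with \code{a},
#'   \code{b}, \code{w} (each length \code{n_order}), the sector-centre
#'   angles \code{alpha}, the input \code{sectors} and the fitted values
#'   \code{fitted}.
#' @export
fit_fourier <- function(sectors, n_order = 4) {
  n <- length(sectors)
  stopifnot(n > 2 * n_order, all(is.finite(sectors)))
  alpha <- (seq_len(n) - 0.5) * 2 * pi / n
  X <- do.call(cbind, lapply(seq_len(n_order), function(k) {
    cbind(cos(k * alpha), sin(k * alpha))
  }))
  cf <- qr.solve(X, sectors - 1)
  a <- cf[seq(1, 2 * n_order, by = 2)]
  b <- cf[seq(2, 2 * n_order, by = 2)]
  structure(
    list(
      a = a, b = b, w = sqrt(a^2 + b^2), alpha = alpha,
      sectors = sectors, fitted = as.vector(1 + X %*% cf)
    ),
    class = "fourier_profile"
  )
}

#' Evaluate a fitted Fourier profile
#'
#' @param object a \code{\link{fit_fourier}} result.
#' @param alpha angles (radians) at which to evaluate the fitted series.
#' @param ... unused.
#' @return numeric vector Y(alpha).
#' @export
predict.fourier_profile <- function(object, alpha, ...) {
  y <- rep(1, length(alpha))
  for (k in seq_along(object$a)) {
    y <- y + object$a[k] * cos(k * alpha) + object$b[k] * sin(k * alpha)
  }
  y
}

#' Morphology-space coordinates of a cell
#'
#' Maps the Fourier weights to a point in adhesion-morphology space. The
#' radial coordinate is \eqn{r = \max(Y) - 1.25} with the maximum taken over
#' the fitted continuous curve (1-degree steps). The angular coordinate
#' \eqn{\varphi = \arg(x_w + i y_w)} combines the weights barycentrically:
#' \eqn{x_w = \sqrt{3}/2 (w_3 - w_2)}, \eqn{y_w = w_4 - 0.5 (w_2 + w_3)},
#' so pure 2nd/3rd/4th-order profiles sit at 210, 330 and 90 degrees. The
#' plot position is \code{max(r, 0) * (cos phi, sin phi)}: deeply isotropic
#' cells (negative r) are drawn at the origin.
#'
#' @param ff a \code{\link{fit_fourier}} result.
#' @param step_deg evaluation step for the curve maximum (degrees).
#' @return list with \code{r}, \code{phi_deg} (in [0, 360)), \code{x},
#'   \code{y}, \code{max_y} and the weights \code{w}.
#' @export
morphology_point <- function(ff, step_deg = 1) {
  stopifnot(inherits(ff, "fourier_profile"))
  al <- seq(0, 2 * pi - 1e-9, by = deg2rad(step_deg))
  max_y <- max(predict(ff, al))
  r <- max_y - 1.25
  w <- ff$w
  xw <- sqrt(3) / 2 * (w[3] - w[2])
  yw <- w[4] - 0.5 * (w[2] + w[3])
  phi <- rad2deg(atan2(yw, xw)) %% 360
  rp <- max(r, 0)
  list(
    r = r, phi_deg = phi, x = rp * cos(deg2rad(phi)),
    y = rp * sin(deg2rad(phi)), max_y = max_y, w = w
  )
}

#' Classify an adhesion morphology point
#'
#' Cells with \code{r < r_isotropic} (default 0.33) are isotropic. Otherwise
#' the class follows the morphology angle in 120-degree sectors centred on
#' the pure-component directions: bipolar for phi in [150, 270), triangular
#' for [270, 360) or [0, 30), quadratic for [30, 150).
#'
#' @param r morphology-space distance.
#' @param phi_deg morphology angle in degrees.
#' @param r_isotropic isotropic radius threshold.
#' @return one of \code{"isotropic"}, \code{"bipolar"}, \code{"triangular"},
#'   \code{"quadratic"}.
#' @export
classify_morphology <- function(r, phi_deg, r_isotropic = 0.33) {
  stopifnot(is.finite(r), is.finite(phi_deg))
  if (r < r_isotropic) return("isotropic")
  p <- phi_deg %% 360
  if (p >= 150 && p < 270) {
    "bipolar"
  } else if (p >= 30 && p < 150) {
    "quadratic"
  } else {
    "triangular"
  }
}

#' Population morphology map
#'
#' Bins the pooled morphology points of a population on a square grid of bin
#' width \code{bin} over [-1, 1]^2, smooths with a Gaussian, and normalizes
#' the result to its maximum.
#'
#' @param points data.frame with columns \code{x}, \code{y} (and optionally
#'   \code{cell_id}, \code{class}).
#' @param bin bin width in morphology units.
#' @param sigma_bins Gaussian smoothing sigma in bins.
#' @return object of class \code{morphology_map}: list with \code{grid}
#'   (max-normalized density, rows = y bins, cols = x bins), bin centre
#'   vectors \code{xmid}, \code{ymid}, \code{n_cells} and
#'   \code{class_fractions} (when classes were supplied).
#' @export
population_map <- function(points, bin = 0.02, sigma_bins = 2) {
  if (NROW(points) == 0L) stop("empty population")
  nb <- round(2 / bin)
  ix <- pmin(pmax(floor((points$x + 1) / bin) + 1L, 1L), nb)
  iy <- pmin(pmax(floor((points$y + 1) / bin) + 1L, 1L), nb)
  grid <- matrix(0, nb, nb) # rows = y, cols = x
  for (i in seq_along(ix)) grid[iy[i], ix[i]] <- grid[iy[i], ix[i]] + 1
  if (sigma_bins > 0) grid <- blur2(grid, sigma_bins)
  grid <- grid / max(grid)
  mids <- -1 + (seq_len(nb) - 0.5) * bin
  cf <- NULL
  if (!is.null(points$class)) {
    tab <- table(factor(points$class, levels = c("isotropic", "bipolar",
                                                 "triangular", "quadratic")))
    cf <- as.numeric(tab) / sum(tab)
    names(cf) <- names(tab)
  }
  structure(
    list(grid = grid, xmid = mids, ymid = mids, bin = bin,
         sigma_bins = sigma_bins, n_cells = NROW(points),
         class_fractions = cf),
    class = "morphology_map"
  )
}

#' @export
print.morphology_map <- function(x, ...) {
  cat("morphology map:", x$n_cells, "cells on a", length(x$xmid), "x",
      length(x$ymid), "grid (bin", x$bin, ")\n")
  if (!is.null(x$class_fractions)) {
    cat("class fractions:",
        paste(sprintf("%s %.2f", names(x$class_fractions), x$class_fractions),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Contour plot of a morphology map
#'
#' Draws the smoothed, max-normalized density as filled contours with the
#' isotropic circle (r = 0.33) and the three class-sector boundaries.
#'
#' @param x a \code{\link{population_map}} result.
#' @param levels contour levels.
#' @param r_isotropic isotropic radius drawn as the inner circle.
#' @param ... passed to \code{\link[graphics]{contour}}.
#' @export
plot.morphology_map <- function(x, levels = seq(0.1, 0.9, by = 0.2),
                                r_isotropic = 0.33, ...) {
  graphics::image(
    x$xmid, x$ymid, t(x$grid),
    col = grDevices::hcl.colors(64, "YlGnBu", rev = TRUE),
    xlab = "x", ylab = "y", asp = 1
  )
  graphics::contour(x$xmid, x$ymid, t(x$grid), levels = levels, add = TRUE,
                    drawlabels = FALSE, ...)
  th <- seq(0, 2 * pi, length.out = 181)
  graphics::lines(r_isotropic * cos(th), r_isotropic * sin(th), lty = 2)
  for (ang in c(30, 150, 270)) { # sector boundaries
    graphics::segments(
      r_isotropic * cos(deg2rad(ang)), r_isotropic * sin(deg2rad(ang)),
      cos(deg2rad(ang)), sin(deg2rad(ang)), lty = 3
    )
  }
  invisible(x)
}

#' Representative cell of a population
#'
#' Returns the cell whose morphology point lies nearest (Euclidean) to the
#' global maximum of the population map; ties are broken towards the smallest
#' \code{cell_id}, so the choice is deterministic under input reordering.
#'
#' @param points data.frame with columns \code{x}, \code{y}, \code{cell_id}.
#' @param map the \code{\link{population_map}} computed from the same points.
#' @return the selected \code{cell_id}.
#' @export
representative_cell <- function(points, map) {
  stopifnot(inherits(map, "morphology_map"), NROW(points) > 0L)
  mx <- which(map$grid == max(map$grid), arr.ind = TRUE)[1, ]
  px <- map$xmid[mx[2]]
  py <- map$ymid[mx[1]]
  d2 <- (points$x - px)^2 + (points$y - py)^2
  ids <- if (!is.null(points$cell_id)) points$cell_id else seq_len(NROW(points))
  ids[order(d2, ids)][1]
}

#' Normalized cross-correlation between two morphology maps
#'
#' Zero-lag normalized cross-correlation (cosine similarity)
#' \eqn{\sum A B / \sqrt{\sum A^2 \sum B^2}} over the grid cells; 1 for
#' identical maps, 0 for maps with disjoint support.
#'
#' @param map_a,map_b \code{\link{population_map}} results (or plain
#'   matrices) on the same grid.
#' @return correlation in [-1, 1].
#' @export
morphology_cc <- function(map_a, map_b) {
  a <- if (inherits(map_a, "morphology_map")) map_a$grid else map_a
  b <- if (inherits(map_b, "morphology_map")) map_b$grid else map_b
  if (!all(dim(a) == dim(b))) stop("maps must share the same grid geometry")
  na <- sum(a^2)
  nb <- sum(b^2)
  if (na == 0 || nb == 0) stop("all-zero map: cross-correlation undefined")
  sum(a * b) / sqrt(na * nb)
}
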