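# Cell segmentation from the F-actin channel and per-cell geometry.

#' Denoise and normalize a raw fluorescence image
#'
#' 3x3 median filter followed by min-max normalization of the dynamic range to
#' [0, 1]. A constant image normalizes to all zeros and is flagged with the
#' attribute \code{"constant"}.
#'
#' @param raw 2-D nonnegative intensity matrix (any scale, e.g. 16-bit counts).
#' @return matrix in [0, 1].
#' @export
preprocess <- function(raw) {
  stopifnot(is.matrix(raw))
  if (any(!is.finite(raw)) || any(raw < 0)) {
    stop("raw image must be finite and nonnegative")
  }
  mx <- max(raw)
  x <- if (mx > 0) raw / mx else raw # median filter operates on [0, 1]
  x <- median2(x, 1)
  normalize01(x)
}

#' Background model from the lowest peak of the intensity histogram
#'
#' Builds a 256-bin histogram of the image, smooths it with a 5-bin moving
#' average, and takes the lowest-intensity local maximum as the background
#' level \code{bg}. Its spread \code{sd} is the sigma of a Gaussian fitted to
#' the raw counts within +-15 bins of the peak, with a half-width at
#' half-maximum fallback (HWHM / 1.177) if the fit fails.
#'
#' @param img intensity matrix in [0, 1] (see \code{\link{preprocess}}).
#' @param bins number of histogram bins.
#' @param fov_id identifier used in error messages.
#' @return list with \code{bg} and \code{sd} (both on the [0, 1] intensity
#'   scale).
#' @export
estimate_background <- function(img, bins = 256, fov_id = "image") {
  stopifnot(is.matrix(img))
  v <- as.vector(img)
  if (min(v) < 0 || max(v) > 1) stop("image must be normalized to [0, 1]")
  if (stats::var(v) == 0) {
    return(list(bg = v[1], sd = 0))
  }
  breaks <- seq(0, 1, length.out = bins + 1)
  mids <- (breaks[-1] + breaks[-(bins + 1)]) / 2
  counts <- tabulate(pmin(pmax(findInterval(v, breaks, rightmost.closed = TRUE), 1L), bins), bins)
  # 5-bin moving average with zero padding at the ends
  padded <- c(0, 0, counts, 0, 0)
  sm <- vapply(seq_len(bins), function(i) mean(padded[i:(i + 4)]), numeric(1))
  # local maxima over a +-2 bin neighbourhood, above the noise floor
  floor_c <- max(1, 0.05 * max(sm))
  peaks <- which(vapply(seq_len(bins), function(i) {
    win <- sm[max(1, i - 2):min(bins, i + 2)]
    sm[i] >= max(win) && sm[i] > floor_c
  }, logical(1)))
  if (length(peaks) == 0L) {
    stop(sprintf("no background peak detectable in intensity histogram (%s)", fov_id))
  }
  p <- peaks[1]
  bg <- mids[p]
  win <- max(1, p - 15):min(bins, p + 15)
  sd_est <- NA_real_
  fit <- try(
    suppressWarnings(stats::nls(
      cnt ~ A * exp(-(x - mu)^2 / (2 * sg^2)),
      data = data.frame(cnt = counts[win], x = mids[win]),
      start = list(A = counts[p], mu = bg, sg = 2 * (mids[2] - mids[1])),
      control = stats::nls.control(maxiter = 200, warnOnly = TRUE)
    )),
    silent = TRUE
  )
  binw <- mids[2] - mids[1]
  if (!inherits(fit, "try-error")) {
    cf <- stats::coef(fit)
    if (is.finite(cf[["sg"]]) && cf[["sg"]] > 0) sd_est <- abs(cf[["sg"]])
  }
  # reject fits outside the resolvable range of the histogram window
  if (!is.finite(sd_est) || sd_est < binw / 3 || sd_est > 20 * binw) {
    # HWHM fallback on the smoothed histogram
    half <- sm[p] / 2
    lo <- p
    while (lo > 1 && sm[lo] > half) lo <- lo - 1
    hi <- p
    while (hi < bins && sm[hi] > half) hi <- hi + 1
    hwhm <- (mids[hi] - mids[lo]) / 2
    sd_est <- hwhm / 1.177
  }
  # a peak narrower than a bin is resolution-limited, not noise-free
  sd_est <- max(sd_est, binw / 2.355)
  list(bg = bg, sd = sd_est)
}

#' Threshold an image against its background model
#'
#' A pixel belongs to the foreground iff its value exceeds
#' \code{bg + k * sd} (default k = 10).
#'
#' @param img intensity matrix in [0, 1].
#' @param model background model from \code{\link{estimate_background}}.
#' @param k threshold multiplier on the background spread.
#' @return logical matrix.
#' @export
binarize <- function(img, model, k = 10) {
  stopifnot(is.matrix(img), is.list(model))
  img > model$bg + k * model$sd
}

# Fill background holes (not connected to the image border) strictly smaller
# than max_hole pixels.
fill_small_holes <- function(m, max_hole = 1000) {
  inv <- EBImage::bwlabel(!m)
  inv <- as.matrix(inv)
  if (max(inv) == 0) return(m)
  border <- unique(c(inv[1, ], inv[nrow(inv), ], inv[, 1], inv[, ncol(inv)]))
  sizes <- tabulate(inv, nbins = max(inv))
  fill <- setdiff(which(sizes < max_hole), border)
  if (length(fill)) m[inv %in% fill] <- TRUE
  m
}

#' Morphological cleaning and labelling of a binary cell mask
#'
#' Applies the mask-cleaning sequence: opening with a disc of radius
#' \code{opening_radius} (removes thin bridges between touching cells),
#' removal of opened components strictly smaller than \code{min_size} pixels,
#' restoration of the surviving components' pre-opening pixels (label-
#' constrained geodesic propagation within the original mask, so bridge pixels
#' are split between their two cells rather than re-merging them), filling of
#' interior holes strictly smaller than \code{max_hole} pixels, and smoothing
#' of the outlines with a \code{smooth} x \code{smooth} median filter.
#'
#' @param mask logical matrix.
#' @param opening_radius disc radius for the opening (pixels).
#' @param min_size minimum object size (pixels, strict).
#' @param max_hole maximum size of a hole that gets filled (pixels, strict).
#' @param smooth median-filter window edge for outline smoothing (odd).
#' @return integer label matrix (0 = background); empty mask gives all zeros.
#' @export
clean_and_label <- function(mask, opening_radius = 5, min_size = 1000,
                            max_hole = 1000, smooth = 7) {
  stopifnot(is.matrix(mask))
  mask <- mask > 0
  out <- array(0L, dim(mask))
  if (!any(mask)) return(out)
  brush <- EBImage::makeBrush(2 * opening_radius + 1, shape = "disc")
  opened <- as.matrix(EBImage::opening(EBImage::Image(mask * 1), brush)) > 0.5
  lab <- as.matrix(EBImage::bwlabel(opened))
  if (max(lab) == 0) return(out)
  sizes <- tabulate(lab, nbins = max(lab))
  keep <- which(sizes >= min_size)
  if (length(keep) == 0L) return(out)
  seeds <- array(0L, dim(lab))
  for (i in seq_along(keep)) seeds[lab == keep[i]] <- i
  restored <- as.matrix(EBImage::propagate(
    x = EBImage::Image(array(0, dim(mask))),
    seeds = EBImage::Image(seeds),
    mask = EBImage::Image(mask * 1),
    lambda = 1
  ))
  nid <- 0L
  for (i in seq_along(keep)) {
    mi <- restored == i
    if (!any(mi)) next
    mi <- fill_small_holes(mi, max_hole)
    mi <- median2(mi * 1, (smooth - 1L) %/% 2L) > 0.5
    if (!any(mi)) next
    nid <- nid + 1L
    out[mi] <- nid
  }
  out
}

#' Per-cell geometry from a label map
#'
#' Builds one record per labelled object with pixel count, area, centroid and
#' ellipticity. Ellipticity is the long-to-short axis ratio of the equivalent
#' ellipse, \eqn{\sqrt{\lambda_1/\lambda_2}} of the second central moment
#' matrix of the binary mask (1 for a disc). Objects can be excluded manually
#' (e.g. clumped platelets identified during visual QC) via
#' \code{exclusions}, and border-touching objects are flagged excluded by
#' default since truncated cells bias all downstream metrics; excluded records
#' are kept with their reason.
#'
#' @param labels integer label matrix from \code{\link{clean_and_label}}.
#' @param pixel_size_nm pixel edge length in nanometres.
#' @param fov_id field-of-view identifier.
#' @param exclusions data.frame with columns \code{fov_id}, \code{cell_id} of
#'   manually excluded objects (ids not present trigger a warning, not an
#'   error).
#' @param exclude_border flag border-touching cells as excluded.
#' @return data.frame with columns \code{fov_id, cell_id, n_px, area_um2,
#'   centroid_x, centroid_y, ellipticity, excluded, exclude_reason}.
#'   Coordinates are 1-based pixel indices (x = column, y = row).
#' @export
extract_cells <- function(labels, pixel_size_nm = 60, fov_id = "fov",
                          exclusions = NULL, exclude_border = TRUE) {
  stopifnot(is.matrix(labels))
  n <- max(labels)
  ps_um <- pixel_size_nm / 1000
  if (n == 0L) {
    return(data.frame(
      fov_id = character(), cell_id = integer(), n_px = integer(),
      area_um2 = numeric(), centroid_x = numeric(), centroid_y = numeric(),
      ellipticity = numeric(), excluded = logical(),
      exclude_reason = character(), stringsAsFactors = FALSE
    ))
  }
  man <- integer(0)
  if (!is.null(exclusions)) {
    ex <- exclusions[exclusions$fov_id == fov_id, , drop = FALSE]
    man <- as.integer(ex$cell_id)
    missing_ids <- setdiff(man, seq_len(n))
    if (length(missing_ids)) {
      warning(sprintf(
        "exclusion ids not present in %s: %s", fov_id,
        paste(missing_ids, collapse = ", ")
      ))
      man <- intersect(man, seq_len(n))
    }
  }
  g <- coord_grids(nrow(labels), ncol(labels))
  rec <- lapply(seq_len(n), function(i) {
    sel <- labels == i
    npx <- sum(sel)
    xs <- g$x[sel]
    ys <- g$y[sel]
    x0 <- mean(xs)
    y0 <- mean(ys)
    if (npx > 1) {
      cm <- stats::cov(cbind(xs, ys)) * (npx - 1) / npx
      ev <- sort(eigen(cm, symmetric = TRUE, only.values = TRUE)$values,
                 decreasing = TRUE)
      ell <- if (ev[2] > 0) sqrt(ev[1] / ev[2]) else Inf
    } else {
      ell <- 1
    }
    border <- any(sel[1, ]) || any(sel[nrow(sel), ]) ||
      any(sel[, 1]) || any(sel[, ncol(sel)])
    reason <- NA_character_
    if (i %in% man) {
      reason <- "manual"
    } else if (exclude_border && border) {
      reason <- "border"
    }
    data.frame(
      fov_id = fov_id, cell_id = i, n_px = npx,
      area_um2 = npx * ps_um^2, centroid_x = x0, centroid_y = y0,
      ellipticity = ell, excluded = !is.na(reason),
      exclude_reason = reason, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rec)
}

#' Gate fully spread cells by area
#'
#' Keeps cells whose area is strictly larger than \code{min_area_um2}
#' (default 20 um^2, the fully-spread criterion) and that are not excluded.
#'
#' @param cells data.frame from \code{\link{extract_cells}}.
#' @param min_area_um2 strict lower area bound in um^2.
#' @return subset of \code{cells}.
#' @export
gate_spread <- function(cells, min_area_um2 = 20) {
  cells[cells$area_um2 > min_area_um2 & !cells$excluded, , drop = FALSE]
}
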