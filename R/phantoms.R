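# Synthetic dual-channel phantoms with ground truth.
#
# The generator emulates the imaging conditions the analysis expects: a dark
# background (~5% of the dynamic range) with additive Gaussian noise, bright
# elliptical cells carrying a ridge-stripe fibre texture of controlled
# orientation statistics in the actin channel, and rim-located vinculin
# puncta whose circumferential intensity profile follows 1 + a*cos(k*alpha).
#
# Cell rendering is designed so that the ground-truth orientation statistics
# are not contaminated by structures that are not fibres: the texture is a
# zero-mean modulation around a flat mean level (a mean-intensity gradient
# inside the cell would add its own, radially oriented curvature to the
# orientation tensor), the mean dims towards the rim (lamellipodium-like,
# keeping the weight of boundary pixels low), the boundary step is sharp (so
# its tangential signature stays confined to the tensor-blur depth), and the
# centre is a non-fibrous flat plateau (granulomere-like, avoiding the
# aliasing of centre-symmetric patterns at small radii).

#' Specify one phantom cell
#'
#' @param center numeric length-2 (x, y) centre in pixel coordinates.
#' @param semi_axes numeric length-2 ellipse semi-axes in pixels (sorted so
#'   the first is the larger; the long axis lies along x).
#' @param fibre_pattern one of \code{"parallel"}, \code{"radial"},
#'   \code{"circumferential"}, \code{"spiral"}, \code{"random"}.
#' @param fibre_angle_deg stripe orientation for the parallel pattern
#'   (degrees).
#' @param spiral_pitch_deg angle between fibre and radial direction for the
#'   spiral pattern (degrees; 45 gives the mixed radial-order anchor 0.5).
#' @param fibre_contrast peak-to-trough amplitude of the fibre texture
#'   modulation (intensity fraction; capped so intensities stay positive).
#' @param vinculin_order integer k in {0, 2, 3, 4}: angular symmetry of the
#'   vinculin puncta arrangement (0 = uniform rim).
#' @param vinculin_amplitude modulation amplitude a in [0, 1] of the
#'   circumferential profile 1 + a*cos(k*alpha - phase).
#' @param vinculin_phase_deg phase of the modulation (degrees).
#' @return object of class \code{phantom_cell}.
#' @export
phantom_cell <- function(center, semi_axes,
                         fibre_pattern = c("parallel", "radial",
                                           "circumferential", "spiral",
                                           "random"),
                         fibre_angle_deg = 0, spiral_pitch_deg = 45,
                         fibre_contrast = 0.7,
                         vinculin_order = 0, vinculin_amplitude = 0,
                         vinculin_phase_deg = 0) {
  fibre_pattern <- match.arg(fibre_pattern)
  stopifnot(
    length(center) == 2L, all(is.finite(center)),
    length(semi_axes) == 2L, all(semi_axes > 0),
    fibre_contrast > 0,
    vinculin_order %in% c(0L, 2L, 3L, 4L)
  )
  if (vinculin_amplitude < 0 || vinculin_amplitude > 1) {
    stop("vinculin_amplitude must lie in [0, 1] (amplitudes > 1 imply negative intensities)")
  }
  structure(
    list(
      center = as.numeric(center),
      semi_axes = sort(as.numeric(semi_axes), decreasing = TRUE),
      fibre_pattern = fibre_pattern,
      fibre_angle_deg = fibre_angle_deg,
      spiral_pitch_deg = spiral_pitch_deg,
      fibre_contrast = fibre_contrast,
      vinculin_order = as.integer(vinculin_order),
      vinculin_amplitude = vinculin_amplitude,
      vinculin_phase_deg = vinculin_phase_deg
    ),
    class = "phantom_cell"
  )
}

#' Specify a phantom field of view
#'
#' @param image_size integer length-2 (rows, cols), at least 64 x 64.
#' @param pixel_size_nm pixel edge length in nanometres.
#' @param background_level actin-channel background as a fraction of the
#'   dynamic range.
#' @param background_noise_sd additive Gaussian noise sd (both channels).
#' @param vinculin_background vinculin-channel background level (immuno
#'   stainings have a darker background than the cytosolic actin signal).
#' @param cells list of \code{\link{phantom_cell}} specs.
#' @param seed integer RNG seed; a fixed seed makes the rendered images
#'   bit-identical across runs.
#' @param cell_level mean actin intensity in the cell body.
#' @param rim_level mean actin intensity the rim dims down to.
#' @param rim_start ellipse coordinate at which the rim dimming starts.
#' @param min_intensity lower bound on cell intensity (texture troughs are
#'   capped to stay above it; must clear the segmentation threshold).
#' @param edge_px width of the boundary intensity step.
#' @param core_frac fraction of the semi-axes occupied by the non-fibrous
#'   central plateau.
#' @param stripe_period fibre stripe period in pixels.
#' @param punctum_sigma Gaussian sigma of a vinculin punctum (pixels).
#' @param puncta_radii radial positions of the puncta as fractions of the
#'   local rim radius.
#' @return object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(image_size = c(256, 256), pixel_size_nm = 60,
                         background_level = 0.05, background_noise_sd = 0.005,
                         vinculin_background = 0.01,
                         cells = list(), seed = 1L,
                         cell_level = 0.55, rim_level = 0.27,
                         rim_start = 0.82, min_intensity = 0.13,
                         edge_px = 2, core_frac = 0.35,
                         stripe_period = 8, punctum_sigma = 2,
                         puncta_radii = c(0.72, 0.84)) {
  stopifnot(
    length(image_size) == 2L, all(image_size >= 64),
    pixel_size_nm > 0, background_level >= 0, background_noise_sd >= 0,
    vinculin_background >= 0, cell_level > rim_level,
    rim_level >= min_intensity, min_intensity > 0, edge_px > 0,
    rim_start > 0 && rim_start < 1, stripe_period > 0,
    punctum_sigma > 0, length(puncta_radii) >= 1
  )
  if (background_level + 6 * background_noise_sd >= min_intensity) {
    stop("background_level + 6 * background_noise_sd must stay below min_intensity")
  }
  for (cl in cells) {
    if (!inherits(cl, "phantom_cell")) stop("cells must be phantom_cell objects")
  }
  structure(
    list(
      image_size = as.integer(image_size), pixel_size_nm = pixel_size_nm,
      background_level = background_level,
      background_noise_sd = background_noise_sd,
      vinculin_background = vinculin_background,
      cells = cells, seed = as.integer(seed),
      cell_level = cell_level, rim_level = rim_level,
      rim_start = rim_start, min_intensity = min_intensity,
      edge_px = edge_px, core_frac = core_frac,
      stripe_period = stripe_period, punctum_sigma = punctum_sigma,
      puncta_radii = puncta_radii
    ),
    class = "phantom_spec"
  )
}

# local ellipse radius at polar angle alpha for semi-axes (a, b)
ellipse_radius <- function(a, b, alpha) {
  a * b / sqrt((b * cos(alpha))^2 + (a * sin(alpha))^2)
}

#' Render a fibre texture with a known orientation map
#'
#' Generates a ridge-stripe intensity texture (raised-cosine stripes of the
#' given period) inside a region, together with the exact axial angle of the
#' ridges at every pixel. Patterns: \code{parallel} (stripes at a fixed
#' angle), \code{radial} (spokes radiating from the centre; angle = direction
#' from centre), \code{circumferential} (concentric rings; angle
#' perpendicular to the radius), \code{spiral} (logarithmic spiral whose
#' fibres everywhere make \code{pitch_deg} with the radial direction) and
#' \code{random} (independent stripe orientation per square block; consumes
#' the current RNG stream).
#'
#' @param pattern pattern name (see above).
#' @param mask logical matrix: the region to texture (must be nonempty).
#' @param center numeric (x, y) used by the centre-symmetric patterns.
#' @param angle_deg stripe angle for \code{parallel} (degrees).
#' @param pitch_deg spiral pitch relative to the radial direction (degrees).
#' @param period stripe period in pixels.
#' @param block_px block edge for the \code{random} pattern.
#' @return list with \code{tex} (intensity grid in [0, 1], zero outside the
#'   region) and \code{angle} (axial angle map in radians, \code{NA} outside
#'   the region).
#' @export
make_fibre_texture <- function(pattern, mask, center = NULL, angle_deg = 0,
                               pitch_deg = 45, period = 8, block_px = 12) {
  if (!pattern %in% c("parallel", "radial", "circumferential", "spiral",
                      "random")) {
    stop("unknown fibre pattern: ", pattern)
  }
  stopifnot(is.matrix(mask))
  if (!any(mask)) stop("texture region is empty")
  nr <- nrow(mask)
  nc <- ncol(mask)
  g <- coord_grids(nr, nc)
  if (is.null(center)) {
    center <- c(mean(g$x[mask]), mean(g$y[mask]))
  }
  dx <- g$x - center[1]
  dy <- g$y - center[2]
  rho <- sqrt(dx^2 + dy^2)
  psi <- atan2(dy, dx)
  tex <- array(0, dim(mask))
  ang <- array(NA_real_, dim(mask))
  if (pattern == "parallel") {
    th <- deg2rad(angle_deg)
    u <- -g$x * sin(th) + g$y * cos(th)
    tex <- 0.5 * (1 + cos(2 * pi * u / period))
    ang[] <- wrap_axial(th)
  } else if (pattern == "radial") {
    # spokes: angular stripe frequency chosen for ~`period` px arc spacing
    # near the rim, where most of the weight lives
    rmid <- 0.9 * max(rho[mask])
    nspokes <- max(6, round(2 * pi * rmid / period))
    tex <- 0.5 * (1 + cos(nspokes * psi))
    ang <- wrap_axial(psi)
  } else if (pattern == "circumferential") {
    tex <- 0.5 * (1 + cos(2 * pi * rho / period))
    ang <- wrap_axial(psi + pi / 2)
  } else if (pattern == "spiral") {
    beta <- deg2rad(pitch_deg)
    rmid <- 0.9 * max(rho[mask])
    kg <- 2 * pi * rmid / period
    lr <- log(pmax(rho, 0.5))
    tex <- 0.5 * (1 + cos(kg * (cos(beta) * lr - sin(beta) * psi)))
    ang <- wrap_axial(psi + pi / 2 - beta)
  } else { # random: per-block orientation from the current RNG stream
    bi <- ((row(mask) - 1L) %/% block_px)
    bj <- ((col(mask) - 1L) %/% block_px)
    nbi <- max(bi) + 1L
    nbj <- max(bj) + 1L
    th_block <- matrix(stats::runif(nbi * nbj, -pi / 2, pi / 2), nbi, nbj)
    th <- th_block[cbind(as.vector(bi) + 1L, as.vector(bj) + 1L)]
    th <- matrix(th, nr, nc)
    u <- -g$x * sin(th) + g$y * cos(th)
    tex <- 0.5 * (1 + cos(2 * pi * u / period))
    ang <- wrap_axial(th)
  }
  tex[!mask] <- 0
  ang[!mask] <- NA_real_
  list(tex = tex, angle = ang)
}

# Render rim puncta whose in-mask per-sector integrated intensity matches
# `sector_targets` (length 20). Puncta sit at the 20 sector-centre angles at
# the given radial fractions of the local rim radius; their amplitudes are
# solved by a short render-measure-correct loop so that sector sums hit the
# targets despite edge truncation and sector leakage.
render_puncta <- function(mask, center, semi_axes, sector_targets,
                          sigma = 2, radii_frac = c(0.72, 0.84)) {
  n_sec <- length(sector_targets)
  stopifnot(n_sec >= 4, all(sector_targets >= 0))
  nr <- nrow(mask)
  nc <- ncol(mask)
  g <- coord_grids(nr, nc)
  sec_width <- 2 * pi / n_sec
  alpha_c <- (seq_len(n_sec) - 0.5) * sec_width
  # sector index of every in-mask pixel (about the true centre)
  ang_pix <- atan2(g$y - center[2], g$x - center[1]) %% (2 * pi)
  sec_pix <- pmin(floor(ang_pix / sec_width) + 1L, n_sec)
  # unit-amplitude punctum patches and their per-sector in-mask masses
  rad <- ceiling(4 * sigma)
  n_per <- length(radii_frac)
  n_punc <- n_sec * n_per
  patches <- vector("list", n_punc)
  masses <- matrix(0, n_sec, n_punc) # sector x punctum
  p <- 0L
  for (s in seq_len(n_sec)) {
    re <- ellipse_radius(semi_axes[1], semi_axes[2], alpha_c[s])
    for (f in radii_frac) {
      p <- p + 1L
      px <- center[1] + f * re * cos(alpha_c[s])
      py <- center[2] + f * re * sin(alpha_c[s])
      i0 <- max(1L, floor(py) - rad)
      i1 <- min(nr, ceiling(py) + rad)
      j0 <- max(1L, floor(px) - rad)
      j1 <- min(nc, ceiling(px) + rad)
      ii <- i0:i1
      jj <- j0:j1
      gx <- matrix(rep(jj, each = length(ii)), length(ii))
      gy <- matrix(rep(ii, times = length(jj)), length(ii))
      val <- exp(-((gx - px)^2 + (gy - py)^2) / (2 * sigma^2))
      patches[[p]] <- list(ii = ii, jj = jj, val = val)
      inm <- mask[ii, jj, drop = FALSE]
      sp <- matrix(sec_pix[cbind(as.vector(gy), as.vector(gx))],
                   length(ii))
      for (s2 in unique(as.vector(sp[inm]))) {
        masses[s2, p] <- sum(val[inm & sp == s2])
      }
    }
  }
  punc_sec <- rep(seq_len(n_sec), each = n_per)
  amp <- sector_targets[punc_sec] /
    pmax(vapply(seq_len(n_punc),
                function(p) sum(masses[, punc_sec == punc_sec[p], drop = FALSE]),
                numeric(1)), 1e-9)
  for (it in 1:4) { # linear system is diagonally dominant; fixed point
    achieved <- as.vector(masses %*% amp)
    corr <- ifelse(achieved > 1e-9, sector_targets / achieved, 1)
    amp <- amp * corr[punc_sec]
  }
  img <- array(0, dim(mask))
  for (p in seq_len(n_punc)) {
    pa <- patches[[p]]
    img[pa$ii, pa$jj] <- img[pa$ii, pa$jj] + amp[p] * pa$val
  }
  img
}

#' Render a vinculin puncta pattern with k-fold symmetry
#'
#' Places Gaussian puncta near the rim of the region so that the
#' circumferentially integrated intensity (20 angular sectors about the
#' centre) is proportional to \eqn{1 + a \cos(k\alpha - \alpha_0)}.
#'
#' @param k integer angular order (0, 2, 3 or 4).
#' @param amplitude modulation amplitude a in [0, 1].
#' @param mask logical region matrix.
#' @param center numeric (x, y) centre; defaults to the region centroid.
#' @param semi_axes rim semi-axes; defaults to an effective disc radius.
#' @param phase_deg modulation phase alpha0 (degrees).
#' @param sigma punctum Gaussian sigma (pixels).
#' @param radii_frac radial punctum positions as fractions of the rim radius.
#' @param n_sectors number of sectors the profile is defined on.
#' @return intensity grid (matrix), background-free.
#' @export
make_vinculin_pattern <- function(k, amplitude, mask, center = NULL,
                                  semi_axes = NULL, phase_deg = 0,
                                  sigma = 2, radii_frac = c(0.72, 0.84),
                                  n_sectors = 20) {
  stopifnot(k %in% c(0L, 2L, 3L, 4L))
  if (amplitude < 0 || amplitude > 1) {
    stop("amplitude must lie in [0, 1] (amplitudes > 1 imply negative intensities)")
  }
  if (!any(mask)) stop("region is empty")
  g <- coord_grids(nrow(mask), ncol(mask))
  if (is.null(center)) center <- c(mean(g$x[mask]), mean(g$y[mask]))
  if (is.null(semi_axes)) {
    r_eff <- sqrt(sum(mask) / pi)
    semi_axes <- c(r_eff, r_eff)
  }
  alpha_c <- (seq_len(n_sectors) - 0.5) * 2 * pi / n_sectors
  targets <- 1 + amplitude * cos(k * (alpha_c - deg2rad(phase_deg)))
  render_puncta(mask, center, semi_axes, targets,
                sigma = sigma, radii_frac = radii_frac)
}

# map a cell spec to its ground-truth morphology class
truth_class <- function(k, amplitude, r_isotropic = 0.33) {
  if (k == 0L || (amplitude - 0.25) < r_isotropic) return("isotropic")
  c(`2` = "bipolar", `3` = "triangular", `4` = "quadratic")[[as.character(k)]]
}

#' Render a phantom field of view
#'
#' Draws the actin and vinculin channels of a phantom FOV plus its ground
#' truth. Rendering is fully determined by the spec (including its seed):
#' running the same spec twice yields identical pixel arrays. Cells whose
#' ellipses overlap or extend beyond the image are rejected.
#'
#' The vinculin sector targets are compensated for the diffuse background the
#' phantom itself adds inside the cell mask, so that the *total*
#' circumferential profile a downstream sector analysis sees follows
#' \code{1 + a cos(k alpha - alpha0)}.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return object of class \code{phantom_fov}: list with \code{actin} and
#'   \code{vinculin} (matrices in [0, 1]) and \code{truth} (label map,
#'   axial angle map, per-cell table, per-cell sector profiles).
#' @export
make_fov <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  nr <- spec$image_size[1]
  nc <- spec$image_size[2]
  set.seed(spec$seed)
  actin <- matrix(
    spec$background_level + stats::rnorm(nr * nc, sd = spec$background_noise_sd),
    nr, nc
  )
  vinc <- matrix(
    spec$vinculin_background + stats::rnorm(nr * nc, sd = spec$background_noise_sd),
    nr, nc
  )
  vinc_base <- vinc
  labels <- array(0L, c(nr, nc))
  angle_map <- array(NA_real_, c(nr, nc))
  g <- coord_grids(nr, nc)
  cells_df <- NULL
  profiles <- list()
  vinc_cells <- list()
  n_sec <- 20L
  alpha_c <- (seq_len(n_sec) - 0.5) * 2 * pi / n_sec
  sec_width <- 2 * pi / n_sec
  for (i in seq_along(spec$cells)) {
    cl <- spec$cells[[i]]
    a <- cl$semi_axes[1]
    b <- cl$semi_axes[2]
    cx <- cl$center[1]
    cy <- cl$center[2]
    if (cx - a < 1 || cx + a > nc || cy - b < 1 || cy + b > nr) {
      stop(sprintf("cell %d extends beyond the image", i))
    }
    e <- sqrt(((g$x - cx) / a)^2 + ((g$y - cy) / b)^2)
    mask <- e <= 1
    if (any(labels[mask] != 0L)) {
      stop(sprintf("cell %d overlaps a previously placed cell", i))
    }
    labels[mask] <- i
    # flat mean level dimming towards the rim, zero-mean texture
    # modulation, non-fibrous central plateau, sharp boundary step
    rmin <- min(a, b)
    tx <- make_fibre_texture(
      cl$fibre_pattern, mask, center = c(cx, cy),
      angle_deg = cl$fibre_angle_deg, pitch_deg = cl$spiral_pitch_deg,
      period = spec$stripe_period
    )
    mid <- spec$cell_level - (spec$cell_level - spec$rim_level) *
      smoothstep((e - spec$rim_start) / (1 - spec$rim_start))
    amp <- pmin(cl$fibre_contrast / 2, mid - spec$min_intensity)
    w_core <- smoothstep((e - spec$core_frac) / 0.1)
    cell_int <- mid + 2 * amp * (tx$tex - 0.5) * w_core
    edge_ramp <- pmin(1, pmax(0, (1 - e) * rmin / spec$edge_px))
    actin[mask] <- actin[mask] +
      (cell_int[mask] - spec$background_level) * edge_ramp[mask]
    tex_ok <- mask & w_core > 0.05
    angle_map[tex_ok] <- tx$angle[tex_ok]
    # vinculin: sector targets compensated for the diffuse background the
    # phantom itself adds inside the analysis mask
    ang_pix <- atan2(g$y - cy, g$x - cx) %% (2 * pi)
    sec_pix <- pmin(floor(ang_pix / sec_width) + 1L, n_sec)
    n_c <- tabulate(sec_pix[mask], n_sec)
    b_c <- spec$vinculin_background * n_c
    t_c <- 1 + cl$vinculin_amplitude *
      cos(cl$vinculin_order * (alpha_c - deg2rad(cl$vinculin_phase_deg)))
    if (cl$vinculin_order == 0L) t_c <- rep(1, n_sec)
    mass_base <- 25 # mean punctum mass budget per sector
    s_tot <- max(mean(b_c) + mass_base, 1.25 * max(b_c / pmax(t_c, 1e-6)))
    p_c <- pmax(s_tot * t_c - b_c, 0)
    vinc_cells[[i]] <- list(
      mask = mask, center = c(cx, cy), axes = c(a, b),
      p_c = p_c, t_c = t_c
    )
    cls <- truth_class(cl$vinculin_order, cl$vinculin_amplitude)
    al_t <- switch(cl$fibre_pattern, parallel = 1, random = 0, NA_real_)
    rad_t <- switch(cl$fibre_pattern,
      radial = 1, circumferential = 0,
      spiral = 0.5 * cos(2 * deg2rad(cl$spiral_pitch_deg)) + 0.5,
      random = 0.5, NA_real_
    )
    cells_df <- rbind(cells_df, data.frame(
      cell_id = i, center_x = cx, center_y = cy,
      semi_a = a, semi_b = b, fibre_pattern = cl$fibre_pattern,
      vinculin_order = cl$vinculin_order,
      vinculin_amplitude = cl$vinculin_amplitude,
      class = cls, alignment_target = al_t, radial_target = rad_t,
      stringsAsFactors = FALSE
    ))
    profiles[[i]] <- t_c
  }
  actin <- pmin(pmax(actin, 0), 1)
  # Render the vinculin puncta, then calibrate the per-sector targets
  # against the channel as the analysis sees it (after median denoising and
  # min-max normalization, which shifts the effective diffuse background):
  # two multiplicative corrections bring the preprocessed circumferential
  # profile onto 1 + a*cos(k*alpha) to well under a percent.
  if (length(vinc_cells)) {
    render_all <- function() {
      v <- vinc_base
      for (vc in vinc_cells) {
        v <- v + render_puncta(vc$mask, vc$center, vc$axes, vc$p_c,
                               sigma = spec$punctum_sigma,
                               radii_frac = spec$puncta_radii)
      }
      pmin(pmax(v, 0), 1)
    }
    for (it in 1:2) {
      vp <- preprocess(render_all())
      for (j in seq_along(vinc_cells)) {
        vc <- vinc_cells[[j]]
        prof <- sector_profile(vp, vc$mask, vc$center, n_sectors = n_sec)
        if (is.null(attr(prof, "flag"))) {
          ratio <- vc$t_c / pmax(prof, 0.05)
          vinc_cells[[j]]$p_c <- vc$p_c *
            pmin(pmax(ratio, 0.5), 2)
        }
      }
    }
    vinc <- render_all()
  } else {
    vinc <- pmin(pmax(vinc, 0), 1)
  }
  structure(
    list(
      actin = actin, vinculin = vinc,
      truth = list(labels = labels, angle = angle_map,
                   cells = cells_df, profiles = profiles),
      spec = spec
    ),
    class = "phantom_fov"
  )
}

#' @export
print.phantom_fov <- function(x, ...) {
  cat(
    "phantom FOV:", nrow(x$actin), "x", ncol(x$actin), "px,",
    max(x$truth$labels), "cells\n"
  )
  invisible(x)
}

#' Write a phantom FOV to disk
#'
#' Writes 16-bit TIFFs for the two channels and the label map, plus a JSON
#' ground-truth sidecar.
#'
#' @param fov a \code{\link{make_fov}} result.
#' @param dir output directory (created if needed).
#' @param stem filename stem; files are \code{<stem>_actin.tif},
#'   \code{<stem>_vinculin.tif}, \code{<stem>_labels.tif},
#'   \code{<stem>_truth.json}.
#' @return invisibly, the written file paths.
#' @export
write_fov <- function(fov, dir, stem = "fov1") {
  stopifnot(inherits(fov, "phantom_fov"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pa <- file.path(dir, paste0(stem, "_actin.tif"))
  pv <- file.path(dir, paste0(stem, "_vinculin.tif"))
  pl <- file.path(dir, paste0(stem, "_labels.tif"))
  pj <- file.path(dir, paste0(stem, "_truth.json"))
  tiff::writeTIFF(fov$actin, pa, bits.per.sample = 16)
  tiff::writeTIFF(fov$vinculin, pv, bits.per.sample = 16)
  tiff::writeTIFF(fov$truth$labels / 65535, pl, bits.per.sample = 16)
  jsonlite::write_json(
    list(cells = fov$truth$cells, profiles = fov$truth$profiles),
    pj, auto_unbox = TRUE, digits = NA
  )
  invisible(c(pa, pv, pl, pj))
}

#' Simulate a dose-response table from a logistic Hill model
#'
#' \eqn{y = bottom + (top - bottom) / (1 + (dose/ic50)^{hill})} plus additive
#' Gaussian noise. With \code{hill > 0} the response falls from \code{top}
#' (dose -> 0) to \code{bottom} (dose -> infinity) and equals
#' \code{(top + bottom)/2} at \code{dose = ic50}.
#'
#' @param top,bottom asymptotic response levels.
#' @param ic50 half-maximal dose (> 0).
#' @param hill Hill slope.
#' @param doses vector of positive doses.
#' @param noise_sd additive Gaussian noise sd.
#' @param reps replicates per dose.
#' @param seed optional RNG seed.
#' @return data.frame with columns \code{dose}, \code{response}.
#' @export
make_dose_response <- function(top, bottom, ic50, hill, doses,
                               noise_sd = 0, reps = 1, seed = NULL) {
  stopifnot(ic50 > 0, all(doses > 0), noise_sd >= 0, reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  d <- rep(doses, each = reps)
  y <- bottom + (top - bottom) / (1 + (d / ic50)^hill)
  if (noise_sd > 0) y <- y + stats::rnorm(length(y), sd = noise_sd)
  data.frame(dose = d, response = y)
}

#' Phantom specs for a class-labelled population
#'
#' Convenience generator for end-to-end screens: lays out cells on a grid
#' over several FOVs, assigning each cell a vinculin class (k = 2, 3 or 4)
#' and cycling through the fibre patterns.
#'
#' @param n_per_class named integer vector: cells per class, names among
#'   \code{bipolar}, \code{triangular}, \code{quadratic}, \code{isotropic}.
#' @param amplitude vinculin modulation amplitude for the patterned classes.
#' @param fov_size FOV edge length (pixels).
#' @param grid_n cells per FOV edge (grid_n^2 cells per FOV).
#' @param radius_range min/max cell radius in pixels (cells are near-circular).
#' @param seed base seed; each FOV gets seed + fov index.
#' @param ... further arguments passed to \code{\link{phantom_spec}}.
#' @return list of \code{\link{phantom_spec}} objects.
#' @export
phantom_population_spec <- function(n_per_class = c(bipolar = 20,
                                                    triangular = 20,
                                                    quadratic = 20),
                                    amplitude = 0.6, fov_size = 640,
                                    grid_n = 4, radius_range = c(46, 52),
                                    seed = 1L, ...) {
  k_of <- c(bipolar = 2L, triangular = 3L, quadratic = 4L, isotropic = 0L)
  stopifnot(all(names(n_per_class) %in% names(k_of)))
  ks <- rep(k_of[names(n_per_class)], n_per_class)
  amps <- ifelse(ks == 0L, 0, amplitude)
  patterns <- rep_len(
    c("parallel", "radial", "circumferential", "spiral", "random"),
    length(ks)
  )
  set.seed(seed)
  ord <- sample.int(length(ks)) # interleave classes across FOVs
  ks <- ks[ord]
  amps <- amps[ord]
  per_fov <- grid_n^2
  n_fov <- ceiling(length(ks) / per_fov)
  spacing <- fov_size / grid_n
  centers <- spacing / 2 + spacing * (seq_len(grid_n) - 1)
  specs <- vector("list", n_fov)
  idx <- 0L
  for (f in seq_len(n_fov)) {
    cells <- list()
    for (gy in seq_len(grid_n)) {
      for (gx in seq_len(grid_n)) {
        idx <- idx + 1L
        if (idx > length(ks)) break
        r <- stats::runif(1, radius_range[1], radius_range[2])
        jit <- stats::runif(2, -6, 6)
        phase <- stats::runif(1, 0, 360)
        th <- stats::runif(1, -90, 90)
        cells[[length(cells) + 1L]] <- phantom_cell(
          center = c(centers[gx] + jit[1], centers[gy] + jit[2]),
          semi_axes = c(r * stats::runif(1, 1.0, 1.08), r),
          fibre_pattern = patterns[idx], fibre_angle_deg = th,
          vinculin_order = ks[idx], vinculin_amplitude = amps[idx],
          vinculin_phase_deg = phase
        )
      }
    }
    specs[[f]] <- phantom_spec(
      image_size = c(fov_size, fov_size), cells = cells,
      seed = seed + f, ...
    )
  }
  specs
}
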