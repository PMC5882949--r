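# Batch orchestration: configuration, per-FOV processing, per-cell table
# assembly, population summaries and run comparison.

#' Analysis configuration
#'
#' Collects every tunable parameter of the pipeline with its default:
#' pixel size 60 nm, spread gate 20 um^2 (strict), background threshold
#' multiplier 10, opening radius 5 px, minimum object 1000 px, maximum
#' filled hole 1000 px, 7x7 outline median, unsharp sigmas 3/5/7/9 px,
#' fibre-mask threshold 0.08, tensor blur sigma 4 px, 20 sectors,
#' morphology bin 0.02, isotropic radius 0.33, map smoothing 2 bins.
#'
#' @param pixel_size_nm pixel edge in nanometres.
#' @param gate_area_um2 strict lower area bound for fully spread cells.
#' @param threshold_k background threshold multiplier (bg + k * sd).
#' @param opening_radius disc radius of the mask opening (px).
#' @param min_object_px minimum object size (px).
#' @param max_hole_px maximum filled hole size (px).
#' @param outline_median outline median-filter window (odd, px).
#' @param unsharp_sigmas unsharp masking sigmas (px).
#' @param fibre_threshold fibre-mask threshold on the enhanced image.
#' @param tensor_sigma orientation tensor blur sigma (px).
#' @param n_sectors vinculin sectors.
#' @param map_bin morphology map bin width.
#' @param map_sigma_bins morphology map smoothing sigma (bins).
#' @param r_isotropic isotropic classification radius.
#' @param exclude_border flag border-touching cells as excluded.
#' @param literal_radial use the single-angle radial-order form.
#' @param seed RNG seed recorded with the run.
#' @return object of class \code{run_config} (a validated list).
#' @export
run_config <- function(pixel_size_nm = 60, gate_area_um2 = 20,
                       threshold_k = 10, opening_radius = 5,
                       min_object_px = 1000, max_hole_px = 1000,
                       outline_median = 7, unsharp_sigmas = c(3, 5, 7, 9),
                       fibre_threshold = 0.08, tensor_sigma = 4,
                       n_sectors = 20, map_bin = 0.02, map_sigma_bins = 2,
                       r_isotropic = 0.33, exclude_border = TRUE,
                       literal_radial = FALSE, seed = 1L) {
  cfg <- list(
    pixel_size_nm = pixel_size_nm, gate_area_um2 = gate_area_um2,
    threshold_k = threshold_k, opening_radius = opening_radius,
    min_object_px = min_object_px, max_hole_px = max_hole_px,
    outline_median = outline_median, unsharp_sigmas = unsharp_sigmas,
    fibre_threshold = fibre_threshold, tensor_sigma = tensor_sigma,
    n_sectors = n_sectors, map_bin = map_bin,
    map_sigma_bins = map_sigma_bins, r_isotropic = r_isotropic,
    exclude_border = exclude_border, literal_radial = literal_radial,
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$pixel_size_nm > 0, cfg$gate_area_um2 >= 0, cfg$threshold_k >= 0,
    cfg$opening_radius >= 1, cfg$min_object_px >= 0, cfg$max_hole_px >= 0,
    cfg$outline_median %% 2 == 1, all(cfg$unsharp_sigmas > 0),
    cfg$fibre_threshold >= 0, cfg$tensor_sigma > 0, cfg$n_sectors >= 8,
    cfg$map_bin > 0, cfg$map_sigma_bins >= 0, cfg$r_isotropic > 0
  )
  structure(cfg, class = "run_config")
}

#' Read an analysis configuration from a YAML or JSON file
#'
#' Unknown keys are rejected; missing keys keep their defaults.
#'
#' @param path file ending in .yaml/.yml or .json.
#' @return a validated \code{\link{run_config}}.
#' @export
read_run_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config file must be .yaml, .yml or .json")
  }
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  }
  do.call(run_config, vals)
}

#' @export
print.run_config <- function(x, ...) {
  cat("run configuration:\n")
  for (nm in names(x)) {
    cat(sprintf("  %-16s %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  }
  invisible(x)
}

#' Analyse one field of view
#'
#' Runs the full per-FOV pipeline: preprocessing of both channels,
#' histogram background model, thresholding at bg + k*sd, morphological
#' cleaning and labelling, per-cell geometry, the spread-area gate, the
#' orientation field and fibre mask, and — per gated cell — fibre alignment,
#' radial order, the circumferential vinculin profile, its Fourier fit,
#' morphology point and class.
#'
#' @param actin raw F-actin image (matrix).
#' @param vinculin raw vinculin image (matrix, same shape).
#' @param config a \code{\link{run_config}}.
#' @param fov_id identifier for this FOV.
#' @param exclusions optional manual exclusion table (fov_id, cell_id).
#' @return object of class \code{fov_analysis}: list with the per-cell
#'   \code{cells} data.frame (all cells, including excluded/ungated ones,
#'   with metric columns filled for analysed cells and a \code{flags}
#'   column), the \code{labels} map, the background model, and per-cell
#'   sector \code{profiles}.
#' @export
analyze_fov <- function(actin, vinculin, config = run_config(),
                        fov_id = "fov1", exclusions = NULL) {
  stopifnot(is.matrix(actin), is.matrix(vinculin),
            all(dim(actin) == dim(vinculin)))
  act <- preprocess(actin)
  vin <- preprocess(vinculin)
  bgm <- estimate_background(act, fov_id = fov_id)
  mask <- binarize(act, bgm, k = config$threshold_k)
  labels <- clean_and_label(
    mask, opening_radius = config$opening_radius,
    min_size = config$min_object_px, max_hole = config$max_hole_px,
    smooth = config$outline_median
  )
  cells <- extract_cells(
    labels, pixel_size_nm = config$pixel_size_nm, fov_id = fov_id,
    exclusions = exclusions, exclude_border = config$exclude_border
  )
  met_cols <- c("alignment", "mean_orientation_deg", "radial_order",
                "fibre_px", "w1", "w2", "w3", "w4", "r", "phi_deg",
                "x", "y")
  for (m in met_cols) cells[[m]] <- rep(NA_real_, nrow(cells))
  cells$class <- rep(NA_character_, nrow(cells))
  cells$gated <- rep(FALSE, nrow(cells))
  cells$flags <- rep(NA_character_, nrow(cells))
  profiles <- list()
  if (nrow(cells) > 0) {
    gated <- gate_spread(cells, config$gate_area_um2)
    cells$gated <- cells$cell_id %in% gated$cell_id
    if (any(cells$gated)) {
      field <- orientation_field(act, sigma = config$tensor_sigma)
      fmask <- fibre_mask(act, sigmas = config$unsharp_sigmas,
                          threshold = config$fibre_threshold)
      for (i in which(cells$gated)) {
        id <- cells$cell_id[i]
        cmask <- labels == id
        centroid <- c(cells$centroid_x[i], cells$centroid_y[i])
        flags <- character(0)
        fa <- fibre_alignment(field, fmask, cmask)
        ro <- radial_order(field, fmask, centroid, cmask,
                           literal = config$literal_radial)
        cells$alignment[i] <- fa$alignment
        cells$mean_orientation_deg[i] <- rad2deg(fa$mean_orientation)
        cells$radial_order[i] <- ro$radial_order
        cells$fibre_px[i] <- fa$n_px
        if (!is.na(fa$flag)) flags <- c(flags, fa$flag)
        prof <- sector_profile(vin, cmask, centroid,
                               n_sectors = config$n_sectors)
        if (!is.null(attr(prof, "flag"))) {
          flags <- c(flags, attr(prof, "flag"))
        } else {
          ff <- fit_fourier(prof)
          mp <- morphology_point(ff)
          cells$w1[i] <- mp$w[1]
          cells$w2[i] <- mp$w[2]
          cells$w3[i] <- mp$w[3]
          cells$w4[i] <- mp$w[4]
          cells$r[i] <- mp$r
          cells$phi_deg[i] <- mp$phi_deg
          cells$x[i] <- mp$x
          cells$y[i] <- mp$y
          cells$class[i] <- classify_morphology(mp$r, mp$phi_deg,
                                                config$r_isotropic)
        }
        profiles[[as.character(id)]] <- as.numeric(prof)
        if (length(flags)) cells$flags[i] <- paste(flags, collapse = ";")
      }
    }
  }
  structure(
    list(cells = cells, labels = labels, background = bgm,
         profiles = profiles, fov_id = fov_id, config = config),
    class = "fov_analysis"
  )
}

#' @export
print.fov_analysis <- function(x, ...) {
  cat(sprintf(
    "FOV %s: %d objects, %d gated (bg %.4f, sd %.4f)\n",
    x$fov_id, nrow(x$cells), sum(x$cells$gated),
    x$background$bg, x$background$sd
  ))
  invisible(x)
}

# pair *_actin.tif / *_vinculin.tif files in a directory by stem
pair_channels <- function(dir) {
  fa <- sort(list.files(dir, pattern = "_actin\\.tiff?$", full.names = TRUE))
  stems <- sub("_actin\\.tiff?$", "", basename(fa))
  fv <- file.path(dir, paste0(stems, "_vinculin.tif"))
  fv2 <- file.path(dir, paste0(stems, "_vinculin.tiff"))
  fv[!file.exists(fv)] <- fv2[!file.exists(fv)]
  data.frame(fov_id = stems, actin = fa, vinculin = fv,
             stringsAsFactors = FALSE)
}

#' Read a single-channel TIFF as an intensity matrix
#'
#' @param path file path; multi-sample TIFFs take the first channel.
#' @return numeric matrix scaled to [0, 1].
#' @export
read_channel <- function(path) {
  x <- tiff::readTIFF(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  x
}

#' Run the full pipeline over a batch of FOVs
#'
#' Processes every actin/vinculin image pair, assembles the per-cell table,
#' and summarises the gated, classified population as a morphology map with
#' class fractions and a representative cell. FOVs that fail (unreadable
#' file, channel mismatch, no background peak) are recorded in
#' \code{errors} and the run continues. With an output directory the
#' per-cell CSV, the map matrix CSV, per-FOV label TIFFs, a JSON summary and
#' a log are written; reruns with the same configuration are byte-identical.
#'
#' @param input either a directory containing \code{*_actin.tif} /
#'   \code{*_vinculin.tif} pairs, a manifest data.frame with columns
#'   \code{fov_id}, \code{actin}, \code{vinculin} (file paths), or a list of
#'   in-memory FOVs (each a list with \code{actin}, \code{vinculin}
#'   matrices, optionally named by FOV id).
#' @param config a \code{\link{run_config}}.
#' @param exclusions optional manual exclusion table (fov_id, cell_id) or a
#'   CSV path.
#' @param out_dir optional output directory.
#' @return object of class \code{platelet_run}: \code{cells} (all FOVs),
#'   \code{map} (\code{\link{population_map}} of the classified cells, or
#'   NULL), \code{class_fractions}, \code{representative}
#'   (fov_id/cell_id), \code{errors}, \code{config}.
#' @export
run_batch <- function(input, config = run_config(), exclusions = NULL,
                      out_dir = NULL) {
  if (is.character(exclusions)) {
    exclusions <- utils::read.csv(exclusions, stringsAsFactors = FALSE)
  }
  if (is.character(input)) {
    manifest <- pair_channels(input)
  } else if (is.data.frame(input)) {
    manifest <- input
  } else {
    manifest <- NULL
  }
  fovs <- list()
  errors <- list()
  # echo the configuration into the run log so a run is self-describing
  log <- c("config:", vapply(names(config), function(nm) {
    sprintf("  %s = %s", nm, paste(format(config[[nm]]), collapse = " "))
  }, character(1)))
  read_pair <- function(row) {
    if (!file.exists(row$actin) || !file.exists(row$vinculin)) {
      stop("missing channel file for FOV ", row$fov_id)
    }
    list(actin = read_channel(row$actin), vinculin = read_channel(row$vinculin))
  }
  if (!is.null(manifest)) {
    items <- lapply(seq_len(nrow(manifest)), function(i) manifest[i, ])
    ids <- manifest$fov_id
  } else {
    items <- input
    ids <- names(input)
    if (is.null(ids)) ids <- sprintf("fov%03d", seq_along(input))
  }
  cells <- NULL
  for (i in seq_along(items)) {
    id <- ids[i]
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      pair <- if (!is.null(manifest)) read_pair(items[[i]]) else items[[i]]
      if (!all(dim(pair$actin) == dim(pair$vinculin))) {
        stop("channel shape mismatch in FOV ", id)
      }
      analyze_fov(pair$actin, pair$vinculin, config, fov_id = id,
                  exclusions = exclusions)
    }, error = function(e) e)
    dt <- proc.time()[["elapsed"]] - t0
    if (inherits(res, "error")) {
      errors[[id]] <- conditionMessage(res)
      log <- c(log, sprintf("FOV %s: ERROR %s (%.2fs)", id,
                            conditionMessage(res), dt))
      next
    }
    fovs[[id]] <- res
    ng <- sum(res$cells$gated)
    if (nrow(res$cells) == 0L || ng == 0L) {
      log <- c(log, sprintf("FOV %s: no analysable cells (%.2fs)", id, dt))
    } else {
      log <- c(log, sprintf("FOV %s: %d cells, %d gated (%.2fs)",
                            id, nrow(res$cells), ng, dt))
    }
    cells <- rbind(cells, res$cells)
  }
  map <- NULL
  fractions <- NULL
  rep_cell <- NULL
  if (!is.null(cells)) {
    cls <- cells[cells$gated & !is.na(cells$class), , drop = FALSE]
    if (nrow(cls) > 0) {
      pts <- data.frame(
        x = cls$x, y = cls$y, class = cls$class,
        cell_id = seq_len(nrow(cls)) # pooled index; ties deterministic
      )
      map <- population_map(pts, bin = config$map_bin,
                            sigma_bins = config$map_sigma_bins)
      fractions <- map$class_fractions
      ri <- representative_cell(pts, map)
      rep_cell <- cls[ri, c("fov_id", "cell_id", "class", "x", "y")]
    }
  }
  run <- structure(
    list(cells = cells, fovs = fovs, map = map,
         class_fractions = fractions, representative = rep_cell,
         errors = errors, log = log, config = config),
    class = "platelet_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

# write CSV tables, label maps, summary JSON and the log for a run
write_run <- function(run, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (!is.null(run$cells)) {
    utils::write.csv(run$cells, file.path(out_dir, "cells.csv"),
                     row.names = FALSE)
  }
  if (!is.null(run$map)) {
    utils::write.csv(run$map$grid, file.path(out_dir, "morphology_map.csv"),
                     row.names = FALSE)
    grDevices::png(file.path(out_dir, "morphology_map.png"), 600, 600)
    plot(run$map)
    grDevices::dev.off()
  }
  for (id in names(run$fovs)) {
    lab <- run$fovs[[id]]$labels
    tiff::writeTIFF(lab / 65535, file.path(out_dir, paste0(id, "_labels.tif")),
                    bits.per.sample = 16)
  }
  summ <- list(
    n_fov = length(run$fovs), n_cells = NROW(run$cells),
    n_gated = sum(run$cells$gated %||% 0),
    class_fractions = as.list(run$class_fractions),
    representative = as.list(run$representative),
    errors = run$errors, config = unclass(run$config)
  )
  jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(run$log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.platelet_run <- function(x, ...) {
  cat(sprintf("platelet morphometry run: %d FOVs, %d cells, %d gated\n",
              length(x$fovs), NROW(x$cells),
              sum(x$cells$gated %||% 0)))
  if (!is.null(x$class_fractions)) {
    cat("class fractions:",
        paste(sprintf("%s %.2f", names(x$class_fractions),
                      x$class_fractions), collapse = ", "), "\n")
  }
  if (length(x$errors)) {
    cat("errors:", paste(names(x$errors), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.platelet_run <- function(object, ...) {
  print(object)
  g <- object$cells[object$cells$gated, , drop = FALSE]
  if (NROW(g)) {
    cat("\ngated population:\n")
    for (m in c("area_um2", "ellipticity", "alignment", "radial_order")) {
      cat(sprintf("  %-12s mean %.3f  sd %.3f\n", m,
                  mean(g[[m]], na.rm = TRUE), stats::sd(g[[m]], na.rm = TRUE)))
    }
  }
  invisible(object)
}

#' Plot the population morphology map of a run
#'
#' @param x a \code{\link{run_batch}} result.
#' @param ... passed to \code{\link{plot.morphology_map}}.
#' @export
plot.platelet_run <- function(x, ...) {
  if (is.null(x$map)) stop("run has no morphology map")
  plot(x$map, r_isotropic = x$config$r_isotropic, ...)
}

#' Compare two runs
#'
#' Reproducibility report between two completed runs: mean absolute
#' differences and CVs of the per-cell metrics of the gated populations,
#' plus the normalized cross-correlation of the two morphology maps.
#'
#' @param a,b \code{\link{run_batch}} results.
#' @return a \code{\link{reproducibility}} report.
#' @export
compare_runs <- function(a, b) {
  stopifnot(inherits(a, "platelet_run"), inherits(b, "platelet_run"))
  ga <- a$cells[a$cells$gated, , drop = FALSE]
  gb <- b$cells[b$cells$gated, , drop = FALSE]
  metrics <- c("area_um2", "ellipticity", "alignment", "radial_order")
  maps <- if (!is.null(a$map) && !is.null(b$map)) list(a$map, b$map) else NULL
  reproducibility(list(ga, gb), metrics = metrics, maps = maps)
}
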