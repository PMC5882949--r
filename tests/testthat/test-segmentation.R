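test_that("preprocess removes hot pixels and normalizes to [0, 1]", {
  set.seed(1)
  raw <- matrix(runif(64 * 64, 100, 4100), 64, 64)
  raw[30, 30] <- 60000 # isolated hot pixel
  out <- preprocess(raw)
  expect_equal(range(out), c(0, 1))
  expect_lt(out[30, 30], 0.9) # hot pixel removed by the median
  # monotone map: rank order preserved away from filter effects
  flat <- matrix(rep(seq(0, 1, length.out = 64), each = 64), 64)
  pf <- preprocess(flat * 4000 + 100)
  expect_true(all(diff(pf[32, ]) >= 0))
  # constant image flagged and mapped to zeros
  cst <- preprocess(matrix(7, 32, 32))
  expect_true(all(cst == 0))
  expect_true(isTRUE(attr(cst, "constant")))
  expect_error(preprocess(matrix(-1, 8, 8)), "nonnegative")
})

test_that("background model recovers the generating noise parameters", {
  set.seed(42)
  img <- matrix(pmin(pmax(rnorm(256 * 256, 0.1, 0.01), 0), 1), 256, 256)
  m <- estimate_background(img)
  expect_equal(m$bg, 0.1, tolerance = 0.02)
  expect_equal(m$sd, 0.01, tolerance = 0.2 * 0.01 / 0.01) # +-20 %
  expect_gt(m$sd, 0.008)
  expect_lt(m$sd, 0.012)
})

test_that("background peak is unaffected by a bright foreground minority", {
  set.seed(7)
  img <- matrix(pmin(pmax(rnorm(200 * 200, 0.1, 0.01), 0), 1), 200, 200)
  bg_only <- estimate_background(img)
  img[disc_mask(200, 200, 100, 100, 35)] <- 0.8 # ~10 % bright foreground
  with_fg <- estimate_background(img)
  expect_lt(abs(with_fg$bg - bg_only$bg), 1 / 256 + 1e-9) # within one bin
})

test_that("degenerate background inputs are handled as specified", {
  z <- matrix(0, 64, 64)
  m <- estimate_background(z)
  expect_equal(m$bg, 0)
  expect_equal(m$sd, 0)
})

test_that("binarize thresholds at bg + k*sd", {
  img <- matrix(c(0.25, 0.15, 0.2), 1, 3)
  m <- binarize(img, list(bg = 0.1, sd = 0.01))
  expect_equal(as.vector(m), c(TRUE, FALSE, FALSE)) # 0.2 is not > 0.2
  m0 <- binarize(img, list(bg = 0.1, sd = 0))
  expect_equal(as.vector(m0), c(TRUE, TRUE, TRUE))
})

test_that("cleaning drops small objects and severs thin bridges", {
  # 500 px blob removed, 2000 px blob kept
  m <- disc_mask(120, 200, 50, 60, 12.6) | disc_mask(120, 200, 140, 60, 25.3)
  lab <- clean_and_label(m)
  expect_equal(max(lab), 1)
  kept <- lab > 0
  expect_gt(sum(kept & disc_mask(120, 200, 140, 60, 25.3)), 1500)
  expect_equal(sum(kept & disc_mask(120, 200, 50, 60, 12.6)), 0)
  # two discs joined by a 3 px bridge separate into two labels
  m2 <- disc_mask(140, 220, 60, 70, 25.5) | disc_mask(140, 220, 160, 70, 25.5)
  m2[69:71, 60:160] <- TRUE
  lab2 <- clean_and_label(m2)
  expect_equal(max(lab2), 2)
  # a 50 px interior hole is filled
  m3 <- disc_mask(120, 120, 60, 60, 30) & !disc_mask(120, 120, 60, 60, 4)
  lab3 <- clean_and_label(m3)
  hole_core <- disc_mask(120, 120, 60, 60, 3)
  expect_true(all(lab3[hole_core] > 0))
  # empty input: empty label map, not an error
  expect_equal(max(clean_and_label(matrix(FALSE, 64, 64))), 0)
})

test_that("size filter keeps the >= 1000 px components and drops smaller ones", {
  m <- matrix(FALSE, 150, 240)
  m[20:53, 20:53] <- TRUE     # 1156 px (~1135 after corner rounding) -> kept
  m[20:49, 120:151] <- TRUE   # 960 px -> removed
  m[90:130, 60:110] <- TRUE   # 2091 px -> kept
  lab <- clean_and_label(m)
  expect_equal(max(lab), 2)
  expect_equal(sum(lab[20:49, 120:151] > 0), 0)
  expect_gt(sum(lab[20:53, 20:53] > 0), 1000)
})

test_that("per-cell geometry: area arithmetic and ellipticity", {
  # 10000 px at 60 nm pixels = 36 um^2
  m <- matrix(0L, 150, 150)
  m[disc_mask(150, 150, 75, 75, 56.42)] <- 1L
  cells <- extract_cells(m, pixel_size_nm = 60, exclude_border = FALSE)
  expect_equal(cells$area_um2, sum(m) * 0.0036)
  expect_equal(cells$area_um2, 36, tolerance = 0.01)
  expect_equal(cells$ellipticity, 1, tolerance = 0.01)
  # 2:1 ellipse at arbitrary rotations: ellipticity 2.0 +- 0.05
  for (th in c(0, 0.4, 1.0, 1.3, 2.2)) {
    em <- matrix(0L, 120, 120)
    em[ellipse_mask(120, 120, 60, 60, 40, 20, th)] <- 1L
    ec <- extract_cells(em, exclude_border = FALSE)
    expect_equal(ec$ellipticity, 2, tolerance = 0.025)
  }
})

test_that("mask cleaning and geometry are translation invariant", {
  fov <- cell_fov("parallel", r = 30, n = 160, seed = 4)
  act <- preprocess(fov$actin)
  mask <- binarize(act, estimate_background(act))
  lab <- clean_and_label(mask)
  sh <- matrix(FALSE, 160, 160)
  sh[8:160, 12:160] <- mask[1:153, 1:149] # shift by (+7, +11)
  lab2 <- clean_and_label(sh)
  c1 <- extract_cells(lab, exclude_border = FALSE)
  c2 <- extract_cells(lab2, exclude_border = FALSE)
  expect_equal(c2$centroid_x - c1$centroid_x, 11, tolerance = 1e-6)
  expect_equal(c2$centroid_y - c1$centroid_y, 7, tolerance = 1e-6)
  expect_equal(c2$n_px, c1$n_px)
  expect_equal(c2$ellipticity, c1$ellipticity, tolerance = 1e-9)
})

test_that("manual exclusions and border flags are applied", {
  m <- matrix(0L, 100, 200)
  m[disc_mask(100, 200, 50, 50, 20)] <- 1L
  m[disc_mask(100, 200, 150, 50, 20)] <- 2L
  ex <- data.frame(fov_id = "f1", cell_id = 2)
  cells <- extract_cells(m, fov_id = "f1", exclusions = ex)
  expect_equal(cells$excluded, c(FALSE, TRUE))
  expect_equal(cells$exclude_reason[2], "manual")
  expect_warning(
    extract_cells(m, fov_id = "f1",
                  exclusions = data.frame(fov_id = "f1", cell_id = 9)),
    "not present"
  )
  # border-touching object flagged
  mb <- matrix(0L, 80, 80)
  mb[disc_mask(80, 80, 5, 40, 15)] <- 1L
  cb <- extract_cells(mb)
  expect_true(cb$excluded)
  expect_equal(cb$exclude_reason, "border")
})

test_that("spread gate is strictly greater than 20 um^2", {
  cells <- data.frame(
    fov_id = "f", cell_id = 1:3, area_um2 = c(15, 20, 25),
    excluded = FALSE
  )
  g <- gate_spread(cells)
  expect_equal(g$cell_id, 3)
  expect_equal(nrow(gate_spread(cells[0, ])), 0)
})

test_that("segmentation masks overlap ground truth (Jaccard >= 0.9)", {
  for (pat in c("parallel", "circumferential")) {
    fov <- cell_fov(pat, r = 45, n = 160, seed = 6)
    res <- analyze_fov(fov$actin, fov$vinculin)
    m <- res$labels == 1
    t <- fov$truth$labels == 1
    expect_gte(sum(m & t) / sum(m | t), 0.9)
  }
})
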