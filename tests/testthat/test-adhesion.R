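test_that("sector profile normalizes to mean 1 and localizes signal", {
  m <- disc_mask(100, 100, 50.5, 50.5, 40)
  # uniform staining -> all sectors ~ 1
  prof <- sector_profile(matrix(1, 100, 100), m, c(50.5, 50.5))
  expect_equal(sum(prof), 20)
  expect_lt(max(abs(prof - 1)), 0.03) # rasterization error only
  # all intensity concentrated in one sector
  img <- matrix(0, 100, 100)
  img[45, 80] <- 5 # angle ~ -7 deg -> sector 20
  p2 <- sector_profile(img, m, c(50.5, 50.5))
  expect_equal(p2[20], 20)
  expect_equal(sum(p2[-20]), 0)
  # normalization holds for arbitrary signal
  set.seed(4)
  img3 <- matrix(runif(1e4), 100, 100)
  expect_equal(sum(sector_profile(img3, m, c(50.5, 50.5))), 20)
  # zero total intensity is flagged
  p0 <- sector_profile(matrix(0, 100, 100), m, c(50.5, 50.5))
  expect_true(all(is.na(p0)))
  expect_equal(attr(p0, "flag"), "zero_intensity")
})

test_that("Fourier fit recovers pure harmonics exactly on the sector grid", {
  al <- (1:20 - 0.5) * 2 * pi / 20
  ff <- fit_fourier(1 + 0.5 * cos(2 * al))
  expect_equal(ff$a[2], 0.5, tolerance = 1e-10)
  expect_lt(max(abs(c(ff$a[-2], ff$b))), 1e-10)
  # mixed harmonics
  ff2 <- fit_fourier(1 + 0.3 * cos(2 * al) + 0.2 * sin(3 * al))
  expect_equal(ff2$w[2], 0.3, tolerance = 1e-10)
  expect_equal(ff2$w[3], 0.2, tolerance = 1e-10)
  expect_lt(abs(ff2$w[4]), 1e-10)
  # flat profile -> all weights zero
  expect_lt(max(fit_fourier(rep(1, 20))$w), 1e-12)
  # fitted curve interpolates the generating series
  expect_equal(predict(ff2, al), 1 + 0.3 * cos(2 * al) + 0.2 * sin(3 * al),
               tolerance = 1e-10)
})

test_that("morphology point matches closed-form worked examples", {
  al <- (1:20 - 0.5) * 2 * pi / 20
  # flat profile: max(Y) = 1, r = -0.25, plotted at the origin
  mp0 <- morphology_point(fit_fourier(rep(1, 20)))
  expect_equal(mp0$r, -0.25, tolerance = 1e-9)
  expect_equal(c(mp0$x, mp0$y), c(0, 0))
  # pure 2nd order, a = 0.6: r = 0.35, phi = 210 deg
  mp2 <- morphology_point(fit_fourier(1 + 0.6 * cos(2 * al)))
  expect_equal(mp2$r, 0.35, tolerance = 1e-6)
  expect_equal(mp2$phi_deg, 210, tolerance = 1e-6)
  # pure 3rd order: phi = 330 deg (triangular sector)
  mp3 <- morphology_point(fit_fourier(1 + 0.6 * cos(3 * al)))
  expect_equal(mp3$phi_deg, 330, tolerance = 1e-6)
  # pure 4th order: phi = 90 deg (quadratic sector)
  mp4 <- morphology_point(fit_fourier(1 + 0.6 * cos(4 * al)))
  expect_equal(mp4$phi_deg, 90, tolerance = 1e-6)
})

test_that("classification follows the isotropic circle and 120-degree sectors", {
  expect_equal(classify_morphology(0.2, 123), "isotropic")
  expect_equal(classify_morphology(0.45, 210), "bipolar")
  expect_equal(classify_morphology(0.45, 330), "triangular")
  expect_equal(classify_morphology(0.45, 90), "quadratic")
  # boundaries: 150/270 bipolar side, 30/150 quadratic side
  expect_equal(classify_morphology(0.4, 150), "bipolar")
  expect_equal(classify_morphology(0.4, 269.9), "bipolar")
  expect_equal(classify_morphology(0.4, 270), "triangular")
  expect_equal(classify_morphology(0.4, 29.9), "triangular")
  expect_equal(classify_morphology(0.4, 30), "quadratic")
  expect_equal(classify_morphology(0.4, 149.9), "quadratic")
})

test_that("class switches from isotropic exactly at amplitude 0.58", {
  al <- (1:20 - 0.5) * 2 * pi / 20
  for (k in c(2, 3, 4)) {
    amps <- seq(0.4, 0.8, by = 0.001)
    cls <- vapply(amps, function(a) {
      mp <- morphology_point(fit_fourier(1 + a * cos(k * al)))
      classify_morphology(mp$r, mp$phi_deg)
    }, character(1))
    sw <- amps[which(cls != "isotropic")[1]]
    expect_equal(sw, 0.58, tolerance = 1e-9)
    mp_sw <- morphology_point(fit_fourier(1 + sw * cos(k * al)))
    expect_equal(mp_sw$r, 0.33, tolerance = 1e-6)
  }
})

test_that("rotating the staining pattern leaves weights, r and class unchanged", {
  al <- (1:20 - 0.5) * 2 * pi / 20
  base <- fit_fourier(1 + 0.65 * cos(3 * al))
  mp <- morphology_point(base)
  for (phase in c(0.3, 1.1, 2.7)) {
    rot <- fit_fourier(1 + 0.65 * cos(3 * (al - phase)))
    mpr <- morphology_point(rot)
    expect_equal(mpr$w, mp$w, tolerance = 1e-9)
    # r is read from a 1-degree evaluation grid of the fitted curve
    expect_equal(mpr$r, mp$r, tolerance = 5e-4)
    expect_equal(classify_morphology(mpr$r, mpr$phi_deg), "triangular")
  }
})

test_that("population map is max-normalized with modes where planted", {
  set.seed(10)
  pts <- data.frame(
    x = c(rnorm(40, -0.5, 0.02), rnorm(40, 0.5, 0.02)),
    y = c(rnorm(40, -0.3, 0.02), rnorm(40, 0.4, 0.02)),
    cell_id = 1:80
  )
  map <- population_map(pts)
  expect_equal(max(map$grid), 1)
  expect_equal(dim(map$grid), c(100, 100))
  # two well-separated clusters -> two local maxima
  half <- map$grid[, map$xmid < 0]
  half2 <- map$grid[, map$xmid > 0]
  expect_gt(max(half), 0.5)
  expect_gt(max(half2), 0.5)
  ix1 <- which(map$grid == max(half), arr.ind = TRUE)[1, ]
  expect_lt(abs(map$xmid[ix1[2]] + 0.5), 0.1)
  # single cell: maximum at that cell's bin
  m1 <- population_map(data.frame(x = 0.31, y = -0.11, cell_id = 1))
  ix <- which(m1$grid == 1, arr.ind = TRUE)[1, ]
  expect_lt(abs(m1$xmid[ix[2]] - 0.31), 0.05)
  expect_lt(abs(m1$ymid[ix[1]] + 0.11), 0.05)
  expect_error(population_map(data.frame(x = numeric(0), y = numeric(0))),
               "empty")
})

test_that("representative cell is the one nearest the map maximum", {
  pts <- data.frame(
    x = c(0.40, 0.41, 0.39, 0.42, -0.6),
    y = c(0.10, 0.11, 0.09, 0.12, -0.6),
    cell_id = c(4, 2, 9, 7, 1)
  )
  map <- population_map(pts)
  rep1 <- representative_cell(pts, map)
  expect_true(rep1 %in% c(4, 2, 9, 7)) # a cluster member, not the outlier
  # deterministic under reordering
  perm <- pts[c(3, 5, 1, 4, 2), ]
  expect_identical(representative_cell(perm, population_map(perm)), rep1)
  # single cell returns itself
  p1 <- data.frame(x = 0.2, y = 0.2, cell_id = 42)
  expect_equal(representative_cell(p1, population_map(p1)), 42)
})

test_that("map cross-correlation behaves as a cosine similarity", {
  a <- matrix(0, 50, 50)
  a[10:20, 10:20] <- 1
  b <- matrix(0, 50, 50)
  b[30:40, 30:40] <- 1
  expect_equal(morphology_cc(a, a), 1)
  expect_equal(morphology_cc(a, b), 0)
  expect_equal(morphology_cc(a, b), morphology_cc(b, a))
  expect_error(morphology_cc(a, matrix(0, 50, 50)), "all-zero")
  expect_error(morphology_cc(a, matrix(1, 20, 20)), "geometry")
})
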