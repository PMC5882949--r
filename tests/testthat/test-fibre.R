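test_that("orientation field recovers known grating angles", {
  n <- 128
  g_x <- matrix(rep(1:n, each = n), n)
  g_y <- matrix(rep(1:n, times = n), n)
  inner <- matrix(FALSE, n, n)
  inner[20:(n - 20), 20:(n - 20)] <- TRUE
  for (th_deg in c(0, 30, 45, 75)) {
    th <- th_deg * pi / 180
    u <- -g_x * sin(th) + g_y * cos(th)
    img <- 0.55 + 0.35 * cos(2 * pi * u / 8)
    fld <- orientation_field(img)
    fm <- fibre_mask(img)
    d <- wrap_axial(fld$phi[fm & inner] - th)
    expect_lt(max(abs(d)) * 180 / pi, 3)
  }
})

test_that("orientation field is equivariant under 90-degree rotation", {
  n <- 128
  g_x <- matrix(rep(1:n, each = n), n)
  g_y <- matrix(rep(1:n, times = n), n)
  th <- pi / 6
  img <- 0.55 + 0.35 * cos(2 * pi * (-g_x * sin(th) + g_y * cos(th)) / 8)
  rot <- t(img)[, n:1] # 90-degree rotation
  f1 <- orientation_field(img)
  f2 <- orientation_field(rot)
  fm <- fibre_mask(img)
  inner <- matrix(FALSE, n, n)
  inner[25:(n - 25), 25:(n - 25)] <- TRUE
  sel <- fm & inner
  rot_phi <- t(f2$phi[, n:1]) # map back onto original pixel grid
  d <- wrap_axial(rot_phi[sel] - (f1$phi[sel] + pi / 2))
  expect_lt(sqrt(mean(d^2)) * 180 / pi, 1)
})

test_that("fibre mask is empty on flat images and invariant to global gain", {
  flat <- matrix(0.3, 64, 64)
  fm <- fibre_mask(flat)
  expect_false(any(fm))
  expect_true(isTRUE(attr(fm, "no_fibres")))
  set.seed(3)
  img <- 0.5 + 0.3 * matrix(sin(outer(1:96, 1:96, "+") / 3), 96, 96)
  expect_identical(fibre_mask(img), fibre_mask(0.5 * img))
})

test_that("fibre mask covers the ridge texture of a phantom cell", {
  fov <- cell_fov("parallel", r = 45, n = 160, seed = 8, angle = 20)
  act <- preprocess(fov$actin)
  fm <- fibre_mask(act)
  # ridge crests: top-quartile texture pixels away from core and rim
  tru <- fov$truth$labels == 1 & !is.na(fov$truth$angle)
  crest <- tru & fov$actin > quantile(fov$actin[tru], 0.75)
  expect_gte(sum(fm & crest) / sum(crest), 0.9)
})

test_that("alignment order parameter matches closed forms", {
  # identical angles -> S = 1, any weights
  expect_equal(axial_order(rep(pi / 6, 100), runif(100))$order, 1)
  res <- fibre_alignment(
    structure(list(phi = matrix(pi / 6, 10, 10),
                   weight = matrix(1, 10, 10),
                   low_conf = matrix(FALSE, 10, 10)),
              class = "orientation_field"),
    matrix(TRUE, 10, 10)
  )
  expect_equal(res$alignment, 1)
  expect_equal(res$mean_orientation, pi / 6)
  # half at 0, half at 60 degrees -> S = 0.5 (doubled-angle closed form)
  ao <- axial_order(c(rep(0, 500), rep(pi / 3, 500)))
  expect_equal(ao$order, 0.5, tolerance = 1e-12)
  # uniform random axial angles, n = 1e5 -> S = 0 +- 0.01
  set.seed(123)
  phi <- runif(1e5, -pi / 2, pi / 2)
  expect_lt(axial_order(phi)$order, 0.01)
})

test_that("alignment and radial order ignore global intensity scaling", {
  fov <- cell_fov("spiral", r = 40, n = 128, seed = 9)
  act <- preprocess(fov$actin)
  fld <- orientation_field(act)
  fm <- fibre_mask(act)
  cm <- fov$truth$labels == 1
  ctr <- c(64.5, 64.5)
  s1 <- fibre_alignment(fld, fm, cm)$alignment
  r1 <- radial_order(fld, fm, ctr, cm)$radial_order
  fld$weight <- fld$weight * 7.3 # rescaled weights
  expect_equal(fibre_alignment(fld, fm, cm)$alignment, s1, tolerance = 1e-12)
  expect_equal(radial_order(fld, fm, ctr, cm)$radial_order, r1,
               tolerance = 1e-12)
})

test_that("radial order hits its analytic anchors on pattern phantoms", {
  anchors <- c(radial = 1, circumferential = 0, spiral = 0.5)
  for (pat in names(anchors)) {
    met <- cell_metrics(pat, r = 100, n = 288, seed = 11)
    expect_lt(abs(met$cells$radial_order[1] - anchors[pat]), 0.02)
  }
})

test_that("alignment reaches its limits on parallel and random phantoms", {
  met <- cell_metrics("parallel", r = 100, n = 288, seed = 11, angle = 30)
  expect_equal(met$cells$alignment[1], 1, tolerance = 0.02)
  expect_equal(met$cells$mean_orientation_deg[1], 30, tolerance = 2)
  met2 <- cell_metrics("random", r = 100, n = 288, seed = 12)
  expect_lt(met2$cells$alignment[1], 0.2) # block-random texture decorrelates
})

test_that("literal single-angle radial form cannot reach 0 on rings", {
  # a perfect ring: every fibre tangential to its radius
  n <- 21
  g_x <- matrix(rep(1:n, each = n), n) - 11
  g_y <- matrix(rep(1:n, times = n), n) - 11
  psi <- atan2(g_y, g_x)
  fld <- structure(
    list(phi = wrap_axial(psi + pi / 2), weight = matrix(1, n, n),
         low_conf = matrix(FALSE, n, n)),
    class = "orientation_field"
  )
  fm <- matrix(TRUE, n, n)
  dbl <- radial_order(fld, fm, c(11, 11), literal = FALSE)$radial_order
  lit <- radial_order(fld, fm, c(11, 11), literal = TRUE)$radial_order
  expect_equal(dbl, 0, tolerance = 1e-9) # axial-consistent form: rings -> 0
  expect_equal(lit, 0.5, tolerance = 1e-9) # printed form is stuck at 0.5
})

test_that("alignment decreases monotonically as random texture is mixed in", {
  set.seed(77)
  n <- 2e4
  rand <- runif(n, -pi / 2, pi / 2)
  s_of <- function(frac) {
    phi <- c(rep(pi / 8, round((1 - frac) * n)),
             rand[seq_len(round(frac * n))])
    axial_order(phi)$order
  }
  s <- vapply(c(0, 0.25, 0.5, 0.75, 1), s_of, numeric(1))
  expect_true(all(diff(s) < 0))
  expect_equal(s[1], 1)
  expect_lt(s[5], 0.02)
})

test_that("metrics are flagged, not zeroed, when the fibre mask is empty", {
  fld <- structure(
    list(phi = matrix(0, 8, 8), weight = matrix(1, 8, 8),
         low_conf = matrix(FALSE, 8, 8)),
    class = "orientation_field"
  )
  none <- matrix(FALSE, 8, 8)
  fa <- fibre_alignment(fld, none)
  expect_true(is.na(fa$alignment))
  expect_equal(fa$flag, "no_fibres")
  ro <- radial_order(fld, none, c(4, 4))
  expect_true(is.na(ro$radial_order))
})

test_that("overlay rendering is deterministic and masks background", {
  fov <- cell_fov("radial", r = 30, n = 96, seed = 5)
  act <- preprocess(fov$actin)
  fld <- orientation_field(act)
  fm <- fibre_mask(act)
  ov1 <- render_overlays(fld, fm, c(48.5, 48.5))
  ov2 <- render_overlays(fld, fm, c(48.5, 48.5))
  expect_identical(ov1, ov2)
  # non-mask pixels are black in both overlays
  for (ch in 1:3) {
    expect_true(all(ov1$orientation[, , ch][!fm] == 0))
    expect_true(all(ov1$radial[, , ch][!fm] == 0))
  }
})
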