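# Shared fixture builders. Everything is generated in code at test time.

# one centred cell, returns the rendered FOV
cell_fov <- function(pattern = "parallel", r = 100, n = 288, seed = 11,
                     angle = 0, k = 0, a = 0, phase = 0, ...) {
  ctr <- (n + 1) / 2
  spec <- phantom_spec(
    image_size = c(n, n),
    cells = list(phantom_cell(
      center = c(ctr, ctr), semi_axes = c(r, r), fibre_pattern = pattern,
      fibre_angle_deg = angle, vinculin_order = k, vinculin_amplitude = a,
      vinculin_phase_deg = phase
    )),
    seed = seed, ...
  )
  make_fov(spec)
}

# full single-cell analysis, returns the per-cell row
cell_metrics <- function(..., config = run_config()) {
  fov <- cell_fov(...)
  res <- analyze_fov(fov$actin, fov$vinculin, config = config, fov_id = "t")
  list(fov = fov, res = res, cells = res$cells)
}

# filled disc / ellipse masks on an h x w grid
disc_mask <- function(h, w, cx, cy, r) {
  g_x <- matrix(rep(seq_len(w), each = h), h)
  g_y <- matrix(rep(seq_len(h), times = w), h)
  (g_x - cx)^2 + (g_y - cy)^2 <= r^2
}

ellipse_mask <- function(h, w, cx, cy, a, b, theta = 0) {
  g_x <- matrix(rep(seq_len(w), each = h), h) - cx
  g_y <- matrix(rep(seq_len(h), times = w), h) - cy
  u <- g_x * cos(theta) + g_y * sin(theta)
  v <- -g_x * sin(theta) + g_y * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

# Independent per-pixel orientation oracle: the angle (1 degree steps)
# maximizing the directional second difference of the continuous intensity
# field f(x, y) at step h = 2 px. On a bright ridge the second derivative is
# ~0 along the ridge and strongly negative across it, so the argmax is the
# ridge direction. Sampling f analytically avoids interpolation artefacts
# that would otherwise bias the argmax toward grid axes.
brute_force_orientation <- function(f, sel_idx, n, h = 2) {
  ys <- ((sel_idx - 1) %% n) + 1
  xs <- ((sel_idx - 1) %/% n) + 1
  best <- rep(-Inf, length(sel_idx))
  bestpsi <- numeric(length(sel_idx))
  for (a_deg in 0:179) {
    ps <- a_deg * pi / 180
    D <- f(xs + h * cos(ps), ys + h * sin(ps)) +
      f(xs - h * cos(ps), ys - h * sin(ps)) - 2 * f(xs, ys)
    b <- D > best
    best[b] <- D[b]
    bestpsi[b] <- ps
  }
  bestpsi
}
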