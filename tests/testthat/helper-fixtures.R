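# Shared fixtures: prototype optics, small fast scenes, one cached mask.

proto_cfg <- function(...) optical_config(...)

# 64-row frames keep FFTs fast while preserving the full 1280-column
# geometry that the bandpass radii refer to.
small_scene <- function(rows = 64, noise_sigma = 2,
                        baseline = baseline_poly(offset = 100, gx = 10),
                        seed = 7, ...) {
  scene_config(rows = rows, noise_sigma = noise_sigma, baseline = baseline,
               seed = seed, ...)
}

mask64 <- build_mask(c(64, 1280))

# Closed-form ABCD elements used as an independent oracle for the
# matrix-product implementation.
abcd_closed <- function(cfg, x1, x2) {
  F1 <- cfg$f1; F2 <- cfg$f2; d <- cfg$d
  list(
    A = 1 - x2 / F2 - d / F1 + d * x2 / (F1 * F2) - x2 / F1,
    B = x1 + x2 + d - x1 * d / F1 - x1 * x2 / F2 - x2 * d / F2 -
      x1 * x2 / F1 + x1 * x2 * d / (F1 * F2),
    C = -1 / F1 - 1 / F2 + d / (F1 * F2),
    D = 1 - x1 / F1 - x1 / F2 - d / F2 + x1 * d / (F1 * F2))
}

# Numerical root of B(x2) = 0, independent of the closed-form solver.
image_distance_by_root <- function(cfg, x1, lower = 1, upper = 200) {
  stats::uniroot(function(x2) system_matrix(cfg, x1, x2)$B,
                 lower = lower, upper = upper, tol = 1e-12)$root
}
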