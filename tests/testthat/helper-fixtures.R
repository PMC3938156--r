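# Shared fixtures, computed once per test run.

gt55 <- default_gradient_table()          # study-style 55-direction scheme
gt30 <- default_gradient_table(30)
gt20 <- default_gradient_table(20)

G55 <- cbind(gt55$gx, gt55$gy, gt55$gz)

# Noise-free single-tensor signal for eigenvalues `ev` rotated by `R`.
tensor_signal <- function(gtab, ev = c(1.7e-3, 3e-4, 3e-4),
                          R = diag(3), S0 = 1000) {
  D <- R %*% diag(ev) %*% t(R)
  G <- cbind(gtab$gx, gtab$gy, gtab$gz)
  S0 * exp(-gtab$bval * rowSums((G %*% D) * G))
}

# Noise-free ball-and-stick attenuation profile over the b > 0 gradients.
stick_profile <- function(gtab, v, f = 1, d = 1.7e-3) {
  G <- cbind(gtab$gx, gtab$gy, gtab$gz)[gtab$bval > 0, , drop = FALSE]
  b <- gtab$bval[gtab$bval > 0]
  q2 <- drop(G %*% (v / sqrt(sum(v^2))))^2
  (1 - f) * exp(-b * d) + f * exp(-b * d * q2)
}

# A single straight bundle along +x in a small slab.
straight_bundle_sim <- function(gtab = gt55, snr = Inf, seed = 1,
                                grid_shape = c(24, 12, 6), fraction = 0.6) {
  mid <- grid_shape / 2
  simulate_subject(
    list(fiber_bundle(rbind(c(2, mid[2], mid[3]),
                            c(grid_shape[1] - 2, mid[2], mid[3])),
                      radius = 1.6, stick_fraction = fraction)),
    grid_shape, gtab, snr = snr, rng_seed = seed)
}

# Compact multi-blob structured image for registration tests.
blob_image <- function(grid_shape = c(20, 20, 8)) {
  g <- as.matrix(expand.grid(x = seq_len(grid_shape[1]) - 0.5,
                             y = seq_len(grid_shape[2]) - 0.5,
                             z = seq_len(grid_shape[3]) - 0.5))
  blob <- function(c0, s) exp(-rowSums(sweep(g, 2, c0)^2) / (2 * s^2))
  array(500 * blob(c(4, 10, 4), 1.8) + 800 * blob(c(15, 6, 3), 1.8) +
          600 * blob(c(10, 16, 5), 1.8) + 400 * blob(c(7, 5, 5), 1.5),
        grid_shape)
}

# Angle (deg) between two axial directions.
axis_angle <- function(u, v) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  acos(min(1, abs(sum(u * v)))) * 180 / pi
}
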