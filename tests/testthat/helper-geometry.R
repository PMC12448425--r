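# Fixture builders: small analytic masks constructed in code.

ball_grid <- function(r, sp = 1, margin = 3, label = "tumor") {
  n <- ceiling(2 * (r + margin) / sp)
  ax <- (seq_len(n) - 0.5) * sp - n * sp / 2
  d2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  tf <- diag(4); tf[1:3, 1:3] <- diag(rep(sp, 3)); tf[1:3, 4] <- ax[1]
  volume_grid(array(as.integer(d2 <= r^2), dim = c(n, n, n)),
              rep(sp, 3), tf, label)
}

block_grid <- function(dims, lo, hi, sp = 1, label = "mask") {
  a <- array(0L, dim = dims)
  a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- 1L
  volume_grid(a, rep(sp, 3), label = label)
}

# independent enclosed-volume oracle: flux of F = (0, 0, z) through the mesh
# (divergence 1), computed per-triangle from scratch
mesh_volume_flux_oracle <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$triangles
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- c_ - a
  nz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]   # z-component of cross product
  zc <- (a[, 3] + b[, 3] + c_[, 3]) / 3
  sum(0.5 * nz * zc)
}

expect_rel_error <- function(measured, truth, tol_frac) {
  expect_lt(abs(measured - truth) / abs(truth), tol_frac)
}

# evaluate an expression under a fixed seed, restoring the RNG afterwards
with_seed_local <- function(seed, code) {
  tumorshape:::with_seed(seed, code)
}
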