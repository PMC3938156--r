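# Internal helpers shared across modules.

# Evaluate `expr` with a locally seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n == 0) return(v)
  v / n
}

# Canonical representative of an axial (sign-free) orientation:
# first coordinate with |x| > 1e-12 is made positive.
canonical_axis <- function(v) {
  for (x in v) {
    if (abs(x) > 1e-12) {
      if (x < 0) v <- -v
      break
    }
  }
  v
}

# Angle in degrees between two directions, ignoring sign (axial angle).
axial_angle_deg <- function(u, v) {
  c <- abs(sum(unit(u) * unit(v)))
  acos(min(1, max(-1, c))) * 180 / pi
}

# Signed angle in degrees between two directions.
angle_deg <- function(u, v) {
  c <- sum(unit(u) * unit(v))
  acos(min(1, max(-1, c))) * 180 / pi
}

# 3x3 rotation from small-angle Euler angles (x, y, z order, radians).
euler_rotation <- function(rx, ry, rz) {
  cx <- cos(rx); sx <- sin(rx)
  cy <- cos(ry); sy <- sin(ry)
  cz <- cos(rz); sz <- sin(rz)
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

# Vectorised trilinear interpolation of a 3D array `vol` at continuous
# 0-based voxel coordinates (voxel centre at i + 0.5). `pts` is n x 3.
# Out-of-bounds samples return `fill`.
trilinear <- function(vol, pts, fill = 0) {
  dims <- dim(vol)
  p <- pts - 0.5
  i0 <- floor(p)
  fr <- p - i0
  val <- numeric(nrow(pts))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ix <- i0[, 1] + dx
    iy <- i0[, 2] + dy
    iz <- i0[, 3] + dz
    w <- (if (dx) fr[, 1] else 1 - fr[, 1]) *
      (if (dy) fr[, 2] else 1 - fr[, 2]) *
      (if (dz) fr[, 3] else 1 - fr[, 3])
    ok <- ix >= 0 & ix < dims[1] & iy >= 0 & iy < dims[2] & iz >= 0 & iz < dims[3]
    v <- rep(fill, nrow(pts))
    if (any(ok)) {
      idx <- cbind(ix[ok], iy[ok], iz[ok]) + 1L
      v[ok] <- vol[idx]
    }
    val <- val + w * v
  }
  val
}
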