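# Internal helpers: seed handling, voxel indexing, interpolation.

#' Run code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded generator calls do not
#' disturb the caller's RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(seed))
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
  }
  force(code)
}

# Deterministic child seed for hierarchical stream splitting; keeps per-item
# randomness stable when surrounding layout changes. Stays below 2^31.
child_seed <- function(seed, ...) {
  idx <- c(...)
  x <- as.double(seed) %% 2147483647
  for (i in idx) {
    x <- (x * 69069 + 12345 + as.double(i) * 2654435761) %% 2147483647
  }
  as.integer(x)
}

# 0-based z-major linear index from 1-based array subscripts (iy, ix, iz).
voxel_index <- function(sub, dim) {
  ny <- dim[1]; nx <- dim[2]
  z0 <- sub[, 3] - 1L; y0 <- sub[, 1] - 1L; x0 <- sub[, 2] - 1L
  as.integer(((z0 * ny) + y0) * nx + x0)
}

# Column-major (R-native) linear index <-> (y, x, z) subscripts; this is
# the layout the compiled kernels use. Distinct from the z-major external
# convention of territory_mask$voxels.
cm_subscript <- function(idx, dim) {
  ny <- dim[1]; nx <- dim[2]
  y0 <- idx %% ny
  x0 <- (idx %/% ny) %% nx
  z0 <- idx %/% (ny * nx)
  cbind(y = y0 + 1L, x = x0 + 1L, z = z0 + 1L)
}

voxel_subscript <- function(idx, dim) {
  ny <- dim[1]; nx <- dim[2]
  x0 <- idx %% nx
  y0 <- (idx %/% nx) %% ny
  z0 <- idx %/% (nx * ny)
  cbind(y = y0 + 1L, x = x0 + 1L, z = z0 + 1L)
}

# Physical coordinates (µm, columns x,y,z) of voxel centers given 1-based
# array subscripts; vox is c(z, y, x), origin is c(x, y, z) of the array
# corner (the low corner of voxel (1,1,1)).
voxel_centers <- function(sub, voxel_size, origin = c(0, 0, 0)) {
  cbind(x = origin[1] + (sub[, 2] - 0.5) * voxel_size[["x"]],
        y = origin[2] + (sub[, 1] - 0.5) * voxel_size[["y"]],
        z = origin[3] + (sub[, 3] - 0.5) * voxel_size[["z"]])
}

# Array subscripts (possibly fractional) of physical points on the grid.
point_subscripts <- function(pts, voxel_size, origin = c(0, 0, 0)) {
  cbind(y = (pts[, 2] - origin[2]) / voxel_size[["y"]] + 0.5,
        x = (pts[, 1] - origin[1]) / voxel_size[["x"]] + 0.5,
        z = (pts[, 3] - origin[3]) / voxel_size[["z"]] + 0.5)
}

# Nearest-voxel lookup of a 3D array at physical points; points off the grid
# return `outside`.
sample_nearest <- function(arr, pts, voxel_size, origin = c(0, 0, 0),
                           outside = 0) {
  d <- dim(arr)
  sub <- round(point_subscripts(pts, voxel_size, origin))
  ok <- sub[, 1] >= 1 & sub[, 1] <= d[1] &
        sub[, 2] >= 1 & sub[, 2] <= d[2] &
        sub[, 3] >= 1 & sub[, 3] <= d[3]
  out <- rep(outside, nrow(pts))
  if (any(ok)) out[ok] <- arr[cbind(sub[ok, 1], sub[ok, 2], sub[ok, 3])]
  out
}

# Trilinear interpolation of a 3D array at physical points.
sample_trilinear <- function(arr, pts, voxel_size, origin = c(0, 0, 0)) {
  d <- dim(arr)
  sub <- point_subscripts(pts, voxel_size, origin)
  out <- numeric(nrow(pts))
  for (ax in 1:3) sub[, ax] <- pmin(pmax(sub[, ax], 1), d[ax])
  f <- floor(sub)
  for (ax in 1:3) f[, ax] <- pmin(f[, ax], d[ax] - 1)
  f[, 1] <- pmax(f[, 1], 1); f[, 2] <- pmax(f[, 2], 1); f[, 3] <- pmax(f[, 3], 1)
  w <- sub - f
  for (dy in 0:1) for (dx in 0:1) for (dz in 0:1) {
    wt <- (dy * w[, 1] + (1 - dy) * (1 - w[, 1])) *
          (dx * w[, 2] + (1 - dx) * (1 - w[, 2])) *
          (dz * w[, 3] + (1 - dz) * (1 - w[, 3]))
    out <- out + wt * arr[cbind(pmin(f[, 1] + dy, d[1]),
                                pmin(f[, 2] + dx, d[2]),
                                pmin(f[, 3] + dz, d[3]))]
  }
  out
}

# Uniform random unit vector.
runit3 <- function() {
  repeat {
    v <- rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-12) return(v / n)
  }
}

# Random 3D rotation matrix (uniform via QR of a Gaussian matrix).
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Cumulative arclength of an ordered point matrix.
polyline_arclength <- function(pts) {
  if (nrow(pts) < 2) return(0)
  c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
}

# Resample an ordered polyline at n equally spaced arclength positions.
resample_polyline <- function(pts, n) {
  s <- polyline_arclength(pts)
  L <- s[length(s)]
  if (L <= 0) return(pts[rep(1, n), , drop = FALSE])
  si <- seq(0, L, length.out = n)
  out <- sapply(1:3, function(ax) approx(s, pts[, ax], xout = si, ties = "ordered")$y)
  colnames(out) <- c("x", "y", "z")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
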