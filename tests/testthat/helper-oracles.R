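# Independent brute-force oracles used to check the package implementations.

# Flood-fill connected components on a 3D logical array (26- or
# 6-connectivity), straightforward queue implementation.
oracle_components <- function(mask, connectivity = 26) {
  d <- dim(mask)
  lab <- array(0L, d)
  nxt <- 0L
  offs <- expand.grid(dy = -1:1, dx = -1:1, dz = -1:1)
  offs <- offs[!(offs$dy == 0 & offs$dx == 0 & offs$dz == 0), ]
  if (connectivity == 6)
    offs <- offs[abs(offs$dy) + abs(offs$dx) + abs(offs$dz) == 1, ]
  idx <- which(mask, arr.ind = TRUE)
  for (s in seq_len(nrow(idx))) {
    if (lab[idx[s, 1], idx[s, 2], idx[s, 3]] > 0) next
    nxt <- nxt + 1L
    queue <- list(idx[s, ])
    lab[idx[s, 1], idx[s, 2], idx[s, 3]] <- nxt
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      for (o in seq_len(nrow(offs))) {
        w <- v + c(offs$dy[o], offs$dx[o], offs$dz[o])
        if (any(w < 1) || any(w > d)) next
        if (mask[w[1], w[2], w[3]] && lab[w[1], w[2], w[3]] == 0) {
          lab[w[1], w[2], w[3]] <- nxt
          queue[[length(queue) + 1]] <- w
        }
      }
    }
  }
  lab
}

# Two-sided Fisher exact p-value by exhaustive hypergeometric enumeration
# over all tables with the observed margins.
oracle_fisher <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c2 <- tab[2, 1]; d2 <- tab[2, 2]
  r1 <- a + b; c1 <- a + c2; n <- a + b + c2 + d2
  prob <- function(x) {
    choose(r1, x) * choose(n - r1, c1 - x) / choose(n, c1)
  }
  xs <- max(0, c1 - (n - r1)):min(r1, c1)
  ps <- vapply(xs, prob, numeric(1))
  p_obs <- prob(a)
  sum(ps[ps <= p_obs * (1 + 1e-7)])
}

# Exact two-sided Mann-Whitney p-value by enumerating all assignments of
# the combined sample ranks (no ties).
oracle_mann_whitney <- function(x, y) {
  nx <- length(x); ny <- length(y)
  ranks <- rank(c(x, y))
  u_obs <- sum(ranks[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- combn(nx + ny, nx)
  us <- apply(combos, 2, function(ix) sum(seq_len(nx + ny)[ix]) -
                nx * (nx + 1) / 2)
  mu <- nx * ny / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Analytic flat-capped tube indicator: voxel centers within `radius` of the
# segment from p1 to p2 and between its end planes.
oracle_tube_mask <- function(dim3, voxel_size, origin, p1, p2, radius) {
  sub <- which(array(TRUE, dim3), arr.ind = TRUE)
  ctr <- cbind(origin[1] + (sub[, 2] - 0.5) * voxel_size[["x"]],
               origin[2] + (sub[, 1] - 0.5) * voxel_size[["y"]],
               origin[3] + (sub[, 3] - 0.5) * voxel_size[["z"]])
  ax <- p2 - p1
  L <- sqrt(sum(ax^2))
  ax <- ax / L
  w <- sweep(ctr, 2, p1)
  t <- as.numeric(w %*% ax)
  perp2 <- rowSums(w^2) - t^2
  array(t >= 0 & t <= L & perp2 <= radius^2 + 1e-12, dim3)
}

# Count of strict local maxima of a discrete profile (boundaries included).
oracle_peak_count <- function(p) {
  n <- length(p)
  ext <- c(-Inf, p, -Inf)
  sum(vapply(seq_len(n), function(i) ext[i + 1] > ext[i] &&
               ext[i + 1] > ext[i + 2], logical(1)))
}

# Convenience: render a straight two-color tube and segment it.
make_straight_territory <- function(S = 6, width = 0.67,
                                    paint = paint_scheme_preset("chrI_halves"),
                                    direction = c(1, 0, 0),
                                    optics = optics_noise_free(),
                                    bead_profile = NULL, bead_count = 1L) {
  r <- width / 2
  L <- S * width
  direction <- direction / sqrt(sum(direction^2))
  cl <- outer(seq(0, L, length.out = 60), direction) +
    matrix(c(1.2, 1.2, 1.2), 60, 3, byrow = TRUE)
  colnames(cl) <- c("x", "y", "z")
  tube <- territory_from_centerline(cl, r, bead_profile = bead_profile,
                                    bead_count = bead_count, paint = paint,
                                    stage = "extended")
  img <- render_voxels(tube, optics)
  reg <- array(TRUE, dim(img$channels[[1]]))
  masks <- lapply(seq_along(img$channels), function(ch)
    segment_channel(img, ch, region = reg))
  terrs <- assemble_territories(masks, paint, img$voxel_size, img$origin)
  list(model = tube, img = img, territory = terrs[[1]], n_territories = length(terrs))
}
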