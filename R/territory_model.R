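#' Construct a territory model from an explicit centerline
#'
#' Low-level constructor for the geometric ground-truth description of one
#' chromosome territory: a centerline curve (ordered 3D points, µm), a tube
#' radius, and a beads-on-a-string intensity profile along arclength.
#'
#' @param centerline Matrix (n x 3, columns x,y,z, µm), n >= 2, no duplicate
#'   consecutive points.
#' @param tube_radius Tube radius in µm (> 0); territory width D equals
#'   `2 * tube_radius`.
#' @param bead_profile Intensity multipliers in `[0, 1]` sampled uniformly
#'   along arclength. Default: flat profile of length 200.
#' @param bead_count Number of intensity beads planted in the profile.
#' @param paint A [paint_scheme()].
#' @param stage `"compact"` (premeiotic ovoid) or `"extended"` (meiotic
#'   thread).
#' @return Object of class `territory_model` with analytic `length`,
#'   `width` and `slenderness` fields.
#' @export
territory_from_centerline <- function(centerline, tube_radius,
                                      bead_profile = NULL, bead_count = 1L,
                                      paint = paint_scheme_preset("chrI_halves"),
                                      stage = c("compact", "extended")) {
  stage <- match.arg(stage)
  centerline <- as.matrix(centerline)
  stopifnot(ncol(centerline) == 3, nrow(centerline) >= 2, tube_radius > 0)
  steps <- sqrt(rowSums(diff(centerline)^2))
  if (any(steps <= 0)) stop("centerline has duplicate consecutive points")
  colnames(centerline) <- c("x", "y", "z")
  if (is.null(bead_profile)) bead_profile <- rep(1, 200)
  stopifnot(all(bead_profile >= 0), all(bead_profile <= 1), bead_count >= 1)
  L <- sum(steps)
  structure(list(
    centerline = centerline,
    tube_radius = tube_radius,
    width = 2 * tube_radius,
    length = L,
    slenderness = L / (2 * tube_radius),
    bead_profile = bead_profile,
    bead_count = as.integer(bead_count),
    paint = paint,
    stage = stage), class = "territory_model")
}

# Beads-on-a-string profile: exactly `k` local maxima over [0,1] with
# narrow troughs between beads (|cos|^0.5 sharpens the bead plateaus and
# keeps the dim inter-bead gaps to a fraction of the bead spacing, as in
# the discontinuous paint signals of extended territories). The terminal
# beads sit at the chromosome ends, so territory tips stay bright. Troughs
# floor at `trough` times peak intensity. The sample count is a multiple
# of the bead period so every peak falls exactly on a grid point.
bead_profile_fun <- function(k, trough, n = 200) {
  if (k == 1) {
    n <- 2 * ceiling(n / 2) + 1
    u <- seq(0, 1, length.out = n)
    return(trough + (1 - trough) * abs(cos(pi * (u - 0.5)))^0.5)
  }
  n <- (k - 1) * ceiling(n / (k - 1)) + 1
  u <- seq(0, 1, length.out = n)
  trough + (1 - trough) * abs(cos(pi * (k - 1) * u))^0.5
}

# Persistent random walk centerline, rescaled to exact length L.
# turn_sd controls curvature; larger values curl the curve more tightly.
random_centerline <- function(L, n_points, turn_sd) {
  dir <- runit3()
  dirs <- matrix(0, n_points - 1, 3)
  for (i in seq_len(n_points - 1)) {
    dir <- dir + turn_sd * rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    dirs[i, ] <- dir
  }
  pts <- rbind(c(0, 0, 0), apply(dirs, 2, cumsum))
  # two smoothing passes remove kinks so curvature stays well below 1/radius
  for (pass in 1:2) {
    if (nrow(pts) >= 5) {
      inner <- 2:(nrow(pts) - 1)
      pts[inner, ] <- (pts[inner - 1, ] + pts[inner, ] + pts[inner + 1, ]) / 3
    }
  }
  cur <- polyline_arclength(pts)
  pts <- pts * (L / cur[length(cur)])
  pts <- sweep(pts, 2, colMeans(pts))
  colnames(pts) <- c("x", "y", "z")
  pts
}

# Wound (helical) centerline: used when the requested length cannot fit the
# allowed extent as a near-straight tube. Helix radius and pitch are chosen
# so successive turns stay clear of each other by more than the tube
# diameter; a mild wobble and a random rotation keep shapes varied. The
# curve is rescaled to exact length L.
helix_centerline <- function(L, max_extent, r, n_points, wobble = 0.05) {
  # successive turns must stay clear of each other by more than a tube
  # diameter plus the assembly merge gap plus the blur halo of noisy
  # renders, or rendered turns fuse
  pitch <- 2 * r + 1.1
  # choose the radius that minimizes the bounding sphere of the coil
  grid <- seq(0.9, 0.12, by = -0.03) * max_extent / 2
  grid <- grid[grid >= 1.2 * r]
  circ_of <- function(a) {
    nt <- L / sqrt((2 * pi * a)^2 + pitch^2)
    sqrt(a^2 + (nt * pitch / 2)^2)
  }
  if (length(grid) == 0)
    stop("infeasible territory geometry: cannot wind length ", signif(L, 3),
         " um within extent ", signif(max_extent, 3), " um")
  circs <- vapply(grid, circ_of, numeric(1))
  a <- grid[which.min(circs)]
  if (min(circs) + r > 0.95 * max_extent / 2)
    stop("infeasible territory geometry: cannot wind length ", signif(L, 3),
         " um within extent ", signif(max_extent, 3), " um")
  turn_len <- sqrt((2 * pi * a)^2 + pitch^2)
  nt <- L / turn_len
  theta <- seq(0, 2 * pi * nt, length.out = n_points)
  phase <- runif(2, 0, 2 * pi)
  pts <- cbind(a * cos(theta + phase[1]),
               a * sin(theta + phase[1]),
               theta / (2 * pi) * pitch) +
    outer(a * wobble * sin(0.9 * theta + phase[2]), c(1, 0, 0))
  pts <- pts %*% t(random_rotation())
  cur <- polyline_arclength(pts)
  pts <- pts * (L / cur[length(cur)])
  pts <- sweep(pts, 2, colMeans(pts))
  colnames(pts) <- c("x", "y", "z")
  pts
}

# Largest center-to-center distance of a point set (true diameter; a
# bounding-box diagonal would overestimate planar curves by up to sqrt(2)).
points_extent <- function(pts) {
  dm <- as.matrix(dist(pts))
  max(dm)
}

# Minimum spatial distance between centerline points whose arclength
# separation exceeds a U-turn at the given clearance; points nearby along
# the curve are allowed to be nearby in space.
self_clearance <- function(pts, clearance) {
  n <- nrow(pts)
  s <- polyline_arclength(pts)
  min_arc <- 3.5 * clearance
  best <- Inf
  for (i in seq_len(n - 1)) {
    j <- which(s - s[i] > min_arc)
    if (length(j) == 0) next
    d2 <- (pts[j, 1] - pts[i, 1])^2 + (pts[j, 2] - pts[i, 2])^2 +
      (pts[j, 3] - pts[i, 3])^2
    best <- min(best, min(d2))
  }
  sqrt(best)
}

#' Generate a ground-truthed synthetic chromosome territory
#'
#' Draws a territory model at a target slenderness ratio: the tube diameter
#' (territory width D) is drawn from a normal distribution and the centerline
#' is a smoothed persistent random walk rescaled so that the analytic
#' slenderness (centerline length / D) equals the target. Compact-stage
#' territories are nearly straight short tubes (premeiotic ovoids); extended
#' territories are longer, curlier threads with pronounced bead modulation.
#'
#' @param stage `"compact"` or `"extended"`.
#' @param target_slenderness Desired analytic slenderness (>= 1). Defaults:
#'   1.5 (compact), 8 (extended).
#' @param width_mean,width_sd Territory width (diameter) distribution in µm.
#'   Defaults 0.67 and 0.05, the measured premeiotic territory width.
#' @param bead_count Number of intensity beads (>= 1).
#' @param bead_trough Trough-to-peak intensity ratio of the bead modulation;
#'   defaults 0.85 (compact, nearly uniform) / 0.1 (extended).
#' @param paint A [paint_scheme()].
#' @param seed Integer seed; identical seeds and parameters give identical
#'   models.
#' @param max_extent Maximum allowed spatial extent (µm) so the territory can
#'   fit its nucleus; generation retries with tighter curling and errors if
#'   infeasible.
#' @param n_points Number of centerline vertices.
#' @return A `territory_model`.
#' @export
generate_territory <- function(stage = c("compact", "extended"),
                               target_slenderness = NULL,
                               width_mean = 0.67, width_sd = 0.05,
                               bead_count = 1L, bead_trough = NULL,
                               paint = paint_scheme_preset("chrI_halves"),
                               seed = 1L, max_extent = Inf, n_points = 50L) {
  stage <- match.arg(stage)
  if (is.null(target_slenderness))
    target_slenderness <- if (stage == "compact") 1.5 else 8
  if (is.null(bead_trough))
    bead_trough <- if (stage == "compact") 0.85 else 0.1
  if (target_slenderness < 1) stop("target_slenderness must be >= 1")
  if (bead_count < 1) stop("bead_count must be >= 1")
  if (width_mean <= 0) stop("width_mean must be positive")
  with_seed(seed, {
    w <- 0
    while (w < max(0.05, width_mean - 4 * width_sd) ||
           w > width_mean + 4 * width_sd)
      w <- rnorm(1, width_mean, width_sd)
    r <- w / 2
    L <- target_slenderness * w
    turn_sd <- if (stage == "compact") 0.10 else 0.22
    # decide the curve family up front: near-straight persistent walks when
    # the length fits the allowed extent, wound arcs when it must curl
    tight <- is.finite(max_extent) && (1.1 * L + 2 * r > max_extent)
    model <- NULL
    for (attempt in 1:40) {
      # long constrained threads use the wound helix family; shorter ones
      # curl a random walk progressively until it fits
      use_helix <- tight && L >= 2.5
      pts <- if (use_helix) helix_centerline(L, max_extent, r, n_points)
             else random_centerline(L, n_points, turn_sd)
      # fit = the territory's bounding sphere (around its centroid) stays
      # within the allowed diameter
      circ <- max(sqrt(rowSums(sweep(pts, 2, colMeans(pts))^2)))
      ok_fit <- circ + r <= max_extent / 2
      ok_self <- self_clearance(pts, 2.2 * r) > 2.2 * r
      if (ok_fit && ok_self) {
        model <- pts
        break
      }
      # too spread out -> curl harder; self-colliding -> straighten a little
      if (!use_helix) turn_sd <- if (!ok_fit) turn_sd * 1.3 else turn_sd * 0.8
    }
    if (is.null(model))
      stop("infeasible territory geometry: cannot fit length ", signif(L, 3),
           " um within extent ", signif(max_extent, 3), " um")
    territory_from_centerline(model, r,
                              bead_profile_fun(bead_count, bead_trough),
                              bead_count, paint, stage)
  })
}

#' Rigidly transform a territory model
#'
#' @param model A `territory_model`.
#' @param rotation 3x3 rotation matrix.
#' @param translation Length-3 offset in µm.
#' @export
transform_territory <- function(model, rotation = diag(3),
                                translation = c(0, 0, 0)) {
  pts <- model$centerline %*% t(rotation)
  pts <- sweep(pts, 2, -translation)
  colnames(pts) <- c("x", "y", "z")
  model$centerline <- pts
  model
}

#' @export
print.territory_model <- function(x, ...) {
  cat(sprintf("<territory_model> %s %s: L=%.2f um, D=%.2f um, S=%.2f, beads=%d\n",
              x$paint$chromosome_id, x$stage, x$length, x$width,
              x$slenderness, x$bead_count))
  invisible(x)
}
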