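#' Configuration taxonomy for homolog pair association patterns
#'
#' The nine association patterns scored for homolog pairs, plus `"random"`
#' (unconstrained uniform placement, used for premeiotic nuclei):
#' V-PC / V-NPC (association only at the PC / non-PC terminus), Y-PC / Y-NPC
#' (partial lengthwise alignment starting from the PC / non-PC end), X
#' (middle-only association), O (both ends associated, middle apart), full
#' (lengthwise alignment along the entire chromosome), no_alignment
#' (territories in contact without homologous register) and no_contact.
#' @export
configuration_levels <- function() {
  c("V-PC", "Y-PC", "V-NPC", "Y-NPC", "X", "O", "other",
    "full", "no_alignment", "no_contact")
}

#' Proximity categories for edge-to-edge territory distances
#' @export
proximity_levels <- function() c("touching", "close", "intermediate", "far")

#' Alignment states
#' @export
alignment_levels <- function() c("unaligned", "partial", "full")

# Paired coordinate runs planted for each configuration.
# Returned as a 2-column matrix of [start, end] runs on [0,1] in
# PC-oriented coordinates (0 = PC end).
config_paired_runs <- function(configuration, terminal_fraction = 0.08,
                               paired_fraction = 0.5) {
  switch(configuration,
    "V-PC" = rbind(c(0, terminal_fraction)),
    "Y-PC" = rbind(c(0, paired_fraction)),
    "V-NPC" = rbind(c(1 - terminal_fraction, 1)),
    "Y-NPC" = rbind(c(1 - paired_fraction, 1)),
    "X" = rbind(c(0.40, 0.60)),
    "O" = rbind(c(0, terminal_fraction), c(1 - terminal_fraction, 1)),
    "full" = rbind(c(0, 1)),
    "other" = rbind(c(0, 0.12), c(0.44, 0.56), c(0.88, 1)),
    "no_alignment" = ,
    "no_contact" = matrix(numeric(0), 0, 2),
    stop("unknown configuration: ", configuration))
}

# Smooth offset magnitude profile: near zero on paired runs, m_far elsewhere,
# cosine ramps of width `ramp` in coordinate units.
offset_magnitude <- function(u, runs, m_near, m_far, ramp = 0.03) {
  if (nrow(runs) == 0) return(rep(m_far, length(u)))
  m <- rep(m_far, length(u))
  for (i in seq_len(nrow(runs))) {
    a <- runs[i, 1]; b <- runs[i, 2]
    inside <- u >= a & u <= b
    m[inside] <- pmin(m[inside], m_near)
    lo <- u >= a - ramp & u < a
    m[lo] <- pmin(m[lo], m_near + (m_far - m_near) * 0.5 *
                    (1 - cos(pi * (a - u[lo]) / ramp)))
    hi <- u > b & u <= b + ramp
    m[hi] <- pmin(m[hi], m_near + (m_far - m_near) * 0.5 *
                    (1 - cos(pi * (u[hi] - b) / ramp)))
  }
  m
}

# Build homolog B from homolog A by displacing out of A's best-fit plane
# with a magnitude profile keyed to the planted paired runs (runs given in
# chromosome coordinates, i.e. already un-flipped from PC orientation).
# Displacing along the plane normal keeps the two curves from crossing even
# when A is strongly curled.
make_partner <- function(modelA, runs, m_near, m_far, v = NULL) {
  pts <- modelA$centerline
  u <- polyline_arclength(pts)
  u <- u / u[length(u)]
  if (is.null(v)) {
    pc <- prcomp(pts)
    v <- pc$rotation[, 3] * sample(c(-1, 1), 1)
  }
  m <- offset_magnitude(u, runs, m_near, m_far)
  ptsB <- pts + outer(m, v)
  colnames(ptsB) <- c("x", "y", "z")
  modelB <- modelA
  modelB$centerline <- ptsB
  modelB$length <- sum(sqrt(rowSums(diff(ptsB)^2)))
  modelB$slenderness <- modelB$length / modelB$width
  modelB
}

# Analytic per-bin association profile from two centerlines: a coordinate bin
# is paired when the same-coordinate points lie within epsilon.
analytic_profile <- function(ptsA, ptsB, epsilon, bins = 20L) {
  um <- (seq_len(bins) - 0.5) / bins
  A <- resample_at(ptsA, um)
  B <- resample_at(ptsB, um)
  sqrt(rowSums((A - B)^2)) <= epsilon
}

resample_at <- function(pts, u) {
  s <- polyline_arclength(pts)
  L <- s[length(s)]
  out <- sapply(1:3, function(ax) approx(s, pts[, ax], xout = u * L,
                                         ties = "ordered")$y)
  matrix(out, ncol = 3, dimnames = list(NULL, c("x", "y", "z")))
}

# Minimum distance between two discretized centerlines.
curve_distance <- function(ptsA, ptsB) {
  cpp_min_set_distance(resample_polyline(ptsA, 120), resample_polyline(ptsB, 120))
}

# Centerline running along the nuclear periphery: an arc on a circle of
# radius rho at height z0 (concentric with the nucleus), randomly rotated,
# with a mild radial wobble. Extended territories that are NOT associated
# with their homolog live here, which lets two of them sit on opposite
# sides of the nucleus at large edge-to-edge distances.
peripheral_arc <- function(L, rho, z0 = 0, n_points = 50L, wobble = 0.04,
                           rot = random_rotation()) {
  theta_max <- L / rho
  if (theta_max > 5.6) stop("arc too long for the peripheral shell")
  theta <- seq(0, theta_max, length.out = n_points) + runif(1, 0, 2 * pi)
  rr <- rho * (1 + wobble * sin(2.1 * theta + runif(1, 0, 2 * pi)))
  pts <- cbind(rr * cos(theta), rr * sin(theta), 0)
  cur <- polyline_arclength(pts)
  pts <- pts * (L / cur[length(cur)]) # mild in-plane rescale to exact length
  pts[, 3] <- z0
  pts <- pts %*% t(rot)
  colnames(pts) <- c("x", "y", "z")
  pts
}

# Two mirrored peripheral arcs on opposite sides of the nucleus, jointly
# rotated: the geometry that lets two extended, unassociated territories
# keep a large edge-to-edge distance inside the nuclear sphere.
antipodal_arcs <- function(LA, LB, R, r) {
  reach <- (R - 1.1 * r) / 1.05
  for (frac in seq(0.72, 0.35, by = -0.045)) {
    z0 <- frac * reach
    rho <- sqrt(max(reach^2 - z0^2, 1e-6))
    if (max(LA, LB) / rho <= 5.6) {
      rot <- random_rotation()
      A <- peripheral_arc(LA, rho, z0, rot = rot)
      B <- peripheral_arc(LB, rho, -z0, rot = rot)
      return(list(A = A, B = B))
    }
  }
  stop("cannot separate peripheral arcs inside the nucleus")
}

#' Generate a ground-truthed synthetic nucleus
#'
#' Realizes the geometry of one nucleus: for every requested chromosome pair,
#' a pair of homologous territory models planted in one of the association
#' configurations of [configuration_levels()]. The planted truth (analytic
#' association profile, edge distance, proximity category, alignment state) is
#' recorded alongside the geometry.
#'
#' @param pairs List of per-chromosome specs; each element a list with fields
#'   `paint` ([paint_scheme()]), `configuration`, and optional `stage`,
#'   `target_slenderness`, `bead_count`, `width_mean`, `width_sd`,
#'   `paired_fraction` (for Y configurations, default 0.5).
#' @param nuclear_radius Nuclear radius in µm (default 2).
#' @param clustered Logical: confine chromatin to one side of the nucleus
#'   (transition-zone hallmark).
#' @param seed Integer seed.
#' @param bins Number of coordinate bins for the recorded association truth.
#' @return Object of class `nucleus_spec`: `territories` (list of
#'   `territory_model` with `$chromosome_id` and `$homolog`), `pair_truth`
#'   (per-pair ground truth), `nuclear_radius`, `clustered`.
#' @export
generate_nucleus <- function(pairs, nuclear_radius = 2, clustered = FALSE,
                             seed = 1L, bins = 20L) {
  stopifnot(length(pairs) >= 1)
  for (p in pairs)
    if (!(p$configuration %in% c(configuration_levels(), "random")))
      stop("unknown configuration: ", p$configuration)
  with_seed(seed, {
    territories <- list()
    pair_truth <- list()
    background <- list()
    if (is.finite(nuclear_radius)) {
      # unpainted chromatin of the remaining chromosome complement: gives the
      # DAPI channel a realistic (and, in clustered nuclei, asymmetric) bulk
      for (bi in 1:6) {
        bg <- generate_territory("compact", target_slenderness = runif(1, 1.3, 2.5),
                                 seed = child_seed(seed, 900, bi),
                                 max_extent = 1.1 * nuclear_radius)
        bg <- place_in_sphere(bg, nuclear_radius, clustered)
        bg$dapi_only <- TRUE
        background[[bi]] <- bg
      }
    }
    for (pi in seq_along(pairs)) {
      p <- pairs[[pi]]
      stage <- p$stage %||% (if (p$configuration == "random") "compact" else "extended")
      placed <- NULL
      for (attempt in 1:40) {
        placed <- try(place_pair(p, stage, nuclear_radius, clustered,
                                 child_seed(seed, pi, attempt), bins),
                      silent = TRUE)
        if (!inherits(placed, "try-error")) break
        placed <- NULL
      }
      if (is.null(placed))
        stop("could not realize configuration ", p$configuration,
             " inside nuclear radius ", nuclear_radius)
      for (t in placed$territories) territories[[length(territories) + 1]] <- t
      pair_truth[[pi]] <- placed$truth
    }
    structure(list(territories = territories, pair_truth = pair_truth,
                   background = background,
                   nuclear_radius = nuclear_radius, clustered = clustered,
                   seed = seed),
              class = "nucleus_spec")
  })
}

# Realize one homolog pair in its configuration and place it in the nucleus.
place_pair <- function(p, stage, R, clustered, seed, bins) {
  with_seed(seed, {
    cfg <- p$configuration
    tf <- p$terminal_fraction %||% 0.08
    pf <- p$paired_fraction %||% 0.5
    # only fully aligned pairs keep the initially drawn geometry; all other
    # configurations get their placement rebuilt (peripheral shell arcs),
    # so their initial draw is unconstrained
    ext <- if (cfg == "full") 1.9 * R else Inf
    gen <- function(s) generate_territory(
      stage = stage,
      target_slenderness = p$target_slenderness,
      width_mean = p$width_mean %||% 0.67, width_sd = p$width_sd %||% 0.05,
      bead_count = p$bead_count %||% (if (stage == "compact") 1L else 4L),
      bead_trough = p$bead_trough,
      paint = p$paint, seed = s,
      max_extent = ext)
    A <- gen(child_seed(seed, 1))
    D <- A$width; r <- A$tube_radius
    if (cfg %in% c("random", "no_contact")) {
      B <- gen(child_seed(seed, 2))
      B$tube_radius <- A$tube_radius; B$width <- A$width
      B$slenderness <- B$length / B$width
      # long unassociated territories run along the nuclear periphery; short
      # ones are placed anywhere in the nucleoplasm
      peripheral <- is.finite(R) && (A$length + 2 * r > 1.0 * R)
      ok <- FALSE
      for (try_i in 1:80) {
        if (peripheral && cfg == "no_contact") {
          arcs <- antipodal_arcs(A$length, B$length, R, r)
          A2 <- A; A2$centerline <- arcs$A
          B2 <- B; B2$centerline <- arcs$B
        } else if (peripheral) {
          rho <- 0.8 * R - r
          A2 <- A; A2$centerline <- peripheral_arc(A$length, rho)
          B2 <- B; B2$centerline <- peripheral_arc(B$length, rho)
        } else {
          A2 <- place_in_sphere(A, R, clustered)
          B2 <- place_in_sphere(B, R, clustered)
        }
        dcc <- curve_distance(A2$centerline, B2$centerline)
        if (cfg == "random" || dcc - 2 * r > 2 * D) { ok <- TRUE; break }
      }
      if (!ok) stop("no_contact placement failed")
      A <- A2; B <- B2
    } else {
      runs_pc <- config_paired_runs(cfg, tf, pf)
      runs <- if (p$paint$pc_end == "right" && nrow(runs_pc) > 0)
        cbind(1 - runs_pc[, 2], 1 - runs_pc[, 1]) else runs_pc
      use_shell <- is.finite(R) && A$length + 2 * r > 1.0 * R
      if (cfg == "full") {
        off <- runit3() * 0.3 * r
        B <- A
        B$centerline <- sweep(A$centerline, 2, -off)
      } else if (use_shell && !(cfg %in% c("no_alignment"))) {
        # partial-association configurations of long territories: homolog A
        # is a planar arc on the peripheral shell, homolog B is displaced
        # along the shell axis, where there is guaranteed clearance; the
        # whole complex is then randomly rotated about the nuclear center
        m_far <- 2.2 * D
        reach <- R - 1.2 * r
        # the 4% radial wobble of the arc eats into the reach budget
        rho <- sqrt(reach^2 - (0.55 * m_far)^2) / 1.05
        if (A$length / rho > 5.6)
          stop("territory too long for the shell construction")
        ptsA <- peripheral_arc(A$length, rho, z0 = -m_far / 2, rot = diag(3))
        A$centerline <- ptsA
        B <- make_partner(A, runs, m_near = 0.35 * D, m_far = m_far,
                          v = c(0, 0, 1))
        rot <- random_rotation()
        A$centerline <- A$centerline %*% t(rot)
        B$centerline <- B$centerline %*% t(rot)
        colnames(A$centerline) <- colnames(B$centerline) <- c("x", "y", "z")
        attr(B, "placed") <- TRUE
      } else if (cfg == "no_alignment" && use_shell) {
        # long territories: both homologs on the peripheral shell, B rotated
        # about the contact point so its left end rests on A's right end
        sph <- nonhomologous_on_shell(A, R, r)
        A <- sph$A; B <- sph$B
      } else if (cfg == "no_alignment") {
        B <- make_nonhomologous_contact(A, r)
      } else {
        B <- make_partner(A, runs, m_near = 0.35 * D, m_far = 2.2 * D)
      }
      if (!isTRUE(attr(B, "placed"))) {
        # rigidly place the pair complex inside the nucleus
        comp <- place_complex(list(A, B), R, clustered)
        A <- comp[[1]]; B <- comp[[2]]
      }
    }
    eps <- D
    prof <- analytic_profile(A$centerline, B$centerline, eps, bins)
    dcc <- curve_distance(A$centerline, B$centerline)
    edge_d <- max(0, dcc - 2 * r)
    touching <- dcc <= 2 * r + 1e-9
    # verify the planted pattern survived placement
    expect_runs <- if (cfg %in% c("random")) NULL else
      config_paired_runs(cfg, tf, pf)
    if (cfg %in% c("no_contact", "no_alignment") && any(prof))
      stop("planted profile violated")
    if (cfg == "full" && !all(prof)) stop("planted profile violated")
    A$chromosome_id <- p$paint$chromosome_id; A$homolog <- 1L
    B$chromosome_id <- p$paint$chromosome_id; B$homolog <- 2L
    truth <- list(
      chromosome_id = p$paint$chromosome_id,
      configuration = cfg,
      paired_runs = expect_runs,
      profile = prof,
      paired_fraction = mean(prof),
      edge_distance = edge_d,
      touching = touching,
      scale_D = D,
      proximity = classify_proximity(edge_d, D, touching = touching),
      alignment_state = classify_alignment_state(prof),
      slenderness = c(A$slenderness, B$slenderness),
      bead_count = c(A$bead_count, B$bead_count),
      width = c(A$width, B$width),
      length = c(A$length, B$length))
    list(territories = list(A, B), truth = truth)
  })
}

# Non-homologous contact on the peripheral shell: A is an arc on the shell;
# B is A's arc carried to A's right end by a sphere rotation and then
# spun about the radial axis there, so the two tubes touch at one point but
# no coordinate bin is in homologous register.
nonhomologous_on_shell <- function(A, R, r) {
  rho <- 0.8 * R - r
  thetaA <- A$length / rho
  if (thetaA > 5.6) stop("arc too long for the shell")
  for (try_i in 1:150) {
    phi0 <- runif(1, 0, 2 * pi)
    # A: arc in the equatorial plane ending at the contact point
    tA <- seq(phi0, phi0 + thetaA, length.out = 50)
    ptsA <- cbind(rho * cos(tA), rho * sin(tA), 0)
    pc <- ptsA[50, ]
    rhat <- pc / sqrt(sum(pc^2))
    # B: great arc through the contact point in the plane spanned by the
    # radial direction there and the pole axis; the contact sits near B's
    # middle, so the association is non-homologous (A end on B middle)
    thetaB <- A$length / rho
    dlt <- runif(1, -0.15, 0.15)
    tB <- seq(-thetaB / 2 + dlt, thetaB / 2 + dlt, length.out = 50)
    ptsB <- outer(rho * cos(tB), rhat) + outer(rho * sin(tB), c(0, 0, 1))
    colnames(ptsA) <- colnames(ptsB) <- c("x", "y", "z")
    # verify: no homologous register, touching, clearance away from the
    # T-junction (a physical exclusion radius around the contact point),
    # everything inside the nucleus
    prof <- analytic_profile(ptsA, ptsB, 2 * r, 20L)
    rsA <- resample_polyline(ptsA, 60)
    rsB <- resample_polyline(ptsB, 60)
    excl <- max(0.9, 3 * r)
    keepA <- sqrt(colSums((t(rsA) - pc)^2)) > excl
    keepB <- sqrt(colSums((t(rsB) - pc)^2)) > excl
    clear <- if (sum(keepA) >= 3 && sum(keepB) >= 3)
      cpp_min_set_distance(rsA[keepA, , drop = FALSE],
                           rsB[keepB, , drop = FALSE]) else Inf
    if (!any(prof) && clear > 2.2 * r) {
      rot <- random_rotation()
      Anew <- A; Anew$centerline <- ptsA %*% t(rot)
      Bnew <- A; Bnew$centerline <- ptsB %*% t(rot)
      colnames(Anew$centerline) <- colnames(Bnew$centerline) <- c("x", "y", "z")
      attr(Bnew, "placed") <- TRUE
      return(list(A = Anew, B = Bnew))
    }
  }
  stop("no_alignment shell placement failed")
}

rotation_about <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Territory in non-homologous contact with A: a partner emanating from A's
# right end in a transverse direction, so masks touch but no coordinate bin
# is in homologous register.
make_nonhomologous_contact <- function(A, r) {
  pts <- A$centerline
  n <- nrow(pts)
  tangent <- pts[n, ] - pts[n - 1, ]
  tangent <- tangent / max(sqrt(sum(tangent^2)), 1e-9)
  v <- runit3()
  v <- v - sum(v * tangent) * tangent
  v <- v / max(sqrt(sum(v^2)), 1e-9)
  # B starts at A's right end (homologous coordinates anti-correlated:
  # B's left end sits at A's right end) and runs transversally away.
  sB <- polyline_arclength(pts)
  LB <- sB[length(sB)]
  uu <- seq(0, 1, length.out = n)
  start <- pts[n, ] + v * (1.8 * r)
  # gentle arc in the plane spanned by v and a second transverse direction
  w <- runit3(); w <- w - sum(w * v) * v; w <- w / max(sqrt(sum(w^2)), 1e-9)
  ptsB <- t(vapply(uu, function(ui)
    start + v * (LB * ui * 0.9) + w * (LB * 0.25 * sin(pi * ui)),
    numeric(3)))
  colnames(ptsB) <- c("x", "y", "z")
  B <- A
  B$centerline <- ptsB
  B$length <- sum(sqrt(rowSums(diff(ptsB)^2)))
  B$slenderness <- B$length / B$width
  B
}

# Place a single territory uniformly at random inside the nuclear sphere
# (optionally within the clustered hemisphere cap), random orientation.
place_in_sphere <- function(model, R, clustered = FALSE) {
  pts0 <- model$centerline
  pts0 <- sweep(pts0, 2, colMeans(pts0))
  r <- model$tube_radius
  circ <- max(sqrt(rowSums(pts0^2)))
  fit_r <- R - circ - r
  if (fit_r < 0) stop("territory does not fit nuclear sphere")
  for (i in 1:100) {
    rot <- random_rotation()
    pts <- pts0 %*% t(rot)
    # uniform center within the sphere of feasible placements
    repeat {
      c0 <- runif(3, -fit_r, fit_r)
      if (sum(c0^2) <= fit_r^2) break
    }
    # clustered chromatin sits toward one side, as far as fits allow
    if (clustered && c0[1] < 0.3 * min(fit_r, R / 2)) next
    pts <- sweep(pts, 2, -c0)
    if (max(sqrt(rowSums(pts^2))) + r <= R) {
      model$centerline <- pts
      colnames(model$centerline) <- c("x", "y", "z")
      return(model)
    }
  }
  stop("territory does not fit nuclear sphere")
}

# Rigidly place a multi-territory complex inside the nucleus.
place_complex <- function(models, R, clustered = FALSE) {
  all_pts <- do.call(rbind, lapply(models, `[[`, "centerline"))
  ctr <- colMeans(all_pts)
  rmax <- max(vapply(models, `[[`, numeric(1), "tube_radius"))
  for (i in 1:300) {
    rot <- random_rotation()
    repeat {
      c0 <- runif(3, -R, R)
      if (sum(c0^2) <= R^2) break
    }
    if (clustered && c0[1] < 0.15 * R) next
    ok <- TRUE
    out <- vector("list", length(models))
    for (j in seq_along(models)) {
      pts <- sweep(models[[j]]$centerline, 2, ctr) %*% t(rot)
      pts <- sweep(pts, 2, -c0)
      if (max(sqrt(rowSums(pts^2))) + rmax > R) { ok <- FALSE; break }
      m <- models[[j]]
      m$centerline <- pts
      colnames(m$centerline) <- c("x", "y", "z")
      out[[j]] <- m
    }
    if (ok) return(out)
  }
  stop("pair complex does not fit nuclear sphere")
}

#' @export
print.nucleus_spec <- function(x, ...) {
  cat(sprintf("<nucleus_spec> %d territories, %d pairs, R=%.1f um%s\n",
              length(x$territories), length(x$pair_truth), x$nuclear_radius,
              if (x$clustered) ", clustered" else ""))
  for (pt in x$pair_truth)
    cat(sprintf("  %s: %s (paired %.2f, edge %.2f um)\n", pt$chromosome_id,
                pt$configuration, pt$paired_fraction, pt$edge_distance))
  invisible(x)
}
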