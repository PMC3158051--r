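# Scoring a homolog pair from its segmented territory mask(s).
#
# Two territories: standard route — per-territory centerlines, orientation
# from terminal paint colors, per-coordinate association profile.
#
# One territory (the homologs are in contact and segment as a single
# connected mask): the mask is decomposed through its curve skeleton. The
# diameter path and its residual branches give the total skeleton length T
# and the tip set; the chromosome-end identity of each tip (from the paint
# colors) plus cycle detection identify the association pattern, and the
# paired fraction follows from skeleton arithmetic: for a pair folded at
# one end, the path between the two same-end tips has length 2(1-f)L and
# the total skeleton length is (2-f)L, giving the single-chromosome length
# L = T - path/2 and paired fraction f = 1 - path/(2L).

# Residual branches of a mask relative to a covering path.
# Returns per-branch: length (µm), tip point, attachment arc fraction; and
# whether any residual component closes a cycle (attaches over a wide arc
# span of the path).
skeleton_branches <- function(tm, cl, cover_radius, min_branch) {
  mask <- tm$mask
  d <- dim(mask)
  vox_arr <- c(tm$voxel_size[["y"]], tm$voxel_size[["x"]], tm$voxel_size[["z"]])
  pts_mask <- mask_points(tm)
  pathp <- resample_polyline(cl$points, max(60L, nrow(cl$points)))
  dist_to_path <- cpp_nn_distance(pts_mask, pathp)
  resid <- dist_to_path > cover_radius
  if (!any(resid)) return(list(branches = list(), cycle = FALSE))
  rmask <- array(FALSE, d)
  rmask[which(mask, arr.ind = TRUE)[resid, , drop = FALSE]] <- TRUE
  lab <- array(cpp_label_components(as.logical(rmask), d, 26L), dim = d)
  k <- max(lab)
  branches <- list()
  cycle <- FALSE
  path_s <- polyline_arclength(pathp)
  for (i in seq_len(k)) {
    comp <- lab == i
    nvox <- sum(comp)
    if (nvox < 4) next
    cpts <- voxel_centers(which(comp, arr.ind = TRUE), tm$voxel_size,
                          tm$origin)
    # arc positions on the path where this component comes close
    dpc <- cpp_nn_distance(cpts, pathp)
    # thin surface slivers hug the covering path; genuine arms, stubs and
    # ring halves reach well beyond the cover radius
    if (max(dpc) <= cover_radius + 0.25) next
    # attachment points: where the component actually meets the path (its
    # closest approach), not merely where it runs loosely parallel to it
    near <- dpc <= min(dpc) + 2 * max(tm$voxel_size)
    att_idx <- apply(cpts[near, , drop = FALSE], 1, function(p)
      which.min(colSums((t(pathp) - p)^2)))
    if (length(att_idx) == 0)
      att_idx <- which.min(colSums((t(pathp) - cpts[which.min(dpc), ])^2))
    att_s <- path_s[att_idx] / max(path_s)
    # robust span: a ring closure attaches in clusters at two far-apart
    # path positions; an arm attaches at one spot and merely grazes the
    # path elsewhere, so the 10-90% quantile span stays small
    span <- diff(quantile(att_s, c(0.1, 0.9), names = FALSE))
    # attachment voxel: component voxel closest to the path
    a_vox <- which.min(dpc)
    ss <- which(comp, arr.ind = TRUE)[a_vox, ]
    start_idx <- (ss[1] - 1L) + d[1] * ((ss[2] - 1L) + d[2] * (ss[3] - 1L))
    g <- cpp_geodesic(as.logical(comp), d, vox_arr, start_idx,
                      rep(1, length(comp)))
    gd <- replace(g$dist, !comp, -Inf)
    tip_i <- which.max(gd)
    blen0 <- gd[tip_i]
    # a genuine ring closure is voluminous, reaches far from the path and
    # re-attaches at two distant positions; unpaired homolog arms and
    # noisy slivers fail at least one of these
    if (span > 0.5 && blen0 > min_branch &&
        max(dpc) > cover_radius + 0.45 &&
        nvox > 0.08 * length(pts_mask[, 1])) {
      cycle <- TRUE
      next
    }
    # precise branch length: full-mask geodesic from the branch tip to the
    # nearest covering-path voxel
    gf <- cpp_geodesic(as.logical(mask), d, vox_arr, tip_i - 1L,
                       rep(1, length(mask)))
    psub <- round(point_subscripts(pathp, tm$voxel_size, tm$origin))
    psub <- psub[psub[, 1] >= 1 & psub[, 1] <= d[1] &
                   psub[, 2] >= 1 & psub[, 2] <= d[2] &
                   psub[, 3] >= 1 & psub[, 3] <= d[3], , drop = FALSE]
    pidx <- (psub[, 1] - 1L) + d[1] * ((psub[, 2] - 1L) + d[2] * (psub[, 3] - 1L))
    pidx <- pidx[mask[psub]]
    blen <- if (length(pidx)) min(gf$dist[pidx + 1L]) else blen0
    if (!is.finite(blen)) blen <- blen0
    if (blen < min_branch) next
    tip_sub <- cm_subscript(tip_i - 1L, d)
    # midpoint of the branch path (for occupancy checks along the branch)
    bpath <- integer(0)
    cur <- tip_i - 1L
    while (cur >= 0) {
      bpath <- c(bpath, cur)
      cur <- g$parent[cur + 1L]
    }
    qpos <- unique(pmax(1L, round(length(bpath) *
                                    seq(0.15, 0.85, length.out = 9))))
    qsub <- cm_subscript(bpath[qpos], d)
    branches[[length(branches) + 1]] <- list(
      length = blen,
      tip = voxel_centers(tip_sub, tm$voxel_size, tm$origin)[1, ],
      mid = voxel_centers(qsub, tm$voxel_size, tm$origin),
      attach = median(att_s))
  }
  list(branches = branches, cycle = cycle)
}

# Chromosome-end identity ("left"/"right"/NA) of a point from the paint
# colors around it, refined by a second sample displaced towards `inward`.
classify_tip_end <- function(img, paint, tip, inward, r_hat) {
  channels <- paint_channels(paint)
  obs_tip <- sample_ball(img, channels, tip, 1.5 * r_hat)
  dirv <- inward - tip
  nd <- sqrt(sum(dirv^2))
  obs_in <- if (nd > 1e-9)
    sample_ball(img, channels, tip + dirv / nd * min(3.5 * r_hat, nd / 2),
                1.5 * r_hat) else obs_tip
  score_end <- function(u_tip, u_in) {
    signature_match(obs_tip, unlist(channels_at(paint, u_tip)), channels) +
      signature_match(obs_in, unlist(channels_at(paint, u_in)), channels)
  }
  sl <- score_end(0.02, 0.15)
  sr <- score_end(0.98, 0.85)
  if (max(sl, sr) <= 0) return(NA_character_)
  if (abs(sl - sr) <= 0.03 * max(sl, sr)) return(NA_character_)
  if (sl > sr) "left" else "right"
}

# Mean per-channel intensity in a small ball around a point.
sample_ball <- function(img, channels, center, radius) {
  offs <- rbind(c(0, 0, 0), diag(3) * radius / 2, -diag(3) * radius / 2)
  pts <- sweep(offs, 2, -center)
  vapply(channels, function(ch)
    mean(sample_trilinear(img$channels[[ch]], pts, img$voxel_size,
                          img$origin)), numeric(1))
}

# Dominant-channel coordinate sequence along a centerline: each sample maps
# to the midpoint coordinate of the interval painted by its dominant
# channel. Used to detect coordinate "resets" (non-homologous contact).
coordinate_sequence <- function(img, cl, paint) {
  channels <- paint_channels(paint)
  prof <- profile_along(img, cl, channels)
  if (is.null(dim(prof))) prof <- matrix(prof, ncol = 1)
  mids <- vapply(channels, function(ch) {
    ivs <- do.call(rbind, lapply(paint$segments, function(s)
      if (ch %in% s$channels && length(s$channels) == 1) s$interval else NULL))
    if (is.null(ivs))
      ivs <- do.call(rbind, lapply(paint$segments, function(s)
        if (ch %in% s$channels) s$interval else NULL))
    mean(rowMeans(ivs))
  }, numeric(1))
  floor_lvl <- 0.05 * max(prof)
  dom <- apply(prof, 1, function(v) {
    o <- sort(v, decreasing = TRUE)
    # double-labeled zones (two comparable channels) carry no orientation
    if (o[1] <= floor_lvl) return(NA_real_)
    if (length(o) > 1 && o[1] < 1.5 * o[2]) return(NA_real_)
    mids[which.max(v)]
  })
  dom[!is.na(dom)]
}

# A residual arm is consistent with a fold-through traversal when its
# length matches the stretch of path between its attachment and the end it
# duplicates; a T-contact of non-homologous territories violates this.
fold_consistent <- function(blen, attach, bend, P, tol = 0.25) {
  expect <- if (bend == "left") attach * P else (1 - attach) * P
  abs(blen - expect) < tol * P
}

# A merged (double-occupancy) stretch of a fold-through path carries about
# twice the summed paint intensity of the single-occupancy stretch.
run_double_occupancy <- function(img, cl, paint, x, bend, ends,
                                 min_ratio = 1.4) {
  # per-position maximum channel, not the sum: double-labeled ends emit
  # into two channels without being doubly occupied
  tot <- apply(profile_along(img, cl, paint_channels(paint)), 1, max)
  n <- length(tot)
  sfrac <- seq(0, 1, length.out = n)
  u <- if (!is.na(ends[1]) && ends[1] == "right") 1 - sfrac else sfrac
  in_run <- if (bend == "left") u >= x else u <= 1 - x
  if (sum(in_run) < 4 || sum(!in_run) < 4) return(FALSE)
  # compare upper quartiles: bead troughs pull medians of both strands down
  stats::quantile(tot[in_run], 0.75, names = FALSE) >=
    min_ratio * stats::quantile(tot[!in_run], 0.75, names = FALSE)
}

# The merged stub of a folded pair carries doubled paint signal at its
# interior, unlike an arm of a non-homologous contact.
stub_double_occupancy <- function(img, cl, paint, br, min_ratio = 1.3) {
  blens <- vapply(br$branches, `[[`, numeric(1), "length")
  b <- br$branches[[which.max(blens)]]
  chans <- paint_channels(paint)
  # occupancy must be read per channel (the maximum across channels, not
  # the sum: double-LABELED chromosome ends emit 1x into two channels and
  # would otherwise mimic double occupancy); beads modulate both strands,
  # so compare the brightest point along the branch against the brightest
  # single-occupancy stretch. For a folded pair the path middle traverses
  # the merged (doubled) run, so the single-tube reference comes from the
  # terminal quarters of the path, which are the visible unpaired arms.
  stub_int <- max(apply(b$mid, 1, function(p)
    max(sample_ball(img, chans, p, 0.15))))
  tot <- apply(profile_along(img, cl, chans), 1, max)
  tot <- as.numeric(stats::filter(tot, rep(1 / 3, 3), sides = 2))
  tot <- tot[!is.na(tot)]
  n <- length(tot)
  arms <- c(tot[seq_len(ceiling(n / 4))], tot[(n - ceiling(n / 4)):n])
  ref <- stats::quantile(arms, 0.9, names = FALSE)
  stub_int >= min_ratio * ref
}

has_coordinate_reset <- function(useq, drop = 0.3) {
  if (length(useq) < 4) return(FALSE)
  # orient so the sequence is globally increasing
  if (cor(seq_along(useq), useq, method = "spearman") < 0) useq <- rev(useq)
  run_max <- cummax(useq)
  any(run_max - useq > drop)
}

# Synthesize a logical bin profile from paired coordinate runs.
runs_to_profile <- function(runs, bins = 20L) {
  um <- (seq_len(bins) - 0.5) / bins
  p <- rep(FALSE, bins)
  if (!is.null(runs) && nrow(runs) > 0)
    for (i in seq_len(nrow(runs)))
      p <- p | (um >= runs[i, 1] & um <= runs[i, 2])
  p
}

# Decompose a single merged pair mask into an association profile.
decompose_merged_pair <- function(tm, img, paint, bins = 20L,
                                  terminal_cutoff = 0.15) {
  cl <- extract_centerline(tm)
  D_hat <- estimate_width(tm, cl)
  r_hat <- D_hat / 2
  br <- skeleton_branches(tm, cl, cover_radius = 1.6 * r_hat,
                          min_branch = max(0.22, 2 * max(tm$voxel_size)))
  Tlen <- cl$length + sum(vapply(br$branches, `[[`, numeric(1), "length"))
  n_pts <- nrow(cl$points)
  end_pts <- list(p1 = cl$points[1, ], p2 = cl$points[n_pts, ])
  in_pts <- list(cl$points[max(1, round(0.2 * n_pts)), ],
                 cl$points[round(0.8 * n_pts), ])
  ends <- c(classify_tip_end(img, paint, end_pts$p1, in_pts[[1]], r_hat),
            classify_tip_end(img, paint, end_pts$p2, in_pts[[2]], r_hat))
  P <- cl$length
  blens <- vapply(br$branches, `[[`, numeric(1), "length")
  batt <- vapply(br$branches, `[[`, numeric(1), "attach")
  bends <- vapply(br$branches, function(b)
    classify_tip_end(img, paint, b$tip, cl$points[round(nrow(cl$points) *
      min(max(b$attach, 0.05), 0.95)), ], r_hat) %||% NA_character_,
    character(1))
  tf <- min(0.1, terminal_cutoff - 0.02)
  nb <- length(br$branches)
  runs <- NULL
  if (br$cycle) {
    # a residual component re-attaching far along the path closes a ring:
    # homologs associated at both ends, apart in the middle
    runs <- rbind(c(0, tf), c(1 - tf, 1))
  } else if (!any(is.na(ends)) && ends[1] == ends[2] &&
             (nb == 0 || stub_double_occupancy(img, cl, paint, br))) {
    # folded pair: merged at the end opposite to the two visible tips; the
    # merged stub (carrying doubled paint signal) is the longest residual
    # branch, and its share of the single-chromosome length is the paired
    # fraction
    stub <- if (nb > 0) max(blens) else 0
    f <- if (stub > 0) stub / (P / 2 + stub) else 0.05
    f <- min(max(f, 0.02), 0.85)
    runs <- if (ends[1] == "right") rbind(c(0, f)) else rbind(c(1 - f, 1))
  } else if (nb >= 2 && min(batt) < 0.22 && max(batt) > 0.78) {
    # residual structure re-attaching at both path ends: ring traversal of
    # an O pair (the far half of the ring may split into two pieces)
    runs <- rbind(c(0, tf), c(1 - tf, 1))
  } else if (nb >= 2 && !any(is.na(bends)) &&
             all(sort(unique(bends)) == c("left", "right"))) {
    {
      # interior cross: the path runs left arm -> merged core -> right arm,
      # with the other two arms as residual branches
      bl <- max(blens[bends == "left"])
      bright <- max(blens[bends == "right"])
      u1 <- min(max(bl / P, 0.02), 0.45)
      u2 <- 1 - min(max(bright / P, 0.02), 0.45)
      if (u2 - u1 < 0.04) { u1 <- 0.48 - 0.02; u2 <- 0.48 + 0.06 }
      runs <- rbind(c(u1, u2))
    }
  } else if (nb >= 1 && !is.na(bends[which.max(blens)]) &&
             fold_consistent(blens[which.max(blens)],
                             batt[which.max(blens)],
                             bends[which.max(blens)], P) &&
             run_double_occupancy(img, cl, paint,
                                  blens[which.max(blens)] / P,
                                  bends[which.max(blens)], ends)) {
    # one visible residual arm whose length matches its attachment point
    # and whose merged stretch carries doubled paint signal: the path
    # traversed a whole homolog through the merged run and the arm is the
    # partner's unpaired side
    j <- which.max(blens)
    x <- min(max(blens[j] / P, 0.03), 0.9)
    runs <- if (bends[j] == "left") rbind(c(x, 1)) else rbind(c(0, 1 - x))
  } else {
    useq <- coordinate_sequence(img, cl, paint)
    if (has_coordinate_reset(useq)) {
      runs <- matrix(numeric(0), 0, 2)
    } else if (nb >= 1 && all(batt > 0.2 & batt < 0.8)) {
      # residual arm(s) re-emerging mid-path without any coordinate reset:
      # an interior cross with (possibly) one arm lost in the cover
      f <- min(max(2 - Tlen / P, 0.08), 0.5)
      ctr <- mean(batt)
      a <- min(max(ctr - f / 2, terminal_cutoff + 0.02),
               1 - terminal_cutoff - 0.02 - f)
      runs <- rbind(c(a, a + f))
    } else {
      runs <- rbind(c(0, 1))
    }
  }
  profile <- runs_to_profile(runs, bins)
  attr(profile, "paired_fraction") <- mean(profile)
  attr(profile, "flagged") <- any(is.na(ends))
  list(profile = profile, D = D_hat, centerline = cl)
}

#' Score the spatial relationship and configuration of a homolog pair
#'
#' Produces the full pair record for a chromosome whose segmentation
#' yielded one (merged) or two territories: edge distance, proximity
#' category, association profile, alignment state and association
#' configuration.
#'
#' @param territories List of 1 or 2 [territory_mask()] for the chromosome.
#' @param img The source `voxel_image`.
#' @param paint The chromosome's [paint_scheme()].
#' @param bins Association profile bins (default 20).
#' @param epsilon_factor Pairing threshold as a multiple of the width D
#'   (default 1).
#' @param terminal_cutoff V-versus-Y cutoff (coordinate fraction, default
#'   0.15).
#' @param boundary_2d Passed to [classify_proximity()].
#' @return One-row data frame: `edge_distance_d`, `scale_D`, `proximity`,
#'   `paired_fraction`, `alignment_state`, `configuration`, `flagged`.
#' @export
score_pair <- function(territories, img, paint, bins = 20L,
                       epsilon_factor = 1, terminal_cutoff = 0.15,
                       boundary_2d = "intermediate") {
  stopifnot(length(territories) %in% 1:2)
  if (length(territories) == 1) {
    dec <- decompose_merged_pair(territories[[1]], img, paint, bins,
                                 terminal_cutoff)
    profile <- dec$profile
    D <- dec$D
    d <- 0
    touching <- TRUE
  } else {
    clA <- extract_centerline(territories[[1]])
    clB <- extract_centerline(territories[[2]])
    clA <- orient_centerline(clA, img, paint)
    clB <- orient_centerline(clB, img, paint)
    DA <- estimate_width(territories[[1]], clA)
    DB <- estimate_width(territories[[2]], clB)
    D <- (DA + DB) / 2
    ed <- edge_distance(territories[[1]], territories[[2]])
    d <- as.numeric(ed)
    touching <- attr(ed, "touching")
    profile <- association_profile(clA, clB, scale_D = D,
                                   epsilon = epsilon_factor * D, bins = bins)
  }
  state <- classify_alignment_state(profile)
  config <- classify_configuration(profile, pc_end = paint$pc_end,
                                   touching = touching,
                                   terminal_cutoff = terminal_cutoff)
  data.frame(
    chromosome_id = paint$chromosome_id,
    n_territories = length(territories),
    edge_distance_d = d,
    scale_D = D,
    proximity = classify_proximity(d, D, touching = touching,
                                   boundary_2d = boundary_2d),
    paired_fraction = attr(profile, "paired_fraction") %||% mean(profile),
    alignment_state = state,
    configuration = config,
    flagged = isTRUE(attr(profile, "flagged")),
    stringsAsFactors = FALSE)
}
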