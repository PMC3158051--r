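#' Edge-to-edge distance between two territory masks
#'
#' Shortest Euclidean surface-to-surface distance in µm; 0 when the masks
#' overlap or are 26-adjacent (touching). For masks on the same voxel grid,
#' overlap and adjacency are tested exactly; otherwise contact is inferred
#' from surface distances below the diagonal voxel pitch.
#'
#' @param tmA,tmB [territory_mask()] objects.
#' @return Distance in µm with attribute `"touching"` (logical).
#' @export
edge_distance <- function(tmA, tmB) {
  same_grid <- identical(dim(tmA$mask), dim(tmB$mask)) &&
    isTRUE(all.equal(tmA$origin, tmB$origin)) &&
    isTRUE(all.equal(tmA$voxel_size, tmB$voxel_size))
  diag_pitch <- sqrt(sum(pmax(tmA$voxel_size, tmB$voxel_size)^2))
  touching <- FALSE
  if (same_grid && any(tmA$mask & tmB$mask)) {
    touching <- TRUE
  }
  if (!touching) {
    sA <- surface_points(tmA$mask, tmA$voxel_size, tmA$origin)
    sB <- surface_points(tmB$mask, tmB$voxel_size, tmB$origin)
    dmin <- cpp_min_set_distance(sA, sB)
    if (dmin <= diag_pitch + 1e-9) touching <- TRUE
    d <- if (touching) 0 else dmin
  } else d <- 0
  structure(d, touching = touching)
}

#' Classify the spatial relationship of two territories
#'
#' Distances are expressed in units of the territory width D: touching
#' (contact), close (0 < d <= D), intermediate (D < d <= 2D) and far
#' (d > 2D). The printed category bounds overlap at exactly d = 2D
#' ("D<d<=2D" vs "2D<=d"); the default resolves that boundary to
#' intermediate, `boundary_2d = "far"` flips it.
#'
#' @param d Edge distance(s), µm, >= 0.
#' @param D Territory width scale unit, µm, > 0.
#' @param touching Logical (recycled): mask contact under 26-connectivity.
#' @param boundary_2d Category assigned at exactly d = 2D.
#' @return Character vector of categories.
#' @export
classify_proximity <- function(d, D, touching = FALSE,
                               boundary_2d = c("intermediate", "far")) {
  boundary_2d <- match.arg(boundary_2d)
  if (any(d < 0)) stop("negative edge distance")
  if (any(D <= 0)) stop("width scale D must be positive")
  touching <- rep_len(touching, length(d))
  out <- character(length(d))
  for (i in seq_along(d)) {
    out[i] <- if (touching[i] || d[i] == 0) "touching"
    else if (d[i] <= D) "close"
    else if (d[i] < 2 * D) "intermediate"
    else if (d[i] == 2 * D) boundary_2d
    else "far"
  }
  out
}

# Observed channel signature (mean per-channel intensity) near a relative
# arclength position of a centerline.
signature_at <- function(img, cl, channels, pos, window = 0.04) {
  n <- nrow(cl$points)
  lo <- max(1L, round((pos - window) * (n - 1)) + 1L)
  hi <- min(n, round((pos + window) * (n - 1)) + 1L)
  pts <- cl$points[lo:hi, , drop = FALSE]
  vapply(channels, function(ch)
    mean(sample_trilinear(img$channels[[ch]], pts, img$voxel_size,
                          img$origin)), numeric(1))
}

# Cosine match between an observed channel signature and the indicator of
# an expected channel set.
signature_match <- function(obs, expected_channels, channels) {
  ind <- as.numeric(channels %in% expected_channels)
  no <- sqrt(sum(obs^2)); ni <- sqrt(sum(ind^2))
  if (no <= 0 || ni <= 0) return(0)
  sum(obs * ind) / (no * ni)
}

#' Orient a centerline along the chromosome coordinate
#'
#' Uses the paint scheme's terminal colors: channel signatures sampled near
#' both centerline ends (and slightly inward, which disambiguates paints
#' whose two ends share the same double-label dyes) are matched against the
#' channels expected at coordinates 0 and 1. The points are reversed if
#' needed so that the first point is the chromosome's left end; when the
#' two orientations score indistinguishably the centerline is flagged
#' unorientable (`oriented = FALSE`).
#'
#' @param cl A `centerline`.
#' @param img The source `voxel_image`.
#' @param paint The territory's [paint_scheme()].
#' @return The centerline, possibly reversed, with `oriented` set.
#' @export
orient_centerline <- function(cl, img, paint) {
  channels <- paint_channels(paint)
  probe <- c(0.03, 0.12, 0.25)
  score <- function(flip) {
    s <- 0
    for (p in probe) {
      obs_l <- signature_at(img, cl, channels, if (flip) 1 - p else p)
      obs_r <- signature_at(img, cl, channels, if (flip) p else 1 - p)
      s <- s + signature_match(obs_l, unlist(channels_at(paint, p)), channels) +
        signature_match(obs_r, unlist(channels_at(paint, 1 - p)), channels)
    }
    s
  }
  s0 <- score(FALSE); s1 <- score(TRUE)
  if (s1 > s0) {
    cl$points <- cl$points[rev(seq_len(nrow(cl$points))), , drop = FALSE]
    cl$arclength <- rev(cl$length - cl$arclength)
    cl$tips <- cl$tips[2:1, , drop = FALSE]
  }
  cl$oriented <- abs(s1 - s0) > 0.02 * max(abs(s0), abs(s1), 1e-9)
  cl
}

#' Per-coordinate homolog association profile
#'
#' Divides the chromosome coordinate into bins and marks a bin paired when
#' the two centerline points mapped to that bin lie within `epsilon`
#' (default one territory width D) of each other. If a centerline is
#' unorientable the profile is computed under both orientations and the one
#' maximizing the paired fraction is returned, flagged.
#'
#' @param clA,clB Oriented centerlines of the two homologs.
#' @param scale_D Territory width D (µm), the default pairing distance.
#' @param epsilon Pairing distance threshold (µm); default `scale_D`.
#' @param bins Number of coordinate bins (default 20).
#' @return Logical vector of length `bins` with attributes
#'   `paired_fraction` and `flagged`.
#' @export
association_profile <- function(clA, clB, scale_D, epsilon = scale_D,
                                bins = 20L) {
  um <- (seq_len(bins) - 0.5) / bins
  flips_A <- if (isTRUE(clA$oriented)) FALSE else c(FALSE, TRUE)
  flips_B <- if (isTRUE(clB$oriented)) FALSE else c(FALSE, TRUE)
  best <- NULL
  for (fa in flips_A) for (fb in flips_B) {
    ua <- if (fa) 1 - um else um
    ub <- if (fb) 1 - um else um
    A <- resample_at(clA$points, ua)
    B <- resample_at(clB$points, ub)
    paired <- sqrt(rowSums((A - B)^2)) <= epsilon
    if (is.null(best) || mean(paired) > mean(best)) best <- paired
  }
  structure(best,
            paired_fraction = mean(best),
            flagged = !(isTRUE(clA$oriented) && isTRUE(clB$oriented)))
}

#' Classify the alignment state of a homolog pair
#'
#' Full when at least `full_threshold` of coordinate bins are paired and
#' both terminal bins are paired; unaligned when at most
#' `unaligned_threshold` are paired; partial otherwise.
#'
#' @param profile Logical association profile.
#' @param full_threshold Paired fraction for full alignment (default 0.9).
#' @param unaligned_threshold Paired fraction at or below which the pair is
#'   unaligned (default 0.05).
#' @export
classify_alignment_state <- function(profile, full_threshold = 0.9,
                                     unaligned_threshold = 0.05) {
  f <- mean(profile)
  n <- length(profile)
  if (f >= full_threshold && profile[1] && profile[n]) "full"
  else if (f <= unaligned_threshold) "unaligned"
  else "partial"
}

#' Classify the association configuration of a homolog pair
#'
#' Maps an association profile to the configuration taxonomy
#' ([configuration_levels()]). Decision order: no_contact when nothing is
#' paired and the territories are not touching; no_alignment when touching
#' without any homologous register; full per
#' [classify_alignment_state()]; V-PC / V-NPC when the single paired run is
#' confined to the terminal `terminal_cutoff` fraction at the PC / non-PC
#' end; Y-PC / Y-NPC when a single run starts at an end and extends further;
#' X for a single interior run; O for runs at both ends with an unpaired
#' middle; `other` for any remaining pattern.
#'
#' @param profile Logical association profile (chromosome coordinates,
#'   bin 1 = left end).
#' @param pc_end `"left"` or `"right"`: which end carries the pairing
#'   center.
#' @param touching Logical: territories in contact.
#' @param terminal_cutoff Coordinate fraction defining "end-only"
#'   association (default 0.15).
#' @inheritParams classify_alignment_state
#' @export
classify_configuration <- function(profile, pc_end = "left",
                                   touching = FALSE, terminal_cutoff = 0.15,
                                   full_threshold = 0.9) {
  n <- length(profile)
  # work in PC-oriented coordinates: bin 1 adjacent to the PC
  pp <- if (pc_end == "right") rev(profile) else profile
  if (!any(pp)) return(if (touching) "no_alignment" else "no_contact")
  if (classify_alignment_state(pp, full_threshold) == "full") return("full")
  r <- rle(as.logical(pp))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- cbind(start = starts[r$values], end = ends[r$values])
  nr <- nrow(runs)
  u_start <- (runs[, "start"] - 1) / n
  u_end <- runs[, "end"] / n
  at_pc <- runs[, "start"] == 1
  at_npc <- runs[, "end"] == n
  if (nr == 1) {
    if (at_pc[1] && u_end[1] <= terminal_cutoff + 1e-9) return("V-PC")
    if (at_npc[1] && u_start[1] >= 1 - terminal_cutoff - 1e-9) return("V-NPC")
    if (at_pc[1]) return("Y-PC")
    if (at_npc[1]) return("Y-NPC")
    return("X")
  }
  if (nr == 2 && any(at_pc) && any(at_npc)) return("O")
  "other"
}
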