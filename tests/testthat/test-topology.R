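# Edge distances, proximity categories, association profiles and the
# configuration taxonomy.

ball_mask <- function(center, radius, d = c(60, 60, 30), h = 0.1) {
  sub <- which(array(TRUE, d), arr.ind = TRUE)
  ctr <- cbind(x = (sub[, 2] - 0.5) * h, y = (sub[, 1] - 0.5) * h,
               z = (sub[, 3] - 0.5) * h)
  array(rowSums(sweep(ctr, 2, center)^2) <= radius^2, d)
}

test_that("edge distance matches the analytic sphere separation", {
  vox <- c(z = 0.1, y = 0.1, x = 0.1)
  A <- territory_mask(ball_mask(c(1.4, 3, 1.5), 1), vox)
  B <- territory_mask(ball_mask(c(4.4, 3, 1.5), 1), vox)
  d <- edge_distance(A, B)
  expect_lt(abs(as.numeric(d) - 1), 0.11)
  expect_false(attr(d, "touching"))
  # brute force over surface voxel pairs agrees
  sA <- chromterr:::surface_points(A$mask, vox)
  sB <- chromterr:::surface_points(B$mask, vox)
  brute <- min(as.matrix(dist(rbind(sA, sB)))[seq_len(nrow(sA)),
                                              nrow(sA) + seq_len(nrow(sB))])
  expect_equal(as.numeric(d), brute)
})

test_that("overlapping and identical masks have zero edge distance", {
  vox <- c(z = 0.1, y = 0.1, x = 0.1)
  A <- territory_mask(ball_mask(c(2, 2, 1.5), 0.8), vox)
  B <- territory_mask(ball_mask(c(2.5, 2, 1.5), 0.8), vox)
  dAB <- edge_distance(A, B)
  expect_identical(as.numeric(dAB), 0)
  expect_true(attr(dAB, "touching"))
  dAA <- edge_distance(A, A)
  expect_identical(as.numeric(dAA), 0)
  # symmetry
  expect_equal(as.numeric(edge_distance(B, A)), as.numeric(dAB))
})

test_that("proximity categories partition every distance exactly once", {
  D <- 0.67
  ratios <- seq(0, 4, by = 0.01)
  cats <- classify_proximity(ratios * D, D)
  expect_true(all(cats %in% proximity_levels()))
  # printed boundaries
  expect_identical(classify_proximity(0.5 * D, D), "close")
  expect_identical(classify_proximity(1.0 * D, D), "close")
  expect_identical(classify_proximity(1.5 * D, D), "intermediate")
  expect_identical(classify_proximity(3.0 * D, D), "far")
  expect_identical(classify_proximity(0, D, touching = TRUE), "touching")
  # the printed bounds overlap at exactly d = 2D; both resolutions exposed
  expect_identical(classify_proximity(2 * D, D), "intermediate")
  expect_identical(classify_proximity(2 * D, D, boundary_2d = "far"), "far")
  expect_error(classify_proximity(-0.1, D), "negative")
})

test_that("association profiles pair coincident and separate centerlines", {
  mk_cl <- function(pts) {
    s <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
    structure(list(points = pts, arclength = s, length = s[length(s)],
                   oriented = TRUE, method = "synthetic"),
              class = "centerline")
  }
  base <- cbind(x = seq(0, 5, length.out = 50), y = 0, z = 0)
  same <- association_profile(mk_cl(base), mk_cl(base), scale_D = 0.67)
  expect_true(all(same))
  apart <- base; apart[, 2] <- 3
  none <- association_profile(mk_cl(base), mk_cl(apart), scale_D = 0.67)
  expect_false(any(none))
  # swapping homologs leaves the profile unchanged
  half <- base
  half[, 2] <- c(rep(0, 25), seq(0, 2.5, length.out = 25))
  pAB <- association_profile(mk_cl(base), mk_cl(half), scale_D = 0.67)
  pBA <- association_profile(mk_cl(half), mk_cl(base), scale_D = 0.67)
  expect_identical(as.logical(pAB), as.logical(pBA))
})

test_that("alignment states follow the paired-fraction rules", {
  expect_identical(classify_alignment_state(rep(TRUE, 20)), "full")
  expect_identical(classify_alignment_state(rep(FALSE, 20)), "unaligned")
  half <- c(rep(TRUE, 10), rep(FALSE, 10))
  expect_identical(classify_alignment_state(half), "partial")
  # full needs both terminal bins paired
  no_end <- c(FALSE, rep(TRUE, 19))
  expect_identical(classify_alignment_state(no_end), "partial")
  # exactly one of twenty bins paired sits at the unaligned boundary (5%)
  one_bin <- c(TRUE, rep(FALSE, 19))
  expect_identical(classify_alignment_state(one_bin), "unaligned")
  two_bins <- c(TRUE, TRUE, rep(FALSE, 18))
  expect_identical(classify_alignment_state(two_bins), "partial")
})

test_that("configuration taxonomy covers the decision table", {
  prof <- function(runs, n = 20) {
    um <- (seq_len(n) - 0.5) / n
    p <- rep(FALSE, n)
    for (i in seq_len(nrow(runs)))
      p <- p | (um >= runs[i, 1] & um <= runs[i, 2])
    p
  }
  expect_identical(classify_configuration(prof(rbind(c(0, 0.1))), "left",
                                          touching = TRUE), "V-PC")
  expect_identical(classify_configuration(prof(rbind(c(0, 0.5))), "left",
                                          touching = TRUE), "Y-PC")
  expect_identical(classify_configuration(prof(rbind(c(0.9, 1))), "left",
                                          touching = TRUE), "V-NPC")
  expect_identical(classify_configuration(prof(rbind(c(0.5, 1))), "left",
                                          touching = TRUE), "Y-NPC")
  expect_identical(classify_configuration(prof(rbind(c(0.4, 0.6))), "left",
                                          touching = TRUE), "X")
  expect_identical(classify_configuration(
    prof(rbind(c(0, 0.1), c(0.9, 1))), "left", touching = TRUE), "O")
  expect_identical(classify_configuration(
    prof(rbind(c(0, 0.1), c(0.45, 0.55), c(0.9, 1))), "left",
    touching = TRUE), "other")
  expect_identical(classify_configuration(prof(rbind(c(0, 1))), "left",
                                          touching = TRUE), "full")
  empty <- rep(FALSE, 20)
  expect_identical(classify_configuration(empty, "left", touching = TRUE),
                   "no_alignment")
  expect_identical(classify_configuration(empty, "left", touching = FALSE),
                   "no_contact")
  # PC on the right end mirrors the labels
  expect_identical(classify_configuration(prof(rbind(c(0.9, 1))), "right",
                                          touching = TRUE), "V-PC")
  expect_identical(classify_configuration(prof(rbind(c(0, 0.5))), "right",
                                          touching = TRUE), "Y-NPC")
})

test_that("planted Y-PC boundary is recovered within one bin", {
  paint <- paint_scheme_preset("chrII_thirds")
  nuc <- generate_nucleus(list(list(paint = paint, configuration = "Y-PC",
                                    stage = "extended",
                                    target_slenderness = 7,
                                    paired_fraction = 0.5)), seed = 21)
  img <- render_voxels(nuc, optics_noise_free())
  sc <- score_nucleus(img, list(paint), run_config(optics = optics_noise_free()))
  expect_identical(sc$pairs$configuration, "Y-PC")
  expect_lt(abs(sc$pairs$paired_fraction - 0.5), 0.15)
})

test_that("orientation from terminal colors flips reversed centerlines", {
  paint <- paint_scheme_preset("chrI_halves")
  res <- make_straight_territory(S = 6, paint = paint)
  cl <- extract_centerline(res$territory)
  cl <- orient_centerline(cl, res$img, paint)
  expect_true(cl$oriented)
  # channel 1 paints the left half: the first centerline point must sample
  # more channel-1 than channel-2 signal
  s1 <- chromterr:::sample_trilinear(res$img$channels[[1]],
                                     cl$points[3, , drop = FALSE],
                                     res$img$voxel_size, res$img$origin)
  s2 <- chromterr:::sample_trilinear(res$img$channels[[2]],
                                     cl$points[3, , drop = FALSE],
                                     res$img$voxel_size, res$img$origin)
  expect_gt(s1, s2)
})
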