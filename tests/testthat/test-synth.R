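# Ground-truthed generator: paint schemes, territory models, nuclei, gonads.

test_that("paint schemes validate interval structure", {
  expect_s3_class(paint_scheme("chrA", list(
    list(interval = c(0, 0.5), channels = 1L),
    list(interval = c(0.5, 1), channels = 2L))), "paint_scheme")
  # overlapping intervals rejected
  expect_error(paint_scheme("chrA", list(
    list(interval = c(0, 0.6), channels = 1L),
    list(interval = c(0.5, 1), channels = 2L))), "overlap")
  # degenerate interval rejected
  expect_error(paint_scheme("chrA", list(
    list(interval = c(0.7, 0.7), channels = 1L))))
  # uncovered (grey) regions are allowed; double-labeled ends carry two
  # channels
  p <- paint_scheme("chrB", list(
    list(interval = c(0, 0.1), channels = c(1L, 3L)),
    list(interval = c(0.3, 1), channels = 2L)))
  expect_identical(channels_at(p, 0.05)[[1]], c(1L, 3L))
  expect_identical(channels_at(p, 0.2)[[1]], integer(0))
  expect_identical(paint_channels(p), c(1L, 2L, 3L))
})

test_that("generate_territory hits its analytic slenderness and is deterministic", {
  t1 <- generate_territory("compact", target_slenderness = 1.5, seed = 42)
  t2 <- generate_territory("compact", target_slenderness = 1.5, seed = 42)
  expect_identical(t1, t2)
  expect_true(abs(t1$slenderness - 1.5) <= 0.05 * 1.5)
  # width drawn from the stated distribution stays plausible
  ws <- vapply(1:40, function(i)
    generate_territory("compact", seed = i)$width, numeric(1))
  expect_true(abs(mean(ws) - 0.67) < 0.05)
  expect_error(generate_territory("compact", target_slenderness = 0.5),
               "slenderness")
  expect_error(generate_territory("extended", target_slenderness = 12,
                                  seed = 1, max_extent = 0.8), "infeasible")
})

test_that("bead profiles carry exactly the planted number of peaks", {
  for (k in 1:6) {
    t <- generate_territory("extended", bead_count = k, seed = k + 10)
    expect_identical(oracle_peak_count(t$bead_profile), k)
  }
})

test_that("planted nucleus truth is consistent with its geometry", {
  paint <- paint_scheme_preset("chrII_thirds")
  for (cfg in c("V-PC", "Y-PC", "full", "no_contact")) {
    nuc <- generate_nucleus(list(list(paint = paint, configuration = cfg,
                                      stage = "extended",
                                      target_slenderness = 7)),
                            seed = 3 + nchar(cfg))
    tr <- nuc$pair_truth[[1]]
    A <- nuc$territories[[1]]; B <- nuc$territories[[2]]
    # recompute the association profile by brute-force discretization
    um <- (seq_len(20) - 0.5) / 20
    pA <- chromterr:::resample_at(A$centerline, um)
    pB <- chromterr:::resample_at(B$centerline, um)
    prof <- sqrt(rowSums((pA - pB)^2)) <= tr$scale_D
    expect_identical(prof, as.logical(tr$profile))
    if (cfg == "full") expect_true(all(tr$profile))
    if (cfg == "no_contact") {
      expect_false(any(tr$profile))
      expect_gt(tr$edge_distance, 2 * tr$scale_D)
    }
    # territories stay inside the nuclear sphere
    for (m in nuc$territories)
      expect_lte(max(sqrt(rowSums(m$centerline^2))) + m$tube_radius,
                 nuc$nuclear_radius + 1e-6)
  }
})

test_that("same seed reproduces the same nucleus and gonad", {
  paint <- paint_scheme_preset("chrI_halves")
  n1 <- generate_nucleus(list(list(paint = paint, configuration = "Y-PC",
                                   stage = "extended")), seed = 11)
  n2 <- generate_nucleus(list(list(paint = paint, configuration = "Y-PC",
                                   stage = "extended")), seed = 11)
  expect_identical(n1, n2)
  g1 <- generate_gonad("wildtype", rows = c(premeiotic = 2, transition = 2,
                                            pachytene = 2),
                       nuclei_per_row = 1, seed = 5)
  g2 <- generate_gonad("wildtype", rows = c(premeiotic = 2, transition = 2,
                                            pachytene = 2),
                       nuclei_per_row = 1, seed = 5)
  expect_identical(g1$layout, g2$layout)
})

test_that("gonad layout plants the requested zones", {
  g <- generate_gonad("wildtype",
                      rows = c(premeiotic = 3, transition = 3, pachytene = 3),
                      nuclei_per_row = 2, seed = 9)
  expect_identical(unique(g$layout$zone_planted[g$layout$row <= 3]),
                   "premeiotic")
  expect_identical(unique(g$layout$zone_planted[g$layout$row > 6]),
                   "pachytene")
  expect_true(all(g$layout$clustered[g$layout$zone_planted == "transition"]))
  expect_error(generate_gonad("wildtype", nuclei_per_row = 0), "empty layout")
})

test_that("syp-1 gonads use the six-zone subdivision", {
  g <- generate_gonad("syp1", rows = c(premeiotic = 2, meiotic = 27),
                      nuclei_per_row = 1, seed = 2)
  meiotic <- g$layout[g$layout$row > 2, ]
  widths <- as.integer(table(factor(meiotic$zone_planted,
                                    levels = paste0("zone", 2:6))))
  expect_identical(widths, c(5L, 5L, 5L, 5L, 7L))
})

test_that("noise-free renders equal the analytic tube times the profile", {
  paint <- paint_scheme_preset("chrI_halves")
  p1 <- c(1, 1.5, 1.5); p2 <- c(6.2, 1.5, 1.5)
  cl <- outer(seq(0, 1, length.out = 50), p2 - p1) +
    matrix(p1, 50, 3, byrow = TRUE)
  colnames(cl) <- c("x", "y", "z")
  tube <- territory_from_centerline(cl, 0.3, paint = paint)
  img <- render_voxels(tube, optics_noise_free(photon_scale = 100))
  want <- oracle_tube_mask(dim(img$channels[[1]]), img$voxel_size,
                           img$origin, p1, p2, 0.3)
  got <- (img$channels[[1]] + img$channels[[2]]) > 0
  expect_identical(got, want)
  # flat profile: every inside voxel carries exactly photon_scale counts
  expect_equal(max(abs((img$channels[[1]] + img$channels[[2]])[want] - 100)),
               0)
  # linearity in photon_scale
  img2 <- render_voxels(tube, optics_noise_free(photon_scale = 200))
  expect_equal(img2$channels[[1]], 2 * img$channels[[1]])
})

test_that("double-labeled intervals emit into both channels", {
  paint <- paint_scheme_preset("chrII_thirds")
  res <- make_straight_territory(S = 6, paint = paint)
  img <- res$img
  # terminal 5% voxels are positive in channels 1 and 3 simultaneously
  both <- img$channels[[1]] > 0 & img$channels[[3]] > 0
  expect_gt(sum(both), 0)
})

test_that("noise-free renders conserve expected photons", {
  paint <- paint_scheme_preset("chrI_halves")
  t <- generate_territory("extended", target_slenderness = 6, bead_count = 3,
                          seed = 17)
  img <- render_voxels(t, optics_noise_free(photon_scale = 150))
  total <- sum(img$channels[[1]]) + sum(img$channels[[2]])
  vox_vol <- prod(img$voxel_size)
  analytic <- 150 * (pi * t$tube_radius^2 * t$length / vox_vol) *
    mean(t$bead_profile)
  # tolerance: one voxel shell around the tube surface
  shell <- 150 * (2 * pi * t$tube_radius * t$length * 0.1 / vox_vol)
  expect_lt(abs(total - analytic), shell)
})

test_that("rendering rejects territories outside the field of view", {
  paint <- paint_scheme_preset("chrI_halves")
  cl <- cbind(x = seq(0, 3, length.out = 10), y = 1, z = 1)
  tube <- territory_from_centerline(cl, 0.3, paint = paint)
  expect_error(render_voxels(tube, optics_noise_free(),
                             fov = list(lo = c(0.5, 0, 0), hi = c(2, 2, 2))),
               "field of view")
})
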