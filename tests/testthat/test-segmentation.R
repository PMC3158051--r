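# Channel segmentation and territory assembly.

test_that("noise-free segmentation recovers the analytic tube exactly", {
  paint <- paint_scheme_preset("chrI_halves")
  res <- make_straight_territory(S = 5, width = 0.6, paint = paint)
  img <- res$img
  m <- segment_channel(img, 1, region = array(TRUE, dim(img$channels[[1]]))) |
    segment_channel(img, 2, region = array(TRUE, dim(img$channels[[1]])))
  want <- img$channels[[1]] + img$channels[[2]] > 0
  expect_identical(unname(m), unname(want))
})

test_that("an all-zero channel yields an empty-mask flag", {
  paint <- paint_scheme_preset("chrI_halves")
  res <- make_straight_territory(S = 4, paint = paint)
  img <- res$img
  img$channels[[2]] <- array(0, dim(img$channels[[2]]))
  m <- segment_channel(img, 2)
  expect_false(any(m))
  expect_true(attr(m, "empty"))
})

test_that("segmentation is idempotent on binary images", {
  paint <- paint_scheme_preset("chrI_halves")
  res <- make_straight_territory(S = 4, paint = paint)
  img <- res$img
  img$channels[[1]] <- (img$channels[[1]] > 0) * 1
  m1 <- segment_channel(img, 1, region = array(TRUE, dim(img$channels[[1]])))
  img$channels[[1]] <- m1 * 1
  m2 <- segment_channel(img, 1, region = array(TRUE, dim(img$channels[[1]])))
  expect_identical(m1, m2)
})

test_that("well-separated tubes give two components matching the oracle", {
  paint <- paint_scheme_preset("chrI_halves")
  cl1 <- cbind(x = seq(1, 4, length.out = 30), y = 1, z = 1)
  cl2 <- cbind(x = seq(1, 4, length.out = 30), y = 3, z = 1)
  t1 <- territory_from_centerline(cl1, 0.3, paint = paint)
  t2 <- territory_from_centerline(cl2, 0.3, paint = paint)
  nuc <- structure(list(territories = list(t1, t2), pair_truth = list(),
                        background = list(),
                        nuclear_radius = Inf, clustered = FALSE),
                   class = "nucleus_spec")
  img <- render_voxels(nuc, optics_noise_free(), dapi = FALSE)
  m <- segment_channel(img, 1, region = array(TRUE, dim(img$channels[[1]])))
  lab_pkg <- chromterr:::cpp_label_components(as.logical(m), dim(m), 26L)
  lab_orc <- oracle_components(m, 26)
  expect_identical(max(lab_pkg), 2L)
  expect_identical(max(lab_pkg), max(lab_orc))
  # identical partition up to label order
  expect_identical(length(unique(paste(lab_pkg[m], lab_orc[m]))), 2L)
})

test_that("assembly merges bead gaps but keeps distinct homologs apart", {
  paint <- paint_scheme_preset("chrI_halves")
  # a beaded tube whose inter-bead gaps fall below threshold still
  # assembles into one territory
  res <- make_straight_territory(
    S = 7, paint = paint,
    bead_profile = chromterr:::bead_profile_fun(4, 0), bead_count = 4L,
    optics = optics_noise_free())
  expect_identical(res$n_territories, 1L)
  # a fully aligned pair assembles into a single territory
  nuc_full <- generate_nucleus(list(list(paint = paint,
                                         configuration = "full",
                                         stage = "extended")), seed = 31)
  img <- render_voxels(nuc_full, optics_noise_free())
  segs <- segment_image(img, list(paint))
  expect_identical(length(segs[["chrI"]]), 1L)
  # a no-contact pair assembles into exactly two
  nuc_nc <- generate_nucleus(list(list(paint = paint,
                                       configuration = "no_contact",
                                       stage = "extended")), seed = 32)
  img2 <- render_voxels(nuc_nc, optics_noise_free())
  segs2 <- segment_image(img2, list(paint))
  expect_identical(length(segs2[["chrI"]]), 2L)
})

test_that("territory masks expose z-major voxel indices within bounds", {
  paint <- paint_scheme_preset("chrI_halves")
  res <- make_straight_territory(S = 3, paint = paint)
  tm <- res$territory
  d <- dim(tm$mask)
  expect_true(all(tm$voxels >= 0 & tm$voxels < prod(d)))
  expect_identical(length(tm$voxels), sum(tm$mask))
})
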