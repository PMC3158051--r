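# Centerline, width, slenderness and painted-segment counting.

test_that("straight tube length and width are recovered", {
  paint <- paint_scheme_preset("chrI_halves")
  res <- make_straight_territory(S = 7.5, width = 0.67, paint = paint,
                                 direction = c(0.8, 0.5, 0.33))
  cl <- extract_centerline(res$territory)
  expect_lt(abs(cl$length - res$model$length) / res$model$length, 0.05)
  D <- estimate_width(res$territory, cl)
  expect_gte(D, 0.57)
  expect_lte(D, 0.77)
})

test_that("a sphere has slenderness near one", {
  d <- c(21, 21, 21)
  sub <- which(array(TRUE, d), arr.ind = TRUE)
  ctr <- (sub - 0.5) * 0.1
  ball <- array(rowSums(sweep(ctr, 2, c(1.05, 1.05, 1.05))^2) <= 0.5^2, d)
  tm <- territory_mask(ball, c(z = 0.1, y = 0.1, x = 0.1))
  cl <- extract_centerline(tm)
  D <- estimate_width(tm, cl)
  expect_lt(abs(cl$length - 1) , 0.2)
  expect_lt(abs(cl$length / D - 1), 0.35)
})

test_that("a U-shaped tube measures its full arc, not the chord", {
  paint <- paint_scheme_preset("chrI_halves")
  th <- seq(0, pi, length.out = 60)
  clu <- cbind(x = 1.5 + cos(th), y = 1.5 + sin(th), z = 1.5)
  tube <- territory_from_centerline(clu, 0.3, paint = paint,
                                    stage = "extended")
  img <- render_voxels(tube, optics_noise_free())
  reg <- array(TRUE, dim(img$channels[[1]]))
  terrs <- assemble_territories(
    list(segment_channel(img, 1, region = reg),
         segment_channel(img, 2, region = reg)),
    paint, img$voxel_size, img$origin)
  cl <- extract_centerline(terrs[[1]])
  expect_lt(abs(cl$length - pi) / pi, 0.06)  # arc length, chord would be 2
})

test_that("slenderness and the highly-extended call follow the strict threshold", {
  expect_equal(slenderness(4.69, 0.67), 7)
  expect_true(classify_extension(slenderness(4.69, 0.67)))
  expect_false(classify_extension(6))       # strict: exactly 6 is negative
  expect_true(classify_extension(6 + 1e-9))
  expect_false(classify_extension(1))
  expect_error(slenderness(0, 1), "positive")
  expect_error(slenderness(1, -1), "positive")
})

test_that("width recovery over a compact panel matches the generator", {
  paint <- paint_scheme_preset("chrI_halves")
  widths <- vapply(1:16, function(i) {
    t <- generate_territory("compact", target_slenderness = 1.8,
                            width_mean = 0.67, width_sd = 0.05,
                            seed = 100 + i)
    img <- render_voxels(t, optics_noise_free())
    reg <- array(TRUE, dim(img$channels[[1]]))
    terrs <- assemble_territories(
      list(segment_channel(img, 1, region = reg),
           segment_channel(img, 2, region = reg)),
      paint, img$voxel_size, img$origin)
    estimate_width(terrs[[1]], extract_centerline(terrs[[1]]))
  }, numeric(1))
  # sample mean within 2 standard errors of the generator mean
  se <- sd(widths) / sqrt(length(widths))
  expect_lt(abs(mean(widths) - 0.67), 2 * se + 0.02)
})

test_that("painted segments: uniform ovoid counts one, beads count exactly", {
  # single-fluorophore paint: the count reflects intensity structure only
  mono <- paint_scheme("chrM", list(list(interval = c(0, 1), channels = 1L)))
  flat <- make_straight_territory(S = 2, paint = mono,
                                  bead_profile = rep(1, 200))
  cl <- extract_centerline(flat$territory)
  expect_identical(count_painted_segments(flat$img, cl, mono), 1L)
  for (k in c(3L, 5L)) {
    prof <- chromterr:::bead_profile_fun(k, 0)   # zero-intensity troughs
    res <- make_straight_territory(S = 8, paint = mono,
                                   bead_profile = prof, bead_count = k)
    cl <- extract_centerline(res$territory)
    expect_identical(count_painted_segments(res$img, cl, mono), k)
    expect_identical(oracle_peak_count(prof), k)
  }
})

test_that("spatially resolved two-color halves count as two segments", {
  paint <- paint_scheme_preset("chrI_halves")
  res <- make_straight_territory(S = 6, paint = paint,
                                 bead_profile = rep(1, 200))
  cl <- extract_centerline(res$territory)
  expect_identical(count_painted_segments(res$img, cl, paint), 2L)
})

test_that("inserting a full-depth gap increases the count by one", {
  mono <- paint_scheme("chrM", list(list(interval = c(0, 1), channels = 1L)))
  for (k in 2:4) {
    p1 <- chromterr:::bead_profile_fun(k, 0)
    p2 <- chromterr:::bead_profile_fun(k + 1L, 0)
    r1 <- make_straight_territory(S = 9, paint = mono, bead_profile = p1,
                                  bead_count = k)
    r2 <- make_straight_territory(S = 9, paint = mono, bead_profile = p2,
                                  bead_count = k + 1L)
    k1 <- count_painted_segments(r1$img, extract_centerline(r1$territory),
                                 mono)
    k2 <- count_painted_segments(r2$img, extract_centerline(r2$territory),
                                 mono)
    expect_identical(k2 - k1, 1L)
  }
})

test_that("morphometry is invariant under rigid motion of the geometry", {
  paint <- paint_scheme_preset("chrI_halves")
  base <- generate_territory("extended", target_slenderness = 7,
                             bead_count = 3, seed = 61)
  measure <- function(model) {
    img <- render_voxels(model, optics_noise_free())
    reg <- array(TRUE, dim(img$channels[[1]]))
    terrs <- assemble_territories(
      list(segment_channel(img, 1, region = reg),
           segment_channel(img, 2, region = reg)),
      paint, img$voxel_size, img$origin)
    cl <- extract_centerline(terrs[[1]])
    c(D = estimate_width(terrs[[1]], cl), L = cl$length,
      k = count_painted_segments(img, cl, paint))
  }
  m0 <- measure(base)
  set.seed(8)
  rot <- chromterr:::random_rotation()
  m1 <- measure(transform_territory(base, rot, c(0.63, -0.41, 0.28)))
  expect_lt(abs(m0["D"] - m1["D"]), 0.1)   # within one voxel
  expect_lt(abs(m0["L"] - m1["L"]), 0.25)
  expect_identical(m0["k"], m1["k"])
})
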