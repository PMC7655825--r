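test_that("microwell detection recovers a synthetic grid to pixel accuracy", {
  sim <- simulate_device_images(n_rows = 10, n_cols = 10, seed = 3)
  grid <- detect_microwells(sim$brightfield)
  expect_equal(nrow(grid$wells), 100)
  expect_equal(grid$radius, sim$params$well_radius, tolerance = 0.1)
  # match detected centers to truth by nearest neighbor
  d <- sqrt(outer(grid$wells$x, sim$truth$x, `-`)^2 +
            outer(grid$wells$y, sim$truth$y, `-`)^2)
  nearest <- apply(d, 1, min)
  expect_lt(max(nearest), 1.5)
  # local thresholding is invariant to a global intensity offset
  grid2 <- detect_microwells(sim$brightfield + 0.07)
  expect_equal(grid2$wells, grid$wells)
  expect_error(detect_microwells(matrix(0.5, 50, 50)), "blank")
})

test_that("occupancy calls from bimodal well intensities match truth", {
  sim <- simulate_device_images(n_rows = 10, n_cols = 10, occupancy = 0.3,
                                seed = 5)
  grid <- detect_microwells(sim$brightfield)
  # use truth ordering via nearest-neighbor match
  occ <- call_occupied_wells(grid, sim$green + sim$magenta)
  d <- sqrt(outer(grid$wells$x, sim$truth$x, `-`)^2 +
            outer(grid$wells$y, sim$truth$y, `-`)^2)
  truth_occ <- sim$truth$occupied[apply(d, 1, which.min)]
  tp <- sum(occ$occupied & truth_occ)
  expect_gte(tp / sum(truth_occ), 0.99)              # recall
  expect_gte(tp / max(sum(occ$occupied), 1), 0.99)   # precision
  # threshold sits strictly between the fitted component means
  thr <- bimodal_threshold(occ$mean_intensity)
  fit <- attr(thr, "fit")
  expect_gt(as.numeric(thr), min(fit$mu))
  expect_lt(as.numeric(thr), max(fit$mu))
})

test_that("an empty device yields zero occupied wells", {
  sim <- simulate_device_images(occupancy = 0, seed = 2)
  grid <- detect_microwells(sim$brightfield)
  expect_warning(occ <- call_occupied_wells(grid, sim$green), "unoccupied")
  expect_equal(sum(occ$occupied), 0)
})

test_that("feature extraction matches closed forms on analytic shapes", {
  img <- paint_disk(matrix(0, 41, 41), 20, 20, 10, 100)
  rec <- extract_cell_features(img, well_id = 1)$record
  expect_equal(rec$area, pi * 100, tolerance = 0.03)
  expect_equal(rec$mean_intensity, 100)
  expect_equal(rec$median_intensity, 100)
  expect_equal(rec$sd_intensity, 0)
  expect_gte(rec$circularity, 0.85)
  expect_gte(rec$roundness, 0.9)
  expect_equal(rec$major_axis, 20, tolerance = 0.07)
  expect_equal(rec$feret, 20, tolerance = 0.07)
  expect_equal(rec$width, 21)
  expect_equal(rec$height, 21)
  expect_gte(rec$solidity, 0.97)

  # 2:1 ellipse: roundness ~ 0.5, major ~ 2 x minor
  ell <- paint_ellipse(matrix(0, 45, 45), 22, 22, 16, 8, 50)
  rec <- extract_cell_features(ell, well_id = 2)$record
  expect_equal(rec$roundness, 0.5, tolerance = 0.05)
  expect_equal(rec$major_axis / rec$minor_axis, 2, tolerance = 0.05)
  expect_equal(rec$feret, 32, tolerance = 0.05)
  expect_equal(rec$min_feret, 16, tolerance = 0.08)

  sq <- matrix(0, 31, 31); sq[10:20, 10:20] <- 80
  rec <- extract_cell_features(sq, well_id = 3)$record
  expect_equal(rec$area, 121)
  expect_equal(rec$solidity, 1)
  expect_equal(rec$width, 11)
  # Feret diameters are measured between pixel centers: 10 px across the
  # side, 10*sqrt(2) across the diagonal
  expect_equal(rec$min_feret, 10, tolerance = 1e-8)
  expect_equal(rec$feret, 10 * sqrt(2), tolerance = 1e-8)
})

test_that("wells with zero or multiple particles are excluded", {
  two <- paint_disk(paint_disk(matrix(0, 41, 41), 10, 10, 5, 90),
                    30, 30, 5, 90)
  out <- extract_cell_features(two, well_id = 7)
  expect_null(out$record)
  expect_equal(out$excluded, "multiple_particles")
  out <- extract_cell_features(matrix(0, 21, 21), well_id = 8)
  expect_equal(out$excluded, "no_particle")
})

test_that("features are translation invariant and intensity equivariant", {
  a <- paint_disk(matrix(0, 61, 61), 15, 15, 8, 100)
  b <- paint_disk(matrix(0, 61, 61), 40, 35, 8, 100)
  ra <- extract_cell_features(a, 1)$record
  rb <- extract_cell_features(b, 1)$record
  expect_equal(ra[-1], rb[-1])
  c2 <- paint_disk(matrix(0, 61, 61), 15, 15, 8, 250)
  rc <- extract_cell_features(c2, 1)$record
  intensity_cols <- c("mean_intensity", "min_intensity", "max_intensity",
                      "median_intensity")
  expect_equal(unlist(rc[intensity_cols]), 2.5 * unlist(ra[intensity_cols]))
  shape_cols <- c("area", "perimeter", "circularity", "roundness", "solidity",
                  "feret", "min_feret", "major_axis", "minor_axis")
  expect_equal(unlist(rc[shape_cols]), unlist(ra[shape_cols]))
})

test_that("bead tracking tolerates jitter and falls back for missing beads", {
  set.seed(8)
  base <- expand.grid(x = seq(15, 135, by = 30), y = seq(15, 135, by = 30))
  n <- nrow(base)
  mk <- function(jit) data.frame(x = base$x + runif(n, -jit, jit),
                                 y = base$y + runif(n, -jit, jit),
                                 ch5 = runif(n, 90, 110) * rep(c(1, 20), length.out = n),
                                 ch3 = runif(n, 90, 110))
  det0 <- lapply(1:8, function(k) mk(0))
  tab <- track_beads_across_cycles(det0, radius = 10)
  expect_equal(nrow(tab), n)
  expect_equal(tab$n_missing_cycles, rep(0L, n))
  expect_equal(tab$ch5_cycleB, det0[[2]]$ch5)

  det <- lapply(1:8, function(k) mk(2))
  tab <- track_beads_across_cycles(det, radius = 10)
  expect_equal(tab$n_missing_cycles, rep(0L, n))
  # each later-cycle intensity came from the detection nearest the cycle-A bead
  for (k in 2:8) {
    d <- sqrt(outer(det[[1]]$x, det[[k]]$x, `-`)^2 +
              outer(det[[1]]$y, det[[k]]$y, `-`)^2)
    expect_equal(tab[[paste0("ch5_cycle", LETTERS[k])]],
                 det[[k]]$ch5[apply(d, 1, which.min)])
  }

  # drop bead 5 from cycle C; its intensity reads from the image at the
  # cycle-A position and the bead is flagged
  det[[3]] <- det[[3]][-5, ]
  imgs <- lapply(1:8, function(k) list(ch5 = matrix(7, 150, 150),
                                       ch3 = matrix(3, 150, 150)))
  tab <- track_beads_across_cycles(det, radius = 10, images = imgs)
  expect_equal(tab$n_missing_cycles[5], 1L)
  expect_equal(tab$ch5_cycleC[5], 7)
  expect_equal(tab$ch3_cycleC[5], 3)
  tab2 <- track_beads_across_cycles(det, radius = 10)
  expect_true(is.na(tab2$ch5_cycleC[5]))
})

test_that("multiplet labels follow the two-color object-count rule", {
  grid <- structure(list(
    wells = data.frame(well_id = 1:4,
                       x = c(20, 60, 100, 140), y = rep(20, 4)),
    radius = 12, dim = c(41, 161)
  ), class = "microwell_grid")
  green <- magenta <- matrix(0, 41, 161)
  green <- paint_disk(green, 20, 20, 4, 1)                 # well 1: singlet
  green <- paint_disk(green, 56, 20, 4, 1)                 # well 2: green+magenta
  magenta <- paint_disk(magenta, 64, 20, 4, 1)
  green <- paint_disk(green, 94, 20, 4, 1)                 # well 3: two green
  green <- paint_disk(green, 106, 20, 4, 1)
  res <- identify_multiplets(green, magenta, grid)
  expect_equal(res$label, c("singlet", "mixed_multiplet",
                            "single_multiplet", "empty"))
  # labels partition the non-empty wells
  expect_true(all(res$label %in% c("empty", "singlet", "single_multiplet",
                                   "mixed_multiplet")))
})
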