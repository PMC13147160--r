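# Deformation area, centroids, perimeter/circularity, per-cell records.

test_that("deformation area matches brute-force pixel enumeration", {
  withr::local_seed(101)
  for (rep in 1:25) {
    a <- random_mask(50, 50); b <- random_mask(50, 50)
    brute <- sum(vapply(seq_along(a), function(i) b[i] && !a[i], TRUE))
    expect_identical(deformation_area(a, b), as.numeric(brute))
    # pixel-count identity A_CD(A, B) = |B| - |A intersect B|
    expect_identical(deformation_area(a, b), sum(b) - sum(a & b) + 0)
    expect_identical(deformation_area(a, a), 0)
    expect_gte(deformation_area(a, b), 0)
  }
})

test_that("integer-pixel translation gains exactly what it loses", {
  a <- matrix(FALSE, 20, 20); a[6:15, 3:12] <- TRUE
  b <- matrix(FALSE, 20, 20); b[6:15, 6:15] <- TRUE # 3 px right
  expect_identical(deformation_area(a, b, pixel_size_um = 1), 30)
  expect_identical(deformation_area(a, b, direction = "lost"), 30)
  expect_error(deformation_area(a, matrix(FALSE, 10, 10)), "shapes differ")
})

test_that("centroid follows the pixel-center convention and is linear", {
  one <- matrix(FALSE, 9, 9); one[4, 7] <- TRUE
  expect_equal(mask_centroid(one, 2), c(x_um = 6.5 * 2, y_um = 3.5 * 2))
  d <- make_disk(12, 61, cx = 31, cy = 31)
  cen <- mask_centroid(d, 1)
  expect_lt(abs(cen["x_um"] - 30.5), 0.5)
  expect_lt(abs(cen["y_um"] - 30.5), 0.5)
  # union of two equal disks: midpoint of the individual centroids
  d2 <- make_disk(8, 80, cx = 20, cy = 25) | make_disk(8, 80, cx = 56, cy = 45)
  c1 <- mask_centroid(make_disk(8, 80, cx = 20, cy = 25))
  c2 <- mask_centroid(make_disk(8, 80, cx = 56, cy = 45))
  expect_equal(mask_centroid(d2), (c1 + c2) / 2, tolerance = 1e-12)
  expect_error(mask_centroid(matrix(FALSE, 4, 4)), "empty")
})

test_that("perimeter estimator meets its closed-form tolerances", {
  p_disk <- mask_perimeter(make_disk(50, 120), 1)
  expect_lt(abs(p_disk - 100 * pi) / (100 * pi), 0.03)
  expect_match(attr(p_disk, "estimator"), "subpixel")
  sq10 <- matrix(FALSE, 20, 20); sq10[6:15, 6:15] <- TRUE
  expect_lt(abs(as.numeric(mask_perimeter(sq10)) - 40) / 40, 0.10)
  expect_error(mask_perimeter(matrix(FALSE, 5, 5)), "empty")
  two <- make_disk(5, 60, cx = 15, cy = 15) | make_disk(5, 60, cx = 45, cy = 45)
  expect_error(mask_perimeter(two), "2 components")
})

test_that("perimeter scales linearly under nearest-neighbour upscaling", {
  for (m in list(make_disk(20, 60), {
    sq <- matrix(FALSE, 40, 40); sq[11:30, 11:30] <- TRUE; sq
  })) {
    big <- m[rep(seq_len(nrow(m)), each = 2), rep(seq_len(ncol(m)), each = 2)]
    ratio <- as.numeric(mask_perimeter(big)) / as.numeric(mask_perimeter(m))
    expect_gt(ratio, 1.9)
    expect_lt(ratio, 2.1)
  }
})

test_that("circularity matches continuous-limit values per shape class", {
  expect_lt(abs(circularity_index(make_disk(50, 120)) - 1), 0.06)
  sq <- matrix(FALSE, 120, 120); sq[11:110, 11:110] <- TRUE
  expect_lt(abs(circularity_index(sq) - 4 / pi) / (4 / pi), 0.10)
  rect <- matrix(FALSE, 80, 130); rect[11:60, 11:110] <- TRUE
  expect_lt(abs(circularity_index(rect) - 9 / (2 * pi)) / (9 / (2 * pi)), 0.10)
})

test_that("circularity is invariant to the pixel size", {
  m <- make_disk(25, 70)
  expect_equal(circularity_index(m, 0.25), circularity_index(m, 1),
               tolerance = 1e-12)
})

test_that("rasterized generator circles keep circularity in [1, 1.10]", {
  for (radius_um in c(5, 7.5)) { # 20 and 30 px at 0.25 um/px
    cfg <- motility_sim_config(n_cells = 1, n_frames = 3,
                               protrusion_amplitude = 0,
                               mean_speed_um_per_min = 1,
                               base_radius_um = radius_um,
                               field_size_px = c(160, 160), seed = 29)
    mv <- rasterize_movie(cfg)
    for (fr in mv$frames) {
      ci <- circularity_index(fr == 1L, cfg$pixel_size_um)
      expect_gte(ci, 1.0)
      expect_lte(ci, 1.10)
    }
  }
})

test_that("centroid displacement uses non-overlapping 3-min boundaries", {
  frames <- translating_track_frames(n_frames = 60, dx = 1, N = 100,
                                     interval_s = 20)
  # dx=1 px/frame would exit; rebuild translating slowly within the field
  frames <- lapply(seq_len(60), function(t) {
    m <- matrix(0L, 100, 100)
    c0 <- 10 + ((t - 1) %/% 9) # 1 px step per 9 frames
    m[40:47, c0:(c0 + 7)] <- 1L
    mask_frame(m, t - 1L, 20, 1)
  })
  tracks <- build_tracks(frames)
  disp <- centroid_displacement(tracks[[1]], interval_s = 180)
  expect_identical(nrow(disp), 6L)
  expect_identical(disp$frame_from, c(0L, 9L, 18L, 27L, 36L, 45L))
  expect_identical(disp$frame_to, c(9L, 18L, 27L, 36L, 45L, 54L))
  expect_equal(disp$displacement_um, rep(1, 6), tolerance = 1e-12)
  expect_error(centroid_displacement(tracks[[1]], interval_s = 170),
               "not divisible")
})

test_that("a ballistic cell covers speed times interval per pair", {
  # 1 um/min at 1 um/px, 20-s frames: 1 px per 3 frames; use 3 px / 9 frames
  frames <- lapply(seq_len(30), function(t) {
    m <- matrix(0L, 80, 80)
    c0 <- 10 + (t - 1) # 1 px per frame = 3 um/min
    m[30:37, c0:(c0 + 7)] <- 1L
    mask_frame(m, t - 1L, 20, 1)
  })
  tracks <- build_tracks(frames)
  disp <- centroid_displacement(tracks[[1]], 180)
  expect_equal(disp$displacement_um, rep(9, nrow(disp)), tolerance = 1e-12)
})

test_that("stationary cells report zero displacement and zero deformation", {
  frames <- lapply(seq_len(12), function(t) {
    m <- matrix(0L, 40, 40); m[15:22, 15:22] <- 1L
    mask_frame(m, t - 1L, 20, 1)
  })
  tr <- filter_tracks(build_tracks(frames))[[1]]
  rec <- compute_motility(tr, interval_s = 60)
  expect_true(all(rec$pairs$displacement_um == 0))
  expect_true(all(rec$pairs$acd_um2 == 0))
})

test_that("motility record is internally consistent and translation-symmetric", {
  frames <- lapply(seq_len(20), function(t) {
    m <- matrix(0L, 70, 70)
    c0 <- 8 + 2 * (t - 1)
    m[30:37, c0:(c0 + 7)] <- 1L
    mask_frame(m, t - 1L, 20, 1)
  })
  tr <- filter_tracks(build_tracks(frames))[[1]]
  rec <- compute_motility(tr, interval_s = 180)
  # rigid translation: area gained equals area lost at every pair
  expect_equal(rec$pairs$acd_um2, rec$pairs$area_lost_um2)
  expect_equal(rec$summaries$mean_acd_um2, mean(rec$pairs$acd_um2))
  expect_equal(rec$summaries$mean_displacement_um,
               mean(rec$pairs$displacement_um))
  expect_equal(rec$summaries$mean_circularity,
               mean(rec$circularity$circularity))
  expect_identical(rec$summaries$n_pairs, nrow(rec$pairs))
  tab <- motility_summary_table(list(rec))
  expect_identical(tab$mean_acd_um2, rec$summaries$mean_acd_um2)
})

test_that("tracks that failed inclusion are refused unless overridden", {
  frames <- lapply(seq_len(12), function(t) {
    m <- matrix(0L, 30, 30); m[1:6, 10:15] <- 1L # touches the border
    mask_frame(m, t - 1L, 20, 1)
  })
  tr <- filter_tracks(build_tracks(frames))[[1]]
  expect_false(tr$included)
  expect_error(compute_motility(tr, interval_s = 60), "inclusion")
  rec <- compute_motility(tr, interval_s = 60, require_included = FALSE)
  expect_s3_class(rec, "motility_record")
})

test_that("programmed speed and protrusion drive the matching metrics", {
  run_cohort <- function(speed, ampl, seed) {
    cfg <- motility_sim_config(n_cells = 6, n_frames = 28,
                               frame_interval_s = 20,
                               mean_speed_um_per_min = speed,
                               persistence = 0.5,
                               protrusion_amplitude = ampl,
                               field_size_px = c(420, 420), seed = seed)
    mv <- rasterize_movie(cfg)
    frames <- lapply(seq_along(mv$frames), function(k)
      mask_frame(mv$frames[[k]], k - 1L, 20, 0.25))
    tracks <- Filter(function(tr) isTRUE(tr$included),
                     filter_tracks(build_tracks(frames)))
    recs <- lapply(tracks, compute_motility, interval_s = 180)
    motility_summary_table(recs)
  }
  slow <- run_cohort(0.4, 0.15, 61)
  fast <- run_cohort(2.0, 0.15, 61)
  expect_gt(mean(fast$mean_displacement_um), mean(slow$mean_displacement_um))
  calm <- run_cohort(1, 0.1, 67)
  wild <- suppressWarnings(run_cohort(1, 0.4, 67))
  expect_gt(mean(wild$mean_acd_um2), mean(calm$mean_acd_um2))
})
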