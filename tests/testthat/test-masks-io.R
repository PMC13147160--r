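# Mask-stack I/O, segmentation, component labeling, tracking, inclusion.

test_that("mask stacks round-trip through TIFF + sidecar bit-identically", {
  cfg <- motility_sim_config(n_cells = 2, n_frames = 60, frame_interval_s = 20,
                             protrusion_amplitude = 0.15,
                             field_size_px = c(220, 220), seed = 31)
  mv <- rasterize_movie(cfg)
  path <- file.path(withr::local_tempdir(), "movie.tif")
  write_mask_stack(mv, path)
  frames <- read_mask_stack(path)
  expect_length(frames, 60L)
  expect_identical(frames[[60]]$time_s, 59 * 20)
  for (t in c(1, 30, 60))
    expect_identical(frames[[t]]$pixels, mv$frames[[t]])
  expect_identical(frames[[1]]$pixel_size_um, cfg$pixel_size_um)
})

test_that("stack reading enforces page count and sidecar completeness", {
  d <- withr::local_tempdir()
  one <- file.path(d, "one.tif")
  tiff::writeTIFF(list(matrix(0, 8, 8)), one, bits.per.sample = 16L)
  jsonlite::write_json(list(frame_interval_s = 20, pixel_size_um = 0.25),
                       paste0(one, ".json"), auto_unbox = TRUE)
  expect_error(read_mask_stack(one), ">= 2 pages")
  two <- file.path(d, "two.tif")
  tiff::writeTIFF(list(matrix(0, 8, 8), matrix(0, 8, 8)), two,
                  bits.per.sample = 16L)
  jsonlite::write_json(list(pixel_size_um = 0.25), paste0(two, ".json"),
                       auto_unbox = TRUE)
  expect_error(read_mask_stack(two), "frame_interval_s")
  expect_error(read_mask_stack(file.path(d, "absent.tif")), "not found")
})

test_that("component labeling distinguishes 4- and 8-connectivity", {
  m <- matrix(FALSE, 5, 5)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE
  expect_identical(max(label_components(m, 8L)), 1L)
  expect_identical(max(label_components(m, 4L)), 2L)
  expect_identical(max(label_components(matrix(FALSE, 3, 3))), 0L)
})

test_that("otsu segmentation recovers a synthetic disk", {
  truth <- make_disk(15, 80)
  gray <- ifelse(truth, 0.8, 0.1) + 0.01 * matrix(sin(1:6400), 80, 80)
  seg <- segment_frame(gray)
  expect_lt(abs(sum(seg) - sum(truth)) / sum(truth), 0.05)
  # all-zero frame: empty mask with a warning, not an error
  expect_warning(empty <- segment_frame(matrix(0, 20, 20)), "blank")
  expect_false(any(empty))
  # two disks: two 8-connected components; specks below 20 px removed
  g2 <- matrix(0.05, 90, 90)
  g2[make_disk(10, 90, cx = 25, cy = 25)] <- 0.9
  g2[make_disk(10, 90, cx = 65, cy = 65)] <- 0.9
  g2[2, 2] <- 0.9 # a 1-px speck
  seg2 <- segment_frame(g2)
  expect_identical(max(label_components(seg2)), 2L)
})

test_that("a translating cell yields one full-length track", {
  frames <- translating_track_frames(n_frames = 12, dx = 2)
  tracks <- build_tracks(frames)
  expect_length(tracks, 1L)
  expect_identical(tracks[[1]]$frames, 0:11)
})

test_that("a cell that disappears ends its track at the last seen frame", {
  frames <- translating_track_frames(n_frames = 12, dx = 2)
  for (t in 9:12) frames[[t]]$pixels[] <- 0L # vanishes at frame 8
  tracks <- build_tracks(frames)
  expect_length(tracks, 1L)
  expect_identical(tracks[[1]]$frames, 0:7)
})

test_that("overlap linking preserves identity for two passing cells", {
  # two squares crossing in x while vertically separated by a 4-px gap
  N <- 80; nf <- 15
  frames <- lapply(seq_len(nf), function(t) {
    m <- matrix(0L, N, N)
    ca <- 5 + (t - 1) * 4        # cell 1 moves right
    cb <- 61 - (t - 1) * 4       # cell 2 moves left
    m[20:27, ca:(ca + 7)] <- 1L
    m[39:46, cb:(cb + 7)] <- 2L
    mask_frame(m, t - 1L, 20, 1)
  })
  tracks <- build_tracks(frames)
  expect_length(tracks, 2L)
  for (tr in tracks) {
    expect_identical(tr$frames, 0:(nf - 1L))
    # identity: each track's mask must coincide with one generator label
    truth_label <- frames[[1]]$pixels[tr$pixels[[1]][1]]
    for (k in c(1, 8, nf)) {
      truth <- which(frames[[k]]$pixels == truth_label)
      inter <- length(intersect(tr$pixels[[k]], truth))
      iou <- inter / length(union(tr$pixels[[k]], truth))
      expect_gt(iou, 0.5)
      expect_identical(sort(tr$pixels[[k]]), sort(truth))
    }
  }
})

test_that("track masks partition the foreground in every frame", {
  cfg <- motility_sim_config(n_cells = 4, n_frames = 8,
                             protrusion_amplitude = 0.2,
                             mean_speed_um_per_min = 2,
                             field_size_px = c(280, 280), seed = 41)
  mv <- rasterize_movie(cfg)
  frames <- lapply(seq_along(mv$frames), function(k)
    mask_frame(mv$frames[[k]], k - 1L, 20, 0.25))
  tracks <- build_tracks(frames)
  for (t in seq_len(8)) {
    pix <- unlist(lapply(tracks, function(tr) {
      pos <- match(t - 1L, tr$frames)
      if (is.na(pos)) integer(0) else tr$pixels[[pos]]
    }))
    expect_false(anyDuplicated(pix) > 0)
    expect_identical(sort(pix), sort(which(mv$frames[[t]] != 0L)))
  }
})

test_that("inclusion criteria flag border contact, truncation and proximity", {
  N <- 60; nf <- 10
  frames <- lapply(seq_len(nf), function(t) {
    m <- matrix(0L, N, N)
    m[10:17, 10:17] <- 1L                       # well-behaved cell
    if (t <= 8) m[30:37, (2 + 4 * (t - 1)):(9 + 4 * (t - 1))] <- 2L # exits
    m[50:57, 20:27] <- 3L
    m[50:57, 29:36] <- 4L                       # 1-px gap to cell 3
    mask_frame(m, t - 1L, 20, 1)
  })
  tracks <- filter_tracks(build_tracks(frames))
  flags <- do.call(rbind, lapply(tracks, function(tr) tr$flags))
  included <- vapply(tracks, function(tr) tr$included, TRUE)
  expect_identical(sum(included), 1L)
  # the exiting cell fails full duration (it leaves through the border too)
  exiting <- which(!flags[, "full_duration"])
  expect_length(exiting, 1L)
  # the close pair both fail the non-overlap criterion
  expect_identical(sum(!flags[, "non_overlapping"]), 2L)
})

test_that("filtering is idempotent and order-independent", {
  frames <- translating_track_frames(n_frames = 10, dx = 1)
  frames <- lapply(seq_along(frames), function(t) {
    m <- frames[[t]]$pixels
    m[40:47, 40:47] <- 2L
    mask_frame(m, t - 1L, 20, 1)
  })
  tracks <- build_tracks(frames)
  f1 <- filter_tracks(tracks)
  f2 <- filter_tracks(f1)
  expect_identical(lapply(f1, `[[`, "flags"), lapply(f2, `[[`, "flags"))
  frev <- filter_tracks(rev(tracks))
  ids <- vapply(frev, function(tr) tr$cell_id, 1L)
  expect_identical(lapply(frev[order(ids)], `[[`, "flags"),
                   lapply(f1, `[[`, "flags"))
})

test_that("generator cohorts pass all inclusion criteria by construction", {
  cfg <- motility_sim_config(n_cells = 4, n_frames = 10,
                             protrusion_amplitude = 0.2,
                             mean_speed_um_per_min = 1.5,
                             field_size_px = c(300, 300), seed = 43)
  mv <- rasterize_movie(cfg)
  frames <- lapply(seq_along(mv$frames), function(k)
    mask_frame(mv$frames[[k]], k - 1L, 20, 0.25))
  tracks <- filter_tracks(build_tracks(frames))
  expect_true(all(vapply(tracks, function(tr) tr$included, TRUE)))
  rep <- inclusion_report(tracks)
  expect_true(all(rep$pass))
  expect_identical(nrow(rep), 4L * 3L)
})
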