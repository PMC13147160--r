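# Mask-stack I/O, segmentation of synthetic grayscale frames, 8-connected
# component labeling, overlap-based track building and the cell-inclusion
# criteria (full duration, in field, non-overlapping).

#' Construct a single mask frame
#'
#' @param pixels integer label matrix or logical matrix (row, col raster;
#'   origin top-left).
#' @param frame_index 0-based frame index.
#' @param frame_interval_s frame interval, seconds; `time_s` is
#'   `frame_index * frame_interval_s`.
#' @param pixel_size_um pixel size, um/px.
#' @return an object of class `mask_frame`.
#' @export
mask_frame <- function(pixels, frame_index, frame_interval_s, pixel_size_um) {
  if (!is.matrix(pixels)) stopf("'pixels' must be a 2-D matrix")
  if (any(pixels < 0)) stopf("labels must be non-negative integers")
  structure(list(frame_index = as.integer(frame_index),
                 time_s = as.numeric(frame_index) * as.numeric(frame_interval_s),
                 pixels = pixels,
                 pixel_size_um = pixel_size_um),
            class = "mask_frame")
}

#' Write a labeled mask stack as multi-page TIFF plus JSON sidecar
#'
#' Pages are stored as 16-bit grayscale; labels must lie in 0..65535.
#' The sidecar records `frame_interval_s`, `pixel_size_um` and the label
#' values present, and is what [read_mask_stack()] needs to restore timing
#' and scale metadata.
#'
#' @param frames list of integer label matrices (or a [rasterize_movie()]
#'   result, whose `frames` element is used).
#' @param path output TIFF path.
#' @param frame_interval_s,pixel_size_um acquisition metadata; taken from
#'   the movie's config when `frames` is a `rasterize_movie()` result.
#' @param sidecar_path JSON sidecar path; default `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_mask_stack <- function(frames, path, frame_interval_s = NULL,
                             pixel_size_um = NULL,
                             sidecar_path = paste0(path, ".json")) {
  if (is.list(frames) && !is.null(frames$frames)) {
    frame_interval_s <- frame_interval_s %||% frames$config$frame_interval_s
    pixel_size_um <- pixel_size_um %||% frames$config$pixel_size_um
    frames <- frames$frames
  }
  if (is.null(frame_interval_s) || is.null(pixel_size_um))
    stopf("frame_interval_s and pixel_size_um are required")
  mx <- max(vapply(frames, max, 1))
  if (mx > 65535) stopf("labels exceed the 16-bit range")
  tiff::writeTIFF(lapply(frames, function(m) m / 65535), path,
                  bits.per.sample = 16L, compression = "none")
  labels <- sort(unique(unlist(lapply(frames, function(m)
    unique(as.vector(m[m != 0]))))))
  jsonlite::write_json(
    list(frame_interval_s = frame_interval_s,
         pixel_size_um = pixel_size_um, labels = labels),
    sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a multi-page TIFF mask stack
#'
#' @param path TIFF path (>= 2 pages).
#' @param sidecar path to the JSON sidecar, or a list already holding the
#'   fields `frame_interval_s` and `pixel_size_um`.
#' @return a list of [mask_frame()] objects, ordered by page; integer label
#'   values are preserved exactly.
#' @export
read_mask_stack <- function(path, sidecar = paste0(path, ".json")) {
  if (!file.exists(path)) stopf("mask stack not found: %s", path)
  if (is.character(sidecar)) {
    if (!file.exists(sidecar)) stopf("sidecar not found: %s", sidecar)
    sidecar <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  }
  missing <- setdiff(c("frame_interval_s", "pixel_size_um"), names(sidecar))
  if (length(missing))
    stopf("sidecar is missing required field(s): %s",
          paste(missing, collapse = ", "))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2L)
    stopf("mask stack must have >= 2 pages, found %d", length(pages))
  bad <- which(vapply(pages, function(p) length(dim(p)) != 2L, TRUE))
  if (length(bad))
    stopf("non-2-D page(s): %s", paste(bad, collapse = ", "))
  lapply(seq_along(pages), function(i)
    mask_frame(pages[[i]], i - 1L, sidecar$frame_interval_s,
               sidecar$pixel_size_um))
}

#' Label connected components of a binary mask
#'
#' Components are defined under 8-connectivity by default (diagonal
#' neighbors touch). Labels are assigned in raster-scan order of each
#' component's first pixel, so labeling is deterministic.
#'
#' @param mask logical or 0/1 matrix.
#' @param connectivity 8 (default) or 4.
#' @return an integer matrix of labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 8L) {
  mask <- as_mask(mask)
  if (!connectivity %in% c(4L, 8L)) stopf("connectivity must be 4 or 8")
  H <- nrow(mask); W <- ncol(mask)
  idx <- which(mask)
  out <- matrix(0L, H, W)
  if (!length(idx)) return(out)
  id_of <- integer(H * W)
  id_of[idx] <- seq_along(idx)
  r0 <- ((idx - 1L) %% H) + 1L
  c0 <- ((idx - 1L) %/% H) + 1L
  offs <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8L) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  edges <- lapply(offs, function(o) {
    rr <- r0 + o[1]; cc <- c0 + o[2]
    ok <- rr >= 1L & rr <= H & cc <= W
    nb <- rr[ok] + (cc[ok] - 1L) * H
    hit <- mask[nb]
    cbind(id_of[idx[ok][hit]], id_of[nb[hit]])
  })
  edges <- do.call(rbind, edges)
  g <- igraph::make_graph(as.integer(t(edges)), n = length(idx),
                          directed = FALSE)
  memb <- igraph::components(g)$membership
  first <- vapply(split(seq_along(idx), memb), min, 1L)
  relabel <- integer(length(first))
  relabel[order(first)] <- seq_along(first)
  out[idx] <- relabel[memb]
  out
}

#' Segment a grayscale frame into a binary cell mask
#'
#' Otsu global threshold, hole filling, and removal of objects smaller than
#' `min_size_px` pixels (8-connectivity). Stands in for interactive contour
#' selection when the input is synthetic grayscale rather than masks.
#'
#' @param gray single-channel numeric matrix; values are rescaled to [0, 1]
#'   by the maximum when needed.
#' @param method thresholding method; only `"otsu"` is implemented.
#' @param min_size_px minimum object size retained, px.
#' @return a logical matrix (TRUE = cell).
#' @export
segment_frame <- function(gray, method = "otsu", min_size_px = 20L) {
  if (!is.matrix(gray) || !is.numeric(gray))
    stopf("'gray' must be a single-channel numeric matrix")
  method <- match.arg(method, "otsu")
  if (max(gray) <= 0) {
    warnf("blank frame: returning an empty mask")
    return(matrix(FALSE, nrow(gray), ncol(gray)))
  }
  g <- gray / max(gray)
  thr <- EBImage::otsu(EBImage::Image(g))
  bin <- g > thr
  if (!any(bin)) {
    warnf("no foreground above the Otsu threshold: returning an empty mask")
    return(bin)
  }
  filled <- EBImage::imageData(EBImage::fillHull(EBImage::Image(bin * 1))) > 0
  lab <- label_components(filled)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_size_px)
  filled & (lab %in% keep) & lab > 0L
}

# component pixel lists + centroids (px) of one labeled frame
frame_components <- function(lab) {
  fg <- which(lab > 0L)
  if (!length(fg)) return(list())
  by_lab <- split(fg, lab[fg])
  H <- nrow(lab)
  lapply(by_lab, function(ix) {
    r <- ((ix - 1L) %% H) + 1L
    c <- ((ix - 1L) %/% H) + 1L
    list(pixels = ix, size = length(ix),
         centroid = c(mean(c) - 0.5, mean(r) - 0.5)) # (x, y) px
  })
}

#' Build cell tracks by maximal mask overlap across frames
#'
#' Per-frame 8-connected components are linked frame-to-frame by maximal
#' intersection-over-union (IoU); ties are broken by smaller centroid
#' distance, then smaller component label. Components with no overlapping
#' predecessor start new tracks; a track whose component finds no successor
#' ends (tracks cover one contiguous frame range).
#'
#' @param frames list of [mask_frame()] objects (>= 2), binary or labeled;
#'   labels are re-derived from connectivity so touching cells merge into
#'   one component (and are later excluded by [filter_tracks()]).
#' @return a list of `cell_track` objects, ordered by cell id (assignment
#'   order).
#' @export
build_tracks <- function(frames) {
  if (length(frames) < 2L) stopf("need >= 2 frames to build tracks")
  stopifnot(all(vapply(frames, inherits, TRUE, "mask_frame")))
  nf <- length(frames)
  dim_px <- dim(frames[[1]]$pixels)
  s <- frames[[1]]$pixel_size_um
  fi <- frames[[2]]$time_s - frames[[1]]$time_s
  comps <- lapply(frames, function(f)
    frame_components(label_components(f$pixels != 0)))

  tracks <- list()          # finished + active
  active <- integer(0)      # indices into tracks, aligned with comp ids below
  active_comp <- integer(0) # component index (within frame) per active track

  new_track <- function(comp_i, t) {
    list(cell_id = length(tracks) + 1L, start_frame = t - 1L,
         pixels = list(comps[[t]][[comp_i]]$pixels))
  }
  for (ci in seq_along(comps[[1]])) tracks[[ci]] <- new_track(ci, 1L)
  active <- seq_along(comps[[1]])
  active_comp <- seq_along(comps[[1]])

  for (t in seq_len(nf - 1L)) {
    cur <- comps[[t]]; nxt <- comps[[t + 1L]]
    # candidate links between overlapping components
    cand <- NULL
    if (length(cur) && length(nxt)) {
      nxt_lab <- matrix(0L, dim_px[1], dim_px[2])
      for (j in seq_along(nxt)) nxt_lab[nxt[[j]]$pixels] <- j
      rows <- list()
      for (i in seq_along(cur)) {
        hits <- nxt_lab[cur[[i]]$pixels]
        hits <- hits[hits > 0L]
        if (!length(hits)) next
        tb <- table(hits)
        for (k in seq_along(tb)) {
          j <- as.integer(names(tb)[k]); inter <- as.integer(tb[k])
          iou <- inter / (cur[[i]]$size + nxt[[j]]$size - inter)
          dc <- sqrt(sum((cur[[i]]$centroid - nxt[[j]]$centroid)^2))
          rows[[length(rows) + 1L]] <- c(i, j, iou, dc)
        }
      }
      if (length(rows)) cand <- do.call(rbind, rows)
    }
    matched_cur <- integer(0); matched_nxt <- integer(0)
    link <- integer(length(cur)) # cur comp -> nxt comp (0 = none)
    if (!is.null(cand)) {
      ord <- order(-cand[, 3], cand[, 4], cand[, 1], cand[, 2])
      for (r in ord) {
        i <- cand[r, 1]; j <- cand[r, 2]
        if (i %in% matched_cur || j %in% matched_nxt) next
        link[i] <- j
        matched_cur <- c(matched_cur, i); matched_nxt <- c(matched_nxt, j)
      }
    }
    new_active <- integer(0); new_active_comp <- integer(0)
    for (a in seq_along(active)) {
      j <- link[active_comp[a]]
      if (j > 0L) {
        ti <- active[a]
        tracks[[ti]]$pixels[[length(tracks[[ti]]$pixels) + 1L]] <-
          nxt[[j]]$pixels
        new_active <- c(new_active, ti)
        new_active_comp <- c(new_active_comp, j)
      }
    }
    for (j in seq_along(nxt)) {
      if (!(j %in% matched_nxt)) {
        tracks[[length(tracks) + 1L]] <- new_track(j, t + 1L)
        new_active <- c(new_active, length(tracks))
        new_active_comp <- c(new_active_comp, j)
      }
    }
    active <- new_active; active_comp <- new_active_comp
  }

  lapply(tracks, function(tr) {
    structure(list(
      cell_id = tr$cell_id, start_frame = tr$start_frame,
      frames = tr$start_frame + seq_along(tr$pixels) - 1L,
      pixels = tr$pixels, dim = dim_px, pixel_size_um = s,
      frame_interval_s = fi, n_frames_total = nf,
      flags = NULL, included = NA),
      class = "cell_track")
  })
}

#' Reconstruct a track's binary mask at one covered frame
#'
#' @param track a `cell_track`.
#' @param frame 0-based frame index (must be covered by the track).
#' @return a logical matrix of the full field.
#' @export
track_mask <- function(track, frame) {
  pos <- match(frame, track$frames)
  if (is.na(pos))
    stopf("track %d does not cover frame %d", track$cell_id, frame)
  m <- matrix(FALSE, track$dim[1], track$dim[2])
  m[track$pixels[[pos]]] <- TRUE
  m
}

#' Apply the cell-inclusion criteria to built tracks
#'
#' A track is included iff it (a) is present in every frame of the
#' recording, (b) never touches the raster border, and (c) never comes
#' within `min_gap_px` pixels (Chebyshev distance) of another cell's mask.
#' Excluded tracks keep their per-criterion flags for reporting; the
#' operation is idempotent and independent of track order.
#'
#' @param tracks list of `cell_track` objects from [build_tracks()].
#' @param min_gap_px minimum allowed pixel gap to any other cell.
#' @return the tracks, each with `flags` (named logical: `full_duration`,
#'   `in_field`, `non_overlapping`) and `included` filled in.
#' @export
filter_tracks <- function(tracks, min_gap_px = 2L) {
  if (!length(tracks)) return(tracks)
  dim_px <- tracks[[1]]$dim
  nf <- tracks[[1]]$n_frames_total
  border <- c(1L, dim_px[1])
  # per-frame union of each other's pixels, computed once
  frame_union <- vector("list", nf)
  for (tr in tracks) for (k in seq_along(tr$frames)) {
    f <- tr$frames[k] + 1L
    frame_union[[f]] <- c(frame_union[[f]], tr$pixels[[k]])
  }
  lapply(tracks, function(tr) {
    full_duration <- tr$start_frame == 0L && length(tr$frames) == nf
    in_field <- TRUE; non_overlapping <- TRUE
    for (k in seq_along(tr$frames)) {
      ix <- tr$pixels[[k]]
      r <- ((ix - 1L) %% dim_px[1]) + 1L
      c <- ((ix - 1L) %/% dim_px[1]) + 1L
      if (any(r == 1L | r == dim_px[1] | c == 1L | c == dim_px[2]))
        in_field <- FALSE
      if (non_overlapping) {
        others <- setdiff(frame_union[[tr$frames[k] + 1L]], ix)
        if (length(others)) {
          guard <- dilate_indices(ix, dim_px, as.integer(min_gap_px))
          if (any(guard %in% others)) non_overlapping <- FALSE
        }
      }
    }
    tr$flags <- c(full_duration = full_duration, in_field = in_field,
                  non_overlapping = non_overlapping)
    tr$included <- all(tr$flags)
    tr
  })
}

#' Per-track inclusion report
#'
#' @param tracks tracks processed by [filter_tracks()].
#' @return a long data.frame `cell_id, criterion, pass`.
#' @export
inclusion_report <- function(tracks) {
  do.call(rbind, lapply(tracks, function(tr) {
    if (is.null(tr$flags)) stopf("run filter_tracks() first")
    data.frame(cell_id = tr$cell_id, criterion = names(tr$flags),
               pass = unname(tr$flags), row.names = NULL)
  }))
}
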