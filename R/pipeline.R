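# End-to-end orchestration: simulate -> rasterize -> track -> filter ->
# per-cell metrics -> cohort comparisons, with a JSON manifest recording
# every configurable analysis decision.

#' Acquisition schedule summary
#'
#' Reports the total imaging time and the number of complete
#' metric-interval pairs a recording supports. Total time is reported under
#' both conventions: `n_frames * interval` (the counting convention under
#' which 60 frames at 20 s span 20 min) and `(n_frames - 1) * interval`
#' (first-to-last span). Metric pairs are non-overlapping boundary pairs
#' (frames 0, 9, 18, ... for 20-s frames and the default 3-min interval);
#' 60 frames yield 6 complete pairs with 5 trailing frames unused.
#'
#' @param n_frames number of frames (>= 2).
#' @param interval_s frame interval, seconds (> 0).
#' @param metric_interval_s metric interval, seconds (default 180). When it
#'   is not a multiple of `interval_s`, a warning is raised and pairs are
#'   spaced `floor(metric_interval_s / interval_s)` frames apart.
#' @return a list: `n_frames`, `interval_s`, `total_time_min`
#'   (`n_frames * interval / 60`), `total_span_min`
#'   (`(n_frames - 1) * interval / 60`), `frames_per_pair`,
#'   `pair_interval_s`, `n_pairs`, `unused_trailing_frames`.
#' @export
#' @examples
#' validate_acquisition(60, 20) # 20 min, 6 pairs, 5 trailing frames
validate_acquisition <- function(n_frames, interval_s,
                                 metric_interval_s = 180) {
  assert_scalar_number(n_frames, "n_frames", min = 2)
  assert_scalar_number(interval_s, "interval_s", min = 0, strict_min = TRUE)
  step <- metric_interval_s / interval_s
  if (abs(step - round(step)) > 1e-9) {
    step <- max(1, floor(step))
    warnf(paste("metric interval %g s is not a multiple of the frame",
                "interval %g s; pairs spaced %d frames (%g s) apart"),
          metric_interval_s, interval_s, as.integer(step), step * interval_s)
  } else {
    step <- as.integer(round(step))
  }
  n_pairs <- length(interval_pairs(as.integer(n_frames), step))
  if (n_pairs == 0L)
    warnf("recording too short for even one %g-s pair", metric_interval_s)
  list(n_frames = as.integer(n_frames), interval_s = interval_s,
       total_time_min = n_frames * interval_s / 60,
       total_span_min = (n_frames - 1) * interval_s / 60,
       frames_per_pair = as.integer(step),
       pair_interval_s = step * interval_s,
       n_pairs = n_pairs,
       unused_trailing_frames = as.integer(n_frames - (n_pairs * step + 1L)))
}

#' Run the full synthetic motility pipeline over named conditions
#'
#' For every condition: simulate an amoeboid cohort, rasterize it into a
#' labeled mask movie, rebuild tracks from the masks by overlap linking,
#' apply the inclusion criteria, and compute per-cell motility records.
#' Requested condition pairs are then compared per metric with Welch's
#' t-test and fold changes. All randomness derives from `seed` (condition
#' `i` gets child seed `child_seed(seed, i, 4)`), so repeated runs are
#' bit-identical.
#'
#' @param conditions named list; each element a list of
#'   [motility_sim_config()] arguments (without `seed`), or a ready config.
#' @param seed integer root seed.
#' @param interval_s metric interval, seconds.
#' @param min_gap_px inclusion gap threshold, px (see [filter_tracks()]).
#' @param comparisons list of 2-element character vectors
#'   `c(reference, test)` naming conditions to compare; default none.
#' @param out_dir optional output directory; when given, per-cell and
#'   per-pair CSVs, the inclusion report, comparison tables and a JSON run
#'   manifest are written there.
#' @param write_movies also write each condition's mask movie as TIFF +
#'   sidecar under `out_dir` (requires `out_dir`).
#' @return a list with `cells` (per-cell summary data.frame across
#'   conditions), `pairs` (long per-pair table), `inclusion` (per-track
#'   criterion report), `comparisons` (per-metric Welch/fold table or
#'   NULL), `manifest` (the manifest list).
#' @export
run_motility_pipeline <- function(conditions, seed = 1L, interval_s = 180,
                                  min_gap_px = 2L, comparisons = NULL,
                                  out_dir = NULL, write_movies = FALSE) {
  if (is.null(names(conditions)) || any(names(conditions) == ""))
    stopf("'conditions' must be a named list")
  if (write_movies && is.null(out_dir))
    stopf("write_movies = TRUE requires out_dir")
  warnings_log <- character(0)
  collect <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  })

  cells <- list(); pairs <- list(); incl <- list()
  for (i in seq_along(conditions)) {
    cname <- names(conditions)[i]
    cond_args <- conditions[[i]]
    cfg <- if (inherits(cond_args, "motility_sim_config")) cond_args else
      do.call(motility_sim_config,
              c(cond_args, list(seed = child_seed(seed, i, 4L))))
    movie <- collect(rasterize_movie(cfg, min_gap_px = min_gap_px + 1L))
    frames <- lapply(seq_along(movie$frames), function(k)
      mask_frame(movie$frames[[k]], k - 1L, cfg$frame_interval_s,
                 cfg$pixel_size_um))
    tracks <- filter_tracks(build_tracks(frames), min_gap_px = min_gap_px)
    rep_i <- inclusion_report(tracks)
    rep_i$condition <- cname
    incl[[cname]] <- rep_i
    ok <- Filter(function(tr) isTRUE(tr$included), tracks)
    if (!length(ok)) {
      breakdown <- stats::aggregate(pass ~ criterion, rep_i, sum)
      stopf("condition '%s': zero included cells (passes by criterion: %s)",
            cname, paste(sprintf("%s=%d", breakdown$criterion,
                                 breakdown$pass), collapse = ", "))
    }
    records <- collect(lapply(ok, compute_motility,
                              interval_s = interval_s))
    tab <- motility_summary_table(records)
    tab$condition <- cname
    cells[[cname]] <- tab
    pr <- do.call(rbind, lapply(records, function(r)
      cbind(cell_id = r$cell_id, r$pairs)))
    pr$condition <- cname
    pairs[[cname]] <- pr
    if (write_movies)
      write_mask_stack(movie, file.path(out_dir,
                                        paste0("movie_", cname, ".tif")))
  }
  cells <- do.call(rbind, cells); rownames(cells) <- NULL
  pairs <- do.call(rbind, pairs); rownames(pairs) <- NULL
  incl <- do.call(rbind, incl); rownames(incl) <- NULL

  cmp <- NULL
  if (length(comparisons)) {
    metrics <- c("mean_acd_um2", "mean_displacement_um", "mean_circularity")
    cmp <- do.call(rbind, lapply(comparisons, function(pr2) {
      ref <- pr2[1]; tst <- pr2[2]
      do.call(rbind, lapply(metrics, function(mt) {
        va <- cells[cells$condition == ref, mt]
        vb <- cells[cells$condition == tst, mt]
        w <- collect(welch_t_test(va, vb))
        data.frame(reference = ref, test = tst, metric = mt,
                   n_ref = length(va), mean_ref = mean(va), sd_ref = sd(va),
                   n_test = length(vb), mean_test = mean(vb),
                   sd_test = sd(vb), t_statistic = w$t_statistic,
                   welch_df = w$welch_df, p_value = w$p_value,
                   stars = w$stars, fold_change = w$fold_change)
      }))
    }))
    rownames(cmp) <- NULL
  }

  manifest <- list(
    package = "coldmotility",
    version = as.character(utils::packageVersion("coldmotility")),
    r_version = as.character(getRversion()),
    seed = seed, interval_s = interval_s, min_gap_px = min_gap_px,
    perimeter_estimator = PERIMETER_ESTIMATOR,
    flux_level_rule = "protocol",
    conditions = lapply(seq_along(conditions), function(i) {
      sub <- cells[cells$condition == names(conditions)[i], ]
      list(name = names(conditions)[i], n_included = nrow(sub))
    }),
    units = "um",
    warnings = warnings_log)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(cells, file.path(out_dir, "cells.csv"), row.names = FALSE)
    write.csv(pairs, file.path(out_dir, "pairs.csv"), row.names = FALSE)
    write.csv(incl, file.path(out_dir, "inclusion.csv"), row.names = FALSE)
    if (!is.null(cmp))
      write.csv(cmp, file.path(out_dir, "comparisons.csv"),
                row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(cells = cells, pairs = pairs, inclusion = incl, comparisons = cmp,
       manifest = manifest)
}
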