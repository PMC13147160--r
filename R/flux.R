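# Mitochondrial respiration parameters from phase-labeled OCR traces
# (mito stress test: basal -> oligomycin -> FCCP -> rotenone/antimycin A),
# with protein normalization and per-condition grouping.

validate_flux_trace <- function(trace) {
  need <- c("well", "cycle", "phase", "time_min", "ocr")
  missing <- setdiff(need, names(trace))
  if (length(missing))
    stopf("flux trace is missing column(s): %s",
          paste(missing, collapse = ", "))
  absent <- setdiff(FLUX_PHASES, unique(trace$phase))
  if (length(absent))
    stopf("flux trace is missing phase(s): %s",
          paste(absent, collapse = ", "))
  ord <- match(trace$phase[order(trace$cycle)], FLUX_PHASES)
  if (is.unsorted(ord))
    stopf("phases out of order: expected %s",
          paste(FLUX_PHASES, collapse = " -> "))
  invisible(trace)
}

#' Summarize one well's trace into per-phase OCR levels
#'
#' Default rule (`"protocol"`), following common mito-stress-test report
#' conventions: basal = last basal-phase cycle; oligomycin = minimum
#' post-oligomycin cycle; FCCP = maximum post-FCCP cycle; rotenone/
#' antimycin A = mean of its cycles. The alternative `"phase_mean"` rule
#' uses the mean of every phase's cycles.
#'
#' @param trace one well's trace: data.frame with columns `well, cycle,
#'   phase, time_min, ocr` (phases in canonical order, each present).
#' @param level_rule `"protocol"` (default) or `"phase_mean"`.
#' @return named numeric vector of raw OCR levels (`basal`, `oligomycin`,
#'   `fccp`, `rotAA`), with attribute `level_rule`.
#' @export
phase_summary <- function(trace, level_rule = c("protocol", "phase_mean")) {
  level_rule <- match.arg(level_rule)
  validate_flux_trace(trace)
  trace <- trace[order(trace$cycle), ]
  ocr_of <- function(ph) trace$ocr[trace$phase == ph]
  levels <- if (level_rule == "protocol") c(
    basal = tail(ocr_of("basal"), 1),
    oligomycin = min(ocr_of("oligomycin")),
    fccp = max(ocr_of("fccp")),
    rotAA = mean(ocr_of("rotAA"))
  ) else vapply(setNames(FLUX_PHASES, FLUX_PHASES),
                function(ph) mean(ocr_of(ph)), 1)
  structure(levels, level_rule = level_rule)
}

#' Derive respiration parameters from per-phase OCR levels
#'
#' Standard mito-stress-test arithmetic: non-mitochondrial respiration is
#' the rotenone/antimycin A level; basal respiration = basal level minus
#' non-mito; ATP-linked = basal minus oligomycin level; proton leak =
#' oligomycin level minus non-mito (so ATP-linked + proton leak = basal
#' respiration exactly); maximal = FCCP level minus non-mito; spare
#' capacity = maximal minus basal respiration (also reported as percent,
#' `100 * maximal / basal`). Negative spare capacity is reported with a
#' warning, never clamped, so QC can flag such wells.
#'
#' @param levels per-phase levels from [phase_summary()] (or a named
#'   vector with the same names).
#' @param protein_ug total protein per well, ug; required when
#'   `normalize = TRUE`.
#' @param normalize divide all parameters by `protein_ug`.
#' @return an object of class `flux_parameters` (named list of parameters
#'   plus `normalized` flag and `level_rule` metadata).
#' @export
#' @examples
#' compute_flux_parameters(c(basal = 50, oligomycin = 20, fccp = 120,
#'                           rotAA = 10))
compute_flux_parameters <- function(levels, protein_ug = NULL,
                                    normalize = FALSE) {
  if (!all(FLUX_PHASES %in% names(levels)))
    stopf("levels must name all of: %s", paste(FLUX_PHASES, collapse = ", "))
  lv <- as.numeric(levels[FLUX_PHASES])
  names(lv) <- FLUX_PHASES
  p <- list(
    nonmito = lv["rotAA"],
    basal_respiration = lv["basal"] - lv["rotAA"],
    atp_linked = lv["basal"] - lv["oligomycin"],
    proton_leak = lv["oligomycin"] - lv["rotAA"],
    maximal_respiration = lv["fccp"] - lv["rotAA"])
  p$spare_capacity_abs <- p$maximal_respiration - p$basal_respiration
  p$spare_capacity_pct <-
    if (p$basal_respiration > 0) 100 * p$maximal_respiration / p$basal_respiration
    else NA_real_
  if (p$spare_capacity_abs < 0)
    warnf("FCCP level below basal: spare capacity is negative (%.3g)",
          p$spare_capacity_abs)
  if (normalize) {
    if (is.null(protein_ug) || !is.finite(protein_ug) || protein_ug <= 0)
      stopf("normalize = TRUE needs protein_ug > 0")
    scale_fields <- setdiff(names(p), "spare_capacity_pct")
    p[scale_fields] <- lapply(p[scale_fields], function(v) v / protein_ug)
  }
  structure(c(lapply(p, unname),
              list(normalized = normalize,
                   protein_ug = if (normalize) protein_ug else NA_real_,
                   level_rule = attr(levels, "level_rule") %||% "unknown")),
            class = "flux_parameters")
}

#' @export
print.flux_parameters <- function(x, ...) {
  cat(sprintf("<flux_parameters>%s basal %.3g | ATP-linked %.3g | leak %.3g | maximal %.3g | spare %.3g (%.0f%%)\n",
              if (x$normalized) " [per ug protein]" else "",
              x$basal_respiration, x$atp_linked, x$proton_leak,
              x$maximal_respiration, x$spare_capacity_abs,
              x$spare_capacity_pct))
  invisible(x)
}

#' Group flux traces by condition: time courses and parameter comparisons
#'
#' Computes, per condition, the per-cycle OCR time course (mean +/- SEM
#' across wells, the convention for time-course panels) and per-well
#' respiration parameters summarized as mean +/- SD (the convention for
#' summary parameters), with Welch's t-test between the two conditions on
#' every summary parameter.
#'
#' @param traces data.frame of stacked per-well traces (columns `well,
#'   cycle, phase, time_min, ocr, protein_ug` plus `condition`).
#' @param reference,test the two condition labels to compare.
#' @param normalize divide parameters by each well's protein content.
#' @param level_rule passed to [phase_summary()].
#' @return list with `time_course` (condition, cycle, phase, time_min,
#'   mean_ocr, sem_ocr, n), `well_parameters` (one row per well) and
#'   `comparison` (one row per parameter: group means +/- SD, Welch t, df,
#'   p, stars, fold change test/reference).
#' @export
group_flux <- function(traces, reference, test, normalize = TRUE,
                       level_rule = "protocol") {
  stopifnot("condition" %in% names(traces))
  conditions <- c(reference, test)
  if (!all(conditions %in% traces$condition))
    stopf("conditions not found in traces: %s",
          paste(setdiff(conditions, traces$condition), collapse = ", "))
  traces <- traces[traces$condition %in% conditions, ]

  # per-condition cycle grid must agree across wells
  tc <- lapply(conditions, function(cond) {
    sub <- traces[traces$condition == cond, ]
    wells <- unique(sub$well)
    if (length(wells) < 2L)
      stopf("condition '%s' has %d well(s); need >= 2", cond, length(wells))
    counts <- vapply(wells, function(w) nrow(sub[sub$well == w, ]), 1L)
    if (length(unique(counts)) != 1L)
      stopf("wells of condition '%s' have differing cycle counts", cond)
    agg_mean <- stats::aggregate(ocr ~ cycle + phase + time_min, sub, mean)
    agg_sd <- stats::aggregate(ocr ~ cycle + phase + time_min, sub, sd)
    n <- length(wells)
    data.frame(condition = cond, cycle = agg_mean$cycle,
               phase = agg_mean$phase, time_min = agg_mean$time_min,
               mean_ocr = agg_mean$ocr, sem_ocr = agg_sd$ocr / sqrt(n),
               n = n)
  })
  time_course <- do.call(rbind, tc)
  time_course <- time_course[order(time_course$condition,
                                   time_course$cycle), ]

  params <- do.call(rbind, lapply(split(traces,
                                        traces[c("well", "condition")],
                                        drop = TRUE), function(sub) {
    lv <- phase_summary(sub, level_rule)
    fp <- compute_flux_parameters(lv, protein_ug = sub$protein_ug[1],
                                  normalize = normalize)
    data.frame(condition = sub$condition[1], well = sub$well[1],
               basal_respiration = fp$basal_respiration,
               atp_linked = fp$atp_linked, proton_leak = fp$proton_leak,
               maximal_respiration = fp$maximal_respiration,
               spare_capacity_abs = fp$spare_capacity_abs,
               spare_capacity_pct = fp$spare_capacity_pct,
               nonmito = fp$nonmito)
  }))
  rownames(params) <- NULL

  par_names <- c("basal_respiration", "atp_linked", "proton_leak",
                 "maximal_respiration", "spare_capacity_abs", "nonmito")
  comparison <- do.call(rbind, lapply(par_names, function(pn) {
    va <- params[params$condition == reference, pn]
    vb <- params[params$condition == test, pn]
    w <- tryCatch(welch_t_test(va, vb), error = function(e) {
      warnf("parameter '%s': %s; comparison fields set to NA",
            pn, conditionMessage(e))
      list(t_statistic = NA_real_, welch_df = NA_real_,
           p_value = NA_real_, stars = NA_character_)
    })
    data.frame(parameter = pn,
               mean_ref = mean(va), sd_ref = sd(va), n_ref = length(va),
               mean_test = mean(vb), sd_test = sd(vb), n_test = length(vb),
               t_statistic = w$t_statistic, welch_df = w$welch_df,
               p_value = w$p_value, stars = w$stars,
               fold_change = if (mean(va) > 0) mean(vb) / mean(va)
                             else NA_real_)
  }))

  list(time_course = time_course, well_parameters = params,
       comparison = comparison)
}
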