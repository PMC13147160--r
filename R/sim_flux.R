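# Synthetic mito-stress-test traces: basal measurements followed by
# sequential oligomycin, FCCP and rotenone/antimycin A injections.

#' Canonical mito-stress-test phase order
#' @export
FLUX_PHASES <- c("basal", "oligomycin", "fccp", "rotAA")

#' Simulate a phase-labeled extracellular-flux (OCR/ECAR) trace
#'
#' Generates one well's mito-stress-test trace: `n_cycles_per_phase`
#' measurement cycles per phase in the canonical order basal, oligomycin,
#' FCCP, rotenone/antimycin A, with i.i.d. Gaussian measurement noise around
#' the programmed phase level. Each cycle spans 6 min (3 min mixing + 3 min
#' measurement, timestamped at the end of the measurement period).
#'
#' @param phase_levels named numeric vector or list of true OCR levels
#'   (pmol O2/min) with names `basal`, `oligomycin`, `fccp`, `rotAA`; all
#'   levels must be non-negative.
#' @param n_cycles_per_phase measurement cycles per phase (>= 1).
#' @param noise_sd SD of the measurement noise, OCR units.
#' @param protein_ug total protein per well, ug (> 0).
#' @param seed integer seed; fixed seed gives a reproducible trace.
#' @param well well identifier.
#' @param ecar_levels optional phase ECAR levels (mpH/min), same names;
#'   defaults to a flat 10 mpH/min (the assay here tracks ECAR only
#'   descriptively).
#' @return a data.frame with columns `well, cycle, phase, time_min, ocr,
#'   ecar, protein_ug`, one row per measurement cycle.
#' @export
#' @examples
#' tr <- simulate_flux_trace(c(basal = 50, oligomycin = 20, fccp = 120,
#'                             rotAA = 10), noise_sd = 0, protein_ug = 2,
#'                           seed = 1)
#' tr$ocr
simulate_flux_trace <- function(phase_levels, n_cycles_per_phase = 3L,
                                noise_sd = 0, protein_ug = 1, seed = 1L,
                                well = "W1", ecar_levels = NULL) {
  phase_levels <- unlist(phase_levels)
  if (!all(FLUX_PHASES %in% names(phase_levels)))
    stopf("phase_levels must name all of: %s",
          paste(FLUX_PHASES, collapse = ", "))
  phase_levels <- phase_levels[FLUX_PHASES]
  if (any(phase_levels < 0))
    stopf("negative phase level(s): %s",
          paste(names(phase_levels)[phase_levels < 0], collapse = ", "))
  assert_scalar_number(n_cycles_per_phase, "n_cycles_per_phase", min = 1)
  assert_scalar_number(noise_sd, "noise_sd", min = 0)
  assert_scalar_number(protein_ug, "protein_ug", min = 0, strict_min = TRUE)
  if (is.null(ecar_levels))
    ecar_levels <- setNames(rep(10, 4), FLUX_PHASES)
  ecar_levels <- unlist(ecar_levels)[FLUX_PHASES]

  n <- as.integer(n_cycles_per_phase)
  phase <- factor(rep(FLUX_PHASES, each = n), levels = FLUX_PHASES)
  cycle <- seq_along(phase)
  withr::with_seed(as.integer(seed), {
    ocr <- rep(phase_levels, each = n) + rnorm(length(phase), 0, noise_sd)
    ecar <- rep(ecar_levels, each = n) + rnorm(length(phase), 0, noise_sd / 5)
  })
  data.frame(well = well, cycle = cycle, phase = as.character(phase),
             time_min = cycle * 6, ocr = as.numeric(ocr),
             ecar = as.numeric(ecar), protein_ug = protein_ug)
}
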