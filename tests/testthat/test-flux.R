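# Flux traces: simulation, phase levels, respiration parameters, grouping.

LEVELS <- c(basal = 50, oligomycin = 20, fccp = 120, rotAA = 10)

test_that("noiseless traces reproduce their phase levels exactly", {
  tr <- simulate_flux_trace(LEVELS, n_cycles_per_phase = 3, noise_sd = 0,
                            protein_ug = 2, seed = 1)
  expect_identical(nrow(tr), 12L)
  expect_equal(tr$ocr, rep(unname(LEVELS), each = 3))
  expect_identical(tr$phase, rep(c("basal", "oligomycin", "fccp", "rotAA"),
                                 each = 3))
  expect_true(!is.unsorted(tr$time_min))
  expect_error(simulate_flux_trace(c(LEVELS[1:3], rotAA = -1)), "negative")
})

test_that("flux simulation is reproducible and well calibrated", {
  t1 <- simulate_flux_trace(LEVELS, noise_sd = 2, seed = 42)
  t2 <- simulate_flux_trace(LEVELS, noise_sd = 2, seed = 42)
  expect_identical(t1, t2)
  # phase means within 3 SE of the programmed levels, pooled over replicates
  for (s in 1:5) {
    tr <- simulate_flux_trace(LEVELS, n_cycles_per_phase = 5, noise_sd = 2,
                              seed = 100 + s)
    for (ph in names(LEVELS)) {
      m <- mean(tr$ocr[tr$phase == ph])
      expect_lt(abs(m - LEVELS[[ph]]), 4 * 2 / sqrt(5))
    }
  }
})

test_that("phase levels follow the protocol rules", {
  tr <- simulate_flux_trace(LEVELS, n_cycles_per_phase = 3, noise_sd = 0,
                            protein_ug = 1, seed = 1)
  tr$ocr <- c(48, 50, 52,  25, 20, 22,  100, 120, 110,  9, 10, 11)
  lv <- phase_summary(tr)
  expect_equal(unname(lv["basal"]), 52)      # last basal cycle
  expect_equal(unname(lv["oligomycin"]), 20) # minimum
  expect_equal(unname(lv["fccp"]), 120)      # maximum
  expect_equal(unname(lv["rotAA"]), 10)      # mean
  expect_identical(attr(lv, "level_rule"), "protocol")
  lv2 <- phase_summary(tr, level_rule = "phase_mean")
  expect_equal(unname(lv2["basal"]), 50)
  expect_error(phase_summary(tr[tr$phase != "fccp", ]), "fccp")
})

test_that("parameter arithmetic matches the standard derivation", {
  fp <- compute_flux_parameters(LEVELS)
  expect_equal(fp$nonmito, 10)
  expect_equal(fp$basal_respiration, 40)
  expect_equal(fp$proton_leak, 10)
  expect_equal(fp$atp_linked, 30)
  expect_equal(fp$maximal_respiration, 110)
  expect_equal(fp$spare_capacity_abs, 70)
  expect_equal(fp$spare_capacity_pct, 100 * 110 / 40)
  half <- compute_flux_parameters(LEVELS, protein_ug = 2, normalize = TRUE)
  expect_equal(half$basal_respiration, 20)
  expect_equal(half$spare_capacity_abs, 35)
  expect_equal(half$spare_capacity_pct, fp$spare_capacity_pct) # ratio
})

test_that("ATP-linked + proton leak equals basal respiration on random traces", {
  withr::local_seed(5)
  for (i in 1:100) {
    lv <- c(basal = runif(1, 20, 80), oligomycin = runif(1, 5, 30),
            fccp = runif(1, 40, 150), rotAA = runif(1, 1, 15))
    fp <- suppressWarnings(compute_flux_parameters(lv))
    expect_equal(fp$atp_linked + fp$proton_leak, fp$basal_respiration,
                 tolerance = 1e-12)
    expect_equal(fp$spare_capacity_abs,
                 fp$maximal_respiration - fp$basal_respiration,
                 tolerance = 1e-12)
  }
})

test_that("negative spare capacity warns but is not clamped", {
  lv <- c(basal = 50, oligomycin = 20, fccp = 45, rotAA = 10)
  expect_warning(fp <- compute_flux_parameters(lv), "negative")
  expect_equal(fp$spare_capacity_abs, -5)
})

test_that("raising FCCP raises maximal and spare capacity, basal untouched", {
  lo <- compute_flux_parameters(LEVELS)
  hi <- compute_flux_parameters(replace(LEVELS, "fccp", 150))
  expect_gt(hi$maximal_respiration, lo$maximal_respiration)
  expect_gt(hi$spare_capacity_abs, lo$spare_capacity_abs)
  expect_equal(hi$basal_respiration, lo$basal_respiration)
})

test_that("normalization is equivariant in the protein content", {
  f1 <- compute_flux_parameters(LEVELS, protein_ug = 1, normalize = TRUE)
  f3 <- compute_flux_parameters(LEVELS, protein_ug = 3, normalize = TRUE)
  for (fld in c("basal_respiration", "atp_linked", "proton_leak",
                "maximal_respiration", "spare_capacity_abs", "nonmito"))
    expect_equal(f3[[fld]], f1[[fld]] / 3, tolerance = 1e-12)
})

make_condition_traces <- function(levels, cond, n_wells, noise, seed0) {
  do.call(rbind, lapply(seq_len(n_wells), function(w) {
    tr <- simulate_flux_trace(levels, n_cycles_per_phase = 3,
                              noise_sd = noise, protein_ug = 1,
                              seed = seed0 + w, well = paste0(cond, w))
    tr$condition <- cond
    tr
  }))
}

test_that("identical wells give zero SEM; SEM equals SD over sqrt n", {
  traces <- make_condition_traces(LEVELS, "A", 5, noise = 0, seed0 = 10)
  traces2 <- make_condition_traces(LEVELS * 1.2, "B", 5, noise = 0,
                                   seed0 = 20)
  expect_warning(
    g <- group_flux(rbind(traces, traces2), "A", "B", normalize = FALSE),
    "NA")
  expect_true(all(g$time_course$sem_ocr == 0))
  noisy <- rbind(make_condition_traces(LEVELS, "A", 4, 3, 30),
                 make_condition_traces(LEVELS, "B", 4, 3, 40))
  gn <- group_flux(noisy, "A", "B", normalize = FALSE)
  one <- gn$time_course[gn$time_course$condition == "A" &
                        gn$time_course$cycle == 1, ]
  vals <- noisy$ocr[noisy$condition == "A" & noisy$cycle == 1]
  expect_equal(one$sem_ocr, sd(vals) / sqrt(4), tolerance = 1e-12)
})

test_that("a programmed spare-capacity ratio is recovered from noisy wells", {
  # non-acclimated: basal_resp 20, maximal 27.7, spare 7.66; acclimated:
  # maximal x1.69 and spare x3.49 with basal held comparable
  non_ac <- c(basal = 30, oligomycin = 15, fccp = 37.66, rotAA = 10)
  ac <- c(basal = 30.1, oligomycin = 15, fccp = 56.78, rotAA = 10)
  traces <- rbind(make_condition_traces(non_ac, "nonAC", 5, 0.8, 100),
                  make_condition_traces(ac, "AC", 5, 0.8, 200))
  g <- group_flux(traces, "nonAC", "AC", normalize = TRUE)
  cmp <- g$comparison
  spare <- cmp[cmp$parameter == "spare_capacity_abs", ]
  programmed <- (56.78 - 30.1) / (37.66 - 30)
  expect_lt(abs(spare$fold_change - programmed) / programmed, 0.15)
  expect_identical(nrow(g$well_parameters), 10L)
})

test_that("wells with unequal cycle grids are rejected", {
  a <- make_condition_traces(LEVELS, "A", 2, 0, 1)
  a <- a[!(a$well == "A1" & a$cycle == 12), ] # drop one cycle
  b <- make_condition_traces(LEVELS, "B", 2, 0, 5)
  expect_error(group_flux(rbind(a, b), "A", "B"), "cycle counts")
})
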