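model <- fit_calibration(gen_calibrants(noise = 0))
truth <- default_calibration_truth()

test_that("fingerprints are row-normalised with flagged zero rows", {
  # three voltages of narrow arrival peaks plus two empty voltages
  recs <- do.call(rbind, lapply(c(50, 100, 150), function(v)
    data.frame(charge = 17, voltage = v,
               drift_ms = vinlock:::drift_from_ccs(6266, 17, 117000,
                                                   truth) + 0.001 * 1:50,
               intensity = 1)))
  # the empty voltages carry one zero-intensity record so the rows exist
  recs <- rbind(recs, data.frame(charge = 17, voltage = c(200, 240),
                                 drift_ms = 20, intensity = 0))
  fp <- build_fingerprint(recs, model, 117000, ccs_bins = 64)
  expect_equal(unname(rowSums(fp$intensity)[1:3]), rep(1, 3),
               tolerance = 1e-9)
  expect_true(all(fp$zero_rows[4:5]))
  expect_equal(unname(rowSums(fp$intensity)[4:5]), c(0, 0))
  expect_error(build_fingerprint(rbind(recs,
    data.frame(charge = 18, voltage = 50, drift_ms = 20,
               intensity = 1)), model, 117000), "mixed charge")
  expect_error(build_fingerprint(recs[recs$voltage < 150, ], model,
                                 117000), "5 distinct voltages")
})

test_that("smoothing and rebinning conserve row normalisation", {
  v <- variant_params("vinculin")
  recs <- gen_ciu(v, seed = 5, mean_ions = 300)
  fp <- build_fingerprint(recs, model, v$mass, smooth_sd = 2)
  expect_equal(unname(rowSums(fp$intensity)[!fp$zero_rows]),
               rep(1, sum(!fp$zero_rows)), tolerance = 1e-6)
  fp2 <- vinlock:::rebin_fingerprint(fp, seq(min(fp$ccs_axis),
                                             max(fp$ccs_axis),
                                             length.out = 101))
  expect_equal(unname(rowSums(fp2$intensity)[!fp2$zero_rows]),
               rep(1, sum(!fp2$zero_rows)), tolerance = 1e-9)
})

test_that("a single conformer yields one state occupying every voltage", {
  v <- variant_params("vinculin")
  v$transitions$c_so$mid <- 1e6 # never leaves C
  recs <- gen_ciu(v, seed = 2, mean_ions = 500)
  fp <- build_fingerprint(recs, model, v$mass)
  expect_warning(st <- detect_states(fp, seed = 1), "fewer than 2")
  expect_length(st, 1)
  expect_true(all(st[[1]]$occupancy > 0.999))
  expect_equal(unname(st[[1]]$voltage_range), c(50, 240))
})

test_that("state detection recovers the generator's conformer family", {
  v <- variant_params("vinculin")
  fp <- build_fingerprint(gen_ciu(v, seed = 7), model, v$mass)
  st <- detect_states(fp, seed = 7)
  expect_length(st, 3)
  expect_equal(vapply(st, function(s) s$label, character(1)),
               c("C", "SO", "O"))
  cents <- vapply(st, function(s) s$centroid, numeric(1))
  truth_cents <- vapply(v$state_ccs, function(s) s$centroid, numeric(1))
  expect_true(all(abs(cents - truth_cents) < 30))
  expect_true(all(diff(cents) > 0))
  # per-voltage occupancies sum to one across states
  occ <- vapply(st, function(s) s$occupancy, numeric(39))
  expect_equal(unname(rowSums(occ)), rep(1, 39), tolerance = 1e-6)
})

test_that("state labels are stable under intensity rescaling", {
  v <- variant_params("T12")
  fp <- build_fingerprint(gen_ciu(v, seed = 4), model, v$mass)
  fp_scaled <- fp
  fp_scaled$row_counts <- fp$row_counts * 3.7
  a <- states_table(detect_states(fp, seed = 2))
  b <- states_table(detect_states(fp_scaled, seed = 2))
  expect_equal(a$label, b$label)
  expect_equal(a$centroid, b$centroid, tolerance = 1e-3)
})

test_that("transition reports carry onset, completion and mode", {
  mk_state <- function(label, centroid, occ, voltages) {
    vr <- if (any(occ >= 0.1)) range(voltages[occ >= 0.1]) else
      c(NA_real_, NA_real_)
    structure(list(label = label, centroid = centroid, width = 50,
                   occupancy = stats::setNames(occ, voltages),
                   voltage_range = vr, presence_threshold = 0.1),
              class = "conformer_state")
  }
  voltages <- seq(50, 240, by = 5)
  p1 <- stats::plogis((voltages - 160) / 9.8)
  st <- list(mk_state("C", 6266, 1 - p1, voltages),
             mk_state("SO", 6970, p1, voltages))
  tr <- detect_transitions(st, step = 5)
  expect_equal(tr$onset_voltage, 140)
  expect_equal(tr$completion_voltage, 180)
  expect_equal(tr$coexistence_width, 40)
  expect_equal(tr$mode, "gradual")
  # sharp switch: abrupt
  sharp <- stats::plogis((voltages - 140) / 1.5)
  st2 <- list(mk_state("C", 6266, 1 - sharp, voltages),
              mk_state("SO", 6970, sharp, voltages))
  tr2 <- detect_transitions(st2, step = 5)
  expect_equal(tr2$mode, "abrupt")
  expect_lte(tr2$coexistence_width, 5)
  # a state that never appears is reported absent
  st3 <- list(mk_state("C", 6266, rep(1, 39), voltages),
              mk_state("SO", 6970, rep(0, 39), voltages))
  expect_equal(detect_transitions(st3)$mode, "absent")
  expect_error(detect_transitions(st3[1]), ">= 2 states")
  # coexistence widens monotonically as the presence threshold drops
  widths <- vapply(c(0.3, 0.2, 0.1, 0.05, 0.02), function(th)
    detect_transitions(st, presence_threshold = th)$coexistence_width,
    numeric(1))
  expect_true(all(diff(widths) >= 0))
})

test_that("stability profiles expose dwell windows", {
  voltages <- seq(50, 240, by = 5)
  occ_always <- rep(1, length(voltages))
  occ_never <- rep(0, length(voltages))
  st <- list(
    structure(list(label = "C", centroid = 6000, width = 50,
                   occupancy = stats::setNames(occ_always, voltages),
                   voltage_range = c(50, 240)),
              class = "conformer_state"),
    structure(list(label = "SO", centroid = 7000, width = 50,
                   occupancy = stats::setNames(occ_never, voltages),
                   voltage_range = c(NA, NA)),
              class = "conformer_state"))
  sp <- stability_profile(st, step = 5)
  expect_equal(sp$dwell, c(195, 0))
  # T12-A974K's semi-open state dwells for less than T12's
  for (nm in c("T12", "T12_A974K")) {
    v <- variant_params(nm)
    fp <- build_fingerprint(gen_ciu(v, seed = 6), model, v$mass)
    dw <- stability_profile(detect_states(fp, seed = 6))
    assign(paste0("dwell_", nm), dw$dwell[dw$state == "SO"])
  }
  expect_lt(dwell_T12_A974K, dwell_T12)
})

test_that("variant comparison aligns profiles and orders onsets", {
  fps <- list()
  for (nm in c("vinculin", "T12")) {
    v <- variant_params(nm)
    fps[[nm]] <- build_fingerprint(gen_ciu(v, seed = 8), model, v$mass)
  }
  cmp <- compare_variants(fps, at_voltages = c(125), seed = 8)
  expect_equal(sort(unique(cmp$profiles$variant)), c("T12", "vinculin"))
  # at 125 V T12 is already semi-open: its intensity mass above
  # 6,500 A^2 exceeds vinculin's
  mass_above <- function(nm) {
    pr <- cmp$profiles[cmp$profiles$variant == nm, ]
    sum(pr$intensity[pr$ccs > 6500])
  }
  expect_gt(mass_above("T12"), mass_above("vinculin"))
  expect_lt(cmp$onsets$onset_voltage[cmp$onsets$variant == "T12"],
            cmp$onsets$onset_voltage[cmp$onsets$variant == "vinculin"])
  # identical fingerprints: zero profile differences
  cmp2 <- compare_variants(list(a = fps$T12, b = fps$T12),
                           at_voltages = c(100, 230), seed = 1)
  pa <- cmp2$profiles[cmp2$profiles$variant == "a",
                      c("voltage", "ccs", "intensity")]
  pb <- cmp2$profiles[cmp2$profiles$variant == "b",
                      c("voltage", "ccs", "intensity")]
  expect_equal(pa, pb, ignore_attr = TRUE)
})

test_that("fingerprint CSV round trip preserves the matrix", {
  v <- variant_params("vinculin")
  fp <- build_fingerprint(gen_ciu(v, seed = 3, mean_ions = 200), model,
                          v$mass, ccs_bins = 50)
  path <- withr::local_tempfile(fileext = ".csv")
  write_fingerprint_csv(fp, path)
  fp2 <- read_fingerprint_csv(path, charge_state = 17)
  expect_equal(fp2$voltages, fp$voltages)
  expect_equal(fp2$ccs_axis, fp$ccs_axis, tolerance = 1e-6)
  expect_equal(fp2$intensity, unname(fp$intensity), tolerance = 1e-6)
})
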