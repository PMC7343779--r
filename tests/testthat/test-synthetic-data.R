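test_that("phantom construction validates its specification", {
  expect_error(make_phantom("slab", theta_deg = 95),
               class = "cortexdti_parameter_error")
  expect_error(make_phantom("shell", r_inner = 5, r_outer = 5),
               class = "cortexdti_parameter_error")
  expect_error(make_phantom("slab", thickness = 2),
               class = "cortexdti_parameter_error")
  expect_error(make_phantom("slab", lambdas = c(1, 2, 3) * 1e-3),
               class = "cortexdti_parameter_error")
})

test_that("zero-tilt noiseless phantoms have exactly radial principal directions", {
  ph <- make_phantom("shell", theta_deg = 0, sigma_deg = 0, seed = 5)
  dev <- acos(pmin(abs(rowSums(ph$truth$e1 * ph$truth$normals)), 1))
  expect_lt(max(dev), 1e-6)
  ph2 <- make_phantom("slab", theta_deg = 30, sigma_deg = 0, seed = 5)
  expect_equal(mean(ph2$truth$deviation_rad), pi / 6, tolerance = 1e-9)
  # two parcels, hemisphere split
  expect_setequal(unique(ph$ribbon$parcel[ph$ribbon$tissue == 2L]), 1:2)
})

test_that("phantoms regenerate bit-identically under a fixed seed", {
  a <- make_phantom("shell", theta_deg = 20, sigma_deg = 5, seed = 42)
  b <- make_phantom("shell", theta_deg = 20, sigma_deg = 5, seed = 42)
  expect_identical(a$tensors$D, b$tensors$D)
  expect_identical(a$truth$e1, b$truth$e1)
})

test_that("simulated DWI round-trips through the tensor fit", {
  ph <- make_phantom("slab", dim = c(6L, 6L, 10L), theta_deg = 15,
                     sigma_deg = 0, seed = 9)
  grad <- gradient_scheme(24, 2000)
  dwi <- simulate_dwi(ph$tensors, grad$bvals, grad$bvecs, snr = Inf)
  # b0 equals S0 exactly at infinite SNR
  expect_equal(max(abs(dwi$signals[, , , 1] - 1000)), 0)
  tf <- fit_tensor(dwi)
  expect_lt(max(abs(tf$D - ph$tensors$D)) / max(abs(ph$tensors$D)), 1e-6)
  # isotropic voxels produce identical signal in every direction
  iso_sig <- dwi$signals[1, 1, 1, -1]
  expect_lt(diff(range(iso_sig)) / mean(iso_sig), 1e-10)
  expect_error(simulate_dwi(ph$tensors, grad$bvals, grad$bvecs, snr = 0),
               class = "cortexdti_parameter_error")
})

test_that("Rician noise behaves like its model", {
  ph <- make_phantom("slab", dim = c(8L, 8L, 10L), theta_deg = 0,
                     sigma_deg = 0, seed = 2)
  grad <- gradient_scheme(12, 1000)
  d1 <- simulate_dwi(ph$tensors, grad$bvals, grad$bvecs, snr = 20, seed = 3)
  d2 <- simulate_dwi(ph$tensors, grad$bvals, grad$bvecs, snr = 20, seed = 3)
  expect_identical(d1$signals, d2$signals)
  expect_true(all(d1$signals >= 0))
  # noise level: b0 sd close to s0/snr (Rician ~ Gaussian at high SNR)
  b0 <- d1$signals[, , , 1]
  expect_lt(abs(sd(b0) - 50) / 50, 0.25)
})

test_that("gradient schemes are valid acquisition designs", {
  g <- gradient_scheme(64, 2000)
  expect_length(g$bvals, 65)
  expect_equal(sum(g$bvals < 50), 1)
  norms <- sqrt(colSums(g$bvecs[, -1]^2))
  expect_true(all(abs(norms - 1) < 1e-12))
  expect_gte(cortexdti:::design_rank(g$bvals, g$bvecs), 6)
  expect_error(gradient_scheme(5), class = "cortexdti_parameter_error")
})

test_that("cohort generation respects the study design", {
  cohorts <- make_cohorts(seed = 3)
  counts <- dplyr::count(cohorts, cohort, diagnosis)
  expect_equal(sum(counts$n[counts$cohort == "selection"]), 60)
  expect_equal(sum(counts$n[counts$cohort == "training"]), 54)
  expect_equal(sum(counts$n[counts$cohort == "test"]), 66)
  expect_equal(counts$n[counts$cohort == "test" & counts$diagnosis == "svPPA"], 18)
  # disjoint membership by construction
  expect_equal(anyDuplicated(cohorts$id), 0)
  # reproducible
  expect_identical(make_cohorts(seed = 3), cohorts)
  # MMSE separation mirrors the demographics
  m <- tapply(cohorts$mmse, cohorts$group, mean)
  expect_gt(m[["HS"]] - m[["FTD"]], 4)
  # empty spec gives an empty, well-formed table
  empty <- make_cohorts(cohort_spec(n = list(
    selection = c(HS = 0, bvFTD = 0, svPPA = 0, nfvPPA = 0))), seed = 1)
  expect_equal(nrow(empty), 0)
  expect_true(all(c("id", "diagnosis", "angle_r_wb") %in% names(empty)))
})

test_that("generated feature means and spreads match the specification", {
  spec <- cohort_spec(n = list(selection = c(HS = 1000, bvFTD = 0,
                                             svPPA = 0, nfvPPA = 0)))
  big <- make_cohorts(spec, seed = 4)
  base <- spec$baseline_mean; sdv <- spec$baseline_sd
  se <- sdv / sqrt(1000)
  v <- big$angle_r_fusiform_left
  expect_lt(abs(mean(v) - base), 4 * se)
  expect_lt(abs(sd(v) - sdv) / sdv, 0.1)

  spec2 <- cohort_spec(n = list(selection = c(HS = 0, bvFTD = 0,
                                              svPPA = 1000, nfvPPA = 0)))
  sv <- make_cohorts(spec2, seed = 5)
  expect_lt(abs(mean(sv$angle_r_fusiform_left) - (base + 0.10)), 4 * se)
  expect_lt(abs(mean(sv$angle_r_lingual_right) - base), 4 * se)
})

test_that("null-elevation cohorts reject at about the nominal rate", {
  set.seed(131)
  spec <- cohort_spec(elevation = 0, shared_elevation = 0,
                      n = list(selection = c(HS = 12, bvFTD = 12,
                                             svPPA = 12, nfvPPA = 12)))
  reps <- 200
  rej <- replicate(reps, {
    d <- make_cohorts(spec, seed = sample.int(1e6, 1))
    anova_oneway(d, "angle_r_fusiform_left", "diagnosis")$p_value < 0.05
  })
  mc <- 3 * sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(mean(rej) - 0.05), mc + 0.01)
})

test_that("default elevations give power to detect the svPPA regions after pooled FDR", {
  set.seed(141)
  affected <- c("angle_r_fusiform_left", "angle_r_entorhinal_left",
                "angle_r_temporalpole_right", "angle_r_inferiortemporal_right")
  hits <- replicate(20, {
    d <- make_cohorts(cohort_spec(n = list(
      selection = c(HS = 30, bvFTD = 30, svPPA = 30, nfvPPA = 30))),
      seed = sample.int(1e6, 1))
    regions <- c(affected, sample(setdiff(regional_feature_names(), affected), 7))
    tests <- purrr::map_dfr(regions, function(rc) {
      dplyr::mutate(posthoc_pairwise(d, rc, "diagnosis"), region = rc)
    })
    tests <- dplyr::bind_cols(tests, fdr_bh(tests$p_value)[-1])
    sv_hs <- dplyr::filter(tests, region %in% affected,
                           (group1 == "HS" & group2 == "svPPA") |
                             (group1 == "svPPA" & group2 == "HS"))
    all(sv_hs$significant)
  })
  expect_gte(mean(hits), 0.95)
})
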