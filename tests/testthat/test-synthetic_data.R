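test_that("default stage parameters encode the calibrated trajectories", {
  params <- default_stage_params()
  expect_identical(names(params), c("G", "GY", "YG", "Y", "M"))
  expect_equal(params$G$class_fractions[["TAG"]], 0.293, tolerance = 1e-12)
  expect_equal(params$GY$class_fractions[["TAG"]], 0.795, tolerance = 1e-12)
  expect_equal(params$Y$class_fractions[["TAG"]], 0.856, tolerance = 1e-12)
  expect_equal(params$M$class_fractions[["TAG"]], 0.908, tolerance = 1e-12)
  expect_equal(params$M$class_fractions[["PC"]], 0.054, tolerance = 1e-12)
  expect_equal(params$M$class_fractions[["MGDG"]], 0.0009, tolerance = 1e-12)
  for (p in params) {
    expect_equal(sum(p$class_fractions), 1, tolerance = 1e-9)
    for (sf in p$species_fractions) {
      expect_equal(sum(sf), 1, tolerance = 1e-9)
      expect_true(all(sf >= 0 & sf <= 1))
    }
  }
  # anchored within-class trajectories
  expect_equal(params$G$species_fractions$DAG[["34:2"]], 0.2221, tolerance = 1e-12)
  expect_equal(vapply(params, function(p) p$species_fractions$DAG[["40:3"]], 0),
               c(G = 0.026, GY = 0.090, YG = 0.088, Y = 0.127, M = 0.178),
               tolerance = 1e-12)
  expect_equal(vapply(params, function(p) p$species_fractions$DAG[["38:3"]], 0),
               c(G = 0.032, GY = 0.080, YG = 0.072, Y = 0.136, M = 0.238),
               tolerance = 1e-12)
  expect_equal(params$G$species_fractions$PC[["36:3"]], 0.193, tolerance = 1e-12)
})

test_that("invalid stage parameters are rejected", {
  expect_error(stage_params("G", c(TAG = 0.5), list()), "sum to 1")
  expect_error(stage_params("G", c(TAG = 1), list(TAG = c("62:4" = 0.9))),
               "sum to 1")
  expect_error(stage_params("G", c(TAG = 1), list(TAG = c("62:4" = 1)), cv = -1))
})

test_that("profiles are exact at zero noise and bit-reproducible by seed", {
  params <- default_stage_params(cv = 0)
  p1 <- simulate_profile(params, n_replicates = 2, seed = 9)
  p2 <- simulate_profile(params, n_replicates = 2, seed = 9)
  expect_identical(p1, p2)
  cf <- class_fractions(p1)
  m <- cf[cf$stage == "M" & cf$class == "TAG", "mol_pct"]
  expect_equal(m, rep(90.8, 2), tolerance = 1e-9)
  expect_true(!is.null(attr(p1, "generation")))  # parameter record travels
  noisy1 <- simulate_profile(params$G, n_replicates = 3, seed = 5)
  noisy2 <- simulate_profile(params$G, n_replicates = 3, seed = 5)
  expect_identical(noisy1, noisy2)
})

test_that("noisy replicate fractions concentrate around the parameters", {
  params <- default_stage_params(cv = 0.2)
  prof <- simulate_profile(params$G, n_replicates = 400, seed = 13)
  cf <- class_fractions(prof)
  tag <- cf$mol_pct[cf$class == "TAG"]
  se <- stats::sd(tag) / sqrt(length(tag))
  expect_lt(abs(mean(tag) - 29.3), 3 * se + 0.15)
})

test_that("the peak table is the exact inverse of normalisation at zero noise", {
  params <- default_stage_params(cv = 0)
  prof <- simulate_profile(params, n_replicates = 2, seed = 3)
  pk <- simulate_peak_table(prof)
  back <- is_normalize(pk)
  key <- function(d) d[order(d$sample, d$species), c("sample", "species", "pmol")]
  a <- key(prof); b <- key(back)
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b, tolerance = 1e-12)
  # zero amounts give zero responses
  prof0 <- transform(prof[1:3, ], pmol = 0)
  expect_true(all(simulate_peak_table(prof0)$response[
    !(simulate_peak_table(prof0)$species %in%
        default_internal_standards()$standard_species)] == 0))
})

test_that("amounts recovered under response noise stay near the truth", {
  params <- default_stage_params(cv = 0)
  prof <- simulate_profile(params["G"], n_replicates = 1, seed = 2)
  truth <- stats::setNames(prof$pmol, prof$species)
  hits <- 0L; total <- 0L
  for (s in 1:100) {
    pk <- simulate_peak_table(prof, response_cv = 0.05, seed = s)
    rec <- is_normalize(pk)
    rel <- abs(rec$pmol - truth[rec$species]) / truth[rec$species]
    hits <- hits + sum(rel <= 0.15)  # 3 x CV
    total <- total + length(rel)
  }
  expect_gt(hits / total, 0.95)
})

test_that("simulated spectra carry the designed intensity structure", {
  model <- list(sn13_sn2_ratio = 2.5, salt_to_acid = 0.05,
                mz_jitter_sd = 0, intensity_cv = 0, base_intensity = 100)
  sp <- simulate_ms2("TAG 22:1/18:2/22:1", model = model, seed = 1)
  expect_equal(sp$precursor_mz, oracle_tag_na_mz(list(c(22, 1), c(18, 2), c(22, 1))),
               tolerance = 1e-4)
  pk <- sp$peaks
  i679 <- pk$intensity[abs(pk$mz - 679.56) < 0.05]
  i737 <- pk$intensity[abs(pk$mz - 737.64) < 0.05]
  expect_equal(i679, 100)          # sn-1/3 loss at base intensity
  expect_equal(i737, 100 / 2.5)    # sn-2 loss suppressed by the ratio
  salt <- pk$intensity[abs(pk$mz - 657.58) < 0.05]
  expect_equal(salt, 100 * 0.05)   # salt losses much weaker
  expect_identical(sp$metadata$true_sn2, "18:2")
  expect_identical(simulate_ms2("TAG 22:1/18:2/22:1", model = model, seed = 4),
                   simulate_ms2("TAG 22:1/18:2/22:1", model = model, seed = 4))
  expect_error(simulate_ms2("PC 16:0/18:2"), "TAG")
  expect_error(simulate_ms2(parse_species("22:1/18:2/22:1")), "sn-resolved")
})

test_that("annotation recovers the simulated sn-2 end to end", {
  sp <- simulate_ms2("TAG 20:1/18:2/22:1", seed = 8)
  ann <- annotate(sp)
  expect_identical(ann$sn2[1], "18:2")
  expect_identical(ann$triad[1], "18:2/20:1/22:1")
})

test_that("sn-2 recovery is perfect at strong dominance and silent at none", {
  species <- c("TAG 22:1/18:2/22:1", "TAG 20:1/18:2/22:1", "TAG 22:1/18:2/24:1")
  run <- function(ratio, n = 200) {
    calls <- character(n); truth <- character(n)
    model <- list(sn13_sn2_ratio = ratio, salt_to_acid = 0.05,
                  mz_jitter_sd = 0.05, intensity_cv = 0.05,
                  base_intensity = 100)
    for (i in seq_len(n)) {
      spstr <- species[(i - 1) %% length(species) + 1]
      sp <- simulate_ms2(spstr, model = model, seed = 1000 + i)
      truth[i] <- sp$metadata$true_sn2
      ann <- annotate(sp)
      calls[i] <- if (is.na(ann$sn2[1])) "abstain" else ann$sn2[1]
    }
    list(calls = calls, truth = truth)
  }
  strong <- run(2.5)
  expect_identical(strong$calls, strong$truth)      # 100% recovery, 0 abstentions
  flat <- run(1.0)
  expect_true(all(flat$calls == "abstain"))         # no false positional calls
})

test_that("the full synthetic-to-fraction pipeline recovers stage TAG levels", {
  params <- default_stage_params(cv = 0.05)
  prof <- simulate_profile(params, n_replicates = 3, seed = 17)
  cf <- class_fractions(is_normalize(simulate_peak_table(prof)))
  sm <- stage_summary(cf)
  tag <- sm[sm$class == "TAG", ]
  want <- c(G = 29.3, GY = 79.5, YG = 82.5, Y = 85.6, M = 90.8)
  # within 1 percentage point at every stage
  expect_true(all(abs(tag$mean - want[as.character(tag$stage)]) < 1))
})

test_that("bundled datasets embed their provenance and regenerate identically", {
  d1 <- simulate_dataset(n_replicates = 1, seed = 23)
  d2 <- simulate_dataset(n_replicates = 1, seed = 23)
  expect_identical(d1$profile, d2$profile)
  expect_identical(d1$peak_table, d2$peak_table)
  expect_identical(lapply(d1$spectra, `[[`, "peaks"),
                   lapply(d2$spectra, `[[`, "peaks"))
  expect_identical(d1$seed, 23)
  expect_true(length(d1$spectra) > 0)
  expect_identical(attr(d1$profile, "generation")$seed, 23)
})
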