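# small hand-built peak table: one sample, standards at unit response
make_peaks <- function(responses, sample = "G_1", stage = "G", rep = 1) {
  std <- default_internal_standards()
  rbind(
    data.frame(sample = sample, stage = stage, replicate = rep,
               species = names(responses), response = unname(responses)),
    data.frame(sample = sample, stage = stage, replicate = rep,
               species = std$standard_species, response = 1)
  )
}

test_that("responses scale to pmol through the class standard", {
  pk <- make_peaks(c("PE 34:2" = 1, "TAG 62:4" = 0.5, "MGDG 36:6" = 0))
  prof <- is_normalize(pk)
  expect_equal(prof$pmol[prof$species == "PE 34:2"], 125)
  expect_equal(prof$pmol[prof$species == "TAG 62:4"], 62.5)
  expect_equal(prof$pmol[prof$species == "MGDG 36:6"], 0)
  # standards themselves never appear in the profile
  expect_false(any(prof$species %in% default_internal_standards()$standard_species))
})

test_that("response factors and fallback mapping are honoured", {
  std <- internal_standards(c("PE", "DAG", "SQDG"),
                            c("PE 18:0/18:0", "DAG 18:0/22:6", "SQDG 16:0/18:0"),
                            spiked_pmol = c(125, 125, 125),
                            response_factor = c(2, 1, 1))
  pk <- make_peaks(c("PC 34:2" = 1))
  prof <- is_normalize(pk, standards = std)
  expect_equal(prof$pmol, 250)  # PC falls back to the PE standard, factor 2
  expect_error(is_normalize(pk, fallback = c(TAG = "DAG")),
               "no internal standard or fallback")
})

test_that("a sample without its standard response errors informatively", {
  pk <- make_peaks(c("TAG 62:4" = 0.5))
  pk <- pk[pk$species != "DAG 18:0/22:6", ]
  expect_error(is_normalize(pk), "G_1.*DAG")
})

test_that("uniform response rescaling doubles amounts but not fractions", {
  pk <- make_peaks(c("TAG 62:4" = 0.5, "PC 34:2" = 0.2, "PE 34:2" = 0.1))
  pk2 <- pk
  endo <- !(pk2$species %in% default_internal_standards()$standard_species)
  pk2$response[endo] <- pk2$response[endo] * 2
  p1 <- is_normalize(pk)
  p2 <- is_normalize(pk2)
  expect_equal(p2$pmol, 2 * p1$pmol)
  expect_equal(class_fractions(p2)$mol_pct, class_fractions(p1)$mol_pct,
               tolerance = 1e-12)
})

test_that("class fractions reproduce a zero-noise reference composition", {
  params <- default_stage_params(cv = 0)
  prof <- simulate_profile(params["G"], n_replicates = 1, seed = 1)
  cf <- class_fractions(prof)
  got <- stats::setNames(cf$mol_pct, cf$class)
  expect_equal(got[["TAG"]], 29.3, tolerance = 1e-9)
  expect_equal(got[["PA"]], 28.5, tolerance = 1e-9)
  expect_equal(got[["PC"]], 10.1, tolerance = 1e-9)
  expect_equal(got[["DGDG"]], 8.4, tolerance = 1e-9)
  expect_equal(got[["MGDG"]], 7.1, tolerance = 1e-9)
  expect_equal(got[["PE"]], 3.4, tolerance = 1e-9)
  expect_equal(got[["DAG"]], 3.3, tolerance = 1e-9)
  expect_equal(got[["PG"]], 2.7, tolerance = 1e-9)
  expect_equal(sum(got), 100, tolerance = 1e-9)
})

test_that("single-class profiles give 100 percent and zero profiles error", {
  prof <- data.frame(sample = "s", stage = "G", replicate = 1,
                     species = "TAG 62:4", pmol = 3)
  expect_equal(class_fractions(prof)$mol_pct, 100)
  zero <- transform(prof, pmol = 0)
  expect_error(class_fractions(zero), "all-zero")
})

test_that("within-class fractions anchor to the reference and sum to 100", {
  params <- default_stage_params(cv = 0)
  prof <- simulate_profile(params["G"], n_replicates = 1, seed = 1)
  sf <- species_fraction_within_class(prof, "DAG")
  expect_equal(sf$pct_of_class[sf$species == "DAG 16:0/18:2"], 22.21,
               tolerance = 1e-9)
  expect_equal(sum(sf$pct_of_class), 100, tolerance = 1e-9)
  one <- data.frame(sample = "s", stage = "G", replicate = 1,
                    species = "PA 16:0/18:2", pmol = 5)
  expect_equal(species_fraction_within_class(one, "PA")$pct_of_class, 100)
  expect_error(species_fraction_within_class(one, "TAG"), "no TAG species")
})

test_that("acyl accounting counts chain occurrences weighted by amount", {
  prof <- data.frame(sample = "s", stage = "G", replicate = 1,
                     species = "TAG 22:1/18:2/22:1", pmol = 1)
  ap <- acyl_mole_pct(prof)
  expect_equal(ap$mol_pct[ap$acyl == "22:1"], 200 / 3, tolerance = 1e-9)
  expect_equal(ap$mol_pct[ap$acyl == "18:2"], 100 / 3, tolerance = 1e-9)
  scaled <- transform(prof, pmol = pmol * 7)
  expect_equal(acyl_mole_pct(scaled)$mol_pct, ap$mol_pct, tolerance = 1e-12)
})

test_that("acyl percentages agree with the per-chain expansion oracle", {
  catalog <- unlist(unname(lapply(default_species_catalog(), unname)))
  set.seed(61)
  for (i in 1:50) {
    spp <- sample(catalog, sample(3:8, 1))
    prof <- data.frame(sample = "s", stage = "G", replicate = 1,
                       species = spp, pmol = stats::runif(length(spp), 0.1, 10))
    got <- acyl_mole_pct(prof)
    want <- oracle_acyl_pct(prof$species, prof$pmol)
    expect_equal(stats::setNames(got$mol_pct, got$acyl),
                 want[sort(names(want))], tolerance = 1e-9)
  }
})

test_that("class-total species are excluded from acyl accounting with a warning", {
  prof <- data.frame(sample = "s", stage = "G", replicate = 1,
                     species = c("TAG 22:1/18:2/22:1", "TAG 62:4"),
                     pmol = c(1, 1))
  expect_warning(ap <- acyl_mole_pct(prof), "class-total")
  expect_equal(sum(ap$mol_pct), 100, tolerance = 1e-9)
})

test_that("stage summaries report SD conventions and brute-force means", {
  vals <- data.frame(stage = c("G", "G", "G", "M"),
                     class = "TAG",
                     mol_pct = c(10, 12, 14, 90))
  sm <- stage_summary(vals)
  g <- sm[sm$stage == "G", ]
  expect_equal(g$mean, mean(c(10, 12, 14)))
  expect_equal(g$sd, stats::sd(c(10, 12, 14)))
  expect_identical(g$n, 3L)
  m <- sm[sm$stage == "M", ]
  expect_true(is.na(m$sd))   # single replicate: SD missing, not 0
  same <- stage_summary(data.frame(stage = "G", class = "TAG",
                                   mol_pct = c(5, 5, 5)))
  expect_equal(same$sd, 0)
  with_p <- stage_summary(vals, anova = TRUE)
  expect_true("anova_p" %in% names(with_p))
})

test_that("quantification operations do not mutate their inputs", {
  pk <- make_peaks(c("TAG 22:1/18:2/22:1" = 0.5, "PC 16:0/18:2" = 0.2))
  pk_copy <- pk
  prof <- is_normalize(pk)
  expect_identical(pk, pk_copy)
  prof_copy <- prof
  class_fractions(prof)
  acyl_mole_pct(prof)
  expect_identical(prof, prof_copy)
})
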