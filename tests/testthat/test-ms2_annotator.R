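triad_62_4 <- lapply(c("22:1", "18:2", "22:1"), parse_fatty_acid)
triad_60_4 <- lapply(c("20:1", "18:2", "22:1"), parse_fatty_acid)
triad_64_4 <- lapply(c("22:1", "18:2", "24:1"), parse_fatty_acid)

# four-peak spectrum transcribed from the sodiated 62:4 worked example
spec_62_4 <- ms2_spectrum(1017.9, c(657.6, 679.6, 715.7, 737.6),
                          c(8, 100, 5, 40))
# six-peak spectrum for the sodiated 60:4 precursor
spec_60_4 <- ms2_spectrum(989.9, c(629.6, 651.5, 657.6, 679.6, 687.7, 709.6),
                          c(6, 70, 8, 90, 4, 30))

test_that("fragment counts follow triad symmetry", {
  expect_identical(nrow(predict_fragments(triad_62_4)), 4L)
  expect_identical(nrow(predict_fragments(triad_60_4)), 6L)
})

test_that("predicted fragment m/z match the reference spectra", {
  p62 <- predict_fragments(triad_62_4)
  get <- function(p, acyl, kind) p$mz[p$acyl == acyl & p$loss_kind == kind]
  expect_equal(get(p62, "22:1", "acid"), 679.56, tolerance = 0.01)
  expect_equal(get(p62, "18:2", "acid"), 737.64, tolerance = 0.01)
  expect_equal(get(p62, "22:1", "sodium-salt"), 657.58, tolerance = 0.01)
  expect_equal(get(p62, "18:2", "sodium-salt"), 715.66, tolerance = 0.01)
  p60 <- predict_fragments(triad_60_4)
  expect_equal(get(p60, "22:1", "acid"), 651.53, tolerance = 0.01)
  expect_equal(get(p60, "20:1", "acid"), 679.56, tolerance = 0.01)
  expect_equal(get(p60, "18:2", "acid"), 709.61, tolerance = 0.01)
  expect_true(all(p62$mz < p62$precursor_mz))
  expect_true(all(p60$mz < p60$precursor_mz))
})

test_that("fragment prediction conserves mass and salt spacing", {
  set.seed(51)
  for (i in 1:20) {
    tri <- replicate(3, random_fatty_acid(), simplify = FALSE)
    p <- predict_fragments(tri)
    expect_equal(p$mz + p$loss_da, p$precursor_mz, tolerance = 1e-6)
    for (a in unique(p$acyl)) {
      pair <- p[p$acyl == a, ]
      expect_equal(pair$mz[pair$loss_kind == "acid"] -
                     pair$mz[pair$loss_kind == "sodium-salt"],
                   21.981944, tolerance = 1e-6)
    }
  }
})

test_that("an inconsistent precursor formula is rejected", {
  expect_error(predict_fragments(triad_62_4, chem_formula("C63H114O6")),
               "inconsistent")
  expect_silent(predict_fragments(triad_62_4, chem_formula("C65H118O6")))
})

test_that("matching picks the nearest peak within tolerance", {
  p <- predict_fragments(triad_62_4)
  m <- match_spectrum(spec_62_4, p, tolerance = 0.3)
  hit <- m[m$acyl == "22:1" & m$loss_kind == "acid", ]
  expect_true(hit$matched)
  expect_equal(hit$observed_mz, 679.6)
  expect_equal(hit$error_da, 679.6 - hit$mz, tolerance = 1e-9)
  expect_lt(abs(hit$error_da), 0.05)
  empty <- match_spectrum(ms2_spectrum(1017.9), p, tolerance = 0.3)
  expect_identical(sum(empty$matched), 0L)
})

test_that("near-isobaric predictions sharing one peak are flagged", {
  tri <- lapply(c("18:0", "18:1", "22:1"), parse_fatty_acid)
  p <- predict_fragments(tri)
  # the 18:0 and 18:1 acid losses differ by one H2 (2.016 Da); a peak
  # midway is the nearest to both at a wide nominal tolerance
  mz_pair <- sort(p$mz[p$acyl %in% c("18:0", "18:1") & p$loss_kind == "acid"])
  mid <- mean(mz_pair)
  expect_true(all(abs(mz_pair - mid) < 1.5))  # brute-force distance check
  m <- match_spectrum(ms2_spectrum(p$precursor_mz[1], mid, 100), p,
                      tolerance = 1.5)
  shared <- m[m$acyl %in% c("18:0", "18:1") & m$loss_kind == "acid", ]
  expect_true(all(shared$matched))
  expect_true(all(shared$shared))
})

test_that("sn-2 assignment follows the dominance and similarity rules", {
  # symmetric triad: weakest acid loss called sn-2 under dominance
  res <- assign_sn2(triad_62_4, c("22:1" = 100, "18:2" = 40))
  expect_identical(format(res$sn2), "18:2")
  # equal intensities: dominance unmet, abstain
  expect_null(assign_sn2(triad_62_4, c("22:1" = 50, "18:2" = 50))$sn2)
  # asymmetric triad with similar flanking losses
  res3 <- assign_sn2(triad_60_4,
                     c("20:1" = 90, "22:1" = 70, "18:2" = 30),
                     dominance_ratio = 1.5, similarity_ratio = 3)
  expect_identical(format(res3$sn2), "18:2")
  # flanking losses too dissimilar: abstain
  bad <- assign_sn2(triad_60_4, c("20:1" = 95, "22:1" = 30, "18:2" = 18),
                    similarity_ratio = 3)
  expect_null(bad$sn2)
  expect_match(bad$reason, "similar")
  # missing intensity or no positional contrast: abstain
  expect_null(assign_sn2(triad_60_4, c("20:1" = 90, "18:2" = 30))$sn2)
  mono <- replicate(3, fatty_acid(18, 1), simplify = FALSE)
  expect_null(assign_sn2(mono, c("18:1" = 10))$sn2)
})

test_that("worked-example spectra annotate to the expected regioisomers", {
  a62 <- annotate(spec_62_4)
  expect_identical(a62$triad[1], "18:2/22:1/22:1")
  expect_identical(a62$total[1], "62:4")
  expect_identical(a62$sn2[1], "18:2")
  expect_false(a62$ambiguous[1])
  a60 <- annotate(spec_60_4)
  expect_identical(a60$triad[1], "18:2/20:1/22:1")
  expect_identical(a60$sn2[1], "18:2")
  expect_false(a60$ambiguous[1])
})

test_that("all eight survey precursors admit candidates over the default pool", {
  for (mz in c(853.8, 879.8, 907.8, 935.9, 959.9, 989.9, 1017.9, 1046.0)) {
    ann <- annotate(ms2_spectrum(mz))
    expect_gt(nrow(ann), 0)
  }
})

test_that("a peakless spectrum lists candidates but abstains everywhere", {
  ann <- annotate(ms2_spectrum(1017.9))
  expect_gt(nrow(ann), 0)
  expect_true(all(ann$coverage == 0))
  expect_true(all(is.na(ann$sn2)))
})

test_that("no candidate within tolerance yields an empty diagnosed result", {
  ann <- annotate(ms2_spectrum(500.0))
  expect_identical(nrow(ann), 0L)
  expect_match(attr(ann, "diagnostic"), "no candidate")
})

test_that("co-supported isobaric triads raise the ambiguity flag", {
  # peaks covering BOTH 62:4 triads 22:1/18:2/22:1 and 20:1/18:2/24:1
  p1 <- predict_fragments(triad_62_4)
  p2 <- predict_fragments(lapply(c("20:1", "18:2", "24:1"), parse_fatty_acid))
  mz <- c(p1$mz, p2$mz)
  ann <- annotate(ms2_spectrum(1017.9, mz, rep(50, length(mz))))
  expect_true(all(ann$ambiguous))
  expect_gt(sum(ann$coverage >= 0.5), 1)
  expect_true(is.na(ann$sn2[1]))
  expect_match(ann$sn2_reason[1], "multiple triads")
})

test_that("non-sodiated precursors never receive positional calls", {
  sp <- ms2_spectrum(1013.0, numeric(), numeric(), adduct = "[M+NH4]+")
  # shift precursor so that an ammoniated TAG matches nothing sodiated;
  # use the sodiated m/z grid but declare NH4: composition only
  sp2 <- ms2_spectrum(1017.9, c(679.6, 737.6), c(100, 40), adduct = "[M+NH4]+")
  ann <- annotate(sp2)
  expect_true(is.na(ann$sn2[1]))
  expect_match(ann$sn2_reason[1], "sodiated")
})

test_that("annotation is deterministic with a stable tie-break order", {
  a <- annotate(spec_62_4)
  b <- annotate(spec_62_4)
  expect_identical(a, b)
  # tie on zero coverage resolves lexicographically
  ann <- annotate(ms2_spectrum(1017.9))
  expect_identical(ann$triad, sort(ann$triad))
})
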