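# Synthetic phantom cohort generator.

test_that("the default composition reproduces the cohort table", {
  comp <- phantom_config("tiny")$composition
  expect_equal(sum(comp$count), 330)
  expect_equal(sum(comp$count[comp$significant]), 76)
  get <- function(zone, sig) comp$count[comp$zone == zone &
                                          comp$significant == sig]
  expect_equal(get("PZ", FALSE), 155); expect_equal(get("PZ", TRUE), 36)
  expect_equal(get("TZ", FALSE), 73);  expect_equal(get("TZ", TRUE), 9)
  expect_equal(get("AFS", FALSE), 24); expect_equal(get("AFS", TRUE), 31)
  expect_equal(get("SV", FALSE), 2);   expect_equal(get("SV", TRUE), 0)
})

test_that("generated (zone, class) counts equal the configured counts", {
  co <- tiny_cohort(n_per_cell = 4L)
  zones <- vapply(co$findings, `[[`, character(1), "zone")
  sig <- vapply(co$findings, function(f) isTRUE(f$significant), logical(1))
  expect_equal(unname(table(zones, sig))[, ], matrix(4L, 2, 2)[, ])
  # patients carry 1-3 findings
  pat <- table(vapply(co$findings, `[[`, character(1), "patient_id"))
  expect_true(all(pat >= 1 & pat <= 3))
  # empty composition gives a valid empty cohort
  empty <- generate_cohort(phantom_config("tiny",
    composition = data.frame(zone = "PZ", significant = FALSE, count = 0L)),
    seed = 1)
  expect_length(empty$findings, 0)
})

test_that("cohort generation is bit-reproducible under the seed", {
  a <- generate_cohort(phantom_config("tiny",
    composition = data.frame(zone = "PZ", significant = TRUE, count = 2L)),
    seed = 5)
  b <- generate_cohort(phantom_config("tiny",
    composition = data.frame(zone = "PZ", significant = TRUE, count = 2L)),
    seed = 5)
  expect_identical(a$volumes[[1]]$ADC$intensities,
                   b$volumes[[1]]$ADC$intensities)
  c2 <- generate_cohort(phantom_config("tiny",
    composition = data.frame(zone = "PZ", significant = TRUE, count = 2L)),
    seed = 6)
  expect_false(identical(a$volumes[[1]]$ADC$intensities,
                         c2$volumes[[1]]$ADC$intensities))
})

test_that("phantom volumes survive the standard pipeline with the right extents", {
  samples <- tiny_samples()
  for (s in samples[1:4]) {
    for (m in names(s$vois)) {
      expect_equal(dim(s$vois[[m]]), c(16L, 16L, 6L))
      expect_true(all(s$vois[[m]] >= 0 & s$vois[[m]] <= 1))
    }
    expect_equal(sum(s$zone_code), 1)
  }
})

test_that("the phantom embodies the PI-RADS zone-modality prior", {
  # single-modality oracle: mean intensity in a central lesion mask minus
  # the background mean, thresholded -- dominant sequences must separate
  # the classes, swapped pairs must not
  comp <- data.frame(zone = c("PZ", "PZ", "TZ", "TZ"),
                     significant = c(FALSE, TRUE, FALSE, TRUE),
                     count = rep(40L, 4))
  co <- generate_cohort(phantom_config("tiny", composition = comp),
                        seed = 77)
  samples <- cohort_samples(co)
  zones <- vapply(samples, function(s) s$finding$zone, character(1))
  y <- vapply(samples, `[[`, integer(1), "label")
  mask_score <- function(s, m) {
    g <- s$vois[[m]]
    mean(g[6:11, 6:11, 3:4]) - mean(g[c(2:4, 13:15), c(2:4, 13:15), ])
  }
  oracle_auc_for <- function(m, zone) {
    i <- zones == zone
    v <- vapply(samples[i], mask_score, numeric(1), m = m)
    auc_score(y[i], -v)   # lesions are hypointense in ADC/T2W
  }
  expect_gt(oracle_auc_for("ADC", "PZ"), 0.8)       # dominant for PZ
  expect_gt(oracle_auc_for("T2W_tra", "TZ"), 0.8)   # dominant for TZ
  expect_lt(oracle_auc_for("T2W_tra", "PZ"), 0.7)   # swapped: weak
  expect_lt(oracle_auc_for("ADC", "TZ"), 0.7)       # swapped: weak
})

test_that("zero effect sizes remove the class signal", {
  eff <- .default_effects <- list(
    significant = list(
      PZ_stream = c(T2W = 0, DWI = 0, ADC = 0, KTRANS = 0),
      TZ_stream = c(T2W = 0, DWI = 0, ADC = 0, KTRANS = 0)),
    insignificant = list(
      PZ_stream = c(T2W = 0, DWI = 0, ADC = 0, KTRANS = 0),
      TZ_stream = c(T2W = 0, DWI = 0, ADC = 0, KTRANS = 0)))
  comp <- data.frame(zone = "PZ", significant = c(FALSE, TRUE),
                     count = c(40L, 40L))
  co <- generate_cohort(phantom_config("tiny", composition = comp,
                                       effects = eff, amplitude_jitter_sd = 0),
                        seed = 78)
  samples <- cohort_samples(co)
  y <- vapply(samples, `[[`, integer(1), "label")
  v <- vapply(samples, function(s) mean(s$vois$ADC[6:11, 6:11, 3:4]),
              numeric(1))
  expect_lt(abs(auc_score(y, v) - 0.5), 0.2)
})

test_that("a cohort written to disk round-trips through the readers", {
  co <- tiny_cohort(n_per_cell = 2L)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  recs <- read_findings(file.path(dir, "findings.csv"))
  expect_length(recs, length(co$findings))
  expect_equal(vapply(recs, `[[`, character(1), "zone"),
               vapply(co$findings, `[[`, character(1), "zone"))
  f <- co$findings[[1]]
  s <- read_volume(file.path(dir, sprintf("%s-%s-%s.nii.gz", f$patient_id,
                                          f$finding_id, "ADC")), "ADC")
  expect_equal(s$intensities, co$volumes[[1]]$ADC$intensities,
               tolerance = 1e-5)
  expect_true(file.exists(file.path(dir, "manifest.json")))
})
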