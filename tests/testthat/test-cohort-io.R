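# Findings-table input, significance labelling, geometry and VOI extraction.

test_that("read_findings parses the PROSTATEx dialect", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ProxID,fid,pos,zone,ClinSig",
               "ProstateX-0000,1,25.1 30.2 -10.0,PZ,TRUE",
               "ProstateX-0001,1,\"(1.5, 2.5, 3.5)\",AS,FALSE",
               "ProstateX-0001,2,0 0 0,SV,FALSE"), f)
  recs <- read_findings(f)
  expect_length(recs, 3)
  expect_s3_class(recs[[1]], "finding_record")
  expect_equal(recs[[1]]$zone, "PZ")
  expect_true(recs[[1]]$significant)
  expect_equal(recs[[1]]$position_mm, c(25.1, 30.2, -10.0))
  # PROSTATEx abbreviates the anterior fibromuscular stroma as "AS"
  expect_equal(recs[[2]]$zone, "AFS")
  expect_false(recs[[2]]$significant)
})

test_that("read_findings handles empty tables and reports malformed rows", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("ProxID,fid,pos,zone,ClinSig", f)
  expect_length(read_findings(f), 0)

  writeLines(c("ProxID,fid,pos,zone,ClinSig",
               "P-1,1,0 0 0,XX,TRUE",
               "P-2,1,not a position,PZ,TRUE"), f)
  expect_error(read_findings(f), "row 1.*XX")
  expect_error(read_findings(f), "row 2")

  writeLines(c("ProxID,fid,zone,ClinSig", "P-1,1,PZ,TRUE"), f)
  expect_error(read_findings(f), "position")
})

test_that("significance labelling follows the biopsy rule", {
  # PI-RADS <= 2: not biopsied, insignificant by definition
  expect_equal(label_significance(2), "insignificant")
  expect_equal(label_significance(1), "insignificant")
  # biopsied: Gleason >= 7 is clinically significant
  expect_equal(label_significance(4, gleason = 7), "significant")
  expect_equal(label_significance(3, gleason = 6), "insignificant")
  expect_equal(label_significance(5, gleason = 9), "significant")
  # inconsistent records
  expect_error(label_significance(4), "inconsistent")
  expect_error(label_significance(2, gleason = 7), "not biopsied")
})

test_that("every consistent (pirads, gleason) pair maps to exactly one class", {
  for (p in 1:5) {
    if (p <= 2) {
      expect_true(label_significance(p) %in% c("significant", "insignificant"))
    } else {
      for (g in 5:10)
        expect_equal(label_significance(p, g),
                     if (g >= 7) "significant" else "insignificant")
    }
  }
})

test_that("world_to_voxel inverts the affine and rounds to nearest", {
  s <- volume_series("DWI", array(0, c(4, 4, 4)), spacing_mm = c(2, 2, 3))
  expect_equal(world_to_voxel(c(0, 0, 0), s), c(0L, 0L, 0L))
  expect_equal(world_to_voxel(c(4, 4, 3), s), c(2L, 2L, 1L))
  expect_equal(world_to_voxel(c(4.9, 0, 0), s), c(2L, 0L, 0L))
  # non-trivial origin and orientation
  rot <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  s2 <- volume_series("DWI", array(0, c(4, 4, 4)), spacing_mm = c(2, 2, 3),
                      origin_mm = c(10, -5, 2), orientation = rot)
  idx <- c(1L, 2L, 3L)
  world <- s2$origin_mm + rot %*% (s2$spacing_mm * idx)
  expect_equal(world_to_voxel(as.numeric(world), s2), idx)
  s3 <- s
  s3$orientation <- matrix(0, 3, 3)
  expect_error(world_to_voxel(c(0, 0, 0), s3), "singular")
})

test_that("VOI extents follow round(edge/spacing) for the native spacings", {
  mk <- function(mod, sp, d) volume_series(mod, array(rnorm(prod(d)), d),
                                           spacing_mm = sp)
  centre <- c(40, 40, 24)
  v_t2 <- extract_voi(mk("T2W_tra", c(0.5, 0.5, 3), c(160, 160, 16)), centre)
  expect_equal(dim(v_t2$grid), c(60L, 60L, 10L))
  v_kt <- extract_voi(mk("KTRANS", c(1.5, 1.5, 3), c(60, 60, 16)), centre)
  expect_equal(dim(v_kt$grid), c(20L, 20L, 10L))
  v_dwi <- extract_voi(mk("DWI", c(2, 2, 3), c(44, 44, 16)), centre)
  expect_equal(dim(v_dwi$grid), c(15L, 15L, 10L))
})

test_that("extent times spacing differs from the requested edge by < spacing", {
  set.seed(7)
  for (i in 1:25) {
    sp <- runif(3, 0.3, 4)
    edge <- runif(1, 10, 50)
    s <- volume_series("ADC", array(0, c(64, 64, 32)), spacing_mm = sp)
    v <- extract_voi(s, sp * c(30, 30, 14), edge_mm = edge)
    expect_true(all(abs(dim(v$grid) * sp - edge) < sp))
  }
})

test_that("re-extraction from a VOI at its centre is the identity", {
  set.seed(8)
  s <- volume_series("DWI", array(rnorm(40 * 40 * 20), c(40, 40, 20)),
                     spacing_mm = c(2, 2, 3))
  v1 <- extract_voi(s, c(40, 40, 30), edge_mm = 30)
  # wrap the VOI as a series whose centre voxel sits at the same offset
  s2 <- volume_series("DWI", v1$grid, spacing_mm = c(2, 2, 3))
  ctr2 <- c(2, 2, 3) * (dim(v1$grid) %/% 2)
  v2 <- extract_voi(s2, ctr2, edge_mm = 30)
  expect_identical(v2$grid, v1$grid)
})

test_that("border lesions are padded by edge replication, full miss errors", {
  s <- volume_series("DWI", array(seq_len(10 * 10 * 10), c(10, 10, 10)),
                     spacing_mm = c(2, 2, 3))
  v <- extract_voi(s, c(0, 0, 0), edge_mm = 30)   # window extends below 0
  expect_equal(dim(v$grid), c(15L, 15L, 10L))
  # replicated leading planes equal the first source plane values
  expect_equal(v$grid[1, , ], v$grid[8, , ])      # clamped x-index region
  expect_error(extract_voi(s, c(500, 500, 500)), "outside")
})

test_that("volume NIfTI round-trip preserves data and geometry", {
  f <- withr::local_tempfile(fileext = ".nii.gz")
  arr <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  s <- volume_series("ADC", arr, spacing_mm = c(2, 2, 3),
                     origin_mm = c(-10, 5, 2))
  write_volume(s, f)
  s2 <- read_volume(f, "ADC")
  expect_equal(s2$intensities, arr, tolerance = 1e-6)
  expect_equal(s2$spacing_mm, c(2, 2, 3), tolerance = 1e-6)
  expect_equal(s2$origin_mm, c(-10, 5, 2), tolerance = 1e-6)
})

test_that("MHD/RAW volumes are read with spacing and offset", {
  dir <- withr::local_tempdir()
  arr <- array(rnorm(6 * 5 * 4), c(6, 5, 4))
  raw <- file.path(dir, "vol.raw")
  writeBin(as.numeric(arr), raw, size = 4)
  hdr <- file.path(dir, "vol.mhd")
  writeLines(c("ObjectType = Image", "NDims = 3", "DimSize = 6 5 4",
               "ElementSpacing = 1.5 1.5 3", "Offset = 1 2 3",
               "ElementType = MET_FLOAT", "ElementDataFile = vol.raw"), hdr)
  s <- read_volume(hdr, "KTRANS")
  expect_equal(dim(s$intensities), c(6L, 5L, 4L))
  expect_equal(s$intensities, arr, tolerance = 1e-6)
  expect_equal(s$spacing_mm, c(1.5, 1.5, 3))
  expect_equal(s$origin_mm, c(1, 2, 3))
})
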