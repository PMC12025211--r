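test_that("patient volumes respect the L3 rounding rule and alignment", {
  pp <- phantom_params(image_size = 32, slices_per_patient = 40,
                       l3_fraction = 0.05)
  p <- generate_patient(pp, 123)
  expect_equal(sum(p$l3_flags), 2)           # round(0.05 * 40)
  expect_length(p$slices, 40)
  expect_length(p$masks, 40)
  expect_true(all(vapply(p$slices, function(s) all(is.finite(s)), TRUE)))
  # contiguous flags and at least one L3 even at extreme fractions
  p2 <- generate_patient(phantom_params(image_size = 32,
                                        slices_per_patient = 10,
                                        l3_fraction = 0.01), 5)
  expect_equal(sum(p2$l3_flags), 1)
})

test_that("tissue HU values stay inside their post-processing ranges", {
  pp <- phantom_params(image_size = 32, slices_per_patient = 10)
  cohort <- generate_cohort(pp, 3, seed = 9)
  ranges <- list(`1` = c(29, 150), `2` = c(-150, -50), `3` = c(-190, -30))
  for (p in cohort) {
    hu <- unlist(p$slices)
    mk <- unlist(p$masks)
    expect_true(all(mk %in% 0:4))
    for (k in 1:3) {
      v <- hu[mk == k]
      expect_gt(length(v), 0)
      expect_true(all(v >= ranges[[as.character(k)]][1]))
      expect_true(all(v <= ranges[[as.character(k)]][2]))
    }
  }
})

test_that("same seed gives bit-identical volumes, different seeds differ", {
  pp <- phantom_params(image_size = 32, slices_per_patient = 8)
  a <- generate_patient(pp, 42)
  b <- generate_patient(pp, 42)
  c <- generate_patient(pp, 43)
  expect_identical(a, b)
  expect_false(identical(a$slices[[1]], c$slices[[1]]))
  co1 <- generate_cohort(pp, 3, seed = 5)
  co2 <- generate_cohort(pp, 3, seed = 5)
  expect_identical(unclass(co1), unclass(co2))
})

test_that("single-patient cohort equals generate_patient with derived seed", {
  pp <- phantom_params(image_size = 32, slices_per_patient = 8)
  co <- generate_cohort(pp, 1, seed = 17)
  seeds <- ctbalance:::derive_seeds(17, 1)
  expect_identical(co[[1]], generate_patient(pp, seeds[1], "P001"))
})

test_that("cohort minority fraction converges to l3_fraction", {
  # 10^4 slices in total across the cohort
  pp <- phantom_params(image_size = 16, slices_per_patient = 40,
                       l3_fraction = 0.05)
  cohort <- generate_cohort(pp, 250, seed = 3)
  flags <- unlist(lapply(cohort, `[[`, "l3_flags"))
  expect_length(flags, 1e4)
  expect_lt(abs(mean(flags) - 0.05), 0.005)
})

test_that("masks and images are geometrically consistent", {
  pp <- phantom_params(image_size = 48, slices_per_patient = 6)
  p <- generate_patient(pp, 11)
  for (z in seq_along(p$masks)) {
    mk <- p$masks[[z]]
    # VAT never touches the background (it lies strictly inside the abdomen)
    vat <- which(mk == 3, arr.ind = TRUE)
    if (nrow(vat)) {
      expect_true(all(vat[, 1] > 1 & vat[, 1] < nrow(mk) &
                        vat[, 2] > 1 & vat[, 2] < ncol(mk)))
      bad <- 0L
      for (r in seq_len(nrow(vat))) {
        i <- vat[r, 1]; j <- vat[r, 2]
        nb <- c(mk[i - 1, j], mk[i + 1, j], mk[i, j - 1], mk[i, j + 1])
        if (any(nb == 0)) bad <- bad + 1L
      }
      expect_identical(bad, 0L)
    }
  }
})

test_that("invalid phantom parameters are rejected", {
  expect_error(phantom_params(l3_fraction = 0.6), "l3_fraction")
  expect_error(phantom_params(l3_fraction = 0), "l3_fraction")
  expect_error(phantom_params(image_size = -4), "image_size")
  expect_error(phantom_params(slices_per_patient = 1), "slices_per_patient")
})

test_that("cohort write/read round-trips bit-exactly and reports bad paths", {
  pp <- phantom_params(image_size = 16, slices_per_patient = 6)
  cohort <- generate_cohort(pp, 2, seed = 21)
  dir <- file.path(tempdir(), "cohort_rt")
  write_cohort(cohort, dir)
  back <- read_cohort(dir)
  for (i in seq_along(cohort)) {
    expect_identical(back[[i]]$slices, cohort[[i]]$slices)
    expect_identical(back[[i]]$masks, cohort[[i]]$masks)
    expect_identical(back[[i]]$l3_flags, cohort[[i]]$l3_flags)
    expect_identical(back[[i]]$pixel_spacing_mm, cohort[[i]]$pixel_spacing_mm)
  }
  missing_dir <- file.path(tempdir(), "no_such_cohort")
  expect_error(read_cohort(missing_dir), "no_such_cohort")
  file.remove(file.path(dir, "P002_mask.nii.gz"))
  expect_error(read_cohort(dir), "P002_mask")
  unlink(dir, recursive = TRUE)
})
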