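test_that("channel mass shifts reproduce the K4/K8/R6/R10 isotope arithmetic", {
  hsp90 <- peptide_spec("GVVDSEDLPLNISR", 1) # 1 Arg, 0 Lys
  expect_equal(channel_mass_shift(hsp90, "medium"), 6.020129, tolerance = 1e-6)
  expect_equal(channel_mass_shift(hsp90, "heavy"), 10.008269, tolerance = 1e-6)
  expect_identical(channel_mass_shift(hsp90, "light"), 0)

  enolase <- peptide_spec("VNQIGSVTESLQACK", 2) # 1 Lys, 0 Arg
  expect_equal(channel_mass_shift(enolase, "medium"), 4.025107, tolerance = 1e-6)

  no_label <- peptide_spec("GAVLIPFWSTCYNQDEHM", 2) # no K, no R
  for (ch in c("light", "medium", "heavy")) {
    expect_identical(channel_mass_shift(no_label, ch), 0)
  }

  expect_error(peptide_spec("PEPTIDEX1"), "invalid sequence")
})

test_that("mass shift is additive over sequence concatenation", {
  set.seed(11)
  aa <- c("G", "A", "S", "K", "R", "P", "L", "E")
  for (i in 1:20) {
    s1 <- paste(sample(aa, 8, replace = TRUE), collapse = "")
    s2 <- paste(sample(aa, 10, replace = TRUE), collapse = "")
    for (ch in c("medium", "heavy")) {
      expect_equal(
        channel_mass_shift(peptide_spec(paste0(s1, s2)), ch),
        channel_mass_shift(peptide_spec(s1), ch) + channel_mass_shift(peptide_spec(s2), ch)
      )
    }
  }
})

test_that("expected m/z spacing halves when charge doubles and is zero for same channel", {
  enolase1 <- peptide_spec("VNQIGSVTESLQACK", 1)
  enolase2 <- peptide_spec("VNQIGSVTESLQACK", 2)
  expect_equal(expected_mz_spacing(enolase2, c("light", "medium")), 2.012554,
               tolerance = 1e-6)
  expect_identical(
    expected_mz_spacing(enolase1, c("light", "heavy")),
    2 * expected_mz_spacing(enolase2, c("light", "heavy"))
  )
  hsp90 <- peptide_spec("GVVDSEDLPLNISR", 1)
  expect_equal(expected_mz_spacing(hsp90, c("light", "heavy")), 10.008269,
               tolerance = 1e-6)
  expect_identical(expected_mz_spacing(hsp90, c("medium", "medium")), 0)
})

test_that("triplet detection recovers planted triplets and stays empty without partners", {
  # high recovery over many random peptides, clean spectra
  set.seed(21)
  aa <- names(silacdiff:::RESIDUE_MONO)
  found <- 0L
  n_pep <- 100L
  for (i in seq_len(n_pep)) {
    seqi <- paste0(paste(sample(aa, sample(7:15, 1), replace = TRUE), collapse = ""),
                   sample(c("K", "R"), 1))
    spec <- peptide_spec(seqi, sample(1:3, 1))
    sim <- simulate_peaklist(spec, n_noise_peaks = 0, seed = i)
    trip <- detect_triplets(sim$peaks, spec, tolerance_ppm = 10)
    if (nrow(trip) == 1) found <- found + 1L
  }
  expect_gte(found / n_pep, 0.99)

  spec <- peptide_spec("GVVDSEDLPLNISR", 1)
  sim <- simulate_peaklist(spec, n_noise_peaks = 0, seed = 7)

  # medium peak shifted 0.1 Da off: far outside 10 ppm at m/z ~1500
  shifted <- sim$peaks
  shifted$mz[2] <- shifted$mz[2] + 0.1
  shifted <- shifted[order(shifted$mz), ]
  expect_identical(nrow(detect_triplets(shifted, spec, 10)), 0L)

  # lone light peak and empty list
  lone <- sim$peaks[1, ]
  expect_identical(nrow(detect_triplets(lone, spec, 10)), 0L)
  expect_identical(nrow(detect_triplets(sim$peaks[0, ], spec, 10)), 0L)
})

test_that("triplet detection reports nothing on pure-noise spectra", {
  spec <- peptide_spec("VNQIGSVTESLQACK", 2)
  clean <- 0L
  for (s in 1:20) {
    set.seed(1000 + s)
    peaks <- tibble::tibble(mz = sort(runif(100, 400, 1600)),
                            intensity = runif(100, 1e4, 1e6))
    if (nrow(detect_triplets(peaks, spec, 10)) == 0) clean <- clean + 1L
  }
  expect_gte(clean / 20, 0.95)
})

test_that("incorporation efficiency is a scale-invariant intensity fraction", {
  expect_identical(incorporation_efficiency(0, 42), 1)
  expect_identical(incorporation_efficiency(7, 7), 0.5)
  expect_identical(incorporation_efficiency(2, 98), 0.98)
  expect_identical(
    incorporation_efficiency(3, 17),
    incorporation_efficiency(3 * 1e5, 17 * 1e5)
  )
  expect_error(incorporation_efficiency(0, 0), "both intensities are zero")
  expect_error(incorporation_efficiency(-1, 5), ">= 0")
})

test_that("Arg-to-Pro conversion is flagged from planted satellites and vacuous without Pro", {
  spec <- peptide_spec("GVVDSEDLPLNISR", 1) # one Pro
  with_sat <- simulate_peaklist(spec, channels = "medium", conversion_fraction = 0.2,
                                seed = 3)
  res <- check_arg_pro_conversion(with_sat$peaks, spec, "medium",
                                  satellite_threshold = 0.05)
  expect_true(res$converted)
  expect_equal(res$satellite_fraction, 0.2, tolerance = 1e-9)

  no_sat <- simulate_peaklist(spec, channels = "medium", seed = 3)
  res2 <- check_arg_pro_conversion(no_sat$peaks, spec, "medium")
  expect_false(res2$converted)
  expect_identical(res2$satellite_fraction, 0)

  no_pro <- peptide_spec("VNQIGSVTESLQACK", 2)
  sim3 <- simulate_peaklist(no_pro, channels = "heavy", seed = 4)
  res3 <- check_arg_pro_conversion(sim3$peaks, no_pro, "heavy")
  expect_false(res3$converted)
  expect_identical(res3$satellite_fraction, 0)
})
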