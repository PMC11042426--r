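# Mass binning, intensity thresholding, spectrum attachment, SNOG
# filtering, TIC normalization.

test_that("features land on the fixed 0.1-amu grid and sum within bins", {
  cfg <- run_config()
  f <- data.frame(mass = c(2371.8638, 2371.88, 1237.4565, 999.9),
                  rt = c(1, 2, 3, 4),
                  intensity = c(1e7, 4e6, 3e6, 1e6), sample = "s")
  expect_message(h <- bin_features(f, cfg), "dropped 1")
  expect_equal(h$bins$center, c(1237.5, 2371.9))
  expect_equal(h$bins$intensity, c(3e6, 1.4e7))
  # intensity-weighted bin mass
  expect_equal(h$bins$mass[2], (2371.8638 * 1e7 + 2371.88 * 4e6) / 1.4e7)
  # order independence
  h2 <- suppressMessages(bin_features(f[c(3, 1, 4, 2), ], cfg))
  expect_equal(h2$bins, h$bins)
})

test_that("binning conserves total in-range intensity (brute-force oracle)", {
  set.seed(41)
  cfg <- run_config()
  f <- data.frame(mass = runif(300, 900, 5100), rt = runif(300, 0, 3000),
                  intensity = runif(300, 1, 1e6), sample = "s")
  h <- suppressMessages(bin_features(f, cfg))
  in_range <- f$mass >= 1000 & f$mass <= 5000
  expect_equal(h$tic, sum(f$intensity[in_range]), tolerance = 1e-12)
  expect_equal(sum(h$bins$intensity), h$tic)
  expect_false(is.unsorted(h$bins$center, strictly = TRUE))
})

test_that("the cumulative intensity threshold removes strictly-below bins", {
  cfg <- run_config()
  f <- data.frame(mass = c(1500.0, 1600.0), rt = c(1, 2),
                  intensity = c(4.9e6, 5.1e6), sample = "s")
  h <- bin_features(f, cfg)
  ht <- threshold_bins(h, 5e6)
  expect_equal(ht$bins$center, 1600.0)
  expect_equal(ht$tic, 5.1e6)
  # threshold 0 is the identity
  expect_equal(threshold_bins(h, 0)$bins, h$bins)
  expect_warning(threshold_bins(h, 1e9), "below")
})

test_that("spectrum precursor masses deconvolute onto the right bins", {
  p <- 1.00727646688
  s <- make_spec(c(224.1118), c(10), id = "x",
                 precursor_mz = 1186.4355, charge = 2L)
  expect_equal(spectrum_mplush(s), (1186.4355 - p) * 2 + p)
  expect_equal(spectrum_mplush(s), 2371.8637, tolerance = 1e-4)
  # z = 1 is the identity
  s1 <- make_spec(1, 1, precursor_mz = 1789.6730, charge = 1L)
  expect_equal(spectrum_mplush(s1), 1789.6730)
  expect_error(spectrum_mplush(make_spec(1, 1, charge = NA_integer_)),
               "unknown charge")
})

test_that("attach_spectra assigns nearest centers and aggregates SNOG", {
  cfg <- run_config()
  f <- data.frame(mass = c(2371.9, 2372.0), rt = c(1, 2),
                  intensity = c(1e7, 1e7), sample = "s")
  h <- bin_features(f, cfg)
  sps <- list(
    # mass 2371.97: distances 0.07 vs 0.03 -> bin 2372.0
    make_spec(224.1118, 10, id = "tie", precursor_mz = 2371.97, charge = 1L),
    make_spec(c(204.0867, 224.1118), c(80, 20), id = "a",
              precursor_mz = (2371.9 - 1.00727646688) / 2 + 1.00727646688,
              charge = 2L),
    make_spec(c(204.0867, 224.1118), c(60, 40), id = "b",
              precursor_mz = 2371.9, charge = 1L),
    make_spec(224.1118, 5, id = "nocharge", precursor_mz = 1200,
              charge = NA_integer_))
  scores <- score_spectra(sps)
  h <- attach_spectra(h, sps, scores)
  expect_equal(attr(h, "n_unassigned"), 1L)  # the unknown-charge spectrum
  expect_equal(h$bins$n_spectra, c(2L, 1L))
  expect_equal(h$bins$spectra[[2]]$id, "tie")
  # equal-weight mean of snog 0.2 and 0.4 -> 0.3
  expect_equal(h$bins$snog[1], 0.3)
  # intensity weights shift the aggregate
  hw <- attach_spectra(h, sps, scores, weights = c(1, 3, 1, 1))
  expect_equal(hw$bins$snog[1], (0.2 * 3 + 0.4 * 1) / 4)
  # max aggregation available
  hm <- attach_spectra(h, sps, scores, aggregate = "max")
  expect_equal(hm$bins$snog[1], 0.4)
})

test_that("snog_filter drops no-evidence and low-score bins", {
  cfg <- run_config()
  f <- data.frame(mass = c(1237.5, 1155.4, 1444.4), rt = 1:3,
                  intensity = c(1e7, 2e7, 6e6), sample = "s")
  h <- bin_features(f, cfg)
  sps <- list(
    make_spec(c(204.0867, 224.1118), c(50, 50), id = "gly",
              precursor_mz = 1237.5, charge = 1L),
    # hexose-oligomer contaminant: no reporter -> snog 0
    make_spec(c(163.0601, 325.1129), c(80, 20), id = "cont",
              precursor_mz = 1155.4, charge = 1L))
  h <- attach_spectra(h, sps, score_spectra(sps))
  hf <- snog_filter(h, 0.03)
  expect_equal(hf$bins$center, 1237.5)       # contaminant + no-evidence gone
  expect_equal(attr(hf, "n_rejected"), 2L)
  expect_equal(hf$tic, 1e7)
})

test_that("tic_normalize scales to unit sum and is idempotent", {
  cfg <- run_config()
  f <- data.frame(mass = c(1500.0, 1600.0), rt = 1:2,
                  intensity = c(6e6, 1.4e7), sample = "s")
  h <- bin_features(f, cfg)
  hn <- tic_normalize(h)
  expect_equal(hn$bins$intensity, c(0.3, 0.7))
  expect_equal(sum(hn$bins$intensity), 1)
  expect_equal(tic_normalize(hn)$bins$intensity, hn$bins$intensity)
  h0 <- h; h0$bins <- h0$bins[0, ]; h0$tic <- 0
  expect_error(tic_normalize(h0), "TIC")
})
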