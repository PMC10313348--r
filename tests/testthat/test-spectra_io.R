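test_that("spectrum constructor enforces peak invariants", {
  s <- spectrum(c(300, 100, 100, 200), c(1, 2, 3, 0), precursor_mz = 400,
                charge = 2L, ion_label = c("y2", NA, "b1", "b2"))
  # sorted ascending, exact ties merged by summation, zero intensity dropped
  expect_equal(s$peaks$mz, c(100, 300))
  expect_equal(s$peaks$intensity, c(5, 1))
  expect_equal(s$peaks$ion_label, c("b1", "y2"))
  expect_error(spectrum(-1, 1), "positive")
  expect_error(spectrum(100, -1), "non-negative")
})

test_that("MSP round trip preserves spectra field by field", {
  fx <- lapply(1:5, function(i) toy_predict(c("PEPTIDEK", "ACDEFGHIK",
                                              "LMNPQRSTK", "VWYAGDEKR",
                                              "GGSSTTKLM")[[i]], 2L))
  path <- withr::local_tempfile(fileext = ".msp")
  write_msp(fx, path)
  back <- read_msp(path)
  expect_length(back, 5L)
  for (i in seq_along(fx)) {
    expect_equal(back[[i]]$peptide, fx[[i]]$peptide)
    expect_equal(back[[i]]$charge, fx[[i]]$charge)
    expect_equal(back[[i]]$precursor_mz, fx[[i]]$precursor_mz, tolerance = 1e-6)
    expect_equal(back[[i]]$peaks$mz, fx[[i]]$peaks$mz, tolerance = 1e-4)
    expect_equal(back[[i]]$peaks$intensity, fx[[i]]$peaks$intensity,
                 tolerance = 1e-6)
    expect_equal(back[[i]]$peaks$ion_label, fx[[i]]$peaks$ion_label)
  }
})

test_that("MSP parser handles annotations, decoy prefixes and empty files", {
  path <- withr::local_tempfile(fileext = ".msp")
  writeLines(c("Name: DECOY_ACDEFGHK/2",
               "PrecursorMZ: 500.25",
               "Num peaks: 2",
               "100.5\t10.0\ty3/0.01",
               "200.5\t20.0"), path)
  s <- read_msp(path)[[1L]]
  expect_true(s$is_decoy)
  expect_equal(s$peptide, "ACDEFGHK")
  expect_equal(s$peaks$ion_label, c("y3", NA))
  # file-level decoy flag is the primary convention
  writeLines(c("Name: ACDEFGHK/2", "PrecursorMZ: 500.25", "Num peaks: 1",
               "100.5 1.0"), path)
  expect_true(read_msp(path, is_decoy = TRUE)[[1L]]$is_decoy)
  writeLines(character(0), path)
  expect_length(read_msp(path), 0L)
})

test_that("malformed or truncated MSP records raise informative errors", {
  path <- withr::local_tempfile(fileext = ".msp")
  writeLines(c("Name: ACDEFGHK/2", "PrecursorMZ: 500.25", "Num peaks: 3",
               "100.5 1.0"), path)
  expect_error(read_msp(path), "truncated final record")
  writeLines(c("Name: ACDEFGHK/2", "PrecursorMZ: 500.25", "Num peaks: 1",
               "oops not_numbers"), path)
  expect_error(read_msp(path), "record 1")
})

test_that("MGF parser follows the stated conventions", {
  path <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "TITLE=scan_1", "PEPMASS=450.12", "CHARGE=2+",
               "100.1 5", "END IONS",
               "BEGIN IONS", "TITLE=scan_2", "PEPMASS=460.0",
               "100.2 6", "END IONS"), path)
  qs <- read_mgf(path)
  expect_length(qs, 2L)
  expect_equal(qs[[1L]]$charge, 2L)
  expect_equal(qs[[2L]]$charge, 0L)        # absent CHARGE -> unknown
  expect_equal(vapply(qs, function(q) q$native_id, ""), c("scan_1", "scan_2"))
  writeLines(c("BEGIN IONS", "TITLE=x", "100 1", "END IONS"), path)
  expect_error(read_mgf(path), "PEPMASS")
  writeLines(c("BEGIN IONS", "BEGIN IONS", "END IONS"), path)
  expect_error(read_mgf(path), "nested")
})

test_that("MGF round trip preserves queries", {
  fx <- small_fixture()
  path <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(fx$queries[1:5], path)
  back <- read_mgf(path)
  expect_length(back, 5L)
  for (i in 1:5) {
    expect_equal(back[[i]]$native_id, fx$queries[[i]]$native_id)
    expect_equal(back[[i]]$peaks$mz, fx$queries[[i]]$peaks$mz, tolerance = 1e-4)
  }
})

test_that("preprocess sqrt-transforms and unit-normalizes", {
  expect_equal(preprocess(toy_spectrum(100, 100))$peaks$intensity, 1.0)
  s <- preprocess(toy_spectrum(c(100, 200), c(9, 16)))
  expect_equal(s$peaks$intensity, c(3 / 5, 4 / 5))
  s <- preprocess(toy_spectrum(c(1, 2, 3, 4) * 100, rep(7, 4)))
  expect_equal(s$peaks$intensity, rep(0.5, 4))
  # norm-1 property over random spectra
  set.seed(11)
  for (i in 1:20) {
    s <- random_spectrum(sample(5:60, 1))
    expect_equal(sum(s$peaks$intensity^2), 1, tolerance = 1e-9)
  }
  expect_error(preprocess(spectrum(numeric(0), numeric(0))),
               "empty spectrum")
})

test_that("top-k window denoising keeps the k most intense peaks per window", {
  s <- toy_spectrum(c(50, 60, 150), c(5, 9, 2))
  d <- denoise_top_k_window(s, k = 1, w = 100)
  expect_equal(d$peaks$mz, c(60, 150))
  # k >= peaks per window is the identity; single peak unchanged
  expect_equal(denoise_top_k_window(s, k = 5, w = 100)$peaks, s$peaks)
  one <- toy_spectrum(123, 4)
  expect_equal(denoise_top_k_window(one, 1, 10)$peaks, one$peaks)
  # never increases peak count and is idempotent
  set.seed(5)
  for (i in 1:10) {
    s <- random_spectrum(40)
    d <- denoise_top_k_window(s, k = 3, w = 50)
    expect_lte(nrow(d$peaks), nrow(s$peaks))
    expect_equal(denoise_top_k_window(d, k = 3, w = 50)$peaks, d$peaks)
  }
})

test_that("ppm tolerance converts linearly to Da", {
  expect_equal(ppm_to_da(10, 1500), 0.015)
  expect_equal(ppm_to_da(0, 700), 0)
  expect_equal(ppm_to_da(10, 500), 0.005)
})
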