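# Shared test fixtures, built in code and memoised so only the tests that
# need the expensive artifacts pay for them.

.fx_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fx_cache)) assign(key, force(expr), envir = .fx_cache)
  get(key, envir = .fx_cache)
}

# a tiny deterministic spectrum with well-separated peaks
toy_spectrum <- function(mz = c(100, 300, 500, 700), int = (seq_along(mz) + 1)^2,
                         pmz = 450, charge = 2L, peptide = "PEPTIDEK",
                         ...) {
  spectrum(mz, int, native_id = paste0(peptide, "/", charge),
           precursor_mz = pmz, charge = charge, peptide = peptide, ...)
}

# random unit-norm spectra for scoring property tests
random_spectrum <- function(n_peaks, mz_range = c(100, 1800)) {
  mz <- sort(stats::runif(n_peaks, mz_range[[1L]], mz_range[[2L]]))
  preprocess(spectrum(mz, stats::runif(n_peaks, 0.1, 100),
                      precursor_mz = 500, charge = 2L, peptide = "TESTPEPK"))
}

# small fixture shared by module tests
small_fixture <- function() memo("small_fx", {
  generate_fixture(fixture_config(seed = 2024L, n_target_spectra = 300L,
                                  n_queries = 80L))
})

small_target_index <- function(n_partitions = 4L) {
  memo(paste0("small_idx_", n_partitions), {
    dir <- file.path(tempdir(), paste0("fragidx_small_", n_partitions))
    build_index(small_fixture()$target,
                index_config(n_partitions = n_partitions), dir)
    dir
  })
}

# the default study-condition fixture (2000 target + 2000 decoy spectra,
# 500 queries, moderate noise) used by the acceptance tests
default_fixture <- function() memo("default_fx", {
  generate_fixture(fixture_config(seed = 7L))
})

default_index <- function(n_partitions = 64L, what = c("target", "decoy")) {
  what <- match.arg(what)
  memo(sprintf("default_idx_%s_%d", what, n_partitions), {
    dir <- file.path(tempdir(), sprintf("fragidx_default_%s_%d", what,
                                        n_partitions))
    build_index(default_fixture()[[what]],
                index_config(n_partitions = n_partitions), dir)
    dir
  })
}

# linear-scan reference for candidate_window
window_linear_oracle <- function(pi, charge, query_mz, tol_da) {
  hit <- (pi$charge_by_rank == charge) &
    abs(pi$pmz_by_rank - query_mz) <= tol_da
  which(hit)
}
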