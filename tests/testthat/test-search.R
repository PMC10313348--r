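test_that("queries are scheduled to every intersecting partition", {
  boundaries <- c(500, 600)
  q_at <- function(pmz) toy_spectrum(pmz = pmz, charge = 2L)
  # boundary query with nonzero tolerance lands in both adjacent partitions
  s <- schedule(list(q_at(500)), boundaries, tol_ppm = 10)
  expect_equal(s[[1L]], c(1L, 2L))
  # zero tolerance, interior query: exactly one partition
  s <- schedule(list(q_at(550)), boundaries, tol_ppm = 0)
  expect_equal(s[[1L]], 2L)
  # query below every library precursor: scheduled nowhere
  s <- schedule(list(q_at(300)), boundaries, tol_ppm = 10,
                pmz_range = c(450, 700))
  expect_length(s[[1L]], 0L)
})

test_that("candidate windows agree with a linear scan", {
  fx <- small_fixture()
  pi <- build_precursor_index(fx$target)
  set.seed(21)
  for (i in 1:50) {
    z <- sample(2:4, 1)
    mz <- runif(1, 400, 1500)
    tol <- runif(1, 0, 0.5)
    w <- candidate_window(pi, z, mz, tol)
    got <- if (nrow(w) && w[[1, "hi"]] > w[[1, "lo"]])
      w[[1, "lo"]]:(w[[1, "hi"]] - 1L) else integer(0)
    expect_equal(got, window_linear_oracle(pi, z, mz, tol))
  }
  # explicit cases
  lib <- lapply(c(400, 500, 600), function(m)
    toy_spectrum(pmz = m, charge = 2L, peptide = sprintf("P%dK", m)))
  pi3 <- build_precursor_index(lib)
  w <- candidate_window(pi3, 2L, 500, 0.015)
  expect_equal(w[[1, "hi"]] - w[[1, "lo"]], 1L)
  expect_equal(pi3$ranked_ids[[w[[1, "lo"]]]], 1L)
  w <- candidate_window(pi3, 2L, 500, 1000)       # spans the whole block
  expect_equal(c(w[[1, "lo"]], w[[1, "hi"]]), c(1L, 4L))
  w <- candidate_window(pi3, 5L, 500, 10)         # absent charge
  expect_equal(nrow(w), 0L)
})

test_that("index accumulation equals the brute-force binned dot product", {
  fx <- small_fixture()
  lib <- fx$target[1:20]
  dir <- withr::local_tempdir()
  build_index(lib, index_config(n_partitions = 1L), dir)
  pi <- load_precursor_index(dir)
  part <- load_partition(dir, 1L, pi)
  prep <- lapply(lib, preprocess)
  # the brute-force oracle sums intensity products over shared bins, over the
  # indexed fragment m/z range
  in_range <- function(s) {
    s$peaks <- s$peaks[s$peaks$mz < 2000, , drop = FALSE]
    s
  }
  # a spectrum fully inside the range accumulates its unit self dot product
  self_i <- which(vapply(prep, function(s) max(s$peaks$mz) < 2000, NA))[[1L]]
  acc <- accumulate(prep[[self_i]], part, c(1L, length(lib) + 1L), 0.2)
  expect_equal(acc[[pi$rank_of[[self_i]]]], 1.0, tolerance = 1e-6)
  # full window accumulator equals binned_dot for every candidate
  set.seed(31)
  queries <- perturb_queries(lib[sample(20, 8)], fx$cfg)
  for (q in lapply(queries, preprocess)) {
    acc <- accumulate(q, part, c(1L, length(lib) + 1L), 0.2)
    expect_gte(min(acc), 0)
    expect_lte(max(acc), 1 + 1e-6)
    for (id in 0:19) {
      expect_equal(acc[[pi$rank_of[[id + 1L]]]],
                   binned_dot(q, in_range(prep[[id + 1L]]), 0.2),
                   tolerance = 1e-6)
    }
  }
  # no shared bins -> all-zero accumulator
  far <- preprocess(toy_spectrum(c(1900, 1950), c(1, 1), pmz = 500))
  expect_equal(accumulate(far, part, c(1L, 21L), 0.2), rep(0, 20))
})

test_that("self-search returns every library spectrum as its own rank-1", {
  fx <- small_fixture()
  dir <- small_target_index(4L)
  psms <- search_run(fx$target[seq(1, 300, by = 6)], dir, search_params())
  top <- psms[psms$rank == 1L, ]
  expect_equal(nrow(top), 50L)
  expect_equal(top$library_id, seq(0L, 299L, by = 6L))
  expect_equal(top$final_score,
               vapply(fx$target[seq(1, 300, by = 6)], function(s) {
                 sp <- preprocess(s)
                 score_pair(sp, sp, scoring_params(0.2), 0.2)[["final_score"]]
               }, 0), tolerance = 1e-9)
})

test_that("top-X output is capped by the candidate count with contiguous ranks", {
  lib <- lapply(c(500.000, 500.002, 500.004, 700), function(m)
    toy_spectrum(mz = c(100, 200, 300) + m / 10, pmz = m, charge = 2L,
                 peptide = sprintf("PEP%.3fK", m)))
  dir <- withr::local_tempdir()
  build_index(lib, index_config(n_partitions = 1L), dir)
  psms <- search_run(list(toy_spectrum(mz = c(150, 250, 350), pmz = 500.001,
                                       charge = 2L)),
                     dir, search_params(top_x = 5L))
  expect_equal(psms$rank, 1:3)                  # only 3 in-tolerance candidates
  expect_equal(sort(psms$library_id), 0:2)
})

test_that("searching with a mismatched bin width is refused", {
  dir <- small_target_index(4L)
  expect_error(search_run(small_fixture()$queries[1:2], dir,
                          search_params(bin_width = 0.5)),
               "bin width mismatch")
})

test_that("queries without candidates yield an explicit marker row", {
  dir <- small_target_index(4L)
  q <- toy_spectrum(pmz = 399, charge = 2L)     # below the library range
  psms <- search_run(list(q), dir, search_params())
  expect_equal(nrow(psms), 1L)
  expect_equal(psms$rank, 0L)
  expect_true(is.na(psms$library_id))
})

test_that("indexed search equals exhaustive scoring on perturbed queries", {
  fx <- small_fixture()
  dir <- small_target_index(4L)
  params <- search_params(n_rescore = Inf)
  psms <- search_run(fx$queries, dir, params)
  prep_lib <- lapply(fx$target, preprocess)
  for (qi in seq_along(fx$queries)) {
    got <- psms[psms$query_id == qi & psms$rank == 1L, ]
    want <- oracle_search(preprocess(fx$queries[[qi]]), prep_lib, params,
                          B = 0.2, preprocessed = TRUE)
    want <- want[want$rank == 1L, ]
    if (nrow(want) == 0L || is.na(want$library_id)) {
      expect_true(nrow(got) == 0L || is.na(got$library_id))
    } else {
      expect_equal(got$library_id, want$library_id)
      expect_equal(got$final_score, want$final_score, tolerance = 1e-6)
    }
  }
})

test_that("search results are independent of partitioning and repeatable", {
  fx <- small_fixture()
  qs <- fx$queries[1:40]
  runs <- lapply(c(1L, 4L, 16L), function(np)
    search_run(qs, small_target_index(np), search_params(n_rescore = Inf)))
  expect_equal(runs[[2L]]$library_id, runs[[1L]]$library_id)
  expect_equal(runs[[3L]]$library_id, runs[[1L]]$library_id)
  expect_equal(runs[[2L]]$final_score, runs[[1L]]$final_score, tolerance = 1e-6)
  expect_equal(runs[[3L]]$final_score, runs[[1L]]$final_score, tolerance = 1e-6)
  # byte-level determinism of the emitted PSM table
  again <- search_run(qs, small_target_index(4L), search_params(n_rescore = Inf))
  expect_identical(runs[[2L]], again)
})

test_that("oracle search handles degenerate inputs", {
  q <- toy_spectrum(pmz = 500, charge = 2L)
  expect_equal(oracle_search(q, list(), search_params())$rank, 0L)
  lib <- list(toy_spectrum(mz = c(900, 1000), pmz = 500.001, charge = 2L,
                           peptide = "AAAAAAK"))
  got <- oracle_search(q, lib, search_params())
  expect_equal(got$rank, 1L)                    # single candidate is rank-1
  expect_equal(got$library_id, 0L)
})
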