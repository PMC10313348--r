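test_that("precursor index orders by (charge, m/z) with exact inverse", {
  lib <- list(toy_spectrum(pmz = 500, charge = 2L, peptide = "AAAAAAK"),
              toy_spectrum(pmz = 400, charge = 2L, peptide = "CCCCCCK"),
              toy_spectrum(pmz = 300, charge = 3L, peptide = "DDDDDDK"))
  pi <- build_precursor_index(lib)
  expect_equal(pi$ranked_ids, c(1L, 0L, 2L))
  expect_equal(pi$rank_of[pi$ranked_ids + 1L], seq_along(pi$ranked_ids))
  one <- build_precursor_index(lib[1L])
  expect_equal(one$ranked_ids, 0L)
  expect_equal(one$rank_of, 1L)
  expect_error(build_precursor_index(list()), "empty library")
  # permutation property on a larger random library
  set.seed(9)
  rec <- data.frame(charge = sample(2:4, 1000, TRUE),
                    precursor_mz = runif(1000, 400, 1500),
                    peptide = sprintf("PEP%04dK", 1:1000),
                    is_decoy = FALSE, native_id = sprintf("s%04d", 1:1000))
  pi <- build_precursor_index(rec)
  expect_equal(pi$rank_of[pi$ranked_ids + 1L], 1:1000)
  # within each charge block, m/z non-decreasing
  expect_true(all(tapply(pi$pmz_by_rank, pi$charge_by_rank,
                         function(x) !is.unsorted(x))))
})

test_that("fragment bins follow the half-open convention", {
  expect_equal(bin_of(500.05, 0.2), 2500L)
  expect_equal(bin_of(500.2, 0.2), 2501L)
  expect_equal(bin_of(0, 0.2), 0L)
})

test_that("partition boundaries split precursors into near-equal counts", {
  mk <- function(pmz) build_precursor_index(
    data.frame(charge = 2L, precursor_mz = pmz,
               peptide = sprintf("P%dK", seq_along(pmz)), is_decoy = FALSE,
               native_id = sprintf("s%d", seq_along(pmz))))
  expect_equal(make_partition_boundaries(mk(c(400, 800)), 1), numeric(0))
  b <- make_partition_boundaries(mk(c(400, 500, 600, 700)), 2)
  expect_length(b, 1L)
  expect_true(b > 500 && b <= 600)
  expect_equal(as.integer(table(partition_of(c(400, 500, 600, 700), b))),
               c(2L, 2L))
  expect_warning(b4 <- make_partition_boundaries(mk(rep(555, 6)), 4),
                 "non-empty partitions")
  expect_length(b4, 0L)
})

test_that("index build conserves fragments and is partition-invariant", {
  fx <- small_fixture()
  lib <- fx$target[1:50]
  n_peaks <- sum(vapply(lib, function(s) {
    p <- preprocess(s)$peaks
    sum(p$mz >= 0 & p$mz < 2000)         # the indexed m/z range
  }, 0L))
  d1 <- withr::local_tempdir()
  d8 <- withr::local_tempdir()
  m1 <- build_index(lib, index_config(n_partitions = 1L), d1)
  m8 <- build_index(lib, index_config(n_partitions = 8L), d8)
  expect_equal(m1$n_fragments, n_peaks)
  expect_equal(m8$n_fragments, n_peaks)
  # multiset of (bin, parent, mz, intensity) identical across partitionings
  gather <- function(dir) {
    man <- read_manifest(dir)
    pi <- load_precursor_index(dir)
    ent <- do.call(rbind, lapply(man$partitions$pid, function(pid) {
      p <- load_partition(dir, pid, pi)
      bins <- rep(seq_len(p$n_bins) - 1L + p$bin0, p$bin_counts)
      data.frame(bin = bins, parent = p$parent, mz = p$mz,
                 intensity = p$intensity)
    }))
    ent[order(ent$bin, ent$parent, ent$mz), , drop = FALSE]
  }
  e1 <- gather(d1); e8 <- gather(d8)
  rownames(e1) <- rownames(e8) <- NULL
  expect_equal(e8, e1)
})

test_that("bins are parent-rank sorted and partitions own their precursors", {
  dir <- small_target_index(4L)
  pi <- load_precursor_index(dir)
  man <- read_manifest(dir)
  for (pid in man$partitions$pid) {
    p <- load_partition(dir, pid, pi)
    off <- p$bin_offsets
    for (b in which(p$bin_counts > 0L)) {
      r <- p$rank[(off[[b]] + 1L):(off[[b + 1L]])]
      expect_false(is.unsorted(r))
    }
    pmz <- pi$records$precursor_mz[p$parent + 1L]
    expect_true(all(pmz >= p$precursor_interval[[1L]] &
                      pmz < p$precursor_interval[[2L]]))
    # every parent id resolves through rank_of to a consistent record
    expect_equal(pi$ranked_ids[p$rank], p$parent)
  }
})

test_that("empty partitions are valid and searchable", {
  lib <- list(toy_spectrum(pmz = 500, charge = 2L, peptide = "AAAAAAK"),
              toy_spectrum(pmz = 501, charge = 2L, peptide = "CCCCCCK"))
  dir <- withr::local_tempdir()
  build_index(lib, index_config(partition_boundaries = c(450, 499)), dir)
  p <- load_partition(dir, 1L)            # interval [0, 450): no precursors
  expect_equal(sum(p$bin_counts), 0L)
  q <- preprocess(toy_spectrum(pmz = 400, charge = 2L, peptide = "AAAAAAK"))
  expect_equal(accumulate(q, p, c(1L, 3L), 0.2), c(0, 0))
})

test_that("partition files round-trip byte-identically and verify checksums", {
  dir <- small_target_index(4L)
  man <- read_manifest(dir)
  row <- man$partitions[2L, ]
  src <- file.path(dir, row$frag_file)
  p <- fragidx:::read_partition_file(src)
  copy <- withr::local_tempfile(fileext = ".frag")
  bins <- rep(seq_len(p$n_bins) - 1L + p$bin0, p$bin_counts)
  fragidx:::write_partition_file(copy, p$pid, p$bin0, p$n_bins, bin = bins,
                                 mz = p$mz, intensity = p$intensity,
                                 parent = p$parent, label = p$label)
  expect_identical(unname(tools::md5sum(copy)), unname(tools::md5sum(src)))
  expect_error(load_partition(dir, 999L), "out of range")
  # corruption is detected
  dir2 <- withr::local_tempdir()
  file.copy(list.files(dir, full.names = TRUE), dir2)
  con <- file(file.path(dir2, row$frag_file), "r+b")
  seek(con, 40L, rw = "write"); writeBin(as.raw(255L), con); close(con)
  expect_error(load_partition(dir2, row$pid), "checksum mismatch")
})

test_that("duplicate target native ids abort the build", {
  lib <- list(toy_spectrum(pmz = 500, charge = 2L, peptide = "AAAAAAK"),
              toy_spectrum(pmz = 600, charge = 2L, peptide = "AAAAAAK"))
  expect_error(build_index(lib, index_config(n_partitions = 1L),
                           withr::local_tempdir()),
               "duplicate native ids")
})

test_that("partitioning bounds the memory needed per loaded partition", {
  fx <- small_fixture()
  d1 <- withr::local_tempdir(); d64 <- withr::local_tempdir()
  build_index(fx$target, index_config(n_partitions = 1L), d1)
  build_index(fx$target, index_config(n_partitions = 64L), d64)
  size1 <- max(file.info(list.files(d1, "\\.frag$", full.names = TRUE))$size)
  size64 <- max(file.info(list.files(d64, "\\.frag$", full.names = TRUE))$size)
  # the largest partition a search must hold is far below the full index
  expect_lt(size64 - 40000, size1 / 4)  # header/bin-count overhead excluded
})
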