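## Partitioned fragment-ion index.
##
## The index has two parts. The precursor index ranks every library spectrum
## by (charge, precursor m/z) and keeps the inverse id -> rank permutation,
## so a precursor-tolerance window becomes a contiguous rank interval found
## by binary search. The fragment index stores every (preprocessed) peak as
## a triplet (m/z, intensity, parent id) inside half-open m/z bins of width
## B; within a bin entries are sorted by parent rank, so the entries hit by
## one query peak and one candidate window form a contiguous run amenable to
## a batch multiply-add.
##
## The fragment index is split into partitions tied to non-overlapping
## precursor m/z intervals (equal-count quantile split): each partition is a
## complete, independently loadable fragment index over the library subset
## whose precursors fall inside its interval, which bounds the memory needed
## at search time by the largest partition rather than the whole library.

FRAG_MAGIC <- "FIDX"
SPEC_MAGIC <- "FSPC"
INDEX_FORMAT_VERSION <- 1L

#' Index configuration
#'
#' @param bin_width_da fragment bin width B in Da (default 0.2).
#' @param n_partitions number of precursor m/z partitions (default 64).
#' @param mz_min,mz_max indexed fragment m/z range (half-open, default
#'   \[0, 2000) Da); fragments outside are dropped and counted.
#' @param partition_boundaries optional sorted vector of inner precursor m/z
#'   cut points; when `NULL` they are placed at precursor quantiles during
#'   the build.
#' @return A list of class `index_config`.
#' @export
index_config <- function(bin_width_da = 0.2, n_partitions = 64L,
                         mz_min = 0, mz_max = 2000,
                         partition_boundaries = NULL) {
  stopifnot(bin_width_da > 0, n_partitions >= 1L, mz_max > mz_min, mz_min >= 0)
  if (!is.null(partition_boundaries)) {
    partition_boundaries <- as.numeric(partition_boundaries)
    if (is.unsorted(partition_boundaries, strictly = TRUE))
      stop("partition_boundaries must be strictly increasing")
  }
  structure(list(bin_width_da = bin_width_da,
                 n_partitions = as.integer(n_partitions),
                 mz_min = mz_min, mz_max = mz_max,
                 partition_boundaries = partition_boundaries),
            class = "index_config")
}

#' Fragment bin index of an m/z value
#'
#' Bins are half-open: a fragment at exactly a bin boundary belongs to the
#' upper bin.
#'
#' @param mz m/z value(s) in Thomson (>= 0).
#' @param B bin width in Da (> 0).
#' @return Integer bin index `floor(mz / B)`.
#' @export
bin_of <- function(mz, B) {
  stopifnot(all(mz >= 0), B > 0)
  as.integer(floor(mz / B))
}

#' Build a precursor index from library spectra
#'
#' Ids are assigned densely in stream order (0..N-1); ranks order the ids by
#' (charge, precursor m/z), ties broken by id for determinism, and `rank_of`
#' is the exact inverse permutation (`rank_of[ranked_ids[r] + 1] == r`).
#'
#' @param library list of library [spectrum()] objects, or a data.frame with
#'   columns `charge`, `precursor_mz`, `peptide`, `is_decoy`, `native_id`.
#' @return A list of class `precursor_index` with elements `records`
#'   (per-id data.frame), `ranked_ids` (0-based ids in rank order),
#'   `rank_of` (1-based ranks indexed by id + 1) and per-charge block
#'   bounds used for candidate windows.
#' @export
build_precursor_index <- function(library) {
  rec <- if (is.data.frame(library)) library else {
    if (!length(library)) stop("empty library")
    data.frame(
      charge = vapply(library, function(s) s$charge, 0L),
      precursor_mz = vapply(library, function(s) s$precursor_mz, 0),
      peptide = vapply(library, function(s) s$peptide, ""),
      is_decoy = vapply(library, function(s) s$is_decoy, FALSE),
      native_id = vapply(library, function(s) s$native_id, ""),
      stringsAsFactors = FALSE)
  }
  if (!nrow(rec)) stop("empty library")
  rec$id <- seq_len(nrow(rec)) - 1L
  o <- order(rec$charge, rec$precursor_mz, rec$id)
  ranked_ids <- rec$id[o]
  rank_of <- integer(nrow(rec))
  rank_of[ranked_ids + 1L] <- seq_along(ranked_ids)   # linear-scan inverse
  charge_r <- rec$charge[o]
  charges <- unique(charge_r)
  blocks <- data.frame(
    charge = charges,
    start = match(charges, charge_r),
    end = length(charge_r) - match(charges, rev(charge_r)) + 1L)
  structure(list(records = rec, ranked_ids = ranked_ids, rank_of = rank_of,
                 pmz_by_rank = rec$precursor_mz[o],
                 charge_by_rank = charge_r,
                 blocks = blocks),
            class = "precursor_index")
}

#' Equal-count partition boundaries from a precursor index
#'
#' Places `n - 1` inner cut points at precursor m/z quantiles so the
#' resulting half-open intervals (first starting at 0, last unbounded) hold
#' near-equal spectrum counts. If fewer than `n` distinct precursor m/z
#' values exist, fewer non-empty partitions are produced with a warning.
#'
#' @param pi a [build_precursor_index()] result.
#' @param n requested partition count (>= 1).
#' @return Numeric vector of inner boundaries (length `n_effective - 1`,
#'   possibly empty).
#' @export
make_partition_boundaries <- function(pi, n) {
  stopifnot(inherits(pi, "precursor_index"), n >= 1)
  if (n == 1) return(numeric(0))
  pmz <- sort(pi$records$precursor_mz)
  N <- length(pmz)
  idx <- floor(seq_len(n - 1) * N / n) + 1L
  b <- pmz[pmin(idx, N)]
  b <- b[b > pmz[[1L]]]           # a cut at/below the minimum splits nothing
  b <- unique(b)
  if (length(b) < n - 1)
    warning(sprintf("only %d non-empty partitions possible (requested %d)",
                    length(b) + 1L, n))
  b
}

#' Partition id of a precursor m/z
#'
#' @param pmz precursor m/z value(s).
#' @param boundaries inner cut points from [make_partition_boundaries()].
#' @return 1-based partition id(s).
#' @export
partition_of <- function(pmz, boundaries) {
  findInterval(pmz, boundaries) + 1L
}

ion_series_code <- function(label) {
  out <- integer(length(label))
  out[!is.na(label) & startsWith(label, "b")] <- 1L
  out[!is.na(label) & startsWith(label, "y")] <- 2L
  out
}

code_to_label <- function(code) {
  c(NA_character_, "b", "y")[code + 1L]
}

# iterate a library source: list of Spectrum, or file path(s) (.msp/.mgf)
stream_library <- function(src, handler, is_decoy = FALSE) {
  if (is.list(src)) {
    for (s in src) handler(s)
    return(invisible(length(src)))
  }
  n <- 0L
  for (path in src) {
    n <- n + if (grepl("\\.mgf$", path, ignore.case = TRUE))
      stream_mgf(path, handler, is_decoy = is_decoy)
    else
      stream_msp(path, handler, is_decoy = is_decoy)
  }
  invisible(n)
}

#' Build the partitioned fragment index on disk
#'
#' Two-phase, memory-bounded construction. Pass A streams the library
#' collecting only precursor records, fixes the precursor index and the
#' partition boundaries. Pass B streams the library again: each spectrum is
#' preprocessed ([preprocess()]), its in-range fragments are appended to the
#' spill file of the partition owning its precursor, and its full-precision
#' peaks are appended to that partition's spectra sidecar. The finalize step
#' rewrites every spill with each bin's entries sorted by parent rank. Peak
#' working memory is bounded by the largest single partition plus the
#' precursor index, never by total library size.
#'
#' @param library library source: list of [spectrum()] objects or path(s) to
#'   `.msp`/`.mgf` files.
#' @param cfg an [index_config()].
#' @param out_dir output directory (created if missing).
#' @param decoy_library optional second source whose spectra are flagged as
#'   decoys.
#' @return Invisibly, the manifest (also written as `manifest.json`).
#' @export
build_index <- function(library, cfg = index_config(), out_dir,
                        decoy_library = NULL) {
  stopifnot(inherits(cfg, "index_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2L) != 0L) stop("output directory not writable: ", out_dir)

  ## ---- pass A: precursor records only --------------------------------
  acc <- new.env(parent = emptyenv())
  acc$charge <- integer(0); acc$pmz <- numeric(0); acc$pep <- character(0)
  acc$dec <- logical(0); acc$nid <- character(0)
  take <- function(decoy_src) function(s) {
    if (is.na(s$peptide)) stop("library spectrum without peptide: ", s$native_id)
    acc$charge <- c(acc$charge, s$charge)
    acc$pmz <- c(acc$pmz, s$precursor_mz)
    acc$pep <- c(acc$pep, s$peptide)
    acc$dec <- c(acc$dec, s$is_decoy || decoy_src)
    acc$nid <- c(acc$nid, s$native_id)
  }
  stream_library(library, take(FALSE))
  if (!is.null(decoy_library)) stream_library(decoy_library, take(TRUE), is_decoy = TRUE)
  rec <- data.frame(charge = acc$charge, precursor_mz = acc$pmz,
                    peptide = acc$pep, is_decoy = acc$dec,
                    native_id = acc$nid, stringsAsFactors = FALSE)
  if (!nrow(rec)) stop("empty library")
  tgt_ids <- rec$native_id[!rec$is_decoy]
  if (anyDuplicated(tgt_ids))
    stop("duplicate native ids across target library: ",
         tgt_ids[duplicated(tgt_ids)][[1L]])
  pi <- build_precursor_index(rec)
  boundaries <- cfg$partition_boundaries
  if (is.null(boundaries))
    boundaries <- make_partition_boundaries(pi, cfg$n_partitions)
  n_part <- length(boundaries) + 1L
  B <- cfg$bin_width_da
  bin0 <- bin_of(cfg$mz_min, B)
  n_bins <- bin_of(cfg$mz_max - cfg$mz_max * 1e-12, B) - bin0 + 1L

  ## ---- pass B: spill fragments + spectra sidecars per partition ------
  spill_path <- function(pid) file.path(out_dir, sprintf("part_%04d.spill", pid))
  spec_path <- function(pid) file.path(out_dir, sprintf("part_%04d.spec", pid))
  frag_path <- function(pid) file.path(out_dir, sprintf("part_%04d.frag", pid))
  for (pid in seq_len(n_part)) {         # sidecar headers (count patched later)
    con <- file(spec_path(pid), "wb")
    writeChar(SPEC_MAGIC, con, eos = NULL)
    writeBin(c(INDEX_FORMAT_VERSION, pid, 0L), con, size = 4L, endian = "little")
    close(con)
    file.create(spill_path(pid))
  }
  # appends are buffered in small per-partition raw chunks and flushed in
  # batches, so at most a couple of file handles are open at a time and the
  # pending buffer stays small regardless of library size
  buf <- new.env(parent = emptyenv())
  buf$spill <- vector("list", n_part); buf$spec <- vector("list", n_part)
  buf$pending <- 0L
  flush_buffers <- function(force = FALSE) {
    if (!force && buf$pending < 4e6) return(invisible())
    for (pid in seq_len(n_part)) {
      if (length(buf$spill[[pid]])) {
        con <- file(spill_path(pid), "ab")
        writeBin(unlist(buf$spill[[pid]], use.names = FALSE), con)
        close(con)
        buf$spill[[pid]] <- list()
      }
      if (length(buf$spec[[pid]])) {
        con <- file(spec_path(pid), "ab")
        writeBin(unlist(buf$spec[[pid]], use.names = FALSE), con)
        close(con)
        buf$spec[[pid]] <- list()
      }
    }
    buf$pending <- 0L
  }
  n_spec_part <- integer(n_part)
  n_dropped <- 0L
  pb_state <- new.env(parent = emptyenv())
  pb_state$next_id <- 0L
  emit <- function(s) {
    id <- pb_state$next_id
    pb_state$next_id <- id + 1L
    s <- preprocess(s)
    pid <- partition_of(s$precursor_mz, boundaries)
    p <- s$peaks
    lab <- ion_series_code(p$ion_label)
    chunk <- c(writeBin(c(id, nrow(p)), raw(), size = 4L, endian = "little"),
               writeBin(c(s$precursor_mz, p$mz, p$intensity), raw(),
                        size = 8L, endian = "little"),
               as.raw(lab))
    buf$spec[[pid]] <- c(buf$spec[[pid]], list(chunk))
    buf$pending <- buf$pending + length(chunk)
    n_spec_part[[pid]] <<- n_spec_part[[pid]] + 1L
    inr <- p$mz >= cfg$mz_min & p$mz < cfg$mz_max
    n_dropped <<- n_dropped + sum(!inr)
    if (any(inr)) {
      chunk <- c(writeBin(c(id, sum(inr), bin_of(p$mz[inr], B)), raw(),
                          size = 4L, endian = "little"),
                 writeBin(c(p$mz[inr], p$intensity[inr]), raw(),
                          size = 8L, endian = "little"),
                 as.raw(lab[inr]))
      buf$spill[[pid]] <- c(buf$spill[[pid]], list(chunk))
      buf$pending <- buf$pending + length(chunk)
    }
    flush_buffers()
  }
  stream_library(library, emit)
  if (!is.null(decoy_library)) stream_library(decoy_library, emit, is_decoy = TRUE)
  flush_buffers(force = TRUE)
  for (pid in seq_len(n_part)) {         # patch spectrum counts
    con <- file(spec_path(pid), "r+b")
    seek(con, 12L, rw = "write")
    writeBin(n_spec_part[[pid]], con, size = 4L, endian = "little")
    close(con)
  }

  ## ---- finalize: sort each spill by (bin, parent rank), rewrite ------
  n_entries_part <- integer(n_part)
  for (pid in seq_len(n_part)) {
    sp <- read_spill(spill_path(pid))
    file.remove(spill_path(pid))
    o <- order(sp$bin, pi$rank_of[sp$parent + 1L])
    write_partition_file(frag_path(pid), pid, bin0, n_bins,
                         bin = sp$bin[o], mz = sp$mz[o],
                         intensity = sp$intensity[o],
                         parent = sp$parent[o], label = sp$label[o])
    n_entries_part[[pid]] <- length(sp$bin)
  }

  ## ---- precursor table + manifest ------------------------------------
  prec_path <- file.path(out_dir, "precursors.tsv")
  out_rec <- pi$records
  out_rec$precursor_mz <- sprintf("%.17g", out_rec$precursor_mz)
  utils::write.table(out_rec[, c("id", "charge", "precursor_mz", "peptide",
                                 "is_decoy", "native_id")],
                     prec_path, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- data.frame(
    pid = seq_len(n_part),
    frag_file = basename(vapply(seq_len(n_part), frag_path, "")),
    spec_file = basename(vapply(seq_len(n_part), spec_path, "")),
    n_entries = n_entries_part,
    n_spectra = n_spec_part,
    frag_md5 = unname(tools::md5sum(vapply(seq_len(n_part), frag_path, ""))),
    spec_md5 = unname(tools::md5sum(vapply(seq_len(n_part), spec_path, ""))),
    stringsAsFactors = FALSE)
  manifest <- list(
    format_version = INDEX_FORMAT_VERSION,
    bin_width_da = B,
    n_partitions = n_part,
    mz_min = cfg$mz_min, mz_max = cfg$mz_max,
    bin0 = bin0, n_bins = n_bins,
    boundaries = as.numeric(boundaries),
    n_spectra = nrow(rec),
    n_fragments = sum(n_entries_part),
    n_dropped_out_of_range = n_dropped,
    precursor_mz_range = range(rec$precursor_mz),
    precursor_file = "precursors.tsv",
    partitions = files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

read_spill <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  parent <- list(); bin <- list(); mz <- list(); it <- list(); lab <- list()
  i <- 0L
  while (seek(con, where = NA) < sz) {
    i <- i + 1L
    hd <- readBin(con, "integer", 2L, size = 4L, endian = "little")
    n <- hd[[2L]]
    bin[[i]] <- readBin(con, "integer", n, size = 4L, endian = "little")
    mz[[i]] <- readBin(con, "double", n, size = 8L, endian = "little")
    it[[i]] <- readBin(con, "double", n, size = 8L, endian = "little")
    lab[[i]] <- as.integer(readBin(con, "raw", n))
    parent[[i]] <- rep.int(hd[[1L]], n)
  }
  list(parent = as.integer(unlist(parent, use.names = FALSE)),
       bin = as.integer(unlist(bin, use.names = FALSE)),
       mz = as.numeric(unlist(mz, use.names = FALSE)),
       intensity = as.numeric(unlist(it, use.names = FALSE)),
       label = as.integer(unlist(lab, use.names = FALSE)))
}

# final partition file: FIDX, version, pid, bin0, n_bins, n_entries,
# bin_counts[uint32 x n_bins], mz[f32], intensity[f32], parent[uint32],
# label[uint8]; entries in (bin, parent-rank) order, little-endian.
write_partition_file <- function(path, pid, bin0, n_bins, bin, mz, intensity,
                                 parent, label) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(FRAG_MAGIC, con, eos = NULL)
  writeBin(c(INDEX_FORMAT_VERSION, as.integer(pid), as.integer(bin0),
             as.integer(n_bins), length(bin)), con, size = 4L, endian = "little")
  counts <- integer(n_bins)
  if (length(bin)) {
    tb <- table(factor(bin - bin0 + 1L, levels = seq_len(n_bins)))
    counts <- as.integer(tb)
  }
  writeBin(counts, con, size = 4L, endian = "little")
  writeBin(mz, con, size = 4L, endian = "little")
  writeBin(intensity, con, size = 4L, endian = "little")
  writeBin(as.integer(parent), con, size = 4L, endian = "little")
  writeBin(as.raw(label), con)
  invisible(path)
}

read_partition_file <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(magic, FRAG_MAGIC)) stop("corrupt partition file: ", path)
  hd <- readBin(con, "integer", 5L, size = 4L, endian = "little")
  n_bins <- hd[[4L]]; n <- hd[[5L]]
  counts <- readBin(con, "integer", n_bins, size = 4L, endian = "little")
  list(pid = hd[[2L]], bin0 = hd[[3L]], n_bins = n_bins,
       bin_counts = counts,
       mz = readBin(con, "double", n, size = 4L, endian = "little"),
       intensity = readBin(con, "double", n, size = 4L, endian = "little"),
       parent = readBin(con, "integer", n, size = 4L, endian = "little"),
       label = as.integer(readBin(con, "raw", n)))
}

read_spectra_file <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(magic, SPEC_MAGIC)) stop("corrupt spectra file: ", path)
  hd <- readBin(con, "integer", 3L, size = 4L, endian = "little")
  n_spec <- hd[[3L]]
  ids <- integer(n_spec)
  spectra <- vector("list", n_spec)
  for (i in seq_len(n_spec)) {
    h <- readBin(con, "integer", 2L, size = 4L, endian = "little")
    pmz <- readBin(con, "double", 1L, size = 8L, endian = "little")
    mz <- readBin(con, "double", h[[2L]], size = 8L, endian = "little")
    it <- readBin(con, "double", h[[2L]], size = 8L, endian = "little")
    lab <- as.integer(readBin(con, "raw", h[[2L]]))
    ids[[i]] <- h[[1L]]
    spectra[[i]] <- list(precursor_mz = pmz, mz = mz, intensity = it,
                         label = lab)
  }
  list(ids = ids, spectra = spectra)
}

#' Read the index manifest
#'
#' @param index_dir index directory produced by [build_index()].
#' @return The manifest list.
#' @export
read_manifest <- function(index_dir) {
  path <- file.path(index_dir, "manifest.json")
  if (!file.exists(path)) stop("not an index directory (no manifest): ", index_dir)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Load the precursor index of a built index
#'
#' @param index_dir index directory produced by [build_index()].
#' @return A `precursor_index` (see [build_precursor_index()]).
#' @export
load_precursor_index <- function(index_dir) {
  man <- read_manifest(index_dir)
  rec <- utils::read.table(file.path(index_dir, man$precursor_file),
                           header = TRUE, sep = "\t",
                           colClasses = c("integer", "integer", "numeric",
                                          "character", "logical", "character"),
                           quote = "", comment.char = "")
  rec <- rec[order(rec$id), , drop = FALSE]
  build_precursor_index(rec[, c("charge", "precursor_mz", "peptide",
                                "is_decoy", "native_id")])
}

#' Load one index partition into memory
#'
#' Materializes the partition's fragment bins (entries in parent-rank order)
#' together with the full-precision reference spectra owned by the
#' partition. File integrity is verified against the manifest checksums;
#' loading one partition never touches another partition's files.
#'
#' @param index_dir index directory produced by [build_index()].
#' @param pid 1-based partition id.
#' @param pi optional preloaded [load_precursor_index()] result (loaded on
#'   demand when `NULL`) used to attach parent ranks to the entries.
#' @return A list of class `partition`.
#' @export
load_partition <- function(index_dir, pid, pi = NULL) {
  man <- read_manifest(index_dir)
  if (!(pid %in% man$partitions$pid))
    stop("partition id out of range: ", pid)
  row <- man$partitions[man$partitions$pid == pid, ]
  fpath <- file.path(index_dir, row$frag_file)
  spath <- file.path(index_dir, row$spec_file)
  if (!identical(unname(tools::md5sum(fpath)), row$frag_md5))
    stop("checksum mismatch (corrupt partition file): ", fpath)
  if (!identical(unname(tools::md5sum(spath)), row$spec_md5))
    stop("checksum mismatch (corrupt spectra file): ", spath)
  if (is.null(pi)) pi <- load_precursor_index(index_dir)
  frag <- read_partition_file(fpath)
  spec <- read_spectra_file(spath)
  interval <- c(
    if (pid == 1L) 0 else man$boundaries[[pid - 1L]],
    if (pid > length(man$boundaries)) Inf else man$boundaries[[pid]])
  structure(list(
    pid = pid,
    precursor_interval = interval,
    bin0 = frag$bin0, n_bins = frag$n_bins,
    bin_counts = frag$bin_counts,
    bin_offsets = c(0L, cumsum(frag$bin_counts)),
    mz = frag$mz, intensity = frag$intensity,
    parent = frag$parent, label = frag$label,
    rank = pi$rank_of[frag$parent + 1L],
    spectrum_ids = spec$ids,
    spectra = spec$spectra), class = "partition")
}
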