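## Query scheduling, candidate windowing, index accumulation and rescoring.
##
## A query is scheduled to every partition whose precursor interval
## intersects its tolerance window. Within a partition, a binary search on
## the precursor index turns the (charge, m/z +- tol) constraint into a
## contiguous rank window; the fragment index then accumulates the binned
## dot product of the query against every candidate simultaneously: each
## query peak visits exactly one fragment bin, a binary search inside the
## bin isolates the entries whose parent rank falls in the window, and the
## run of intensity products is added to the per-rank accumulator in one
## vectorized multiply-add. The top accumulator candidates are rescored
## with the Gaussian bias-adjusted similarity (see scoring.R), results are
## merged across partitions and the top X matches per query retained.

#' Search parameters
#'
#' @param tol_ppm precursor tolerance in ppm (default 10), applied on m/z.
#' @param bin_width fragment bin width in Da; must equal the bin width the
#'   index was built with (`NULL`, the default, adopts the index value).
#' @param top_x number of output PSMs per query (default 1).
#' @param n_rescore accumulator-ranked candidates rescored per query per
#'   partition (default 50; `Inf` rescores the whole candidate window, which
#'   makes the indexed search exactly equivalent to exhaustive scoring).
#' @param sigma Gaussian spread of the rescoring similarity; defaults to the
#'   index bin width.
#' @param match_cutoff_sigmas truncation radius for peak matching.
#' @param denoise optional `list(k =, w =)` applying [denoise_top_k_window()]
#'   to queries before preprocessing (off by default).
#' @return A list of class `search_params`.
#' @export
search_params <- function(tol_ppm = 10, bin_width = NULL, top_x = 1L,
                          n_rescore = 50, sigma = NULL,
                          match_cutoff_sigmas = 5, denoise = NULL) {
  stopifnot(tol_ppm >= 0, top_x >= 1L, n_rescore >= top_x)
  structure(list(tol_ppm = tol_ppm, bin_width = bin_width,
                 top_x = as.integer(top_x),
                 n_rescore = n_rescore, sigma = sigma,
                 match_cutoff_sigmas = match_cutoff_sigmas,
                 denoise = denoise),
            class = "search_params")
}

#' Schedule queries to index partitions
#'
#' Each query is assigned to every partition whose precursor interval
#' intersects `[precursor_mz - tol, precursor_mz + tol]`; a query exactly at
#' a boundary (with nonzero tolerance) lands in both adjacent partitions.
#' When the library's precursor m/z range is supplied, queries whose window
#' misses it entirely are scheduled nowhere.
#'
#' @param queries list of query [spectrum()] objects.
#' @param boundaries inner partition cut points.
#' @param tol_ppm precursor tolerance in ppm.
#' @param pmz_range optional `c(min, max)` precursor m/z range of the library.
#' @return List (one element per query) of integer partition-id vectors
#'   (possibly empty).
#' @export
schedule <- function(queries, boundaries, tol_ppm, pmz_range = NULL) {
  lapply(queries, function(q) {
    tol <- ppm_to_da(tol_ppm, q$precursor_mz)
    lo <- q$precursor_mz - tol
    hi <- q$precursor_mz + tol
    if (!is.null(pmz_range) && (hi < pmz_range[[1L]] || lo > pmz_range[[2L]]))
      return(integer(0))
    seq.int(findInterval(lo, boundaries) + 1L, findInterval(hi, boundaries) + 1L)
  })
}

#' Candidate rank window for one query
#'
#' Binary search on the precursor index: returns, for each matching charge
#' block, the half-open rank interval `[lo, hi)` of library spectra with
#' that charge and precursor m/z within `tol_da` of `query_mz`. A query
#' charge of 0 ("unknown") searches every charge block.
#'
#' @param pi a [build_precursor_index()] result.
#' @param charge query charge (0 = unknown).
#' @param query_mz query precursor m/z.
#' @param tol_da precursor tolerance in Da.
#' @return Integer matrix with columns `lo`, `hi` (one row per charge
#'   block searched; empty windows have `lo == hi`).
#' @export
candidate_window <- function(pi, charge, query_mz, tol_da) {
  blocks <- pi$blocks
  if (charge > 0L) blocks <- blocks[blocks$charge == charge, , drop = FALSE]
  out <- matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("lo", "hi")))
  for (i in seq_len(nrow(blocks))) {
    bs <- blocks$start[[i]]; be <- blocks$end[[i]]
    pmz <- pi$pmz_by_rank[bs:be]
    lo <- bs + findInterval(query_mz - tol_da, pmz, left.open = TRUE)
    hi <- bs + findInterval(query_mz + tol_da, pmz)
    out <- rbind(out, c(lo, hi))
  }
  out
}

#' Accumulate the binned dot product through a partition
#'
#' For each query peak only the single fragment bin `bin_of(mz, B)` is
#' visited; a binary search inside the bin (entries are parent-rank sorted)
#' isolates the contiguous run with rank in `[lo, hi)` and the intensity
#' products are added to the per-rank accumulator as one batch multiply-add.
#'
#' @param query preprocessed query [spectrum()].
#' @param part a [load_partition()] result.
#' @param win integer vector `c(lo, hi)`: half-open candidate rank window.
#' @param B fragment bin width in Da (must equal the index bin width).
#' @return Numeric accumulator of length `hi - lo` (scores for ranks
#'   `lo .. hi-1`).
#' @export
accumulate <- function(query, part, win, B) {
  lo <- win[[1L]]; hi <- win[[2L]]
  acc <- numeric(max(hi - lo, 0L))
  if (hi <= lo) return(acc)
  qb <- bin_of(query$peaks$mz, B) - part$bin0
  qi <- query$peaks$intensity
  hits <- list(); adds <- list(); nh <- 0L
  for (j in seq_along(qb)) {
    b <- qb[[j]]
    if (b < 0L || b >= part$n_bins) next
    e0 <- part$bin_offsets[[b + 1L]]
    ne <- part$bin_counts[[b + 1L]]
    if (!ne) next
    ranks <- part$rank[(e0 + 1L):(e0 + ne)]
    i1 <- findInterval(lo - 1L, ranks) + 1L
    i2 <- findInterval(hi - 1L, ranks)
    if (i1 > i2) next
    idx <- (e0 + i1):(e0 + i2)
    nh <- nh + 1L
    hits[[nh]] <- part$rank[idx] - lo + 1L
    adds[[nh]] <- qi[[j]] * part$intensity[idx]
  }
  if (nh) {
    # one batched multiply-add; rowsum collapses repeated (peak, entry)
    # contributions to the same parent rank
    agg <- rowsum(unlist(adds, use.names = FALSE),
                  unlist(hits, use.names = FALSE))
    at <- as.integer(rownames(agg))
    acc[at] <- acc[at] + agg[, 1L]
  }
  acc
}

partition_spectrum <- function(part, id, peptide = NA_character_,
                               is_decoy = FALSE, charge = 0L) {
  i <- match(id, part$spectrum_ids)
  sp <- part$spectra[[i]]
  structure(list(native_id = as.character(id),
                 precursor_mz = sp$precursor_mz, charge = charge,
                 peptide = peptide, is_decoy = is_decoy,
                 retention_time = NA_real_,
                 peaks = data.frame(mz = sp$mz, intensity = sp$intensity,
                                    ion_label = code_to_label(sp$label),
                                    stringsAsFactors = FALSE)),
            class = "Spectrum")
}

SCORE_COLS <- c("dot", "similarity", "bias", "bias_adjusted",
                "reflection_similarity", "reflection_bias",
                "reflection_bias_adjusted", "final_score", "log_hyperscore",
                "shared_peak_count", "mz_sd_matched",
                "abs_mass_diff_precursor", "peptide_length")

empty_psm_table <- function() {
  cols <- c(list(query_id = integer(0), title = character(0),
                 library_id = integer(0), peptide = character(0),
                 is_decoy = logical(0), rank = integer(0),
                 index_dot = numeric(0)),
            stats::setNames(rep(list(numeric(0)), length(SCORE_COLS)), SCORE_COLS),
            list(delta_final = numeric(0), f_value = numeric(0)))
  do.call(data.frame, c(cols, stringsAsFactors = FALSE))
}

# rank candidate rows of one query: sort, tie-break, top X, rank-dependent
# features; marker row for queries without candidates.
finalize_query <- function(rows, qid, title, top_x) {
  if (is.null(rows) || !nrow(rows)) {
    out <- empty_psm_table()[NA_integer_, , drop = FALSE][1L, , drop = FALSE]
    out$query_id <- qid; out$title <- title; out$rank <- 0L
    rownames(out) <- NULL
    return(out)
  }
  # best instance per library spectrum (a query scheduled to two partitions
  # is rescored in both; keep the better-scoring instance)
  o <- order(-rows$final_score, -rows$shared_peak_count, rows$library_id)
  rows <- rows[o, , drop = FALSE]
  rows <- rows[!duplicated(rows$library_id), , drop = FALSE]
  rows <- utils::head(rows, top_x)
  rows$rank <- seq_len(nrow(rows))
  d2 <- if (nrow(rows) >= 2L) rows$final_score[[2L]] else 0
  dot2 <- if (nrow(rows) >= 2L) rows$dot[[2L]] else 0
  rows$delta_final <- rows$final_score[[1L]] - d2
  rows$f_value <- f_value(rows$dot[[1L]], dot2)
  rownames(rows) <- NULL
  rows
}

#' Search query spectra against a built index
#'
#' Runs the full indexed search: read/preprocess queries, schedule them to
#' partitions, accumulate binned dot products over candidate windows,
#' rescore the top accumulator candidates with the Gaussian bias-adjusted
#' similarity, merge across partitions and retain the top X matches per
#' query. Queries are processed independently; results do not depend on
#' processing order. Queries with no candidate are reported as an explicit
#' marker row (`rank == 0`, `NA` library id).
#'
#' @param queries path to an MGF file or a list of raw (not preprocessed)
#'   query [spectrum()] objects.
#' @param index_dir index directory from [build_index()].
#' @param params a [search_params()].
#' @return A PSM data.frame: `query_id`, `title`, `library_id`, `peptide`,
#'   `is_decoy`, `rank`, `index_dot` (accumulator score) and the full score
#'   vector (see [score_pair()], plus `delta_final` and `f_value`).
#' @export
search_run <- function(queries, index_dir, params = search_params()) {
  stopifnot(inherits(params, "search_params"))
  man <- read_manifest(index_dir)
  B <- man$bin_width_da
  if (!is.null(params$bin_width) && params$bin_width != B)
    stop(sprintf("bin width mismatch: search requested %g Da but the index was built with %g Da",
                 params$bin_width, B))
  pi <- load_precursor_index(index_dir)
  if (is.character(queries)) queries <- read_mgf(queries)
  if (!length(queries)) return(empty_psm_table())
  if (!is.null(params$denoise))
    queries <- lapply(queries, denoise_top_k_window,
                      k = params$denoise$k, w = params$denoise$w)
  queries <- lapply(queries, preprocess)
  titles <- vapply(queries, function(q) q$native_id, "")
  sched <- schedule(queries, man$boundaries, params$tol_ppm,
                    pmz_range = man$precursor_mz_range)
  sp <- scoring_params(sigma = if (is.null(params$sigma)) B else params$sigma,
                       match_cutoff_sigmas = params$match_cutoff_sigmas)
  per_query <- vector("list", length(queries))
  by_part <- split(rep(seq_along(queries), lengths(sched)),
                   unlist(sched, use.names = FALSE))
  for (pid_chr in names(by_part)) {
    pid <- as.integer(pid_chr)
    part <- load_partition(index_dir, pid, pi = pi)
    in_part <- !is.na(match(pi$ranked_ids, part$spectrum_ids))
    for (qi in by_part[[pid_chr]]) {
      q <- queries[[qi]]
      tol <- ppm_to_da(params$tol_ppm, q$precursor_mz)
      wins <- candidate_window(pi, q$charge, q$precursor_mz, tol)
      cand_rank <- integer(0); cand_acc <- numeric(0)
      for (w in seq_len(nrow(wins))) {
        lo <- wins[[w, "lo"]]; hi <- wins[[w, "hi"]]
        if (hi <= lo) next
        ranks <- lo:(hi - 1L)
        keep <- in_part[ranks]
        if (!any(keep)) next
        acc <- accumulate(q, part, c(lo, hi), B)
        cand_rank <- c(cand_rank, ranks[keep])
        cand_acc <- c(cand_acc, acc[keep])
      }
      if (!length(cand_rank)) next
      o <- order(-cand_acc, cand_rank)
      take <- utils::head(o, if (is.finite(params$n_rescore))
        params$n_rescore else length(o))
      rows <- lapply(take, function(ci) {
        rank <- cand_rank[[ci]]
        id <- pi$ranked_ids[[rank]]
        rec <- pi$records[id + 1L, ]
        R <- partition_spectrum(part, id, peptide = rec$peptide,
                                is_decoy = rec$is_decoy, charge = rec$charge)
        sv <- score_pair(q, R, sp, B = B)
        c(list(query_id = qi, title = titles[[qi]], library_id = id,
               peptide = rec$peptide, is_decoy = rec$is_decoy, rank = NA_integer_,
               index_dot = cand_acc[[ci]]),
          as.list(sv), list(delta_final = NA_real_, f_value = NA_real_))
      })
      rows <- do.call(rbind, lapply(rows, function(r)
        as.data.frame(r, stringsAsFactors = FALSE)))
      per_query[[qi]] <- rbind(per_query[[qi]], rows)
    }
  }
  out <- do.call(rbind, lapply(seq_along(queries), function(qi)
    finalize_query(per_query[[qi]], qi, titles[[qi]], params$top_x)))
  rownames(out) <- NULL
  out
}

#' Exhaustive reference search (no index)
#'
#' Scores every in-tolerance candidate of a query directly with the scoring
#' module, with the same ranking and tie-breaking as [search_run()]. Serves
#' as the independent equivalence oracle for the indexed search on small
#' libraries.
#'
#' @param query one raw query [spectrum()].
#' @param library list of library [spectrum()] objects, in build order (so
#'   library ids are positions - 1).
#' @param params a [search_params()].
#' @param B fragment bin width in Da for the binned dot feature.
#' @param preprocessed set to TRUE when `library` (and `query`) are already
#'   preprocessed.
#' @return PSM data.frame with the same columns as [search_run()].
#' @export
oracle_search <- function(query, library, params = search_params(), B = 0.2,
                          preprocessed = FALSE) {
  if (!preprocessed) {
    query <- preprocess(query)
    library <- lapply(library, preprocess)
  }
  if (!length(library))
    return(finalize_query(NULL, 1L, query$native_id, params$top_x))
  pmz <- vapply(library, function(s) s$precursor_mz, 0)
  chg <- vapply(library, function(s) s$charge, 0L)
  tol <- ppm_to_da(params$tol_ppm, query$precursor_mz)
  hit <- abs(pmz - query$precursor_mz) <= tol &
    (query$charge == 0L | chg == query$charge)
  if (!any(hit))
    return(finalize_query(NULL, 1L, query$native_id, params$top_x))
  sp <- scoring_params(sigma = if (is.null(params$sigma)) B else params$sigma,
                       match_cutoff_sigmas = params$match_cutoff_sigmas)
  rows <- lapply(which(hit), function(i) {
    R <- library[[i]]
    sv <- score_pair(query, R, sp, B = B)
    c(list(query_id = 1L, title = query$native_id, library_id = i - 1L,
           peptide = R$peptide, is_decoy = R$is_decoy, rank = NA_integer_,
           index_dot = binned_dot(query, R, B)),
      as.list(sv), list(delta_final = NA_real_, f_value = NA_real_))
  })
  rows <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  finalize_query(rows, 1L, query$native_id, params$top_x)
}
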