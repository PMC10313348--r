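## Target-decoy competition and FDR estimation.
##
## Target and decoy libraries are searched separately; per query only the
## higher-scoring of the best target and best decoy hit survives the
## competition. At a score threshold t the decoy count estimates the number
## of false target matches:
##
##   FDR(t) = N_false(t) / N_target(t) ~= N_decoy(t) / N_target(t)
##
## and q-values are the monotonized (cumulative-minimum) FDR. An entrapment
## library (real but sample-foreign peptides appended to the targets) gives
## the orthogonal estimate FDR_trap(t) = N_trap(t) / N_target(t) * R, with
## R the target/entrapment peptide-count ratio. When ground truth is known
## the true FDR can be measured directly.

#' Target-decoy competition
#'
#' Merges separate target and decoy search results: per query only the
#' higher-final-score rank-1 hit is kept. An exact score tie is resolved in
#' favor of the target (the number of ties is recorded in the `n_ties`
#' attribute).
#'
#' @param target_psms,decoy_psms PSM tables from [search_run()] /
#'   [oracle_search()] against the target and decoy libraries.
#' @return Data.frame of competed rank-1 PSMs with a `label` column (+1
#'   target, -1 decoy) and an `is_entrapment` placeholder (see
#'   [flag_entrapment()]).
#' @export
compete <- function(target_psms, decoy_psms) {
  t1 <- target_psms[!is.na(target_psms$rank) & target_psms$rank == 1L, , drop = FALSE]
  d1 <- decoy_psms[!is.na(decoy_psms$rank) & decoy_psms$rank == 1L, , drop = FALSE]
  qids <- union(t1$query_id, d1$query_id)
  ti <- match(qids, t1$query_id)
  di <- match(qids, d1$query_id)
  ts <- ifelse(is.na(ti), -Inf, t1$final_score[ti])
  ds <- ifelse(is.na(di), -Inf, d1$final_score[di])
  take_target <- ts >= ds            # tie -> target
  n_ties <- sum(is.finite(ts) & ts == ds)
  rows <- rbind(t1[ti[take_target], , drop = FALSE],
                d1[di[!take_target], , drop = FALSE])
  rows$label <- rep(c(1L, -1L), c(sum(take_target), sum(!take_target)))
  rows <- rows[order(rows$query_id), , drop = FALSE]
  rows$is_entrapment <- NA
  rownames(rows) <- NULL
  attr(rows, "n_ties") <- n_ties
  rows
}

#' Flag entrapment PSMs
#'
#' A target PSM is an entrapment hit when its peptide occurs in the
#' entrapment peptide set and not in the true-target peptide set.
#'
#' @param competed a [compete()] result.
#' @param entrapment_peptides character vector of entrapment peptides.
#' @param target_peptides character vector of true-target (non-entrapment)
#'   peptides.
#' @return `competed` with `is_entrapment` filled in.
#' @export
flag_entrapment <- function(competed, entrapment_peptides, target_peptides) {
  competed$is_entrapment <- competed$label == 1L &
    competed$peptide %in% entrapment_peptides &
    !(competed$peptide %in% target_peptides)
  competed
}

fdr_sweep <- function(competed, extra = NULL) {
  o <- order(-competed$final_score)
  sc <- competed$final_score[o]
  lab <- competed$label[o]
  n_target <- cumsum(lab == 1L)
  n_decoy <- cumsum(lab == -1L)
  last <- !duplicated(sc, fromLast = TRUE)   # one row per distinct threshold
  fdr <- ifelse(n_target == 0L, 0, n_decoy / n_target)
  q <- rev(cummin(rev(fdr)))
  out <- data.frame(threshold = sc, n_target = n_target, n_decoy = n_decoy,
                    fdr = fdr, q = q)
  if (!is.null(extra)) for (nm in names(extra)) {
    out[[nm]] <- cumsum(extra[[nm]][o])
  }
  out[last, , drop = FALSE]
}

#' Target-decoy FDR curve
#'
#' Sweeps a threshold over every distinct competed score, counting accepted
#' targets and decoys; `fdr = n_decoy / n_target` (no +1 correction by
#' default, switchable) and q-values are the cumulative minimum from the
#' most permissive threshold upward.
#'
#' @param competed a [compete()] result.
#' @param plus_one add the conservative +1 to the decoy count.
#' @return Data.frame of class `fdr_curve`: `threshold`, `n_target`,
#'   `n_decoy`, `fdr`, `q` (thresholds descending in score).
#' @export
tdc_fdr <- function(competed, plus_one = FALSE) {
  if (!any(competed$label == 1L)) stop("no target PSMs")
  out <- fdr_sweep(competed)
  if (plus_one) {
    out$fdr <- ifelse(out$n_target == 0L, 0, (out$n_decoy + 1) / out$n_target)
    out$q <- rev(cummin(rev(out$fdr)))
  }
  rownames(out) <- NULL
  class(out) <- c("fdr_curve", "data.frame")
  out
}

#' Attach q-values to competed PSMs
#'
#' @param competed a [compete()] result.
#' @param curve optional precomputed [tdc_fdr()] curve.
#' @return `competed` with a `q_value` column.
#' @export
assign_q <- function(competed, curve = tdc_fdr(competed)) {
  idx <- findInterval(-competed$final_score, -curve$threshold)
  competed$q_value <- curve$q[pmax(idx, 1L)]
  competed
}

#' Entrapment FDR curve
#'
#' `fdr_trap(t) = n_trap(t) / n_target(t) * R`, where `R` is the ratio of
#' target database size over entrapment database size in peptides.
#'
#' @param competed a [compete()] result with `is_entrapment` flags (see
#'   [flag_entrapment()]).
#' @param R target/entrapment peptide-count ratio (> 0).
#' @return Data.frame: `threshold`, `n_target`, `n_trap`, `fdr_trap`.
#' @export
entrapment_fdr <- function(competed, R) {
  if (!is.numeric(R) || R <= 0) stop("R must be > 0")
  if (anyNA(competed$is_entrapment))
    stop("is_entrapment flags not set; call flag_entrapment() first")
  out <- fdr_sweep(competed, extra = list(n_trap = competed$is_entrapment))
  out$fdr_trap <- ifelse(out$n_target == 0L, 0, out$n_trap / out$n_target * R)
  rownames(out) <- NULL
  out[, c("threshold", "n_target", "n_trap", "fdr_trap")]
}

#' True FDR curve from ground truth
#'
#' Counts accepted target PSMs whose peptide differs from the generating
#' peptide recorded for the query (exact string match on the modified
#' sequence; I/L are distinct). Queries absent from the truth map are
#' excluded with a warning.
#'
#' @param competed a [compete()] result.
#' @param truth named character vector: query title -> correct peptide
#'   (foreign queries carry the marker value `"foreign"`).
#' @return Data.frame: `threshold`, `n_target`, `n_false`, `fdr_true`.
#' @export
true_fdr <- function(competed, truth) {
  known <- competed$title %in% names(truth)
  if (!all(known)) {
    warning(sprintf("%d queries missing from truth map, excluded", sum(!known)))
    competed <- competed[known, , drop = FALSE]
  }
  if (!nrow(competed))
    return(data.frame(threshold = numeric(0), n_target = integer(0),
                      n_false = integer(0), fdr_true = numeric(0)))
  wrong <- competed$label == 1L &
    competed$peptide != unname(truth[competed$title])
  out <- fdr_sweep(competed, extra = list(n_false = wrong))
  out$fdr_true <- ifelse(out$n_target == 0L, 0, out$n_false / out$n_target)
  rownames(out) <- NULL
  out[, c("threshold", "n_target", "n_false", "fdr_true")]
}

PIN_FEATURES <- c("final_score", "bias_adjusted", "reflection_bias_adjusted",
                  "similarity", "reflection_similarity", "dot", "bias",
                  "reflection_bias", "log_hyperscore", "f_value",
                  "delta_final", "shared_peak_count", "mz_sd_matched",
                  "abs_mass_diff_precursor", "peptide_length")
PIN_RT_FEATURES <- c("rt_diff_abs", "rt_diff_sq", "rt_diff_log", "rt_diff_rel")

#' Write PSMs as a Percolator pin-tab file
#'
#' Tab-separated with header `SpecId`, `Label` (+1/-1), `ScanNr`, the score
#' and metadata feature columns, then `Peptide` (flanked `-.PEPTIDE.-`) and
#' `Proteins`. Retention-time distance columns are included when present.
#' Marker rows for queries without candidates (`rank == 0`) are skipped; any
#' missing feature column or non-finite feature value is an error.
#'
#' @param psms PSM table (targets and decoys; a `label` column is used when
#'   present, otherwise `is_decoy`).
#' @param path output path.
#' @param proteins optional character vector of protein accessions per row
#'   (defaults to the peptide itself).
#' @return Invisibly, `path`.
#' @export
write_pin <- function(psms, path, proteins = NULL) {
  psms <- psms[!is.na(psms$rank) & psms$rank >= 1L, , drop = FALSE]
  feats <- c(PIN_FEATURES, intersect(PIN_RT_FEATURES, names(psms)))
  missing <- setdiff(feats, names(psms))
  if (length(missing))
    stop("missing pin feature column: ", missing[[1L]])
  label <- if ("label" %in% names(psms)) psms$label
           else ifelse(psms$is_decoy, -1L, 1L)
  fm <- as.matrix(psms[, feats, drop = FALSE])
  if (nrow(fm) && any(!is.finite(fm))) {
    bad <- feats[which(!is.finite(fm), arr.ind = TRUE)[1L, 2L]]
    stop("non-finite value in pin feature column: ", bad)
  }
  out <- data.frame(
    SpecId = sprintf("%s_%d_%d", psms$title, psms$query_id, psms$rank),
    Label = as.integer(label),
    ScanNr = psms$query_id,
    psms[, feats, drop = FALSE],
    Peptide = sprintf("-.%s.-", psms$peptide),
    Proteins = if (is.null(proteins)) psms$peptide else proteins,
    stringsAsFactors = FALSE, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
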