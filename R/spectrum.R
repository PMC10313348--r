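#' Construct a mass spectrum
#'
#' A `Spectrum` couples one precursor (m/z and charge) with its peak list.
#' Library spectra additionally carry the generating peptide sequence and a
#' decoy flag; query spectra need not. Peaks are stored sorted strictly
#' ascending by m/z; peaks with exactly coincident m/z are merged by intensity
#' summation (predicted libraries can emit coincident b/y masses) and
#' zero-intensity peaks are dropped.
#'
#' @param mz numeric vector of fragment m/z values in Thomson (> 0).
#' @param intensity numeric vector of non-negative peak intensities.
#' @param native_id source scan identifier string.
#' @param precursor_mz precursor m/z in Thomson.
#' @param charge integer precursor charge; `0` means "unknown" (queries only).
#' @param peptide optional peptide sequence (required for library spectra).
#' @param is_decoy logical decoy flag.
#' @param ion_label optional character vector of ion annotations (e.g. "b5",
#'   "y7"); `NA` where unannotated.
#' @param retention_time optional retention time in seconds.
#' @return An object of class `Spectrum`: a list with elements `native_id`,
#'   `precursor_mz`, `charge`, `peptide`, `is_decoy`, `retention_time` and
#'   `peaks` (a data.frame with columns `mz`, `intensity`, `ion_label`).
#' @export
spectrum <- function(mz, intensity, native_id = "", precursor_mz = NA_real_,
                     charge = 0L, peptide = NA_character_, is_decoy = FALSE,
                     ion_label = NULL, retention_time = NA_real_) {
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity))
    stop("mz and intensity must have equal length")
  if (is.null(ion_label)) ion_label <- rep(NA_character_, length(mz))
  ion_label <- as.character(ion_label)
  if (length(ion_label) != length(mz))
    stop("ion_label must match peak count")
  if (any(!is.finite(mz)) || any(mz <= 0)) stop("peak m/z must be positive")
  if (any(!is.finite(intensity)) || any(intensity < 0))
    stop("peak intensities must be non-negative")
  keep <- intensity > 0
  mz <- mz[keep]; intensity <- intensity[keep]; ion_label <- ion_label[keep]
  if (length(mz)) {
    o <- order(mz)
    mz <- mz[o]; intensity <- intensity[o]; ion_label <- ion_label[o]
    # merge exact m/z ties by intensity summation, first non-NA label wins
    if (anyDuplicated(mz)) {
      grp <- cumsum(!duplicated(mz))
      intensity <- as.numeric(tapply(intensity, grp, sum))
      lab <- tapply(ion_label, grp, function(l) {
        nn <- l[!is.na(l)]
        if (length(nn)) nn[[1L]] else NA_character_
      })
      ion_label <- as.character(lab)
      mz <- mz[!duplicated(grp)]
    }
  }
  charge <- as.integer(charge)
  if (is.na(charge) || charge < 0L) stop("charge must be >= 0 (0 = unknown)")
  structure(list(
    native_id = as.character(native_id),
    precursor_mz = as.numeric(precursor_mz),
    charge = charge,
    peptide = as.character(peptide),
    is_decoy = isTRUE(is_decoy),
    retention_time = as.numeric(retention_time),
    peaks = data.frame(mz = mz, intensity = intensity, ion_label = ion_label,
                       stringsAsFactors = FALSE)
  ), class = "Spectrum")
}

#' @export
print.Spectrum <- function(x, ...) {
  cat(sprintf("<Spectrum %s  precursor %.4f m/z  charge %s  %d peaks%s%s>\n",
              x$native_id,
              x$precursor_mz,
              if (x$charge > 0L) x$charge else "?",
              nrow(x$peaks),
              if (!is.na(x$peptide)) paste0("  peptide ", x$peptide) else "",
              if (x$is_decoy) "  [decoy]" else ""))
  invisible(x)
}

#' Square-root transform and unit-normalize peak intensities
#'
#' Raw intensities are square rooted (to de-emphasize dominant peaks) and the
#' resulting intensity vector is scaled to unit Euclidean norm, so the binned
#' dot product of two preprocessed spectra lies in \[0, 1\]. m/z values are
#' unchanged. The transform is *not* idempotent: apply it exactly once per
#' spectrum, before indexing or scoring.
#'
#' @param s a `Spectrum`.
#' @return The preprocessed `Spectrum`.
#' @export
preprocess <- function(s) {
  stopifnot(inherits(s, "Spectrum"))
  i <- s$peaks$intensity
  if (!length(i) || all(i == 0)) stop("empty spectrum after preprocessing")
  i <- sqrt(i)
  s$peaks$intensity <- i / sqrt(sum(i * i))
  s
}

#' Top-k in window-w noise reduction
#'
#' Within each consecutive absolute m/z window `[j*w, (j+1)*w)` only the `k`
#' most intense peaks are retained; relative peak order is preserved. This
#' filter is optional and off by default throughout the package.
#'
#' @param s a `Spectrum`.
#' @param k number of peaks to keep per window (>= 1).
#' @param w window width in Da (> 0).
#' @return The filtered `Spectrum`.
#' @export
denoise_top_k_window <- function(s, k, w) {
  stopifnot(inherits(s, "Spectrum"), k >= 1, w > 0)
  p <- s$peaks
  if (nrow(p) <= k) return(s)
  win <- floor(p$mz / w)
  keep <- unlist(lapply(split(seq_len(nrow(p)), win), function(idx) {
    if (length(idx) <= k) return(idx)
    idx[rank(-p$intensity[idx], ties.method = "first") <= k]
  }), use.names = FALSE)
  s$peaks <- p[sort(keep), , drop = FALSE]
  rownames(s$peaks) <- NULL
  s
}

#' Convert a ppm tolerance to Daltons at a given m/z
#'
#' @param tol_ppm tolerance in parts per million (>= 0).
#' @param mz reference m/z in Thomson (> 0).
#' @return Tolerance in Da: `mz * tol_ppm * 1e-6` (10 ppm at m/z 1500 is
#'   0.015 Da).
#' @export
ppm_to_da <- function(tol_ppm, mz) {
  stopifnot(all(tol_ppm >= 0), all(mz > 0))
  mz * tol_ppm * 1e-6
}
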