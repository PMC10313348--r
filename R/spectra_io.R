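## MSP (NIST text) and MGF (Matrix Science text) readers and writers.
## Both readers stream: files are consumed in line chunks and each complete
## record is handed to a callback, so an arbitrarily large library never has
## to fit in memory at once. mzML/mzXML are deliberately not supported.

CHUNK_LINES <- 65536L

#' Stream spectra from an MSP library file
#'
#' Reads a NIST-style MSP file record by record (`Name:` ... `Num peaks:` ...
#' peak lines) and calls `handler` once per spectrum, in file order, without
#' loading the whole file into memory.
#'
#' @param path path to an MSP file.
#' @param handler function of one argument (a [spectrum()]) called per record.
#' @param is_decoy logical: flag every spectrum in this file as decoy
#'   (separate decoy libraries are the primary decoy convention).
#' @param decoy_prefix peptides whose `Name:` starts with this prefix are
#'   additionally flagged (and the prefix stripped); default `"DECOY_"`.
#' @return Invisibly, the number of spectra streamed.
#' @export
stream_msp <- function(path, handler, is_decoy = FALSE, decoy_prefix = "DECOY_") {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "r")
  on.exit(close(con))
  buf <- character(0)
  n_seen <- 0L
  repeat {
    chunk <- readLines(con, n = CHUNK_LINES, warn = FALSE)
    eof <- length(chunk) < CHUNK_LINES
    buf <- c(buf, chunk)
    res <- parse_msp_buffer(buf, n_seen, handler, is_decoy, decoy_prefix, eof)
    buf <- res$leftover
    n_seen <- res$n_seen
    if (eof) break
  }
  invisible(n_seen)
}

# Parse complete MSP records from `lines`; returns leftover lines and updated
# record count. With eof=TRUE a trailing partial record is an error.
parse_msp_buffer <- function(lines, n_seen, handler, is_decoy, decoy_prefix, eof) {
  i <- 1L
  n <- length(lines)
  repeat {
    while (i <= n && !grepl("^Name:", lines[[i]])) {
      if (nzchar(trimws(lines[[i]])) && !grepl("^#", lines[[i]]))
        stop(sprintf("MSP record %d: unexpected line before Name: '%s'",
                     n_seen + 1L, lines[[i]]))
      i <- i + 1L
    }
    if (i > n) return(list(leftover = character(0), n_seen = n_seen))
    start <- i
    # locate "Num peaks:" header within this record
    j <- i + 1L
    npk <- NA_integer_
    while (j <= n) {
      if (grepl("^Num [Pp]eaks:", lines[[j]])) {
        npk <- as.integer(trimws(sub("^Num [Pp]eaks:", "", lines[[j]])))
        break
      }
      if (grepl("^Name:", lines[[j]]))
        stop(sprintf("MSP record %d: missing 'Num peaks:' header", n_seen + 1L))
      j <- j + 1L
    }
    if (j > n || j + npk > n) {
      if (eof) {
        if (j > n)
          stop(sprintf("MSP record %d: truncated record (no 'Num peaks:')",
                       n_seen + 1L))
        stop(sprintf("MSP record %d: truncated final record (expected %d peaks)",
                     n_seen + 1L, npk))
      }
      return(list(leftover = lines[start:n], n_seen = n_seen))
    }
    if (is.na(npk) || npk < 0L)
      stop(sprintf("MSP record %d: bad 'Num peaks:' value", n_seen + 1L))
    s <- parse_msp_record(lines[start:j], lines[seq_len(npk) + j],
                          n_seen + 1L, is_decoy, decoy_prefix)
    handler(s)
    n_seen <- n_seen + 1L
    i <- j + npk + 1L
  }
}

parse_msp_record <- function(header, peak_lines, ordinal, is_decoy, decoy_prefix) {
  name <- trimws(sub("^Name:", "", header[[1L]]))
  peptide <- NA_character_
  charge <- 0L
  if (grepl("/", name, fixed = TRUE)) {
    peptide <- sub("/.*$", "", name)
    ch <- suppressWarnings(as.integer(sub("^[^/]*/", "", name)))
    if (!is.na(ch)) charge <- ch
  } else {
    peptide <- name
  }
  pmz <- NA_real_
  rt <- NA_real_
  for (h in header[-1L]) {
    if (grepl("^(PrecursorMZ|PRECURSORMZ):", h)) {
      pmz <- as.numeric(trimws(sub("^[^:]*:", "", h)))
    } else if (grepl("^Comment:", h)) {
      cm <- h
      m <- regmatches(cm, regexpr("Charge=[0-9]+", cm))
      if (length(m) && charge == 0L)
        charge <- as.integer(sub("Charge=", "", m))
      m <- regmatches(cm, regexpr("Parent=[0-9.eE+-]+", cm))
      if (length(m) && is.na(pmz))
        pmz <- as.numeric(sub("Parent=", "", m))
      m <- regmatches(cm, regexpr("RetentionTime=[0-9.eE+-]+", cm))
      if (length(m))
        rt <- as.numeric(sub("RetentionTime=", "", m))
    } else if (grepl("^MW:", h) && is.na(pmz) && charge > 0L) {
      pmz <- as.numeric(trimws(sub("^MW:", "", h))) / charge
    }
  }
  if (is.na(pmz))
    stop(sprintf("MSP record %d ('%s'): no precursor m/z", ordinal, name))
  decoy <- is_decoy
  if (!is.na(peptide) && nzchar(decoy_prefix) &&
      startsWith(peptide, decoy_prefix)) {
    decoy <- TRUE
    peptide <- substring(peptide, nchar(decoy_prefix) + 1L)
  }
  pk <- parse_peak_lines(peak_lines, ordinal)
  spectrum(pk$mz, pk$intensity,
           native_id = name, precursor_mz = pmz, charge = charge,
           peptide = peptide, is_decoy = decoy, ion_label = pk$ion_label,
           retention_time = rt)
}

# Peak lines: "mz intensity" optionally followed by an annotation column such
# as 'y3/0.01' or '"b5/-0.002"'; the ion label is the part before '/'.
parse_peak_lines <- function(lines, ordinal) {
  toks <- strsplit(trimws(lines), "[ \t]+")
  nt <- lengths(toks)
  if (any(nt < 2L)) {
    bad <- which(nt < 2L)[[1L]]
    stop(sprintf("MSP record %d: malformed peak line '%s'", ordinal, lines[[bad]]))
  }
  mz <- suppressWarnings(as.numeric(vapply(toks, `[[`, "", 1L)))
  it <- suppressWarnings(as.numeric(vapply(toks, `[[`, "", 2L)))
  if (any(is.na(mz)) || any(is.na(it))) {
    bad <- which(is.na(mz) | is.na(it))[[1L]]
    stop(sprintf("MSP record %d: non-numeric peak line '%s'", ordinal, lines[[bad]]))
  }
  lab <- rep(NA_character_, length(mz))
  has3 <- nt >= 3L
  if (any(has3)) {
    ann <- vapply(toks[has3], `[[`, "", 3L)
    ann <- gsub('"', "", ann)
    ann <- sub("/.*$", "", ann)
    ann[!nzchar(ann) | ann == "?"] <- NA_character_
    lab[has3] <- ann
  }
  list(mz = mz, intensity = it, ion_label = lab)
}

#' Read an MSP library into a list of spectra
#'
#' Convenience wrapper over [stream_msp()] for libraries that fit in memory.
#'
#' @inheritParams stream_msp
#' @return A list of [spectrum()] objects in file order.
#' @export
read_msp <- function(path, is_decoy = FALSE, decoy_prefix = "DECOY_") {
  out <- new.env(parent = emptyenv())
  out$l <- vector("list", 256L)
  out$n <- 0L
  stream_msp(path, function(s) {
    out$n <- out$n + 1L
    if (out$n > length(out$l)) out$l <- c(out$l, vector("list", length(out$l)))
    out$l[[out$n]] <- s
  }, is_decoy = is_decoy, decoy_prefix = decoy_prefix)
  out$l[seq_len(out$n)]
}

#' Write spectra to an MSP file
#'
#' Canonical dialect: `Name: PEPTIDE/charge`, `PrecursorMZ:`, `Num peaks:`,
#' peak lines with 4 decimal places on m/z and scientific-notation
#' intensities, annotation column where ion labels are present.
#'
#' @param spectra list of [spectrum()] objects.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_msp <- function(spectra, path) {
  lines <- unlist(lapply(spectra, function(s) {
    p <- s$peaks
    lab <- ifelse(is.na(p$ion_label), "", paste0("\t", p$ion_label))
    c(sprintf("Name: %s%s/%d", if (s$is_decoy) "DECOY_" else "",
              if (is.na(s$peptide)) s$native_id else s$peptide, s$charge),
      sprintf("PrecursorMZ: %.6f", s$precursor_mz),
      if (!is.na(s$retention_time))
        sprintf("Comment: RetentionTime=%.3f", s$retention_time),
      sprintf("Num peaks: %d", nrow(p)),
      sprintf("%.4f\t%.9e%s", p$mz, p$intensity, lab),
      "")
  }), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}

#' Stream spectra from an MGF file
#'
#' Reads `BEGIN IONS`/`END IONS` blocks. `PEPMASS` is required; a missing
#' `CHARGE` is recorded as charge 0 ("unknown"). The spectrum id is taken
#' from `TITLE` (or `index=<ordinal>` when absent); `SEQ=` lines, when
#' present, annotate the peptide.
#'
#' @inheritParams stream_msp
#' @param path path to an MGF file.
#' @return Invisibly, the number of spectra streamed.
#' @export
stream_mgf <- function(path, handler, is_decoy = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "r")
  on.exit(close(con))
  buf <- character(0)
  n_seen <- 0L
  repeat {
    chunk <- readLines(con, n = CHUNK_LINES, warn = FALSE)
    eof <- length(chunk) < CHUNK_LINES
    buf <- c(buf, chunk)
    res <- parse_mgf_buffer(buf, n_seen, handler, is_decoy, eof)
    buf <- res$leftover
    n_seen <- res$n_seen
    if (eof) break
  }
  invisible(n_seen)
}

parse_mgf_buffer <- function(lines, n_seen, handler, is_decoy, eof) {
  i <- 1L
  n <- length(lines)
  repeat {
    while (i <= n && trimws(lines[[i]]) != "BEGIN IONS") {
      if (trimws(lines[[i]]) == "END IONS")
        stop(sprintf("MGF block %d: END IONS without BEGIN IONS", n_seen + 1L))
      i <- i + 1L
    }
    if (i > n) return(list(leftover = character(0), n_seen = n_seen))
    j <- i + 1L
    while (j <= n && trimws(lines[[j]]) != "END IONS") {
      if (trimws(lines[[j]]) == "BEGIN IONS")
        stop(sprintf("MGF block %d: nested BEGIN IONS", n_seen + 1L))
      j <- j + 1L
    }
    if (j > n) {
      if (eof) stop(sprintf("MGF block %d: truncated (no END IONS)", n_seen + 1L))
      return(list(leftover = lines[i:n], n_seen = n_seen))
    }
    s <- parse_mgf_block(lines[(i + 1L):(j - 1L)], n_seen + 1L, is_decoy)
    handler(s)
    n_seen <- n_seen + 1L
    i <- j + 1L
  }
}

parse_mgf_block <- function(body, ordinal, is_decoy) {
  body <- body[nzchar(trimws(body))]
  is_kv <- grepl("^[A-Z]+=", body)
  kv <- body[is_kv]
  title <- sub("^TITLE=", "", kv[startsWith(kv, "TITLE=")])
  title <- if (length(title)) title[[1L]] else sprintf("index=%d", ordinal)
  pm <- kv[startsWith(kv, "PEPMASS=")]
  if (!length(pm))
    stop(sprintf("MGF block %d ('%s'): PEPMASS missing", ordinal, title))
  pmz <- as.numeric(strsplit(sub("^PEPMASS=", "", pm[[1L]]), "[ \t]+")[[1L]][[1L]])
  ch <- kv[startsWith(kv, "CHARGE=")]
  charge <- 0L
  if (length(ch)) {
    chs <- sub("^CHARGE=", "", ch[[1L]])
    charge <- as.integer(sub("[+-]$", "", chs))
    if (is.na(charge)) charge <- 0L
  }
  rt <- kv[startsWith(kv, "RTINSECONDS=")]
  rt <- if (length(rt)) as.numeric(sub("^RTINSECONDS=", "", rt[[1L]])) else NA_real_
  seq <- kv[startsWith(kv, "SEQ=")]
  peptide <- if (length(seq)) sub("^SEQ=", "", seq[[1L]]) else NA_character_
  pk <- parse_peak_lines(body[!is_kv], ordinal)
  spectrum(pk$mz, pk$intensity, native_id = title, precursor_mz = pmz,
           charge = charge, peptide = peptide, is_decoy = is_decoy,
           ion_label = pk$ion_label, retention_time = rt)
}

#' Read an MGF file into a list of spectra
#'
#' @inheritParams stream_mgf
#' @return A list of [spectrum()] objects in file order.
#' @export
read_mgf <- function(path, is_decoy = FALSE) {
  out <- new.env(parent = emptyenv())
  out$l <- vector("list", 256L)
  out$n <- 0L
  stream_mgf(path, function(s) {
    out$n <- out$n + 1L
    if (out$n > length(out$l)) out$l <- c(out$l, vector("list", length(out$l)))
    out$l[[out$n]] <- s
  }, is_decoy = is_decoy)
  out$l[seq_len(out$n)]
}

#' Write spectra to an MGF file
#'
#' @param spectra list of [spectrum()] objects.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_mgf <- function(spectra, path) {
  lines <- unlist(lapply(spectra, function(s) {
    p <- s$peaks
    c("BEGIN IONS",
      sprintf("TITLE=%s", s$native_id),
      sprintf("PEPMASS=%.6f", s$precursor_mz),
      if (s$charge > 0L) sprintf("CHARGE=%d+", s$charge),
      if (!is.na(s$retention_time)) sprintf("RTINSECONDS=%.3f", s$retention_time),
      if (!is.na(s$peptide)) sprintf("SEQ=%s", s$peptide),
      sprintf("%.4f\t%.9e", p$mz, p$intensity),
      "END IONS",
      "")
  }), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}
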