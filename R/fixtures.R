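## Deterministic synthetic-data generator.
##
## Emulates the predicted-spectral-library setting end to end: random
## protein sequences are digested with trypsin rules, each (peptide, charge)
## pair in the configured precursor m/z range gets a b/y-ion spectrum with a
## smooth, peptide-specific intensity profile (a stand-in for a learned
## fragmentation predictor, which only emits b/y ions), pseudo-reversed
## decoys and a disjoint entrapment proteome are generated the same way,
## and query runs are produced by perturbing library spectra (m/z jitter,
## intensity noise, peak dropout, contaminant peaks, precursor jitter) with
## a recorded ground truth. Every artifact is byte-reproducible from
## (config, seed).

# monoisotopic residue masses; C carries fixed carbamidomethylation (+57.02146)
RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919 + 57.02146, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259,
  M = 131.04049, H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333,
  W = 186.07931)
PROTON_MASS <- 1.007276
WATER_MASS <- 18.010565

#' Fixture generator configuration
#'
#' Defaults reflect a typical tryptic search space: peptide lengths 7-30,
#' charge states 2-4, precursor m/z 400-1500, up to two missed cleavages.
#' Query noise (m/z jitter 0.02 Da, intensity CV 0.2, 10% peak dropout,
#' 5 contaminant peaks) is moderate: rank-1 recovery is high but not
#' saturated, so the FDR machinery has signal to discriminate.
#'
#' @param seed mandatory RNG seed.
#' @param n_target_spectra total target library size (entrapment included).
#' @param entrapment_fraction share of target spectra drawn from the
#'   disjoint entrapment proteome.
#' @param n_queries number of query spectra.
#' @param fraction_foreign probability a query is generated from a peptide
#'   absent from every library (a planted false candidate).
#' @param peptide_length inclusive length range of retained peptides.
#' @param charges precursor charge states enumerated per peptide.
#' @param mz_range precursor m/z range in Thomson; (peptide, charge) pairs
#'   outside it are skipped.
#' @param missed_cleavages maximum missed cleavages in the digest.
#' @param protein_length residues per synthetic protein.
#' @param mz_jitter Gaussian fragment m/z jitter SD in Da.
#' @param int_cv lognormal intensity noise coefficient of variation.
#' @param dropout per-peak dropout probability.
#' @param n_contaminant uniform-random contaminant peaks per query.
#' @param precursor_jitter_ppm uniform precursor m/z jitter budget in ppm.
#' @return A list of class `fixture_config`.
#' @export
fixture_config <- function(seed, n_target_spectra = 2000L,
                           entrapment_fraction = 0.25, n_queries = 500L,
                           fraction_foreign = 0.1,
                           peptide_length = c(7L, 30L), charges = 2:4,
                           mz_range = c(400, 1500), missed_cleavages = 2L,
                           protein_length = 300L,
                           mz_jitter = 0.02, int_cv = 0.2, dropout = 0.1,
                           n_contaminant = 5L, precursor_jitter_ppm = 5) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_target_spectra >= 1, n_queries >= 0,
            entrapment_fraction >= 0, entrapment_fraction < 1,
            fraction_foreign >= 0, fraction_foreign <= 1,
            mz_jitter >= 0, int_cv >= 0, dropout >= 0, dropout < 1,
            n_contaminant >= 0)
  structure(as.list(environment()), class = "fixture_config")
}

#' Generate a random proteome
#'
#' Random sequences over the 20-letter amino-acid alphabet with K/R
#' frequencies tuned (~4.5% each) so that tryptic peptides fall mostly in
#' the configured length range.
#'
#' @param n_proteins number of proteins.
#' @param protein_length residues per protein.
#' @param seed RNG seed.
#' @return Named character vector of protein sequences.
#' @export
generate_proteome <- function(n_proteins, protein_length = 300L, seed) {
  set.seed(seed)
  if (n_proteins == 0L) return(stats::setNames(character(0), character(0)))
  aa <- names(RESIDUE_MASS)
  p <- stats::setNames(rep((1 - 0.09) / 18, 20L), aa)
  p[c("K", "R")] <- 0.045
  seqs <- vapply(seq_len(n_proteins), function(i)
    paste(sample(aa, protein_length, replace = TRUE, prob = p), collapse = ""),
    "")
  stats::setNames(seqs, sprintf("PROT%05d", seq_len(n_proteins)))
}

#' Write protein sequences as FASTA
#'
#' @param proteome named character vector of sequences.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(proteome, path) {
  lines <- if (length(proteome))
    as.vector(rbind(paste0(">", names(proteome)), unname(proteome)))
  else character(0)
  writeLines(lines, path)
  invisible(path)
}

#' Tryptic digestion of one protein
#'
#' Cleaves C-terminal to K/R except before P, emitting all products with
#' 0..`missed_cleavages` missed cleavages. No length or mass filtering is
#' applied here.
#'
#' @param protein protein sequence.
#' @param missed_cleavages maximum missed cleavages.
#' @return Character vector of peptides.
#' @export
digest <- function(protein, missed_cleavages = 2L) {
  chars <- strsplit(protein, "")[[1L]]
  n <- length(chars)
  if (!n) return(character(0))
  cut <- which(chars %in% c("K", "R"))
  cut <- cut[cut < n & chars[pmin(cut + 1L, n)] != "P" | cut == n]
  stops <- unique(c(cut, n))
  starts <- c(1L, utils::head(stops, -1L) + 1L)
  out <- character(0)
  for (mc in 0:missed_cleavages) {
    i <- seq_len(length(starts) - mc)
    if (!length(i)) break
    out <- c(out, substring(protein, starts[i], stops[i + mc]))
  }
  out
}

#' Neutral monoisotopic peptide mass
#'
#' @param peptide peptide sequence (standard residues; C is fixed
#'   carbamidomethylated).
#' @return Mass in Da (residue sum + water).
#' @export
peptide_mass <- function(peptide) {
  res <- RESIDUE_MASS[strsplit(peptide, "")[[1L]]]
  if (anyNA(res)) stop("unknown residue in peptide: ", peptide)
  sum(res) + WATER_MASS
}

# deterministic per-(peptide, charge) profile parameters in [0,1]
profile_hash <- function(peptide, charge) {
  v <- utf8ToInt(peptide)
  h <- (sum(v * seq_along(v)) * 2654435761 + sum(v) * 97 + charge * 131071) %%
    2147483647
  u <- numeric(4L)
  for (i in 1:4) {
    h <- (h * 48271) %% 2147483647
    u[[i]] <- h / 2147483647
  }
  u
}

#' Predict a b/y-ion spectrum for a peptide
#'
#' Emits singly charged b and y ions (plus doubly charged ones when the
#' precursor charge is >= 3) at monoisotopic masses, with intensities drawn
#' from a smooth position-dependent bell profile whose parameters are hashed
#' deterministically from (peptide, charge) — distinct peptides get distinct
#' fragmentation patterns and the same input always yields the same
#' spectrum. Cysteine is fixed carbamidomethylated.
#'
#' @param peptide peptide sequence over the standard 20 residues.
#' @param charge precursor charge (>= 1).
#' @param is_decoy decoy flag carried into the spectrum.
#' @return A library [spectrum()] with ion labels set.
#' @export
toy_predict <- function(peptide, charge, is_decoy = FALSE) {
  res <- RESIDUE_MASS[strsplit(peptide, "")[[1L]]]
  if (anyNA(res)) stop("unknown residue in peptide: ", peptide)
  n <- length(res)
  stopifnot(n >= 2L, charge >= 1L)
  idx <- seq_len(n - 1L)
  b_neutral <- cumsum(res)[idx]
  y_neutral <- rev(cumsum(rev(res)))[idx + 1L] + WATER_MASS
  u <- profile_hash(peptide, charge)
  center_b <- n * (0.25 + 0.5 * u[[1L]])
  width <- n * (0.15 + 0.2 * u[[2L]])
  center_y <- n * (0.25 + 0.5 * u[[3L]])
  y_scale <- 0.6 + 0.8 * u[[4L]]
  b_int <- 0.05 + exp(-0.5 * ((idx - center_b) / width)^2)
  y_int <- 0.05 + y_scale * exp(-0.5 * (((n - idx) - center_y) / width)^2)
  mz <- c(b_neutral + PROTON_MASS, y_neutral + PROTON_MASS)
  it <- c(b_int, y_int)
  lab <- c(sprintf("b%d", idx), sprintf("y%d", n - idx))
  if (charge >= 3L) {
    mz <- c(mz, (b_neutral + 2 * PROTON_MASS) / 2,
            (y_neutral + 2 * PROTON_MASS) / 2)
    it <- c(it, 0.3 * b_int, 0.3 * y_int)
    lab <- c(lab, sprintf("b%d(2+)", idx), sprintf("y%d(2+)", n - idx))
  }
  it <- 100 * it / max(it)
  spectrum(mz, it,
           native_id = sprintf("%s%s/%d", if (is_decoy) "DECOY_" else "",
                               peptide, charge),
           precursor_mz = (sum(res) + WATER_MASS + charge * PROTON_MASS) / charge,
           charge = as.integer(charge), peptide = peptide,
           is_decoy = is_decoy, ion_label = lab)
}

#' Pseudo-reverse decoy peptides
#'
#' Reverses all but the C-terminal residue of each peptide (preserving the
#' tryptic terminus and the precursor mass). Decoys colliding with the
#' target set or each other are deterministically reshuffled until disjoint;
#' irreducible collisions (palindrome-like peptides) are dropped with a
#' warning.
#'
#' @param peptides character vector of target peptides.
#' @param seed RNG seed for collision reshuffling.
#' @return Character vector of decoy peptides, named by their target.
#' @export
make_decoys <- function(peptides, seed) {
  set.seed(seed)
  pseudo_rev <- function(p) {
    ch <- strsplit(p, "")[[1L]]
    n <- length(ch)
    paste(c(rev(ch[-n]), ch[[n]]), collapse = "")
  }
  taken <- c(peptides)
  out <- character(0)
  nm <- character(0)
  for (p in peptides) {
    d <- pseudo_rev(p)
    tries <- 0L
    while (d %in% taken && tries < 20L) {
      ch <- strsplit(p, "")[[1L]]
      n <- length(ch)
      d <- paste(c(sample(ch[-n]), ch[[n]]), collapse = "")
      tries <- tries + 1L
    }
    if (d %in% taken) {
      warning("irreducible decoy collision, peptide dropped: ", p)
      next
    }
    taken <- c(taken, d)
    out <- c(out, d)
    nm <- c(nm, p)
  }
  stats::setNames(out, nm)
}

# enumerate (peptide, charge) pairs within the configured m/z range
enumerate_spectra <- function(peptides, cfg) {
  if (!length(peptides))
    return(data.frame(peptide = character(0), charge = integer(0),
                      precursor_mz = numeric(0)))
  mass <- vapply(peptides, peptide_mass, 0)
  out <- do.call(rbind, lapply(cfg$charges, function(z) {
    pmz <- (mass + z * PROTON_MASS) / z
    ok <- pmz >= cfg$mz_range[[1L]] & pmz <= cfg$mz_range[[2L]]
    data.frame(peptide = peptides[ok], charge = rep.int(as.integer(z), sum(ok)),
               precursor_mz = pmz[ok], stringsAsFactors = FALSE)
  }))
  out[order(out$peptide, out$charge), , drop = FALSE]
}

#' Perturb library spectra into a noisy query run
#'
#' For each sampled source spectrum: every fragment m/z is jittered with
#' Gaussian SD `mz_jitter`, intensities are multiplied by lognormal noise of
#' coefficient of variation `int_cv`, peaks are dropped with probability
#' `dropout` (the most intense peak is always kept), `n_contaminant`
#' uniform-random peaks are added, and the precursor m/z is jittered
#' uniformly within the ppm budget.
#'
#' @param sources list of library [spectrum()] objects to perturb.
#' @param cfg a [fixture_config()] (noise fields are used).
#' @param titles character vector of query titles.
#' @return List of query [spectrum()] objects (charge kept, peptide
#'   stripped).
#' @export
perturb_queries <- function(sources, cfg, titles = NULL) {
  if (is.null(titles)) titles <- sprintf("query_%05d", seq_along(sources))
  sdlog <- sqrt(log(1 + cfg$int_cv^2))
  lapply(seq_along(sources), function(i) {
    s <- sources[[i]]
    p <- s$peaks
    n <- nrow(p)
    mz <- p$mz + stats::rnorm(n, 0, cfg$mz_jitter)
    it <- p$intensity * stats::rlnorm(n, -sdlog^2 / 2, sdlog)
    keep <- stats::runif(n) >= cfg$dropout
    keep[which.max(it)] <- TRUE
    mz <- mz[keep]; it <- it[keep]
    if (cfg$n_contaminant > 0L) {
      mz <- c(mz, stats::runif(cfg$n_contaminant, 100, 1500))
      it <- c(it, stats::runif(cfg$n_contaminant, 0, 0.5 * max(it)))
    }
    pmz <- s$precursor_mz *
      (1 + stats::runif(1L, -cfg$precursor_jitter_ppm,
                        cfg$precursor_jitter_ppm) * 1e-6)
    spectrum(abs(mz), it, native_id = titles[[i]], precursor_mz = pmz,
             charge = s$charge)
  })
}

#' Generate the full synthetic fixture
#'
#' Produces a target library (main + disjoint entrapment spectra), the
#' matching pseudo-reverse decoy library, a noisy query run with ground
#' truth, and the target/entrapment peptide bookkeeping. With `dir` set,
#' writes `target.msp`, `decoy.msp`, `queries.mgf`, `truth.tsv`,
#' `proteome.fasta`, `entrapment_peptides.txt` and `manifest.json`.
#'
#' @param cfg a [fixture_config()].
#' @param dir optional output directory.
#' @return List: `target` (list of spectra; main first, then entrapment),
#'   `decoy`, `queries`, `truth` (data.frame `query_id`, `title`,
#'   `peptide`, `is_foreign`), `main_peptides`, `entrapment_peptides`,
#'   `R` (target/entrapment peptide ratio), `cfg`.
#' @export
generate_fixture <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "fixture_config"))
  n_entrap <- round(cfg$n_target_spectra * cfg$entrapment_fraction)
  n_main <- cfg$n_target_spectra - n_entrap
  n_foreign_pool <- max(ceiling(cfg$n_queries * cfg$fraction_foreign * 2), 10L)

  ## grow a peptide pool until every quota can be filled
  set.seed(cfg$seed)
  peptides <- character(0)
  proteome <- character(0)
  batch <- 0L
  repeat {
    batch <- batch + 1L
    prot <- generate_proteome(40L, cfg$protein_length,
                              seed = cfg$seed + 1000L * batch)
    proteome <- c(proteome, prot)
    peps <- unlist(lapply(prot, digest, missed_cleavages = cfg$missed_cleavages),
                   use.names = FALSE)
    len <- nchar(peps)
    peps <- peps[len >= cfg$peptide_length[[1L]] & len <= cfg$peptide_length[[2L]]]
    peptides <- unique(c(peptides, peps))
    spec_tab <- enumerate_spectra(peptides, cfg)
    # assign peptides (in pool order) to main/entrapment until quotas filled
    per_pep <- table(factor(spec_tab$peptide, levels = peptides))
    cum <- cumsum(as.integer(per_pep))
    usable <- which(as.integer(per_pep) > 0L)
    if (length(usable) >= n_foreign_pool + 50L &&
        max(cum) >= n_main + n_entrap + 0L) {
      # peptides contributing spectra, in pool order
      contributing <- peptides[usable]
      counts <- as.integer(per_pep)[usable]
      ccum <- cumsum(counts)
      i_main <- which(ccum >= n_main)[[1L]]
      ccum2 <- cumsum(counts[-(1:i_main)])
      if (length(ccum2) && max(ccum2) >= n_entrap) {
        i_entrap <- i_main + which(ccum2 >= n_entrap)[[1L]]
        if (length(contributing) - i_entrap >= n_foreign_pool) break
      }
    }
    if (batch > 50L) stop("fixture generator failed to reach peptide quotas")
  }
  main_peps <- contributing[seq_len(i_main)]
  entrap_peps <- contributing[(i_main + 1L):i_entrap]
  foreign_peps <- contributing[(i_entrap + 1L):(i_entrap + n_foreign_pool)]

  tab_main <- enumerate_spectra(main_peps, cfg)
  tab_main <- utils::head(tab_main[order(match(tab_main$peptide, main_peps)), ],
                          n_main)
  tab_entrap <- enumerate_spectra(entrap_peps, cfg)
  tab_entrap <- utils::head(tab_entrap[order(match(tab_entrap$peptide,
                                                   entrap_peps)), ], n_entrap)
  target_tab <- rbind(tab_main, tab_entrap)
  target <- Map(toy_predict, target_tab$peptide, target_tab$charge)
  names(target) <- NULL

  decoy_map <- make_decoys(unique(target_tab$peptide), seed = cfg$seed + 7L)
  keep <- target_tab$peptide %in% names(decoy_map)
  decoy_tab <- target_tab[keep, , drop = FALSE]
  decoy <- Map(function(p, z) toy_predict(decoy_map[[p]], z, is_decoy = TRUE),
               decoy_tab$peptide, decoy_tab$charge)
  names(decoy) <- NULL

  ## queries: perturbed main-target spectra plus foreign peptides
  set.seed(cfg$seed + 13L)
  n_q <- cfg$n_queries
  truth <- NULL
  queries <- list()
  if (n_q > 0L) {
    is_foreign <- stats::runif(n_q) < cfg$fraction_foreign
    main_idx <- seq_len(nrow(tab_main))   # queries never come from entrapment
    src_main <- sample(main_idx, n_q, replace = TRUE)
    foreign_tab <- enumerate_spectra(foreign_peps, cfg)
    src_foreign <- sample(seq_len(nrow(foreign_tab)), n_q, replace = TRUE)
    sources <- lapply(seq_len(n_q), function(i) {
      if (is_foreign[[i]])
        toy_predict(foreign_tab$peptide[[src_foreign[[i]]]],
                    foreign_tab$charge[[src_foreign[[i]]]])
      else target[[src_main[[i]]]]
    })
    titles <- sprintf("query_%05d", seq_len(n_q))
    queries <- perturb_queries(sources, cfg, titles)
    truth <- data.frame(
      query_id = seq_len(n_q), title = titles,
      peptide = ifelse(is_foreign, "foreign",
                       vapply(sources, function(s) s$peptide, "")),
      is_foreign = is_foreign, stringsAsFactors = FALSE)
  }

  fx <- list(target = target, decoy = decoy, queries = queries, truth = truth,
             main_peptides = unique(tab_main$peptide),
             entrapment_peptides = unique(tab_entrap$peptide),
             R = length(unique(target_tab$peptide)) /
               max(length(unique(tab_entrap$peptide)), 1L),
             cfg = cfg)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_msp(target, file.path(dir, "target.msp"))
    write_msp(decoy, file.path(dir, "decoy.msp"))
    write_mgf(queries, file.path(dir, "queries.mgf"))
    write_fasta(proteome, file.path(dir, "proteome.fasta"))
    if (!is.null(truth))
      utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    writeLines(fx$entrapment_peptides, file.path(dir, "entrapment_peptides.txt"))
    jsonlite::write_json(
      list(seed = cfg$seed, n_target = length(target), n_decoy = length(decoy),
           n_queries = length(queries),
           n_foreign = if (is.null(truth)) 0L else sum(truth$is_foreign),
           n_main_peptides = length(fx$main_peptides),
           n_entrapment_peptides = length(fx$entrapment_peptides),
           R = fx$R),
      file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  fx
}
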