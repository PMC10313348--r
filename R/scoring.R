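## Spectral similarity scoring.
##
## Candidates pre-ranked through the fragment index by a binned dot product
## are rescored here by resolving the binning: a Gaussian bell of standard
## deviation sigma is put over each peak so that small m/z shifts decay the
## matched intensity product smoothly instead of falling off a bin edge.
## For a query Q and reference R (both preprocessed to unit norm):
##
##   similarity(Q,R) = sum_k max_l  I_l * I_k * phi(mz_l, mz_k)
##   phi(x,mu)       = exp(-((x-mu)/sigma)^2 / 2)
##   bias(Q,R)       = sum_k term_k^2 / sum_k term_k
##
## with k over reference peaks and l over query peaks. The dot bias flags
## matches dominated by few peak pairs; the bias-adjusted similarity is
## similarity * (1 - bias). The reflection score applies the same formulas
## after discarding unmatched query peaks (treated as noise) and
## renormalizing the survivors, and the final score is the average of the
## plain and reflection bias-adjusted similarities.

#' Scoring parameters
#'
#' @param sigma Gaussian spread in Da modelling the fragment tolerance;
#'   by convention set equal to the fragment bin width (default 0.2 Da).
#' @param match_cutoff_sigmas truncation radius: peak pairs further apart
#'   than this many sigmas are treated as non-matching (phi exactly 0).
#'   The default 5 ignores contributions below exp(-12.5) ~ 4e-6 and makes
#'   the sorted-merge evaluation exact to tolerance while bounding work.
#' @return A list of class `scoring_params`.
#' @export
scoring_params <- function(sigma = 0.2, match_cutoff_sigmas = 5) {
  stopifnot(sigma > 0, match_cutoff_sigmas > 0)
  structure(list(sigma = sigma, match_cutoff_sigmas = match_cutoff_sigmas),
            class = "scoring_params")
}

#' Gaussian peak-match factor
#'
#' `exp(-0.5 ((x - mu)/sigma)^2)`, truncated to exactly 0 beyond
#' `cutoff_sigmas` standard deviations.
#'
#' @param x,mu m/z values in Thomson (vectorized).
#' @param sigma Gaussian spread in Da.
#' @param cutoff_sigmas truncation radius in sigmas.
#' @return Match factor in \[0, 1\].
#' @export
phi <- function(x, mu, sigma, cutoff_sigmas = 5) {
  stopifnot(sigma > 0)
  z <- (x - mu) / sigma
  out <- exp(-0.5 * z * z)
  out[abs(z) > cutoff_sigmas] <- 0
  out
}

# Per-reference-peak best matched term: term_k = max_l I_l I_k phi(mz_l,mz_k).
# Sorted-merge evaluation, O(|R| log |Q| + total peaks inside the truncation
# radius). Returns term_k, the argmax query index (0 = unmatched) and the
# raw intensity product of the best pair.
gauss_terms <- function(qmz, qint, rmz, rint, p) {
  nk <- length(rmz)
  r <- p$match_cutoff_sigmas * p$sigma
  term <- numeric(nk)
  best <- integer(nk)
  prod_raw <- numeric(nk)
  if (!length(qmz) || !nk)
    return(list(term = term, best = best, prod_raw = prod_raw))
  lo <- findInterval(rmz - r, qmz, left.open = TRUE) + 1L
  hi <- findInterval(rmz + r, qmz)
  inv2s2 <- 0.5 / (p$sigma * p$sigma)
  for (k in seq_len(nk)) {
    if (lo[[k]] > hi[[k]]) next
    idx <- lo[[k]]:hi[[k]]
    d <- qmz[idx] - rmz[[k]]
    v <- qint[idx] * exp(-d * d * inv2s2)
    b <- which.max(v)
    term[[k]] <- rint[[k]] * v[[b]]
    best[[k]] <- idx[[b]]
    prod_raw[[k]] <- rint[[k]] * qint[idx[[b]]]
  }
  list(term = term, best = best, prod_raw = prod_raw)
}

#' Gaussian similarity between a query and a reference spectrum
#'
#' For each reference peak the best-matching query peak (by intensity product
#' weighted with [phi()]) contributes once; the contributions are summed.
#' Both spectra must be preprocessed (unit Euclidean norm) so a self-match of
#' well-separated peaks scores 1.
#'
#' @param Q,R preprocessed [spectrum()] objects (query, reference).
#' @param p [scoring_params()].
#' @return Similarity score.
#' @export
similarity <- function(Q, R, p = scoring_params()) {
  sum(gauss_terms(Q$peaks$mz, Q$peaks$intensity,
                  R$peaks$mz, R$peaks$intensity, p)$term)
}

#' Quadratic-loop reference evaluation of [similarity()]
#'
#' Evaluates the max-over-query-peaks form directly from the full
#' `|Q| x |R|` matrix of Gaussian-weighted intensity products. Used as the
#' independent check of the sorted-merge implementation.
#'
#' @inheritParams similarity
#' @return Similarity score.
#' @export
similarity_oracle <- function(Q, R, p = scoring_params()) {
  qm <- Q$peaks$mz; qi <- Q$peaks$intensity
  rm_ <- R$peaks$mz; ri <- R$peaks$intensity
  if (!length(qm) || !length(rm_)) return(0)
  ph <- phi(outer(qm, rm_, "-"), 0, p$sigma, p$match_cutoff_sigmas)
  m <- (qi * ph) * rep(ri, each = length(qi))
  sum(apply(m, 2L, max))
}

#' Dot bias of a Gaussian similarity match
#'
#' Fraction of the similarity concentrated in few peak pairs:
#' `sum(term^2) / sum(term)` over the per-reference-peak matched terms. By
#' convention the bias is 1 (maximal) when the similarity is 0, so the
#' bias-adjusted similarity of a non-match is 0.
#'
#' @inheritParams similarity
#' @return Bias in (0, 1\] (1 when similarity is 0).
#' @export
bias <- function(Q, R, p = scoring_params()) {
  term <- gauss_terms(Q$peaks$mz, Q$peaks$intensity,
                      R$peaks$mz, R$peaks$intensity, p)$term
  s <- sum(term)
  if (s <= 0) return(1)
  sum(term * term) / s
}

#' Bias-adjusted similarity
#'
#' `similarity * (1 - bias)`: rewards matches spread over many peaks and
#' penalizes matches carried by a single dominant pair.
#'
#' @inheritParams similarity
#' @return Bias-adjusted similarity in \[0, similarity).
#' @export
bias_adjusted <- function(Q, R, p = scoring_params()) {
  term <- gauss_terms(Q$peaks$mz, Q$peaks$intensity,
                      R$peaks$mz, R$peaks$intensity, p)$term
  s <- sum(term)
  if (s <= 0) return(0)
  s * (1 - sum(term * term) / s)
}

#' Reflection scores: similarity on matched query peaks only
#'
#' Query peaks with no reference peak within the truncation radius are
#' considered noise (reference libraries predict only b/y ions, so real but
#' unpredicted ion types should not penalize a correct match). The surviving
#' query intensities are renormalized to unit Euclidean norm and the
#' similarity, bias and bias adjustment are recomputed against `R`. With no
#' matched query peak all three values are 0.
#'
#' @inheritParams similarity
#' @return Named numeric vector: `reflection_similarity`, `reflection_bias`,
#'   `reflection_bias_adjusted`.
#' @export
reflection_scores <- function(Q, R, p = scoring_params()) {
  qm <- Q$peaks$mz; qi <- Q$peaks$intensity
  rm_ <- R$peaks$mz
  r <- p$match_cutoff_sigmas * p$sigma
  if (!length(qm) || !length(rm_))
    return(c(reflection_similarity = 0, reflection_bias = 0,
             reflection_bias_adjusted = 0))
  # a query peak is matched iff some reference peak lies within the radius
  lo <- findInterval(qm - r, rm_, left.open = TRUE) + 1L
  hi <- findInterval(qm + r, rm_)
  keep <- lo <= hi
  if (!any(keep))
    return(c(reflection_similarity = 0, reflection_bias = 0,
             reflection_bias_adjusted = 0))
  qm2 <- qm[keep]
  qi2 <- qi[keep]
  qi2 <- qi2 / sqrt(sum(qi2 * qi2))
  term <- gauss_terms(qm2, qi2, rm_, R$peaks$intensity, p)$term
  s <- sum(term)
  b <- if (s > 0) sum(term * term) / s else 1
  c(reflection_similarity = s, reflection_bias = b,
    reflection_bias_adjusted = if (s > 0) s * (1 - b) else 0)
}

#' Binned spectral dot product
#'
#' The score the fragment index accumulates: intensities are summed within
#' half-open m/z bins of width `B` and the per-bin sums multiplied, i.e. a
#' peak pair contributes iff both peaks fall in the same bin.
#'
#' @inheritParams similarity
#' @param B bin width in Da.
#' @return Dot product in \[0, 1\] for unit-norm spectra.
#' @export
binned_dot <- function(Q, R, B) {
  stopifnot(B > 0)
  qb <- floor(Q$peaks$mz / B)
  rb <- floor(R$peaks$mz / B)
  qs <- rowsum(Q$peaks$intensity, qb)
  rs <- rowsum(R$peaks$intensity, rb)
  common <- intersect(rownames(qs), rownames(rs))
  if (!length(common)) return(0)
  sum(qs[common, 1L] * rs[common, 1L])
}

#' Log-hyperscore of a match
#'
#' `ln(N_b!) + ln(N_y!) + ln(N_other!) + ln(1 + sum of matched intensity
#' products)`, with N_b / N_y the counts of matched b- and y-labelled
#' reference peaks and unlabelled reference peaks counted in a single third
#' series. Log-factorials are evaluated via the log-gamma function. Emitted
#' as a rescoring feature only.
#'
#' @inheritParams similarity
#' @return Log-hyperscore (0 when nothing matches).
#' @export
log_hyperscore <- function(Q, R, p = scoring_params()) {
  g <- gauss_terms(Q$peaks$mz, Q$peaks$intensity,
                   R$peaks$mz, R$peaks$intensity, p)
  matched <- g$term > 0
  if (!any(matched)) return(0)
  lab <- R$peaks$ion_label[matched]
  series <- ifelse(is.na(lab), "other",
                   ifelse(startsWith(lab, "b"), "b",
                          ifelse(startsWith(lab, "y"), "y", "other")))
  n_b <- sum(series == "b")
  n_y <- sum(series == "y")
  n_o <- sum(series == "other")
  lgamma(n_b + 1) + lgamma(n_y + 1) + lgamma(n_o + 1) +
    log1p(sum(g$prod_raw[matched]))
}

#' SpectraST-style f-value feature
#'
#' `0.6 * dot1 - 0.4 * (dot1 - dot2)` from the binned dot products of the
#' top-ranked and runner-up matches of a query (`dot2 = 0` when no runner-up
#' exists). A rescoring feature, never the primary ranking score.
#'
#' @param dot1 binned dot product of the rank-1 match.
#' @param dot2 binned dot product of the rank-2 match (default 0).
#' @return f-value.
#' @export
f_value <- function(dot1, dot2 = 0) {
  0.6 * dot1 - 0.4 * (dot1 - dot2)
}

#' Full score vector for one query-reference pair
#'
#' Computes every per-pair score and metadata feature carried by a PSM:
#' binned dot, Gaussian similarity/bias/bias-adjusted similarity, the
#' reflection variants, their average (the final ranking score), the
#' log-hyperscore, shared peak count, the standard deviation of matched
#' fragment m/z differences, the absolute precursor m/z difference and the
#' peptide length. Rank-dependent features (`delta_final`, `f_value`) are
#' filled in after ranking.
#'
#' @inheritParams similarity
#' @param B fragment bin width in Da used for the binned dot product.
#' @return Named numeric vector of scores.
#' @export
score_pair <- function(Q, R, p = scoring_params(), B = p$sigma) {
  g <- gauss_terms(Q$peaks$mz, Q$peaks$intensity,
                   R$peaks$mz, R$peaks$intensity, p)
  s <- sum(g$term)
  b <- if (s > 0) sum(g$term * g$term) / s else 1
  ba <- if (s > 0) s * (1 - b) else 0
  refl <- reflection_scores(Q, R, p)
  matched <- g$term > 0
  n_match <- sum(matched)
  dmz <- Q$peaks$mz[g$best[matched]] - R$peaks$mz[matched]
  mz_sd <- if (n_match >= 2L) stats::sd(dmz) else 0
  lab <- R$peaks$ion_label[matched]
  series <- ifelse(is.na(lab), "other",
                   ifelse(startsWith(lab, "b"), "b",
                          ifelse(startsWith(lab, "y"), "y", "other")))
  lh <- if (n_match)
    lgamma(sum(series == "b") + 1) + lgamma(sum(series == "y") + 1) +
      lgamma(sum(series == "other") + 1) + log1p(sum(g$prod_raw[matched]))
  else 0
  pep_len <- if (!is.na(R$peptide)) nchar(R$peptide) else 0
  pmz_diff <- if (is.na(Q$precursor_mz) || is.na(R$precursor_mz)) 0
              else abs(Q$precursor_mz - R$precursor_mz)
  c(dot = binned_dot(Q, R, B),
    similarity = s,
    bias = b,
    bias_adjusted = ba,
    refl,
    final_score = (ba + refl[["reflection_bias_adjusted"]]) / 2,
    log_hyperscore = lh,
    shared_peak_count = n_match,
    mz_sd_matched = mz_sd,
    abs_mass_diff_precursor = pmz_diff,
    peptide_length = pep_len)
}
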