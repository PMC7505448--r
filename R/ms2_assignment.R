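#' @title MS2 spectrum assignment
#' @description Match predicted fragment ions to observed MS2 peaks and
#'   score candidates with a hypergeometric match probability, assigning
#'   each spectrum to its best lipid candidate.
#' @name ms2_assignment
NULL

#' Construct an MS2 spectrum
#'
#' @param precursor_mz Precursor m/z (Da/charge).
#' @param polarity `"positive"` or `"negative"`.
#' @param retention_time Minutes; must lie in the 0-17 min gradient span.
#' @param mz,intensity Peak list vectors (intensities >= 0). Peaks are
#'   stored sorted by m/z whatever the input order.
#' @param run_id Integer acquisition-run index (iterative exclusion runs).
#' @return An `ms2_spectrum` object.
#' @export
ms2_spectrum <- function(precursor_mz, polarity, retention_time,
                         mz, intensity = rep(1, length(mz)), run_id = 1L) {
  stopifnot(precursor_mz > 0, polarity %in% c("positive", "negative"))
  if (retention_time < 0 || retention_time > 17) {
    stop("retention_time outside the 0-17 min gradient")
  }
  if (length(mz) != length(intensity)) stop("mz/intensity length mismatch")
  if (any(mz <= 0)) stop("peak m/z must be positive")
  if (any(intensity < 0)) stop("peak intensities must be >= 0")
  ord <- order(mz)
  structure(list(precursor_mz = precursor_mz, polarity = polarity,
                 retention_time = retention_time,
                 mz = mz[ord], intensity = intensity[ord],
                 run_id = as.integer(run_id)),
            class = "ms2_spectrum")
}

#' @export
format.ms2_spectrum <- function(x, ...) {
  sprintf("MS2 %s m/z %.4f @ %.2f min (%d peaks, run %d)",
          x$polarity, x$precursor_mz, x$retention_time, length(x$mz), x$run_id)
}

#' @export
print.ms2_spectrum <- function(x, ...) cat(format(x), "\n")

#' Match theoretical fragments against observed peaks
#'
#' Greedy nearest-m/z matching: fragments are processed in increasing
#' order of their distance to the closest available peak, each fragment
#' matches at most one peak within `tol_ppm`, and each peak is consumed
#' at most once. The result is invariant to the input ordering of peaks
#' and fragments.
#'
#' @param spectrum An [ms2_spectrum()].
#' @param fragment_mz Numeric vector of theoretical fragment m/z.
#' @param tol_ppm Match tolerance in parts-per-million (> 0).
#' @return List with `n_matched` and `matched_mz` (the matched peak m/z,
#'   in fragment order of the matches made).
#' @export
match_fragments <- function(spectrum, fragment_mz, tol_ppm = 20) {
  stopifnot(tol_ppm > 0)
  fragment_mz <- sort(unique(fragment_mz))
  if (length(fragment_mz) == 0 || length(spectrum$mz) == 0) {
    return(list(n_matched = 0L, matched_mz = numeric(0)))
  }
  peaks <- spectrum$mz
  used <- rep(FALSE, length(peaks))
  # candidate (fragment, peak) pairs within tolerance, best first
  cand <- do.call(rbind, lapply(seq_along(fragment_mz), function(i) {
    d <- abs(peaks - fragment_mz[i])
    ok <- which(d <= fragment_mz[i] * tol_ppm * 1e-6)
    if (length(ok) == 0) return(NULL)
    cbind(frag = i, peak = ok, d = d[ok])
  }))
  if (is.null(cand)) return(list(n_matched = 0L, matched_mz = numeric(0)))
  cand <- cand[order(cand[, "d"], cand[, "frag"], cand[, "peak"]), , drop = FALSE]
  frag_done <- rep(FALSE, length(fragment_mz))
  matched <- numeric(0)
  for (r in seq_len(nrow(cand))) {
    fi <- cand[r, "frag"]; pi <- cand[r, "peak"]
    if (frag_done[fi] || used[pi]) next
    frag_done[fi] <- TRUE
    used[pi] <- TRUE
    matched <- c(matched, peaks[pi])
  }
  list(n_matched = length(matched), matched_mz = sort(matched))
}

#' Hypergeometric fragment-match score
#'
#' Under the null that `n_peaks` observed peaks fall uniformly at random
#' into `n_bins` m/z tolerance bins of which `n_theoretical` are predicted
#' fragment positions, the number of coincidences X is hypergeometric.
#' The score is `-log10 P(X >= n_matched)`; 0 when nothing matched.
#'
#' @param n_bins Number of tolerance-width bins spanning the spectrum.
#' @param n_theoretical Number of predicted fragment bins (<= n_bins).
#' @param n_peaks Number of observed peaks (<= n_bins).
#' @param n_matched Number of matched fragments
#'   (<= min(n_theoretical, n_peaks)).
#' @return Non-negative score.
#' @examples
#' hypergeometric_score(10, 4, 5, 3) # -log10(66/252)
#' @export
hypergeometric_score <- function(n_bins, n_theoretical, n_peaks, n_matched) {
  if (n_matched < 0 || n_matched > min(n_theoretical, n_peaks)) {
    stop("n_matched must be between 0 and min(n_theoretical, n_peaks)")
  }
  if (n_theoretical > n_bins || n_peaks > n_bins) {
    stop("n_theoretical and n_peaks cannot exceed n_bins")
  }
  if (n_matched == 0) return(0.0)
  # P(X >= k) with X ~ Hypergeom(n_bins, n_theoretical successes, n_peaks draws)
  logp <- stats::phyper(n_matched - 1, n_theoretical, n_bins - n_theoretical,
                        n_peaks, lower.tail = FALSE, log.p = TRUE)
  max(0, -logp / log(10))
}

# Bin count for the hypergeometric null: spectrum m/z span divided by
# twice the fragment tolerance (in Da at the span midpoint). Clamped so
# the score's preconditions always hold.
spectrum_bin_count <- function(spectrum, tol_ppm, n_theoretical) {
  span <- diff(range(spectrum$mz))
  mid <- mean(range(spectrum$mz))
  width <- 2 * tol_ppm * 1e-6 * mid
  n <- if (span > 0 && width > 0) floor(span / width) else 0
  max(n, length(spectrum$mz) + n_theoretical)
}

#' Score one candidate lipid against a spectrum
#'
#' @param spectrum An [ms2_spectrum()].
#' @param species A [lipid_species()].
#' @param adduct Precursor adduct consistent with the spectrum polarity.
#' @param fragment_tol_ppm Fragment match tolerance (ppm).
#' @return A one-row data.frame (`match_result`): species name, adduct,
#'   counts, score, precursor error in ppm, and matched m/z values in a
#'   list column.
#' @export
score_candidate <- function(spectrum, species, adduct, fragment_tol_ppm = 20) {
  frags <- predict_fragments(species, spectrum$polarity, adduct)
  mres <- match_fragments(spectrum, frags$mz, fragment_tol_ppm)
  n_theor <- nrow(frags)
  n_bins <- spectrum_bin_count(spectrum, fragment_tol_ppm, n_theor)
  score <- hypergeometric_score(n_bins, n_theor, length(spectrum$mz),
                                mres$n_matched)
  prec_err <- (spectrum$precursor_mz - precursor_mz(species, adduct)) /
    precursor_mz(species, adduct) * 1e6
  out <- data.frame(species = species$name, class = species$lipid_class,
                    adduct = adduct, n_theoretical = n_theor,
                    n_matched = mres$n_matched, score = score,
                    precursor_ppm_error = prec_err, stringsAsFactors = FALSE)
  out$matched_mz <- list(mres$matched_mz)
  out
}

#' Assign an MS2 spectrum against a lipid library
#'
#' Candidates are species/adduct pairs whose theoretical precursor m/z
#' lies within `precursor_tol_ppm` of the observed precursor and whose
#' adduct polarity matches the spectrum. All candidates are scored; the
#' result is sorted by descending score (ties broken by smaller absolute
#' precursor error) and truncated below `min_score`.
#'
#' @param spectrum An [ms2_spectrum()].
#' @param library A `lipid_library` from [build_lipid_library()].
#' @param precursor_tol_ppm Precursor tolerance (ppm), default 10.
#' @param fragment_tol_ppm Fragment tolerance (ppm), default 20.
#' @param min_score Minimum score kept (default 2, i.e. P <= 0.01).
#' @param adducts Adducts to consider (default all supported).
#' @return data.frame of ranked match results (possibly zero rows).
#' @export
assign_spectrum <- function(spectrum, library, precursor_tol_ppm = 10,
                            fragment_tol_ppm = 20, min_score = 2,
                            adducts = supported_adducts()) {
  stopifnot(nrow(library) > 0)
  species <- attr(library, "species")
  adducts <- adducts[vapply(adducts, adduct_polarity, character(1)) ==
                       spectrum$polarity]
  rows <- list()
  for (ad in adducts) {
    theo <- (library$monoisotopic_mass + .ADDUCTS[[ad]]$delta)
    err <- abs(spectrum$precursor_mz - theo) / theo * 1e6
    for (i in which(err <= precursor_tol_ppm)) {
      rows[[length(rows) + 1]] <-
        score_candidate(spectrum, species[[library$name[i]]], ad,
                        fragment_tol_ppm)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(species = character(0), class = character(0),
                      adduct = character(0), n_theoretical = integer(0),
                      n_matched = integer(0), score = numeric(0),
                      precursor_ppm_error = numeric(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, rows)
  res <- res[res$score >= min_score, , drop = FALSE]
  res <- res[order(-res$score, abs(res$precursor_ppm_error)), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Merge spectra from iterative-exclusion runs
#'
#' Takes the union of several acquisition runs; spectra whose precursor
#' m/z agree within `tol_ppm` and retention times within `rt_window`
#' minutes are collapsed, keeping the spectrum with more peaks.
#'
#' @param runs List of lists of [ms2_spectrum()] (one list per run).
#' @param tol_ppm Precursor agreement tolerance (default 5 ppm).
#' @param rt_window Retention-time agreement window (default 0.2 min).
#' @return Flat list of merged spectra.
#' @export
merge_iterative_runs <- function(runs, tol_ppm = 5, rt_window = 0.2) {
  stopifnot(length(runs) >= 1)
  all_spec <- do.call(c, runs)
  if (length(all_spec) <= 1) return(all_spec)
  # prefer richer spectra so the keeper of each group has the most peaks
  npk <- vapply(all_spec, function(s) length(s$mz), integer(1))
  ord <- order(-npk)
  kept <- list()
  for (i in ord) {
    s <- all_spec[[i]]
    dup <- any(vapply(kept, function(k) {
      abs(k$precursor_mz - s$precursor_mz) / s$precursor_mz * 1e6 <= tol_ppm &&
        abs(k$retention_time - s$retention_time) <= rt_window
    }, logical(1)))
    if (!dup) kept[[length(kept) + 1]] <- s
  }
  # deterministic output order: by precursor then RT
  key <- order(vapply(kept, `[[`, numeric(1), "precursor_mz"),
               vapply(kept, `[[`, numeric(1), "retention_time"))
  kept[key]
}

#' Export a manual-review table of top candidates per spectrum
#'
#' Assignments are conventionally confirmed by eye; this produces the
#' table an analyst would review: up to `top_n` candidates per spectrum
#' with scores and matched fragments.
#'
#' @param spectra List of [ms2_spectrum()].
#' @param library A `lipid_library`.
#' @param top_n Candidates retained per spectrum (default 3).
#' @param ... Passed to [assign_spectrum()].
#' @return data.frame with one row per (spectrum, candidate).
#' @export
review_table <- function(spectra, library, top_n = 3, ...) {
  rows <- lapply(seq_along(spectra), function(i) {
    res <- assign_spectrum(spectra[[i]], library, ...)
    if (nrow(res) == 0) return(NULL)
    res <- utils::head(res, top_n)
    res$spectrum_id <- i
    res$rank <- seq_len(nrow(res))
    res$precursor_mz <- spectra[[i]]$precursor_mz
    res$retention_time <- spectra[[i]]$retention_time
    res$matched_mz <- vapply(res$matched_mz, function(x)
      paste(sprintf("%.4f", x), collapse = ";"), character(1))
    res
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0) {
    return(data.frame(spectrum_id = integer(0), rank = integer(0),
                      species = character(0), score = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("spectrum_id", "rank", "species", "class", "adduct",
          "precursor_mz", "retention_time", "n_theoretical", "n_matched",
          "score", "precursor_ppm_error", "matched_mz")]
}
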