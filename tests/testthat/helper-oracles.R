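# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: masses come from a separately transcribed
# atomic-mass table, and the hypergeometric tail is computed by direct
# combinatorial enumeration of binomial coefficients.

# CODATA/AME atomic masses, transcribed independently of R/masses.R
ORACLE_MASSES <- c(
  C = 12.0,
  H = 1.007825032,
  N = 14.003074005,
  O = 15.994914620,
  P = 30.973761998
)
ORACLE_ELECTRON <- 0.000548579909

# element-wise mass sum from a formula string like "C42H82NO8P"
oracle_mass_from_string <- function(s) {
  m <- gregexpr("([A-Z])([0-9]*)", s)[[1]]
  parts <- regmatches(s, list(m))[[1]]
  total <- 0
  for (p in parts) {
    el <- gsub("[0-9]", "", p)
    n <- gsub("[A-Z]", "", p)
    n <- if (nzchar(n)) as.numeric(n) else 1
    total <- total + n * ORACLE_MASSES[[el]]
  }
  total
}

# deprotonated fatty-acid anion mass for a c:d chain
oracle_carboxylate_mz <- function(carbons, dbs) {
  h <- 2 * carbons - 1 - 2 * dbs
  carbons * ORACLE_MASSES[["C"]] + h * ORACLE_MASSES[["H"]] +
    2 * ORACLE_MASSES[["O"]] + ORACLE_ELECTRON
}

# P(X >= k), X ~ Hypergeometric(N bins, T success bins, P draws), by
# explicit enumeration of favourable configurations
oracle_hyper_tail <- function(N, T, P, k) {
  js <- k:min(T, P)
  js <- js[P - js <= N - T]
  sum(choose(T, js) * choose(N - T, P - js)) / choose(N, P)
}

# build a noise-free MS2 spectrum for a species in its informative mode
noise_free_spectrum <- function(species, polarity, adduct = NULL, rt = 5) {
  if (is.null(adduct)) adduct <- if (polarity == "positive") "[M+H]+" else "[M-H]-"
  fr <- predict_fragments(species, polarity, adduct)
  ms2_spectrum(precursor_mz(species, adduct), polarity, rt,
               fr$mz, rep(1, nrow(fr)))
}

# small paper-like ground truth without replicate jitter
exact_truth <- function(seed = 1) {
  generate_lipidome("paper-like", seed = seed, jitter_sigma = 0)
}
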