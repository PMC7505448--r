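#' Monoisotopic atomic masses
#'
#' Monoisotopic masses (Da) of the elements occurring in phospholipids and
#' sphingolipids, taken from the NIST/CODATA atomic mass evaluation. Shipped
#' as a constant so that no network lookup is ever needed.
#'
#' @format Named numeric vector (element symbol -> Da).
#' @export
ATOMIC_MASSES <- c(
  C = 12.0,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.9949146196,
  P = 30.97376163
)

#' Mass of a proton in Da (charge carrier for [M+H]+ / [M-H]-).
#' @export
PROTON_MASS <- 1.007276467

# Adduct mass deltas for singly charged species. The delta already accounts
# for electron gain/loss, so precursor m/z = (M + delta) / |z|.
.ADDUCTS <- list(
  "[M+H]+"    = list(delta = 1.007276467,  polarity = "positive"),
  "[M+Na]+"   = list(delta = 22.98922142,  polarity = "positive"),
  "[M-H]-"    = list(delta = -1.007276467, polarity = "negative"),
  "[M+HCOO]-" = list(delta = 44.998201,    polarity = "negative")
)

#' Supported precursor adducts
#'
#' @return Character vector of adduct labels understood by
#'   [precursor_mz()] and [predict_fragments()].
#' @export
supported_adducts <- function() names(.ADDUCTS)

#' Monoisotopic mass of an elemental formula
#'
#' Sums `count * monoisotopic atomic mass` over the elements of a formula.
#' Additive: `monoisotopic_mass(a) + monoisotopic_mass(b)` equals the mass
#' of the merged formula.
#'
#' @param formula Named numeric vector of element counts, e.g.
#'   `c(C = 42, H = 82, N = 1, O = 8, P = 1)`. An empty vector has mass 0.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass(c(H = 2, O = 1)) # water, 18.0106 Da
#' @export
monoisotopic_mass <- function(formula) {
  if (length(formula) == 0) return(0.0)
  el <- names(formula)
  if (is.null(el) || any(!nzchar(el))) {
    stop("formula must be a named vector of element counts")
  }
  unknown <- setdiff(el, names(ATOMIC_MASSES))
  if (length(unknown) > 0) {
    stop("unsupported element(s): ", paste(unknown, collapse = ", "))
  }
  sum(unlist(formula) * ATOMIC_MASSES[el])
}

# Merge formulas by element-wise addition; `mult` scales each term.
formula_sum <- function(..., mult = NULL) {
  terms <- list(...)
  if (is.null(mult)) mult <- rep(1, length(terms))
  acc <- c()
  for (i in seq_along(terms)) {
    f <- terms[[i]]
    for (el in names(f)) {
      acc[el] <- (if (el %in% names(acc)) acc[[el]] else 0) + mult[i] * f[[el]]
    }
  }
  acc <- acc[acc != 0]
  # canonical Hill-like order: C, H, then alphabetical
  ord <- c("C", "H", setdiff(sort(names(acc)), c("C", "H")))
  acc[ord[ord %in% names(acc)]]
}

# Format a formula vector as a compact string, e.g. "C42H82NO8P".
format_formula <- function(formula) {
  paste0(vapply(names(formula), function(el) {
    n <- formula[[el]]
    if (n == 1) el else paste0(el, n)
  }, character(1)), collapse = "")
}

# Parse "C42H82NO8P" back into a named count vector.
parse_formula <- function(x) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", x)[[1]]
  parts <- regmatches(x, list(m))[[1]]
  out <- c()
  for (p in parts) {
    el <- gsub("[0-9]", "", p)
    n <- gsub("[A-Za-z]", "", p)
    out[el] <- (if (el %in% names(out)) out[[el]] else 0) +
      (if (nzchar(n)) as.numeric(n) else 1)
  }
  out
}
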