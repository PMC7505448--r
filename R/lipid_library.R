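#' @title Lipid species and the mass library
#' @description Constructors and mass/fragment calculators for the
#'   phospholipid and sphingolipid classes seen in plasma extracellular
#'   vesicles: PC, PE, PI, PS, PG, SM, the lyso forms LPC/LPE/LPI, and
#'   cardiolipin (CL).
#' @name lipid_library
NULL

.DIACYL_CLASSES <- c("PC", "PE", "PI", "PS", "PG")
.LYSO_CLASSES <- c("LPC", "LPE", "LPI")
.SUPPORTED_CLASSES <- c(.DIACYL_CLASSES, .LYSO_CLASSES, "SM", "CL")

# Head-group alcohols condensed onto the phosphate (neutral molecules).
.HEAD_ALCOHOLS <- list(
  PC = c(C = 5, H = 13, N = 1, O = 1),  # choline
  PE = c(C = 2, H = 7, N = 1, O = 1),   # ethanolamine
  PI = c(C = 6, H = 12, O = 6),         # myo-inositol
  PS = c(C = 3, H = 7, N = 1, O = 3),   # serine
  PG = c(C = 3, H = 8, O = 3)           # glycerol
)
.GLYCEROL <- c(C = 3, H = 8, O = 3)
.PHOSPHORIC_ACID <- c(H = 3, O = 4, P = 1)
.WATER <- c(H = 2, O = 1)

#' Construct an acyl or sphingoid chain
#'
#' @param carbons Integer chain length (>= 1 for real chains).
#' @param double_bonds Integer number of C=C double bonds.
#' @param linkage `"ester"` for acyl chains, `"sphingoid-d"` for the
#'   dihydroxy sphingoid backbone of sphingomyelin (e.g. d18:1).
#' @return An `acyl_chain` object.
#' @examples
#' acyl_chain(16, 0)
#' acyl_chain(18, 1, "sphingoid-d")
#' @export
acyl_chain <- function(carbons, double_bonds, linkage = c("ester", "sphingoid-d")) {
  linkage <- match.arg(linkage)
  if (length(carbons) != 1 || length(double_bonds) != 1 ||
      carbons != round(carbons) || double_bonds != round(double_bonds)) {
    stop("carbons and double_bonds must be single integers")
  }
  if (carbons < 0 || double_bonds < 0) stop("invalid-species: negative chain counts")
  if (double_bonds > carbons / 2) stop("invalid-species: too many double bonds")
  structure(list(carbons = as.integer(carbons),
                 double_bonds = as.integer(double_bonds),
                 linkage = linkage),
            class = "acyl_chain")
}

#' @export
format.acyl_chain <- function(x, ...) {
  paste0(if (x$linkage == "sphingoid-d") "d" else "", x$carbons, ":", x$double_bonds)
}

#' @export
print.acyl_chain <- function(x, ...) cat(format(x), "\n")

# Parse "16:0" or "d18:1" into an acyl_chain.
parse_chain <- function(txt) {
  sph <- grepl("^d", txt)
  body <- sub("^d", "", txt)
  parts <- strsplit(body, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop("cannot parse chain: ", txt)
  acyl_chain(as.integer(parts[1]), as.integer(parts[2]),
             if (sph) "sphingoid-d" else "ester")
}

# Free fatty acid CnH(2n-2d)O2 for an ester chain.
fatty_acid_formula <- function(chain) {
  c(C = chain$carbons, H = 2 * chain$carbons - 2 * chain$double_bonds, O = 2)
}

# Free sphingoid base (dC:D) CnH(2n+3-2d)NO2, e.g. sphingosine C18H37NO2.
sphingoid_formula <- function(chain) {
  c(C = chain$carbons, H = 2 * chain$carbons + 3 - 2 * chain$double_bonds,
    N = 1, O = 2)
}

validate_chains <- function(lipid_class, chains) {
  n <- length(chains)
  ok <- switch(lipid_class,
    PC = , PE = , PI = , PS = , PG = n == 2,
    LPC = , LPE = , LPI = n == 1,
    SM = n == 2,
    CL = n == 4,
    stop("unsupported-class: ", lipid_class)
  )
  if (!ok) stop("invalid-species: ", lipid_class, " requires a different chain count")
  for (i in seq_along(chains)) {
    ch <- chains[[i]]
    if (!inherits(ch, "acyl_chain")) stop("chains must be acyl_chain objects")
    if (ch$carbons == 0) stop("invalid-species: zero-carbon chain")
    sph <- ch$linkage == "sphingoid-d"
    if (sph && !(lipid_class == "SM" && i == 1)) {
      stop("invalid-species: sphingoid base only valid as first chain of SM")
    }
    if (lipid_class == "SM" && i == 1 && !sph) {
      stop("invalid-species: SM first chain must be sphingoid (d-notation)")
    }
  }
  invisible(TRUE)
}

#' Elemental formula of a lipid species
#'
#' Assembles the neutral-species formula from the backbone (glycerol, or a
#' sphingoid base for SM), phosphate(s), head-group alcohol and fatty acyl
#' chains, with one water lost per condensation bond. Cardiolipin uses
#' three glycerols and two phosphates.
#'
#' @param lipid_class One of `r paste(.SUPPORTED_CLASSES, collapse = ", ")`.
#' @param chains List of [acyl_chain()] objects (count must match class).
#' @return Named numeric vector of element counts.
#' @examples
#' elemental_formula("PC", list(acyl_chain(16, 0), acyl_chain(18, 1)))
#' @export
elemental_formula <- function(lipid_class, chains) {
  if (!lipid_class %in% .SUPPORTED_CLASSES) {
    stop("unsupported-class: ", lipid_class)
  }
  validate_chains(lipid_class, chains)
  if (lipid_class == "SM") {
    # sphingoid base + phosphocholine head + amide-linked N-acyl chain:
    # base + H3PO4 + choline - 2 H2O (phosphodiester) + FA - H2O (amide)
    fa <- fatty_acid_formula(chains[[2]])
    return(formula_sum(sphingoid_formula(chains[[1]]), .PHOSPHORIC_ACID,
                       .HEAD_ALCOHOLS$PC, fa, .WATER,
                       mult = c(1, 1, 1, 1, -3)))
  }
  if (lipid_class == "CL") {
    fas <- Reduce(function(a, b) formula_sum(a, b),
                  lapply(chains, fatty_acid_formula))
    # 3 glycerols + 2 phosphates, 4 phosphoester + 4 acyl-ester bonds
    return(formula_sum(.GLYCEROL, .PHOSPHORIC_ACID, fas, .WATER,
                       mult = c(3, 2, 1, -8)))
  }
  head_key <- sub("^L", "", lipid_class)  # LPC shares the PC head, etc.
  head <- .HEAD_ALCOHOLS[[head_key]]
  fas <- Reduce(function(a, b) formula_sum(a, b),
                lapply(chains, fatty_acid_formula))
  n_bonds <- 2 + length(chains)  # glycerol-P, P-head, one ester per chain
  formula_sum(.GLYCEROL, .PHOSPHORIC_ACID, head, fas, .WATER,
              mult = c(1, 1, 1, 1, -n_bonds))
}

#' Construct a lipid species
#'
#' @param lipid_class Head-group class label (see [elemental_formula()]).
#' @param chains List of [acyl_chain()] objects, or a character vector such
#'   as `c("16:0", "18:1")` / `c("d18:1", "16:0")`.
#' @return A `lipid_species` object with fields `lipid_class`, `chains`,
#'   `formula`, `monoisotopic_mass` and a canonical `name`.
#' @examples
#' lipid_species("PC", c("16:0", "18:1"))
#' lipid_species("SM", c("d18:1", "16:0"))
#' @export
lipid_species <- function(lipid_class, chains) {
  if (is.character(chains)) chains <- lapply(chains, parse_chain)
  if (inherits(chains, "acyl_chain")) chains <- list(chains)
  # sn-position is not resolved by MS: canonicalize ester chain order
  # (sphingoid base stays first for SM)
  est <- vapply(chains, function(c) c$linkage == "ester", logical(1))
  key <- vapply(chains, function(c) c$carbons * 100 + c$double_bonds, numeric(1))
  chains <- c(chains[!est], chains[est][order(key[est])])
  formula <- elemental_formula(lipid_class, chains)
  structure(list(
    lipid_class = lipid_class,
    chains = chains,
    formula = formula,
    monoisotopic_mass = monoisotopic_mass(formula),
    name = paste0(lipid_class, " ",
                  paste(vapply(chains, format, character(1)), collapse = "/"))
  ), class = "lipid_species")
}

#' @export
format.lipid_species <- function(x, ...) {
  sprintf("%s (%s, %.4f Da)", x$name, format_formula(x$formula),
          x$monoisotopic_mass)
}

#' @export
print.lipid_species <- function(x, ...) cat(format(x), "\n")

#' Precursor m/z of a lipid under an adduct
#'
#' @param species A [lipid_species()] (or a bare monoisotopic mass in Da).
#' @param adduct One of [supported_adducts()].
#' @param charge Must be 1 (singly charged precursors only).
#' @return m/z in Da/charge.
#' @examples
#' pc <- lipid_species("PC", c("16:0", "18:1"))
#' precursor_mz(pc, "[M+H]+")
#' @export
precursor_mz <- function(species, adduct, charge = 1) {
  if (!adduct %in% names(.ADDUCTS)) stop("unsupported adduct: ", adduct)
  if (length(charge) != 1 || charge != 1) stop("only singly charged (charge = 1) supported")
  mass <- if (inherits(species, "lipid_species")) species$monoisotopic_mass else species
  (mass + .ADDUCTS[[adduct]]$delta) / abs(charge)
}

adduct_polarity <- function(adduct) .ADDUCTS[[adduct]]$polarity

# m/z of a charged fragment from its neutral-fragment formula.
# positive: lose an electron; negative: gain one.
ion_mz <- function(formula, polarity) {
  e <- 0.00054857990907
  m <- monoisotopic_mass(formula)
  if (polarity == "positive") m - e else m + e
}

#' Predict MS2 fragment ions for a lipid species
#'
#' Minimal canonical glycerophospholipid rule set:
#' \itemize{
#'   \item positive mode (PC, SM, LPC): phosphocholine head-group ion at
#'     m/z 184.0733, plus neutral losses of each ester/amide chain as the
#'     free fatty acid and as its ketene from the protonated precursor;
#'   \item negative mode (PE, PI, PS, PG and lyso forms, CL): one
#'     carboxylate anion [RCOO]- per chain, plus lyso ions (deprotonated
#'     precursor minus one chain as fatty acid or ketene).
#' }
#' The list is sorted by m/z with duplicates (within 1e-6 Da) merged, so
#' library generation is deterministic.
#'
#' @param species A [lipid_species()].
#' @param polarity `"positive"` or `"negative"`.
#' @param adduct Precursor adduct; must match `polarity`.
#' @return data.frame with columns `label`, `mz`, `polarity`.
#' @examples
#' pc <- lipid_species("PC", c("16:0", "18:1"))
#' predict_fragments(pc, "positive", "[M+H]+")
#' @export
predict_fragments <- function(species, polarity = c("positive", "negative"),
                              adduct = NULL) {
  polarity <- match.arg(polarity)
  if (is.null(adduct)) adduct <- if (polarity == "positive") "[M+H]+" else "[M-H]-"
  if (!adduct %in% names(.ADDUCTS)) stop("unsupported adduct: ", adduct)
  if (adduct_polarity(adduct) != polarity) {
    stop("polarity/adduct mismatch: ", adduct, " is not ", polarity)
  }
  frags <- list()
  add <- function(label, mz) frags[[length(frags) + 1]] <<- list(label = label, mz = mz)

  prec <- precursor_mz(species, adduct)
  chains <- species$chains
  ester <- Filter(function(c) c$linkage != "sphingoid-d", chains)

  if (polarity == "positive") {
    # phosphocholine ion C5H15NO4P+ for choline-headgroup classes
    if (species$lipid_class %in% c("PC", "LPC", "SM")) {
      add("phosphocholine head ion",
          ion_mz(c(C = 5, H = 15, N = 1, O = 4, P = 1), "positive"))
    }
    for (ch in ester) {
      fa <- fatty_acid_formula(ch)
      ket <- formula_sum(fa, .WATER, mult = c(1, -1))
      add(paste0("[M+H-FA(", format(ch), ")]+"), prec - monoisotopic_mass(fa))
      add(paste0("[M+H-ketene(", format(ch), ")]+"), prec - monoisotopic_mass(ket))
    }
  } else {
    for (ch in ester) {
      fa <- fatty_acid_formula(ch)
      carbox <- formula_sum(fa, c(H = 1), mult = c(1, -1))
      add(paste0("[RCOO(", format(ch), ")]-"), ion_mz(carbox, "negative"))
      if (length(ester) > 1) {
        ket <- formula_sum(fa, .WATER, mult = c(1, -1))
        add(paste0("[M-H-FA(", format(ch), ")]-"), prec - monoisotopic_mass(fa))
        add(paste0("[M-H-ketene(", format(ch), ")]-"), prec - monoisotopic_mass(ket))
      }
    }
  }
  if (length(frags) == 0) {
    return(data.frame(label = character(0), mz = numeric(0),
                      polarity = character(0), stringsAsFactors = FALSE))
  }
  df <- data.frame(
    label = vapply(frags, `[[`, character(1), "label"),
    mz = vapply(frags, `[[`, numeric(1), "mz"),
    polarity = polarity,
    stringsAsFactors = FALSE
  )
  df <- df[df$mz > 0, , drop = FALSE]
  df <- df[order(df$mz), , drop = FALSE]
  keep <- c(TRUE, diff(df$mz) > 1e-6)
  df <- df[keep, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Build a lipid mass library
#'
#' Enumerates species over chain bounds (carbons 12-24, double bonds 0-6
#' per chain by default) or wraps an explicit species list, returning the
#' table that MS2 assignment searches against.
#'
#' @param species Optional list of [lipid_species()]; if `NULL`, species
#'   are enumerated from `classes` and the chain bounds.
#' @param classes Classes to enumerate when `species` is `NULL`.
#' @param carbons Integer vector of allowed per-chain carbon numbers.
#' @param double_bonds Integer vector of allowed per-chain double bonds.
#' @return A `lipid_library`: data.frame with columns `name`, `class`,
#'   `chains`, `formula`, `monoisotopic_mass`, plus the species objects in
#'   `attr(, "species")`.
#' @export
build_lipid_library <- function(species = NULL,
                                classes = c("PC", "PE", "PI", "SM", "LPC"),
                                carbons = seq(12L, 24L, by = 2L),
                                double_bonds = 0:2) {
  if (is.null(species)) {
    species <- list()
    combos <- expand.grid(c = carbons, d = double_bonds)
    combos <- combos[combos$d <= combos$c / 2, , drop = FALSE]
    chain_set <- Map(function(c, d) acyl_chain(c, d), combos$c, combos$d)
    for (cls in classes) {
      if (cls %in% .LYSO_CLASSES) {
        for (ch in chain_set) species[[length(species) + 1]] <-
            lipid_species(cls, list(ch))
      } else if (cls == "SM") {
        base <- acyl_chain(18, 1, "sphingoid-d")
        for (ch in chain_set) species[[length(species) + 1]] <-
            lipid_species(cls, list(base, ch))
      } else if (cls %in% .DIACYL_CLASSES) {
        n <- length(chain_set)
        for (i in seq_len(n)) for (j in i:n) {
          species[[length(species) + 1]] <-
            lipid_species(cls, list(chain_set[[i]], chain_set[[j]]))
        }
      } else stop("enumeration not supported for class ", cls)
    }
  }
  names(species) <- vapply(species, `[[`, character(1), "name")
  species <- species[!duplicated(names(species))]
  df <- data.frame(
    name = vapply(species, `[[`, character(1), "name"),
    class = vapply(species, `[[`, character(1), "lipid_class"),
    chains = vapply(species, function(s)
      paste(vapply(s$chains, format, character(1)), collapse = "/"), character(1)),
    formula = vapply(species, function(s) format_formula(s$formula), character(1)),
    monoisotopic_mass = vapply(species, `[[`, numeric(1), "monoisotopic_mass"),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$monoisotopic_mass, df$name), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "species") <- species[df$name]
  class(df) <- c("lipid_library", "data.frame")
  df
}

#' Write / read a lipid library as CSV
#'
#' @param library A `lipid_library` from [build_lipid_library()].
#' @param path CSV file path.
#' @return `read_lipid_library` returns the reconstructed `lipid_library`.
#' @export
write_lipid_library <- function(library, path) {
  utils::write.csv(as.data.frame(library)[, c("class", "chains", "formula",
                                              "monoisotopic_mass")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lipid_library
#' @export
read_lipid_library <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  species <- Map(function(cls, ch) {
    lipid_species(cls, strsplit(ch, "/", fixed = TRUE)[[1]])
  }, df$class, df$chains)
  build_lipid_library(species = unname(species))
}
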