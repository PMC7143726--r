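#' @include AllClasses.R
NULL

# monoisotopic masses of the most abundant isotope (Da)
.ELEMENT_MASS <- c(
    C = 12.0,
    H = 1.0078250319,
    N = 14.0030740052,
    O = 15.9949146221,
    P = 30.97376151,
    S = 31.97207069
)

#' Monoisotopic proton mass (Da) used for all adduct arithmetic
#' @export
PROTON_MASS <- 1.0072765

.WATER_MASS <- 2 * .ELEMENT_MASS[["H"]] + .ELEMENT_MASS[["O"]]

#' Parse a molecular formula string
#'
#' Accepts element symbols with optional counts (e.g. \code{"C27H45N9O12"})
#' over the supported element set C, H, N, O, P, S. An empty string parses
#' to the empty formula.
#'
#' @param formula formula string, or an already-parsed named numeric
#'   vector (returned unchanged after validation).
#' @return named numeric vector of element counts.
#' @export
parseFormula <- function(formula) {
    if (is.numeric(formula)) {
        bad <- setdiff(names(formula), names(.ELEMENT_MASS))
        if (length(bad))
            stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
        return(formula[formula != 0])
    }
    formula <- gsub("[ _]", "", formula)
    if (!nzchar(formula)) return(stats::setNames(numeric(0), character(0)))
    parts <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
    if (!length(parts) || sum(nchar(parts)) != nchar(formula))
        stop("unparseable formula: '", formula, "'")
    elem <- sub("[0-9]*$", "", parts)
    cnt <- sub("^[A-Za-z]+", "", parts)
    cnt <- ifelse(nzchar(cnt), as.numeric(cnt), 1)
    bad <- setdiff(elem, names(.ELEMENT_MASS))
    if (length(bad))
        stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
    out <- tapply(cnt, factor(elem, levels = unique(elem)), sum)
    stats::setNames(as.numeric(out), names(out))
}

#' Combine molecular formulas
#'
#' Element-wise addition/subtraction of formulas; subtraction that would
#' drive any element count negative is an error (a molecule cannot lose
#' atoms it does not have).
#'
#' @param a,b formula strings or named count vectors.
#' @return named numeric vector of element counts (zero counts dropped).
#' @export
addFormulas <- function(a, b) {
    a <- parseFormula(a); b <- parseFormula(b)
    els <- union(names(a), names(b))
    out <- stats::setNames(numeric(length(els)), els)
    out[names(a)] <- out[names(a)] + a
    out[names(b)] <- out[names(b)] + b
    out[out != 0]
}

#' @rdname addFormulas
#' @export
subtractFormulas <- function(a, b) {
    a <- parseFormula(a); b <- parseFormula(b)
    els <- union(names(a), names(b))
    out <- stats::setNames(numeric(length(els)), els)
    out[names(a)] <- out[names(a)] + a
    out[names(b)] <- out[names(b)] - b
    if (any(out < 0))
        stop("subtraction yields negative count for: ",
             paste(names(out)[out < 0], collapse = ", "))
    out[out != 0]
}

#' Neutral monoisotopic mass of a molecular formula
#'
#' Sum of count times the mass of each element's most abundant isotope.
#' For instance the cyclic hexapeptide siderophore desferriferrichrome,
#' C27H45N9O12, computes to 687.3188 Da.
#'
#' @param formula formula string or named count vector.
#' @return numeric(1), mass in Da.
#' @examples
#' monoisotopicMass("C27H45N9O12")  # 687.3188
#' monoisotopicMass("H2O")          # 18.0106
#' @export
monoisotopicMass <- function(formula) {
    f <- parseFormula(formula)
    if (!length(f)) return(0)
    sum(f * .ELEMENT_MASS[names(f)])
}

#' m/z of a protonated ion, and back
#'
#' \code{mzFromNeutral} computes the m/z of \eqn{[M+zH]^{z+}}:
#' \eqn{(M + z \cdot m_p)/z} with the proton mass \eqn{m_p = 1.0072765}
#' Da. \code{neutralFromMz} inverts it: \eqn{M = z(m/z - m_p)}.
#'
#' @param neutralMass neutral monoisotopic mass (Da).
#' @param mz observed m/z (Th).
#' @param charge positive integer charge state.
#' @return numeric(1).
#' @examples
#' mzFromNeutral(687.3188, 1)  # 688.3261
#' mzFromNeutral(729.3294, 2)  # 365.6720
#' @export
mzFromNeutral <- function(neutralMass, charge = 1) {
    if (any(charge < 1)) stop("'charge' must be >= 1")
    (neutralMass + charge * PROTON_MASS) / charge
}

#' @rdname mzFromNeutral
#' @export
neutralFromMz <- function(mz, charge = 1) {
    if (any(charge < 1)) stop("'charge' must be >= 1")
    charge * (mz - PROTON_MASS)
}

# residue elemental compositions (loss of water relative to the free
# amino acid); hOrn is N5-acetyl-N5-hydroxyornithine, the hydroxamate
# building block of ferrichrome-type siderophores
.RESIDUE_FORMULA <- list(
    "Gly"     = "C2H3NO",
    "Ala"     = "C3H5NO",
    "Ser"     = "C3H5NO2",
    "Leu/Ile" = "C6H11NO",
    "Arg"     = "C6H12N4O",
    "hOrn"    = "C7H12N2O3"
)

#' Amino-acid residue masses
#'
#' Monoisotopic residue masses (Da) of the residues read from the
#' fragment ladders: Gly, Ala, Ser, the isobaric Leu/Ile pair (never
#' disambiguated at this resolution, reported as a merged symbol), Arg,
#' and hOrn (N5-acetyl-N5-hydroxyornithine, the hydroxamate monomer of
#' ferrichrome siderophores). Masses are computed from the elemental
#' compositions, e.g. Gly = 57.02146, hOrn = 172.08479.
#'
#' @return named numeric vector of residue masses.
#' @export
residueMasses <- function() {
    vapply(.RESIDUE_FORMULA, monoisotopicMass, numeric(1))
}

#' Peptide masses from residue sequences
#'
#' A cyclic peptide's neutral mass is the plain sum of its residue masses
#' (the backbone closes on itself); a linear peptide adds one water. The
#' two therefore differ by exactly 18.0106 Da for any sequence. Three Gly
#' plus three hOrn residues, cyclic, give 687.3188 Da — the
#' desferriferrichrome mass.
#'
#' @param residues character vector of residue symbols present in
#'   [residueMasses()] (e.g. \code{c("Gly", "hOrn")}).
#' @return numeric(1), neutral monoisotopic mass in Da.
#' @examples
#' cyclicPeptideMass(rep(c("Gly", "hOrn"), each = 3))  # 687.3188
#' linearPeptideMass("Gly")                            # 75.0320
#' @export
cyclicPeptideMass <- function(residues) {
    if (!length(residues)) stop("empty residue list")
    rm <- residueMasses()
    bad <- setdiff(residues, names(rm))
    if (length(bad))
        stop("unknown residue symbol(s): ", paste(bad, collapse = ", "))
    sum(rm[residues])
}

#' @rdname cyclicPeptideMass
#' @export
linearPeptideMass <- function(residues) {
    cyclicPeptideMass(residues) + .WATER_MASS
}
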