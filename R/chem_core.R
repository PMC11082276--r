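# Elemental formula arithmetic, monoisotopic masses and adduct ion m/z.
# All downstream mass calculations in the package go through this file.

# Monoisotopic atomic masses in Da (IUPAC/CIAAW 2021 values, >= 6 decimals).
# Committed as constants: no runtime lookup.
.ATOMIC_MASSES <- c(
  H  = 1.0078250319,
  C  = 12.0,
  N  = 14.0030740052,
  O  = 15.9949146221,
  Na = 22.98976928,
  P  = 30.97376151,
  S  = 31.97207069
)

#' Electron rest mass in Da
#'
#' Used to correct ion m/z for the electrons gained or lost on ionisation.
#' Subtracted for positive ions, added for negative ions (see [ion_mz()]).
#'
#' @format A length-one numeric, 0.000548579909 Da (CODATA).
#' @export
ELECTRON_MASS <- 0.000548579909

#' Construct an elemental formula
#'
#' A formula is a named count vector over element symbols, the unit of all
#' mass arithmetic in the package. Counts must be non-negative integers.
#' Formulas support `+` and `-`; subtraction that would drive any element
#' count negative is an error (you cannot remove atoms that are not there).
#'
#' @param ... named integer counts, e.g. `chem_formula(C = 65, H = 118, O = 6)`.
#'   Alternatively a single unnamed character string in Hill-style notation,
#'   e.g. `chem_formula("C65H118O6")`.
#' @return An object of class `chem_formula`.
#' @examples
#' chem_formula(C = 22, H = 42, O = 2)          # erucic acid
#' chem_formula("C65H118O6") + chem_formula(Na = 1)
#' @seealso [monoisotopic_mass()], [ion_mz()]
#' @export
chem_formula <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.null(names(args)) && is.character(args[[1L]])) {
    return(parse_chem_formula(args[[1L]]))
  }
  counts <- unlist(args)
  if (length(counts) == 0L) {
    return(structure(numeric(0), names = character(0), class = "chem_formula"))
  }
  if (is.null(names(counts)) || any(names(counts) == "")) {
    stop("all element counts must be named, e.g. chem_formula(C = 3, H = 8, O = 3)")
  }
  if (any(counts < 0)) {
    stop("element counts must be non-negative, got: ",
         paste(names(counts)[counts < 0], collapse = ", "))
  }
  if (any(counts != round(counts))) {
    stop("element counts must be whole numbers")
  }
  counts <- counts[counts > 0]
  if (length(counts) == 0L) {
    return(structure(numeric(0), names = character(0), class = "chem_formula"))
  }
  # collapse duplicate symbols, fix a deterministic element order
  counts <- tapply(counts, names(counts), sum)
  counts <- counts[order(names(counts))]
  structure(as.numeric(counts), names = names(counts), class = "chem_formula")
}

#' Parse a Hill-style formula string
#'
#' @param text a string such as `"C65H118O6"` or `"C2H8NO4P"`. Element
#'   symbols are one upper-case letter optionally followed by one lower-case
#'   letter; a missing count means 1.
#' @return A `chem_formula`.
#' @export
parse_chem_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- gsub("\\s", "", text)
  if (s == "") return(chem_formula())
  m <- gregexpr("[A-Z][a-z]?[0-9]*", s)[[1L]]
  toks <- regmatches(s, list(m))[[1L]]
  if (sum(attr(m, "match.length")) != nchar(s)) {
    stop("cannot parse formula string: '", text, "'")
  }
  sym <- sub("[0-9]*$", "", toks)
  n <- sub("^[A-Za-z]+", "", toks)
  n <- ifelse(n == "", 1L, as.integer(n))
  do.call(chem_formula, as.list(stats::setNames(n, sym)))
}

#' @export
format.chem_formula <- function(x, ...) {
  if (length(x) == 0L) return("(empty)")
  # Hill order: C, H, then alphabetical
  sym <- names(x)
  ord <- order(match(sym, c("C", "H"), nomatch = 3L), sym)
  paste0(sym[ord], ifelse(x[ord] == 1, "", x[ord]), collapse = "")
}

#' @export
print.chem_formula <- function(x, ...) {
  cat("<chem_formula> ", format(x), "\n", sep = "")
  invisible(x)
}

.as_count_vector <- function(x) {
  if (inherits(x, "chem_formula")) stats::setNames(as.numeric(x), names(x)) else x
}

.counts_to_formula <- function(counts) {
  counts <- counts[counts != 0]
  if (any(counts < 0)) {
    stop("formula subtraction would give negative counts for: ",
         paste(names(counts)[counts < 0], collapse = ", "))
  }
  do.call(chem_formula, as.list(counts))
}

.combine_counts <- function(a, b, sign) {
  a <- .as_count_vector(a)
  b <- .as_count_vector(b)
  sym <- union(names(a), names(b))
  va <- stats::setNames(rep(0, length(sym)), sym)
  va[names(a)] <- a
  vb <- stats::setNames(rep(0, length(sym)), sym)
  vb[names(b)] <- b
  va + sign * vb
}

#' @export
`+.chem_formula` <- function(e1, e2) .counts_to_formula(.combine_counts(e1, e2, +1))

#' @export
`-.chem_formula` <- function(e1, e2) .counts_to_formula(.combine_counts(e1, e2, -1))

#' @export
`==.chem_formula` <- function(e1, e2) {
  d <- .combine_counts(e1, e2, -1)
  all(d == 0)
}

#' Multiply a formula by a non-negative integer
#'
#' @param x a `chem_formula`.
#' @param n a non-negative integer.
#' @return A `chem_formula` with every count scaled by `n`.
#' @export
formula_times <- function(x, n) {
  stopifnot(inherits(x, "chem_formula"), n >= 0, n == round(n))
  if (n == 0 || length(x) == 0L) return(chem_formula())
  .counts_to_formula(.as_count_vector(x) * n)
}

#' Monoisotopic mass of a formula
#'
#' Sum over elements of count times the standard monoisotopic atomic mass.
#' The empty formula has mass 0.
#'
#' @param formula a [chem_formula()].
#' @return Mass in Da (double precision; no rounding).
#' @examples
#' monoisotopic_mass(chem_formula(H = 2, O = 1))  # 18.010565
#' @export
monoisotopic_mass <- function(formula) {
  stopifnot(inherits(formula, "chem_formula"))
  if (length(formula) == 0L) return(0)
  sym <- names(formula)
  unknown <- setdiff(sym, names(.ATOMIC_MASSES))
  if (length(unknown) > 0L) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  sum(as.numeric(formula) * .ATOMIC_MASSES[sym])
}

# ---------------------------------------------------------------------------
# Adducts

.make_adduct <- function(name, delta, sign, z) {
  structure(list(name = name, delta = delta, sign = sign, z = z),
            class = "lt_adduct")
}

# delta is a signed count vector applied to the neutral's counts.
.ADDUCT_REGISTRY <- list(
  "[M+H]+"   = .make_adduct("[M+H]+",   c(H = 1),         +1L, 1L),
  "[M+Na]+"  = .make_adduct("[M+Na]+",  c(Na = 1),        +1L, 1L),
  "[M+NH4]+" = .make_adduct("[M+NH4]+", c(N = 1, H = 4),  +1L, 1L),
  "[M-H]-"   = .make_adduct("[M-H]-",   c(H = -1),        -1L, 1L)
)

#' List or fetch registered adducts
#'
#' The registry covers the singly charged adducts used in glycerolipid
#' work: `[M+H]+`, `[M+Na]+`, `[M+NH4]+` and `[M-H]-`. The deprotonated
#' adduct carries a negative hydrogen delta, so forming it on a
#' hydrogen-free neutral is an error.
#'
#' @param name an adduct name; omit to list all names.
#' @return The adduct object, or a character vector of names.
#' @export
adducts <- function(name = NULL) {
  if (is.null(name)) return(names(.ADDUCT_REGISTRY))
  ad <- .ADDUCT_REGISTRY[[name]]
  if (is.null(ad)) {
    stop("unknown adduct '", name, "'; registered: ",
         paste(names(.ADDUCT_REGISTRY), collapse = ", "))
  }
  ad
}

#' m/z of an adduct ion
#'
#' Computes `(mass(neutral + delta) - sign * z * m_e) / z`: positive ions
#' lose `z` electrons (mass subtracted), negative ions gain them. The
#' electron correction of ~0.00055 Da per charge is what brings sodiated
#' TAG m/z into agreement with high-resolution values at the fourth
#' decimal; it can be switched off for comparison with conventions that
#' ignore it.
#'
#' @param neutral the neutral molecule as a [chem_formula()].
#' @param adduct an adduct name (see [adducts()]) or adduct object.
#' @param electron_correction logical; apply the electron-mass term
#'   (default `TRUE`).
#' @return m/z at full double precision.
#' @examples
#' ion_mz(chem_formula("C65H118O6"), "[M+Na]+")  # 1017.8821
#' @export
ion_mz <- function(neutral, adduct, electron_correction = TRUE) {
  stopifnot(inherits(neutral, "chem_formula"))
  if (is.character(adduct)) adduct <- adducts(adduct)
  stopifnot(inherits(adduct, "lt_adduct"))
  counts <- .combine_counts(neutral, adduct$delta, +1)
  ion <- .counts_to_formula(counts)  # errors on negative counts
  m <- monoisotopic_mass(ion)
  if (electron_correction) m <- m - adduct$sign * adduct$z * ELECTRON_MASS
  m / adduct$z
}

# ---------------------------------------------------------------------------
# Fatty acyls

#' Fatty acid / acyl descriptor
#'
#' Identity is carbon count and double-bond count only; double-bond
#' positions and geometry are not modelled. The free-acid formula is
#' `C_c H_(2c-2db) O2`, so `2c - 2db - 2 >= 0` is required for a
#' non-negative hydrogen count on the acyl residue.
#'
#' @param carbons integer >= 2.
#' @param double_bonds integer >= 0.
#' @return An object of class `fatty_acid`.
#' @examples
#' fatty_acid(22, 1)  # erucic
#' @export
fatty_acid <- function(carbons, double_bonds) {
  stopifnot(length(carbons) == 1L, length(double_bonds) == 1L)
  carbons <- as.integer(carbons)
  double_bonds <- as.integer(double_bonds)
  if (is.na(carbons) || carbons < 2L) stop("carbons must be an integer >= 2")
  if (is.na(double_bonds) || double_bonds < 0L) stop("double_bonds must be >= 0")
  if (2L * carbons - 2L * double_bonds - 2L < 0L) {
    stop("invalid acyl ", carbons, ":", double_bonds,
         " (free-acid hydrogen count would be negative)")
  }
  structure(list(carbons = carbons, double_bonds = double_bonds),
            class = "fatty_acid")
}

#' Parse C:DB shorthand into a fatty acid
#'
#' @param text e.g. `"22:1"`.
#' @return A [fatty_acid()].
#' @export
parse_fatty_acid <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  m <- regmatches(text, regexec("^\\s*(\\d+):(\\d+)\\s*$", text))[[1L]]
  if (length(m) == 0L) stop("cannot parse acyl shorthand: '", text, "'")
  fatty_acid(as.integer(m[2L]), as.integer(m[3L]))
}

#' @export
format.fatty_acid <- function(x, ...) paste0(x$carbons, ":", x$double_bonds)

#' @export
print.fatty_acid <- function(x, ...) {
  cat("<fatty_acid> ", format(x), "\n", sep = "")
  invisible(x)
}

#' @export
`==.fatty_acid` <- function(e1, e2) {
  e1$carbons == e2$carbons && e1$double_bonds == e2$double_bonds
}

#' Free-acid formula of an acyl
#'
#' @param fa a [fatty_acid()].
#' @return `chem_formula` of the free fatty acid `C_c H_(2c-2db) O2`.
#' @export
fatty_acid_formula <- function(fa) {
  stopifnot(inherits(fa, "fatty_acid"))
  chem_formula(C = fa$carbons, H = 2L * fa$carbons - 2L * fa$double_bonds, O = 2L)
}

#' Neutral-loss masses for an acyl ejected from a sodiated precursor
#'
#' Sodiated glycerolipid precursors fragment by losing an acyl substituent
#' either as the free fatty acid (RCOOH) or as its sodium salt (RCOONa).
#' The salt loss exceeds the acid loss by exactly the Na-H mass difference
#' (21.981944 Da).
#'
#' @param fa a [fatty_acid()].
#' @return Named numeric of length two: `acid` and `sodium_salt` loss in Da.
#' @examples
#' acyl_neutral_losses(fatty_acid(22, 1))  # 338.3185, 360.3004
#' @export
acyl_neutral_losses <- function(fa) {
  acid <- monoisotopic_mass(fatty_acid_formula(fa))
  salt <- acid - .ATOMIC_MASSES[["H"]] + .ATOMIC_MASSES[["Na"]]
  c(acid = acid, sodium_salt = salt)
}
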