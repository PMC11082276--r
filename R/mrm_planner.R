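# Class-resolved acquisition planning: precursor-ion scans, neutral-loss
# scans and MRM transition tables with collision energies and dwell times.

# Head-group diagnostics per class. Losses/diagnostics are stored as
# elemental formulas and their masses COMPUTED, never looked up: the
# printed nominal values (141, 277, 185, 189, 115, 179, 341 Da; m/z 184,
# 225) must fall out of the arithmetic.
#
# The scanned adduct per class is the one whose head-group arithmetic
# reproduces the published nominal losses: PE/PS lose their full phospho
# head from [M+H]+; PI/PG/PA lose the full head plus NH3 from [M+NH4]+;
# MGDG/DGDG lose the anhydro glycosyl residue plus NH3 from [M+NH4]+.
# The source method does not state the adducts; this assignment is the
# unique one consistent with the printed numbers.
.HEAD_SCANS <- list(
  PC   = list(type = "precursor-of", polarity = "+", adduct = "[M+H]+",
              # phosphocholine cation C5H15NO4P+
              diagnostic = c(C = 5, H = 15, N = 1, O = 4, P = 1),
              charged = +1L, ce = 35),
  SQDG = list(type = "precursor-of", polarity = "-", adduct = "[M-H]-",
              # sulfoquinovosyl anion C6H9O7S-
              diagnostic = c(C = 6, H = 9, O = 7, S = 1),
              charged = -1L, ce = -55),
  PE   = list(type = "neutral-loss", polarity = "+", adduct = "[M+H]+",
              diagnostic = c(C = 2, H = 8, N = 1, O = 4, P = 1),  # phosphoethanolamine
              charged = 0L, ce = 29),
  PI   = list(type = "neutral-loss", polarity = "+", adduct = "[M+NH4]+",
              diagnostic = c(C = 6, H = 16, N = 1, O = 9, P = 1), # inositol phosphate + NH3
              charged = 0L, ce = 21),
  PS   = list(type = "neutral-loss", polarity = "+", adduct = "[M+H]+",
              diagnostic = c(C = 3, H = 8, N = 1, O = 6, P = 1),  # phosphoserine
              charged = 0L, ce = 21),
  PG   = list(type = "neutral-loss", polarity = "+", adduct = "[M+NH4]+",
              diagnostic = c(C = 3, H = 12, N = 1, O = 6, P = 1), # glycerophosphate + NH3
              charged = 0L, ce = 25),
  PA   = list(type = "neutral-loss", polarity = "+", adduct = "[M+NH4]+",
              diagnostic = c(H = 6, N = 1, O = 4, P = 1),         # phosphoric acid + NH3
              charged = 0L, ce = 25),
  MGDG = list(type = "neutral-loss", polarity = "+", adduct = "[M+NH4]+",
              diagnostic = c(C = 6, H = 13, N = 1, O = 5),        # anhydrohexose + NH3
              charged = 0L, ce = 8),
  DGDG = list(type = "neutral-loss", polarity = "+", adduct = "[M+NH4]+",
              diagnostic = c(C = 12, H = 23, N = 1, O = 10),      # anhydrodihexose + NH3
              charged = 0L, ce = 11)
)

# round half away from zero (base round() goes to even)
.round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Head-group diagnostic scan for a lipid class
#'
#' Returns the class-specific survey scan of a triple-quadrupole
#' glycerolipid method: a precursor-ion scan on a diagnostic fragment (PC
#' on phosphocholine m/z 184, SQDG on the sulfoquinovosyl anion m/z 225)
#' or a neutral-loss scan on the head-group residue (PE 141, PI 277, PS
#' 185, PG 189, PA 115, MGDG 179, DGDG 341 Da). All values are computed
#' from the stored head formulas; `nominal` is the half-away-from-zero
#' integer rounding of the exact value.
#'
#' DAG, TAG and CL have no informative head-group scan and are quantified
#' by MRM only: requesting them is an error pointing to
#' [build_transitions()].
#'
#' @param class a diacyl phospho- or galactolipid class name.
#' @return A list of class `scan_definition` with fields `class`,
#'   `scan_type`, `polarity`, `adduct`, `diagnostic_formula`, `value`
#'   (exact m/z or Da), `nominal`, `ce_ev`, `dwell_ms`.
#' @examples
#' head_group_diagnostic("PE")$nominal   # 141
#' head_group_diagnostic("DGDG")$nominal # 341
#' @export
head_group_diagnostic <- function(class) {
  lipid_classes(class)  # validates the name
  if (class %in% c("DAG", "TAG", "CL")) {
    stop(class, " is quantified by MRM only; use build_transitions()")
  }
  sc <- .HEAD_SCANS[[class]]
  if (is.null(sc)) stop("no head-group scan registered for class ", class)
  f <- .counts_to_formula(sc$diagnostic)
  value <- if (sc$charged > 0L) {
    monoisotopic_mass(f) - ELECTRON_MASS
  } else if (sc$charged < 0L) {
    monoisotopic_mass(f) + ELECTRON_MASS
  } else {
    monoisotopic_mass(f)
  }
  stopifnot(value > 0, sign(sc$ce) == ifelse(sc$polarity == "+", 1, -1))
  structure(list(class = class, scan_type = sc$type, polarity = sc$polarity,
                 adduct = sc$adduct, diagnostic_formula = f,
                 value = value, nominal = .round_half_away(value),
                 ce_ev = sc$ce, dwell_ms = 30),
            class = "scan_definition")
}

#' @export
print.scan_definition <- function(x, ...) {
  cat(sprintf("<scan> %s %s %s %.4f (nominal %d) CE %g eV\n",
              x$class, x$scan_type, x$polarity, x$value,
              as.integer(x$nominal), x$ce_ev))
  invisible(x)
}

.NH3_MASS <- .ATOMIC_MASSES[["N"]] + 3 * .ATOMIC_MASSES[["H"]]

#' Build an MRM transition table
#'
#' One acquisition scheme row per species (and, for molecular-level
#' DAG/TAG, per distinct acyl): DAG and TAG are monitored as ammoniated
#' ions at 19 and 26 eV with 30 ms dwell, CL as deprotonated ions at
#' -45 eV with 50 ms dwell, and the diacyl phospho-/galactolipid classes
#' through their head-group scan (product = precursor - neutral loss, or
#' the fixed diagnostic fragment for precursor-ion classes).
#'
#' Product ions for ammoniated DAG/TAG are the diacyl fragments from loss
#' of one acyl as the free acid together with ammonia; class-total species
#' (acyl split unknown) fall back to the ammonia-loss pseudo-molecular
#' transition. CL rows use a Q3 = Q1 pseudo-transition.
#'
#' @param species character vector or list of [lipid_species()] (strings
#'   are parsed). Class-total and molecular levels accepted; an empty
#'   input yields an empty table.
#' @return A `data.frame` with columns `species`, `class`, `polarity`,
#'   `adduct`, `Q1_mz`, `Q3_mz`, `CE_eV`, `dwell_ms`, sorted by species
#'   label then Q3 (input order never matters).
#' @examples
#' build_transitions(c("TAG 62:4", "PE 34:2"))
#' @export
build_transitions <- function(species) {
  if (length(species) == 0L) {
    return(data.frame(species = character(), class = character(),
                      polarity = character(), adduct = character(),
                      Q1_mz = numeric(), Q3_mz = numeric(),
                      CE_eV = numeric(), dwell_ms = numeric()))
  }
  if (is.character(species)) species <- lapply(species, parse_species)
  stopifnot(all(vapply(species, inherits, TRUE, "lipid_species")))
  rows <- lapply(species, .transitions_for_species)
  out <- do.call(rbind, rows)
  out <- out[order(out$species, out$Q3_mz), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.transitions_for_species <- function(sp) {
  cls <- sp$class
  neutral <- .assemble_formula(cls, sp$total_c, sp$total_db)
  label <- format_species(sp)
  if (cls %in% c("DAG", "TAG")) {
    adduct <- "[M+NH4]+"
    q1 <- ion_mz(neutral, adduct)
    ce <- if (cls == "DAG") 19 else 26
    if (sp$level == "class-total") {
      q3 <- q1 - .NH3_MASS
    } else {
      labs <- vapply(sp$acyls, format, "")
      acyls <- sp$acyls[!duplicated(labs)]
      q3 <- vapply(acyls, function(a) {
        q1 - .NH3_MASS - acyl_neutral_losses(a)[["acid"]]
      }, 0)
    }
    return(data.frame(species = label, class = cls, polarity = "+",
                      adduct = adduct, Q1_mz = q1, Q3_mz = q3,
                      CE_eV = ce, dwell_ms = 30))
  }
  if (cls == "CL") {
    q1 <- ion_mz(neutral, "[M-H]-")
    return(data.frame(species = label, class = cls, polarity = "-",
                      adduct = "[M-H]-", Q1_mz = q1, Q3_mz = q1,
                      CE_eV = -45, dwell_ms = 50))
  }
  sc <- head_group_diagnostic(cls)
  q1 <- ion_mz(neutral, sc$adduct)
  q3 <- if (sc$scan_type == "neutral-loss") q1 - sc$value else sc$value
  data.frame(species = label, class = cls, polarity = sc$polarity,
             adduct = sc$adduct, Q1_mz = q1, Q3_mz = q3,
             CE_eV = sc$ce_ev, dwell_ms = sc$dwell_ms)
}

#' Write a transition table to CSV
#'
#' @param transitions output of [build_transitions()].
#' @param path output file.
#' @param metadata optional named character vector recorded as `#` comment
#'   header lines (e.g. chromatographic free-text notes).
#' @return `path`, invisibly.
#' @export
write_transitions <- function(transitions, path, metadata = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(metadata)) {
    writeLines(paste0("# ", names(metadata), ": ", metadata), con)
  }
  utils::write.csv(transitions, con, row.names = FALSE)
  invisible(path)
}
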