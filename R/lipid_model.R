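# Lipid species grammar, neutral formula assembly and acyl combinatorics.

# Class registry. A species formula is assembled as
#   n_glycerol * C3H8O3 + head + sum(acyl free acids) - (positions + head_waters) * H2O
# i.e. one condensation water per ester bond, including the bond(s) fixing
# the head group. CL is the one two-backbone class: its "head" is the
# central glycerol plus two phosphates, attached through four
# phosphodiester condensations.
.GLYCEROL <- c(C = 3, H = 8, O = 3)
.WATER <- c(H = 2, O = 1)

.LIPID_CLASSES <- list(
  PC   = list(positions = 2L, n_glycerol = 1L, head = c(C = 5, H = 14, N = 1, O = 4, P = 1), head_waters = 1L),
  PE   = list(positions = 2L, n_glycerol = 1L, head = c(C = 2, H = 8, N = 1, O = 4, P = 1), head_waters = 1L),
  PS   = list(positions = 2L, n_glycerol = 1L, head = c(C = 3, H = 8, N = 1, O = 6, P = 1), head_waters = 1L),
  PI   = list(positions = 2L, n_glycerol = 1L, head = c(C = 6, H = 13, O = 9, P = 1), head_waters = 1L),
  PG   = list(positions = 2L, n_glycerol = 1L, head = c(C = 3, H = 9, O = 6, P = 1), head_waters = 1L),
  PA   = list(positions = 2L, n_glycerol = 1L, head = c(H = 3, O = 4, P = 1), head_waters = 1L),
  MGDG = list(positions = 2L, n_glycerol = 1L, head = c(C = 6, H = 12, O = 6), head_waters = 1L),
  DGDG = list(positions = 2L, n_glycerol = 1L, head = c(C = 12, H = 22, O = 11), head_waters = 1L),
  SQDG = list(positions = 2L, n_glycerol = 1L, head = c(C = 6, H = 12, O = 8, S = 1), head_waters = 1L),
  DAG  = list(positions = 2L, n_glycerol = 1L, head = NULL, head_waters = 0L),
  TAG  = list(positions = 3L, n_glycerol = 1L, head = NULL, head_waters = 0L),
  # central glycerol + 2 x H3PO4 bridging two diacylglycerol backbones
  CL   = list(positions = 4L, n_glycerol = 2L, head = c(C = 3, H = 14, O = 11, P = 2), head_waters = 4L)
)

#' Registered lipid classes
#'
#' @param name a class name (e.g. `"TAG"`); omit to list all names.
#' @return The registry entry (positions, head-group counts) or all names.
#' @export
lipid_classes <- function(name = NULL) {
  if (is.null(name)) return(names(.LIPID_CLASSES))
  cl <- .LIPID_CLASSES[[name]]
  if (is.null(cl)) {
    stop("unknown lipid class '", name, "'; known: ",
         paste(names(.LIPID_CLASSES), collapse = ", "))
  }
  cl
}

.class_for_acyl_count <- c(`2` = "DAG", `3` = "TAG", `4` = "CL")

#' Construct a lipid species
#'
#' A species lives at one of three resolution levels:
#' * `"class-total"`: class plus total carbons:double bonds (e.g. TAG 62:4);
#' * `"molecular"`: the acyl multiset is known (e.g. TAG 22:1/18:2/22:1)
#'   but positions are not;
#' * `"sn-resolved"`: additionally one acyl is designated sn-2. The sn-1
#'   and sn-3 positions are never distinguished.
#'
#' @param class a class name from [lipid_classes()].
#' @param acyls list of [fatty_acid()] (molecular/sn-resolved) or `NULL`.
#' @param total_c,total_db totals; required when `acyls` is `NULL`,
#'   otherwise derived and checked if supplied.
#' @param sn2 index (1-based, into the sorted acyl list) of the sn-2 acyl,
#'   or `NULL`.
#' @return An object of class `lipid_species`.
#' @export
lipid_species <- function(class, acyls = NULL, total_c = NULL, total_db = NULL,
                          sn2 = NULL) {
  cl <- lipid_classes(class)
  if (is.null(acyls)) {
    if (is.null(total_c) || is.null(total_db)) {
      stop("class-total species need total_c and total_db")
    }
    if (!is.null(sn2)) stop("sn-2 designation requires an acyl list")
    level <- "class-total"
    acyl_list <- NULL
  } else {
    stopifnot(is.list(acyls), all(vapply(acyls, inherits, TRUE, "fatty_acid")))
    if (length(acyls) != cl$positions) {
      stop(class, " carries ", cl$positions, " acyls, got ", length(acyls))
    }
    sum_c <- sum(vapply(acyls, `[[`, 0L, "carbons"))
    sum_db <- sum(vapply(acyls, `[[`, 0L, "double_bonds"))
    if (!is.null(total_c) && (total_c != sum_c || total_db != sum_db)) {
      stop("acyl totals ", sum_c, ":", sum_db, " disagree with label ",
           total_c, ":", total_db)
    }
    total_c <- sum_c
    total_db <- sum_db
    # canonical order-free storage: sort acyls; remember which is sn-2
    key <- vapply(acyls, function(a) sprintf("%03d:%03d", a$carbons, a$double_bonds), "")
    ord <- order(key)
    if (!is.null(sn2)) {
      stopifnot(sn2 >= 1L, sn2 <= length(acyls))
      sn2 <- match(sn2, ord)
      level <- "sn-resolved"
    } else {
      level <- "molecular"
    }
    acyl_list <- acyls[ord]
  }
  structure(list(class = class, level = level,
                 total_c = as.integer(total_c), total_db = as.integer(total_db),
                 acyls = acyl_list, sn2 = sn2),
            class = "lipid_species")
}

#' Parse lipid shorthand into a species
#'
#' Accepted forms:
#' * `"TAG 62:4"` — class-total;
#' * `"TAG 22:1/18:2/22:1"` or `"22:1/18:2/22:1"` — molecular (class
#'   inferred from the acyl count when omitted: 2 acyls DAG, 3 TAG, 4 CL);
#' * `"DAG 18:0-22:6"` — dash separator accepted on input; `/` is
#'   canonical on output.
#'
#' @param text species shorthand.
#' @return A [lipid_species()].
#' @seealso [format_species()]
#' @export
parse_species <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- trimws(text)
  m <- regmatches(s, regexec("^([A-Za-z]+)\\s+(\\d+):(\\d+)$", s))[[1L]]
  if (length(m) == 4L) {
    return(lipid_species(toupper(m[2L]),
                         total_c = as.integer(m[3L]),
                         total_db = as.integer(m[4L])))
  }
  m <- regmatches(s, regexec(
    "^(?:([A-Za-z]+)\\s+)?(\\d+:\\d+(?:[/-]\\d+:\\d+)+)$", s))[[1L]]
  if (length(m) == 3L) {
    chains <- strsplit(m[3L], "[/-]")[[1L]]
    acyls <- lapply(chains, parse_fatty_acid)
    class <- toupper(m[2L])
    if (class == "") {
      class <- unname(.class_for_acyl_count[as.character(length(acyls))])
      if (is.na(class)) {
        stop("cannot infer class for ", length(acyls), " acyls in '", text, "'")
      }
    }
    return(lipid_species(class, acyls = acyls))
  }
  stop("malformed species text: '", text,
       "' (expected e.g. 'TAG 62:4', 'PC 34:2' or '22:1/18:2/22:1')")
}

#' Canonical text form of a species
#'
#' Class-total species render as `"TAG 62:4"`; molecular species list the
#' sorted acyl multiset (`"TAG 18:2/22:1/22:1"`). For sn-resolved species
#' the sn-2 acyl is printed in the middle position
#' (`"TAG 22:1/18:2/22:1"`); the flanking order carries no meaning since
#' sn-1 and sn-3 are unresolved.
#'
#' @param species a [lipid_species()].
#' @return A single string; `parse_species(format_species(x))` recovers
#'   the class, level and composition of `x`.
#' @export
format_species <- function(species) {
  stopifnot(inherits(species, "lipid_species"))
  if (species$level == "class-total") {
    return(paste0(species$class, " ", species$total_c, ":", species$total_db))
  }
  labs <- vapply(species$acyls, format, "")
  if (species$level == "sn-resolved" && length(labs) == 3L) {
    flank <- labs[-species$sn2]
    labs <- c(flank[1L], labs[species$sn2], flank[2L])
  }
  paste0(species$class, " ", paste(labs, collapse = "/"))
}

#' @export
format.lipid_species <- function(x, ...) format_species(x)

#' @export
print.lipid_species <- function(x, ...) {
  cat("<lipid_species> ", format_species(x), " [", x$level, "]\n", sep = "")
  invisible(x)
}

#' Neutral elemental formula of a molecular species
#'
#' Assembles glycerol backbone(s), head-group residue and acyl free acids,
#' condensing one water per ester bond. Class-total species are rejected:
#' their acyl split is unknown, so enumerate compositions first (the
#' formula happens to depend only on the totals, but the package keeps the
#' levels honest; see [enumerate_compositions()]).
#'
#' @param species a molecular or sn-resolved [lipid_species()].
#' @return The neutral `chem_formula`.
#' @examples
#' species_formula(parse_species("22:1/18:2/22:1"))  # C65H118O6
#' @export
species_formula <- function(species) {
  stopifnot(inherits(species, "lipid_species"))
  if (species$level == "class-total") {
    stop("species '", format_species(species), "' is class-total; ",
         "enumerate acyl compositions first (enumerate_compositions)")
  }
  .assemble_formula(species$class, species$total_c, species$total_db)
}

# The assembly only needs totals: sum of acid formulas over any split of
# (total_c, total_db) into n acyls is C_totc H_(2totc-2totdb) O_(2n).
.assemble_formula <- function(class, total_c, total_db) {
  cl <- lipid_classes(class)
  counts <- .GLYCEROL * cl$n_glycerol
  counts <- .combine_counts(counts, c(C = total_c,
                                      H = 2 * total_c - 2 * total_db,
                                      O = 2 * cl$positions), +1)
  if (!is.null(cl$head)) counts <- .combine_counts(counts, cl$head, +1)
  n_water <- cl$positions + cl$head_waters
  counts <- .combine_counts(counts, .WATER * n_water, -1)
  .counts_to_formula(counts)
}

#' Default fatty-acid pool
#'
#' The acyl chains relevant to Brassicaceae seed oils: palmitic through
#' nervonic, including the very long chain monounsaturates (20:1
#' eicosenoic, 22:1 erucic, 24:1 nervonic) that dominate late seed
#' maturation.
#'
#' @return List of [fatty_acid()]: 16:0, 16:1, 18:0, 18:1, 18:2, 18:3,
#'   20:0, 20:1, 22:1, 24:1.
#' @export
default_acyl_pool <- function() {
  lapply(list(c(16, 0), c(16, 1), c(18, 0), c(18, 1), c(18, 2), c(18, 3),
              c(20, 0), c(20, 1), c(22, 1), c(24, 1)),
         function(x) fatty_acid(x[1L], x[2L]))
}

# all non-decreasing index tuples of length k over 1..n (multisets)
.multiset_indices <- function(n, k) {
  if (k == 0L) return(matrix(integer(0), nrow = 0L))
  idx <- as.matrix(expand.grid(rep(list(seq_len(n)), k)))
  keep <- rep(TRUE, nrow(idx))
  if (k > 1L) {
    for (j in seq_len(k - 1L)) keep <- keep & idx[, j] <= idx[, j + 1L]
  }
  idx[keep, , drop = FALSE]
}

#' Enumerate acyl compositions consistent with a class total
#'
#' All multisets of `positions(class)` acyls drawn with repetition from a
#' pool whose carbons and double bonds sum to the stated totals.
#' Unsatisfiable totals give an empty list. Output is deduplicated and
#' deterministically sorted by formatted acyl label.
#'
#' @param class a lipid class name.
#' @param total_c,total_db total acyl carbons and double bonds.
#' @param pool list of [fatty_acid()]; default [default_acyl_pool()].
#' @return List of acyl multisets (each a sorted list of `fatty_acid`).
#' @examples
#' length(enumerate_compositions("TAG", 62, 4))
#' @export
enumerate_compositions <- function(class, total_c, total_db,
                                   pool = default_acyl_pool()) {
  cl <- lipid_classes(class)
  stopifnot(length(pool) > 0L)
  cs <- vapply(pool, `[[`, 0L, "carbons")
  dbs <- vapply(pool, `[[`, 0L, "double_bonds")
  # deduplicate the pool itself
  key <- paste(cs, dbs)
  keep <- !duplicated(key)
  pool <- pool[keep]; cs <- cs[keep]; dbs <- dbs[keep]
  idx <- .multiset_indices(length(pool), cl$positions)
  if (nrow(idx) == 0L) return(list())
  sum_c <- matrix(cs[idx], nrow = nrow(idx))
  sum_db <- matrix(dbs[idx], nrow = nrow(idx))
  hit <- rowSums(sum_c) == total_c & rowSums(sum_db) == total_db
  idx <- idx[hit, , drop = FALSE]
  if (nrow(idx) == 0L) return(list())
  out <- lapply(seq_len(nrow(idx)), function(i) {
    acyls <- pool[idx[i, ]]
    k <- vapply(acyls, function(a) sprintf("%03d:%03d", a$carbons, a$double_bonds), "")
    acyls[order(k)]
  })
  labs <- vapply(out, function(a) paste(vapply(a, format, ""), collapse = "/"), "")
  out <- out[!duplicated(labs)]
  labs <- labs[!duplicated(labs)]
  out[order(labs)]
}

#' Check a C:DB label against an acyl list
#'
#' `TRUE` iff the acyl carbons and double bonds sum to the stated totals.
#' Published tables occasionally carry labels inconsistent with their own
#' acyl assignment; this validator flags them. An empty acyl list is an
#' error (the check is meaningless without chains).
#'
#' @param total_c,total_db the label totals.
#' @param acyls list of [fatty_acid()].
#' @return Logical scalar.
#' @examples
#' validate_label_consistency(64, 4,
#'   list(fatty_acid(22, 1), fatty_acid(18, 2), fatty_acid(24, 1)))  # TRUE
#' @export
validate_label_consistency <- function(total_c, total_db, acyls) {
  if (length(acyls) == 0L) stop("acyl list is empty; nothing to validate")
  stopifnot(all(vapply(acyls, inherits, TRUE, "fatty_acid")))
  sum_c <- sum(vapply(acyls, `[[`, 0L, "carbons"))
  sum_db <- sum(vapply(acyls, `[[`, 0L, "double_bonds"))
  sum_c == total_c && sum_db == total_db
}

#' Read a species list from file
#'
#' Accepts a one-column text file (one species per line) or a CSV with a
#' `species` column. Lines are canonicalised through
#' [parse_species()]/[format_species()].
#'
#' @param path file path.
#' @return Character vector of canonical species strings.
#' @export
read_species <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl(",", first) || gsub("\"", "", trimws(first)) == "species") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!"species" %in% names(df)) stop("CSV must have a 'species' column")
    raw <- df$species
  } else {
    raw <- readLines(path)
    raw <- trimws(raw)
    raw <- raw[nzchar(raw) & !startsWith(raw, "#")]
  }
  vapply(raw, function(s) format_species(parse_species(s)), "", USE.NAMES = FALSE)
}
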