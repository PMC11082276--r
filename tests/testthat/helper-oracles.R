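# Independent oracles for mass arithmetic and combinatorics.
# These deliberately do NOT reuse the package's mass table or assembly
# code: masses are NIST atomic masses transcribed separately, sums are
# written out longhand.

ORACLE_MASS <- c(
  H  = 1.00782503207,
  C  = 12.0,
  N  = 14.0030740048,
  O  = 15.9949146196,
  Na = 22.9897692809,
  P  = 30.97376163,
  S  = 31.97207100
)
ORACLE_ELECTRON <- 0.00054857990907

# mass of an explicit element-count vector
oracle_mass <- function(counts) {
  sum(counts * ORACLE_MASS[names(counts)])
}

# free fatty acid C_c H_(2c-2db) O2
oracle_acid_mass <- function(c, db) {
  oracle_mass(c(C = c, H = 2 * c - 2 * db, O = 2))
}

# sodiated TAG precursor m/z for three acyls given as c(c, db) pairs:
# glycerol + three acids - 3 waters + Na, minus one electron
oracle_tag_na_mz <- function(acyls) {
  glycerol <- oracle_mass(c(C = 3, H = 8, O = 3))
  water <- oracle_mass(c(H = 2, O = 1))
  acids <- sum(vapply(acyls, function(a) oracle_acid_mass(a[1], a[2]), 0))
  glycerol + acids - 3 * water + ORACLE_MASS[["Na"]] - ORACLE_ELECTRON
}

# exhaustive pool^k triple/pair loop with multiset dedup
oracle_enumerate <- function(k, total_c, total_db, pool_cdb) {
  n <- length(pool_cdb)
  grid <- expand.grid(rep(list(seq_len(n)), k))
  seen <- character()
  for (i in seq_len(nrow(grid))) {
    sel <- pool_cdb[as.integer(grid[i, ])]
    cs <- vapply(sel, `[`, 0, 1)
    dbs <- vapply(sel, `[`, 0, 2)
    if (sum(cs) == total_c && sum(dbs) == total_db) {
      lab <- paste(sort(paste0(cs, ":", dbs)), collapse = "/")
      seen <- union(seen, lab)
    }
  }
  sort(seen)
}

# brute-force per-chain expansion for acyl mole percentages: one row per
# individual chain occurrence, then tabulate
oracle_acyl_pct <- function(species_strings, pmol) {
  chains <- character()
  weight <- numeric()
  for (i in seq_along(species_strings)) {
    s <- sub("^[A-Z]+ ", "", species_strings[i])
    for (a in strsplit(s, "/")[[1]]) {
      chains <- c(chains, a)
      weight <- c(weight, pmol[i])
    }
  }
  tab <- tapply(weight, chains, sum)
  stats::setNames(as.numeric(100 * tab / sum(tab)), names(tab))
}

random_fatty_acid <- function() {
  c <- sample(2:26, 1)
  db <- sample(0:min(6, c - 1), 1)
  fatty_acid(c, db)
}

random_formula <- function() {
  syms <- c("C", "H", "N", "O", "P", "S", "Na")
  pick <- sample(syms, sample(2:5, 1))
  do.call(chem_formula,
          as.list(stats::setNames(sample(1:60, length(pick), replace = TRUE), pick)))
}
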