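# Internal-standard normalisation of MRM responses to pmol and
# mole-fraction summaries across seed maturation stages.
#
# All operations are pure transformations on tidy data.frames
# (sample, stage, replicate, species, value); nothing mutates its input.

.STAGE_LEVELS <- c("G", "GY", "YG", "Y", "M")

#' Seed maturation stage labels
#'
#' GREEN (12 days after flowering), GREEN-YELLOW (19), YELLOW-GREEN (26),
#' YELLOW (33) and MATURE (45 DAF). The vocabulary is the default for
#' validation and ordering; extra labels are accepted anywhere a stage
#' column appears.
#'
#' @return Character vector `c("G", "GY", "YG", "Y", "M")`.
#' @export
stage_levels <- function() .STAGE_LEVELS

.order_stages <- function(x) {
  factor(x, levels = union(.STAGE_LEVELS, unique(x)))
}

.check_peak_table <- function(peaks) {
  need <- c("sample", "stage", "replicate", "species", "response")
  miss <- setdiff(need, names(peaks))
  if (length(miss)) stop("peak table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(peaks$response < 0, na.rm = TRUE)) stop("raw responses must be >= 0")
  dup <- duplicated(peaks[c("sample", "species")])
  if (any(dup)) {
    stop("duplicated (sample, species) rows: ",
         paste(unique(peaks$sample[dup]), collapse = ", "))
  }
  invisible(peaks)
}

#' Internal-standard set
#'
#' One spiked standard per covered class. The packaged default mirrors a
#' common oilseed workflow: di-stearoyl PE, DAG 18:0/22:6 and SQDG
#' 16:0/18:0, each spiked at 125 pmol per sample, response factor 1.
#'
#' @param class character vector of covered classes.
#' @param standard_species species string of each spiked standard.
#' @param spiked_pmol spiked amount per sample in pmol (> 0).
#' @param response_factor per-class multiplicative response/QC correction
#'   (default 1; supply measured factors when a quality-control extract
#'   has been quantified independently).
#' @return A `data.frame` with one row per covered class.
#' @export
internal_standards <- function(class, standard_species, spiked_pmol,
                               response_factor = 1) {
  stopifnot(length(class) == length(standard_species),
            all(spiked_pmol > 0))
  data.frame(class = class,
             standard_species = vapply(standard_species, function(s)
               format_species(parse_species(s)), "", USE.NAMES = FALSE),
             spiked_pmol = spiked_pmol,
             response_factor = rep_len(response_factor, length(class)))
}

#' @rdname internal_standards
#' @export
default_internal_standards <- function() {
  internal_standards(class = c("PE", "DAG", "SQDG"),
                     standard_species = c("PE 18:0/18:0", "DAG 18:0/22:6",
                                          "SQDG 16:0/18:0"),
                     spiked_pmol = c(125, 125, 125))
}

#' Fallback standard class per unspiked class
#'
#' Classes without their own spiked standard are normalised against a
#' chemically similar one: phospholipids against the PE standard,
#' galactolipids against the SQDG standard, neutral glycerolipids against
#' the DAG standard. The mapping is explicit configuration; a class
#' missing from it is an error, never a silent default.
#'
#' @return Named character vector, class -> standard class.
#' @export
default_standard_fallback <- function() {
  c(PC = "PE", PA = "PE", PG = "PE", PI = "PE", PS = "PE", CL = "PE",
    MGDG = "SQDG", DGDG = "SQDG", TAG = "DAG")
}

.species_class <- function(species_strings) {
  vapply(species_strings, function(s) parse_species(s)$class, "",
         USE.NAMES = FALSE)
}

#' Normalise raw MRM responses to pmol via internal standards
#'
#' Each species' amount is
#' `response / response(class standard) * spiked_pmol * response_factor`,
#' where the class standard is the spiked standard of the species' own
#' class or, for unspiked classes, the one named in the fallback map.
#' The standards' own rows are consumed for the denominators and excluded
#' from the profile. A sample lacking a needed standard response is an
#' error naming the sample and class; a species simply absent from a
#' sample is treated as 0 pmol by downstream summaries.
#'
#' @param peaks a peak table: `data.frame` with columns `sample`, `stage`,
#'   `replicate`, `species`, `response` (unique per sample x species).
#' @param standards an [internal_standards()] table.
#' @param fallback named map class -> standard class for classes without
#'   their own standard; see [default_standard_fallback()].
#' @return A lipidome profile: `data.frame` with columns `sample`,
#'   `stage`, `replicate`, `species`, `pmol`.
#' @export
is_normalize <- function(peaks, standards = default_internal_standards(),
                         fallback = default_standard_fallback()) {
  .check_peak_table(peaks)
  peaks$species <- vapply(peaks$species, function(s)
    format_species(parse_species(s)), "", USE.NAMES = FALSE)
  cls <- .species_class(peaks$species)
  std_class <- ifelse(cls %in% standards$class, cls,
                      unname(fallback[cls]))
  bad <- is.na(std_class)
  if (any(bad)) {
    stop("no internal standard or fallback mapping for class(es): ",
         paste(unique(cls[bad]), collapse = ", "))
  }
  is_std_row <- peaks$species %in% standards$standard_species
  # standard responses per (sample, standard class)
  out_rows <- lapply(split(seq_len(nrow(peaks)), peaks$sample), function(ix) {
    smp <- peaks[ix, , drop = FALSE]
    smp_cls <- std_class[ix]
    std_resp <- stats::setNames(rep(NA_real_, nrow(standards)), standards$class)
    for (k in seq_len(nrow(standards))) {
      hit <- smp$species == standards$standard_species[k]
      if (any(hit)) std_resp[standards$class[k]] <- smp$response[hit][1L]
    }
    needed <- unique(smp_cls[!is_std_row[ix]])
    missing <- needed[is.na(std_resp[needed])]
    if (length(missing)) {
      stop("sample '", smp$sample[1L], "' lacks a standard response for class(es): ",
           paste(missing, collapse = ", "))
    }
    keep <- !is_std_row[ix]
    sm <- smp[keep, , drop = FALSE]
    kcls <- smp_cls[keep]
    k <- match(kcls, standards$class)
    data.frame(sample = sm$sample, stage = sm$stage,
               replicate = sm$replicate, species = sm$species,
               pmol = sm$response / std_resp[kcls] *
                 standards$spiked_pmol[k] * standards$response_factor[k])
  })
  out <- do.call(rbind, out_rows)
  rownames(out) <- NULL
  out[order(out$sample, out$species), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

.check_profile <- function(profile) {
  need <- c("sample", "stage", "replicate", "species", "pmol")
  miss <- setdiff(need, names(profile))
  if (length(miss)) stop("profile lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(profile) == 0L) stop("profile is empty")
  if (any(profile$pmol < 0, na.rm = TRUE)) stop("amounts must be >= 0")
  invisible(profile)
}

#' Class mole fractions per sample
#'
#' 100 x class pmol sum / grand pmol sum, per sample. Fractions within a
#' sample always total 100 and are invariant under rescaling of that
#' sample's amounts. Combine with [stage_summary()] for per-stage
#' mean +/- SD.
#'
#' @param profile a lipidome profile (see [is_normalize()]).
#' @return `data.frame` with columns `sample`, `stage`, `replicate`,
#'   `class`, `mol_pct`.
#' @export
class_fractions <- function(profile) {
  .check_profile(profile)
  cls <- .species_class(profile$species)
  df <- data.frame(sample = profile$sample, stage = profile$stage,
                   replicate = profile$replicate, class = cls,
                   pmol = profile$pmol)
  agg <- stats::aggregate(pmol ~ sample + stage + replicate + class, df, sum)
  tot <- stats::aggregate(pmol ~ sample, agg, sum)
  if (any(tot$pmol == 0)) {
    stop("all-zero profile in sample(s): ",
         paste(tot$sample[tot$pmol == 0], collapse = ", "))
  }
  agg$mol_pct <- 100 * agg$pmol / tot$pmol[match(agg$sample, tot$sample)]
  agg$pmol <- NULL
  agg[order(agg$sample, agg$class), , drop = FALSE] -> agg
  rownames(agg) <- NULL
  agg
}

#' Species mole fractions within one class
#'
#' Like [class_fractions()] but the denominator is restricted to the
#' given class, giving each species as a percentage of its class total
#' per sample.
#'
#' @param profile a lipidome profile.
#' @param class the class to restrict to.
#' @return `data.frame` with columns `sample`, `stage`, `replicate`,
#'   `species`, `pct_of_class`.
#' @export
species_fraction_within_class <- function(profile, class) {
  .check_profile(profile)
  lipid_classes(class)
  keep <- .species_class(profile$species) == class
  if (!any(keep)) stop("profile contains no ", class, " species")
  sub <- profile[keep, , drop = FALSE]
  tot <- stats::aggregate(pmol ~ sample, sub, sum)
  if (any(tot$pmol == 0)) {
    stop("all-zero ", class, " amounts in sample(s): ",
         paste(tot$sample[tot$pmol == 0], collapse = ", "))
  }
  out <- data.frame(sample = sub$sample, stage = sub$stage,
                    replicate = sub$replicate, species = sub$species,
                    pct_of_class = 100 * sub$pmol / tot$pmol[match(sub$sample, tot$sample)])
  out[order(out$sample, out$species), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Acyl chain mole percentages
#'
#' Each molecular-level species contributes `pmol x (occurrences of the
#' acyl)` to the acyl tally; results are percentages of the grand acyl
#' total per sample. Class-total species carry no acyl information and
#' are excluded with a warning.
#'
#' @param profile a lipidome profile.
#' @return `data.frame` with columns `sample`, `stage`, `replicate`,
#'   `acyl`, `mol_pct`.
#' @export
acyl_mole_pct <- function(profile) {
  .check_profile(profile)
  parsed <- lapply(profile$species, parse_species)
  molecular <- vapply(parsed, function(p) p$level != "class-total", TRUE)
  if (!all(molecular)) {
    warning(sum(!molecular), " class-total species excluded from acyl accounting: ",
            paste(utils::head(unique(profile$species[!molecular]), 5L), collapse = ", "))
  }
  if (!any(molecular)) stop("no molecular-level species in profile")
  rows <- do.call(rbind, lapply(which(molecular), function(i) {
    acyls <- vapply(parsed[[i]]$acyls, format, "")
    data.frame(sample = profile$sample[i], stage = profile$stage[i],
               replicate = profile$replicate[i], acyl = acyls,
               chains = profile$pmol[i])
  }))
  agg <- stats::aggregate(chains ~ sample + stage + replicate + acyl, rows, sum)
  tot <- stats::aggregate(chains ~ sample, agg, sum)
  if (any(tot$chains == 0)) {
    stop("all-zero acyl tally in sample(s): ",
         paste(tot$sample[tot$chains == 0], collapse = ", "))
  }
  agg$mol_pct <- 100 * agg$chains / tot$chains[match(agg$sample, tot$sample)]
  agg$chains <- NULL
  agg[order(agg$sample, agg$acyl), , drop = FALSE] -> agg
  rownames(agg) <- NULL
  agg
}

#' Per-stage descriptive summary
#'
#' Mean, SD and n per stage for each level of a key column (species,
#' class or acyl), on any per-sample value table. A single replicate
#' reports SD as `NA`, never 0. Optionally a one-way ANOVA p-value per
#' key across stages is attached as an auxiliary column (it requires
#' >= 2 stages with >= 2 values).
#'
#' @param values a `data.frame` with columns `stage`, the key column and
#'   the value column (e.g. output of [class_fractions()]).
#' @param key name of the grouping column (default `"class"`).
#' @param value name of the value column (default `"mol_pct"`).
#' @param anova add an `anova_p` column (default `FALSE`).
#' @return `data.frame` with columns `stage`, key, `mean`, `sd`, `n` (and
#'   `anova_p`), ordered by stage then key.
#' @export
stage_summary <- function(values, key = "class", value = "mol_pct",
                          anova = FALSE) {
  stopifnot(all(c("stage", key, value) %in% names(values)))
  f <- interaction(values$stage, values[[key]], drop = TRUE)
  split_v <- split(values[[value]], f)
  split_meta <- split(values[c("stage", key)], f)
  out <- do.call(rbind, lapply(names(split_v), function(g) {
    v <- split_v[[g]]
    meta <- split_meta[[g]][1L, , drop = FALSE]
    data.frame(stage = meta$stage, key = meta[[key]],
               mean = mean(v), sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
               n = length(v))
  }))
  names(out)[names(out) == "key"] <- key
  if (anova) {
    out$anova_p <- NA_real_
    for (k in unique(out[[key]])) {
      sub <- values[values[[key]] == k, , drop = FALSE]
      if (length(unique(sub$stage)) >= 2L && nrow(sub) > length(unique(sub$stage))) {
        p <- tryCatch(
          stats::oneway.test(sub[[value]] ~ factor(sub$stage),
                             var.equal = TRUE)$p.value,
          error = function(e) NA_real_)
        out$anova_p[out[[key]] == k] <- p
      }
    }
  }
  out <- out[order(.order_stages(out$stage), out[[key]]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read / write tidy value tables
#'
#' Plumbing for the tidy CSV dialect used throughout (`sample`, `stage`,
#' `replicate`, `species`, value column).
#'
#' @param path file path.
#' @return `read_peak_table()` returns a validated peak table;
#'   `read_profile()` a validated profile.
#' @export
read_peak_table <- function(path) {
  .check_peak_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_peak_table
#' @export
read_profile <- function(path) {
  .check_profile(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_peak_table
#' @param x a data.frame to write.
#' @export
write_tidy_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Export a tidy table as a wide matrix CSV
#'
#' @param values tidy table with `sample`, a key column and a value column.
#' @param path output CSV (rows = key levels, columns = samples).
#' @param key,value column names, as in [stage_summary()].
#' @export
write_wide_csv <- function(values, path, key = "species", value = "pmol") {
  wide <- stats::reshape(values[c("sample", key, value)],
                         idvar = key, timevar = "sample", direction = "wide")
  names(wide) <- sub(paste0("^", value, "\\."), "", names(wide))
  utils::write.csv(wide, path, row.names = FALSE)
  invisible(path)
}

#' Read an internal-standard configuration from YAML
#'
#' Expected structure: a `standards` list of `{class, species, spiked_pmol,
#' response_factor}` entries and an optional `fallback` map.
#'
#' @param path YAML file.
#' @return List with elements `standards` (an [internal_standards()]
#'   table) and `fallback` (named character vector).
#' @export
read_standards_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$standards)) stop("YAML lacks a 'standards' block")
  std <- internal_standards(
    class = vapply(y$standards, `[[`, "", "class"),
    standard_species = vapply(y$standards, `[[`, "", "species"),
    spiked_pmol = vapply(y$standards, function(s) as.numeric(s$spiked_pmol), 0),
    response_factor = vapply(y$standards, function(s)
      if (is.null(s$response_factor)) 1 else as.numeric(s$response_factor), 0))
  fb <- if (is.null(y$fallback)) default_standard_fallback() else unlist(y$fallback)
  list(standards = std, fallback = fb)
}
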