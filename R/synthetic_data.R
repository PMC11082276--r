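# Synthetic stage-resolved lipidome profiles, raw MRM peak tables and
# sodiated-TAG MS2 spectra with the statistical structure the analysis
# pipeline assumes.
#
# Calibration: class mole fractions and the anchored within-class species
# values are the published per-stage measurements for maturing Pennycress
# seed; everything the measurements leave open (remaining species shares,
# unmeasured stages) is filled by an explicit, documented rule so that all
# fraction vectors sum to 1. Replicate noise is multiplicative lognormal:
# amounts are positive and spreads are reported as CVs in this field.

# species catalog: molecular composition for every species the generator
# emits; sn-2 follows the published positional convention (18:2 at sn-2
# where present, printed middle).
.CATALOG <- list(
  TAG = c("54:4" = "18:1/18:2/18:1", "54:5" = "18:1/18:2/18:2",
          "56:3" = "16:0/18:2/22:1", "58:4" = "18:1/18:2/22:1",
          "58:5" = "18:2/18:2/22:1", "60:4" = "20:1/18:2/22:1",
          "62:4" = "22:1/18:2/22:1", "62:5" = "22:1/18:3/22:1",
          "64:4" = "22:1/18:2/24:1"),
  DAG = c("34:2" = "16:0/18:2", "36:3" = "18:1/18:2", "36:4" = "18:2/18:2",
          "36:5" = "18:2/18:3", "36:6" = "18:3/18:3", "38:3" = "18:2/20:1",
          "38:4" = "18:3/20:1", "40:3" = "18:2/22:1", "40:4" = "18:3/22:1"),
  PC  = c("34:1" = "16:0/18:1", "34:2" = "16:0/18:2", "36:2" = "18:1/18:1",
          "36:3" = "18:1/18:2", "36:4" = "18:2/18:2", "36:5" = "18:2/18:3",
          "38:2" = "18:1/20:1", "38:3" = "18:2/20:1", "38:4" = "18:3/20:1",
          "40:2" = "18:1/22:1", "40:3" = "18:2/22:1", "40:4" = "18:3/22:1"),
  PA  = c("34:2" = "16:0/18:2"), PE = c("34:2" = "16:0/18:2"),
  PG  = c("34:2" = "16:0/18:2"), PI = c("34:2" = "16:0/18:2"),
  PS  = c("40:3" = "18:2/22:1"), MGDG = c("36:6" = "18:3/18:3"),
  DGDG = c("36:6" = "18:3/18:3"), SQDG = c("34:3" = "16:0/18:3")
)

#' Species catalog of the synthetic generator
#'
#' The molecular composition assumed for every species the generator can
#' emit, as canonical species strings (acyl-resolved, 18:2/18:3 rendered
#' at the sn-2 middle position for TAG).
#'
#' @return Named list: class -> named character vector (label -> species).
#' @export
default_species_catalog <- function() {
  out <- lapply(names(.CATALOG), function(cl) {
    v <- .CATALOG[[cl]]
    stats::setNames(vapply(paste(cl, v), function(s)
      format_species(parse_species(s)), "", USE.NAMES = FALSE), names(v))
  })
  stats::setNames(out, names(.CATALOG))
}

# fill a fraction vector: anchored values kept, remainder spread uniformly
# over the unanchored labels; errors if anchors exceed the total
.fill_fractions <- function(labels, anchors, total = 100) {
  out <- stats::setNames(rep(NA_real_, length(labels)), labels)
  if (length(anchors)) out[names(anchors)] <- anchors
  left <- total - sum(anchors)
  free <- is.na(out)
  if (left < -1e-9) stop("anchored fractions exceed ", total)
  if (any(free)) {
    out[free] <- left / sum(free)
  } else if (abs(left) > 1e-9) {
    stop("fully anchored fractions do not sum to ", total)
  }
  out / total
}

# remainder spread proportionally to reference weights (G-stage shares)
.fill_proportional <- function(labels, anchors, ref, total = 100) {
  out <- stats::setNames(rep(NA_real_, length(labels)), labels)
  out[names(anchors)] <- anchors
  left <- total - sum(anchors)
  free <- names(out)[is.na(out)]
  if (left < -1e-9) stop("anchored fractions exceed ", total)
  w <- ref[free]
  out[free] <- left * w / sum(w)
  out / total
}

# published class mole fractions at the initial GREEN stage (%); the
# remainder after the eight measured classes is split evenly over the
# minor unmeasured classes PI, PS, SQDG
.G_CLASS_PCT <- c(TAG = 29.3, PA = 28.5, PC = 10.1, DGDG = 8.4, MGDG = 7.1,
                  PE = 3.4, DAG = 3.3, PG = 2.7, PI = 2.4, PS = 2.4, SQDG = 2.4)

#' Stage parameter set for the synthetic generator
#'
#' @param stage stage label.
#' @param class_fractions named numeric, class mole fractions summing to 1.
#' @param species_fractions named list: class -> named numeric of
#'   within-class species fractions (by catalog label), each summing to 1.
#' @param scale total lipid amount per sample in pmol.
#' @param cv replicate noise coefficient of variation (lognormal,
#'   multiplicative; >= 0).
#' @param ms2 MS2 intensity model: `sn13_sn2_ratio` (acid-loss intensity
#'   of a flanking acyl over the sn-2-only acyl), `salt_to_acid`
#'   (sodium-salt over acid loss), `mz_jitter_sd` (Gaussian m/z jitter in
#'   Da), `intensity_cv` (lognormal intensity jitter), `base_intensity`.
#' @return An object of class `stage_params`.
#' @export
stage_params <- function(stage, class_fractions, species_fractions,
                         scale = 2000, cv = 0.05,
                         ms2 = list(sn13_sn2_ratio = 2.5, salt_to_acid = 0.05,
                                    mz_jitter_sd = 0.05, intensity_cv = 0.05,
                                    base_intensity = 100)) {
  stopifnot(cv >= 0, scale > 0,
            ms2$sn13_sn2_ratio > 0, ms2$salt_to_acid > 0)
  if (abs(sum(class_fractions) - 1) > 1e-9) {
    stop("class fractions must sum to 1")
  }
  if (any(class_fractions < 0 | class_fractions > 1)) {
    stop("class fractions must lie in [0, 1]")
  }
  for (cl in names(species_fractions)) {
    sf <- species_fractions[[cl]]
    if (abs(sum(sf) - 1) > 1e-9) stop("species fractions for ", cl, " must sum to 1")
    if (any(sf < 0 | sf > 1)) stop("species fractions for ", cl, " must lie in [0, 1]")
  }
  structure(list(stage = stage, class_fractions = class_fractions,
                 species_fractions = species_fractions, scale = scale,
                 cv = cv, ms2 = ms2),
            class = "stage_params")
}

#' Default stage parameters for the five maturation stages
#'
#' Class mole fractions are anchored to the published stage measurements:
#' the full GREEN-stage breakdown (TAG 29.3%, PA 28.5%, PC 10.1%, DGDG
#' 8.4%, MGDG 7.1%, PE 3.4%, DAG 3.3%, PG 2.7%), the TAG trajectory
#' 79.5% (GY), 85.6% (Y) and 90.8% (M), the MGDG decline (0.8% at Y,
#' 0.09% at M) and the mature-stage PC (5.4%) and DAG (0.8%). Remaining
#' class mass at each stage is spread over the unanchored classes in
#' proportion to their GREEN-stage shares. The unmeasured YG TAG fraction
#' is set to 82.5%, midway between its measured neighbours.
#'
#' Within-class species fractions anchor every published species value
#' (DAG 34:2 = 22.21% at G; the DAG 40:3, 38:3 and 40:4 trajectories; the
#' four major GREEN-stage PC species) and spread the remainder uniformly
#' over the rest of the catalog; TAG species fractions are package
#' defaults encoding the published qualitative trend (62:4/62:5 and other
#' VLCFA species rise with maturation, 54:4/54:5 fall).
#'
#' @param cv,scale,ms2 overrides applied to every stage (see
#'   [stage_params()]).
#' @return Named list of five [stage_params()], in stage order.
#' @export
default_stage_params <- function(cv = 0.05, scale = 2000,
                                 ms2 = list(sn13_sn2_ratio = 2.5,
                                            salt_to_acid = 0.05,
                                            mz_jitter_sd = 0.05,
                                            intensity_cv = 0.05,
                                            base_intensity = 100)) {
  cls <- names(.G_CLASS_PCT)
  class_anchor <- list(
    G  = .G_CLASS_PCT,
    GY = c(TAG = 79.5, DAG = 3.0),
    YG = c(TAG = 82.5, DAG = 3.0),
    Y  = c(TAG = 85.6, DAG = 2.0, MGDG = 0.8),
    M  = c(TAG = 90.8, PC = 5.4, DAG = 0.8, MGDG = 0.09)
  )
  # package-default TAG species trend (percent of class)
  tag_pct <- list(
    G  = c("54:4" = 10, "54:5" = 10, "56:3" = 12, "58:4" = 18, "58:5" = 18,
           "60:4" = 8, "62:4" = 14, "62:5" = 9, "64:4" = 1),
    GY = c("54:4" = 5, "54:5" = 5, "56:3" = 9, "58:4" = 16, "58:5" = 16,
           "60:4" = 10, "62:4" = 24, "62:5" = 13, "64:4" = 2),
    YG = c("54:4" = 4, "54:5" = 4, "56:3" = 8, "58:4" = 15, "58:5" = 15,
           "60:4" = 11, "62:4" = 26, "62:5" = 14, "64:4" = 3),
    Y  = c("54:4" = 3, "54:5" = 3, "56:3" = 7, "58:4" = 14, "58:5" = 14,
           "60:4" = 12, "62:4" = 28, "62:5" = 15, "64:4" = 4),
    M  = c("54:4" = 2, "54:5" = 2, "56:3" = 6, "58:4" = 13, "58:5" = 13,
           "60:4" = 13, "62:4" = 30, "62:5" = 16, "64:4" = 5)
  )
  dag_anchor <- list(
    G  = c("34:2" = 22.21, "40:3" = 2.6, "38:3" = 3.2, "40:4" = 2.0),
    GY = c("40:3" = 9.0, "38:3" = 8.0, "40:4" = 7.5),
    YG = c("40:3" = 8.8, "38:3" = 7.2, "40:4" = 6.4),
    Y  = c("40:3" = 12.7, "38:3" = 13.6, "40:4" = 9.5),
    M  = c("40:3" = 17.8, "38:3" = 23.8, "40:4" = 21.3)
  )
  # GREEN-stage PC anchors, held constant across stages (only the initial
  # stage was reported quantitatively; the maturation trend is qualitative)
  pc_anchor <- c("34:1" = 14.4, "34:2" = 14.6, "36:3" = 19.3, "36:4" = 17.4,
                 "38:2" = 2.0, "38:3" = 2.0, "38:4" = 2.0,
                 "40:2" = 0.8, "40:3" = 0.8, "40:4" = 0.8)
  out <- lapply(stage_levels(), function(st) {
    cf <- if (st == "G") {
      .G_CLASS_PCT / 100
    } else {
      .fill_proportional(cls, class_anchor[[st]], .G_CLASS_PCT)
    }
    sf <- list(
      TAG = .fill_fractions(names(.CATALOG$TAG), tag_pct[[st]]),
      DAG = .fill_fractions(names(.CATALOG$DAG), dag_anchor[[st]]),
      PC  = .fill_fractions(names(.CATALOG$PC), pc_anchor)
    )
    for (cl in setdiff(names(.CATALOG), names(sf))) {
      sf[[cl]] <- .fill_fractions(names(.CATALOG[[cl]]), c())
    }
    stage_params(st, cf, sf, scale = scale, cv = cv, ms2 = ms2)
  })
  stats::setNames(out, stage_levels())
}

# derived sub-seed per stream so profile / response / spectrum draws can
# be regenerated independently from one global seed; kept below 2^31
.substream_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

.rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)  # mean exactly 1
}

#' Simulate replicate lipidome profiles
#'
#' Per replicate and species, amount = scale x class fraction x species
#' fraction x lognormal(mean 1, given CV). Deterministic for a fixed
#' seed; at CV 0 the empirical fractions equal the parameters exactly.
#'
#' @param params a single [stage_params()] or a list of them (one per
#'   stage, as from [default_stage_params()]).
#' @param n_replicates replicates per stage (>= 1).
#' @param seed integer seed for the profile noise stream.
#' @return A lipidome profile `data.frame` (`sample`, `stage`,
#'   `replicate`, `species`, `pmol`) carrying the generation record in
#'   `attr(x, "generation")`.
#' @export
simulate_profile <- function(params, n_replicates = 3, seed = 1) {
  if (inherits(params, "stage_params")) params <- list(params)
  stopifnot(n_replicates >= 1, all(vapply(params, inherits, TRUE, "stage_params")))
  catalog <- default_species_catalog()
  set.seed(.substream_seed(seed, "profile"))
  rows <- list()
  for (p in params) {
    for (r in seq_len(n_replicates)) {
      for (cl in names(p$class_fractions)) {
        cfrac <- p$class_fractions[[cl]]
        if (cfrac == 0) next
        sf <- p$species_fractions[[cl]]
        if (is.null(sf)) stop("no species fractions for class ", cl)
        spp <- catalog[[cl]][names(sf)]
        noise <- .rlnorm_cv(length(sf), p$cv)
        rows[[length(rows) + 1L]] <- data.frame(
          sample = paste0(p$stage, "_", r), stage = p$stage, replicate = r,
          species = unname(spp),
          pmol = p$scale * cfrac * as.numeric(sf) * noise)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "generation") <- list(seed = seed, n_replicates = n_replicates,
                                  stages = vapply(params, `[[`, "", "stage"),
                                  cv = vapply(params, `[[`, 0, "cv"),
                                  scale = vapply(params, `[[`, 0, "scale"))
  out
}

#' Invert a profile to a raw MRM peak table
#'
#' The exact inverse of [is_normalize()]: response = amount /
#' (spiked_pmol x response_factor), with every class standard's own
#' response fixed at 1 and appended per sample. With `response_cv = 0`
#' the round trip through [is_normalize()] reproduces the profile
#' exactly; with noise, endogenous responses are jittered
#' multiplicatively (standards stay at 1, mimicking normalisation against
#' a noiseless reference).
#'
#' @param profile a lipidome profile.
#' @param standards an [internal_standards()] table.
#' @param fallback class fallback map, see [default_standard_fallback()].
#' @param response_cv multiplicative lognormal CV on endogenous responses.
#' @param seed seed for the response noise stream.
#' @return A peak table (`sample`, `stage`, `replicate`, `species`,
#'   `response`) including the standard rows.
#' @export
simulate_peak_table <- function(profile, standards = default_internal_standards(),
                                fallback = default_standard_fallback(),
                                response_cv = 0, seed = 1) {
  .check_profile(profile)
  cls <- .species_class(profile$species)
  std_class <- ifelse(cls %in% standards$class, cls, unname(fallback[cls]))
  if (any(is.na(std_class))) {
    stop("no standard or fallback for class(es): ",
         paste(unique(cls[is.na(std_class)]), collapse = ", "))
  }
  k <- match(std_class, standards$class)
  set.seed(.substream_seed(seed, "response"))
  noise <- .rlnorm_cv(nrow(profile), response_cv)
  out <- data.frame(sample = profile$sample, stage = profile$stage,
                    replicate = profile$replicate, species = profile$species,
                    response = profile$pmol /
                      (standards$spiked_pmol[k] * standards$response_factor[k]) * noise)
  # one row per (sample, standard) at unit response
  meta <- unique(profile[c("sample", "stage", "replicate")])
  std_rows <- merge(meta, data.frame(species = standards$standard_species,
                                     response = 1))
  out <- rbind(out, std_rows[names(out)])
  out <- out[order(out$sample, out$species), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate a sodiated TAG MS2 spectrum with known sn-2
#'
#' Emits one acid-loss peak per distinct acyl (base intensity for an acyl
#' occupying a flanking sn-1/3 position, base / `sn13_sn2_ratio` for the
#' acyl found only at sn-2) plus sodium-salt peaks scaled by
#' `salt_to_acid`. m/z values receive
#' Gaussian jitter, intensities multiplicative lognormal jitter; the
#' precursor is the theoretical `[M+Na]+` plus jitter. The true sn-2
#' label is carried in the spectrum metadata.
#'
#' @param species an sn-resolved TAG [lipid_species()] (or a string such
#'   as `"TAG 22:1/18:2/22:1"`, whose middle acyl is taken as sn-2).
#' @param model the MS2 intensity model list (see [stage_params()]).
#' @param seed seed for the spectrum noise stream.
#' @return An [ms2_spectrum()] with `metadata$true_sn2`.
#' @export
simulate_ms2 <- function(species,
                         model = list(sn13_sn2_ratio = 2.5, salt_to_acid = 0.05,
                                      mz_jitter_sd = 0.05, intensity_cv = 0.05,
                                      base_intensity = 100),
                         seed = 1) {
  if (is.character(species)) {
    # middle acyl of the written form is taken as sn-2
    s <- trimws(species)
    if (grepl("^[A-Za-z]+\\s", s) && sub("\\s.*$", "", s) != "TAG") {
      stop("MS2 simulation covers TAG species only")
    }
    s <- sub("^TAG\\s+", "", s)
    chains <- strsplit(s, "[/-]")[[1L]]
    if (length(chains) != 3L) {
      stop("species string must list three acyls, e.g. 'TAG 22:1/18:2/22:1'")
    }
    acyls <- lapply(trimws(chains), parse_fatty_acid)
    species <- lipid_species("TAG", acyls = acyls, sn2 = 2L)
  }
  stopifnot(inherits(species, "lipid_species"))
  if (species$class != "TAG") stop("MS2 simulation covers TAG species only")
  if (species$level != "sn-resolved") {
    stop("species must be sn-resolved (designate the sn-2 acyl)")
  }
  set.seed(.substream_seed(seed, "spectrum"))
  neutral <- species_formula(species)
  prec <- ion_mz(neutral, "[M+Na]+")
  labs <- vapply(species$acyls, format, "")
  sn2_lab <- labs[species$sn2]
  distinct <- unique(labs)
  mz <- numeric(); int <- numeric()
  for (d in distinct) {
    losses <- acyl_neutral_losses(parse_fatty_acid(d))
    # acid-loss intensity: base for an acyl occupying sn-1/3, base/ratio
    # for an acyl found only at sn-2 (the preferential-loss signature)
    pos <- which(labs == d)
    expect <- if (all(pos == species$sn2)) {
      model$base_intensity / model$sn13_sn2_ratio
    } else {
      model$base_intensity
    }
    mz <- c(mz, prec - losses[["acid"]], prec - losses[["sodium_salt"]])
    int <- c(int, expect, expect * model$salt_to_acid)
  }
  mz <- mz + stats::rnorm(length(mz), 0, model$mz_jitter_sd)
  int <- int * .rlnorm_cv(length(int), model$intensity_cv)
  prec_obs <- prec + stats::rnorm(1, 0, model$mz_jitter_sd)
  ms2_spectrum(prec_obs, mz, int,
               metadata = list(true_sn2 = sn2_lab,
                               species = format_species(species),
                               model = model, seed = seed))
}

#' Generate a complete synthetic dataset
#'
#' Bundles ground-truth profiles, the derived raw peak table and sodiated
#' TAG MS2 spectra (one per TAG species with >= 2 distinct acyls, per
#' stage) together with the full parameter record. Regenerating with the
#' same seed and parameters reproduces the dataset bit for bit.
#'
#' @param params list of [stage_params()]; default
#'   [default_stage_params()].
#' @param n_replicates replicates per stage.
#' @param response_cv CV on raw responses (default 0: the peak table is
#'   the exact inverse image of the profile).
#' @param seed global seed; per-stream sub-seeds are derived from it.
#' @return List with elements `profile`, `peak_table`, `spectra`,
#'   `params`, `seed`.
#' @export
simulate_dataset <- function(params = default_stage_params(), n_replicates = 3,
                             response_cv = 0, seed = 1) {
  profile <- simulate_profile(params, n_replicates, seed)
  peaks <- simulate_peak_table(profile, response_cv = response_cv, seed = seed)
  catalog <- default_species_catalog()
  spectra <- list()
  for (p in params) {
    for (lab in names(catalog$TAG)) {
      sp <- parse_species(catalog$TAG[[lab]])
      if (length(unique(vapply(sp$acyls, format, ""))) < 2L) next
      s <- simulate_ms2(catalog$TAG[[lab]], model = p$ms2,
                        seed = .substream_seed(seed, paste0(p$stage, lab)))
      s$metadata$stage <- p$stage
      spectra[[paste(p$stage, lab)]] <- s
    }
  }
  list(profile = profile, peak_table = peaks, spectra = spectra,
       params = params, seed = seed)
}
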