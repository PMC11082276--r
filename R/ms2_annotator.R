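# Annotation of sodiated TAG tandem mass spectra: candidate triad
# enumeration, acid / sodium-salt loss prediction, peak matching, and
# intensity-based sn-2 assignment.
#
# The physics: [M+Na]+ TAG precursors preferentially eject the sn-1/3
# acyls, so the acid-loss ions for the flanking chains are markedly more
# intense than the one for the sn-2 chain, while sodium-salt losses are
# much weaker throughout. Enantiomers (sn-1 vs sn-3 swap) are
# indistinguishable and never reported.

#' An MS2 peak list with precursor
#'
#' @param precursor_mz precursor ion m/z (> 0).
#' @param mz,intensity numeric vectors of equal length; intensities must
#'   be finite and non-negative. Peaks are stored sorted by m/z.
#' @param adduct assumed precursor adduct (default `"[M+Na]+"`; positional
#'   calls are only ever made on sodiated precursors).
#' @param metadata optional named list (stage label, band id, ...).
#' @return An object of class `ms2_spectrum`.
#' @export
ms2_spectrum <- function(precursor_mz, mz = numeric(), intensity = numeric(),
                         adduct = "[M+Na]+", metadata = list()) {
  stopifnot(is.numeric(precursor_mz), length(precursor_mz) == 1L,
            precursor_mz > 0, length(mz) == length(intensity))
  if (length(intensity) && (any(!is.finite(intensity)) || any(intensity < 0))) {
    stop("intensities must be finite and non-negative")
  }
  ord <- order(mz)
  structure(list(precursor_mz = precursor_mz,
                 peaks = data.frame(mz = as.numeric(mz[ord]),
                                    intensity = as.numeric(intensity[ord])),
                 adduct = adduct, metadata = metadata),
            class = "ms2_spectrum")
}

#' @export
print.ms2_spectrum <- function(x, ...) {
  cat(sprintf("<ms2_spectrum> precursor %.4f (%s), %d peaks\n",
              x$precursor_mz, x$adduct, nrow(x$peaks)))
  invisible(x)
}

#' Read spectra from an MGF file
#'
#' Minimal Mascot Generic Format support: `BEGIN IONS`/`END IONS` blocks
#' with `PEPMASS` (precursor m/z, first field) and optional `TITLE`;
#' two-column peak lines. Only the features this package writes and reads
#' are supported.
#'
#' @param path MGF file path.
#' @param adduct assumed adduct attached to every spectrum.
#' @return List of [ms2_spectrum()].
#' @export
read_mgf <- function(path, adduct = "[M+Na]+") {
  lines <- trimws(readLines(path))
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (lines[i] == "BEGIN IONS") {
      j <- i + 1L
      prec <- NA_real_; title <- NULL; mz <- c(); int <- c()
      while (j <= length(lines) && lines[j] != "END IONS") {
        ln <- lines[j]
        if (startsWith(ln, "PEPMASS=")) {
          prec <- as.numeric(strsplit(sub("^PEPMASS=", "", ln), "\\s+")[[1L]][1L])
        } else if (startsWith(ln, "TITLE=")) {
          title <- sub("^TITLE=", "", ln)
        } else if (grepl("^[0-9]", ln)) {
          xs <- as.numeric(strsplit(ln, "[\t ]+")[[1L]])
          mz <- c(mz, xs[1L]); int <- c(int, xs[2L])
        }
        j <- j + 1L
      }
      if (is.na(prec)) stop("MGF block without PEPMASS in ", path)
      md <- if (is.null(title)) list() else list(title = title)
      out[[length(out) + 1L]] <- ms2_spectrum(prec, mz, int, adduct, md)
      i <- j
    }
    i <- i + 1L
  }
  out
}

#' Write spectra to an MGF file
#'
#' @param spectra a list of [ms2_spectrum()] (or a single spectrum).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  if (inherits(spectra, "ms2_spectrum")) spectra <- list(spectra)
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines("BEGIN IONS", con)
    if (!is.null(sp$metadata$title)) {
      writeLines(paste0("TITLE=", sp$metadata$title), con)
    }
    writeLines(sprintf("PEPMASS=%.6f", sp$precursor_mz), con)
    if (nrow(sp$peaks)) {
      writeLines(sprintf("%.6f %.6f", sp$peaks$mz, sp$peaks$intensity), con)
    }
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}

#' Read a two-column peak list CSV
#'
#' Format: a header comment line `# precursor_mz=<value>` followed by a
#' CSV with columns `mz`, `intensity`.
#'
#' @param path file path.
#' @param adduct assumed precursor adduct.
#' @return An [ms2_spectrum()].
#' @export
read_spectrum_csv <- function(path, adduct = "[M+Na]+") {
  first <- readLines(path, n = 1L)
  m <- regmatches(first, regexec("precursor_mz\\s*=\\s*([0-9.]+)", first))[[1L]]
  if (length(m) != 2L) {
    stop("expected '# precursor_mz=<value>' header line in ", path)
  }
  df <- utils::read.csv(path, comment.char = "#")
  ms2_spectrum(as.numeric(m[2L]), df$mz, df$intensity, adduct)
}

# ---------------------------------------------------------------------------

#' Predict acid and sodium-salt loss fragments for a TAG triad
#'
#' For each distinct acyl of the triad, two product ions of the sodiated
#' precursor are predicted: loss of the acyl as a free fatty acid
#' (RCOOH) and as its sodium salt (RCOONa). A symmetric triad A/B/A thus
#' yields 4 predictions, an asymmetric one 6. Every predicted m/z plus
#' its loss mass reconstructs the theoretical precursor exactly.
#'
#' @param triad list of 3 [fatty_acid()] (or a molecular TAG
#'   [lipid_species()], whose acyls are used).
#' @param precursor_formula optional neutral `chem_formula`; when given it
#'   must equal the TAG formula assembled from the triad (a mismatch is an
#'   error), otherwise it is assembled.
#' @return A `data.frame` with columns `acyl`, `loss_kind`
#'   (`"acid"`/`"sodium-salt"`), `loss_da`, `mz`, `precursor_mz`, and
#'   `sn_role` (always `"undetermined"` at prediction time; roles are a
#'   property of the observed intensities, see [assign_sn2()]).
#' @examples
#' tri <- lapply(c("22:1", "18:2", "22:1"), parse_fatty_acid)
#' predict_fragments(tri)
#' @export
predict_fragments <- function(triad, precursor_formula = NULL) {
  if (inherits(triad, "lipid_species")) {
    if (triad$class != "TAG" || triad$level == "class-total") {
      stop("triad must be a molecular-level TAG")
    }
    triad <- triad$acyls
  }
  stopifnot(length(triad) == 3L, all(vapply(triad, inherits, TRUE, "fatty_acid")))
  sp <- lipid_species("TAG", acyls = triad)
  neutral <- species_formula(sp)
  if (!is.null(precursor_formula) && !(neutral == precursor_formula)) {
    stop("precursor formula ", format(precursor_formula),
         " is inconsistent with triad ", format_species(sp),
         " (expected ", format(neutral), ")")
  }
  prec_mz <- ion_mz(neutral, "[M+Na]+")
  labs <- vapply(triad, format, "")
  acyls <- triad[!duplicated(labs)]
  rows <- lapply(acyls, function(a) {
    losses <- acyl_neutral_losses(a)
    data.frame(acyl = format(a),
               loss_kind = c("acid", "sodium-salt"),
               loss_da = as.numeric(losses),
               mz = prec_mz - as.numeric(losses),
               precursor_mz = prec_mz,
               sn_role = "undetermined")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Match predicted fragments against an observed spectrum
#'
#' Each prediction is matched to its nearest observed peak within the
#' tolerance. One peak may satisfy several near-isobaric predictions; such
#' matches are flagged `shared` rather than arbitrated. Unmatched
#' predictions are retained with `NA` observations.
#'
#' @param spectrum an [ms2_spectrum()].
#' @param predictions output of [predict_fragments()].
#' @param tolerance matching tolerance in Da (> 0); default 0.3, suited to
#'   nominal-mass ion-trap spectra.
#' @return `predictions` augmented with `observed_mz`, `intensity`,
#'   `error_da`, `matched`, `peak_index`, `shared`.
#' @export
match_spectrum <- function(spectrum, predictions, tolerance = 0.3) {
  stopifnot(inherits(spectrum, "ms2_spectrum"), tolerance > 0)
  out <- predictions
  n <- nrow(out)
  out$observed_mz <- NA_real_
  out$intensity <- NA_real_
  out$error_da <- NA_real_
  out$matched <- FALSE
  out$peak_index <- NA_integer_
  peaks <- spectrum$peaks
  if (nrow(peaks) > 0L && n > 0L) {
    for (i in seq_len(n)) {
      d <- abs(peaks$mz - out$mz[i])
      j <- which.min(d)
      if (d[j] <= tolerance) {
        out$observed_mz[i] <- peaks$mz[j]
        out$intensity[i] <- peaks$intensity[j]
        out$error_da[i] <- peaks$mz[j] - out$mz[i]
        out$matched[i] <- TRUE
        out$peak_index[i] <- j
      }
    }
  }
  shared_peaks <- out$peak_index[out$matched][duplicated(out$peak_index[out$matched])]
  out$shared <- out$matched & out$peak_index %in% shared_peaks
  out
}

#' Assign the sn-2 acyl from matched acid-loss intensities
#'
#' Implements the relative-intensity rule for sodiated TAG fragmentation:
#' the acid-loss ion for the sn-2 acyl is the least intense, the sn-1/3
#' losses are similar to each other and clearly stronger. The weakest
#' acid-loss acyl is called sn-2 iff
#' * every other acid-loss intensity is at least `dominance_ratio` times
#'   the weakest, and
#' * for asymmetric triads, the two stronger intensities agree within a
#'   factor `similarity_ratio` (the "two ions of similar abundance"
#'   pattern; symmetric A/B/A triads pool their flanking losses into one
#'   peak, so only the dominance test applies).
#'
#' Anything else - missing intensities, ties, a triad of three identical
#' acyls (no positional contrast exists) - abstains. Abstention is a
#' value, not an error.
#'
#' @param triad list of 3 [fatty_acid()].
#' @param acid_intensities named numeric: acid-loss intensity per distinct
#'   acyl label (e.g. `c("22:1" = 100, "18:2" = 40)`).
#' @param dominance_ratio r >= 1; default 1.5.
#' @param similarity_ratio s >= 1; default 3.
#' @return A list with `sn2` (a [fatty_acid()] or `NULL`) and `reason`
#'   (`"assigned"` or why the call abstained).
#' @examples
#' tri <- lapply(c("22:1", "18:2", "22:1"), parse_fatty_acid)
#' assign_sn2(tri, c("22:1" = 100, "18:2" = 40))$sn2
#' @export
assign_sn2 <- function(triad, acid_intensities,
                       dominance_ratio = 1.5, similarity_ratio = 3) {
  stopifnot(length(triad) == 3L, all(vapply(triad, inherits, TRUE, "fatty_acid")),
            dominance_ratio >= 1, similarity_ratio >= 1)
  labs <- vapply(triad, format, "")
  distinct <- unique(labs)
  abstain <- function(reason) list(sn2 = NULL, reason = reason)
  if (length(distinct) == 1L) {
    return(abstain("triad has a single distinct acyl; no positional contrast"))
  }
  ints <- acid_intensities[distinct]
  if (any(is.na(ints))) {
    return(abstain(paste0("missing acid-loss intensity for: ",
                          paste(distinct[is.na(ints)], collapse = ", "))))
  }
  i_min <- which.min(ints)
  l_min <- ints[i_min]
  others <- ints[-i_min]
  if (l_min <= 0) return(abstain("non-positive minimum intensity"))
  if (!all(others >= dominance_ratio * l_min)) {
    return(abstain("dominance criterion unmet (sn-1/3 losses not clearly stronger)"))
  }
  if (length(distinct) == 3L) {
    if (max(others) > similarity_ratio * min(others)) {
      return(abstain("flanking acid losses not of similar abundance"))
    }
  }
  list(sn2 = parse_fatty_acid(distinct[i_min]), reason = "assigned")
}

#' Annotation configuration
#'
#' @param precursor_tol precursor matching tolerance in Da (default 0.3;
#'   nominal-mass ion trap). For high-resolution data use
#'   `ppm_mode = TRUE` with `ppm = 10`.
#' @param fragment_tol fragment matching tolerance in Da (default 0.3,
#'   wide enough to absorb inconsistent published rounding of the same
#'   ion).
#' @param dominance_ratio,similarity_ratio sn-2 rule parameters, see
#'   [assign_sn2()].
#' @param coverage_threshold minimum coverage for a triad to count as a
#'   serious candidate (default 0.5).
#' @param acid_weight,salt_weight coverage weights; sodium-salt losses
#'   are much weaker ions, so they support coverage (weight 0.25) but are
#'   never required.
#' @param ppm_mode,ppm switch tolerances to parts-per-million.
#' @return A named list.
#' @export
annotate_config <- function(precursor_tol = 0.3, fragment_tol = 0.3,
                            dominance_ratio = 1.5, similarity_ratio = 3,
                            coverage_threshold = 0.5,
                            acid_weight = 1, salt_weight = 0.25,
                            ppm_mode = FALSE, ppm = 10) {
  list(precursor_tol = precursor_tol, fragment_tol = fragment_tol,
       dominance_ratio = dominance_ratio, similarity_ratio = similarity_ratio,
       coverage_threshold = coverage_threshold,
       acid_weight = acid_weight, salt_weight = salt_weight,
       ppm_mode = ppm_mode, ppm = ppm)
}

#' Annotate a sodiated TAG MS2 spectrum
#'
#' Pipeline: (1) enumerate every acyl triad over the pool and keep those
#' whose theoretical `[M+Na]+` m/z lies within the precursor tolerance;
#' (2) predict acid and sodium-salt losses per candidate and match them to
#' the observed peaks; (3) score each candidate by weighted fragment
#' coverage; (4) rank (coverage, then summed matched intensity, then
#' lexicographic triad label - the tie-break never hides ambiguity);
#' (5) call sn-2 on the top candidate only when it is the single candidate
#' reaching the coverage threshold and the precursor is sodiated.
#' The `ambiguous` flag is set whenever more than one triad reaches the
#' coverage threshold: isobaric TAG species can contribute to the same
#' precursor ion, and the flag is the package's way of refusing to exclude
#' co-isolated isomers.
#'
#' @param spectrum an [ms2_spectrum()]. Non-sodiated precursors are
#'   annotated compositionally but sn-2 is always abstained.
#' @param pool candidate acyl pool; default [default_acyl_pool()].
#' @param config an [annotate_config()].
#' @return A `data.frame`, one row per candidate triad: `triad`, `total`,
#'   `theoretical_precursor_mz`, `precursor_error_da`, `coverage`,
#'   `matched_intensity`, `n_matched`, `n_predicted`, `rank`, `sn2`,
#'   `sn2_reason`, `ambiguous`. Full per-fragment match tables are in
#'   `attr(x, "matches")` (named by triad). No candidate within tolerance
#'   gives a zero-row result with a `diagnostic` attribute.
#' @examples
#' sp <- ms2_spectrum(1017.9, c(657.6, 679.6, 715.7, 737.6), c(8, 100, 5, 40))
#' annotate(sp)[1, c("triad", "sn2")]
#' @export
annotate <- function(spectrum, pool = default_acyl_pool(),
                     config = annotate_config()) {
  stopifnot(inherits(spectrum, "ms2_spectrum"))
  prec_tol <- if (config$ppm_mode) {
    spectrum$precursor_mz * config$ppm * 1e-6
  } else {
    config$precursor_tol
  }
  frag_tol <- if (config$ppm_mode) {
    spectrum$precursor_mz * config$ppm * 1e-6
  } else {
    config$fragment_tol
  }
  # candidate triads: all multisets of 3 over the pool whose sodiated
  # theoretical m/z falls within the precursor window
  cs <- vapply(pool, `[[`, 0L, "carbons")
  dbs <- vapply(pool, `[[`, 0L, "double_bonds")
  idx <- .multiset_indices(length(pool), 3L)
  tot_c <- rowSums(matrix(cs[idx], nrow = nrow(idx)))
  tot_db <- rowSums(matrix(dbs[idx], nrow = nrow(idx)))
  totals <- unique(data.frame(c = tot_c, db = tot_db))
  totals$mz <- vapply(seq_len(nrow(totals)), function(i) {
    ion_mz(.assemble_formula("TAG", totals$c[i], totals$db[i]), "[M+Na]+")
  }, 0)
  totals <- totals[abs(totals$mz - spectrum$precursor_mz) <= prec_tol, , drop = FALSE]
  empty <- data.frame(triad = character(), total = character(),
                      theoretical_precursor_mz = numeric(),
                      precursor_error_da = numeric(), coverage = numeric(),
                      matched_intensity = numeric(), n_matched = integer(),
                      n_predicted = integer(), rank = integer(),
                      sn2 = character(), sn2_reason = character(),
                      ambiguous = logical())
  if (nrow(totals) == 0L) {
    attr(empty, "diagnostic") <- sprintf(
      "no candidate TAG totals within %.3g Da of precursor %.4f over the pool",
      prec_tol, spectrum$precursor_mz)
    return(empty)
  }
  cand <- list()
  for (i in seq_len(nrow(totals))) {
    triads <- enumerate_compositions("TAG", totals$c[i], totals$db[i], pool)
    for (tri in triads) {
      cand[[length(cand) + 1L]] <- list(triad = tri, c = totals$c[i],
                                        db = totals$db[i], mz = totals$mz[i])
    }
  }
  if (length(cand) == 0L) {
    attr(empty, "diagnostic") <- "candidate totals have no triad over the pool"
    return(empty)
  }
  w <- c(acid = config$acid_weight, `sodium-salt` = config$salt_weight)
  matches <- list()
  rows <- lapply(cand, function(cc) {
    pred <- predict_fragments(cc$triad)
    mt <- match_spectrum(spectrum, pred, frag_tol)
    triad_lab <- paste(vapply(cc$triad, format, ""), collapse = "/")
    matches[[triad_lab]] <<- mt
    wts <- w[mt$loss_kind]
    coverage <- if (sum(wts) > 0) sum(wts[mt$matched]) / sum(wts) else 0
    data.frame(triad = triad_lab,
               total = paste0(cc$c, ":", cc$db),
               theoretical_precursor_mz = cc$mz,
               precursor_error_da = spectrum$precursor_mz - cc$mz,
               coverage = coverage,
               matched_intensity = sum(mt$intensity[mt$matched], na.rm = TRUE),
               n_matched = sum(mt$matched),
               n_predicted = nrow(mt))
  })
  out <- do.call(rbind, rows)
  ord <- order(-out$coverage, -out$matched_intensity, out$triad)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  n_serious <- sum(out$coverage >= config$coverage_threshold)
  out$ambiguous <- n_serious > 1L
  out$sn2 <- NA_character_
  out$sn2_reason <- "not top-ranked candidate"
  top_lab <- out$triad[1L]
  top_triad <- lapply(strsplit(top_lab, "/")[[1L]], parse_fatty_acid)
  if (spectrum$adduct != "[M+Na]+") {
    out$sn2_reason[1L] <- "positional calls require a sodiated precursor"
  } else if (out$ambiguous[1L]) {
    out$sn2_reason[1L] <- "multiple triads reach the coverage threshold"
  } else if (out$coverage[1L] < config$coverage_threshold) {
    out$sn2_reason[1L] <- "top candidate below coverage threshold"
  } else {
    mt <- matches[[top_lab]]
    acid <- mt[mt$loss_kind == "acid", ]
    ints <- stats::setNames(acid$intensity, acid$acyl)
    call <- assign_sn2(top_triad, ints,
                       dominance_ratio = config$dominance_ratio,
                       similarity_ratio = config$similarity_ratio)
    out$sn2_reason[1L] <- call$reason
    if (!is.null(call$sn2)) out$sn2[1L] <- format(call$sn2)
  }
  rownames(out) <- NULL
  attr(out, "matches") <- matches[out$triad]
  out
}

#' Write an annotation report
#'
#' @param annotation output of [annotate()].
#' @param csv_path report CSV (one row per candidate triad); `NULL` to skip.
#' @param json_path JSON with the full per-fragment match detail; `NULL`
#'   to skip.
#' @return The annotation, invisibly.
#' @export
write_annotation <- function(annotation, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    utils::write.csv(annotation, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    detail <- list(candidates = annotation,
                   matches = attr(annotation, "matches"))
    jsonlite::write_json(detail, json_path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  }
  invisible(annotation)
}
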