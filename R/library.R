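#' Skeleton classes recognised by the library
#'
#' Pentacyclic triterpenoid skeleton subclasses plus the limonoid
#' (tetranortriterpenoid) class and a catch-all `"other"`.
#' @return Character vector of class labels.
#' @export
skeleton_classes <- function() {
  c("oleanane", "ursane", "lupane", "friedelane", "limonoid", "other")
}

#' Construct a single library record
#'
#' One reference compound: identifying metadata, chromatographic retention
#' time, the adduct entries (calculated and, where available, measured m/z)
#' and its collision-energy-resolved MS2 spectra.
#'
#' @param name Compound label (unique within a library).
#' @param formula Formula string or named count vector.
#' @param logp Log p value (dimensionless hydrophobicity), or `NA`.
#' @param rt Retention time in minutes (> 0), or `NA` when unknown (an
#'   MS1-only record usable for mass matching).
#' @param skeleton_class One of [skeleton_classes()].
#' @param adducts `data.frame` with columns `adduct`, `calc_mz`, `meas_mz`
#'   (NA allowed), `observed` (logical). If `NULL`, a single calculated
#'   `[M+H]+` entry is generated from the formula.
#' @param spectra List of [new_spectrum()] objects.
#' @param flags Character vector of provenance flags (e.g.
#'   `"calc_inconsistent"` for source-table rows whose printed calculated
#'   m/z disagrees with the formula).
#' @return Object of class `library_record`.
#' @export
library_record <- function(name, formula, logp = NA_real_, rt = NA_real_,
                           skeleton_class = "other", adducts = NULL,
                           spectra = list(), flags = character()) {
  if (is.character(formula)) formula <- parse_formula(formula)
  skeleton_class <- match.arg(skeleton_class, skeleton_classes())
  if (!is.na(rt) && rt <= 0) stop("rt must be > 0", call. = FALSE)
  if (is.null(adducts)) {
    adducts <- data.frame(adduct = "[M+H]+",
                          calc_mz = adduct_mz(formula, "[M+H]+"),
                          meas_mz = NA_real_, observed = FALSE)
  }
  stopifnot(is.data.frame(adducts),
            all(c("adduct", "calc_mz") %in% names(adducts)),
            nrow(adducts) >= 1)
  if (is.null(adducts$meas_mz)) adducts$meas_mz <- NA_real_
  if (is.null(adducts$observed)) adducts$observed <- !is.na(adducts$meas_mz)
  stopifnot(all(vapply(spectra, inherits, logical(1), "ms2_spectrum")))
  structure(list(name = name, formula = formula,
                 formula_string = format_formula(formula),
                 logp = as.numeric(logp), rt = as.numeric(rt),
                 skeleton_class = skeleton_class,
                 adducts = adducts, spectra = spectra, flags = flags),
            class = "library_record")
}

#' @export
print.library_record <- function(x, ...) {
  cat(sprintf("<library_record> %s (%s, %s), RT %.2f min, %d adduct(s), %d spectrum(s)\n",
              x$name, x$formula_string, x$skeleton_class, x$rt,
              nrow(x$adducts), length(x$spectra)))
  invisible(x)
}

#' Construct a spectral library
#'
#' @param records List of [library_record()] objects with unique names.
#' @param provenance Free-text metadata (instrument, column, gradient, ...).
#' @return Object of class `spectral_library`.
#' @export
spectral_library <- function(records, provenance = "") {
  stopifnot(all(vapply(records, inherits, logical(1), "library_record")))
  nm <- vapply(records, `[[`, character(1), "name")
  if (anyDuplicated(nm))
    stop("duplicate record names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  names(records) <- nm
  structure(list(records = records, provenance = provenance),
            class = "spectral_library")
}

#' @export
print.spectral_library <- function(x, ...) {
  cat(sprintf("<spectral_library> %d record(s), %d spectra\n",
              length(x$records),
              sum(vapply(x$records, function(r) length(r$spectra), integer(1)))))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
length.spectral_library <- function(x) length(x$records)

#' Precursor index of a library
#'
#' All (record, adduct) entries as one table sorted by calculated m/z, the
#' structure behind the sorted-range precursor queries of the matcher.
#'
#' @param lib A `spectral_library`.
#' @return `data.frame` with columns `name`, `adduct`, `calc_mz`, `meas_mz`,
#'   `observed`, sorted ascending by `calc_mz`.
#' @export
adduct_index <- function(lib) {
  stopifnot(inherits(lib, "spectral_library"))
  rows <- lapply(lib$records, function(r) {
    cbind(data.frame(name = r$name), r$adducts[, c("adduct", "calc_mz",
                                                   "meas_mz", "observed")])
  })
  idx <- do.call(rbind, rows)
  rownames(idx) <- NULL
  idx[order(idx$calc_mz, idx$name, idx$adduct), , drop = FALSE]
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 50L)
  first <- first[!startsWith(first, "#")][1]
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.delim(path, sep = sep, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = TRUE)
}

#' Build a spectral library from a compound table and spectra
#'
#' The compound table (path to TSV/CSV or a `data.frame`) has one row per
#' compound-adduct with columns `name`, `formula`, `logp`, `rt`, `adduct`
#' and optionally `mz_calc`, `mz_meas`, `skeleton_class`, `flag`. For every
#' row the calculated adduct m/z is recomputed from the formula and
#' cross-checked against a provided `mz_calc` column; disagreements beyond
#' `calc_tol` raise a warning naming the row (and are recorded as a
#' `calc_inconsistent` flag on the record). The ppm error column is
#' recomputed from the display-rounded (4-decimal) calculated value against
#' the measured one, the convention under which printed table errors
#' reproduce.
#'
#' Because positive-mode screening routinely matches sodium adducts that
#' were not intense enough to be catalogued for every standard, each record
#' is augmented (when `augment_adducts = TRUE`) with calculated entries for
#' all standard adducts in [adduct_table()]; inferred entries carry
#' `observed = FALSE`.
#'
#' @param compound_table Path to a delimited file or a `data.frame`.
#' @param spectra List of `ms2_spectrum` objects named by compound (or
#'   carrying a `compound` attribute), e.g. from [read_msp_spectra()]. An
#'   empty list yields an MS1-only library.
#' @param calc_tol Cross-check tolerance in Da (default 0.0005).
#' @param augment_adducts Add calculated entries for missing standard
#'   adducts (default `TRUE`).
#' @param provenance Free-text provenance stored on the library.
#' @return A `spectral_library`.
#' @export
build_library <- function(compound_table, spectra = list(), calc_tol = 5e-4,
                          augment_adducts = TRUE, provenance = "") {
  tab <- if (is.character(compound_table)) read_delim_auto(compound_table)
         else as.data.frame(compound_table)
  required <- c("name", "formula", "logp", "rt", "adduct")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("compound table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (anyDuplicated(tab[, c("name", "adduct")]))
    stop("duplicate (name, adduct) rows in compound table", call. = FALSE)
  spec_names <- spectrum_keys(spectra)
  records <- list()
  for (nm in unique(tab$name)) {
    rows <- tab[tab$name == nm, , drop = FALSE]
    counts <- tryCatch(parse_formula(rows$formula[1]), error = function(e)
      stop(sprintf("row for '%s': %s", nm, conditionMessage(e)), call. = FALSE))
    flags <- character()
    if (!is.null(rows$flag))
      flags <- unique(rows$flag[!is.na(rows$flag) & nzchar(rows$flag)])
    ad <- data.frame(adduct = rows$adduct,
                     calc_mz = NA_real_, meas_mz = NA_real_,
                     observed = TRUE, error_ppm = NA_real_,
                     stringsAsFactors = FALSE)
    for (i in seq_len(nrow(rows))) {
      recalc <- adduct_mz(counts, rows$adduct[i])
      provided <- if (!is.null(rows$mz_calc)) rows$mz_calc[i] else NA_real_
      if (!is.na(provided) && abs(provided - recalc) > calc_tol) {
        warning(sprintf(
          "calculated m/z mismatch for '%s' %s: table %.4f, from formula %.4f",
          nm, rows$adduct[i], provided, recalc), call. = FALSE)
        flags <- union(flags, "calc_inconsistent")
      }
      ad$calc_mz[i] <- if (!is.na(provided)) provided else recalc
      if (!is.null(rows$mz_meas)) ad$meas_mz[i] <- rows$mz_meas[i]
      if (!is.na(ad$meas_mz[i]))
        ad$error_ppm[i] <- round_half_away(
          ppm_error(round_half_away(ad$calc_mz[i], 4), ad$meas_mz[i]), 1)
    }
    if (augment_adducts) {
      for (a in setdiff(adduct_table()$name, ad$adduct)) {
        ad <- rbind(ad, data.frame(adduct = a,
                                   calc_mz = adduct_mz(counts, a),
                                   meas_mz = NA_real_, observed = FALSE,
                                   error_ppm = NA_real_))
      }
    }
    sp <- spectra[which(!is.na(spec_names) & spec_names == nm)]
    # the record owns the metadata; drop per-spectrum carrier attributes so
    # a record round-trips identically through the archive format
    sp <- lapply(sp, function(s) {
      attributes(s) <- attributes(s)[c("names", "class")]
      s
    })
    cls <- if (!is.null(rows$skeleton_class) && nzchar(rows$skeleton_class[1]))
      rows$skeleton_class[1] else "other"
    records[[nm]] <- library_record(
      name = nm, formula = counts, logp = rows$logp[1], rt = rows$rt[1],
      skeleton_class = cls, adducts = ad, spectra = unname(sp), flags = flags)
  }
  spectral_library(records, provenance = provenance)
}

spectrum_keys <- function(spectra) {
  if (!length(spectra)) return(character(0))
  keys <- names(spectra)
  attr_keys <- vapply(spectra, function(s) {
    k <- attr(s, "compound")
    if (is.null(k)) NA_character_ else k
  }, character(1))
  if (is.null(keys)) keys <- attr_keys
  keys[is.na(keys) | !nzchar(keys)] <- attr_keys[is.na(keys) | !nzchar(keys)]
  keys
}
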