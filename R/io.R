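#' Write a spectral library to disk
#'
#' Three formats are supported. `"archive"` is the package's own versioned
#' plain-text JSON schema and round-trips every field losslessly (full
#' double precision); it is the format the matcher and CLI exchange.
#' `"msp"` writes one NIST-dialect text entry per spectrum (`Name`,
#' `Formula`, `PrecursorMZ`, `RT`, `CollisionEnergy`, `Num Peaks`, peak
#' lines); records without spectra are written as a single `Num Peaks: 0`
#' entry so the compound metadata survives. `"mgf"` writes one
#' `BEGIN IONS` block per spectrum with `PEPMASS` printed at 4 decimals.
#'
#' @param lib A non-empty `spectral_library`.
#' @param path Output file path.
#' @param format `"archive"`, `"msp"` or `"mgf"`.
#' @return `path`, invisibly.
#' @export
write_library <- function(lib, path, format = c("archive", "msp", "mgf")) {
  stopifnot(inherits(lib, "spectral_library"))
  if (!length(lib$records)) stop("library is empty", call. = FALSE)
  format <- match.arg(format)
  switch(format,
         archive = write_archive(lib, path),
         msp = write_msp(lib, path),
         mgf = write_mgf(lib, path))
  invisible(path)
}

#' Read a spectral library
#'
#' Inverse of [write_library()]. The archive format restores every field;
#' MSP and MGF import tolerate absent optional fields (a missing RT becomes
#' `NA`, leaving the record usable for mass-only matching). Malformed
#' entries raise an error naming the entry ordinal; a peak count
#' disagreeing with `Num Peaks`, or a truncated file, is an error rather
#' than a silent partial load.
#'
#' @param path Input file.
#' @param format `"archive"`, `"msp"` or `"mgf"`.
#' @return A `spectral_library`.
#' @export
read_library <- function(path, format = c("archive", "msp", "mgf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  switch(format,
         archive = read_archive(path),
         msp = msp_to_library(read_msp_spectra(path)),
         mgf = msp_to_library(read_mgf_spectra(path)))
}

## ---- archive (versioned JSON) ----

spectrum_to_list <- function(s) {
  list(precursor_mz = s$precursor_mz, adduct = s$adduct,
       collision_energy = s$collision_energy, mode = s$mode,
       mz = s$peaks$mz, intensity = s$peaks$intensity)
}

list_to_spectrum <- function(l) {
  new_spectrum(as.numeric(unlist(l$mz)), as.numeric(unlist(l$intensity)),
               precursor_mz = l$precursor_mz, adduct = l$adduct,
               collision_energy = l$collision_energy, mode = l$mode)
}

write_archive <- function(lib, path) {
  recs <- lapply(unname(lib$records), function(r) {
    list(name = r$name,
         formula = as.list(r$formula),
         logp = r$logp, rt = r$rt, skeleton_class = r$skeleton_class,
         flags = as.list(r$flags),
         adducts = lapply(seq_len(nrow(r$adducts)), function(i)
           as.list(r$adducts[i, , drop = FALSE])),
         spectra = lapply(r$spectra, spectrum_to_list))
  })
  obj <- list(format = "triterpenlib-archive", version = 1L,
              provenance = lib$provenance, records = recs)
  # 17 significant digits round-trips IEEE doubles exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       na = "null", null = "null", pretty = TRUE)
}

read_archive <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e)
                    stop("malformed archive file: ", conditionMessage(e),
                         call. = FALSE))
  if (!identical(obj$format, "triterpenlib-archive"))
    stop("not a triterpenlib archive", call. = FALSE)
  if (!identical(as.integer(obj$version), 1L))
    stop("unsupported archive version: ", obj$version, call. = FALSE)
  records <- lapply(obj$records, function(r) {
    counts <- unlist(r$formula)
    ad <- do.call(rbind, lapply(r$adducts, function(a) {
      # preserve exactly the archived columns; nulls are typed NA
      a <- lapply(a, function(v) if (is.null(v)) NA else v)
      a$meas_mz <- as.numeric(a$meas_mz)
      if (!is.null(a$error_ppm)) a$error_ppm <- as.numeric(a$error_ppm)
      as.data.frame(a, stringsAsFactors = FALSE)
    }))
    library_record(name = r$name, formula = counts,
                   logp = if (is.null(r$logp)) NA_real_ else r$logp,
                   rt = if (is.null(r$rt)) NA_real_ else r$rt,
                   skeleton_class = r$skeleton_class,
                   adducts = ad,
                   spectra = lapply(r$spectra, list_to_spectrum),
                   flags = as.character(unlist(r$flags)))
  })
  spectral_library(records, provenance = as.character(obj$provenance))
}

## ---- MSP (NIST text dialect) ----

write_msp <- function(lib, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in lib$records) {
    spectra <- r$spectra
    if (!length(spectra)) spectra <- list(NULL)
    for (s in spectra) {
      lines <- c(paste0("Name: ", r$name),
                 paste0("Formula: ", r$formula_string))
      if (!is.na(r$logp)) lines <- c(lines, paste0("LogP: ", r$logp))
      if (!is.na(r$rt)) lines <- c(lines, paste0("RT: ", r$rt))
      lines <- c(lines, paste0("SkeletonClass: ", r$skeleton_class))
      if (is.null(s)) {
        lines <- c(lines,
                   sprintf("PrecursorMZ: %.4f", r$adducts$calc_mz[1]),
                   paste0("Adduct: ", r$adducts$adduct[1]),
                   "Num Peaks: 0")
      } else {
        lines <- c(lines,
                   sprintf("PrecursorMZ: %.4f", s$precursor_mz),
                   paste0("Adduct: ", s$adduct),
                   paste0("CollisionEnergy: ", s$collision_energy),
                   paste0("Mode: ", s$mode),
                   paste0("Num Peaks: ", nrow(s$peaks)),
                   sprintf("%.4f %.1f", s$peaks$mz, s$peaks$intensity))
      }
      writeLines(c(lines, ""), con)
    }
  }
}

#' Read spectra from an MSP file
#'
#' Parses a NIST-dialect MSP file into a list of `ms2_spectrum` objects,
#' each carrying `compound` (from `Name:`), and where present `formula`,
#' `rt`, `logp`, `skeleton_class` attributes. This is the form
#' [build_library()] accepts as its `spectra` argument.
#'
#' @param path MSP file path.
#' @return List of `ms2_spectrum` objects with metadata attributes.
#' @export
read_msp_spectra <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  out <- list()
  i <- 1L
  entry <- 0L
  n <- length(lines)
  while (i <= n) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    entry <- entry + 1L
    fields <- list()
    while (i <= n && grepl("^[A-Za-z][A-Za-z0-9 _]*:", lines[i])) {
      key <- sub(":.*$", "", lines[i])
      val <- trimws(sub("^[^:]*:", "", lines[i]))
      fields[[tolower(gsub(" ", "", key))]] <- val
      i <- i + 1L
    }
    if (is.null(fields$name))
      stop(sprintf("MSP entry %d: missing Name field", entry), call. = FALSE)
    if (is.null(fields$numpeaks))
      stop(sprintf("MSP entry %d ('%s'): missing 'Num Peaks'", entry,
                   fields$name), call. = FALSE)
    npk <- as.integer(fields$numpeaks)
    mz <- numeric(0); int <- numeric(0)
    got <- 0L
    while (got < npk) {
      if (i > n || !nzchar(trimws(lines[i])))
        stop(sprintf(
          "MSP entry %d ('%s'): truncated, expected %d peaks but found %d",
          entry, fields$name, npk, got), call. = FALSE)
      parts <- strsplit(trimws(lines[i]), "[\t ;]+")[[1]]
      if (length(parts) < 2L || anyNA(suppressWarnings(as.numeric(parts[1:2]))))
        stop(sprintf("MSP entry %d ('%s'): malformed peak line '%s'",
                     entry, fields$name, lines[i]), call. = FALSE)
      mz <- c(mz, as.numeric(parts[1]))
      int <- c(int, as.numeric(parts[2]))
      got <- got + 1L
      i <- i + 1L
    }
    if (i <= n && nzchar(trimws(lines[i])) &&
        !grepl("^[A-Za-z][A-Za-z0-9 _]*:", lines[i]))
      stop(sprintf("MSP entry %d ('%s'): more peak lines than 'Num Peaks: %d'",
                   entry, fields$name, npk), call. = FALSE)
    s <- new_spectrum(mz, int,
                      precursor_mz = as.numeric(
                        fields$precursormz %||% NA_real_),
                      adduct = fields$adduct %||% NA_character_,
                      collision_energy = fields$collisionenergy %||%
                        NA_character_,
                      mode = fields$mode %||% "targeted")
    attr(s, "compound") <- fields$name
    if (!is.null(fields$formula)) attr(s, "formula") <- fields$formula
    if (!is.null(fields$rt)) attr(s, "rt") <- as.numeric(fields$rt)
    if (!is.null(fields$logp)) attr(s, "logp") <- as.numeric(fields$logp)
    if (!is.null(fields$skeletonclass))
      attr(s, "skeleton_class") <- fields$skeletonclass
    out[[length(out) + 1L]] <- s
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# assemble records from per-spectrum metadata (MSP/MGF import path)
msp_to_library <- function(spectra) {
  keys <- spectrum_keys(spectra)
  records <- lapply(unique(keys), function(nm) {
    sp <- spectra[keys == nm]
    s1 <- sp[[1]]
    formula <- attr(s1, "formula")
    counts <- if (!is.null(formula)) parse_formula(formula) else integer(0)
    ads <- unique(data.frame(
      adduct = vapply(sp, function(s)
        if (is.na(s$adduct)) "[M+H]+" else s$adduct, character(1)),
      calc_mz = vapply(sp, `[[`, numeric(1), "precursor_mz")))
    ads$meas_mz <- NA_real_
    ads$observed <- TRUE
    library_record(name = nm, formula = counts,
                   logp = attr(s1, "logp") %||% NA_real_,
                   rt = attr(s1, "rt") %||% NA_real_,
                   skeleton_class = attr(s1, "skeleton_class") %||% "other",
                   adducts = ads, spectra = unname(sp))
  })
  # drop MS1-only placeholder spectra written as "Num Peaks: 0"
  records <- lapply(records, function(r) {
    r$spectra <- Filter(function(s) nrow(s$peaks) > 0, r$spectra)
    r
  })
  spectral_library(records)
}

## ---- MGF (Mascot generic format) ----

write_mgf <- function(lib, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in lib$records) {
    for (s in r$spectra) {
      writeLines(c("BEGIN IONS",
                   sprintf("TITLE=%s|%s|%s", r$name, s$adduct,
                           s$collision_energy),
                   sprintf("PEPMASS=%.4f", s$precursor_mz),
                   if (!is.na(r$rt)) sprintf("RTINSECONDS=%.2f", r$rt * 60),
                   "CHARGE=1+",
                   sprintf("%.4f %.1f", s$peaks$mz, s$peaks$intensity),
                   "END IONS", ""), con)
    }
  }
}

#' Read spectra from an MGF file
#'
#' Parses Mascot generic format into `ms2_spectrum` objects. Titles written
#' by this package (`compound|adduct|CE`) are decoded back into metadata
#' attributes; foreign titles are kept verbatim as the `compound` attribute.
#'
#' @param path MGF file path.
#' @return List of `ms2_spectrum` objects with metadata attributes.
#' @export
read_mgf_spectra <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  out <- list()
  i <- 1L
  n <- length(lines)
  entry <- 0L
  while (i <= n) {
    if (trimws(lines[i]) != "BEGIN IONS") { i <- i + 1L; next }
    entry <- entry + 1L
    i <- i + 1L
    hdr <- list()
    mz <- numeric(0); int <- numeric(0)
    repeat {
      if (i > n)
        stop(sprintf("MGF block %d: truncated (no END IONS)", entry),
             call. = FALSE)
      ln <- trimws(lines[i])
      if (ln == "END IONS") { i <- i + 1L; break }
      if (grepl("=", ln, fixed = TRUE)) {
        key <- toupper(sub("=.*$", "", ln))
        hdr[[key]] <- sub("^[^=]*=", "", ln)
      } else if (nzchar(ln)) {
        parts <- strsplit(ln, "[\t ]+")[[1]]
        v <- suppressWarnings(as.numeric(parts))
        if (anyNA(v[1]))
          stop(sprintf("MGF block %d: malformed peak line '%s'", entry, ln),
               call. = FALSE)
        mz <- c(mz, v[1])
        int <- c(int, if (length(v) > 1 && !is.na(v[2])) v[2] else 1)
      }
      i <- i + 1L
    }
    pep <- suppressWarnings(as.numeric(strsplit(hdr$PEPMASS %||% "NA",
                                                "[\t ]+")[[1]][1]))
    title <- hdr$TITLE %||% sprintf("entry%d", entry)
    tparts <- strsplit(title, "|", fixed = TRUE)[[1]]
    s <- new_spectrum(mz, int, precursor_mz = pep,
                      adduct = if (length(tparts) >= 2) tparts[2]
                               else NA_character_,
                      collision_energy = if (length(tparts) >= 3) tparts[3]
                                         else NA_character_,
                      mode = "auto")
    attr(s, "compound") <- tparts[1]
    attr(s, "title") <- title
    if (!is.null(hdr$RTINSECONDS))
      attr(s, "rt") <- as.numeric(hdr$RTINSECONDS) / 60
    out[[length(out) + 1L]] <- s
  }
  out
}
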