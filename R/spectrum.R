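#' Construct an MS2 spectrum
#'
#' A spectrum is a peak list (m/z, intensity) plus precursor metadata. Peaks
#' are sorted ascending by m/z at construction; duplicate m/z values (within
#' 1e-6 Da) and peaks outside the instrument scan range are rejected, so a
#' valid object always satisfies the peak-list invariants.
#'
#' @param mz Numeric vector of fragment m/z values (Da).
#' @param intensity Numeric vector of intensities (counts, >= 0), recycled
#'   to length 1 if omitted.
#' @param precursor_mz Precursor m/z (Da).
#' @param adduct Adduct label of the precursor (e.g. `"[M+H]+"`), or `NA`.
#' @param collision_energy Collision energy in eV as a character scalar:
#'   a fixed value (`"20"`), a ramp descriptor (`"ramp 25-62.5"`), or a
#'   derived label such as `"consensus"`.
#' @param mode Acquisition mode, `"targeted"` or `"auto"`.
#' @param scan_range Instrument scan range; peaks outside it are an error.
#' @return An object of class `ms2_spectrum`: a list with elements `peaks`
#'   (data.frame `mz`, `intensity`), `precursor_mz`, `adduct`,
#'   `collision_energy`, `mode`.
#' @export
new_spectrum <- function(mz, intensity = rep(1, length(mz)), precursor_mz,
                         adduct = NA_character_,
                         collision_energy = NA_character_,
                         mode = c("targeted", "auto"),
                         scan_range = c(50, 1200)) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(mz), is.numeric(intensity),
            length(mz) == length(intensity))
  if (any(intensity < 0)) stop("intensities must be >= 0", call. = FALSE)
  if (length(mz)) {
    if (any(mz < scan_range[1] - 1e-9 | mz > scan_range[2] + 1e-9))
      stop(sprintf("peak m/z outside scan range [%g, %g]",
                   scan_range[1], scan_range[2]), call. = FALSE)
    o <- order(mz)
    mz <- mz[o]
    intensity <- intensity[o]
    if (any(diff(mz) < 1e-6))
      stop("duplicate peak m/z within 1e-6 Da", call. = FALSE)
  }
  structure(list(
    peaks = data.frame(mz = as.numeric(mz), intensity = as.numeric(intensity)),
    precursor_mz = as.numeric(precursor_mz),
    adduct = as.character(adduct),
    collision_energy = as.character(collision_energy),
    mode = mode
  ), class = "ms2_spectrum")
}

#' @export
print.ms2_spectrum <- function(x, ...) {
  cat(sprintf("<ms2_spectrum> precursor %.4f %s, CE %s (%s), %d peaks\n",
              x$precursor_mz, x$adduct, x$collision_energy, x$mode,
              nrow(x$peaks)))
  invisible(x)
}

#' Number of peaks in a spectrum
#' @param s An `ms2_spectrum`.
#' @return Integer peak count.
#' @export
n_peaks <- function(s) nrow(s$peaks)

# one single-linkage merge pass: cluster peaks whose gaps are <= mz_tol
merge_peaks_pass <- function(mz, intensity, mz_tol) {
  o <- order(mz)
  mz <- mz[o]
  intensity <- intensity[o]
  grp <- cumsum(c(1, as.integer(diff(mz) > mz_tol)))
  w <- ifelse(intensity > 0, intensity, .Machine$double.eps)
  data.frame(
    mz = as.numeric(tapply(mz * w, grp, sum) / tapply(w, grp, sum)),
    intensity = as.numeric(tapply(intensity, grp, max))
  )
}

#' Consensus spectrum across collision energies
#'
#' Merges spectra of one compound (typically the fixed collision-energy
#' series 10/20/30/40 eV) into a single representative spectrum: peaks
#' within `mz_tol` of each other are clustered (single-linkage, repeated
#' until stable so the operation is idempotent); a cluster is represented by
#' its intensity-weighted mean m/z with the maximum intensity across
#' energies, preserving diagnostic fragments that only appear at some
#' energies.
#'
#' @param spectra List of `ms2_spectrum` objects sharing one precursor.
#' @param mz_tol Clustering tolerance in Da (default 0.005).
#' @return A single `ms2_spectrum` with collision energy `"consensus"`.
#' @export
consensus_spectrum <- function(spectra, mz_tol = 0.005) {
  if (inherits(spectra, "ms2_spectrum")) spectra <- list(spectra)
  if (!length(spectra)) stop("need at least one spectrum", call. = FALSE)
  stopifnot(all(vapply(spectra, inherits, logical(1), "ms2_spectrum")))
  if (mz_tol <= 0) stop("mz_tol must be > 0", call. = FALSE)
  prec <- vapply(spectra, `[[`, numeric(1), "precursor_mz")
  if (diff(range(prec)) > mz_tol)
    stop(sprintf("precursor disagreement beyond tolerance (%.4f-%.4f)",
                 min(prec), max(prec)), call. = FALSE)
  pk <- do.call(rbind, lapply(spectra, `[[`, "peaks"))
  if (!nrow(pk)) {
    return(new_spectrum(numeric(0), numeric(0), mean(prec),
                        adduct = spectra[[1]]$adduct,
                        collision_energy = "consensus",
                        mode = spectra[[1]]$mode))
  }
  repeat {
    merged <- merge_peaks_pass(pk$mz, pk$intensity, mz_tol)
    if (nrow(merged) == nrow(pk)) break
    pk <- merged
  }
  new_spectrum(merged$mz, merged$intensity, mean(prec),
               adduct = spectra[[1]]$adduct,
               collision_energy = "consensus",
               mode = spectra[[1]]$mode)
}
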