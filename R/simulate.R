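#' Acquisition settings for the DDA simulator
#'
#' Defaults mirror the reference acquisition: MS1 at 5 Hz and MS/MS at
#' 12 Hz, an intensity threshold of 1000 counts to trigger precursor
#' selection, 3 active exclusions per precursor, a 50-1200 m/z scan range,
#' and either the fixed collision-energy set (10, 20, 30, 40 eV, targeted
#' mode) or the 25-62.5 eV ramp (auto mode). The per-cycle top-N follows
#' from the scan rates as `floor(ms2_rate / ms1_rate)`.
#'
#' @param ms1_rate MS1 scan rate, Hz.
#' @param ms2_rate MS/MS acquisition rate, Hz.
#' @param intensity_threshold Minimum MS1 intensity (counts) for precursor
#'   selection.
#' @param active_exclusion_count Number of MS2 selections after which a
#'   precursor is excluded.
#' @param scan_range Two-element numeric, low < high (m/z).
#' @param ce_mode `"fixed"` (cycle through `ce_values`) or `"ramp"`.
#' @param ce_values Fixed collision energies, eV.
#' @param ramp Ramp bounds, eV.
#' @param top_n Precursors fragmented per cycle; default derived from the
#'   scan rates.
#' @return Object of class `acquisition_settings`.
#' @export
acquisition_settings <- function(ms1_rate = 5, ms2_rate = 12,
                                 intensity_threshold = 1000,
                                 active_exclusion_count = 3L,
                                 scan_range = c(50, 1200),
                                 ce_mode = c("fixed", "ramp"),
                                 ce_values = c(10, 20, 30, 40),
                                 ramp = c(25, 62.5),
                                 top_n = NULL) {
  ce_mode <- match.arg(ce_mode)
  stopifnot(ms1_rate > 0, ms2_rate > 0, intensity_threshold >= 0,
            active_exclusion_count >= 1, length(scan_range) == 2,
            scan_range[1] < scan_range[2])
  if (is.null(top_n)) top_n <- max(1L, floor(ms2_rate / ms1_rate))
  structure(list(ms1_rate = ms1_rate, ms2_rate = ms2_rate,
                 intensity_threshold = intensity_threshold,
                 active_exclusion_count = as.integer(active_exclusion_count),
                 scan_range = scan_range, ce_mode = ce_mode,
                 ce_values = ce_values, ramp = ramp,
                 top_n = as.integer(top_n)),
            class = "acquisition_settings")
}

#' Noise specification for the DDA simulator
#'
#' @param mz_sigma Gaussian m/z jitter per observation, Da.
#' @param rt_sigma Gaussian retention-time drift per component, minutes.
#' @param intensity_sdlog Log-normal sd of apex intensities.
#' @param base_intensity Median apex intensity, counts.
#' @param decoy_components Number of background (decoy) chromatographic
#'   components with random m/z and RT.
#' @param decoy_fragment_rate Poisson mean of decoy peaks added per MS2
#'   spectrum.
#' @param chrom_sigma Chromatographic Gaussian peak width (sd), minutes.
#' @return Object of class `noise_spec`.
#' @export
noise_spec <- function(mz_sigma = 0.001, rt_sigma = 0.1,
                       intensity_sdlog = 0.3, base_intensity = 2e4,
                       decoy_components = 10L, decoy_fragment_rate = 3,
                       chrom_sigma = 0.05) {
  stopifnot(mz_sigma >= 0, rt_sigma >= 0, intensity_sdlog >= 0,
            base_intensity > 0, decoy_components >= 0,
            decoy_fragment_rate >= 0, chrom_sigma > 0)
  structure(list(mz_sigma = mz_sigma, rt_sigma = rt_sigma,
                 intensity_sdlog = intensity_sdlog,
                 base_intensity = base_intensity,
                 decoy_components = as.integer(decoy_components),
                 decoy_fragment_rate = decoy_fragment_rate,
                 chrom_sigma = chrom_sigma),
            class = "noise_spec")
}

#' In-silico fragment spectrum of a library record
#'
#' Builds a theoretical MS2 spectrum from the neutral-loss series of the
#' record's adduct precursor plus the skeleton-class diagnostic ions, with
#' a deterministic geometric intensity pattern. Used by the simulator (and
#' by mass-only libraries) when no measured spectrum is available.
#'
#' @param record A `library_record`.
#' @param adduct Adduct name; defaults to the record's first adduct.
#' @param ce Collision-energy label stored on the spectrum.
#' @param max_depth Loss-series depth (default 2).
#' @return An `ms2_spectrum`.
#' @export
theoretical_spectrum <- function(record, adduct = NULL, ce = "theoretical",
                                 max_depth = 2L) {
  stopifnot(inherits(record, "library_record"))
  if (is.null(adduct)) adduct <- record$adducts$adduct[1]
  i <- match(adduct, record$adducts$adduct)
  if (is.na(i)) stop("record has no adduct ", adduct, call. = FALSE)
  prec <- record$adducts$calc_mz[i]
  stem <- sub("^\\[(M[^]]*)\\].*$", "\\1", adduct)
  ls <- loss_series(prec, max_depth = max_depth, precursor_label = stem)
  diag <- diagnostic_ions(record$skeleton_class)
  mz <- c(ls$mz, diag$mz)
  int <- c(10000 * 0.8^seq_len(nrow(ls)), rep(5000, nrow(diag)))
  keep <- !duplicated(round(mz, 6))
  s <- new_spectrum(mz[keep], int[keep], precursor_mz = prec,
                    adduct = adduct, collision_energy = as.character(ce),
                    mode = "targeted")
  attr(s, "compound") <- record$name
  s
}

#' Attach in-silico spectra to records lacking measured ones
#'
#' @param lib A `spectral_library`.
#' @param adducts `"observed"` (default) to cover observed adducts only, or
#'   `"all"`.
#' @param replace Also replace existing measured spectra (default `FALSE`).
#' @return The library with spectra attached.
#' @export
add_theoretical_spectra <- function(lib, adducts = c("observed", "all"),
                                    replace = FALSE) {
  adducts <- match.arg(adducts)
  lib$records <- lapply(lib$records, function(r) {
    if (length(r$spectra) && !replace) return(r)
    ad <- r$adducts
    if (adducts == "observed" && any(ad$observed))
      ad <- ad[ad$observed, , drop = FALSE]
    r$spectra <- lapply(ad$adduct, function(a) theoretical_spectrum(r, a))
    r
  })
  lib
}

#' Simulate a data-dependent acquisition run
#'
#' Each library compound-adduct elutes as a Gaussian chromatographic peak
#' centered at its library retention time plus a drawn drift; MS1 scans
#' sample the chromatogram at the MS1 rate; per cycle the top-N precursors
#' above the intensity threshold and not excluded trigger MS2 events
#' (library or in-silico spectrum with m/z jitter plus decoy peaks).
#' Dynamic exclusion follows the rule: a precursor is excluded after
#' `active_exclusion_count` selections and released (counter reset) once
#' it has stayed below the threshold for one full cycle. Background decoy
#' components with random m/z and RT compete for selection. The run is
#' fully reproducible from `seed`, and the exclusion audit
#' ([audit_run()]) is asserted before returning.
#'
#' @param lib A non-empty `spectral_library`.
#' @param settings An [acquisition_settings()] object.
#' @param noise A [noise_spec()] object.
#' @param seed Integer RNG seed.
#' @param rt_pad Minutes of chromatogram simulated beyond the extreme
#'   apexes.
#' @return Object of class `simulated_run`: list with `events` (one row
#'   per MS2 event: cycle, time, compound, adduct, observed precursor m/z,
#'   triggering intensity, collision energy, selection index, exclusion
#'   epoch), `spectra` (list parallel to `events`), `truth` (per component:
#'   compound, adduct, theoretical m/z, apex RT and intensity), plus the
#'   settings, noise and seed.
#' @export
simulate_run <- function(lib, settings = acquisition_settings(),
                         noise = noise_spec(), seed = 1L, rt_pad = 0.5) {
  stopifnot(inherits(lib, "spectral_library"),
            inherits(settings, "acquisition_settings"),
            inherits(noise, "noise_spec"))
  if (!length(lib$records)) stop("library is empty", call. = FALSE)
  set.seed(as.integer(seed))

  comp <- do.call(rbind, lapply(lib$records, function(r) {
    ad <- r$adducts[r$adducts$observed, , drop = FALSE]
    if (!nrow(ad)) ad <- r$adducts[1, , drop = FALSE]
    data.frame(compound = r$name, adduct = ad$adduct, mz = ad$calc_mz,
               rt_library = r$rt, stringsAsFactors = FALSE)
  }))
  comp <- comp[!is.na(comp$rt_library), , drop = FALSE]
  if (!nrow(comp)) stop("no record has a retention time", call. = FALSE)
  rownames(comp) <- NULL
  nc <- nrow(comp)
  comp$apex_rt <- comp$rt_library + stats::rnorm(nc, 0, noise$rt_sigma)
  comp$apex_intensity <- stats::rlnorm(nc, log(noise$base_intensity),
                                       noise$intensity_sdlog)
  t_lo <- min(comp$apex_rt) - rt_pad
  t_hi <- max(comp$apex_rt) + rt_pad
  if (noise$decoy_components > 0) {
    nd <- noise$decoy_components
    comp <- rbind(comp, data.frame(
      compound = NA_character_, adduct = NA_character_,
      mz = stats::runif(nd,
                        settings$scan_range[1] + 0.1 * diff(settings$scan_range),
                        settings$scan_range[2] - 0.1 * diff(settings$scan_range)),
      rt_library = NA_real_,
      apex_rt = stats::runif(nd, t_lo, t_hi),
      apex_intensity = stats::rlnorm(nd, log(noise$base_intensity / 2),
                                     noise$intensity_sdlog * 2)))
  }
  n_all <- nrow(comp)
  is_decoy <- is.na(comp$compound)

  # source spectra per component (library spectrum at requested CE, else
  # in-silico); resolved lazily and cached
  src_cache <- vector("list", n_all)
  source_spectrum <- function(i, ce) {
    key <- paste0(i, "|", ce)
    if (!is.null(src_cache[[i]][[key]])) return(src_cache[[i]][[key]])
    if (is_decoy[i]) {
      s <- NULL
    } else {
      rec <- lib$records[[comp$compound[i]]]
      s <- NULL
      for (cand in rec$spectra) {
        same_adduct <- is.na(cand$adduct) || cand$adduct == comp$adduct[i]
        if (same_adduct && identical(cand$collision_energy, as.character(ce))) {
          s <- cand; break
        }
      }
      if (is.null(s) && length(rec$spectra)) {
        match_ad <- Filter(function(x)
          is.na(x$adduct) || x$adduct == comp$adduct[i], rec$spectra)
        if (length(match_ad)) s <- match_ad[[1]]
      }
      if (is.null(s)) s <- theoretical_spectrum(rec, comp$adduct[i], ce)
    }
    src_cache[[i]][[key]] <<- list(s)
    list(s)
  }

  times <- seq(t_lo, t_hi, by = 1 / (settings$ms1_rate * 60))
  sel_count <- integer(n_all)
  epoch <- integer(n_all) + 1L
  excluded <- logical(n_all)
  below_streak <- integer(n_all)
  events <- vector("list", 2048L)
  spectra <- vector("list", 2048L)
  ne <- 0L

  for (ci in seq_along(times)) {
    t <- times[ci]
    intens <- comp$apex_intensity *
      exp(-(t - comp$apex_rt)^2 / (2 * noise$chrom_sigma^2))
    above <- intens >= settings$intensity_threshold
    eligible <- which(above & !excluded)
    if (length(eligible)) {
      sel <- eligible[order(intens[eligible],
                            decreasing = TRUE)][seq_len(
                              min(settings$top_n, length(eligible)))]
      for (i in sel) {
        sel_count[i] <- sel_count[i] + 1L
        ce <- if (settings$ce_mode == "fixed")
          as.character(settings$ce_values[
            ((sel_count[i] - 1L) %% length(settings$ce_values)) + 1L])
        else sprintf("ramp %g-%g", settings$ramp[1], settings$ramp[2])
        prec_obs <- comp$mz[i] + stats::rnorm(1, 0, noise$mz_sigma)
        src <- source_spectrum(i, ce)[[1]]
        if (is.null(src)) {
          fmz <- numeric(0); fint <- numeric(0)
        } else {
          fmz <- src$peaks$mz + stats::rnorm(nrow(src$peaks), 0,
                                             noise$mz_sigma)
          fint <- src$peaks$intensity * (intens[i] /
                                           noise$base_intensity)
        }
        n_dec <- stats::rpois(1, noise$decoy_fragment_rate)
        if (n_dec > 0) {
          fmz <- c(fmz, stats::runif(n_dec, settings$scan_range[1],
                                     max(settings$scan_range[1] + 1,
                                         min(prec_obs,
                                             settings$scan_range[2]))))
          fint <- c(fint, stats::runif(n_dec, 50, 500))
        }
        keep <- fmz >= settings$scan_range[1] & fmz <= settings$scan_range[2]
        fmz <- fmz[keep]; fint <- fint[keep]
        if (length(fmz)) {
          o <- order(fmz)
          fmz <- fmz[o]; fint <- fint[o]
          dup <- c(FALSE, diff(fmz) < 1e-6)
          fmz <- fmz[!dup]; fint <- fint[!dup]
        }
        ne <- ne + 1L
        if (ne > length(events)) {
          length(events) <- 2L * length(events)
          length(spectra) <- 2L * length(spectra)
        }
        events[[ne]] <- data.frame(
          event = ne, cycle = ci, time = t,
          compound = comp$compound[i], adduct = comp$adduct[i],
          component = i, decoy = is_decoy[i],
          precursor_mz = prec_obs, trigger_intensity = intens[i],
          collision_energy = ce, selection_index = sel_count[i],
          exclusion_epoch = epoch[i], stringsAsFactors = FALSE)
        spectra[[ne]] <- new_spectrum(fmz, fint, precursor_mz = prec_obs,
                                      adduct = comp$adduct[i],
                                      collision_energy = ce, mode =
                                        if (settings$ce_mode == "fixed")
                                          "targeted" else "auto",
                                      scan_range = settings$scan_range)
        if (sel_count[i] >= settings$active_exclusion_count)
          excluded[i] <- TRUE
      }
    }
    below_streak <- ifelse(above, 0L, below_streak + 1L)
    release <- excluded & below_streak >= 1L
    if (any(release)) {
      excluded[release] <- FALSE
      sel_count[release] <- 0L
      epoch[release] <- epoch[release] + 1L
    }
  }

  events_df <- if (ne) do.call(rbind, events[seq_len(ne)]) else
    data.frame(event = integer(0), cycle = integer(0), time = numeric(0),
               compound = character(0), adduct = character(0),
               component = integer(0), decoy = logical(0),
               precursor_mz = numeric(0), trigger_intensity = numeric(0),
               collision_energy = character(0),
               selection_index = integer(0), exclusion_epoch = integer(0))
  run <- structure(list(events = events_df,
                        spectra = if (ne) spectra[seq_len(ne)] else list(),
                        truth = comp[!is_decoy, , drop = FALSE],
                        settings = settings, noise = noise,
                        seed = as.integer(seed), n_cycles = length(times),
                        time_range = c(t_lo, t_hi)),
                   class = "simulated_run")
  audit_run(run)
  run
}

#' @export
print.simulated_run <- function(x, ...) {
  cat(sprintf(paste0("<simulated_run> seed %d: %d MS1 cycles over ",
                     "%.2f-%.2f min, %d MS2 event(s), %d true component(s)\n"),
              x$seed, x$n_cycles, x$time_range[1], x$time_range[2],
              nrow(x$events), nrow(x$truth)))
  invisible(x)
}

#' Audit a simulated run against the acquisition rules
#'
#' Verifies, from the event log alone, that every MS2 event was triggered
#' by an above-threshold MS1 intensity, that no precursor accumulated more
#' than `active_exclusion_count` selections within one exclusion epoch,
#' and that no emitted fragment lies outside the scan range. Called
#' automatically by [simulate_run()]; errors on violation.
#'
#' @param run A `simulated_run`.
#' @return `TRUE`, invisibly.
#' @export
audit_run <- function(run) {
  stopifnot(inherits(run, "simulated_run"))
  ev <- run$events
  s <- run$settings
  if (nrow(ev)) {
    if (any(ev$trigger_intensity < s$intensity_threshold))
      stop("audit: MS2 event triggered below the intensity threshold",
           call. = FALSE)
    per <- stats::aggregate(ev$event,
                            by = list(component = ev$component,
                                      epoch = ev$exclusion_epoch),
                            FUN = length)
    if (any(per$x > s$active_exclusion_count))
      stop("audit: active-exclusion count exceeded within an epoch",
           call. = FALSE)
  }
  for (sp in run$spectra) {
    if (nrow(sp$peaks) &&
        (min(sp$peaks$mz) < s$scan_range[1] - 1e-9 ||
         max(sp$peaks$mz) > s$scan_range[2] + 1e-9))
      stop("audit: fragment outside scan range", call. = FALSE)
  }
  invisible(TRUE)
}

#' Export a simulated run
#'
#' `"mgf"` writes one `BEGIN IONS` block per MS2 event with the ground
#' truth encoded in the TITLE (`event|compound|adduct|scan`), suitable for
#' re-import with [read_queries()]. `"feature-table"` aggregates the MS2
#' events of each component into one query feature row (apex RT from the
#' most intense triggering scan, median observed precursor m/z, fragments
#' from the consensus of the event spectra) and writes a delimited file
#' that [read_queries()] accepts directly; the `compound_truth` column
#' carries the label for benchmarking.
#'
#' Identical seed and settings give byte-identical exports.
#'
#' @param run A `simulated_run`.
#' @param path Output file path.
#' @param format `"mgf"` or `"feature-table"`.
#' @param source_label Value of the `source` column in the feature table.
#' @return `path`, invisibly.
#' @export
export_run <- function(run, path, format = c("mgf", "feature-table"),
                       source_label = sprintf("sim-seed%d", run$seed)) {
  stopifnot(inherits(run, "simulated_run"))
  format <- match.arg(format)
  ev <- run$events
  if (format == "mgf") {
    con <- file(path, "w")
    on.exit(close(con))
    for (k in seq_len(nrow(ev))) {
      sp <- run$spectra[[k]]
      writeLines(c("BEGIN IONS",
                   sprintf("TITLE=event%d|%s|%s|scan=%d", ev$event[k],
                           ifelse(is.na(ev$compound[k]), "decoy",
                                  ev$compound[k]),
                           ifelse(is.na(ev$adduct[k]), "unknown",
                                  ev$adduct[k]),
                           ev$cycle[k]),
                   sprintf("PEPMASS=%.6f %.2f", ev$precursor_mz[k],
                           ev$trigger_intensity[k]),
                   sprintf("RTINSECONDS=%.4f", ev$time[k] * 60),
                   "CHARGE=1+",
                   if (nrow(sp$peaks))
                     sprintf("%.6f %.2f", sp$peaks$mz, sp$peaks$intensity),
                   "END IONS", ""), con)
    }
    return(invisible(path))
  }
  rows <- lapply(unique(ev$component), function(i) {
    sub <- ev[ev$component == i, , drop = FALSE]
    best <- which.max(sub$trigger_intensity)
    pk <- do.call(rbind, lapply(run$spectra[sub$event], `[[`, "peaks"))
    frag <- ""
    if (!is.null(pk) && nrow(pk)) {
      repeat {
        m2 <- merge_peaks_pass(pk$mz, pk$intensity, 0.005)
        if (nrow(m2) == nrow(pk)) break
        pk <- m2
      }
      pk <- pk[order(-pk$intensity), , drop = FALSE][
        seq_len(min(20L, nrow(pk))), , drop = FALSE]
      pk <- pk[order(pk$mz), , drop = FALSE]
      frag <- paste(sprintf("%.4f", pk$mz), collapse = ";")
    }
    data.frame(source = source_label,
               rt = round(sub$time[best], 4),
               precursor_mz = round(stats::median(sub$precursor_mz), 6),
               adduct = ifelse(is.na(sub$adduct[1]), "", sub$adduct[1]),
               fragments = frag,
               compound_truth = ifelse(is.na(sub$compound[1]), "decoy",
                                       sub$compound[1]),
               stringsAsFactors = FALSE)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(source = character(0), rt = numeric(0),
               precursor_mz = numeric(0), adduct = character(0),
               fragments = character(0), compound_truth = character(0))
  tab <- tab[order(tab$rt, tab$precursor_mz), , drop = FALSE]
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
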