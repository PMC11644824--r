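#' Matching parameters
#'
#' Thresholds for library screening. Defaults follow the reference
#' workflow: a 0.005 Da exact-mass tolerance window (applied to both the
#' precursor and, as the conservative reading, the fragments), a 0.5 min
#' retention-time window (covering the largest drift observed on the
#' reference system, 0.41 min, with margin), and a minimum of one matched
#' fragment for the highest identification level.
#'
#' @param precursor_tol Precursor mass tolerance, Da (> 0).
#' @param rt_window Retention-time window, minutes (> 0).
#' @param fragment_tol Fragment mass tolerance, Da (> 0).
#' @param min_fragments Minimum matched fragments for level 1/2 (>= 1).
#' @return Object of class `match_parameters`.
#' @export
match_parameters <- function(precursor_tol = 0.005, rt_window = 0.5,
                             fragment_tol = 0.005, min_fragments = 1L) {
  stopifnot(precursor_tol > 0, rt_window > 0, fragment_tol > 0,
            min_fragments >= 1)
  structure(list(precursor_tol = precursor_tol, rt_window = rt_window,
                 fragment_tol = fragment_tol,
                 min_fragments = as.integer(min_fragments)),
            class = "match_parameters")
}

#' Read query features
#'
#' Query feature lists come either as delimited text (columns `source`,
#' `rt`, `precursor_mz`, `adduct`, `fragments` as a semicolon-separated
#' list, plus optional extras) or as MGF, in which case each block becomes
#' one feature (precursor from `PEPMASS`, RT from `RTINSECONDS`, fragments
#' from the peak list).
#'
#' @param path File path; format chosen by extension (`.mgf` vs delimited).
#' @return `data.frame` with columns `source`, `rt`, `precursor_mz`,
#'   `adduct`, `fragments` (semicolon string; parse with
#'   [parse_fragments()]).
#' @export
read_queries <- function(path) {
  if (grepl("\\.mgf$", path, ignore.case = TRUE)) {
    sp <- read_mgf_spectra(path)
    adduct <- vapply(sp, `[[`, character(1), "adduct")
    # TITLE dialects vary; only keep fields that look like an adduct label
    adduct[!is.na(adduct) & !grepl("^\\[", adduct)] <- NA_character_
    return(data.frame(
      source = vapply(sp, function(s) attr(s, "compound"), character(1)),
      rt = vapply(sp, function(s) attr(s, "rt") %||% NA_real_, numeric(1)),
      precursor_mz = vapply(sp, `[[`, numeric(1), "precursor_mz"),
      adduct = adduct,
      fragments = vapply(sp, function(s)
        paste(sprintf("%.4f", s$peaks$mz), collapse = ";"), character(1)),
      stringsAsFactors = FALSE))
  }
  tab <- read_delim_auto(path)
  required <- c("source", "rt", "precursor_mz", "adduct", "fragments")
  miss <- setdiff(required, names(tab))
  if (length(miss))
    stop("query table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  tab
}

#' Parse a semicolon-separated fragment list
#' @param x Character scalar like `"425.3459;288.9212"` (or `NA`/empty).
#' @return Numeric vector of fragment m/z values.
#' @export
parse_fragments <- function(x) {
  if (is.null(x) || is.na(x) || !nzchar(trimws(x))) return(numeric(0))
  as.numeric(strsplit(trimws(x), "[;, ]+")[[1]])
}

#' Precursor candidates by sorted-range query
#'
#' All (record, adduct) entries of the library whose calculated m/z lies
#' within `tol` of the query precursor, found by binary range search on the
#' sorted [adduct_index()]; equivalent to (and tested against) a
#' brute-force scan.
#'
#' @param precursor_mz Query precursor m/z (Da).
#' @param lib A `spectral_library`.
#' @param tol Mass tolerance in Da (default 0.005).
#' @param adduct Optional adduct hypothesis restricting the candidates.
#' @return `data.frame` with columns `name`, `adduct`, `calc_mz`, `delta`
#'   (query minus calculated), possibly empty.
#' @export
match_precursor <- function(precursor_mz, lib, tol = 0.005, adduct = NULL) {
  idx <- adduct_index(lib)
  lo <- findInterval(precursor_mz - tol, idx$calc_mz) + 1L
  hi <- findInterval(precursor_mz + tol, idx$calc_mz)
  out <- if (hi >= lo) idx[lo:hi, , drop = FALSE] else idx[0, , drop = FALSE]
  out <- out[abs(out$calc_mz - precursor_mz) <= tol, , drop = FALSE]
  if (!is.null(adduct) && !is.na(adduct) && nzchar(adduct))
    out <- out[out$adduct == adduct, , drop = FALSE]
  out$delta <- precursor_mz - out$calc_mz
  rownames(out) <- NULL
  out[, c("name", "adduct", "calc_mz", "delta")]
}

record_consensus <- function(record, mz_tol) {
  if (!length(record$spectra)) return(NULL)
  prec <- vapply(record$spectra, `[[`, numeric(1), "precursor_mz")
  # spectra of different adducts cannot share a precursor: merge per group,
  # then pool the peak lists
  grp <- cumsum(c(1, as.integer(abs(diff(sort(prec))) > mz_tol)))
  ord <- order(prec)
  merged <- lapply(split(ord, grp), function(ii)
    consensus_spectrum(record$spectra[ii], mz_tol))
  pk <- do.call(rbind, lapply(merged, `[[`, "peaks"))
  repeat {
    m2 <- merge_peaks_pass(pk$mz, pk$intensity, mz_tol)
    if (nrow(m2) == nrow(pk)) break
    pk <- m2
  }
  pk
}

#' Match one query feature against the library
#'
#' Generates precursor candidates within the mass-tolerance window, then
#' scores each against retention time and the record's consensus fragment
#' peaks, assigning a metabolomics identification level: level 1 (highest,
#' authentic-standard match) requires precursor, RT inside the window, and
#' at least `min_fragments` matched fragments; level 2 requires precursor
#' and fragments with RT absent or outside the window; level 3 is a
#' precursor-only match. Results are ranked by level, then descending
#' score (fraction of consensus peaks explained by the query fragments),
#' then absolute mass error, with record name as the deterministic
#' tie-break.
#'
#' @param query A one-row `data.frame` (as from [read_queries()]) or list
#'   with `source`, `rt`, `precursor_mz`, `adduct` (optional hypothesis),
#'   `fragments` (semicolon string or numeric vector).
#' @param lib A `spectral_library`.
#' @param params A [match_parameters()] object.
#' @return `data.frame` of ranked match results: `source`, `compound`,
#'   `adduct`, `calc_mz`, `mass_error_ppm`, `rt_drift` (signed, query minus
#'   library), `n_matched`, `n_query_fragments`, `score`, `level`.
#' @export
match_feature <- function(query, lib, params = match_parameters()) {
  q <- as.list(query)
  frags <- if (is.numeric(q$fragments)) q$fragments
           else parse_fragments(q$fragments)
  cand <- match_precursor(q$precursor_mz, lib, params$precursor_tol,
                          adduct = q$adduct)
  res <- lapply(seq_len(nrow(cand)), function(i) {
    rec <- lib$records[[cand$name[i]]]
    rt_drift <- if (!is.null(q$rt) && !is.na(q$rt) && !is.na(rec$rt))
      q$rt - rec$rt else NA_real_
    cons <- record_consensus(rec, params$fragment_tol)
    if (is.null(cons) || !nrow(cons)) {
      n_matched <- 0L; score <- 0
    } else {
      dmat <- outer(frags, cons$mz, function(a, b) abs(a - b))
      n_matched <- if (length(frags))
        sum(apply(dmat, 1, min) <= params$fragment_tol) else 0L
      n_cons_hit <- if (length(frags))
        sum(apply(dmat, 2, min) <= params$fragment_tol) else 0L
      score <- n_cons_hit / nrow(cons)
    }
    rt_ok <- !is.na(rt_drift) && abs(rt_drift) <= params$rt_window
    frag_ok <- n_matched >= params$min_fragments
    level <- if (rt_ok && frag_ok) 1L else if (frag_ok) 2L else 3L
    data.frame(source = q$source %||% NA_character_,
               compound = cand$name[i], adduct = cand$adduct[i],
               calc_mz = cand$calc_mz[i],
               mass_error_ppm = ppm_error(cand$calc_mz[i], q$precursor_mz),
               rt_drift = rt_drift, n_matched = n_matched,
               n_query_fragments = length(frags),
               score = score, level = level)
  })
  res <- if (length(res)) do.call(rbind, res) else
    data.frame(source = character(0), compound = character(0),
               adduct = character(0), calc_mz = numeric(0),
               mass_error_ppm = numeric(0), rt_drift = numeric(0),
               n_matched = integer(0), n_query_fragments = integer(0),
               score = numeric(0), level = integer(0))
  res[order(res$level, -res$score, abs(res$mass_error_ppm), res$compound), ,
      drop = FALSE]
}

#' Screen a feature list against the library
#'
#' Runs [match_feature()] on every query feature, keeps the best assignment
#' per feature, and summarises the run: unique identified compounds (adduct
#' variants of one compound collapse to a single identity because they map
#' to the same library record) and the maximum absolute retention-time
#' drift among level-1 identifications.
#'
#' @param queries `data.frame` of query features (see [read_queries()]).
#' @param lib A `spectral_library`.
#' @param params A [match_parameters()] object.
#' @return Object of class `screening_report`: list with `assignments`
#'   (one row per feature with a candidate; columns as [match_feature()]
#'   plus `rt_drift_abs` rounded to 2 decimals) and `summary` (list with
#'   `n_features`, `n_level1`, `compounds`, `n_compounds`, `max_rt_drift`).
#' @export
screen_run <- function(queries, lib, params = match_parameters()) {
  queries <- as.data.frame(queries)
  rows <- lapply(seq_len(nrow(queries)), function(i) {
    hits <- match_feature(queries[i, , drop = FALSE], lib, params)
    if (!nrow(hits)) return(NULL)
    hits[1, , drop = FALSE]
  })
  assignments <- do.call(rbind, rows)
  if (is.null(assignments))
    assignments <- match_feature(list(precursor_mz = -1), lib, params)[0, ]
  assignments$rt_drift_abs <- round_half_away(abs(assignments$rt_drift), 2)
  rownames(assignments) <- NULL
  lvl1 <- assignments[assignments$level == 1L, , drop = FALSE]
  summary <- list(
    n_features = nrow(queries),
    n_assigned = nrow(assignments),
    n_level1 = nrow(lvl1),
    compounds = sort(unique(lvl1$compound)),
    n_compounds = length(unique(lvl1$compound)),
    max_rt_drift = if (nrow(lvl1)) max(lvl1$rt_drift_abs, na.rm = TRUE)
                   else NA_real_)
  structure(list(assignments = assignments, summary = summary,
                 params = params), class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<screening_report> %d feature(s), %d assigned, ",
                     "%d at level 1\n"),
              s$n_features, s$n_assigned, s$n_level1))
  cat(sprintf("  unique compounds identified (level 1): %d\n", s$n_compounds))
  if (s$n_compounds)
    cat("   ", paste(s$compounds, collapse = "; "), "\n")
  if (!is.na(s$max_rt_drift))
    cat(sprintf("  max |RT drift|: %.2f min\n", s$max_rt_drift))
  invisible(x)
}

#' Write a screening report to disk
#'
#' Writes the per-feature assignments as TSV and the run summary as JSON.
#'
#' @param report A `screening_report`.
#' @param tsv_path,json_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the report.
#' @export
write_report <- function(report, tsv_path = NULL, json_path = NULL) {
  stopifnot(inherits(report, "screening_report"))
  if (!is.null(tsv_path))
    utils::write.table(report$assignments, tsv_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(report$summary, json_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  invisible(report)
}
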