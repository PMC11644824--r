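#' Neutral-loss definitions
#'
#' The neutral losses characteristic of triterpenoid fragmentation (water,
#' carbon monoxide, formic acid, and the C5H8O2 loss seen for
#' dimethylacroyloxy-bearing skeletons). Loss masses are computed from the
#' formulas in the packaged config table, never hard-coded, so the element
#' mass table is the single source of truth.
#'
#' @param labels Optional subset of loss labels to return.
#' @return `data.frame` with columns `label`, `formula`, `mass` (Da).
#' @export
#' @examples
#' neutral_loss_table(c("H2O", "CO"))
neutral_loss_table <- function(labels = NULL) {
  if (is.null(.ttl_cache$losses)) {
    tab <- utils::read.delim(ttl_extdata("neutral_losses.tsv"),
                             comment.char = "#", stringsAsFactors = FALSE)
    tab$mass <- vapply(tab$formula, monoisotopic_mass, numeric(1))
    .ttl_cache$losses <- tab
  }
  tab <- .ttl_cache$losses
  if (is.null(labels)) return(tab)
  i <- match(labels, tab$label)
  if (anyNA(i))
    stop("unknown neutral loss label(s): ",
         paste(labels[is.na(i)], collapse = ", "), call. = FALSE)
  tab[i, , drop = FALSE]
}

# all multisets of 1..max_depth indices from 1..k (non-decreasing sequences)
enumerate_multisets <- function(k, max_depth) {
  out <- list()
  for (d in seq_len(max_depth)) {
    grids <- do.call(expand.grid, rep(list(seq_len(k)), d))
    keep <- if (d == 1) rep(TRUE, nrow(grids)) else
      apply(grids, 1, function(r) all(diff(r) >= 0))
    sel <- grids[keep, , drop = FALSE]
    out <- c(out, lapply(seq_len(nrow(sel)), function(i)
      as.integer(sel[i, ])))
  }
  out
}

#' Enumerate neutral-loss series from a precursor
#'
#' All combinations (multisets) of up to `max_depth` neutral losses,
#' deduplicated by total loss mass, each paired with its theoretical
#' fragment m/z (`precursor_mz` minus the summed loss mass). Labels list
#' the losses in ascending mass order, e.g. `"[M+H-H2O-CO]+"`. Fragments
#' falling below the scan floor are excluded (not an error). When total
#' masses tie, the explanation with fewer losses is kept.
#'
#' @param precursor_mz Precursor m/z in Da.
#' @param losses A `data.frame` as from [neutral_loss_table()] or a
#'   character vector of loss labels.
#' @param max_depth Maximum number of simultaneous losses (>= 1).
#' @param precursor_label Label stem for annotation strings (default
#'   `"M+H"`; use `"M+Na"` for sodium adducts).
#' @param scan_floor Lower m/z bound of the scan range (default 50).
#' @return `data.frame` with columns `label`, `n_losses`, `loss_mass`, `mz`,
#'   sorted by `n_losses` then `loss_mass`.
#' @export
#' @examples
#' loss_series(471.3469, c("H2O", "CO"), max_depth = 2)
loss_series <- function(precursor_mz, losses = neutral_loss_table(),
                        max_depth = 2L, precursor_label = "M+H",
                        scan_floor = 50) {
  if (is.character(losses)) losses <- neutral_loss_table(losses)
  stopifnot(is.data.frame(losses), nrow(losses) >= 1, max_depth >= 1)
  combos <- enumerate_multisets(nrow(losses), max_depth)
  # order loss masses ascending within each combination for the label
  rows <- lapply(combos, function(idx) {
    idx <- idx[order(losses$mass[idx])]
    data.frame(label = paste0("[", precursor_label,
                              paste0("-", losses$label[idx], collapse = ""),
                              "]+"),
               n_losses = length(idx),
               loss_mass = sum(losses$mass[idx]))
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$n_losses, res$loss_mass), , drop = FALSE]
  res <- res[!duplicated(round(res$loss_mass, 6)), , drop = FALSE]
  res$mz <- precursor_mz - res$loss_mass
  res <- res[res$mz >= scan_floor, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Class-diagnostic fragment ions
#'
#' Retro-Diels-Alder (RDA) and related diagnostic product ions per
#' pentacyclic skeleton class. Oleanane skeletons give the directly formed
#' RDA ion at m/z 249.1856 plus 203.1807 and 191.1803; ursanes give the
#' nominal 205 (often the base peak) and 203; lupanes show nominal 191 and
#' 203 but, lacking the ring-C unsaturation, via non-RDA pathways (flagged
#' `rda = FALSE`). Friedelane, limonoid and unclassified skeletons have no
#' catalogued diagnostics: an empty table is returned with attribute
#' `documented_gap = TRUE`. Values known only at nominal (integer)
#' precision are flagged `nominal` and matched at unit-mass tolerance by
#' [annotate_spectrum()].
#'
#' @param class A skeleton class from [skeleton_classes()].
#' @return `data.frame` with columns `mz`, `nominal`, `rda`, `label`.
#' @export
#' @examples
#' diagnostic_ions("ursane")
diagnostic_ions <- function(class) {
  if (!is.character(class) || length(class) != 1L ||
      !class %in% skeleton_classes())
    stop("unknown skeleton class: ", class, call. = FALSE)
  tab <- switch(class,
    oleanane = data.frame(mz = c(249.1856, 203.1807, 191.1803),
                          nominal = FALSE, rda = TRUE),
    ursane = data.frame(mz = c(205, 203), nominal = TRUE, rda = TRUE),
    lupane = data.frame(mz = c(191, 203), nominal = TRUE, rda = FALSE),
    data.frame(mz = numeric(0), nominal = logical(0), rda = logical(0)))
  if (!nrow(tab)) attr(tab, "documented_gap") <- TRUE
  if (nrow(tab))
    tab$label <- sprintf("%s m/z %s", ifelse(tab$rda, "RDA", "non-RDA"),
                         format(tab$mz, trim = TRUE))
  else tab$label <- character(0)
  tab
}

#' Annotate an MS2 spectrum with loss and diagnostic ions
#'
#' Each peak is matched greedily to the nearest theoretical ion within
#' tolerance, drawn from the neutral-loss series of the precursor plus the
#' skeleton-class diagnostic ions. Loss ions and exact-mass diagnostics are
#' matched within `tol`; diagnostics known only at nominal precision within
#' 0.5 Da (the precision at which they are catalogued). Ties are broken
#' toward the explanation with fewer losses. Every peak receives at most
#' one annotation; unexplained peaks are returned unlabeled.
#'
#' The default tolerance (0.01 Da) is deliberately wider than the 0.005 Da
#' identification tolerance: reported fragment values of measured spectra
#' deviate from exact subtraction by up to about 0.01 Da.
#'
#' @param s An `ms2_spectrum`. Its `precursor_mz` and `adduct` supply the
#'   loss-series stem.
#' @param record Optional `library_record` supplying the skeleton class
#'   (and precursor/adduct fallback).
#' @param tol Annotation tolerance in Da for exact-mass ions.
#' @param skeleton_class Override for the skeleton class.
#' @param losses Neutral-loss table (see [neutral_loss_table()]).
#' @param max_depth Maximum simultaneous losses (default 2).
#' @return `data.frame` with one row per peak: `mz`, `intensity`, `label`
#'   (`NA` when unannotated), `theoretical_mz`, `delta` (observed minus
#'   theoretical).
#' @export
annotate_spectrum <- function(s, record = NULL, tol = 0.01,
                              skeleton_class = NULL,
                              losses = neutral_loss_table(),
                              max_depth = 2L) {
  stopifnot(inherits(s, "ms2_spectrum"), tol > 0)
  if (is.null(skeleton_class))
    skeleton_class <- if (!is.null(record)) record$skeleton_class else "other"
  stem <- if (!is.na(s$adduct) && grepl("^\\[(M[^]]*)\\]", s$adduct))
    sub("^\\[(M[^]]*)\\].*$", "\\1", s$adduct) else "M+H"
  theo_loss <- loss_series(s$precursor_mz, losses, max_depth,
                           precursor_label = stem)
  diag <- diagnostic_ions(skeleton_class)
  theo <- rbind(
    data.frame(label = theo_loss$label, mz = theo_loss$mz,
               n_losses = theo_loss$n_losses,
               tol = tol),
    if (nrow(diag)) data.frame(label = diag$label, mz = diag$mz,
                               n_losses = 0L,
                               tol = ifelse(diag$nominal, 0.5, tol)))
  np <- nrow(s$peaks)
  out <- data.frame(mz = s$peaks$mz, intensity = s$peaks$intensity,
                    label = rep(NA_character_, np),
                    theoretical_mz = rep(NA_real_, np),
                    delta = rep(NA_real_, np))
  for (i in seq_len(nrow(out))) {
    d <- abs(theo$mz - out$mz[i])
    ok <- which(d <= theo$tol)
    if (!length(ok)) next
    best <- ok[order(d[ok], theo$n_losses[ok])][1]
    out$label[i] <- theo$label[best]
    out$theoretical_mz[i] <- theo$mz[best]
    out$delta[i] <- out$mz[i] - theo$mz[best]
  }
  stopifnot(all(is.na(out$delta) |
                  abs(out$delta) <= pmax(tol, 0.5) + 1e-12))
  out
}
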