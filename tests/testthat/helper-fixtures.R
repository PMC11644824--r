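# Shared builders and independent brute-force oracles for the test suite.

fixture_library <- local({
  lib <- NULL
  function() {
    if (is.null(lib)) lib <<- triterpenoid_library(quiet = TRUE)
    lib
  }
})

# random molecular formula over the supported elements
rand_formula <- function() {
  els <- c("C", "H", "N", "O", "S", "Na")
  k <- sample(2:4, 1)
  sym <- c("C", "H", sample(setdiff(els, c("C", "H")), k - 2))
  counts <- stats::setNames(sample(1:60, length(sym), replace = TRUE), sym)
  counts
}

# random small spectrum for a given precursor
rand_spectrum <- function(precursor, n = sample(0:8, 1), ce = "20") {
  hi <- min(1195, max(61, precursor))
  mz <- sort(stats::runif(n, 60, hi))
  while (n > 1 && any(diff(mz) < 1e-5))
    mz <- sort(stats::runif(n, 60, hi))
  new_spectrum(mz, stats::runif(n, 100, 1e5), precursor_mz = precursor,
               adduct = "[M+H]+", collision_energy = ce)
}

# random library of k records with 0-2 spectra each
rand_library <- function(k = sample(1:3, 1)) {
  nms <- paste0("cmpd", seq_len(k), "_", sample(1e6, k))
  recs <- lapply(seq_len(k), function(i) {
    f <- rand_formula()
    mzH <- adduct_mz(f, "[M+H]+")
    ad <- data.frame(adduct = c("[M+H]+", "[M+Na]+"),
                     calc_mz = c(mzH, adduct_mz(f, "[M+Na]+")),
                     meas_mz = c(mzH + stats::rnorm(1, 0, 1e-3), NA),
                     observed = c(TRUE, FALSE))
    library_record(nms[i], f, logp = stats::runif(1, 0, 12),
                   rt = stats::runif(1, 1, 13),
                   skeleton_class = sample(skeleton_classes(), 1),
                   adducts = ad,
                   spectra = lapply(seq_len(sample(0:2, 1)), function(j)
                     rand_spectrum(mzH, ce = as.character(10 * j))))
  })
  spectral_library(recs, provenance = "random test library")
}

# brute-force single-linkage cluster count via union-find over all pairs
oracle_cluster_count <- function(mz, tol) {
  n <- length(mz)
  if (!n) return(0L)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (abs(mz[i] - mz[j]) <= tol) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

# brute-force multiset loss enumeration: unique total masses (rounded to
# 1e-6) over all combinations of 1..depth losses, above the scan floor
oracle_loss_count <- function(masses, depth, precursor, floor = 50) {
  totals <- c()
  recurse <- function(start, left, acc) {
    for (i in start:length(masses)) {
      tot <- acc + masses[i]
      totals <<- c(totals, tot)
      if (left > 1) recurse(i, left - 1, tot)
    }
  }
  recurse(1, depth, 0)
  totals <- unique(round(totals, 6))
  sum(precursor - totals >= floor)
}

# brute-force precursor candidate scan
oracle_candidates <- function(precursor_mz, lib, tol) {
  idx <- adduct_index(lib)
  idx <- idx[abs(idx$calc_mz - precursor_mz) <= tol, , drop = FALSE]
  sort(paste(idx$name, idx$adduct))
}
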