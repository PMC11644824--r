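#' @keywords internal
".ttl_cache" <- new.env(parent = emptyenv())

ttl_extdata <- function(file) {
  system.file("extdata", file, package = "triterpenlib", mustWork = TRUE)
}

#' Monoisotopic element mass table
#'
#' Returns the packaged table of monoisotopic element masses (CODATA/NIST
#' values) as a named numeric vector in Da. Carbon is exactly 12 by
#' definition. The table is loaded once per session from a plain-text file
#' shipped with the package and is immutable thereafter.
#'
#' @return Named numeric vector of monoisotopic masses (Da), one entry per
#'   element symbol (C, H, N, O, S, Na, P).
#' @seealso [proton_mass()], [electron_mass()], [monoisotopic_mass()]
#' @export
#' @examples
#' element_masses()[["C"]] # exactly 12
element_masses <- function() {
  if (is.null(.ttl_cache$masses)) {
    tab <- utils::read.delim(ttl_extdata("element_masses.tsv"),
                             comment.char = "#", stringsAsFactors = FALSE)
    m <- stats::setNames(tab$monoisotopic_mass, tab$symbol)
    .ttl_cache$particles <- m[c("proton", "electron")]
    .ttl_cache$masses <- m[setdiff(names(m), c("proton", "electron"))]
  }
  .ttl_cache$masses
}

#' Proton and electron masses
#'
#' Mass of the proton / electron in Da, as used in adduct arithmetic:
#' the `[M+H]+` delta is one proton, the `[M+Na]+` delta is sodium minus
#' one electron.
#'
#' @return A single numeric value (Da).
#' @export
proton_mass <- function() {
  element_masses() # ensure loaded
  unname(.ttl_cache$particles[["proton"]])
}

#' @rdname proton_mass
#' @export
electron_mass <- function() {
  element_masses()
  unname(.ttl_cache$particles[["electron"]])
}

#' Parse a molecular formula string
#'
#' Accepts both the plain style (`"C30H46O4"`) and the underscore-subscript
#' style that typeset compound tables often carry (`"C_30_H_46_O_4_"`,
#' `"C_30_H_50_O"`, `"S_1_"`). An element without a count has an implicit
#' count of one; repeated element symbols are summed. Unknown element
#' symbols and malformed tokens are rejected with the offending position.
#'
#' @param text Single formula string.
#' @return Named integer vector of element counts in Hill order (C, H, then
#'   other elements alphabetically).
#' @export
#' @examples
#' parse_formula("C_30_H_46_O_4_") # C 30, H 46, O 4
#' parse_formula("C")              # implicit count of one
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("formula must be a single character string", call. = FALSE)
  if (!nzchar(text))
    stop("empty formula string", call. = FALSE)
  known <- names(element_masses())
  counts <- integer(0)
  pos <- 1L
  n <- nchar(text)
  while (pos <= n) {
    rest <- substr(text, pos, n)
    m <- regmatches(rest, regexec("^([A-Z][a-z]?)_?([0-9]*)_?", rest))[[1]]
    if (length(m) == 0L || !nzchar(m[1]))
      stop(sprintf("malformed formula '%s': unexpected character at position %d",
                   text, pos), call. = FALSE)
    sym <- m[2]
    # two-letter greedy match may swallow the first letter of the next token
    # only if the two-letter symbol is unknown but the one-letter one is known
    if (!sym %in% known && nchar(sym) == 2L && substr(sym, 1, 1) %in% known)
      sym <- substr(sym, 1, 1)
    if (!sym %in% known)
      stop(sprintf("unknown element '%s' in formula '%s' at position %d",
                   m[2], text, pos), call. = FALSE)
    cnt_str <- if (sym == m[2]) m[3] else ""
    cnt <- if (nzchar(cnt_str)) as.integer(cnt_str) else 1L
    if (cnt < 1L)
      stop(sprintf("element count must be >= 1 ('%s' at position %d in '%s')",
                   sym, pos, text), call. = FALSE)
    counts[sym] <- if (sym %in% names(counts)) counts[[sym]] + cnt else cnt
    consumed <- if (sym == m[2]) nchar(m[1]) else nchar(sym)
    pos <- pos + consumed
  }
  hill_order(counts)
}

# Hill convention: carbon, hydrogen, then remaining elements alphabetically.
hill_order <- function(counts) {
  syms <- names(counts)
  first <- intersect(c("C", "H"), syms)
  rest <- sort(setdiff(syms, first))
  counts[c(first, rest)]
}

#' Serialize element counts to a formula string
#'
#' Inverse of [parse_formula()]: writes the plain Hill-order style with
#' implicit 1 counts omitted, so parse-then-serialize is idempotent.
#'
#' @param counts Named integer vector of element counts.
#' @return Single formula string, e.g. `"C30H46O4"`.
#' @export
format_formula <- function(counts) {
  counts <- hill_order(counts)
  paste0(vapply(names(counts), function(s) {
    if (counts[[s]] == 1L) s else paste0(s, counts[[s]])
  }, character(1)), collapse = "")
}

#' Neutral monoisotopic mass of a formula
#'
#' Sum over elements of count times monoisotopic element mass. The empty
#' formula has mass zero.
#'
#' @param f A formula string (parsed with [parse_formula()]) or a named
#'   numeric vector of element counts.
#' @return Monoisotopic mass in Da.
#' @export
#' @examples
#' monoisotopic_mass("C30H46O4") # 470.3396...
monoisotopic_mass <- function(f) {
  if (is.character(f)) f <- parse_formula(f)
  if (length(f) == 0L) return(0)
  if (is.null(names(f)) || any(!nzchar(names(f))))
    stop("element counts must be a named vector", call. = FALSE)
  m <- element_masses()
  unknown <- setdiff(names(f), names(m))
  if (length(unknown))
    stop("unknown element(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  if (any(f < 0)) stop("element counts must be non-negative", call. = FALSE)
  sum(f * m[names(f)])
}

#' Positive-mode adduct definitions
#'
#' The adduct table shipped with the package: adduct name, mass delta added
#' to the neutral monoisotopic mass, and charge. `[M+H]+` adds one proton;
#' `[M+Na]+` adds sodium minus one electron, so the two deltas differ by
#' 21.981944 Da.
#'
#' @return `data.frame` with columns `name`, `delta_mass` (Da), `charge`.
#' @export
adduct_table <- function() {
  if (is.null(.ttl_cache$adducts)) {
    .ttl_cache$adducts <- utils::read.delim(ttl_extdata("adducts.tsv"),
                                            comment.char = "#",
                                            stringsAsFactors = FALSE)
  }
  .ttl_cache$adducts
}

resolve_adduct <- function(adduct) {
  if (is.list(adduct)) {
    stopifnot(all(c("name", "delta_mass", "charge") %in% names(adduct)))
    return(adduct)
  }
  tab <- adduct_table()
  i <- match(adduct, tab$name)
  if (is.na(i))
    stop(sprintf("unknown adduct '%s' (known: %s)", adduct,
                 paste(tab$name, collapse = ", ")), call. = FALSE)
  as.list(tab[i, ])
}

#' Adduct m/z of a neutral formula
#'
#' Calculated m/z of a singly charged adduct: neutral monoisotopic mass plus
#' the adduct mass delta. Only charge +1 adducts are supported (the library
#' is positive-mode, singly charged). Full precision is returned; use
#' [round_half_away()] with 4 digits for display at table precision.
#'
#' @param f Formula string or named count vector.
#' @param adduct Adduct name (`"[M+H]+"`, `"[M+Na]+"`) or a list with
#'   `name`, `delta_mass`, `charge`.
#' @return m/z in Da (full precision).
#' @export
#' @examples
#' round_half_away(adduct_mz("C30H46O4", "[M+H]+"), 4) # 471.3469
adduct_mz <- function(f, adduct = "[M+H]+") {
  a <- resolve_adduct(adduct)
  if (a$charge != 1L)
    stop("only singly charged (+1) adducts are supported", call. = FALSE)
  monoisotopic_mass(f) + a$delta_mass
}

#' ppm mass error
#'
#' Relative error in parts per million with the convention
#' `(calc - meas) / calc * 1e6`, so a measured value larger than the
#' calculated one gives a negative error.
#'
#' @param calc Calculated (theoretical) m/z, must be > 0.
#' @param meas Measured m/z.
#' @return Error in ppm (full precision; tables print 1 decimal).
#' @export
#' @examples
#' ppm_error(457.3676, 457.3664) # about 2.6 ppm
ppm_error <- function(calc, meas) {
  if (!is.numeric(calc) || !is.numeric(meas))
    stop("calc and meas must be numeric", call. = FALSE)
  if (any(calc <= 0))
    stop("calculated m/z must be > 0", call. = FALSE)
  (calc - meas) / calc * 1e6
}

#' Round half away from zero
#'
#' Display rounding used for table values (4 decimals for m/z, 1 decimal for
#' ppm): ties round away from zero rather than to even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits.
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}
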