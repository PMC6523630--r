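# Elemental-formula arithmetic and mass bookkeeping.
#
# An elemental formula is a named integer vector (element symbol -> count)
# with class "elemental_formula". Absent elements are count 0; equality is
# element-wise. All counts must be non-negative.

# package-local cache for the element mass table
.lr_env <- new.env(parent = emptyenv())

# CODATA electron rest mass in Da; used for charge correction of ion m/z
ELECTRON_MASS <- 0.00054857990907

#' Element monoisotopic mass table
#'
#' Returns the packaged table of monoisotopic atomic masses (Da), read once
#' per session from the versioned plain-text resource shipped with the
#' package.
#'
#' @return A named numeric vector mapping element symbol to monoisotopic mass.
#' @export
element_masses <- function() {
  if (is.null(.lr_env$masses)) {
    path <- system.file("extdata", "element_masses.tsv", package = "lipidrules")
    if (path == "") {
      # not installed (e.g. pkgload during development): resolve relative
      path <- file.path("inst", "extdata", "element_masses.tsv")
    }
    tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
    .lr_env$masses <- stats::setNames(tab$mass, tab$symbol)
  }
  .lr_env$masses
}

new_formula <- function(counts = numeric(0)) {
  counts <- counts[counts != 0]
  if (length(counts)) counts <- counts[order(names(counts))]
  structure(as.numeric(counts), names = names(counts),
            class = "elemental_formula")
}

#' Parse a Hill-style molecular formula
#'
#' Parses strings such as `"C5H14NO4P"` into an elemental formula. An element
#' token without a following digit has count 1. The empty string yields the
#' empty formula (all counts zero).
#'
#' @param text A formula string in element-count notation.
#' @return An `elemental_formula`: a named numeric vector of element counts.
#' @examples
#' parse_formula("C5H14NO4P")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- gsub("[[:space:]]", "", text)
  if (text == "") return(new_formula())
  tokens <- gregexpr("([A-Z][a-z]?)([0-9]*)", text)[[1]]
  matched <- regmatches(text, gregexpr("([A-Z][a-z]?)([0-9]*)", text))[[1]]
  if (sum(attr(tokens, "match.length")) != nchar(text)) {
    stop_parse("malformed formula string: ", sQuote(text))
  }
  known <- names(element_masses())
  counts <- numeric(0)
  for (tok in matched) {
    sym <- gsub("[0-9]+$", "", tok)
    num <- sub("^[A-Za-z]+", "", tok)
    if (!sym %in% known) {
      stop_parse("unknown element symbol ", sQuote(sym), " in ", sQuote(text))
    }
    n <- if (num == "") 1 else as.numeric(num)
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0) + n
  }
  new_formula(counts)
}

as_formula <- function(x) {
  if (inherits(x, "elemental_formula")) x else parse_formula(x)
}

#' Combine two elemental formulas
#'
#' Element-wise `a + sign * b`. A negative resulting count signals an
#' impossible neutral loss and is an error.
#'
#' @param a,b Elemental formulas (or formula strings).
#' @param sign `+1` to add, `-1` to subtract `b`.
#' @return An `elemental_formula`.
#' @export
combine_formulas <- function(a, b, sign = 1) {
  stopifnot(sign %in% c(1, -1))
  a <- as_formula(a); b <- as_formula(b)
  syms <- union(names(a), names(b))
  get0n <- function(f, s) if (s %in% names(f)) f[[s]] else 0
  counts <- vapply(syms, function(s) get0n(a, s) + sign * get0n(b, s),
                   numeric(1))
  names(counts) <- syms
  if (any(counts < 0)) {
    bad <- names(counts)[counts < 0]
    stop("impossible composition: negative count for ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  new_formula(counts)
}

#' Monoisotopic mass of an elemental formula
#'
#' Sum of IUPAC monoisotopic atomic masses times element counts. The empty
#' formula has mass 0. Full double precision is kept internally; round only
#' at I/O.
#'
#' @param f An `elemental_formula` or formula string.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass(parse_formula("C5H14NO4P"))
#' @export
monoisotopic_mass <- function(f) {
  f <- as_formula(f)
  if (!length(f)) return(0)
  masses <- element_masses()
  missing <- setdiff(names(f), names(masses))
  if (length(missing)) {
    stop("no mass-table entry for element(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sum(masses[names(f)] * as.numeric(f))
}

#' Format an elemental formula as a Hill-style string
#'
#' Carbon first, then hydrogen, then remaining elements alphabetically.
#'
#' @param f An `elemental_formula`.
#' @return A single string, `""` for the empty formula.
#' @export
format_formula <- function(f) {
  f <- as_formula(f)
  if (!length(f)) return("")
  syms <- names(f)
  ord <- c(intersect(c("C", "H"), syms), sort(setdiff(syms, c("C", "H"))))
  paste0(vapply(ord, function(s) {
    n <- f[[s]]
    if (n == 1) s else paste0(s, format(n, scientific = FALSE))
  }, character(1)), collapse = "")
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat("<elemental_formula> ", format_formula(x), "\n", sep = "")
  invisible(x)
}

# ---- Adducts ----------------------------------------------------------------

# The covered ESI adduct set. `delta` is the signed elemental change applied
# to the neutral molecule; `charge` its signed charge. The bracketed "[M]+"
# and "[M]-" pseudo-adducts (bare cation/anion, electron correction only) are
# used internally as charge carriers for constant fragments.
.adduct_table <- list(
  "[M+H]+"   = list(delta = c(H = 1),  charge = +1L, mult = 1L),
  "[M+Na]+"  = list(delta = c(Na = 1), charge = +1L, mult = 1L),
  "[M+Li]+"  = list(delta = c(Li = 1), charge = +1L, mult = 1L),
  "[M+NH4]+" = list(delta = c(N = 1, H = 4), charge = +1L, mult = 1L),
  "[M-H]-"   = list(delta = c(H = -1), charge = -1L, mult = 1L),
  "[M+Cl]-"  = list(delta = c(Cl = 1), charge = -1L, mult = 1L),
  "[M-2H]2-" = list(delta = c(H = -2), charge = -2L, mult = 1L),
  "[M]+"     = list(delta = numeric(0), charge = +1L, mult = 1L),
  "[M]-"     = list(delta = numeric(0), charge = -1L, mult = 1L)
)

normalize_adduct_label <- function(label) {
  # accept the Unicode minus sign used in some shorthand sources
  label <- gsub("−", "-", label)
  gsub("[[:space:]]", "", label)
}

#' Adduct specification
#'
#' Look up one of the covered ESI adducts: `[M+H]+`, `[M+Na]+`, `[M+Li]+`,
#' `[M+NH4]+`, `[M-H]-`, `[M+Cl]-`, `[M-2H]2-` (a Unicode minus in the label
#' is accepted). The returned spec carries the signed elemental delta applied
#' to the neutral molecule, the signed charge, and the molecule multiplicity.
#'
#' @param label Adduct label text.
#' @return A list of class `adduct_spec` with fields `label`, `delta`
#'   (signed element counts), `charge`, `mult`.
#' @export
adduct_spec <- function(label) {
  key <- normalize_adduct_label(label)
  spec <- .adduct_table[[key]]
  if (is.null(spec)) {
    stop("unknown adduct label ", sQuote(label), "; covered adducts: ",
         paste(setdiff(names(.adduct_table), c("[M]+", "[M]-")),
               collapse = ", "), call. = FALSE)
  }
  structure(list(label = key, delta = spec$delta, charge = spec$charge,
                 mult = spec$mult), class = "adduct_spec")
}

#' Covered adduct labels
#' @return Character vector of the supported adduct labels.
#' @export
adduct_labels <- function() {
  setdiff(names(.adduct_table), c("[M]+", "[M]-"))
}

adduct_delta_mass <- function(spec) {
  d <- spec$delta
  if (!length(d)) return(0)
  masses <- element_masses()
  sum(masses[names(d)] * as.numeric(d))
}

#' Ion m/z for a neutral mass under an adduct
#'
#' `m/z = (mult * M + mass(delta) - charge * m_e) / |charge|`, i.e. the
#' electron-corrected convention: a proton adds 1.007276 Da.
#'
#' @param neutral_mass Neutral monoisotopic mass in Da (> 0).
#' @param adduct An `adduct_spec` or adduct label text.
#' @return m/z in Th (Da per unit charge).
#' @examples
#' adduct_mz(733.5622, "[M+H]+")
#' @export
adduct_mz <- function(neutral_mass, adduct) {
  if (!is.numeric(neutral_mass) || neutral_mass <= 0) {
    stop("neutral_mass must be a positive number", call. = FALSE)
  }
  if (!inherits(adduct, "adduct_spec")) adduct <- adduct_spec(adduct)
  if (adduct$charge == 0) stop("adduct charge must be nonzero", call. = FALSE)
  (adduct$mult * neutral_mass + adduct_delta_mass(adduct) -
     adduct$charge * ELECTRON_MASS) / abs(adduct$charge)
}

# round-half-even to 4 decimals: the convention used at every I/O surface
round_mz <- function(x) round(x, 4)
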