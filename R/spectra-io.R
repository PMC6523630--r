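# Spectrum file I/O: two-column peak lists and an MSP-dialect text format.
#
# Peak list: one "mz intensity" pair per line, one spectrum per file.
# MSP dialect: blank-line-separated blocks of "KEY: value" headers followed
# by "Num Peaks: n" and n peak lines ("mz intensity [# annotation]").
# Numbers are written with 4 decimals for m/z and 2 for intensity.

msp_header_map <- c(NAME = "name", PRECURSORMZ = "precursor_mz",
                    ADDUCT = "adduct", COLLISIONENERGY = "energy",
                    PROVENANCE = "provenance", COMPOUNDID = "compound_id")

#' Read spectra from a file
#'
#' @param path File path.
#' @param format `"peaklist"` (two whitespace-separated columns, one
#'   spectrum per file) or `"msp"` (block dialect with `NAME`,
#'   `PRECURSORMZ`, `Num Peaks` headers). A declared `Num Peaks` that does
#'   not match the number of peak lines is an error.
#' @return List of `spectrum` objects.
#' @export
read_spectra <- function(path, format = c("msp", "peaklist")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_parse("spectrum file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (format == "peaklist") {
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (!length(lines)) return(list())
    parts <- strsplit(lines, "[[:space:]]+")
    bad <- which(lengths(parts) < 2)
    if (length(bad)) {
      stop_parse("malformed peak-list line ", bad[1], " in ", path)
    }
    mz <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1)))
    intensity <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2)))
    if (anyNA(mz) || anyNA(intensity)) {
      stop_parse("non-numeric peak values in ", path)
    }
    return(list(spectrum(mz, intensity,
                         metadata = list(source = basename(path)))))
  }
  # MSP: split into blocks on blank lines
  blocks <- split(lines, cumsum(!nzchar(trimws(lines))))
  blocks <- lapply(blocks, function(b) b[nzchar(trimws(b))])
  blocks <- Filter(length, blocks)
  lapply(blocks, parse_msp_block, path = path)
}

parse_msp_block <- function(block, path) {
  is_header <- grepl("^[A-Za-z][A-Za-z0-9 _]*:", block)
  headers <- block[is_header]
  peak_lines <- block[!is_header]
  meta <- list()
  n_declared <- NA_integer_
  for (h in headers) {
    key <- toupper(trimws(sub(":.*$", "", h)))
    val <- trimws(sub("^[^:]*:", "", h))
    if (key == "NUM PEAKS") {
      n_declared <- as.integer(val)
    } else if (key %in% names(msp_header_map)) {
      field <- msp_header_map[[key]]
      meta[[field]] <- if (field %in% c("precursor_mz", "energy")) {
        as.numeric(val)
      } else val
    } else {
      meta[[tolower(key)]] <- val
    }
  }
  if (is.na(n_declared)) {
    stop_parse("MSP block without 'Num Peaks' header in ", path)
  }
  if (length(peak_lines) != n_declared) {
    stop_parse("MSP block in ", path, " declares ", n_declared,
               " peaks but has ", length(peak_lines), " peak lines")
  }
  if (!n_declared) return(spectrum(numeric(0), numeric(0), metadata = meta))
  ann <- sub("^[^#]*", "", peak_lines)
  ann <- trimws(sub("^#", "", ann))
  num <- trimws(sub("#.*$", "", peak_lines))
  parts <- strsplit(num, "[[:space:]]+")
  if (any(lengths(parts) < 2)) stop_parse("malformed MSP peak line in ", path)
  mz <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1)))
  intensity <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2)))
  if (anyNA(mz) || anyNA(intensity)) {
    stop_parse("non-numeric MSP peak values in ", path)
  }
  spectrum(mz, intensity, annotation = ann, metadata = meta)
}

format_msp_block <- function(s) {
  md <- s$metadata
  out <- character(0)
  push <- function(key, val) {
    if (!is.null(val) && !is.na(val)) c(out, paste0(key, ": ", val)) else out
  }
  out <- push("NAME", md$name)
  out <- push("COMPOUNDID", md$compound_id)
  out <- push("PRECURSORMZ",
              if (!is.null(md$precursor_mz)) {
                formatC(md$precursor_mz, format = "f", digits = 4)
              } else NULL)
  out <- push("ADDUCT", md$adduct)
  out <- push("COLLISIONENERGY", md$energy)
  out <- push("PROVENANCE", md$provenance)
  out <- c(out, paste0("Num Peaks: ", n_peaks(s)))
  if (n_peaks(s)) {
    pk <- s$peaks
    lines <- paste(formatC(pk$mz, format = "f", digits = 4),
                   formatC(pk$intensity, format = "f", digits = 2))
    has_ann <- nzchar(pk$annotation)
    lines[has_ann] <- paste(lines[has_ann], "#", pk$annotation[has_ann])
    out <- c(out, lines)
  }
  out
}

#' Write spectra to a file
#'
#' Deterministic serialization that round-trips with [read_spectra()] to
#' 1e-4 in m/z and 1e-2 in intensity. An empty spectrum list yields an
#' empty file.
#'
#' @param spectra List of `spectrum` objects (or a single `spectrum`).
#' @param path Output file path.
#' @param format `"msp"` or `"peaklist"` (peaklist holds one spectrum per
#'   file).
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path, format = c("msp", "peaklist")) {
  format <- match.arg(format)
  if (inherits(spectra, "spectrum")) spectra <- list(spectra)
  stopifnot(all(vapply(spectra, inherits, logical(1), "spectrum")))
  if (format == "peaklist") {
    if (length(spectra) > 1) {
      stop("peaklist format holds one spectrum per file", call. = FALSE)
    }
    lines <- if (length(spectra)) {
      pk <- spectra[[1]]$peaks
      paste(formatC(pk$mz, format = "f", digits = 4),
            formatC(pk$intensity, format = "f", digits = 2))
    } else character(0)
    writeLines(lines, path)
    return(invisible(path))
  }
  blocks <- lapply(spectra, format_msp_block)
  lines <- if (length(blocks)) {
    head(unlist(lapply(blocks, c, "")), -1)
  } else character(0)
  writeLines(lines, path)
  invisible(path)
}
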