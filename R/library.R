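# Spectral-library records and the on-disk library file set.
#
# A library directory holds three plain-text files:
#   compounds.tsv        id, name, neutral mass, formula, citation count
#   spectra.msp          all spectra, tagged with COMPOUNDID
#   classifications.tsv  chemical-classification assignments

#' Construct a spectral-library record
#'
#' @param compound_id,name Identifiers.
#' @param neutral_mass Neutral monoisotopic mass (Da).
#' @param formula `elemental_formula` (or formula string).
#' @param spectra List of `spectrum` objects; their metadata (adduct,
#'   energy, provenance) must be consistent with the record.
#' @param citation_count Literature-citation count; compounds without
#'   citation data carry the default floor of 1.
#' @param classification A `classification_record` or `NULL`.
#' @return A `library_record`.
#' @export
library_record <- function(compound_id, name, neutral_mass, formula,
                           spectra = list(), citation_count = 1L,
                           classification = NULL) {
  citation_count <- as.integer(citation_count)
  if (is.na(citation_count) || citation_count < 1L) {
    stop("citation_count must be an integer >= 1", call. = FALSE)
  }
  stopifnot(is.numeric(neutral_mass), neutral_mass > 0)
  structure(list(compound_id = compound_id, name = name,
                 neutral_mass = neutral_mass, formula = as_formula(formula),
                 spectra = spectra, citation_count = citation_count,
                 classification = classification),
            class = "library_record")
}

#' Assemble a spectral library from records
#'
#' @param records List of `library_record`s with unique compound ids.
#' @return A `spectral_library` keyed by compound id.
#' @export
spectral_library <- function(records) {
  ids <- vapply(records, `[[`, character(1), "compound_id")
  if (anyDuplicated(ids)) {
    stop("duplicate compound ids in library", call. = FALSE)
  }
  structure(list(records = stats::setNames(records, ids)),
            class = "spectral_library")
}

#' @export
print.spectral_library <- function(x, ...) {
  cat("<spectral_library> ", length(x$records), " compounds, ",
      sum(vapply(x$records, function(r) length(r$spectra), integer(1))),
      " spectra\n", sep = "")
  invisible(x)
}

#' Write a spectral library to a directory
#'
#' Deterministic serialization (records sorted by compound id) so that
#' identical libraries produce byte-identical file sets.
#'
#' @param lib A `spectral_library`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_library <- function(lib, dir) {
  stopifnot(inherits(lib, "spectral_library"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  recs <- lib$records[order(names(lib$records))]
  comp <- data.frame(
    compound_id = vapply(recs, `[[`, character(1), "compound_id"),
    name = vapply(recs, `[[`, character(1), "name"),
    neutral_mass = vapply(recs, function(r) {
      formatC(r$neutral_mass, format = "f", digits = 6)
    }, character(1)),
    formula = vapply(recs, function(r) format_formula(r$formula),
                     character(1)),
    citation_count = vapply(recs, `[[`, integer(1), "citation_count"),
    stringsAsFactors = FALSE)
  utils::write.table(comp, file.path(dir, "compounds.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  spectra <- unlist(lapply(recs, function(r) {
    lapply(r$spectra, function(s) {
      s$metadata$compound_id <- r$compound_id
      s
    })
  }), recursive = FALSE)
  write_spectra(spectra %||% list(), file.path(dir, "spectra.msp"), "msp")
  cls <- Filter(Negate(is.null), lapply(recs, `[[`, "classification"))
  cls_tab <- data.frame(
    compound_id = vapply(cls, `[[`, character(1), "compound_id"),
    direct_parent = vapply(cls, `[[`, character(1), "direct_parent"),
    alternative_parents = vapply(cls, function(r) {
      paste(r$alternative_parents, collapse = ";")
    }, character(1)),
    ancestors = vapply(cls, function(r) paste(r$ancestors, collapse = ";"),
                       character(1)),
    stringsAsFactors = FALSE)
  utils::write.table(cls_tab, file.path(dir, "classifications.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a spectral library from a directory
#'
#' @param dir Directory written by [write_library()].
#' @return A `spectral_library`.
#' @export
read_library <- function(dir) {
  comp_path <- file.path(dir, "compounds.tsv")
  if (!file.exists(comp_path)) {
    stop_parse("library directory lacks compounds.tsv: ", dir)
  }
  comp <- utils::read.delim(comp_path, stringsAsFactors = FALSE,
                            colClasses = c(compound_id = "character",
                                           name = "character"))
  cls_path <- file.path(dir, "classifications.tsv")
  cls <- if (file.exists(cls_path)) load_classifications(cls_path) else list()
  spec_path <- file.path(dir, "spectra.msp")
  spectra <- if (file.exists(spec_path)) read_spectra(spec_path, "msp")
             else list()
  by_id <- split(spectra, vapply(spectra, function(s) {
    s$metadata$compound_id %||% NA_character_
  }, character(1)))
  records <- lapply(seq_len(nrow(comp)), function(i) {
    id <- comp$compound_id[i]
    library_record(id, comp$name[i], comp$neutral_mass[i],
                   parse_formula(comp$formula[i]),
                   spectra = by_id[[id]] %||% list(),
                   citation_count = comp$citation_count[i],
                   classification = cls[[id]])
  })
  spectral_library(records)
}
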