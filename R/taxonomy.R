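# Chemical-classification records (ChemOnt-style) and the raw class score.
#
# Classification assignments are consumed as input (computed upstream by a
# structure-based classifier); no ontology reasoning is performed here.
# Category labels are free text and compared case-sensitively.

#' Construct a classification record
#'
#' @param compound_id Compound identifier.
#' @param direct_parent The most specific class describing the compound's
#'   dominant skeleton. Must not reappear among the alternative parents.
#' @param alternative_parents Character vector of additional (non-lineage)
#'   category labels.
#' @param ancestors Optional ordered root-to-leaf lineage labels.
#' @return A `classification_record`.
#' @export
classification_record <- function(compound_id, direct_parent,
                                  alternative_parents = character(0),
                                  ancestors = character(0)) {
  if (!nzchar(direct_parent)) {
    stop_parse("classification for ", compound_id,
               ": direct parent must be non-empty")
  }
  alternative_parents <- unique(alternative_parents[nzchar(alternative_parents)])
  if (direct_parent %in% alternative_parents) {
    stop_parse("classification for ", compound_id, ": direct parent ",
               sQuote(direct_parent), " also listed as alternative parent")
  }
  structure(list(compound_id = compound_id, direct_parent = direct_parent,
                 alternative_parents = alternative_parents,
                 ancestors = ancestors),
            class = "classification_record")
}

# all categories describing a compound: direct parent + alternative parents
record_categories <- function(rec) {
  c(rec$direct_parent, rec$alternative_parents)
}

#' Load classification records from a tab-separated file
#'
#' Expected columns: `compound_id`, `direct_parent`, `alternative_parents`
#' (`;`-separated, may be empty), optional `ancestors` (`;`-separated).
#' Duplicate compound ids are rejected.
#'
#' @param path TSV file path.
#' @return Named list of `classification_record`s keyed by compound id.
#' @export
load_classifications <- function(path) {
  if (!file.exists(path)) stop_parse("classification file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("compound_id", "direct_parent", "alternative_parents")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop_parse("classification file lacks column(s): ",
               paste(missing, collapse = ", "))
  }
  if (anyDuplicated(tab$compound_id)) {
    dup <- tab$compound_id[duplicated(tab$compound_id)][1]
    stop_parse("duplicate compound_id in classification file: ", dup)
  }
  split_field <- function(x) {
    if (is.na(x) || !nzchar(x)) character(0)
    else trimws(strsplit(x, ";", fixed = TRUE)[[1]])
  }
  recs <- lapply(seq_len(nrow(tab)), function(i) {
    classification_record(
      compound_id = tab$compound_id[i],
      direct_parent = tab$direct_parent[i],
      alternative_parents = split_field(tab$alternative_parents[i]),
      ancestors = if ("ancestors" %in% names(tab)) {
        split_field(tab$ancestors[i])
      } else character(0))
  })
  stats::setNames(recs, tab$compound_id)
}

#' Build the category pool of a candidate set
#'
#' Counts every category assignment (direct + alternative parents) across
#' the given classification records: the "total pool of chemical classes
#' assigned to all candidate molecules" against which each candidate's
#' class score is measured.
#'
#' @param records List of `classification_record`s.
#' @return A `category_pool`: list with `counts` (named integer vector) and
#'   `total` (sum of counts).
#' @export
category_pool <- function(records) {
  cats <- unlist(lapply(records, record_categories), use.names = FALSE)
  counts <- if (length(cats)) table(cats) else table(character(0))
  counts <- stats::setNames(as.integer(counts), names(counts))
  structure(list(counts = counts, total = sum(counts)),
            class = "category_pool")
}

#' Raw chemical-class score of a candidate
#'
#' Frequency-mass score: the sum, over the candidate's categories (direct
#' parent plus alternative parents), of that category's occurrence count in
#' the candidate pool, divided by the pool's total assignment count.
#' Candidates sharing many categories with the rest of the list score
#' higher, rewarding structurally similar candidates. The score is in
#' (0, 1] when the pool was built from a list containing the candidate.
#'
#' @param record A `classification_record`.
#' @param pool A `category_pool` built from the current candidate list.
#' @return Non-negative score.
#' @export
raw_class_score <- function(record, pool) {
  stopifnot(inherits(record, "classification_record"),
            inherits(pool, "category_pool"))
  if (pool$total == 0) stop("empty category pool", call. = FALSE)
  cats <- record_categories(record)
  hit <- pool$counts[intersect(cats, names(pool$counts))]
  sum(hit) / pool$total
}
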