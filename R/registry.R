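# Fragmentation rule registry: loading, routing, rule application and
# energy-resolved spectrum prediction.
#
# The registry has two parts. The manifest lists, for each covered lipid
# class, the number of curated rules and the adduct types they cover (21
# classes, 344 rules, 50 class/adduct combinations in the packaged default).
# The rules section holds the concrete encoded subset executed by this
# package: constant fragments, neutral losses, and sn-indexed chain losses,
# each with an intensity category per collision energy.

CATEGORY_LEVELS <- c("absent", "low", "medium", "high", "maximum")

#' Numeric relative intensity of an intensity category
#'
#' The categorical abundance levels map to fixed relative intensities:
#' `maximum` is pinned to 100 (the base peak), the other bins use their
#' midpoints: `high` 75 (60--90% bin), `medium` 37.5 (15--60%), `low` 8
#' (1--15%), `absent` 0.
#'
#' @param category Category label(s).
#' @return Numeric relative intensity in \[0, 100\].
#' @export
category_intensity <- function(category) {
  map <- c(absent = 0, low = 8, medium = 37.5, high = 75, maximum = 100)
  bad <- setdiff(unique(category), names(map))
  if (length(bad)) {
    stop("unknown intensity category: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  unname(map[category])
}

#' Path of the packaged default rule registry
#' @return File path of the shipped registry resource.
#' @export
default_registry_path <- function() {
  path <- system.file("extdata", "fragmentation_rules.tsv",
                      package = "lipidrules")
  if (path == "") path <- file.path("inst", "extdata",
                                    "fragmentation_rules.tsv")
  path
}

parse_registry_line <- function(fields, lineno) {
  if (fields[[1]] == "M") {
    if (length(fields) != 4) {
      stop_parse("registry line ", lineno, ": manifest rows need 4 fields")
    }
    list(type = "M",
         class = fields[[2]],
         rule_count = as.integer(fields[[3]]),
         adducts = vapply(strsplit(fields[[4]], ";", fixed = TRUE)[[1]],
                          normalize_adduct_label, character(1),
                          USE.NAMES = FALSE))
  } else if (fields[[1]] == "R") {
    if (!length(fields) %in% c(12L, 13L)) {
      stop_parse("registry line ", lineno,
                 ": rule rows need 12 fields plus an optional pattern")
    }
    if (length(fields) == 12L) fields <- c(fields, "-")
    names(fields) <- c("type", "rule_id", "class", "adduct", "kind", "param",
                       "delta", "carrier", "e10", "e20", "e40", "annotation",
                       "pattern")
    as.list(fields)
  } else {
    stop_parse("registry line ", lineno, ": unknown record type ",
               sQuote(fields[[1]]))
  }
}

build_rule <- function(rec) {
  kind <- rec$kind
  if (!kind %in% c("constant", "neutral_loss", "chain_loss")) {
    stop_parse("rule ", rec$rule_id, ": unknown kind ", sQuote(kind))
  }
  profile <- c(`10` = rec$e10, `20` = rec$e20, `40` = rec$e40)
  bad <- setdiff(profile, CATEGORY_LEVELS)
  if (length(bad)) {
    stop_parse("rule ", rec$rule_id, ": unknown intensity category ",
               paste(bad, collapse = ", "))
  }
  if (all(profile == "absent")) {
    stop_parse("rule ", rec$rule_id, ": at least one energy must be non-absent")
  }
  delta <- if (rec$delta == "-") NULL else parse_formula(rec$delta)
  if (kind %in% c("constant", "neutral_loss") && is.null(delta)) {
    stop_parse("rule ", rec$rule_id, ": kind ", kind, " requires a delta formula")
  }
  sn <- NA_integer_; leaving <- NA_character_
  if (kind == "chain_loss") {
    m <- regmatches(rec$param,
                    regexec("^([0-9]+):(acid|ketene|alkene)$", rec$param))[[1]]
    if (!length(m)) {
      stop_parse("rule ", rec$rule_id, ": chain_loss param must be ",
                 "'<sn>:<acid|ketene|alkene>', got ", sQuote(rec$param))
    }
    sn <- as.integer(m[2]); leaving <- m[3]
  }
  structure(list(rule_id = rec$rule_id, lipid_class = rec$class,
                 adduct_label = normalize_adduct_label(rec$adduct),
                 kind = kind, sn = sn, leaving = leaving, delta = delta,
                 carrier = normalize_adduct_label(rec$carrier),
                 profile = profile, annotation = rec$annotation,
                 pattern = if (identical(rec$pattern, "-")) NA_character_
                           else rec$pattern),
            class = "fragmentation_rule")
}

#' Load a fragmentation rule registry
#'
#' Reads a registry file (see the packaged
#' `extdata/fragmentation_rules.tsv` for the format) and verifies its
#' invariants at load: the manifest must have 21 class rows whose rule
#' counts sum to 344 and whose class/adduct combinations sum to 50, and
#' every concrete rule must target a manifest-covered class/adduct pair.
#'
#' @param path Registry file path; defaults to the packaged registry.
#' @return A `rule_registry`: list with `manifest` (data.frame: class,
#'   rule_count, adducts) and `rules` (list of `fragmentation_rule`),
#'   indexed by class/adduct.
#' @export
load_registry <- function(path = default_registry_path()) {
  if (!file.exists(path)) stop_parse("registry file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  recs <- lapply(which(keep), function(i) {
    parse_registry_line(strsplit(lines[[i]], "\t", fixed = TRUE)[[1]], i)
  })
  man <- Filter(function(r) r$type == "M", recs)
  rul <- Filter(function(r) r$type == "R", recs)

  manifest <- data.frame(
    class = vapply(man, `[[`, character(1), "class"),
    rule_count = vapply(man, `[[`, integer(1), "rule_count"),
    adducts = I(lapply(man, `[[`, "adducts")),
    stringsAsFactors = FALSE)
  if (anyDuplicated(manifest$class)) {
    stop_parse("registry manifest: duplicated class rows")
  }
  if (nrow(manifest) != 21L) {
    stop_parse("registry manifest must have 21 class rows, found ",
               nrow(manifest))
  }
  if (sum(manifest$rule_count) != 344L) {
    stop_parse("registry manifest rule counts must sum to 344, found ",
               sum(manifest$rule_count))
  }
  n_combo <- sum(lengths(manifest$adducts))
  if (n_combo != 50L) {
    stop_parse("registry manifest class/adduct combinations must sum to 50, ",
               "found ", n_combo)
  }

  rules <- lapply(rul, build_rule)
  covered <- function(cls, add) {
    i <- match(cls, manifest$class)
    !is.na(i) && add %in% manifest$adducts[[i]]
  }
  for (r in rules) {
    if (!covered(r$lipid_class, r$adduct_label)) {
      stop_parse("rule ", r$rule_id, ": class/adduct pair (", r$lipid_class,
                 ", ", r$adduct_label, ") is not covered by the manifest")
    }
  }
  index <- split(rules, vapply(rules, function(r) {
    paste(r$lipid_class, r$adduct_label, sep = "|")
  }, character(1)))
  structure(list(manifest = manifest, rules = rules, index = index,
                 path = path), class = "rule_registry")
}

#' @export
print.rule_registry <- function(x, ...) {
  cat("<rule_registry> ", nrow(x$manifest), " classes, ",
      sum(x$manifest$rule_count), " manifest rules, ",
      length(x$rules), " concrete encoded rules\n", sep = "")
  invisible(x)
}

rules_for <- function(reg, lipid_class, adduct_label) {
  rs <- reg$index[[paste(lipid_class, normalize_adduct_label(adduct_label),
                         sep = "|")]]
  if (is.null(rs)) list() else rs
}

#' Route a compound to a prediction strategy
#'
#' Decides how a query compound is handled for a given adduct:
#' `"rule_based"` when the compound is a covered lipid and the manifest
#' covers the class/adduct pair; `"error_uncovered_lipid"` when the compound
#' is a (glycero-/phospho-/sphingo-) lipid but no applicable pattern exists
#' (for such compounds the computation stops rather than falling back to
#' combinatorial fragmentation); `"fallback_external"` for any other
#' compound, flagging that a general-purpose predictor outside this package
#' would be needed.
#'
#' @param s A `lipid_structure`, or any other object for non-lipids.
#' @param adduct Adduct label.
#' @param reg A `rule_registry`.
#' @return One of `"rule_based"`, `"error_uncovered_lipid"`,
#'   `"fallback_external"`.
#' @export
route_compound <- function(s, adduct, reg) {
  stopifnot(inherits(reg, "rule_registry"))
  if (!inherits(s, "lipid_structure")) return("fallback_external")
  adduct <- normalize_adduct_label(adduct)
  i <- match(s$lipid_class, reg$manifest$class)
  if (!is.na(i) && adduct %in% reg$manifest$adducts[[i]]) {
    "rule_based"
  } else {
    # all covered template classes are glycero-/phospho-/sphingolipids
    "error_uncovered_lipid"
  }
}

#' Apply one fragmentation rule to a lipid structure
#'
#' Computes the product-ion m/z of a single rule. Constant fragments ionize
#' the fragment composition under the rule's charge carrier; neutral losses
#' subtract the loss from the ionized precursor; chain losses subtract the
#' indexed chain's leaving group (free acid, ketene or alkene), plus any
#' extra neutral loss the rule specifies. Rules whose carrier is an explicit
#' adduct label re-ionize the residual neutral under that adduct (used for
#' the singly charged products of doubly charged precursors).
#'
#' @param r A `fragmentation_rule`.
#' @param s A `lipid_structure` of the rule's class.
#' @param adduct `adduct_spec` or label matching the rule.
#' @return List with `mz` (full precision), `profile` (category per energy),
#'   `annotation`, `rule_id`.
#' @export
apply_rule <- function(r, s, adduct) {
  stopifnot(inherits(r, "fragmentation_rule"),
            inherits(s, "lipid_structure"))
  if (!inherits(adduct, "adduct_spec")) adduct <- adduct_spec(adduct)
  if (!identical(r$lipid_class, s$lipid_class)) {
    stop_routing("rule ", r$rule_id, " targets class ", r$lipid_class,
                 ", not ", s$lipid_class)
  }
  if (!identical(r$adduct_label, adduct$label)) {
    stop_routing("rule ", r$rule_id, " targets adduct ", r$adduct_label,
                 ", not ", adduct$label)
  }
  neutral <- lipid_formula(s)
  if (r$kind == "constant") {
    mz <- adduct_mz(monoisotopic_mass(r$delta), adduct_spec(r$carrier))
  } else {
    loss <- new_formula()
    if (r$kind == "chain_loss") {
      if (r$sn > length(s$chains)) {
        stop_routing("rule ", r$rule_id, ": structure has no sn-", r$sn,
                     " chain")
      }
      loss <- chain_leaving_formula(s$chains[[r$sn]], r$leaving)
    }
    if (!is.null(r$delta)) loss <- combine_formulas(loss, r$delta)
    if (identical(r$carrier, "precursor")) {
      mz <- adduct_mz(monoisotopic_mass(neutral), adduct) -
        monoisotopic_mass(loss) / abs(adduct$charge)
    } else {
      residual <- combine_formulas(neutral, loss, sign = -1)
      mz <- adduct_mz(monoisotopic_mass(residual), adduct_spec(r$carrier))
    }
  }
  list(mz = mz, profile = r$profile, annotation = r$annotation,
       rule_id = r$rule_id)
}

# fixed per-energy category of the intact precursor ion: base peak when
# little fragmentation occurs (10 and 20 eV), reduced at 40 eV
.precursor_profile <- c(`10` = "maximum", `20` = "maximum", `40` = "medium")

#' Predict an energy-resolved ESI-MS/MS spectrum from the rule registry
#'
#' Emits the precursor ion plus one peak per applicable rule whose intensity
#' category at the requested collision energy is not `absent`. Peaks are
#' sorted by m/z with m/z rounded half-even to 4 decimals at the I/O
#' surface; coinciding product m/z values (as happens for chain losses of
#' identical chains) are merged keeping the highest category. The output is
#' fully deterministic.
#'
#' @param s A `lipid_structure`.
#' @param adduct Adduct label.
#' @param energy Collision energy: exactly 10, 20 or 40 (eV). Other values
#'   are rejected, never nearest-mapped.
#' @param reg A `rule_registry` (default: packaged registry).
#' @return A `spectrum` object with annotated peaks.
#' @examples
#' reg <- load_registry()
#' predict_spectrum(parse_lipid_name("PC(16:0/16:0)"), "[M+H]+", 40, reg)
#' @export
predict_spectrum <- function(s, adduct, energy, reg = load_registry()) {
  if (!is.numeric(energy) || length(energy) != 1L ||
      !energy %in% c(10, 20, 40)) {
    stop_routing("collision energy must be exactly 10, 20 or 40 eV")
  }
  decision <- route_compound(s, adduct, reg)
  if (decision == "error_uncovered_lipid") {
    stop_routing("no fragmentation pattern for lipid class ",
                 sQuote(s$lipid_class), " with adduct ", sQuote(adduct),
                 "; computation stopped")
  }
  if (decision == "fallback_external") {
    stop_routing("compound is not a covered lipid; a general-purpose ",
                 "fragmenter would be required")
  }
  spec <- adduct_spec(adduct)
  ekey <- as.character(energy)

  prec_mz <- precursor_mz(s, spec)
  mz <- prec_mz
  intensity <- category_intensity(.precursor_profile[[ekey]])
  annotation <- paste0("precursor ", spec$label)

  for (r in rules_for(reg, s$lipid_class, spec$label)) {
    cat_e <- r$profile[[ekey]]
    if (cat_e == "absent") next
    pk <- apply_rule(r, s, spec)
    mz <- c(mz, pk$mz)
    intensity <- c(intensity, category_intensity(cat_e))
    annotation <- c(annotation, pk$annotation)
  }

  # merge peaks that coincide at the reported precision (symmetric lipids)
  mz4 <- round_mz(mz)
  ord <- order(mz4, -intensity, annotation)
  mz4 <- mz4[ord]; intensity <- intensity[ord]; annotation <- annotation[ord]
  keep <- !duplicated(mz4)
  spectrum(mz = mz4[keep], intensity = intensity[keep],
           annotation = annotation[keep],
           metadata = list(name = s$canonical_name,
                           precursor_mz = round_mz(prec_mz),
                           adduct = spec$label, energy = energy,
                           provenance = "predicted"))
}
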