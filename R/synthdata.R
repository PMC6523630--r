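# Deterministic generators for synthetic libraries, perturbed query spectra
# and identification challenges.
#
# The generators emulate a curated lipid spectral library: structures drawn
# from the classes with concrete encoded rules, rule-predicted spectra at
# the three collision energies, log-normal literature-citation counts
# floored at 1, and class-lineage chemical classifications. Randomness uses
# one root seed split arithmetically per compound, so growing a library
# never reshuffles earlier records.

# classes with concrete encoded rules, and the adduct used for simulation
.synth_classes <- list(
  "Phosphatidylcholines"     = list(adduct = "[M+H]+",
    alt = c("Glycerophosphocholines", "Glycerophospholipids"),
    n_chains = 2),
  "Phosphatidylserines"      = list(adduct = "[M-H]-",
    alt = c("Glycerophosphoserines", "Glycerophospholipids"),
    n_chains = 2),
  "Phosphatidic acids"       = list(adduct = "[M-H]-",
    alt = c("Glycerophosphates", "Glycerophospholipids"),
    n_chains = 2),
  "Lysophosphatidylcholines" = list(adduct = "[M+H]+",
    alt = c("Glycerophosphocholines", "Glycerophospholipids"),
    n_chains = 1),
  "1,2-Diacylglycerols"      = list(adduct = "[M+NH4]+",
    alt = c("Diradylglycerols", "Glycerolipids"),
    n_chains = 2),
  "Triacylglycerols"         = list(adduct = "[M+NH4]+",
    alt = c("Triradylglycerols", "Glycerolipids"),
    n_chains = 3),
  "Cardiolipins"             = list(adduct = "[M-2H]2-",
    alt = c("Glycerophosphoglycerophosphoglycerols", "Glycerophospholipids"),
    n_chains = 4)
)

#' Configuration for the synthetic-data generators
#'
#' @param n_compounds Number of library compounds.
#' @param seed Root integer seed; every downstream draw derives from it.
#' @param class_mix Named weights over the encoded lipid classes (default
#'   uniform over the classes with concrete rules).
#' @param citation_meanlog,citation_sdlog Log-normal parameters of the
#'   citation-count model; counts are rounded and floored at 1.
#' @param mz_jitter_sd Gaussian m/z jitter SD (Da) applied to query peaks.
#' @param intensity_noise_sd SD of the multiplicative relative-intensity
#'   noise.
#' @param dropout_prob Independent peak-dropout probability.
#' @return A `synth_config`.
#' @export
synth_config <- function(n_compounds = 100L, seed = 1L, class_mix = NULL,
                         citation_meanlog = 3, citation_sdlog = 1,
                         mz_jitter_sd = 0.002, intensity_noise_sd = 0.1,
                         dropout_prob = 0.1) {
  if (is.null(class_mix)) {
    class_mix <- stats::setNames(rep(1, length(.synth_classes)),
                                 names(.synth_classes))
  }
  bad <- setdiff(names(class_mix), names(.synth_classes))
  if (length(bad)) {
    stop("class_mix names must be encoded classes; unknown: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  stopifnot(n_compounds >= 0, all(class_mix >= 0), sum(class_mix) > 0,
            mz_jitter_sd >= 0, intensity_noise_sd >= 0,
            dropout_prob >= 0, dropout_prob <= 1)
  structure(list(n_compounds = as.integer(n_compounds),
                 seed = as.integer(seed),
                 class_mix = class_mix / sum(class_mix),
                 citation_meanlog = citation_meanlog,
                 citation_sdlog = citation_sdlog,
                 mz_jitter_sd = mz_jitter_sd,
                 intensity_noise_sd = intensity_noise_sd,
                 dropout_prob = dropout_prob),
            class = "synth_config")
}

# random chain pool: even-carbon fatty chains common in glycerolipids
random_chain_set <- function(n) {
  lapply(seq_len(n), function(i) {
    carbons <- sample(seq(12L, 22L, by = 2L), 1)
    dbl <- sample(0:min(4L, carbons %/% 4L), 1)
    new_chain(carbons, dbl, "acyl", sn = i)
  })
}

random_structure <- function(cfg, index) {
  with_seed(child_seed(cfg$seed, index, salt = 1L), {
    cls <- sample(names(cfg$class_mix), 1, prob = cfg$class_mix)
    lipid_structure(cls, random_chain_set(.synth_classes[[cls]]$n_chains))
  })
}

class_lineage_record <- function(compound_id, lipid_class) {
  info <- .synth_classes[[lipid_class]]
  classification_record(
    compound_id = compound_id,
    direct_parent = lipid_class,
    alternative_parents = info$alt,
    ancestors = c("Chemical entities", "Lipids and lipid-like molecules",
                  rev(info$alt), lipid_class))
}

#' Generate a synthetic spectral library
#'
#' Draws `cfg$n_compounds` distinct lipid structures from the encoded
#' classes, predicts their spectra at 10, 20 and 40 eV under each class's
#' simulation adduct, assigns floored log-normal citation counts and
#' class-lineage classifications. Fully deterministic given `cfg$seed`.
#'
#' @param cfg A `synth_config`.
#' @param registry A `rule_registry`.
#' @return A `spectral_library`.
#' @export
generate_library <- function(cfg, registry = load_registry()) {
  stopifnot(inherits(cfg, "synth_config"))
  records <- vector("list", cfg$n_compounds)
  seen <- character(0)
  for (i in seq_len(cfg$n_compounds)) {
    s <- random_structure(cfg, i)
    attempt <- 0L
    while (s$canonical_name %in% seen) {
      attempt <- attempt + 1L
      if (attempt > 1000L) stop("cannot draw enough distinct structures",
                                call. = FALSE)
      s <- random_structure(cfg, index = i + 1000L * attempt)
    }
    seen <- c(seen, s$canonical_name)
    adduct <- .synth_classes[[s$lipid_class]]$adduct
    spectra <- lapply(c(10, 20, 40), function(e) {
      predict_spectrum(s, adduct, e, registry)
    })
    citations <- with_seed(child_seed(cfg$seed, i, salt = 2L), {
      max(1L, as.integer(round(stats::rlnorm(1, cfg$citation_meanlog,
                                             cfg$citation_sdlog))))
    })
    id <- sprintf("SYN%04d", i)
    spectra <- lapply(spectra, function(sp) {
      sp$metadata$compound_id <- id
      sp
    })
    records[[i]] <- library_record(
      compound_id = id, name = s$canonical_name,
      neutral_mass = monoisotopic_mass(lipid_formula(s)),
      formula = lipid_formula(s), spectra = spectra,
      citation_count = citations,
      classification = class_lineage_record(id, s$lipid_class))
  }
  spectral_library(records)
}

#' Perturb a spectrum to emulate experimental variation
#'
#' Applies, per peak: Gaussian m/z jitter, multiplicative intensity noise
#' truncated at zero, and independent dropout; the survivors are
#' renormalized. Dropping every peak is an error. Deterministic given
#' `seed`.
#'
#' @param s A non-empty `spectrum`.
#' @param cfg A `synth_config` supplying the perturbation parameters.
#' @param seed Integer seed.
#' @return The perturbed `spectrum`.
#' @export
perturb_spectrum <- function(s, cfg, seed) {
  stopifnot(inherits(s, "spectrum"), inherits(cfg, "synth_config"))
  if (!n_peaks(s)) stop("cannot perturb an empty spectrum", call. = FALSE)
  with_seed(seed, {
    n <- n_peaks(s)
    keep <- stats::runif(n) >= cfg$dropout_prob
    mz <- s$peaks$mz + stats::rnorm(n, 0, cfg$mz_jitter_sd)
    intensity <- s$peaks$intensity *
      pmax(0, 1 + stats::rnorm(n, 0, cfg$intensity_noise_sd))
    if (!any(keep) || all(intensity[keep] <= 0)) {
      stop_routing("perturbation dropped every peak of the spectrum")
    }
    mz <- mz[keep]; intensity <- intensity[keep]
    ann <- s$peaks$annotation[keep]
    # merge peaks the jitter pushed within the duplicate threshold
    ord <- order(mz)
    mz <- mz[ord]; intensity <- intensity[ord]; ann <- ann[ord]
    dup <- c(FALSE, diff(mz) < 1e-6)
    if (any(dup)) {
      mz <- mz[!dup]; intensity <- intensity[!dup]; ann <- ann[!dup]
    }
    out <- spectrum(mz, pmin(100, intensity * (100 / max(intensity))),
                    annotation = ann, metadata = s$metadata)
    out$metadata$provenance <- "perturbed"
    out
  })
}

#' Generate identification challenges from a library
#'
#' Selects `n` distinct true compounds and builds, for each, a query
#' spectrum set by perturbing the truth's spectra under `cfg`. With
#' `withhold = TRUE`, any experimental-provenance spectra of the selected
#' truths are removed from the returned searchable library, so a query can
#' never be matched against its own measured spectrum.
#'
#' @param lib A `spectral_library`.
#' @param n Number of challenges (`n <= ` library size).
#' @param cfg A `synth_config` (perturbation parameters; set the jitter,
#'   noise and dropout to 0 for exact-recovery checks).
#' @param seed Integer seed.
#' @param withhold Withhold the truths' experimental spectra from the
#'   searchable library.
#' @return List with `challenges` (each: `challenge_id`, `true_id`,
#'   `query` list of spectra) and `library` (the searchable library).
#' @export
generate_challenges <- function(lib, n, cfg, seed = cfg$seed,
                                withhold = FALSE) {
  stopifnot(inherits(lib, "spectral_library"))
  ids <- sort(names(lib$records))
  if (n > length(ids)) {
    stop("cannot generate more challenges than library compounds",
         call. = FALSE)
  }
  chosen <- with_seed(child_seed(seed, 0L, salt = 3L), {
    sample(ids, n)
  })
  challenges <- lapply(seq_along(chosen), function(k) {
    rec <- lib$records[[chosen[k]]]
    # an energy whose perturbed spectrum loses every peak is dropped from
    # the query (a real acquisition with no surviving peaks is discarded);
    # a challenge only fails if no energy survives
    query <- lapply(seq_along(rec$spectra), function(j) {
      tryCatch(
        perturb_spectrum(rec$spectra[[j]], cfg,
                         seed = child_seed(seed, k, salt = 10L + j)),
        lipidrules_routing_error = function(e) NULL)
    })
    query <- Filter(Negate(is.null), query)
    if (!length(query)) {
      stop_routing("perturbation emptied every query spectrum of ",
                   rec$compound_id)
    }
    list(challenge_id = sprintf("CH%04d", k), true_id = rec$compound_id,
         query = query)
  })
  search_lib <- lib
  if (withhold) {
    for (id in chosen) {
      rec <- search_lib$records[[id]]
      rec$spectra <- Filter(function(s) {
        !identical(s$metadata$provenance, "experimental")
      }, rec$spectra)
      search_lib$records[[id]] <- rec
    }
  }
  list(challenges = challenges, library = search_lib)
}

#' Run a challenge set through the identification pipeline
#'
#' For each challenge, retrieves candidates around the query's precursor
#' m/z, applies the combined scoring function, ranks, and predicts the
#' chemical class. Challenges whose true compound is not retrieved count as
#' misses (`hit_rank` `NA`).
#'
#' @param challenges Challenge list from [generate_challenges()].
#' @param lib The searchable `spectral_library`.
#' @param cfg A `scoring_config`.
#' @param use_metadata Drop class/citation score terms if `FALSE`.
#' @return Data.frame with one row per challenge: `challenge_id`,
#'   `true_id`, `n_candidates`, `hit_rank`, `predicted_class`,
#'   `class_correct`.
#' @export
run_challenges <- function(challenges, lib, cfg = scoring_config(),
                           use_metadata = TRUE) {
  cls <- lapply(lib$records, `[[`, "classification")
  cls <- Filter(Negate(is.null), cls)
  rows <- lapply(challenges, function(ch) {
    adduct <- ch$query[[1]]$metadata$adduct
    res <- tryCatch(
      identify_compound(ch$query, lib, adduct, cfg, true_id = ch$true_id,
                        use_metadata = use_metadata),
      lipidrules_routing_error = function(e) NULL)
    if (is.null(res)) {
      return(data.frame(challenge_id = ch$challenge_id,
                        true_id = ch$true_id, n_candidates = 0L,
                        hit_rank = NA_integer_,
                        predicted_class = NA_character_,
                        class_correct = NA, stringsAsFactors = FALSE))
    }
    pred <- predict_class(res, cls)
    truth_rec <- cls[[ch$true_id]]
    correct <- if (is.null(truth_rec)) NA else {
      pred %in% record_categories(truth_rec)
    }
    data.frame(challenge_id = ch$challenge_id, true_id = ch$true_id,
               n_candidates = nrow(res$table), hit_rank = res$hit_rank,
               predicted_class = pred, class_correct = correct,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
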