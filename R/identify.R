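# Candidate retrieval, combined scoring, ranking, evaluation metrics,
# chemical-class prediction, and grid-search weight optimization.
#
# The total candidate score is the weighted sum
#   S_TOTAL = a_CFM_ORIG * S_CFM_ORIG + a_CLASS * S_CLASS + a_REF * S_REF
# with non-negative weights summing to 1, where the three terms are the
# spectral-similarity, chemical-class and citation (reference) scores, each
# normalized by its maximum over the candidate list. Candidates whose raw
# spectral similarity reaches the bypass threshold keep only the similarity
# term: a near-perfect spectral match must not be penalized by metadata.

#' Scoring configuration
#'
#' Defaults are the trained coefficients of the combined scoring function:
#' `a_cfm_orig = 0.6`, `a_class = 0.1`, `a_ref = 0.3`, a 95% raw-similarity
#' bypass, and a citation ceiling of 156 counts.
#'
#' @param a_cfm_orig,a_class,a_ref Non-negative weights summing to 1 for the
#'   spectral-similarity, chemical-class and citation terms.
#' @param bypass_threshold Raw (unnormalized) dot-product similarity at or
#'   above which only the spectral-similarity term is applied.
#' @param citation_ceiling Citation counts are capped at this value.
#' @param mz_tolerance Precursor m/z window (Da) for candidate retrieval.
#' @param sim_tolerance Peak-alignment tolerance (Da) for similarity.
#' @return A `scoring_config`.
#' @export
scoring_config <- function(a_cfm_orig = 0.6, a_class = 0.1, a_ref = 0.3,
                           bypass_threshold = 0.95, citation_ceiling = 156L,
                           mz_tolerance = 0.01, sim_tolerance = 0.01) {
  w <- c(a_cfm_orig, a_class, a_ref)
  if (any(w < 0) || abs(sum(w) - 1) > 1e-9) {
    stop("scoring weights must be non-negative and sum to 1", call. = FALSE)
  }
  structure(list(a_cfm_orig = a_cfm_orig, a_class = a_class, a_ref = a_ref,
                 bypass_threshold = bypass_threshold,
                 citation_ceiling = as.integer(citation_ceiling),
                 mz_tolerance = mz_tolerance, sim_tolerance = sim_tolerance),
            class = "scoring_config")
}

#' Cap a citation count at the scoring ceiling
#'
#' Citation counts span several orders of magnitude; uncapped they can push
#' a spectrally weaker but heavily cited compound above the true match, so
#' counts above the ceiling are truncated to it. Idempotent and monotone.
#'
#' @param count Non-negative integer citation count(s).
#' @param ceiling Cap (default 156).
#' @return `pmin(count, ceiling)`.
#' @export
cap_citations <- function(count, ceiling = 156L) {
  if (any(count < 0)) stop("citation count must be >= 0", call. = FALSE)
  pmin(count, ceiling)
}

#' Retrieve candidate records within a precursor m/z window
#'
#' Selects library records whose ionized mass under `adduct` lies within
#' `tol` of the query precursor m/z. Results are in stable compound-id
#' order.
#'
#' @param lib A `spectral_library`.
#' @param precursor_mz Query precursor m/z.
#' @param tol Non-negative window half-width (Da).
#' @param adduct Adduct label used to ionize the library neutral masses.
#' @return List of `library_record`s.
#' @export
retrieve_candidates <- function(lib, precursor_mz, tol, adduct) {
  stopifnot(inherits(lib, "spectral_library"))
  if (!is.numeric(tol) || tol < 0) {
    stop("retrieval tolerance must be >= 0", call. = FALSE)
  }
  spec <- adduct_spec(adduct)
  recs <- lib$records[order(names(lib$records))]
  hits <- Filter(function(r) {
    abs(adduct_mz(r$neutral_mass, spec) - precursor_mz) <= tol + 1e-12
  }, recs)
  unname(hits)
}

# Compound-level raw spectral similarity between a query spectrum set and a
# record. Record spectra are grouped by provenance; within a group the score
# is the mean of per-energy dot products over energies present on both
# sides; the compound-level score is the maximum over groups.
compound_similarity <- function(query_spectra, record, tol = 0.01) {
  if (inherits(query_spectra, "spectrum")) query_spectra <- list(query_spectra)
  if (!length(record$spectra) || !length(query_spectra)) return(0)
  q_energy <- vapply(query_spectra, function(s) {
    as.numeric(s$metadata$energy %||% NA_real_)
  }, numeric(1))
  prov <- vapply(record$spectra, function(s) {
    s$metadata$provenance %||% "predicted"
  }, character(1))
  best <- 0
  for (grp in split(record$spectra, prov)) {
    g_energy <- vapply(grp, function(s) {
      as.numeric(s$metadata$energy %||% NA_real_)
    }, numeric(1))
    shared <- intersect(q_energy[!is.na(q_energy)], g_energy[!is.na(g_energy)])
    if (!length(shared)) next
    scores <- vapply(shared, function(e) {
      dot_product_similarity(query_spectra[[match(e, q_energy)]],
                             grp[[match(e, g_energy)]], tol)
    }, numeric(1))
    best <- max(best, mean(scores))
  }
  best
}

# normalize a score column by its maximum; an all-zero column stays zero
normalize_column <- function(x) {
  m <- max(x)
  if (m <= 0) rep(0, length(x)) else x / m
}

#' Score a candidate list
#'
#' Computes, for every candidate, the three raw score terms (compound-level
#' dot-product similarity against the query spectra; frequency-mass
#' chemical-class score against the candidate pool; capped citation count),
#' normalizes each column by its maximum over the list, and combines them
#' with the configured weights. Candidates whose raw similarity reaches
#' `cfg$bypass_threshold` are flagged and keep `S_TOTAL = S_CFM_ORIG`.
#'
#' @param candidates Non-empty list of `library_record`s.
#' @param cfg A `scoring_config`.
#' @param query Query `spectrum` or list of spectra (one per collision
#'   energy). May be `NULL` when `raw_sim` is supplied.
#' @param raw_sim Optional precomputed raw similarity per candidate,
#'   bypassing the spectral comparison.
#' @param use_metadata If `FALSE`, class and citation terms are dropped and
#'   the score is the normalized similarity alone.
#' @return A data.frame with columns `compound_id`, `S_CFM_ORIG_raw`,
#'   `S_CFM_ORIG`, `S_CLASS`, `S_REF`, `S_TOTAL`, `bypass`.
#' @export
score_candidates <- function(candidates, cfg = scoring_config(),
                             query = NULL, raw_sim = NULL,
                             use_metadata = TRUE) {
  if (!length(candidates)) {
    stop_routing("cannot score an empty candidate list")
  }
  ids <- vapply(candidates, `[[`, character(1), "compound_id")
  if (is.null(raw_sim)) {
    if (is.null(query)) {
      stop("either query spectra or raw_sim must be supplied", call. = FALSE)
    }
    raw_sim <- vapply(candidates, function(r) {
      compound_similarity(query, r, cfg$sim_tolerance)
    }, numeric(1))
  }
  stopifnot(length(raw_sim) == length(candidates))

  cls_recs <- lapply(candidates, `[[`, "classification")
  have_cls <- !vapply(cls_recs, is.null, logical(1))
  raw_class <- rep(0, length(candidates))
  if (any(have_cls)) {
    pool <- category_pool(cls_recs[have_cls])
    raw_class[have_cls] <- vapply(cls_recs[have_cls], raw_class_score,
                                  numeric(1), pool = pool)
  }
  raw_ref <- cap_citations(
    vapply(candidates, `[[`, integer(1), "citation_count"),
    cfg$citation_ceiling)

  s_cfm <- normalize_column(raw_sim)
  s_class <- normalize_column(raw_class)
  s_ref <- normalize_column(raw_ref)
  if (use_metadata) {
    total <- cfg$a_cfm_orig * s_cfm + cfg$a_class * s_class +
      cfg$a_ref * s_ref
  } else {
    total <- s_cfm
  }
  bypass <- raw_sim >= cfg$bypass_threshold
  total[bypass] <- s_cfm[bypass]
  data.frame(compound_id = ids, S_CFM_ORIG_raw = raw_sim,
             S_CFM_ORIG = s_cfm, S_CLASS = s_class, S_REF = s_ref,
             S_TOTAL = total, bypass = bypass, stringsAsFactors = FALSE)
}

#' Rank scored candidates
#'
#' Orders by descending `S_TOTAL`, breaking ties by descending raw
#' similarity and then ascending compound id (for determinism), and assigns
#' competition (min) ranks: candidates with equal `S_TOTAL` share the
#' smallest rank of their group.
#'
#' @param scores Data.frame from [score_candidates()].
#' @param true_id Optional identifier of the known true compound; its rank
#'   is reported as `hit_rank` (`NA` if absent from the list).
#' @return A `ranking_result`: list with `table` (scores plus `rank`,
#'   sorted) and `hit_rank`.
#' @export
rank_candidates <- function(scores, true_id = NULL) {
  if (!is.data.frame(scores) || !nrow(scores)) {
    stop_routing("cannot rank an empty score table")
  }
  ord <- order(-scores$S_TOTAL, -scores$S_CFM_ORIG_raw, scores$compound_id)
  tab <- scores[ord, , drop = FALSE]
  rownames(tab) <- NULL
  # competition ranking on S_TOTAL alone: equal totals share the min rank
  tab$rank <- match(tab$S_TOTAL, tab$S_TOTAL)
  hit_rank <- if (!is.null(true_id)) {
    i <- match(true_id, tab$compound_id)
    if (is.na(i)) NA_integer_ else tab$rank[i]
  } else NA_integer_
  structure(list(table = tab, hit_rank = hit_rank),
            class = "ranking_result")
}

#' @export
print.ranking_result <- function(x, ...) {
  cat("<ranking_result> ", nrow(x$table), " candidates",
      if (!is.na(x$hit_rank)) paste0(", hit rank ", x$hit_rank), "\n",
      sep = "")
  print(utils::head(x$table, 10))
  invisible(x)
}

#' Ranking-quality metrics over a set of identification challenges
#'
#' @param hit_ranks Integer vector of per-challenge ranks of the true
#'   compound (all >= 1). `NA` entries (true compound not retrieved) count
#'   as misses for the top-k counts and are excluded from the averages.
#' @return List with `n`, `top1`, `top3`, `top10` counts, `average_rank`,
#'   `median_rank`, and `medal_score`
#'   (`5 * #rank1 + 3 * #rank2 + 1 * #rank3`).
#' @export
evaluate_ranking <- function(hit_ranks) {
  known <- hit_ranks[!is.na(hit_ranks)]
  if (any(known < 1)) stop("ranks must be >= 1", call. = FALSE)
  list(n = length(hit_ranks),
       top1 = sum(known == 1),
       top3 = sum(known <= 3),
       top10 = sum(known <= 10),
       average_rank = if (length(known)) mean(known) else NA_real_,
       median_rank = if (length(known)) stats::median(known) else NA_real_,
       medal_score = 5 * sum(known == 1) + 3 * sum(known == 2) +
         1 * sum(known == 3))
}

#' Predict the chemical class of a query from its candidate ranking
#'
#' With a unique top-scoring candidate, the prediction is that candidate's
#' direct parent. When several candidates tie at the top score, the
#' prediction is the most frequently occurring category among the direct
#' and alternative parents of all tied candidates; a residual frequency tie
#' is broken lexicographically.
#'
#' @param result A `ranking_result`.
#' @param classifications Named list of `classification_record`s keyed by
#'   compound id (defaults are taken from the ranked candidates if embedded
#'   there is no lookup; pass the library's classification set).
#' @return A single category label.
#' @export
predict_class <- function(result, classifications) {
  stopifnot(inherits(result, "ranking_result"))
  tab <- result$table
  if (!nrow(tab)) stop_routing("empty ranking result")
  top <- tab$compound_id[tab$rank == 1]
  get_rec <- function(id) {
    rec <- classifications[[id]]
    if (is.null(rec)) {
      stop_routing("missing classification for candidate ", id)
    }
    rec
  }
  if (length(top) == 1) {
    return(get_rec(top)$direct_parent)
  }
  cats <- unlist(lapply(top, function(id) record_categories(get_rec(id))),
                 use.names = FALSE)
  freq <- table(cats)
  winners <- names(freq)[freq == max(freq)]
  sort(winners)[1]
}

#' Enumerate the weight grid
#'
#' All non-negative triples `(a_cfm_orig, a_class, a_ref)` summing to 1 at
#' resolution `grid_step`.
#'
#' @param grid_step Step size; must divide 1 evenly (within 1e-9).
#' @return Data.frame with one row per triple.
#' @export
enumerate_weight_grid <- function(grid_step) {
  if (!is.numeric(grid_step) || grid_step <= 0 || grid_step > 1) {
    stop("grid_step must be in (0, 1]", call. = FALSE)
  }
  k <- round(1 / grid_step)
  if (abs(k * grid_step - 1) > 1e-9) {
    stop("grid_step must divide 1 evenly", call. = FALSE)
  }
  g <- expand.grid(i = 0:k, j = 0:k)
  g <- g[g$i + g$j <= k, , drop = FALSE]
  out <- data.frame(a_cfm_orig = g$i / k, a_class = g$j / k,
                    a_ref = (k - g$i - g$j) / k)
  out <- out[order(out$a_cfm_orig, out$a_class), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# precompute the normalized score columns of one task (weight-independent)
prepare_task_columns <- function(task, cfg) {
  sc <- score_candidates(task$candidates, cfg, query = task$query,
                         raw_sim = task$raw_sim)
  list(ids = sc$compound_id, s_cfm = sc$S_CFM_ORIG, s_class = sc$S_CLASS,
       s_ref = sc$S_REF, raw_sim = sc$S_CFM_ORIG_raw,
       true_id = task$true_id)
}

task_top1 <- function(cols, w, cfg) {
  total <- w[1] * cols$s_cfm + w[2] * cols$s_class + w[3] * cols$s_ref
  bypass <- cols$raw_sim >= cfg$bypass_threshold
  total[bypass] <- cols$s_cfm[bypass]
  i <- match(cols$true_id, cols$ids)
  if (is.na(i)) return(FALSE)
  # competition rank 1 means no candidate scores strictly higher
  !any(total > total[i] + 1e-12)
}

#' Grid-search optimization of the scoring weights
#'
#' Enumerates all weight triples at `grid_step` resolution, and per
#' cross-validation fold selects the triple maximizing the top-1
#' identification count on the training split (ties prefer a larger
#' spectral-similarity weight, then a larger citation weight). The reported
#' consensus takes the per-coefficient median across folds, snapped to the
#' grid, with any rounding residue absorbed by the similarity weight so the
#' triple still sums to 1. Deterministic given `seed` (which controls only
#' the fold assignment).
#'
#' @param tasks List of labeled identification tasks; each task is a list
#'   with `query` (spectrum or list of spectra) or a precomputed `raw_sim`
#'   vector, plus `true_id` and `candidates` (list of `library_record`s).
#' @param grid_step Grid resolution (see [enumerate_weight_grid()]).
#' @param folds Number of cross-validation folds (default 5); must not
#'   exceed the number of tasks.
#' @param seed Integer seed for the fold shuffle.
#' @param cfg Base `scoring_config` supplying the bypass threshold and
#'   citation ceiling.
#' @return A `scoring_config` with the consensus weights; the per-fold
#'   selections are attached as attribute `"fold_weights"`.
#' @export
optimize_weights <- function(tasks, grid_step = 0.1, folds = 5, seed = 1,
                             cfg = scoring_config()) {
  if (length(tasks) < folds) {
    stop("need at least as many tasks as folds", call. = FALSE)
  }
  grid <- enumerate_weight_grid(grid_step)
  cols <- lapply(tasks, prepare_task_columns, cfg = cfg)
  fold_of <- with_seed(seed, {
    sample(rep_len(seq_len(folds), length(tasks)))
  })
  pick_best <- function(task_cols) {
    counts <- vapply(seq_len(nrow(grid)), function(g) {
      w <- as.numeric(grid[g, ])
      sum(vapply(task_cols, task_top1, logical(1), w = w, cfg = cfg))
    }, numeric(1))
    best <- which(counts == max(counts))
    # tie rule: larger similarity weight, then larger citation weight
    best <- best[order(-grid$a_cfm_orig[best], -grid$a_ref[best])]
    as.numeric(grid[best[1], ])
  }
  fold_w <- t(vapply(seq_len(folds), function(f) {
    pick_best(cols[fold_of != f])
  }, numeric(3)))
  colnames(fold_w) <- c("a_cfm_orig", "a_class", "a_ref")
  med <- apply(fold_w, 2, stats::median)
  snap <- unname(round(med / grid_step) * grid_step)
  snap[1] <- 1 - snap[2] - snap[3]  # absorb rounding residue
  out <- scoring_config(a_cfm_orig = snap[1], a_class = snap[2],
                        a_ref = snap[3],
                        bypass_threshold = cfg$bypass_threshold,
                        citation_ceiling = cfg$citation_ceiling,
                        mz_tolerance = cfg$mz_tolerance,
                        sim_tolerance = cfg$sim_tolerance)
  attr(out, "fold_weights") <- fold_w
  out
}

#' Identify a query spectrum set against a library
#'
#' End-to-end search: retrieves candidates in the precursor m/z window,
#' scores them with the combined scoring function, and ranks them.
#'
#' @param query A `spectrum` or list of spectra of one compound (the
#'   precursor m/z is read from the first spectrum's metadata unless given).
#' @param lib A `spectral_library`.
#' @param adduct Adduct label of the query.
#' @param cfg A `scoring_config`.
#' @param precursor Optional query precursor m/z override.
#' @param true_id Optional known answer for evaluation.
#' @param use_metadata Drop class/citation terms if `FALSE`.
#' @return A `ranking_result`.
#' @export
identify_compound <- function(query, lib, adduct, cfg = scoring_config(),
                              precursor = NULL, true_id = NULL,
                              use_metadata = TRUE) {
  if (inherits(query, "spectrum")) query <- list(query)
  if (is.null(precursor)) {
    precursor <- query[[1]]$metadata$precursor_mz
    if (is.null(precursor)) {
      stop_routing("query spectra carry no precursor m/z; pass `precursor`")
    }
  }
  cands <- retrieve_candidates(lib, precursor, cfg$mz_tolerance, adduct)
  if (!length(cands)) {
    stop_routing("no library candidates within ", cfg$mz_tolerance,
                 " Da of precursor m/z ", precursor)
  }
  sc <- score_candidates(cands, cfg, query = query,
                         use_metadata = use_metadata)
  rank_candidates(sc, true_id = true_id)
}
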