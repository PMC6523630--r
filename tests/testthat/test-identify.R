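# Candidate retrieval, combined scoring, ranking, metrics, class
# prediction, weight optimization.

proton <- 1.00727646

make_mass_library <- function(precursors) {
  spectral_library(lapply(seq_along(precursors), function(i) {
    library_record(sprintf("L%02d", i), sprintf("compound %d", i),
                   precursors[i] - proton, "C10H20O2")
  }))
}

rand_records <- function(n) {
  cats <- LETTERS[1:6]
  lapply(seq_len(n), function(i) {
    picked <- sample(cats, sample(1:3, 1))
    library_record(sprintf("R%03d", i), sprintf("rand %d", i),
                   500 + i, "C10H20O2",
                   citation_count = sample(1:400, 1),
                   classification = classification_record(
                     sprintf("R%03d", i), picked[1], picked[-1]))
  })
}

test_that("candidate retrieval applies the precursor m/z window", {
  lib <- make_mass_library(c(734.5694, 734.5800, 760.5134))
  hits <- retrieve_candidates(lib, 734.5694, 0.005, "[M+H]+")
  expect_length(hits, 1)
  expect_equal(hits[[1]]$compound_id, "L01")
  expect_length(retrieve_candidates(lib, 734.5694, 0.02, "[M+H]+"), 2)
  expect_error(retrieve_candidates(lib, 734.5694, -1, "[M+H]+"), ">= 0")
  expect_error(retrieve_candidates(lib, 734.5694, 0.01, "[M+X]+"),
               "unknown adduct")
})

test_that("citation capping is a monotone idempotent ceiling at 156", {
  expect_equal(cap_citations(30000L), 156L)
  expect_equal(cap_citations(156L), 156L)
  expect_equal(cap_citations(3L), 3L)
  expect_equal(cap_citations(cap_citations(0:400)), cap_citations(0:400))
  expect_true(all(diff(cap_citations(0:400)) >= 0))
  expect_error(cap_citations(-1L), ">= 0")
})

test_that("scoring weights must be a convex combination", {
  expect_error(scoring_config(0.5, 0.1, 0.3), "sum to 1")
  expect_error(scoring_config(-0.1, 0.4, 0.7), "non-negative")
  cfg <- scoring_config()
  expect_equal(cfg$a_cfm_orig + cfg$a_class + cfg$a_ref, 1)
})

test_that("the combined score reproduces the worked two-candidate example", {
  sc <- score_candidates(two_candidate_records(), raw_sim = c(0.8, 0.4))
  expect_equal(sc$S_CFM_ORIG, c(1.0, 0.5))
  expect_equal(sc$S_CLASS, c(0.5, 1.0))   # class pool {A}, {B, C}
  expect_equal(sc$S_REF, c(1.0, 0.5))
  expect_equal(sc$S_TOTAL, c(0.95, 0.55))
  expect_false(any(sc$bypass))
})

test_that("a single candidate self-normalizes to a total of one", {
  sc <- score_candidates(two_candidate_records()[1], raw_sim = 0.42)
  expect_equal(sc$S_TOTAL, 1.0)
})

test_that("near-perfect spectral matches bypass the metadata terms", {
  sc <- score_candidates(two_candidate_records(), raw_sim = c(0.97, 0.4))
  expect_true(sc$bypass[1])
  expect_false(sc$bypass[2])
  expect_equal(sc$S_TOTAL[1], sc$S_CFM_ORIG[1])
  expect_error(score_candidates(list(), raw_sim = numeric(0)),
               class = "lipidrules_routing_error")
})

test_that("ranking sorts by total score with competition ranks", {
  sc <- score_candidates(two_candidate_records(), raw_sim = c(0.8, 0.4))
  res <- rank_candidates(sc, true_id = "c2")
  expect_equal(res$table$rank, c(1L, 2L))
  expect_equal(res$hit_rank, 2L)

  tied <- data.frame(compound_id = c("a", "b", "c"),
                     S_CFM_ORIG_raw = c(0.5, 0.5, 0.1),
                     S_TOTAL = c(0.9, 0.9, 0.1))
  res2 <- rank_candidates(tied)
  expect_equal(res2$table$rank, c(1L, 1L, 3L))
  expect_error(rank_candidates(tied[0, ]),
               class = "lipidrules_routing_error")
})

test_that("ranking metrics count medals and top-k hits", {
  m <- evaluate_ranking(c(1, 1, 2, 3, 5))
  expect_equal(m$top1, 2); expect_equal(m$top3, 4)
  expect_equal(m$medal_score, 14)
  expect_equal(m$average_rank, 2.4)

  all_gold <- evaluate_ranking(rep(1, 208))
  expect_equal(all_gold$medal_score, 1040)
  expect_equal(all_gold$top1, 208)
  expect_equal(all_gold$top10, 208)

  expect_equal(evaluate_ranking(1)$medal_score, 5)
  expect_error(evaluate_ranking(0), ">= 1")
})

test_that("class prediction uses the top candidate or the tie-pool mode", {
  cls <- list(
    c1 = classification_record("c1", "A", c("B", "C")),
    c2 = classification_record("c2", "B", "D"),
    c3 = classification_record("c3", "Phosphatidylserines"))
  unique_top <- rank_candidates(data.frame(
    compound_id = c("c3", "c1"), S_CFM_ORIG_raw = c(0.9, 0.2),
    S_TOTAL = c(0.9, 0.2)))
  expect_equal(predict_class(unique_top, cls), "Phosphatidylserines")

  tie <- rank_candidates(data.frame(
    compound_id = c("c1", "c2"), S_CFM_ORIG_raw = c(0.5, 0.5),
    S_TOTAL = c(0.8, 0.8)))
  # frequencies: A 1, B 2 (direct of c2 + alternative of c1), C 1, D 1
  expect_equal(predict_class(tie, cls), "B")
  expect_error(predict_class(tie, cls["c1"]), "missing classification")
})

test_that("the weight grid enumerates compositions of one", {
  g <- enumerate_weight_grid(0.5)
  expect_equal(nrow(g), 6L)
  expect_true(all(abs(rowSums(g) - 1) < 1e-12))
  expect_equal(nrow(enumerate_weight_grid(0.1)), choose(10 + 2, 2))
  expect_error(enumerate_weight_grid(0.3), "divide 1 evenly")
  expect_error(enumerate_weight_grid(0), "\\(0, 1\\]")
})

test_that("grid search prefers the similarity weight on similarity-solvable tasks", {
  recs <- two_candidate_records(citations = c(1L, 156L))
  tasks <- lapply(1:6, function(i) {
    list(candidates = recs, raw_sim = c(0.9, 0.2), true_id = "c1")
  })
  out <- optimize_weights(tasks, grid_step = 0.5, folds = 5, seed = 3)
  expect_equal(out$a_cfm_orig, 1)
  expect_equal(out$a_class, 0)
  expect_equal(out$a_ref, 0)
  fw <- attr(out, "fold_weights")
  expect_equal(dim(fw), c(5L, 3L))
  expect_error(optimize_weights(tasks[1:3], 0.5, folds = 5), "as many tasks")
})

test_that("bypass dominance and citation monotonicity hold on random lists", {
  set.seed(2024)
  cfg <- scoring_config()
  for (rep in 1:200) {
    n <- sample(2:8, 1)
    recs <- rand_records(n)
    sims <- runif(n, 0, 0.9)
    # plant a dominant near-perfect match
    j <- sample(n, 1)
    sims[j] <- runif(1, 0.95, 1)
    res <- rank_candidates(score_candidates(recs, cfg, raw_sim = sims))
    expect_equal(res$table$compound_id[1], recs[[j]]$compound_id)
    expect_equal(res$table$rank[1], 1L)

    # raising a sub-ceiling citation count never lowers that total
    k <- sample(n, 1)
    sc1 <- score_candidates(recs, cfg, raw_sim = sims)
    recs2 <- recs
    recs2[[k]]$citation_count <- min(156L,
                                     recs2[[k]]$citation_count + 37L)
    sc2 <- score_candidates(recs2, cfg, raw_sim = sims)
    expect_gte(sc2$S_TOTAL[k], sc1$S_TOTAL[k] - 1e-12)
  }
})

test_that("end-to-end identification finds the planted compound", {
  reg <- load_registry()
  lib <- generate_library(synth_config(25, seed = 9), reg)
  id <- names(lib$records)[10]
  res <- identify_compound(lib$records[[id]]$spectra, lib,
                           lib$records[[id]]$spectra[[1]]$metadata$adduct,
                           true_id = id)
  expect_equal(res$hit_rank, 1L)
  expect_error(identify_compound(lib$records[[id]]$spectra, lib,
                                 "[M+H]+", precursor = 9999),
               class = "lipidrules_routing_error")
})
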