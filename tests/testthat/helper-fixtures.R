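# Test helpers: quick constructors and independent oracles.

spec_of <- function(mz, intensity, ...) {
  spectrum(mz, intensity, metadata = list(...))
}

random_test_spectrum <- function(seed, n_min = 1, n_max = 8) {
  set.seed(seed)
  n <- sample(n_min:n_max, 1)
  spectrum(sort(runif(n, 50, 1000)) + seq_len(n) * 1e-3,
           runif(n, 1, 100))
}

# Independent cosine oracle: normalizes, then repeatedly picks the single
# closest unmatched in-window pair (scanning all pairs each round; ties by
# the lower m/z of the second then first spectrum), and accumulates the
# cosine over the union vectors. A deliberately different code path from
# align_peaks()/dot_product_similarity().
oracle_cosine <- function(a, b, tol) {
  ia <- a$peaks$intensity * 100 / max(a$peaks$intensity)
  ib <- b$peaks$intensity * 100 / max(b$peaks$intensity)
  mza <- a$peaks$mz; mzb <- b$peaks$mz
  free_a <- rep(TRUE, length(mza)); free_b <- rep(TRUE, length(mzb))
  num <- 0
  repeat {
    best <- NULL; best_key <- c(Inf, Inf, Inf)
    for (i in which(free_a)) for (j in which(free_b)) {
      d <- abs(mza[i] - mzb[j])
      if (d <= tol + 1e-12) {
        key <- c(d, mzb[j], mza[i])
        if (key[1] < best_key[1] ||
            (key[1] == best_key[1] && (key[2] < best_key[2] ||
             (key[2] == best_key[2] && key[3] < best_key[3])))) {
          best <- c(i, j); best_key <- key
        }
      }
    }
    if (is.null(best)) break
    num <- num + ia[best[1]] * ib[best[2]]
    free_a[best[1]] <- FALSE; free_b[best[2]] <- FALSE
  }
  denom <- sqrt(sum(ia^2)) * sqrt(sum(ib^2))
  if (denom == 0) 0 else num / denom
}

# Independent molecular-formula oracle: assembles element counts directly
# from hard-coded backbone counts and per-linkage chain arithmetic,
# subtracting one water per condensation.
oracle_backbones <- list(
  "1-Monoacylglycerols"             = c(C = 3, H = 8, O = 3),
  "2-Monoacylglycerols"             = c(C = 3, H = 8, O = 3),
  "1,2-Diacylglycerols"             = c(C = 3, H = 8, O = 3),
  "Triacylglycerols"                = c(C = 3, H = 8, O = 3),
  "Phosphatidic acids"              = c(C = 3, H = 9, O = 6, P = 1),
  "Phosphatidylcholines"            = c(C = 8, H = 20, N = 1, O = 6, P = 1),
  "Phosphatidylethanolamines"       = c(C = 5, H = 14, N = 1, O = 6, P = 1),
  "Lysophosphatidylcholines"        = c(C = 8, H = 20, N = 1, O = 6, P = 1),
  "Lysophosphatidic acids"          = c(C = 3, H = 9, O = 6, P = 1),
  "Phosphatidylserines"             = c(C = 6, H = 14, N = 1, O = 8, P = 1),
  "Cardiolipins"                    = c(C = 9, H = 22, O = 13, P = 2),
  "Phosphatidylglycerols"           = c(C = 6, H = 15, O = 8, P = 1),
  "Lysophosphatidylglycerols"       = c(C = 6, H = 15, O = 8, P = 1),
  "Plasmanyl-PC"                    = c(C = 8, H = 20, N = 1, O = 6, P = 1),
  "Plasmenyl-PC"                    = c(C = 8, H = 20, N = 1, O = 6, P = 1),
  "1-Alkanylglycerophosphocholines" = c(C = 8, H = 20, N = 1, O = 6, P = 1),
  "1-Alkenylglycerophosphocholines" = c(C = 8, H = 20, N = 1, O = 6, P = 1),
  "Phosphatidylinositols"           = c(C = 9, H = 19, O = 11, P = 1),
  "Lysophosphatidylinositols"       = c(C = 9, H = 19, O = 11, P = 1)
)

oracle_lipid_counts <- function(s) {
  add <- function(tot, inc) {
    for (el in names(inc)) {
      tot[el] <- (if (el %in% names(tot)) tot[[el]] else 0) + inc[[el]]
    }
    tot
  }
  free_unit <- function(ch) {
    n <- ch$carbons; d <- ch$double_bonds
    switch(ch$linkage,
      acyl    = c(C = n, H = 2 * n - 2 * d, O = 2),       # fatty acid
      alkyl   = c(C = n, H = 2 * n + 2 - 2 * d, O = 1),   # fatty alcohol
      alkenyl = c(C = n, H = 2 * n - 2 * d, O = 1))       # enol form
  }
  if (s$lipid_class %in% c("Ceramides", "Sphingomyelins")) {
    b <- s$chains[[1]]
    tot <- c(C = b$carbons, H = 2 * b$carbons + 3 - 2 * b$double_bonds,
             N = 1, O = 2)
    tot <- add(tot, free_unit(s$chains[[2]]))
    tot <- add(tot, c(H = -2, O = -1))
    if (s$lipid_class == "Sphingomyelins") {
      tot <- add(tot, c(C = 5, H = 14, N = 1, O = 4, P = 1))
      tot <- add(tot, c(H = -2, O = -1))
    }
  } else {
    tot <- oracle_backbones[[s$lipid_class]]
    for (ch in s$chains) {
      tot <- add(tot, free_unit(ch))
      tot <- add(tot, c(H = -2, O = -1))
    }
  }
  tot[tot != 0]
}

# random structure over all 21 template classes (for round-trip and
# formula fuzzing)
random_test_structure <- function(seed) {
  set.seed(seed)
  cls <- sample(lipid_class_labels(), 1)
  n <- switch(cls,
    "Triacylglycerols" = 3, "Cardiolipins" = 4,
    "1-Monoacylglycerols" = 1, "2-Monoacylglycerols" = 1,
    "Lysophosphatidylcholines" = 1, "Lysophosphatidic acids" = 1,
    "Lysophosphatidylglycerols" = 1, "Lysophosphatidylinositols" = 1,
    "1-Alkanylglycerophosphocholines" = 1,
    "1-Alkenylglycerophosphocholines" = 1,
    2)
  linkages <- switch(cls,
    "Plasmanyl-PC" = c("alkyl", "acyl"),
    "Plasmenyl-PC" = c("alkenyl", "acyl"),
    "1-Alkanylglycerophosphocholines" = "alkyl",
    "1-Alkenylglycerophosphocholines" = "alkenyl",
    "Ceramides" = c("sphingoid", "acyl"),
    "Sphingomyelins" = c("sphingoid", "acyl"),
    rep("acyl", n))
  chains <- lapply(seq_len(n), function(i) {
    carbons <- sample(8:24, 1)
    dbl <- sample(0:min(4, carbons - 1), 1)
    lipidrules:::new_chain(carbons, dbl, linkages[[i]], sn = i)
  })
  lipid_structure(cls, chains)
}

# small two-candidate score fixture used in several tests
two_candidate_records <- function(citations = c(100L, 50L)) {
  list(
    library_record("c1", "cand one", 700, "C10H20O2",
                   citation_count = citations[1],
                   classification = classification_record("c1", "A")),
    library_record("c2", "cand two", 700.01, "C10H21O2",
                   citation_count = citations[2],
                   classification = classification_record("c2", "B", "C")))
}
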