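# Rule registry loading, routing, rule application, spectrum prediction.

reg <- load_registry()

test_that("packaged registry satisfies its manifest invariants at load", {
  expect_equal(nrow(reg$manifest), 21L)
  expect_equal(sum(reg$manifest$rule_count), 344L)
  expect_equal(sum(lengths(reg$manifest$adducts)), 50L)
  expect_true(all(vapply(reg$rules, function(r) {
    i <- match(r$lipid_class, reg$manifest$class)
    r$adduct_label %in% reg$manifest$adducts[[i]]
  }, logical(1))))
})

test_that("registries violating the invariants are rejected at load", {
  lines <- readLines(default_registry_path())
  # corrupt one manifest count: total no longer 344
  bad <- sub("^M\tPhosphatidylcholines\t41", "M\tPhosphatidylcholines\t40",
             lines)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(bad, p1)
  expect_error(load_registry(p1), "sum to 344")
  # add a rule for an unmanifested adduct
  extra <- c(lines, paste("R", "XX_01", "Phosphatidylcholines", "[M+NH4]+",
                          "neutral_loss", "-", "H2O", "precursor",
                          "absent", "low", "low", "bogus", "-", sep = "\t"))
  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(extra, p2)
  expect_error(load_registry(p2), "not covered by the manifest")
})

test_that("routing separates covered lipids, uncovered lipids, non-lipids", {
  pc <- parse_lipid_name("PC(16:0/16:0)")
  expect_equal(route_compound(pc, "[M+H]+", reg), "rule_based")
  expect_equal(route_compound(pc, "[M+NH4]+", reg), "error_uncovered_lipid")
  expect_equal(route_compound(list(smiles = "CCO"), "[M+H]+", reg),
               "fallback_external")
})

test_that("category intensities map bins to fixed relative abundances", {
  expect_equal(category_intensity(c("maximum", "high", "medium", "low",
                                    "absent")),
               c(100, 75, 37.5, 8, 0))
  expect_error(category_intensity("huge"), "unknown intensity category")
})

test_that("rule application computes fragment m/z from the encoded pattern", {
  pc <- parse_lipid_name("PC(16:0/16:0)")
  by_id <- setNames(reg$rules, vapply(reg$rules, `[[`, "", "rule_id"))
  head_rule <- by_id[["PC_H_05"]]
  expect_equal(round(apply_rule(head_rule, pc, "[M+H]+")$mz, 4), 184.0733)
  sn1_acid <- by_id[["PC_H_06"]]
  expect_equal(round(apply_rule(sn1_acid, pc, "[M+H]+")$mz, 4), 478.3292)
  ps <- parse_lipid_name("PS(16:0/18:1)")
  expect_error(apply_rule(head_rule, ps, "[M+H]+"), "targets class")
  expect_error(apply_rule(head_rule, pc, "[M+Na]+"), "targets adduct")
})

test_that("PC [M+H]+ prediction reproduces the consensus energy pattern", {
  pc <- parse_lipid_name("PC(16:0/16:0)")
  s10 <- predict_spectrum(pc, "[M+H]+", 10, reg)
  s20 <- predict_spectrum(pc, "[M+H]+", 20, reg)
  s40 <- predict_spectrum(pc, "[M+H]+", 40, reg)
  # 10 eV: intact precursor only
  expect_equal(s10$peaks$mz, 734.5694)
  # 20 eV: precursor plus the phosphocholine head-group ion
  expect_equal(s20$peaks$mz, c(184.0733, 734.5694))
  # 40 eV: ten fragment peaks beside the precursor; head group is base peak
  expect_equal(nrow(s40$peaks), 11L)
  expect_equal(sum(s40$peaks$mz != 734.5694), 10L)
  expect_equal(s40$peaks$mz[which.max(s40$peaks$intensity)], 184.0733)
  expect_error(predict_spectrum(pc, "[M+H]+", 30, reg), "10, 20 or 40")
  expect_error(predict_spectrum(pc, "[M+NH4]+", 40, reg),
               class = "lipidrules_routing_error")
})

covered_examples <- list(
  c("PC(16:0/18:1)", "[M+H]+"), c("PC(16:0/18:1)", "[M+Na]+"),
  c("PC(16:0/18:1)", "[M+Li]+"), c("PC(16:0/18:1)", "[M+Cl]-"),
  c("PS(16:0/18:1)", "[M-H]-"), c("PS(16:0/18:1)", "[M+H]+"),
  c("PS(16:0/18:1)", "[M+Na]+"), c("PS(16:0/18:1)", "[M+Li]+"),
  c("PA(16:0/18:1)", "[M-H]-"), c("PA(16:0/18:1)", "[M+H]+"),
  c("PA(16:0/18:1)", "[M+Na]+"),
  c("LPC(16:0)", "[M+H]+"), c("LPC(16:0)", "[M+Na]+"),
  c("LPC(16:0)", "[M+Li]+"), c("LPC(16:0)", "[M+Cl]-"),
  c("DG(16:0/18:1)", "[M+NH4]+"), c("DG(16:0/18:1)", "[M+Na]+"),
  c("TG(16:0/18:1/18:2)", "[M+NH4]+"), c("TG(16:0/18:1/18:2)", "[M+Na]+"),
  c("TG(16:0/18:1/18:2)", "[M+Li]+"),
  c("CL(18:0/18:1/18:0/18:2)", "[M-2H]2-"))

test_that("every encoded class/adduct keeps the precursor at all energies", {
  for (ex in covered_examples) {
    s <- parse_lipid_name(ex[1])
    prec <- round(precursor_mz(s, ex[2]), 4)
    for (e in c(10, 20, 40)) {
      sp <- predict_spectrum(s, ex[2], e, reg)
      expect_true(prec %in% sp$peaks$mz,
                  info = paste(ex[1], ex[2], e, "eV"))
      expect_true(all(sp$peaks$intensity > 0))
      # singly charged adducts never yield fragments above the precursor
      if (!grepl("2-", ex[2], fixed = TRUE)) {
        expect_true(all(sp$peaks$mz < prec + 1e-6),
                    info = paste(ex[1], ex[2], e, "eV"))
      }
    }
  }
})

test_that("prediction is deterministic to the byte", {
  s <- parse_lipid_name("PS(16:0/18:1(9Z))")
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_spectra(predict_spectrum(s, "[M-H]-", 40, reg), p1, "msp")
  write_spectra(predict_spectrum(s, "[M-H]-", 40, reg), p2, "msp")
  expect_identical(readLines(p1), readLines(p2))
})

test_that("chain-dependent peaks shift by one CH2 per added carbon", {
  a <- predict_spectrum(parse_lipid_name("PC(16:0/16:0)"), "[M+H]+", 40, reg)
  b <- predict_spectrum(parse_lipid_name("PC(17:0/16:0)"), "[M+H]+", 40, reg)
  shift <- function(sp, what) {
    sp$peaks$mz[grepl(what, sp$peaks$annotation, fixed = TRUE)]
  }
  ch2 <- 14.01565
  # constant head-group fragments do not move
  expect_equal(shift(b, "phosphocholine head group"),
               shift(a, "phosphocholine head group"))
  # precursor-derived and sn-2 peaks move by exactly one CH2
  for (what in c("precursor", "water loss", "sn-2 chain as ketene")) {
    expect_equal(shift(b, what), shift(a, what) + ch2, tolerance = 1e-4)
  }
  # the sn-1 acid-loss peak is insensitive to the sn-1 chain length
  expect_equal(shift(b, "sn-1 chain as free fatty acid"),
               shift(a, "sn-1 chain as free fatty acid"))
})
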