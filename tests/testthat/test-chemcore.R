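# Elemental formulas, monoisotopic masses, adduct m/z, lipid shorthand.

test_that("Hill-style formula parsing handles counts, implicit 1 and errors", {
  f <- parse_formula("C5H14NO4P")
  expect_equal(as.numeric(f[c("C", "H", "N", "O", "P")]), c(5, 14, 1, 4, 1))
  expect_length(parse_formula(""), 0)
  g <- parse_formula("C2H6O4P")
  expect_equal(as.numeric(g[c("C", "H", "O", "P")]), c(2, 6, 4, 1))
  expect_error(parse_formula("C2Xx4"), "unknown element")
  expect_error(parse_formula("c2h4"), "malformed|unknown")
  # repeated element tokens accumulate
  expect_equal(parse_formula("CH3CH3"), parse_formula("C2H6"))
})

test_that("formula combination is element-wise and rejects negative counts", {
  res <- combine_formulas("C40H80NO8P", "C5H14NO4P", sign = -1)
  expect_equal(format_formula(res), "C35H66O4")
  f <- parse_formula("C6H12O6")
  expect_equal(combine_formulas(f, parse_formula("")), f)
  expect_error(combine_formulas("C2H6", "C3H6", sign = -1),
               "negative count")
})

test_that("monoisotopic masses match IUPAC sums at reported precision", {
  expect_equal(round(monoisotopic_mass("C5H14NO4P"), 4), 183.0660)
  expect_equal(monoisotopic_mass(parse_formula("")), 0)
  expect_equal(round(monoisotopic_mass("C2H6O4P"), 4), 125.0004)
  expect_error(monoisotopic_mass(structure(c(Zz = 1), class = "elemental_formula",
                                           names = "Zz")),
               "no mass-table entry")
})

test_that("mass additivity holds to 1e-9 relative over random formulas", {
  set.seed(41)
  syms <- c("C", "H", "N", "O", "P", "S", "Na", "Cl")
  for (i in 1:50) {
    a <- lipidrules:::new_formula(setNames(sample(0:30, 4), sample(syms, 4)))
    b <- lipidrules:::new_formula(setNames(sample(0:30, 4), sample(syms, 4)))
    lhs <- monoisotopic_mass(combine_formulas(a, b, 1))
    rhs <- monoisotopic_mass(a) + monoisotopic_mass(b)
    expect_lt(abs(lhs - rhs), 1e-9 * max(1, rhs))
  }
})

test_that("adduct m/z uses the electron-corrected convention", {
  # anchors carry 4-dp inputs, so compare at 1e-4 rather than re-rounding
  expect_equal(adduct_mz(733.5622, "[M+H]+"), 734.5694, tolerance = 1e-4)
  expect_equal(adduct_mz(733.5622, "[M-H]-"), 732.5549, tolerance = 1e-4)
  expect_equal(round(adduct_mz(1457.0000, "[M-2H]2-"), 4), 727.4927)
  expect_error(adduct_spec("[M+K]+"), "unknown adduct")
  expect_error(adduct_mz(-5, "[M+H]+"), "positive")
  # protonated/deprotonated pair differs by exactly two proton masses
  for (m in c(100.05, 733.5622, 1457)) {
    expect_equal(adduct_mz(m, "[M+H]+") - adduct_mz(m, "[M-H]-"),
                 2 * 1.00727646, tolerance = 1e-7)
  }
})

test_that("lipid shorthand parsing resolves classes, linkages, annotations", {
  s <- parse_lipid_name("PC(16:0/16:0)")
  expect_equal(s$lipid_class, "Phosphatidylcholines")
  expect_equal(vapply(s$chains, `[[`, integer(1), "carbons"), c(16L, 16L))
  expect_equal(vapply(s$chains, `[[`, character(1), "linkage"),
               rep("acyl", 2))

  ps <- parse_lipid_name("PS(16:0/18:1(9Z))")
  expect_equal(ps$lipid_class, "Phosphatidylserines")
  expect_equal(ps$chains[[2]]$double_bonds, 1L)
  expect_equal(ps$chains[[2]]$annotation, "9Z")

  expect_equal(parse_lipid_name("PC(O-16:0/16:0)")$lipid_class,
               "Plasmanyl-PC")
  expect_equal(parse_lipid_name("PC(P-16:0/18:1)")$lipid_class,
               "Plasmenyl-PC")
  expect_equal(parse_lipid_name("LPC(O-16:0)")$lipid_class,
               "1-Alkanylglycerophosphocholines")
  expect_equal(parse_lipid_name("PC(16:0/0:0)")$lipid_class,
               "Lysophosphatidylcholines")
  expect_equal(parse_lipid_name("MG(0:0/18:1/0:0)")$lipid_class,
               "2-Monoacylglycerols")
  expect_equal(parse_lipid_name("SM(d18:1/16:0)")$lipid_class,
               "Sphingomyelins")
  expect_equal(parse_lipid_name(" PC( 16:0 / 16:0 ) ")$canonical_name,
               "PC(16:0/16:0)")

  expect_error(parse_lipid_name("PX(1:2)"), "unknown lipid class prefix")
  expect_error(parse_lipid_name("PC(16:0)"), "2 chain")
  expect_error(parse_lipid_name("PC(16:20/16:0)"), "double bonds")
})

test_that("canonical names round-trip through the parser", {
  for (seed in 1:120) {
    s <- random_test_structure(seed)
    s2 <- parse_lipid_name(canonical_name(s))
    expect_equal(s2$lipid_class, s$lipid_class, info = canonical_name(s))
    expect_equal(s2$chains, s$chains, info = canonical_name(s))
  }
})

test_that("lipid formulas match known compositions and are geometry-blind", {
  expect_equal(format_formula(lipid_formula(parse_lipid_name("PC(16:0/16:0)"))),
               "C40H80NO8P")
  expect_equal(format_formula(lipid_formula(parse_lipid_name("PS(16:0/18:1(9Z))"))),
               "C40H76NO10P")
  expect_equal(format_formula(lipid_formula(parse_lipid_name("Cer(d18:1/16:0)"))),
               "C34H67NO3")
  expect_equal(format_formula(lipid_formula(parse_lipid_name("SM(d18:1/16:0)"))),
               "C39H79N2O6P")
  expect_equal(format_formula(lipid_formula(parse_lipid_name("CL(18:0/18:0/18:0/18:0)"))),
               "C81H158O17P2")
  # double-bond position/geometry annotations never change the mass
  plain <- parse_lipid_name("PC(16:0/18:1)")
  annotated <- parse_lipid_name("PC(16:0/18:1(9Z))")
  expect_equal(lipid_formula(plain), lipid_formula(annotated))
})

test_that("lipid formulas agree with the atom-by-atom oracle on fuzzed structures", {
  for (seed in 1:220) {
    s <- random_test_structure(seed)
    want <- oracle_lipid_counts(s)
    got <- lipid_formula(s)
    expect_equal(sort(names(got)), sort(names(want)),
                 info = canonical_name(s))
    expect_equal(as.numeric(got[names(want)]), as.numeric(want),
                 info = canonical_name(s))
  }
})
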