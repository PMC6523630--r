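# Lipid shorthand parsing and composition templates.
#
# Lipids are treated as modular molecules: a class-specific backbone plus a
# fixed number of fatty chains, each described by carbon count, double-bond
# count, linkage (acyl ester, alkyl ether, alkenyl vinyl-ether, or sphingoid
# base) and optional double-bond position/geometry annotations. Annotations
# such as (9Z) are parsed and retained but never affect mass or
# fragmentation: the rules cannot distinguish stereoisomers or regiomers.

# The 21 covered lipid classes. `backbone` is the fully hydroxylated
# zero-chain scaffold; each attached chain condenses out one H2O.
.lipid_classes <- list(
  "1-Monoacylglycerols"             = list(prefix = "MG",  n_chains = 1L, backbone = "C3H8O3",    kind = "glycero"),
  "2-Monoacylglycerols"             = list(prefix = "MG",  n_chains = 1L, backbone = "C3H8O3",    kind = "glycero"),
  "1,2-Diacylglycerols"             = list(prefix = "DG",  n_chains = 2L, backbone = "C3H8O3",    kind = "glycero"),
  "Triacylglycerols"                = list(prefix = "TG",  n_chains = 3L, backbone = "C3H8O3",    kind = "glycero"),
  "Phosphatidic acids"              = list(prefix = "PA",  n_chains = 2L, backbone = "C3H9O6P",   kind = "glycero"),
  "Phosphatidylcholines"            = list(prefix = "PC",  n_chains = 2L, backbone = "C8H20NO6P", kind = "glycero"),
  "Phosphatidylethanolamines"       = list(prefix = "PE",  n_chains = 2L, backbone = "C5H14NO6P", kind = "glycero"),
  "Lysophosphatidylcholines"        = list(prefix = "LPC", n_chains = 1L, backbone = "C8H20NO6P", kind = "glycero"),
  "Lysophosphatidic acids"          = list(prefix = "LPA", n_chains = 1L, backbone = "C3H9O6P",   kind = "glycero"),
  "Phosphatidylserines"             = list(prefix = "PS",  n_chains = 2L, backbone = "C6H14NO8P", kind = "glycero"),
  "Ceramides"                       = list(prefix = "Cer", n_chains = 2L, backbone = NA,          kind = "sphingo"),
  "Sphingomyelins"                  = list(prefix = "SM",  n_chains = 2L, backbone = NA,          kind = "sphingo"),
  "Cardiolipins"                    = list(prefix = "CL",  n_chains = 4L, backbone = "C9H22O13P2", kind = "glycero"),
  "Phosphatidylglycerols"           = list(prefix = "PG",  n_chains = 2L, backbone = "C6H15O8P",  kind = "glycero"),
  "Lysophosphatidylglycerols"       = list(prefix = "LPG", n_chains = 1L, backbone = "C6H15O8P",  kind = "glycero"),
  "Plasmanyl-PC"                    = list(prefix = "PC",  n_chains = 2L, backbone = "C8H20NO6P", kind = "glycero"),
  "Plasmenyl-PC"                    = list(prefix = "PC",  n_chains = 2L, backbone = "C8H20NO6P", kind = "glycero"),
  "1-Alkanylglycerophosphocholines" = list(prefix = "LPC", n_chains = 1L, backbone = "C8H20NO6P", kind = "glycero"),
  "1-Alkenylglycerophosphocholines" = list(prefix = "LPC", n_chains = 1L, backbone = "C8H20NO6P", kind = "glycero"),
  "Phosphatidylinositols"           = list(prefix = "PI",  n_chains = 2L, backbone = "C9H19O11P", kind = "glycero"),
  "Lysophosphatidylinositols"       = list(prefix = "LPI", n_chains = 1L, backbone = "C9H19O11P", kind = "glycero")
)

#' Covered lipid class labels
#' @return Character vector of the 21 covered lipid class labels.
#' @export
lipid_class_labels <- function() names(.lipid_classes)

new_chain <- function(carbons, double_bonds, linkage = "acyl",
                      annotation = "", sn = NA_integer_) {
  list(carbons = as.integer(carbons), double_bonds = as.integer(double_bonds),
       linkage = linkage, annotation = annotation, sn = as.integer(sn))
}

# one chain token, e.g. "16:0", "18:1(9Z)", "O-16:0", "P-18:0", "d18:1"
parse_chain_token <- function(tok, sn) {
  m <- regmatches(tok, regexec(
    "^(O-|P-|d)?([0-9]+):([0-9]+)(\\(([^()]*)\\))?$", tok))[[1]]
  if (!length(m)) stop_parse("malformed chain token ", sQuote(tok))
  linkage <- switch(m[2], "O-" = "alkyl", "P-" = "alkenyl",
                    "d" = "sphingoid", "acyl")
  carbons <- as.integer(m[3]); dbl <- as.integer(m[4])
  if (carbons > 0 && dbl > carbons - 1) {
    stop_parse("chain ", sQuote(tok), ": double bonds must be <= carbons - 1")
  }
  new_chain(carbons, dbl, linkage, annotation = m[6], sn = sn)
}

#' Construct a lipid structure
#'
#' Low-level constructor; most users should call [parse_lipid_name()].
#' Validates that the chain count and linkage types match the class template.
#'
#' @param lipid_class One of the 21 covered class labels.
#' @param chains List of chain descriptors (from `parse_chain_token`-style
#'   lists with `carbons`, `double_bonds`, `linkage`, `annotation`, `sn`).
#' @return An object of class `lipid_structure`.
#' @export
lipid_structure <- function(lipid_class, chains) {
  tmpl <- .lipid_classes[[lipid_class]]
  if (is.null(tmpl)) stop_parse("unknown lipid class ", sQuote(lipid_class))
  if (length(chains) != tmpl$n_chains) {
    stop_parse(lipid_class, " requires ", tmpl$n_chains, " chain(s), got ",
               length(chains))
  }
  for (ch in chains) {
    if (ch$carbons < 1) stop_parse("chain must have >= 1 carbon")
    if (ch$double_bonds < 0 || ch$double_bonds > ch$carbons - 1) {
      stop_parse("chain double bonds must be in [0, carbons - 1]")
    }
  }
  expected_linkage <- switch(lipid_class,
    "Plasmanyl-PC" = c("alkyl", "acyl"),
    "Plasmenyl-PC" = c("alkenyl", "acyl"),
    "1-Alkanylglycerophosphocholines" = "alkyl",
    "1-Alkenylglycerophosphocholines" = "alkenyl",
    "Ceramides" = c("sphingoid", "acyl"),
    "Sphingomyelins" = c("sphingoid", "acyl"),
    rep("acyl", tmpl$n_chains))
  got <- vapply(chains, `[[`, character(1), "linkage")
  if (!identical(unname(got), unname(expected_linkage))) {
    stop_parse(lipid_class, ": chain linkages (", paste(got, collapse = ","),
               ") do not match the class template (",
               paste(expected_linkage, collapse = ","), ")")
  }
  # canonical sn numbering: the single chain of a 2-monoacylglycerol sits
  # at sn-2 regardless of how the caller indexed it
  if (lipid_class == "2-Monoacylglycerols") chains[[1]]$sn <- 2L
  s <- structure(list(lipid_class = lipid_class, chains = chains,
                      canonical_name = NA_character_),
                 class = "lipid_structure")
  s$canonical_name <- canonical_name(s)
  s
}

# resolve (prefix, parsed chain tokens incl. 0:0 placeholders) to a class
resolve_class <- function(prefix, chains) {
  real <- Filter(function(ch) ch$carbons > 0, chains)
  n_real <- length(real)
  pick <- function(label) list(lipid_class = label, chains = real)
  switch(prefix,
    "PC" = {
      if (length(chains) != 2) stop_parse("PC requires 2 chain positions")
      if (n_real == 1) {
        ch <- real[[1]]
        return(pick(switch(ch$linkage, alkyl = "1-Alkanylglycerophosphocholines",
                           alkenyl = "1-Alkenylglycerophosphocholines",
                           "Lysophosphatidylcholines")))
      }
      l1 <- chains[[1]]$linkage
      pick(switch(l1, alkyl = "Plasmanyl-PC", alkenyl = "Plasmenyl-PC",
                  "Phosphatidylcholines"))
    },
    "LPC" = {
      if (n_real != 1) stop_parse("LPC requires exactly 1 chain")
      ch <- real[[1]]
      pick(switch(ch$linkage, alkyl = "1-Alkanylglycerophosphocholines",
                  alkenyl = "1-Alkenylglycerophosphocholines",
                  "Lysophosphatidylcholines"))
    },
    "PS" = pick("Phosphatidylserines"),
    "PA" = pick("Phosphatidic acids"),
    "PE" = pick("Phosphatidylethanolamines"),
    "PG" = pick("Phosphatidylglycerols"),
    "PI" = pick("Phosphatidylinositols"),
    "LPA" = pick("Lysophosphatidic acids"),
    "LPG" = pick("Lysophosphatidylglycerols"),
    "LPI" = pick("Lysophosphatidylinositols"),
    "MG" = {
      if (n_real != 1) stop_parse("MG requires exactly 1 nonzero chain")
      sn2 <- length(chains) >= 2 && chains[[2]]$carbons > 0
      pick(if (sn2) "2-Monoacylglycerols" else "1-Monoacylglycerols")
    },
    "DG" = {
      if (n_real != 2) stop_parse("DG requires exactly 2 nonzero chains")
      pick("1,2-Diacylglycerols")
    },
    "TG" = pick("Triacylglycerols"),
    "CL" = pick("Cardiolipins"),
    "Cer" = pick("Ceramides"),
    "SM" = pick("Sphingomyelins"),
    stop_parse("unknown lipid class prefix ", sQuote(prefix))
  )
}

#' Parse a lipid shorthand name
#'
#' Parses class-prefix shorthand such as `"PC(16:0/16:0)"` or
#' `"PS(16:0/18:1(9Z))"`. `/` separates sn-positions; `O-` and `P-` chain
#' prefixes denote alkyl (ether) and alkenyl (vinyl-ether) linkage; a `d`
#' prefix marks the dihydroxy sphingoid base of ceramides and sphingomyelins;
#' `0:0` positions are placeholders. Whitespace is ignored.
#'
#' @param text Shorthand name.
#' @return A `lipid_structure` with resolved class and chain descriptors.
#' @examples
#' parse_lipid_name("PC(16:0/16:0)")
#' @export
parse_lipid_name <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- gsub("[[:space:]]", "", text)
  m <- regmatches(text, regexec("^([A-Za-z]+)\\((.*)\\)$", text))[[1]]
  if (!length(m)) stop_parse("cannot parse lipid shorthand ", sQuote(text))
  prefix <- m[2]
  known_prefixes <- c("PC", "LPC", "PS", "PA", "PE", "PG", "PI", "LPA",
                      "LPG", "LPI", "MG", "DG", "TG", "CL", "Cer", "SM")
  if (!prefix %in% known_prefixes) {
    stop_parse("unknown lipid class prefix ", sQuote(prefix))
  }
  toks <- strsplit(m[3], "/", fixed = TRUE)[[1]]
  if (!length(toks)) stop_parse("no chains in ", sQuote(text))
  chains <- lapply(seq_along(toks), function(i) {
    tok <- toks[[i]]
    if (grepl("^0:0$", tok)) new_chain(0L, 0L, "acyl", sn = i)
    else parse_chain_token(tok, sn = i)
  })
  res <- resolve_class(prefix, chains)
  lipid_structure(res$lipid_class, res$chains)
}

format_chain <- function(ch) {
  pre <- switch(ch$linkage, alkyl = "O-", alkenyl = "P-", sphingoid = "d", "")
  ann <- if (!is.null(ch$annotation) && nzchar(ch$annotation)) {
    paste0("(", ch$annotation, ")")
  } else ""
  paste0(pre, ch$carbons, ":", ch$double_bonds, ann)
}

#' Canonical shorthand name of a lipid structure
#'
#' Inverse of [parse_lipid_name()]: `parse_lipid_name(canonical_name(s))`
#' reproduces `s`.
#'
#' @param s A `lipid_structure`.
#' @return The shorthand name as a single string.
#' @export
canonical_name <- function(s) {
  stopifnot(inherits(s, "lipid_structure"))
  tmpl <- .lipid_classes[[s$lipid_class]]
  toks <- vapply(s$chains, format_chain, character(1))
  if (s$lipid_class == "2-Monoacylglycerols") {
    toks <- c("0:0", toks, "0:0")
  }
  paste0(tmpl$prefix, "(", paste(toks, collapse = "/"), ")")
}

#' @export
print.lipid_structure <- function(x, ...) {
  cat("<lipid_structure> ", x$canonical_name, " [", x$lipid_class, "]\n",
      sep = "")
  invisible(x)
}

# net elemental contribution of a condensed chain (chain unit minus H2O)
chain_net_formula <- function(ch) {
  n <- ch$carbons; d <- ch$double_bonds
  counts <- switch(ch$linkage,
    acyl    = c(C = n, H = 2 * n - 2 - 2 * d, O = 1),
    alkyl   = c(C = n, H = 2 * n - 2 * d),
    alkenyl = c(C = n, H = 2 * n - 2 - 2 * d),
    stop("chain_net_formula is undefined for linkage ", ch$linkage))
  new_formula(counts)
}

# free (uncondensed) leaving-group formula of a chain, by leaving form
chain_leaving_formula <- function(ch, form = c("acid", "ketene", "alkene")) {
  form <- match.arg(form)
  n <- ch$carbons; d <- ch$double_bonds
  counts <- switch(form,
    acid   = c(C = n, H = 2 * n - 2 * d, O = 2),
    ketene = c(C = n, H = 2 * n - 2 - 2 * d, O = 1),
    alkene = c(C = n, H = 2 * n - 2 * d))
  new_formula(counts)
}

# dihydroxy sphingoid base C_x H_{2x+3-2y} N O2 (e.g. d18:1 = sphingosine)
sphingoid_formula <- function(ch) {
  stopifnot(ch$linkage == "sphingoid")
  new_formula(c(C = ch$carbons, H = 2 * ch$carbons + 3 - 2 * ch$double_bonds,
                N = 1, O = 2))
}

#' Molecular formula of a lipid structure
#'
#' Assembles the neutral molecular formula from the class backbone plus the
#' chain contributions, condensing out one H2O per ester/ether/amide bond.
#' Double-bond position and geometry annotations are mass-neutral.
#'
#' @param s A `lipid_structure`.
#' @return An `elemental_formula` for the neutral molecule.
#' @examples
#' format_formula(lipid_formula(parse_lipid_name("PC(16:0/16:0)")))
#' @export
lipid_formula <- function(s) {
  stopifnot(inherits(s, "lipid_structure"))
  tmpl <- .lipid_classes[[s$lipid_class]]
  if (tmpl$kind == "sphingo") {
    base <- sphingoid_formula(s$chains[[1]])
    f <- combine_formulas(base, chain_net_formula(s$chains[[2]]))
    if (s$lipid_class == "Sphingomyelins") {
      # phosphocholine head esterified onto the 1-hydroxyl
      f <- combine_formulas(f, parse_formula("C5H14NO4P"))
      f <- combine_formulas(f, parse_formula("H2O"), sign = -1)
    }
    return(f)
  }
  f <- parse_formula(tmpl$backbone)
  for (ch in s$chains) f <- combine_formulas(f, chain_net_formula(ch))
  f
}

#' Precursor ion m/z of a lipid under an adduct
#'
#' Convenience wrapper: monoisotopic mass of [lipid_formula()] passed to
#' [adduct_mz()].
#'
#' @param s A `lipid_structure`.
#' @param adduct Adduct label or `adduct_spec`.
#' @return Precursor m/z (full precision; round at I/O).
#' @export
precursor_mz <- function(s, adduct) {
  adduct_mz(monoisotopic_mass(lipid_formula(s)), adduct)
}
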