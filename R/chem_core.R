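# Elemental-composition arithmetic and monoisotopic mass / m/z computation
# for glycerophospholipids, lyso forms, acyl fragments and adducts.

#' Monoisotopic atomic masses used throughout the package
#'
#' Single pinned table of monoisotopic atomic masses (Da) so that every mass
#' in the package is reproducible bit-for-bit. Carbon is exactly 12 by
#' definition; the remaining values are IUPAC monoisotopic masses. `electron`
#' is the electron rest mass, used for ion electron bookkeeping.
#'
#' @return Named numeric vector of atomic masses in Da.
#' @export
#' @examples
#' atomic_masses()[["H"]]
atomic_masses <- function() {
  c(
    C  = 12,
    H  = 1.00782503,
    D  = 2.01410178,
    O  = 15.99491462,
    P  = 30.97376151,
    N  = 14.00307401,
    Na = 22.98976928,
    K  = 38.96370649,
    Li = 7.01600344,
    electron = 0.00054858
  )
}

.supported_elements <- c("C", "H", "D", "O", "P", "N", "Na", "K", "Li")

#' Elemental composition
#'
#' A multiset of element counts plus an integer charge. This is the
#' arithmetic substrate for all mass computation: species formulae, adduct
#' deltas and fragment ions are all `elemental_composition` objects.
#'
#' @param ... Element counts as named arguments, e.g. `C = 37, H = 69`.
#'   Supported elements: C, H, D (deuterium), O, P, N, Na, K, Li.
#' @param charge Integer charge of the ion (0 for a neutral).
#' @return Object of class `elemental_composition`.
#' @export
#' @examples
#' elemental_composition(C = 37, H = 69, O = 8, P = 1)
elemental_composition <- function(..., charge = 0L) {
  counts <- c(...)
  if (length(counts) == 0) counts <- numeric(0)
  if (is.null(names(counts)) && length(counts) > 0)
    stop("element counts must be named")
  bad <- setdiff(names(counts), .supported_elements)
  if (length(bad))
    stop("unsupported element(s): ", paste(bad, collapse = ", "))
  if (any(counts < 0))
    stop("negative element count: composition must have all counts >= 0")
  if (any(counts != round(counts)))
    stop("element counts must be integers")
  counts <- counts[counts > 0]
  structure(
    list(counts = counts, charge = as.integer(charge)),
    class = "elemental_composition"
  )
}

#' @export
print.elemental_composition <- function(x, ...) {
  cat("<elemental_composition> ", format_formula(x), "\n", sep = "")
  invisible(x)
}

#' Format a composition as a chemical formula string
#'
#' @param comp An `elemental_composition`.
#' @return Character scalar in Hill-like order (C, H, then alphabetical),
#'   with a trailing charge annotation for ions.
#' @export
#' @examples
#' format_formula(composition_of_species("PA", 34, 2))  # "C37H69O8P"
format_formula <- function(comp) {
  stopifnot(inherits(comp, "elemental_composition"))
  counts <- comp$counts
  ord <- c("C", "H", "D", setdiff(sort(names(counts)), c("C", "H", "D")))
  ord <- ord[ord %in% names(counts)]
  parts <- vapply(ord, function(el) {
    n <- counts[[el]]
    if (n == 1) el else paste0(el, n)
  }, character(1))
  z <- comp$charge
  suffix <- if (z == 0) "" else if (z == 1) "+" else if (z == -1) "-" else
    sprintf("%+d", z)
  paste0(paste(parts, collapse = ""), suffix)
}

#' @rdname comp_arith
#' @export
comp_add <- function(a, b) {
  stopifnot(inherits(a, "elemental_composition"),
            inherits(b, "elemental_composition"))
  els <- union(names(a$counts), names(b$counts))
  counts <- vapply(els, function(el) {
    sum(a$counts[el], b$counts[el], na.rm = TRUE)
  }, numeric(1))
  do.call(elemental_composition,
          c(as.list(counts), list(charge = a$charge + b$charge)))
}

#' Composition arithmetic
#'
#' Element-wise addition and subtraction of compositions. Subtracting more
#' atoms than present is an error (an adduct or loss that is chemically
#' impossible for the given neutral). Charges add/subtract.
#'
#' @param a,b `elemental_composition` objects.
#' @return An `elemental_composition`.
#' @name comp_arith
#' @export
comp_subtract <- function(a, b) {
  stopifnot(inherits(a, "elemental_composition"),
            inherits(b, "elemental_composition"))
  els <- union(names(a$counts), names(b$counts))
  counts <- vapply(els, function(el) {
    av <- if (el %in% names(a$counts)) a$counts[[el]] else 0
    bv <- if (el %in% names(b$counts)) b$counts[[el]] else 0
    av - bv
  }, numeric(1))
  if (any(counts < 0)) {
    bad <- names(counts)[counts < 0]
    stop("cannot remove more atoms than present: ", paste(bad, collapse = ", "))
  }
  do.call(elemental_composition,
          c(as.list(counts), list(charge = a$charge - b$charge)))
}

#' @export
`+.elemental_composition` <- function(e1, e2) comp_add(e1, e2)

#' @export
`-.elemental_composition` <- function(e1, e2) comp_subtract(e1, e2)

#' Acyl chain
#'
#' A fatty acyl chain in c:d shorthand (carbons:double bonds), optionally
#' deuterium-labelled (e.g. the 16:0D31 chain of the pre-deuterated
#' positional standard).
#'
#' @param carbons Positive integer, number of carbon atoms (c).
#' @param double_bonds Non-negative integer, number of C=C double bonds (d).
#' @param n_deuterium Non-negative integer count of H->D substitutions
#'   (0 for unlabeled).
#' @return Object of class `acyl_chain`.
#' @export
#' @examples
#' acyl_chain(18, 1)
#' acyl_chain(16, 0, n_deuterium = 31)  # 16:0D31
acyl_chain <- function(carbons, double_bonds, n_deuterium = 0L) {
  carbons <- as.integer(carbons)
  double_bonds <- as.integer(double_bonds)
  n_deuterium <- as.integer(n_deuterium)
  if (is.na(carbons) || carbons < 1) stop("chain must have >= 1 carbon")
  if (is.na(double_bonds) || double_bonds < 0)
    stop("double bonds must be >= 0")
  # free fatty acid CcH(2c-2d)O2 must have a positive hydrogen count
  n_h <- 2 * carbons - 2 * double_bonds
  if (n_h <= 0)
    stop(sprintf("impossible chain %d:%d (non-positive hydrogen count)",
                 carbons, double_bonds))
  if (n_deuterium < 0 || n_deuterium > n_h)
    stop("n_deuterium exceeds hydrogen count of the free fatty acid")
  structure(
    list(carbons = carbons, double_bonds = double_bonds,
         n_deuterium = n_deuterium),
    class = "acyl_chain"
  )
}

#' @export
print.acyl_chain <- function(x, ...) {
  cat("<acyl_chain> ", format_chain(x), "\n", sep = "")
  invisible(x)
}

#' Format an acyl chain in c:d shorthand
#' @param chain An `acyl_chain`.
#' @return Character scalar, e.g. `"18:1"` or `"16:0D31"`.
#' @export
format_chain <- function(chain) {
  stopifnot(inherits(chain, "acyl_chain"))
  lab <- sprintf("%d:%d", chain$carbons, chain$double_bonds)
  if (chain$n_deuterium > 0) lab <- sprintf("%sD%d", lab, chain$n_deuterium)
  lab
}

#' Parse c:d shorthand into an acyl chain
#' @param x Character like `"18:1"` or `"16:0D31"`.
#' @return An `acyl_chain`.
#' @export
parse_chain <- function(x) {
  m <- regmatches(x, regexec("^([0-9]+):([0-9]+)(?:D([0-9]+))?$", x))[[1]]
  if (length(m) == 0) stop("cannot parse chain shorthand: ", x)
  acyl_chain(as.integer(m[2]), as.integer(m[3]),
             if (m[4] == "") 0L else as.integer(m[4]))
}

# Head-group deltas relative to the PA diacyl formula C(m+3)H(2m-2n+5)O8P.
# Only PA/LPA is the validated path; the other classes follow by adding the
# heteroatoms of the class-specific head group.
.headgroup_deltas <- list(
  PA = elemental_composition(),
  PC = elemental_composition(C = 5, H = 11, N = 1),
  PE = elemental_composition(C = 2, H = 5, N = 1),
  PS = elemental_composition(C = 3, H = 5, N = 1, O = 2),
  PG = elemental_composition(C = 3, H = 6, O = 2),
  PI = elemental_composition(C = 6, H = 10, O = 5)
)

.lipid_classes <- c(names(.headgroup_deltas),
                    paste0("L", names(.headgroup_deltas)))

#' Neutral elemental composition of a (lyso)glycerophospholipid species
#'
#' Implements the generalized diacyl formula for phosphatidic acid,
#' C(m+3) H(2m-2n+5) O8 P, where m is the total acyl carbon count and n the
#' total double-bond count, and its lyso analogue C(m+3) H(2m-2n+7) O7 P.
#' Other classes (PC, PE, PS, PG, PI and their lyso forms) are obtained by
#' adding the heteroatoms of the class-specific head group to the PA
#' formula.
#'
#' @param lipid_class One of PA, LPA, PC, LPC, PE, LPE, PS, LPS, PG, LPG,
#'   PI, LPI.
#' @param m Total acyl carbons (positive integer).
#' @param n Total acyl double bonds (non-negative integer).
#' @return Neutral (charge 0) `elemental_composition`.
#' @export
#' @examples
#' composition_of_species("PA", 34, 2)   # C37H69O8P
#' composition_of_species("LPA", 16, 0)  # C19H39O7P
composition_of_species <- function(lipid_class, m, n) {
  lipid_class <- as.character(lipid_class)
  if (!lipid_class %in% .lipid_classes)
    stop("unknown lipid class: ", lipid_class)
  m <- as.integer(m); n <- as.integer(n)
  if (is.na(m) || m < 1) stop("total carbons m must be >= 1 (no acyl carbons)")
  if (is.na(n) || n < 0) stop("total double bonds n must be >= 0")
  is_lyso <- startsWith(lipid_class, "L")
  base_class <- sub("^L", "", lipid_class)
  n_h <- 2 * m - 2 * n + 5
  if (n_h <= 0)
    stop(sprintf("impossible species %s %d:%d (hydrogen count %d <= 0)",
                 lipid_class, m, n, n_h))
  pa <- elemental_composition(C = m + 3, H = n_h, O = 8, P = 1)
  comp <- comp_add(pa, .headgroup_deltas[[base_class]])
  if (is_lyso) {
    # one acyl chain fewer: formally +H2O then -fatty-acyl; net +2H -1O
    comp <- comp_subtract(comp_add(comp, elemental_composition(H = 2)),
                          elemental_composition(O = 1))
  }
  comp
}

#' Monoisotopic mass of a composition
#'
#' Sum of monoisotopic atomic masses, minus `charge` electron masses: ions
#' carry full electron bookkeeping, so an anion is heavier than the sum of
#' its atoms by one electron mass. This is the convention under which the
#' package reproduces printed unit-truncated transition masses such as
#' 223.17 for the 14:2 carboxylate anion.
#'
#' @param comp An `elemental_composition`.
#' @return Mass (for neutrals) or m-independent ion mass in Da. Divide by
#'   |charge| for m/z; [adduct_mz()] does this for you.
#' @export
#' @examples
#' monoisotopic_mass(composition_of_species("PA", 34, 2))  # 672.4730
monoisotopic_mass <- function(comp) {
  stopifnot(inherits(comp, "elemental_composition"))
  am <- atomic_masses()
  if (length(comp$counts) == 0 && comp$charge == 0) return(0)
  m <- sum(am[names(comp$counts)] * comp$counts)
  m - comp$charge * am[["electron"]]
}

# Nine built-in adducts: delta composition applied to the neutral, with
# charge. Subtractive deltas are kept separate so validation can report
# exactly which atoms would go negative.
.builtin_adducts <- list(
  "[M+H]+"      = list(add = c(H = 1),              remove = c(),         charge = +1L),
  "[M+H-H2O]+"  = list(add = c(H = 1),              remove = c(H = 2, O = 1), charge = +1L),
  "[M+NH4]+"    = list(add = c(N = 1, H = 4),       remove = c(),         charge = +1L),
  "[M+Na]+"     = list(add = c(Na = 1),             remove = c(),         charge = +1L),
  "[M+K]+"      = list(add = c(K = 1),              remove = c(),         charge = +1L),
  "[M+Li]+"     = list(add = c(Li = 1),             remove = c(),         charge = +1L),
  "[M-H]-"      = list(add = c(),                   remove = c(H = 1),    charge = -1L),
  "[M+HCO2]-"   = list(add = c(C = 1, H = 1, O = 2), remove = c(),        charge = -1L),
  "[M+CH3CO2]-" = list(add = c(C = 2, H = 3, O = 2), remove = c(),        charge = -1L)
)

#' Names of the nine built-in adducts
#' @return Character vector of adduct names in registry order.
#' @export
adduct_names <- function() names(.builtin_adducts)

#' m/z of a neutral species under an adduct
#'
#' Applies the adduct's composition delta (including charge and electron
#' bookkeeping) and divides by |charge|. All nine built-in adducts are
#' singly charged.
#'
#' @param neutral Neutral `elemental_composition` of the species.
#' @param adduct Adduct name, one of [adduct_names()].
#' @return m/z in Th (Da/e).
#' @export
#' @examples
#' adduct_mz(composition_of_species("PA", 34, 2), "[M-H]-")  # 671.4657
adduct_mz <- function(neutral, adduct) {
  stopifnot(inherits(neutral, "elemental_composition"))
  if (neutral$charge != 0) stop("adduct_mz expects a neutral composition")
  spec <- .builtin_adducts[[adduct]]
  if (is.null(spec)) stop("unknown adduct: ", adduct)
  ion <- neutral
  if (length(spec$add))
    ion <- comp_add(ion, do.call(elemental_composition, as.list(spec$add)))
  if (length(spec$remove))
    ion <- comp_subtract(ion, do.call(elemental_composition,
                                      as.list(spec$remove)))
  ion$charge <- spec$charge
  monoisotopic_mass(ion) / abs(spec$charge)
}

#' Composition of a fatty acyl carboxylate anion [RCOO]-
#'
#' @param chain An `acyl_chain` (or c:d string).
#' @return `elemental_composition` of C(c) H(2c-2d-1) O2 with charge -1,
#'   deuterium substitutions applied.
#' @export
acyl_anion_composition <- function(chain) {
  if (is.character(chain)) chain <- parse_chain(chain)
  stopifnot(inherits(chain, "acyl_chain"))
  c_ <- chain$carbons; d_ <- chain$double_bonds; nd <- chain$n_deuterium
  n_h <- 2 * c_ - 2 * d_ - 1
  if (n_h < 0) stop("impossible carboxylate anion for chain ",
                    format_chain(chain))
  if (nd > n_h) stop("n_deuterium exceeds anion hydrogen count")
  args <- list(C = c_, H = n_h - nd, O = 2, charge = -1L)
  if (nd > 0) args$D <- nd
  args <- args[vapply(args, function(v) !identical(v, 0L) && !identical(v, 0),
                      logical(1))]
  do.call(elemental_composition, args)
}

#' m/z of a fatty acyl carboxylate anion
#'
#' The diagnostic negative-mode fragment of an acyl chain: the free fatty
#' acid minus one proton, with electron bookkeeping, so e.g. the 18:1 anion
#' is 281.2486 (printed as 281.24 after truncation).
#'
#' @param chain An `acyl_chain` or c:d string such as `"18:1"`.
#' @return m/z of the singly charged carboxylate anion.
#' @export
#' @examples
#' acyl_anion_mz("18:1")                       # 281.2486
#' acyl_anion_mz(acyl_chain(16, 0, 31))        # deuterated 16:0D31
acyl_anion_mz <- function(chain) {
  monoisotopic_mass(acyl_anion_composition(chain))
}

#' Truncated decimal display of an m/z value
#'
#' Truncates (never rounds) to `places` decimals, matching the convention of
#' printed unit-resolution transition lists: 671.4657 prints as "671.46",
#' 223.1704 as "223.17". Full precision is always retained internally; this
#' is a display convention only.
#'
#' @param x Non-negative m/z value(s).
#' @param places Number of decimal places (default 2).
#' @return Character vector.
#' @export
#' @examples
#' format_mz(671.4657)  # "671.46" (rounding would give "671.47")
format_mz <- function(x, places = 2L) {
  if (any(x < 0)) stop("m/z must be >= 0")
  scale <- 10^places
  # tiny nudge guards against binary-representation shortfall just below an
  # integer; real masses never sit within 1e-9 of a truncation boundary
  trunc_x <- floor(x * scale + 1e-9) / scale
  formatC(trunc_x, format = "f", digits = places)
}

#' Composition of a free fatty acid
#' @param chain An `acyl_chain` or c:d string.
#' @return Neutral `elemental_composition` C(c) H(2c-2d) O2 (deuterium
#'   applied).
#' @export
fatty_acid_composition <- function(chain) {
  if (is.character(chain)) chain <- parse_chain(chain)
  stopifnot(inherits(chain, "acyl_chain"))
  n_h <- 2 * chain$carbons - 2 * chain$double_bonds
  nd <- chain$n_deuterium
  args <- list(C = chain$carbons, H = n_h - nd, O = 2)
  if (nd > 0) args$D <- nd
  do.call(elemental_composition, args)
}

#' Lipid species
#'
#' A glycerophospholipid species, either at sum-composition level (total
#' carbons m : total double bonds n) or with resolved sn-1/sn-2 chains.
#' Lyso classes carry exactly one chain.
#'
#' @param lipid_class Class string (PA, LPA, PC, ...).
#' @param m,n Sum composition; inferred from chains when those are given.
#' @param sn1,sn2 Optional `acyl_chain`s (or c:d strings) at the sn-1 and
#'   sn-2 glycerol positions.
#' @return Object of class `lipid_species`.
#' @export
#' @examples
#' lipid_species("PA", 34, 2)
#' lipid_species("PA", sn1 = "16:1", sn2 = "18:1")
lipid_species <- function(lipid_class, m = NULL, n = NULL,
                          sn1 = NULL, sn2 = NULL) {
  if (!lipid_class %in% .lipid_classes)
    stop("unknown lipid class: ", lipid_class)
  is_lyso <- startsWith(lipid_class, "L")
  if (is.character(sn1)) sn1 <- parse_chain(sn1)
  if (is.character(sn2)) sn2 <- parse_chain(sn2)
  if (is_lyso) {
    if (!is.null(sn2)) stop("lyso species carry exactly one chain")
    if (!is.null(sn1)) { m <- sn1$carbons; n <- sn1$double_bonds }
  } else if (!is.null(sn1) || !is.null(sn2)) {
    if (is.null(sn1) || is.null(sn2))
      stop("diacyl species need both sn1 and sn2 chains (or neither)")
    mc <- sn1$carbons + sn2$carbons
    nc <- sn1$double_bonds + sn2$double_bonds
    if (!is.null(m) && m != mc)
      stop("chain carbons do not sum to m")
    if (!is.null(n) && n != nc)
      stop("chain double bonds do not sum to n")
    m <- mc; n <- nc
  }
  if (is.null(m) || is.null(n))
    stop("either a sum composition (m, n) or resolved chains are required")
  composition_of_species(lipid_class, m, n)  # validates m, n
  structure(
    list(lipid_class = lipid_class, m = as.integer(m), n = as.integer(n),
         sn1 = sn1, sn2 = sn2),
    class = "lipid_species"
  )
}

#' @export
print.lipid_species <- function(x, ...) {
  cat("<lipid_species> ", format_species(x), "\n", sep = "")
  invisible(x)
}

#' Format a lipid species label
#'
#' `"PA(34:2)"` at sum-composition level, `"PA(16:1/18:1)"` when the sn
#' positions are resolved.
#'
#' @param species A `lipid_species`.
#' @return Character scalar.
#' @export
format_species <- function(species) {
  stopifnot(inherits(species, "lipid_species"))
  if (!is.null(species$sn1) && !is.null(species$sn2)) {
    sprintf("%s(%s/%s)", species$lipid_class,
            format_chain(species$sn1), format_chain(species$sn2))
  } else if (!is.null(species$sn1)) {
    sprintf("%s(%s)", species$lipid_class, format_chain(species$sn1))
  } else {
    sprintf("%s(%d:%d)", species$lipid_class, species$m, species$n)
  }
}

#' Composition of a lipid_species object
#' @param species A `lipid_species`.
#' @return Neutral `elemental_composition` (deuterium of labelled chains
#'   carried through).
#' @export
species_composition <- function(species) {
  stopifnot(inherits(species, "lipid_species"))
  comp <- composition_of_species(species$lipid_class, species$m, species$n)
  nd <- 0L
  for (ch in list(species$sn1, species$sn2))
    if (!is.null(ch)) nd <- nd + ch$n_deuterium
  if (nd > 0) {
    comp <- comp_subtract(comp, elemental_composition(H = nd))
    comp <- comp_add(comp, elemental_composition(D = nd))
  }
  comp
}
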