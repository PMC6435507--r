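# MS1 species/adduct database, MS/MS fragment database, chain-pair
# decomposition of sum compositions, and MRM transition-list design.

#' Chain search space
#'
#' The space of fatty acyl chains considered when decomposing a sum
#' composition into candidate sn-1/sn-2 pairs.
#'
#' @param min_carbons,max_carbons Chain carbon bounds (defaults 12 and 22;
#'   odd-carbon chains are required for the 13:0/17:0-containing internal
#'   standards).
#' @param allow_odd_carbons Allow odd carbon counts (default TRUE).
#' @param max_db_per_chain Maximum double bonds per chain (default 6).
#' @param saturated_above Carbon count above which only saturated chains
#'   (d = 0) are considered (default `Inf`, i.e. no restriction). Used by
#'   [default_transition_space()].
#' @return Object of class `chain_space`.
#' @export
chain_space <- function(min_carbons = 12L, max_carbons = 22L,
                        allow_odd_carbons = TRUE, max_db_per_chain = 6L,
                        saturated_above = Inf) {
  stopifnot(min_carbons >= 1, max_carbons >= min_carbons,
            max_db_per_chain >= 0)
  structure(
    list(min_carbons = as.integer(min_carbons),
         max_carbons = as.integer(max_carbons),
         allow_odd_carbons = isTRUE(allow_odd_carbons),
         max_db_per_chain = as.integer(max_db_per_chain),
         saturated_above = saturated_above),
    class = "chain_space"
  )
}

#' Default chain space for database building
#'
#' 12-22 carbons, odd carbons allowed (internal standards use 12:0/13:0 and
#' 17:0/14:1), up to 6 double bonds per chain.
#'
#' @return A `chain_space`.
#' @export
default_chain_space <- function() chain_space()

#' Default chain space for MRM transition design
#'
#' Even-carbon chains of 14-20 carbons, at most 2 double bonds per chain,
#' with chains longer than 18 carbons restricted to saturated. Under this
#' space PA 34:2 decomposes into exactly the four published candidate pairs
#' (14:2/20:0, 16:0/18:2, 16:1/18:1, 16:2/18:0), i.e. eight MRM transitions.
#'
#' @return A `chain_space`.
#' @export
default_transition_space <- function() {
  chain_space(min_carbons = 14L, max_carbons = 20L,
              allow_odd_carbons = FALSE, max_db_per_chain = 2L,
              saturated_above = 18L)
}

#' Is a chain inside a chain space?
#' @param carbons,double_bonds Chain in c:d form (vectorized).
#' @param space A `chain_space`.
#' @return Logical vector.
#' @export
chain_in_space <- function(carbons, double_bonds, space) {
  stopifnot(inherits(space, "chain_space"))
  ok <- carbons >= space$min_carbons & carbons <= space$max_carbons &
    double_bonds >= 0 & double_bonds <= space$max_db_per_chain
  if (!space$allow_odd_carbons) ok <- ok & carbons %% 2 == 0
  ok & (carbons <= space$saturated_above | double_bonds == 0)
}

#' Enumerate all chains in a chain space
#' @param space A `chain_space`.
#' @return data.frame with columns `carbons`, `double_bonds`.
#' @export
chains_in_space <- function(space) {
  stopifnot(inherits(space, "chain_space"))
  grid <- expand.grid(carbons = space$min_carbons:space$max_carbons,
                      double_bonds = 0:space$max_db_per_chain)
  grid <- grid[chain_in_space(grid$carbons, grid$double_bonds, space), ]
  grid <- grid[order(grid$carbons, grid$double_bonds), ]
  rownames(grid) <- NULL
  grid
}

#' Decompose a sum composition into candidate chain pairs
#'
#' All unordered pairs of chains {c1:d1, c2:d2} with c1 + c2 = m and
#' d1 + d2 = n, each chain inside `space`. The sn order is deliberately NOT
#' decided here — that requires fragment-intensity evidence
#' (see [assign_sn_positions()]).
#'
#' @param m,n Sum composition (total carbons, total double bonds).
#' @param space A `chain_space` (default [default_chain_space()]).
#' @return data.frame with columns `c1`, `d1`, `c2`, `d2` (canonical order
#'   c1 < c2, or c1 == c2 and d1 <= d2), sorted by (c1, d1). Zero rows if no
#'   pair exists.
#' @export
#' @examples
#' decompose_sum_composition(34, 2, default_transition_space())
decompose_sum_composition <- function(m, n, space = default_chain_space()) {
  stopifnot(m >= 0, n >= 0)
  empty <- data.frame(c1 = integer(0), d1 = integer(0),
                      c2 = integer(0), d2 = integer(0))
  hi <- min(space$max_carbons, m - space$min_carbons)
  if (hi < space$min_carbons) return(empty)
  out <- list()
  for (c1 in space$min_carbons:hi) {
    c2 <- m - c1
    if (c2 < c1) break  # canonical order: c1 <= c2
    for (d1 in 0:min(space$max_db_per_chain, n)) {
      d2 <- n - d1
      if (c1 == c2 && d2 < d1) next  # unordered: keep d1 <= d2 when c1 == c2
      if (chain_in_space(c1, d1, space) && chain_in_space(c2, d2, space))
        out[[length(out) + 1L]] <- c(c1, d1, c2, d2)
    }
  }
  if (length(out) == 0) return(empty)
  df <- as.data.frame(do.call(rbind, out))
  names(df) <- c("c1", "d1", "c2", "d2")
  df[] <- lapply(df, as.integer)
  df <- df[order(df$c1, df$d1), ]
  rownames(df) <- NULL
  df
}

#' Build the MS1 species/adduct table
#'
#' One row per (m, n) over the requested ranges: species label, chemical
#' formula, neutral monoisotopic mass and m/z under the nine built-in
#' adducts, each with a full-precision column and a 2-decimal truncated
#' display column. Rows whose sum composition admits no chain pair in
#' `space` (or an impossible hydrogen count) are flagged invalid.
#'
#' @param lipid_class Lipid class, e.g. `"PA"`.
#' @param m_range,n_range Integer vectors (or `lo:hi`) of total carbons and
#'   total double bonds.
#' @param space `chain_space` used for the validity flag.
#' @return data.frame; adduct columns are named by adduct (e.g. `[M-H]-`)
#'   with display twins suffixed `_display`.
#' @export
#' @examples
#' build_ms1_table("PA", 34, 2)[["[M-H]-_display"]]  # "671.46"
build_ms1_table <- function(lipid_class, m_range, n_range,
                            space = default_chain_space()) {
  if (length(m_range) == 0 || length(n_range) == 0)
    stop("empty m or n range")
  composition_of_species(lipid_class, max(m_range), 0)  # class check
  grid <- expand.grid(m = sort(unique(as.integer(m_range))),
                      n = sort(unique(as.integer(n_range))))
  grid <- grid[order(grid$m, grid$n), ]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    m <- grid$m[i]; n <- grid$n[i]
    base <- data.frame(species = sprintf("%s(%d:%d)", lipid_class, m, n),
                       m = m, n = n, stringsAsFactors = FALSE)
    comp <- tryCatch(composition_of_species(lipid_class, m, n),
                     error = function(e) NULL)
    if (is.null(comp)) {
      base$formula <- NA_character_; base$neutral_mass <- NA_real_
      for (ad in adduct_names()) {
        base[[ad]] <- NA_real_; base[[paste0(ad, "_display")]] <- NA_character_
      }
      base$valid <- FALSE
      return(base)
    }
    base$formula <- format_formula(comp)
    base$neutral_mass <- monoisotopic_mass(comp)
    for (ad in adduct_names()) {
      mz <- tryCatch(adduct_mz(comp, ad), error = function(e) NA_real_)
      base[[ad]] <- mz
      base[[paste0(ad, "_display")]] <-
        if (is.na(mz)) NA_character_ else format_mz(mz)
    }
    base$valid <- nrow(decompose_sum_composition(m, n, space)) > 0
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build the MS/MS fragment table for one acyl chain
#'
#' Diagnostic negative-mode fragments attributable to a single fatty acyl
#' chain within a diacyl species: its carboxylate anion [RCOO]- and the
#' lyso-species [M-H]- observed when the complementary chain is lost; plus,
#' for each complementary chain in `space`, the diacyl precursor [M-H]- and
#' the complementary chain's own lyso fragment.
#'
#' @param chain `acyl_chain` or c:d string.
#' @param lipid_class Diacyl class (default `"PA"`); lyso rows use its L-
#'   prefixed form.
#' @param space Complementary-chain space (default [default_chain_space()]).
#' @return data.frame with columns `fragment_type`
#'   (`acyl_anion`/`lyso_MH`/`precursor_MH`/`complement_lyso_MH`), `chain`,
#'   `formula`, `mz`, `mz_display`.
#' @export
#' @examples
#' head(build_msms_table("18:1"))
build_msms_table <- function(chain, lipid_class = "PA",
                             space = default_chain_space()) {
  if (is.character(chain)) chain <- parse_chain(chain)
  stopifnot(inherits(chain, "acyl_chain"))
  if (startsWith(lipid_class, "L"))
    stop("build_msms_table expects a diacyl class")
  lyso_class <- paste0("L", lipid_class)
  row_of <- function(type, chain_lab, comp, mz) {
    data.frame(fragment_type = type, chain = chain_lab,
               formula = format_formula(comp), mz = mz,
               mz_display = format_mz(mz), stringsAsFactors = FALSE)
  }
  an_comp <- acyl_anion_composition(chain)
  lyso_comp <- composition_of_species(lyso_class, chain$carbons,
                                      chain$double_bonds)
  rows <- list(
    row_of("acyl_anion", format_chain(chain), an_comp,
           monoisotopic_mass(an_comp)),
    row_of("lyso_MH", format_chain(chain), lyso_comp,
           adduct_mz(lyso_comp, "[M-H]-"))
  )
  comp_chains <- chains_in_space(space)
  for (i in seq_len(nrow(comp_chains))) {
    cc <- comp_chains$carbons[i]; cd <- comp_chains$double_bonds[i]
    m <- chain$carbons + cc; n <- chain$double_bonds + cd
    prec <- tryCatch(composition_of_species(lipid_class, m, n),
                     error = function(e) NULL)
    if (is.null(prec)) next
    lab <- sprintf("%s+%d:%d", format_chain(chain), cc, cd)
    rows[[length(rows) + 1L]] <-
      row_of("precursor_MH", lab, prec, adduct_mz(prec, "[M-H]-"))
    comp_lyso <- composition_of_species(lyso_class, cc, cd)
    rows[[length(rows) + 1L]] <-
      row_of("complement_lyso_MH", sprintf("%d:%d", cc, cd), comp_lyso,
             adduct_mz(comp_lyso, "[M-H]-"))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Design an MRM transition list
#'
#' For each sum-composition species, one negative-mode transition per
#' distinct candidate chain: Q1 = species [M-H]-, Q3 = chain carboxylate
#' anion. Chains appearing in more than one candidate pair of the same
#' species are flagged `shared_fragment` (their transition cannot by itself
#' distinguish the pairs). Quantitation transitions are negative-mode only;
#' positive adducts live in the MS1 table but generate no transitions.
#'
#' @param species data.frame with columns `m`, `n` (and optionally
#'   `species` labels), or a character vector like `"PA(34:2)"`.
#' @param space `chain_space` (default [default_transition_space()]).
#' @param max_transitions Hard cap on list length (default 75, the duty-
#'   cycle limit of unscheduled MRM at 30 ms dwell).
#' @param priority Optional character vector of species labels; when the
#'   panel overflows, transitions are kept in priority order up to the cap.
#' @param dwell_ms,collision_energy_eV Acquisition metadata recorded on
#'   every transition (defaults 30 ms and 39 eV).
#' @param lipid_class Class (default `"PA"`).
#' @return data.frame of transitions: `species`, `m`, `n`, `q1_mz`, `q3_mz`,
#'   `q1_display`, `q3_display`, `chain`, `shared_fragment`, `dwell_ms`,
#'   `collision_energy_eV`.
#' @export
#' @examples
#' build_transition_list("PA(34:2)")
build_transition_list <- function(species,
                                  space = default_transition_space(),
                                  max_transitions = 75L,
                                  priority = NULL,
                                  dwell_ms = 30, collision_energy_eV = 39,
                                  lipid_class = "PA") {
  if (is.character(species)) {
    mm <- regmatches(species, regexec("^([A-Z]+)\\(([0-9]+):([0-9]+)\\)$",
                                      species))
    bad <- vapply(mm, length, integer(1)) == 0
    if (any(bad)) stop("cannot parse species label(s): ",
                       paste(species[bad], collapse = ", "))
    species <- data.frame(
      species = species,
      m = vapply(mm, function(x) as.integer(x[3]), integer(1)),
      n = vapply(mm, function(x) as.integer(x[4]), integer(1)),
      stringsAsFactors = FALSE)
  }
  if (!is.data.frame(species) || nrow(species) == 0)
    stop("empty species panel")
  if (!all(c("m", "n") %in% names(species)))
    stop("species must have columns m and n")
  if (is.null(species$species))
    species$species <- sprintf("%s(%d:%d)", lipid_class, species$m, species$n)
  if (anyDuplicated(species[c("m", "n")]))
    stop("duplicate species in input panel")

  rows <- lapply(seq_len(nrow(species)), function(i) {
    m <- species$m[i]; n <- species$n[i]
    pairs <- decompose_sum_composition(m, n, space)
    if (nrow(pairs) == 0) return(NULL)
    chains <- rbind(data.frame(c = pairs$c1, d = pairs$d1),
                    data.frame(c = pairs$c2, d = pairs$d2))
    tab <- stats::aggregate(list(n_pairs = rep(1L, nrow(chains))),
                            by = chains[c("c", "d")], FUN = sum)
    # a chain that appears twice in a self-pair is not "shared"
    self <- pairs$c1 == pairs$c2 & pairs$d1 == pairs$d2
    for (j in which(self)) {
      k <- tab$c == pairs$c1[j] & tab$d == pairs$d1[j]
      tab$n_pairs[k] <- tab$n_pairs[k] - 1L
    }
    tab <- tab[order(tab$c, tab$d), ]
    q1 <- adduct_mz(composition_of_species(lipid_class, m, n), "[M-H]-")
    q3 <- vapply(seq_len(nrow(tab)),
                 function(j) acyl_anion_mz(acyl_chain(tab$c[j], tab$d[j])),
                 numeric(1))
    data.frame(
      species = species$species[i], m = m, n = n,
      q1_mz = q1, q3_mz = q3,
      q1_display = format_mz(q1), q3_display = format_mz(q3),
      chain = sprintf("%d:%d", tab$c, tab$d),
      shared_fragment = tab$n_pairs > 1L,
      dwell_ms = dwell_ms, collision_energy_eV = collision_energy_eV,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0)
    stop("no transitions generated: no species decomposes in this space")
  rownames(out) <- NULL
  if (nrow(out) > max_transitions) {
    if (is.null(priority))
      stop(sprintf(
        "transition list overflow: %d transitions exceed the maximum of %d; supply a priority list",
        nrow(out), max_transitions))
    ord <- match(out$species, priority)
    if (anyNA(ord)) stop("priority list does not cover all species")
    out <- out[order(ord), ][seq_len(max_transitions), ]
    rownames(out) <- NULL
  }
  out
}

#' Write a database table to CSV/TSV
#'
#' Plain-text writer mirroring the layouts of the MS1, MS/MS and combined
#' transition workbooks (species, formula, neutral mass, nine adduct
#' columns; transition Q1/Q3/chain/dwell/CE).
#'
#' @param table data.frame from [build_ms1_table()], [build_msms_table()] or
#'   [build_transition_list()].
#' @param path Output path; a `.tsv` extension selects tab separation.
#' @return `path`, invisibly.
#' @export
write_database <- function(table, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(table, path, sep = sep, row.names = FALSE, na = "",
                     qmethod = "double")
  invisible(path)
}
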