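# Ground-truth PA mixtures and simulated MRM/EPI raw data, so that every
# downstream stage (reading, integration, identification, quantitation,
# statistics) is testable without instrument data.
#
# The simulated world: a fly-head-like panel of 39 resolved PA species in a
# three-group design (wild type / PLD-null mutant / reconstituted rescue,
# n = 3), two spiked internal standards, Gaussian elution peaks (sigma
# 0.05 min) co-eluting per species, and EPI fragment spectra in which the
# sn-1 carboxylate anion is sn_bias-fold more intense than the sn-2 anion.

.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' Default synthetic 39-species PA panel
#'
#' A constructed (synthetic) stand-in for a fly-head PA panel: 39 resolved
#' diacyl species drawn from the even-carbon 14-20 chain pool of
#' [default_transition_space()], with deterministic sn orders and log-spread
#' base abundances (0.05-8 pmol, inside the 1 fmol - 12 pmol linear range).
#' Self-paired species (e.g. 18:1/18:1) are excluded so that every species
#' has two distinct diagnostic transitions.
#'
#' @return data.frame: `species`, `sn1`, `sn2`, `m`, `n`,
#'   `base_amount_pmol`.
#' @export
default_panel <- function() {
  pool <- chains_in_space(default_transition_space())
  labs <- sprintf("%d:%d", pool$carbons, pool$double_bonds)
  pairs <- utils::combn(seq_len(nrow(pool)), 2)
  df <- data.frame(
    a = labs[pairs[1, ]], b = labs[pairs[2, ]],
    m = pool$carbons[pairs[1, ]] + pool$carbons[pairs[2, ]],
    n = pool$double_bonds[pairs[1, ]] + pool$double_bonds[pairs[2, ]])
  df <- df[order(df$m, df$n, df$a), ]
  df <- df[seq_len(39), ]
  # alternate the ground-truth sn order so both orders are exercised
  swap <- seq_len(nrow(df)) %% 2 == 0
  sn1 <- ifelse(swap, df$b, df$a)
  sn2 <- ifelse(swap, df$a, df$b)
  amounts <- round(exp(seq(log(0.05), log(8), length.out = 39)), 4)
  # spread amounts across the panel deterministically (not monotone in mass)
  ord <- order(rep_len(1:3, 39), seq_len(39))
  data.frame(
    species = sprintf("PA(%s/%s)", sn1, sn2),
    sn1 = sn1, sn2 = sn2, m = df$m, n = df$n,
    base_amount_pmol = amounts[ord],
    stringsAsFactors = FALSE)
}

#' Default three-group restoration design
#'
#' Wild type (`WT`), a PLD-null mutant (`mutant`) and a reconstituted
#' rescue group (`rescue`), per-species abundance multipliers relative to
#' the WT base amount: 30 of the 39 species are reduced in the mutant
#' (x `reduced_mult`); in the rescue group 16 of those are fully restored
#' (x 1), the other 14 only partially elevated (x `partial_mult`); the 9
#' unreduced species are unchanged throughout.
#'
#' @param panel Panel data.frame (default [default_panel()]).
#' @param n_reduced,n_restored Design counts (defaults 30 and 16).
#' @param reduced_mult,partial_mult Mutant and partial-rescue multipliers
#'   (defaults 0.25 and 0.5).
#' @return data.frame: `species`, `WT`, `mutant`, `rescue`, `reduced`
#'   (logical), `designed_restored` (logical).
#' @export
default_design <- function(panel = default_panel(), n_reduced = 30L,
                           n_restored = 16L, reduced_mult = 0.25,
                           partial_mult = 0.5) {
  stopifnot(n_reduced <= nrow(panel), n_restored <= n_reduced)
  reduced <- seq_len(nrow(panel)) <= n_reduced
  restored <- seq_len(nrow(panel)) <= n_restored
  data.frame(
    species = panel$species,
    WT = 1,
    mutant = ifelse(reduced, reduced_mult, 1),
    rescue = ifelse(!reduced, 1, ifelse(restored, 1, partial_mult)),
    reduced = reduced,
    designed_restored = reduced & restored,
    stringsAsFactors = FALSE)
}

#' Assemble a ground-truth object
#'
#' @param panel Species panel (default [default_panel()]).
#' @param design Group-multiplier design (default [default_design()] on the
#'   panel).
#' @param n_replicates Replicates per group (default 3).
#' @param is_amounts Named vector of spiked internal-standard amounts in
#'   pmol (default 10 pmol each of PA(12:0/13:0) and PA(17:0/14:1)).
#' @param total_phosphate_nmol Total lipid phosphate per sample in nmol
#'   (default 5).
#' @return Object of class `ground_truth`: panel, design, per-sample true
#'   amounts (`amounts`: species x sample matrix, pmol), `meta`
#'   ([sample_meta()]), `is_amounts`.
#' @export
ground_truth <- function(panel = default_panel(),
                         design = default_design(panel),
                         n_replicates = 3L,
                         is_amounts = c("PA(12:0/13:0)" = 10,
                                        "PA(17:0/14:1)" = 10),
                         total_phosphate_nmol = 5) {
  stopifnot(identical(panel$species, design$species))
  groups <- c("WT", "mutant", "rescue")
  stopifnot(all(groups %in% names(design)))
  samples <- expand.grid(replicate = seq_len(n_replicates), group = groups,
                         stringsAsFactors = FALSE)[, 2:1]
  samples$sample_id <- sprintf("%s_%d", samples$group, samples$replicate)
  amounts <- matrix(
    unlist(lapply(seq_len(nrow(samples)), function(j)
      panel$base_amount_pmol * design[[samples$group[j]]])),
    nrow = nrow(panel))
  rownames(amounts) <- panel$species
  colnames(amounts) <- samples$sample_id
  meta <- sample_meta(samples$sample_id, samples$group, samples$replicate,
                      rep(total_phosphate_nmol, nrow(samples)))
  structure(list(panel = panel, design = design, amounts = amounts,
                 meta = meta, is_amounts = is_amounts),
            class = "ground_truth")
}

#' Simulate measured per-species amounts (fast path)
#'
#' Applies multiplicative measurement noise (coefficient of variation `cv`)
#' directly to the true amounts, bypassing the raw-data layer. Intended for
#' statistical simulations over many seeds where the chromatographic and
#' spectral layers (exercised by [simulate_run()]) would add nothing but
#' runtime.
#'
#' @param truth A [ground_truth()] object.
#' @param cv Coefficient of variation of the multiplicative noise.
#' @param seed Integer seed (recorded in the output attributes).
#' @return `quant_result`-shaped data.frame with an attached `seed`
#'   attribute.
#' @export
simulate_amounts <- function(truth, cv = 0.05, seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  .with_seed(seed, {
    a <- truth$amounts
    noise <- matrix(stats::rnorm(length(a), 1, cv), nrow(a), ncol(a))
    meas <- pmax(a * noise, 0)
    out <- do.call(rbind, lapply(seq_len(ncol(meas)), function(j) {
      mrow <- truth$meta[j, ]
      data.frame(sample_id = mrow$sample_id, group = mrow$group,
                 replicate = mrow$replicate,
                 species = rownames(meas),
                 amount_pmol = meas[, j],
                 amount_per_phosphate = meas[, j] / mrow$total_phosphate_nmol,
                 flag = check_linear_range(meas[, j]),
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    class(out) <- c("quant_result", "data.frame")
    attr(out, "seed") <- seed
    out
  })
}

#' MRM transition table for a ground truth panel (analytes + standards)
#'
#' One transition per species chain (Q1 = sum-composition [M-H]-, Q3 =
#' chain carboxylate anion), with the internal standards appended. This is
#' the "method file" a targeted run is acquired with; the analysis pipeline
#' may use it, the ground-truth amounts it may not.
#'
#' @param truth A [ground_truth()] object.
#' @return data.frame: `species`, `position` (sn1/sn2), `chain`, `m`, `n`,
#'   `q1_mz`, `q3_mz`, `is_standard`.
#' @export
truth_transitions <- function(truth) {
  panel <- truth$panel
  is_df <- do.call(rbind, lapply(names(truth$is_amounts), function(lab) {
    mm <- regmatches(lab,
                     regexec("^PA\\(([0-9:]+)/([0-9:]+)\\)$", lab))[[1]]
    c1 <- parse_chain(mm[2]); c2 <- parse_chain(mm[3])
    data.frame(species = lab, sn1 = mm[2], sn2 = mm[3],
               m = c1$carbons + c2$carbons,
               n = c1$double_bonds + c2$double_bonds,
               base_amount_pmol = truth$is_amounts[[lab]],
               stringsAsFactors = FALSE)
  }))
  all_sp <- rbind(panel, is_df)
  all_sp$is_standard <- all_sp$species %in% names(truth$is_amounts)
  rows <- lapply(seq_len(nrow(all_sp)), function(i) {
    q1 <- adduct_mz(composition_of_species("PA", all_sp$m[i], all_sp$n[i]),
                    "[M-H]-")
    data.frame(species = all_sp$species[i],
               position = c("sn1", "sn2"),
               chain = c(all_sp$sn1[i], all_sp$sn2[i]),
               m = all_sp$m[i], n = all_sp$n[i],
               q1_mz = q1,
               q3_mz = c(acyl_anion_mz(all_sp$sn1[i]),
                         acyl_anion_mz(all_sp$sn2[i])),
               is_standard = all_sp$is_standard[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a full LC-MRM-EPI run from ground truth
#'
#' Per sample and species: one Gaussian XIC per diagnostic transition
#' (shared apex per species per sample — encoding co-elution — with
#' optional retention-time jitter; area proportional to amount, split
#' sn_bias : 1 between the sn-1 and sn-2 transitions) and one EPI spectrum
#' at the species apex whose sn-1 fragment is `sn_bias`-fold the sn-2
#' fragment before noise. Internal standards are always included. With all
#' noise terms zero the output is a deterministic function of the truth.
#'
#' @param truth A [ground_truth()] object.
#' @param noise List with `intensity_cv` (multiplicative CV per transition
#'   and per EPI fragment), `mz_sigma_da` (fragment m/z jitter, Da) and
#'   `rt_jitter_min` (per species-sample apex jitter, min).
#' @param sn_bias sn-1 : sn-2 fragment intensity ratio (> 1; default 1.7).
#' @param seed Integer seed; recorded in the run object.
#' @param rt_sigma_min Chromatographic peak sigma (default 0.05 min).
#' @param response_k Instrument response (counts x min per pmol, default
#'   1e4); cancels in ratio-based quantitation.
#' @return Object of class `sim_run`: `samples` (named list with
#'   `chromatograms` and `spectra` per sample), `meta`, `transitions`,
#'   `is_amounts`, `truth`, `seed`.
#' @export
simulate_run <- function(truth,
                         noise = list(intensity_cv = 0.01,
                                      mz_sigma_da = 0.05,
                                      rt_jitter_min = 0.02),
                         sn_bias = 1.7, seed = 1L,
                         rt_sigma_min = 0.05, response_k = 1e4) {
  stopifnot(inherits(truth, "ground_truth"), sn_bias > 1)
  cv <- noise$intensity_cv %||% 0
  mz_sig <- noise$mz_sigma_da %||% 0
  rt_jit <- noise$rt_jitter_min %||% 0
  trans <- truth_transitions(truth)
  species_tab <- unique(trans[c("species", "m", "n", "is_standard")])
  # deterministic elution program: species spaced 0.15 min apart from 6 min
  species_tab$rt_base <- 6 + 0.15 * (seq_len(nrow(species_tab)) - 1)
  w_frac <- c(sn1 = sn_bias / (1 + sn_bias), sn2 = 1 / (1 + sn_bias))
  .with_seed(seed, {
    samples <- list()
    for (j in seq_len(nrow(truth$meta))) {
      sid <- truth$meta$sample_id[j]
      chroms <- list(); spectra <- list()
      for (i in seq_len(nrow(species_tab))) {
        sp <- species_tab$species[i]
        amount <- if (species_tab$is_standard[i]) truth$is_amounts[[sp]]
                  else truth$amounts[sp, sid]
        apex <- species_tab$rt_base[i] +
          if (rt_jit > 0) stats::rnorm(1, 0, rt_jit) else 0
        tr <- trans[trans$species == sp, ]
        tgrid <- seq(species_tab$rt_base[i] - 0.6,
                     species_tab$rt_base[i] + 0.6, by = 0.01)
        for (k in seq_len(nrow(tr))) {
          fac <- if (cv > 0) max(0, stats::rnorm(1, 1, cv)) else 1
          area <- response_k * amount * w_frac[[tr$position[k]]] * fac
          amp <- area / (rt_sigma_min * sqrt(2 * pi))
          y <- amp * exp(-(tgrid - apex)^2 / (2 * rt_sigma_min^2))
          chroms[[length(chroms) + 1L]] <-
            chromatogram(tgrid, y, tr$q1_mz[k], tr$q3_mz[k],
                         id = sprintf("%s|%s|%s", sid, sp, tr$chain[k]))
        }
        # EPI spectrum triggered at the species apex
        f1 <- if (cv > 0) max(0, stats::rnorm(1, 1, cv)) else 1
        f2 <- if (cv > 0) max(0, stats::rnorm(1, 1, cv)) else 1
        mz <- tr$q3_mz + if (mz_sig > 0) stats::rnorm(nrow(tr), 0, mz_sig)
                         else 0
        inten <- 1e3 * amount * c(sn_bias * f1, f2)
        spectra[[length(spectra) + 1L]] <-
          epi_spectrum(mz, inten, precursor_mz = tr$q1_mz[1], rt_min = apex,
                       id = sprintf("%s|%s", sid, sp))
      }
      samples[[sid]] <- list(chromatograms = chroms, spectra = spectra)
    }
    structure(list(samples = samples, meta = truth$meta, transitions = trans,
                   is_amounts = truth$is_amounts, truth = truth, seed = seed),
              class = "sim_run")
  })
}

#' Infer the PA sum composition behind a precursor m/z
#'
#' Scans (m, n) grids for a [M-H]- match within `tol`.
#'
#' @param precursor_mz Observed precursor m/z.
#' @param tol Tolerance in Da (default 0.3).
#' @param m_range,n_range Search grid (defaults 24:44 and 0:8).
#' @return list(m, n) or NULL if nothing matches.
#' @export
infer_sum_composition <- local({
  cache <- new.env(parent = emptyenv())
  function(precursor_mz, tol = 0.3, m_range = 24:44, n_range = 0:8) {
    key <- paste(range(m_range), range(n_range), collapse = "|")
    if (is.null(cache[[key]])) {
      grid <- expand.grid(m = m_range, n = n_range)
      grid$mz <- vapply(seq_len(nrow(grid)), function(i) {
        comp <- tryCatch(composition_of_species("PA", grid$m[i], grid$n[i]),
                         error = function(e) NULL)
        if (is.null(comp)) NA_real_ else adduct_mz(comp, "[M-H]-")
      }, numeric(1))
      cache[[key]] <- grid[!is.na(grid$mz), ]
    }
    grid <- cache[[key]]
    d <- abs(grid$mz - precursor_mz)
    i <- which.min(d)
    if (length(i) == 0 || d[i] > tol) return(NULL)
    list(m = grid$m[i], n = grid$n[i])
  }
})

#' Run the full identification + quantitation pipeline on a simulated run
#'
#' For every sample: integrate all XICs; identify each EPI spectrum
#' (sum-composition inference, fragment matching, pair resolution, sn
#' assignment, co-elution confirmation); quantify each identified species
#' from its sn-1 transition area against the internal standard. Uses only
#' what an analyst has: raw data, the transition table and spiked-standard
#' amounts — never the ground-truth amounts.
#'
#' @param run A `sim_run` (or an equivalent list read back from disk plus
#'   `meta`, `transitions`, `is_amounts`).
#' @param standard Internal standard species for quantitation (default
#'   `"PA(17:0/14:1)"`).
#' @param mz_tol,rt_tol_min Matching tolerances (defaults 0.3 Da, 0.1 min).
#' @return list: `assignments` (per sample identification tables, with
#'   `sample_id`), `quant` (`quant_result` table), `totals`.
#' @export
run_pipeline <- function(run, standard = "PA(17:0/14:1)",
                         mz_tol = 0.3, rt_tol_min = 0.1) {
  trans <- run$transitions
  std_tr <- trans[trans$species == standard & trans$position == "sn1", ]
  if (nrow(std_tr) != 1) stop("standard not in transition table: ", standard)
  all_assign <- list(); all_areas <- list()
  for (sid in names(run$samples)) {
    xics <- run$samples[[sid]]$chromatograms
    area_of <- function(q1, q3) {
      hit <- Filter(function(ch)
        abs(ch$q1_mz - q1) <= mz_tol && abs(ch$q3_mz - q3) <= mz_tol, xics)
      if (length(hit) == 0)
        return(data.frame(area = 0, not_detected = TRUE))
      pk <- integrate_peaks(hit)
      pk <- pk[order(-pk$area), ]
      data.frame(area = pk$area[1], not_detected = pk$not_detected[1])
    }
    asg <- list()
    for (spectrum in run$samples[[sid]]$spectra) {
      mn <- infer_sum_composition(spectrum$precursor_mz, tol = mz_tol)
      if (is.null(mn)) next
      a <- identify_species(spectrum, mn$m, mn$n, xics = xics,
                            mz_tol = mz_tol, rt_tol_min = rt_tol_min)
      if (nrow(a)) { a$sample_id <- sid; asg[[length(asg) + 1L]] <- a }
    }
    asg <- if (length(asg)) do.call(rbind, asg) else NULL
    if (!is.null(asg)) {
      asg <- asg[asg$confidence != "pair_ambiguous", , drop = FALSE]
      asg <- asg[!duplicated(asg$species), , drop = FALSE]
      all_assign[[sid]] <- asg
      sp_areas <- do.call(rbind, lapply(seq_len(nrow(asg)), function(i) {
        ch1 <- parse_chain(asg$sn1[i]); ch2 <- parse_chain(asg$sn2[i])
        q1 <- adduct_mz(composition_of_species(
          "PA", ch1$carbons + ch2$carbons,
          ch1$double_bonds + ch2$double_bonds), "[M-H]-")
        cbind(data.frame(sample_id = sid, species = asg$species[i]),
              area_of(q1, acyl_anion_mz(asg$sn1[i])))
      }))
    } else sp_areas <- NULL
    std_area <- cbind(data.frame(sample_id = sid, species = standard),
                      area_of(std_tr$q1_mz, std_tr$q3_mz))
    all_areas[[sid]] <- rbind(sp_areas, std_area)
  }
  areas <- do.call(rbind, all_areas)
  rownames(areas) <- NULL
  quant <- quantify_species(areas, run$meta, run$is_amounts,
                            standard = standard)
  list(assignments = all_assign, quant = quant,
       totals = total_class_amount(quant))
}
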