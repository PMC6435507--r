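# sn-1/sn-2 positional-isomer assignment from EPI fragment intensities and
# MRM co-elution. The interpretive core of the workflow:
#   match fragments -> resolve chain pairs -> assign sn order -> confirm by RT.
#
# The sn rule: at the calibrated collision energy (39 eV) the sn-1 chain's
# carboxylate anion is the most intense fragment, the sn-2 anion second.
# Intensities are only ever compared WITHIN a candidate pair, never across
# pairs sharing a precursor.

#' Match candidate chain fragments against an EPI spectrum
#'
#' Each distinct chain among the candidate pairs is mapped to the nearest
#' spectrum peak within `mz_tol` (closed interval: a peak exactly at the
#' tolerance boundary matches) or marked absent. A matched peak must also
#' reach `absence_frac` of the base peak; weaker signals count as absent.
#'
#' @param spectrum An `epi_spectrum`.
#' @param candidates data.frame of chain pairs from
#'   [decompose_sum_composition()] (columns c1, d1, c2, d2).
#' @param mz_tol Match tolerance in Da (default 0.3, suited to
#'   unit-resolution Q3; the printed observed fragments deviate up to
#'   ~0.2 Da from theory).
#' @param absence_frac Fraction of the base peak below which a fragment is
#'   called absent (default 0.01).
#' @return data.frame, one row per distinct candidate chain: `chain`,
#'   `theoretical_mz`, `present`, `matched_mz`, `mz_error`, `intensity`.
#' @export
#' @examples
#' sp <- epi_spectrum(c(253.42, 255.28, 279.25, 281.27),
#'                    c(100, 60, 30, 60), precursor_mz = 671.46)
#' match_fragments(sp, decompose_sum_composition(34, 2,
#'                 default_transition_space()))
match_fragments <- function(spectrum, candidates, mz_tol = 0.3,
                            absence_frac = 0.01) {
  stopifnot(inherits(spectrum, "epi_spectrum"), mz_tol > 0)
  if (length(spectrum$mz) == 0) stop("spectrum is empty")
  chains <- unique(rbind(data.frame(c = candidates$c1, d = candidates$d1),
                         data.frame(c = candidates$c2, d = candidates$d2)))
  if (nrow(chains) == 0)
    return(data.frame(chain = character(0), theoretical_mz = numeric(0),
                      present = logical(0), matched_mz = numeric(0),
                      mz_error = numeric(0), intensity = numeric(0)))
  chains <- chains[order(chains$c, chains$d), ]
  base_peak <- max(spectrum$intensity)
  rows <- lapply(seq_len(nrow(chains)), function(i) {
    th <- acyl_anion_mz(acyl_chain(chains$c[i], chains$d[i]))
    dmz <- abs(spectrum$mz - th)
    j <- which.min(dmz)
    # closed interval, with a float-safe epsilon so a peak placed exactly
    # at the boundary matches
    hit <- dmz[j] <= mz_tol + 1e-9 &&
      spectrum$intensity[j] >= absence_frac * base_peak
    data.frame(
      chain = sprintf("%d:%d", chains$c[i], chains$d[i]),
      theoretical_mz = th,
      present = hit,
      matched_mz = if (hit) spectrum$mz[j] else NA_real_,
      mz_error = if (hit) spectrum$mz[j] - th else NA_real_,
      intensity = if (hit) spectrum$intensity[j] else 0,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Resolve candidate pairs from fragment matches
#'
#' A candidate pair is accepted iff BOTH of its chains are present in the
#' spectrum (a self-pair such as 18:1/18:1 needs its single fragment only).
#' Accepted pairs that share a present fragment chain with another accepted
#' pair are flagged `pair_ambiguous`: fragment intensities alone cannot
#' apportion a shared ion, and only retention-time evidence
#' ([confirm_by_coelution()]) can separate them.
#'
#' @param matches Output of [match_fragments()].
#' @param candidates The same candidate pair data.frame.
#' @return data.frame of accepted pairs: `chain_a`, `chain_b` (unordered,
#'   a = lower c:d), `self_pair`, `pair_ambiguous`.
#' @export
resolve_pairs <- function(matches, candidates) {
  empty <- data.frame(chain_a = character(0), chain_b = character(0),
                      self_pair = logical(0), pair_ambiguous = logical(0))
  if (nrow(candidates) == 0) return(empty)
  present <- matches$chain[matches$present]
  lab <- function(c, d) sprintf("%d:%d", c, d)
  acc <- candidates[lab(candidates$c1, candidates$d1) %in% present &
                    lab(candidates$c2, candidates$d2) %in% present, ,
                    drop = FALSE]
  if (nrow(acc) == 0) return(empty)
  out <- data.frame(
    chain_a = lab(acc$c1, acc$d1),
    chain_b = lab(acc$c2, acc$d2),
    self_pair = acc$c1 == acc$c2 & acc$d1 == acc$d2,
    stringsAsFactors = FALSE)
  chain_use <- table(c(out$chain_a[!out$self_pair], out$chain_b[!out$self_pair],
                       out$chain_a[out$self_pair]))
  shared <- names(chain_use)[chain_use > 1]
  out$pair_ambiguous <- out$chain_a %in% shared | out$chain_b %in% shared
  rownames(out) <- NULL
  out
}

#' Assign sn-1/sn-2 order within an accepted pair
#'
#' The chain whose carboxylate anion is more intense is placed at sn-1; if
#' the two intensities differ by no more than `equality_tol` (relative), the
#' order is left `sn_ambiguous`. Identical chains are trivially resolved.
#'
#' @param pair One row of [resolve_pairs()] output (or a list with
#'   `chain_a`, `chain_b`).
#' @param matches Output of [match_fragments()].
#' @param equality_tol Relative intensity difference treated as equal
#'   (default 0.20).
#' @param collision_energy_eV Recorded in the evidence (the sn rule is
#'   calibrated at 39 eV).
#' @return One-row data.frame: `species`, `sn1`, `sn2`, `confidence`
#'   (`resolved`/`sn_ambiguous`), `intensity_sn1`, `intensity_sn2`,
#'   `collision_energy_eV`.
#' @export
assign_sn_positions <- function(pair, matches, equality_tol = 0.20,
                                collision_energy_eV = 39) {
  ia <- matches$intensity[matches$chain == pair$chain_a]
  ib <- matches$intensity[matches$chain == pair$chain_b]
  if (length(ia) != 1 || length(ib) != 1)
    stop("pair chains not found in matches")
  if (pair$chain_a == pair$chain_b) {
    sn1 <- pair$chain_a; sn2 <- pair$chain_b
    conf <- "resolved"; i1 <- ia; i2 <- ib
  } else {
    if (ia >= ib) { sn1 <- pair$chain_a; sn2 <- pair$chain_b; i1 <- ia; i2 <- ib }
    else          { sn1 <- pair$chain_b; sn2 <- pair$chain_a; i1 <- ib; i2 <- ia }
    rel <- (i1 - i2) / max(i1, i2)
    conf <- if (rel <= equality_tol) "sn_ambiguous" else "resolved"
  }
  data.frame(species = sprintf("PA(%s/%s)", sn1, sn2),
             sn1 = sn1, sn2 = sn2, confidence = conf,
             intensity_sn1 = i1, intensity_sn2 = i2,
             collision_energy_eV = collision_energy_eV,
             stringsAsFactors = FALSE)
}

#' Confirm assignments by MRM co-elution
#'
#' For each assignment, the XICs of its two chain transitions (matched by Q3
#' within `mz_tol` and, when available, Q1 within `mz_tol` of
#' `precursor_mz`) must have apexes within `rt_tol_min` of each other.
#' Agreement marks the assignment `rt_confirmed`; a contradiction (apexes
#' further apart) withdraws the confirmation and downgrades confidence to
#' `pair_ambiguous`; missing XICs leave the confidence unchanged with
#' `rt_evidence = "incomplete"`. Distinct species may of course elute at
#' distinct times — only within-pair agreement is required.
#'
#' @param assignments data.frame from [assign_sn_positions()] rows.
#' @param xics List of `chromatogram`s.
#' @param rt_tol_min Apex agreement tolerance in minutes (default 0.1).
#' @param precursor_mz Optional precursor filter for the XICs.
#' @param mz_tol Q1/Q3 matching tolerance in Da (default 0.3).
#' @return `assignments` with added columns `rt_evidence`
#'   (`confirmed`/`contradicted`/`incomplete`), `rt_apex_a`, `rt_apex_b`,
#'   and updated `confidence`.
#' @export
confirm_by_coelution <- function(assignments, xics, rt_tol_min = 0.1,
                                 precursor_mz = NULL, mz_tol = 0.3) {
  if (nrow(assignments) == 0) {
    assignments$rt_evidence <- character(0)
    assignments$rt_apex_a <- numeric(0)
    assignments$rt_apex_b <- numeric(0)
    return(assignments)
  }
  apex_of <- function(chain_lab) {
    th <- acyl_anion_mz(parse_chain(chain_lab))
    hits <- Filter(function(ch) {
      ok <- !is.na(ch$q3_mz) && abs(ch$q3_mz - th) <= mz_tol
      if (ok && !is.null(precursor_mz) && !is.na(ch$q1_mz))
        ok <- abs(ch$q1_mz - precursor_mz) <= mz_tol
      ok
    }, xics)
    if (length(hits) == 0) return(NA_real_)
    pk <- integrate_peaks(hits)
    pk <- pk[!pk$not_detected, , drop = FALSE]
    if (nrow(pk) == 0) return(NA_real_)
    pk$rt_apex_min[which.max(pk$height)]
  }
  assignments$rt_apex_a <- vapply(assignments$sn1, apex_of, numeric(1))
  assignments$rt_apex_b <- vapply(assignments$sn2, apex_of, numeric(1))
  delta <- abs(assignments$rt_apex_a - assignments$rt_apex_b)
  ev <- ifelse(is.na(delta), "incomplete",
               ifelse(delta <= rt_tol_min, "confirmed", "contradicted"))
  assignments$rt_evidence <- ev
  assignments$confidence[ev == "contradicted"] <- "pair_ambiguous"
  # RT is the one evidence that can separate pairs sharing a fragment:
  # a pair-ambiguous assignment is restored only if it co-elutes internally
  # AND every other assignment sharing one of its chains elutes at a
  # demonstrably different time
  mean_apex <- (assignments$rt_apex_a + assignments$rt_apex_b) / 2
  for (i in which(ev == "confirmed" &
                  assignments$confidence == "pair_ambiguous")) {
    others <- setdiff(seq_len(nrow(assignments)), i)
    sharing <- others[assignments$sn1[others] %in%
                        c(assignments$sn1[i], assignments$sn2[i]) |
                      assignments$sn2[others] %in%
                        c(assignments$sn1[i], assignments$sn2[i])]
    separated <- all(is.finite(mean_apex[sharing]) &
                     abs(mean_apex[sharing] - mean_apex[i]) > rt_tol_min)
    if (length(sharing) == 0 || separated)
      assignments$confidence[i] <- "resolved"
  }
  rownames(assignments) <- NULL
  assignments
}

#' Identify the molecular species behind one EPI spectrum
#'
#' Convenience pipeline: candidate decomposition, fragment matching, pair
#' resolution, sn assignment, and (if XICs are supplied) retention-time
#' confirmation. Output is deterministic and independent of input peak
#' ordering.
#'
#' @param spectrum An `epi_spectrum`.
#' @param m,n Sum composition of the precursor.
#' @param space `chain_space` of candidate chains (default
#'   [default_transition_space()]).
#' @param xics Optional list of `chromatogram`s for co-elution checks.
#' @param mz_tol,absence_frac,equality_tol,rt_tol_min Tuning knobs; see the
#'   stage functions.
#' @return data.frame of assignments (possibly zero rows), with evidence
#'   columns.
#' @export
#' @examples
#' sp <- epi_spectrum(c(253.42, 255.28, 279.25, 281.27),
#'                    c(100, 60, 30, 60), precursor_mz = 671.46)
#' identify_species(sp, 34, 2)
identify_species <- function(spectrum, m, n,
                             space = default_transition_space(),
                             xics = NULL, mz_tol = 0.3, absence_frac = 0.01,
                             equality_tol = 0.20, rt_tol_min = 0.1) {
  candidates <- decompose_sum_composition(m, n, space)
  matches <- match_fragments(spectrum, candidates, mz_tol, absence_frac)
  pairs <- resolve_pairs(matches, candidates)
  if (nrow(pairs) == 0) {
    out <- data.frame(species = character(0), sn1 = character(0),
                      sn2 = character(0), confidence = character(0),
                      intensity_sn1 = numeric(0), intensity_sn2 = numeric(0),
                      collision_energy_eV = numeric(0))
  } else {
    out <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
      a <- assign_sn_positions(pairs[i, ], matches, equality_tol)
      if (pairs$pair_ambiguous[i]) a$confidence <- "pair_ambiguous"
      a
    }))
  }
  if (!is.null(xics))
    out <- confirm_by_coelution(out, xics, rt_tol_min,
                                precursor_mz = spectrum$precursor_mz,
                                mz_tol = mz_tol)
  rownames(out) <- NULL
  out
}
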