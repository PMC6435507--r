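# fragment matching, pair resolution, sn assignment, co-elution confirmation

candidates_342 <- function() decompose_sum_composition(
  34, 2, default_transition_space())

test_that("match_fragments resolves the worked 34:2 example", {
  m <- match_fragments(fig5d_spectrum(), candidates_342(), mz_tol = 0.3)
  present <- m$chain[m$present]
  expect_setequal(present, c("16:0", "16:1", "18:1", "18:2"))
  expect_setequal(m$chain[!m$present], c("14:2", "20:0", "16:2", "18:0"))
  # observed peaks sit up to ~0.2 Da above theory at unit resolution
  expect_true(all(abs(m$mz_error[m$present]) <= 0.3))
})

test_that("match_fragments edge rules: closed tolerance, absence floor", {
  cand <- data.frame(c1 = 16L, d1 = 0L, c2 = 18L, d2 = 2L)
  th <- acyl_anion_mz("16:0")
  # peak exactly at the tolerance boundary matches (closed interval)
  sp <- epi_spectrum(c(th + 0.3), c(100), 671.46)
  expect_true(match_fragments(sp, cand, mz_tol = 0.3)$present[
    match_fragments(sp, cand, mz_tol = 0.3)$chain == "16:0"])
  # a peak below absence_frac of the base peak is absent
  sp2 <- epi_spectrum(c(th, 100), c(0.5, 100), 671.46)
  m2 <- match_fragments(sp2, cand, absence_frac = 0.01)
  expect_false(m2$present[m2$chain == "16:0"])
  # empty candidate set -> empty map
  expect_identical(nrow(match_fragments(sp, cand[0, ])), 0L)
  expect_error(match_fragments(epi_spectrum(numeric(0), numeric(0), 671),
                               cand), "empty")
})

test_that("resolve_pairs accepts only fully evidenced pairs", {
  cand <- candidates_342()
  m <- match_fragments(fig5d_spectrum(), cand)
  pairs <- resolve_pairs(m, cand)
  expect_identical(nrow(pairs), 2L)
  expect_setequal(paste(pairs$chain_a, pairs$chain_b),
                  c("16:0 18:2", "16:1 18:1"))
  expect_false(any(pairs$pair_ambiguous))

  # an unpaired fragment accepts nothing
  solo <- epi_spectrum(acyl_anion_mz("16:0"), 100, 671.46)
  expect_identical(nrow(resolve_pairs(match_fragments(solo, cand), cand)), 0L)
})

test_that("a self-pair is accepted from its single fragment", {
  cand <- decompose_sum_composition(36, 2, default_transition_space())
  sp <- epi_spectrum(acyl_anion_mz("18:1"), 100, 699.49)
  pairs <- resolve_pairs(match_fragments(sp, cand), cand)
  expect_identical(nrow(pairs), 1L)
  expect_true(pairs$self_pair)
  asg <- assign_sn_positions(pairs[1, ], match_fragments(sp, cand))
  expect_identical(asg$species, "PA(18:1/18:1)")
  expect_identical(asg$confidence, "resolved")
})

test_that("sn assignment follows the intensity rule with an equality band", {
  cand <- candidates_342()
  m <- match_fragments(fig5d_spectrum(), cand)
  pairs <- resolve_pairs(m, cand)
  asg <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i)
    assign_sn_positions(pairs[i, ], m)))
  expect_setequal(asg$species, c("PA(16:1/18:1)", "PA(16:0/18:2)"))
  # I(253.42)=100 vs I(281.27)=60: clearly ordered
  expect_identical(asg$confidence[asg$species == "PA(16:1/18:1)"], "resolved")
  # within 20% relative difference the order is ambiguous
  m2 <- m
  m2$intensity[m2$chain == "16:1"] <- 66  # vs 18:1 at 60: 9% apart
  asg2 <- assign_sn_positions(pairs[pairs$chain_a == "16:1", ], m2)
  expect_identical(asg2$confidence, "sn_ambiguous")
  expect_identical(asg2$sn1, "16:1")  # still placed by the higher intensity
})

test_that("co-elution confirms, contradicts, or stays incomplete", {
  mk_xic <- function(q3, apex) {
    t <- seq(apex - 0.5, apex + 0.5, 0.01)
    chromatogram(t, 1e4 * exp(-(t - apex)^2 / (2 * 0.05^2)),
                 q1_mz = 671.47, q3_mz = q3)
  }
  asg <- identify_species(fig5d_spectrum(), 34, 2)
  # both species co-elute internally at distinct times (9.45 vs 9.36)
  xics <- list(mk_xic(acyl_anion_mz("16:1"), 9.45),
               mk_xic(acyl_anion_mz("18:1"), 9.45),
               mk_xic(acyl_anion_mz("16:0"), 9.36),
               mk_xic(acyl_anion_mz("18:2"), 9.36))
  conf <- confirm_by_coelution(asg, xics, rt_tol_min = 0.1)
  expect_true(all(conf$rt_evidence == "confirmed"))
  expect_true(all(conf$confidence == "resolved"))

  # an apex contradiction withdraws the pair
  xics2 <- list(mk_xic(acyl_anion_mz("16:1"), 9.45),
                mk_xic(acyl_anion_mz("18:1"), 8.00),
                mk_xic(acyl_anion_mz("16:0"), 9.36),
                mk_xic(acyl_anion_mz("18:2"), 9.36))
  conf2 <- confirm_by_coelution(asg, xics2, rt_tol_min = 0.1)
  bad <- conf2[conf2$sn1 == "16:1", ]
  expect_identical(bad$rt_evidence, "contradicted")
  expect_identical(bad$confidence, "pair_ambiguous")

  # no XICs: evidence incomplete, confidence untouched
  conf3 <- confirm_by_coelution(asg, list(), rt_tol_min = 0.1)
  expect_true(all(conf3$rt_evidence == "incomplete"))
  expect_identical(conf3$confidence, asg$confidence)
})

test_that("sub-threshold peaks never change the output (stability)", {
  sp <- fig5d_spectrum()
  base <- identify_species(sp, 34, 2)
  # inject peaks below absence_frac (1%) of the base peak, incl. at a
  # candidate mass (20:0)
  sp2 <- epi_spectrum(c(sp$mz, acyl_anion_mz("20:0"), 400.0),
                      c(sp$intensity, 0.5, 0.9), sp$precursor_mz, sp$rt_min)
  expect_identical(identify_species(sp2, 34, 2), base)
})

test_that("output is independent of input peak ordering", {
  sp <- fig5d_spectrum()
  set.seed(4)
  for (i in 1:5) {
    ord <- sample(length(sp$mz))
    shuffled <- epi_spectrum(sp$mz[ord], sp$intensity[ord],
                             sp$precursor_mz, sp$rt_min)
    expect_identical(identify_species(shuffled, 34, 2),
                     identify_species(sp, 34, 2))
  }
})

test_that("noise-free pipeline recovers truth exactly for small panels", {
  truth <- small_truth(n_species = 10, n_replicates = 1)
  run <- simulate_run(truth, noise = list(intensity_cv = 0,
                                          mz_sigma_da = 0,
                                          rt_jitter_min = 0),
                      sn_bias = 1.7, seed = 3)
  res <- run_pipeline(run)
  for (sid in names(res$assignments)) {
    asg <- res$assignments[[sid]]
    expect_setequal(asg$species, truth$panel$species)
    expect_true(all(asg$confidence == "resolved"))
  }
  # quantitation recovers amounts up to integration error (< 2%)
  q <- res$quant
  truth_amt <- truth$amounts[cbind(q$species, q$sample_id)]
  expect_true(all(abs(q$amount_pmol - truth_amt) / truth_amt < 0.02))
})
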