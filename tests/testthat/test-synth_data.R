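# ground-truth construction and raw-data simulation

test_that("default panel and design match the stated study world", {
  panel <- default_panel()
  expect_identical(nrow(panel), 39L)
  expect_identical(anyDuplicated(panel$species), 0L)
  # every panel chain lies inside the identification space
  for (ch in unique(c(panel$sn1, panel$sn2))) {
    p <- parse_chain(ch)
    expect_true(chain_in_space(p$carbons, p$double_bonds,
                               default_transition_space()), info = ch)
  }
  # amounts inside the linear range
  expect_true(all(check_linear_range(panel$base_amount_pmol) == "ok"))

  design <- default_design(panel)
  expect_identical(sum(design$mutant < 1), 30L)
  expect_identical(sum(design$designed_restored), 16L)
  expect_true(all(design$rescue[design$reduced & !design$designed_restored]
                  > design$mutant[design$reduced & !design$designed_restored]))
})

test_that("ground truth assembles amounts as base x multiplier", {
  truth <- ground_truth(n_replicates = 3)
  expect_identical(dim(truth$amounts), c(39L, 9L))
  expect_identical(nrow(truth$meta), 9L)
  i <- which(truth$design$reduced)[1]
  expect_equal(truth$amounts[i, "mutant_2"],
               truth$panel$base_amount_pmol[i] * truth$design$mutant[i])
  expect_equal(truth$amounts[i, "WT_1"], truth$panel$base_amount_pmol[i])
})

test_that("simulate_run is deterministic under a fixed seed", {
  truth <- small_truth(n_species = 3, n_replicates = 1)
  r1 <- simulate_run(truth, seed = 123)
  r2 <- simulate_run(truth, seed = 123)
  expect_identical(r1, r2)
  r3 <- simulate_run(truth, seed = 124)
  expect_false(identical(r1, r3))
  # the global RNG stream is left untouched
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(simulate_run(truth, seed = 5)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("noise-free EPI spectra encode the sn bias exactly", {
  panel <- default_panel()[7, ]  # a single resolved species
  truth <- ground_truth(panel, default_design(panel, 1, 1), n_replicates = 1)
  run <- simulate_run(truth, noise = list(intensity_cv = 0, mz_sigma_da = 0,
                                          rt_jitter_min = 0),
                      sn_bias = 1.7, seed = 1)
  sp <- Filter(function(s) grepl(panel$species, s$id, fixed = TRUE),
               run$samples[[1]]$spectra)[[1]]
  expect_length(sp$mz, 2L)
  i_sn1 <- which.min(abs(sp$mz - acyl_anion_mz(panel$sn1)))
  expect_equal(sp$intensity[i_sn1] / sp$intensity[-i_sn1], 1.7,
               tolerance = 1e-12)
  # fragments sit exactly at theory with zero m/z noise
  expect_equal(sort(sp$mz),
               sort(c(acyl_anion_mz(panel$sn1), acyl_anion_mz(panel$sn2))),
               tolerance = 1e-9)
})

test_that("XIC areas are proportional to spiked amounts (no noise)", {
  truth <- small_truth(n_species = 2, n_replicates = 1)
  run <- simulate_run(truth, noise = list(intensity_cv = 0, mz_sigma_da = 0,
                                          rt_jitter_min = 0), seed = 1)
  xics <- run$samples[[1]]$chromatograms
  sn1_area <- function(sp_lab) {
    tr <- run$transitions
    t1 <- tr[tr$species == sp_lab & tr$position == "sn1", ]
    hit <- Filter(function(ch) abs(ch$q3_mz - t1$q3_mz) < 0.01 &&
                    abs(ch$q1_mz - t1$q1_mz) < 0.01, xics)
    integrate_peak(hit[[1]])$area
  }
  a1 <- sn1_area(truth$panel$species[1])
  a2 <- sn1_area(truth$panel$species[2])
  amt <- truth$amounts[, 1]
  expect_equal(a1 / a2, amt[[1]] / amt[[2]], tolerance = 0.02)
})

test_that("quantitation error grows with intensity CV", {
  truth <- small_truth(n_species = 8, n_replicates = 2)
  mean_err <- function(cv) {
    errs <- vapply(1:25, function(s) {
      q <- simulate_amounts(truth, cv = cv, seed = 1000 + s)
      truth_amt <- truth$amounts[cbind(q$species, q$sample_id)]
      mean(abs(q$amount_pmol - truth_amt) / truth_amt)
    }, numeric(1))
    mean(errs)
  }
  e <- vapply(c(0.01, 0.05, 0.15), mean_err, numeric(1))
  expect_true(all(diff(e) > 0))
})

test_that("simulated runs survive an mzML round trip", {
  truth <- small_truth(n_species = 2, n_replicates = 1)
  run <- simulate_run(truth, seed = 2)
  path <- withr::local_tempfile(fileext = ".mzML")
  write_mzml(run$samples[[1]], path)
  back <- read_spectra(path)
  expect_length(back$chromatograms,
                length(run$samples[[1]]$chromatograms))
  expect_length(back$spectra, length(run$samples[[1]]$spectra))
  expect_identical(back$chromatograms[[1]]$intensity,
                   run$samples[[1]]$chromatograms[[1]]$intensity)
})
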