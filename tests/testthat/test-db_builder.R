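# chain spaces, decomposition, MS1/MSMS tables, transition-list design

test_that("decompose_sum_composition matches the published 34:2 candidates", {
  d <- decompose_sum_composition(34, 2, default_transition_space())
  expect_identical(pair_keys(d),
                   c("14:2|20:0", "16:0|18:2", "16:1|18:1", "16:2|18:0"))
  # deterministic sort by (c1, d1)
  expect_identical(d$c1, c(14L, 16L, 16L, 16L))
  expect_identical(d$d1, c(2L, 0L, 1L, 2L))
})

test_that("decompose handles symmetric and empty cases", {
  d <- decompose_sum_composition(24, 0)
  expect_identical(pair_keys(d), "12:0|12:0")
  expect_identical(nrow(decompose_sum_composition(10, 6)), 0L)
  expect_identical(nrow(decompose_sum_composition(0, 0)), 0L)
})

test_that("decompose equals the brute-force oracle on a reduced grid", {
  space <- chain_space(12, 20, allow_odd_carbons = TRUE,
                       max_db_per_chain = 3, saturated_above = 18)
  for (m in seq(24, 40, by = 2)) for (n in 0:5)
    expect_identical(pair_keys(decompose_sum_composition(m, n, space)),
                     oracle_decompose(m, n, space),
                     info = sprintf("m=%d n=%d", m, n))
})

test_that("build_ms1_table has nine adduct columns and the right shape", {
  t1 <- build_ms1_table("PA", 34, 2)
  expect_identical(nrow(t1), 1L)
  expect_true(all(adduct_names() %in% names(t1)))
  expect_identical(t1[["[M-H]-_display"]], "671.46")
  expect_identical(sum(adduct_names() %in% names(t1)), 9L)

  grid <- build_ms1_table("PA", 30:40, 0:6)
  expect_identical(nrow(grid), 11L * 7L)
  expect_true(all(grid$valid[grid$m == 34 & grid$n == 2]))

  # no chain pair in the default space can sum to 10:6
  bad <- build_ms1_table("PA", 10, 6)
  expect_false(bad$valid)
  expect_error(build_ms1_table("PA", integer(0), 0:2), "empty")
  expect_error(build_ms1_table("PQ", 30:34, 0), "unknown lipid class")
})

test_that("build_msms_table lists acyl anion and lyso fragments", {
  t181 <- build_msms_table("18:1")
  an <- t181[t181$fragment_type == "acyl_anion", ]
  expect_equal(an$mz, 281.2486, tolerance = 5e-4)

  t160 <- build_msms_table("16:0")
  lyso <- t160[t160$fragment_type == "lyso_MH", ]
  expect_equal(lyso$mz, 409.2361, tolerance = 5e-4)
  expect_identical(lyso$formula, "C19H39O7P")

  # complementary chains generate precursor + complement-lyso rows
  expect_true(all(c("precursor_MH", "complement_lyso_MH") %in%
                    t160$fragment_type))
  expect_error(build_msms_table("0:0"), ">= 1 carbon|parse")
})

test_that("build_transition_list reproduces the 8-transition 34:2 panel", {
  tl <- build_transition_list("PA(34:2)")
  expect_identical(nrow(tl), 8L)
  expect_setequal(tl$q3_display,
                  c("223.17", "255.23", "253.21", "251.20",
                    "283.26", "281.24", "279.23", "311.29"))
  expect_true(all(tl$q1_display == "671.46"))
  expect_true(all(tl$q1_mz > tl$q3_mz))
  # within one sum composition a chain determines its partner, so no
  # fragment is shared between accepted pairs
  expect_false(any(tl$shared_fragment))
  expect_identical(unique(tl$dwell_ms), 30)
  expect_identical(unique(tl$collision_energy_eV), 39)
})

test_that("transition-list overflow and degenerate panels error", {
  expect_error(build_transition_list(character(0)), "empty|parse")
  expect_error(build_transition_list(data.frame()), "empty")
  panel <- data.frame(m = seq(28, 46, by = 2), n = rep(0:4, 2))
  expect_error(build_transition_list(rbind(panel, panel[1, ])),
               "duplicate")
  wide <- chain_space(12, 24, max_db_per_chain = 6)
  err <- tryCatch(
    build_transition_list(expand.grid(m = seq(30, 40, 2), n = 0:5),
                          space = wide, max_transitions = 75),
    error = conditionMessage)
  expect_match(err, "exceed the maximum of 75")
  expect_match(err, "[0-9]+ transitions")
})

test_that("priority list truncates an overflowing panel deterministically", {
  panel <- data.frame(m = seq(30, 40, 2), n = rep(2, 6))
  labs <- sprintf("PA(%d:%d)", panel$m, panel$n)
  full <- build_transition_list(panel, max_transitions = 1e6)
  capped <- build_transition_list(panel, max_transitions = 10,
                                  priority = rev(labs))
  expect_identical(nrow(capped), 10L)
  # species appear in priority order
  expect_false(is.unsorted(match(capped$species, rev(labs))))
})

test_that("write_database round-trips a transition list through CSV", {
  tl <- build_transition_list("PA(34:2)")
  path <- withr::local_tempfile(fileext = ".csv")
  write_database(tl, path)
  back <- read.csv(path, check.names = FALSE)
  expect_identical(nrow(back), nrow(tl))
  expect_equal(back$q1_mz, tl$q1_mz, tolerance = 1e-9)
  expect_identical(back$chain, tl$chain)
})
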