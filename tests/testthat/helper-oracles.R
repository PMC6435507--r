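# Independent oracles used by unit and acceptance tests. These deliberately
# do NOT reuse the package's enumeration/statistics code paths.

# brute-force chain-pair enumeration: double loop over every chain in the
# space, canonicalized to unordered pairs
oracle_decompose <- function(m, n, space) {
  hit <- list()
  for (c1 in 1:m) for (d1 in 0:n) {
    c2 <- m - c1; d2 <- n - d1
    if (c2 < 1) next
    in_space <- function(cc, dd) {
      ok <- cc >= space$min_carbons && cc <= space$max_carbons &&
        dd <= space$max_db_per_chain
      if (!space$allow_odd_carbons && cc %% 2 == 1) ok <- FALSE
      if (cc > space$saturated_above && dd > 0) ok <- FALSE
      ok
    }
    if (!in_space(c1, d1) || !in_space(c2, d2)) next
    key <- if (c1 < c2 || (c1 == c2 && d1 <= d2))
      sprintf("%d:%d|%d:%d", c1, d1, c2, d2)
    else sprintf("%d:%d|%d:%d", c2, d2, c1, d1)
    hit[[key]] <- TRUE
  }
  keys <- names(hit)
  if (is.null(keys)) character(0) else sort(keys)
}

pair_keys <- function(df) {
  if (nrow(df) == 0) return(character(0))
  sort(sprintf("%d:%d|%d:%d", df$c1, df$d1, df$c2, df$d2))
}

# hand-pinned monoisotopic atomic masses (same constants the package
# documents, summed independently here)
oracle_mass <- function(C = 0, H = 0, D = 0, O = 0, P = 0, charge = 0) {
  C * 12 + H * 1.00782503 + D * 2.01410178 + O * 15.99491462 +
    P * 30.97376151 - charge * 0.00054858
}

# Fig 5D worked-example spectrum: observed fragment m/z with the printed
# intensity ordering I253.42 > I255.28 = I281.27 > I279.25
fig5d_spectrum <- function() {
  epi_spectrum(mz = c(253.42, 255.28, 279.25, 281.27),
               intensity = c(100, 60, 30, 60),
               precursor_mz = 671.46, rt_min = 9.4)
}

# small resolved panel for pipeline tests
small_truth <- function(n_species = 6, n_replicates = 2) {
  panel <- default_panel()[seq_len(n_species), ]
  ground_truth(panel, default_design(panel, n_reduced = min(4, n_species),
                                     n_restored = min(2, n_species)),
               n_replicates = n_replicates)
}
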