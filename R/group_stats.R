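# Per-species two-group comparisons and restoration/elevation calls.
#
# "Restored to wild-type" is operationalized as FAILURE to reject equality
# of the reconstituted group and wild type at the configured alpha — an
# absence-of-evidence criterion, stated prominently here and in the methods
# vignette because it is the implicit rule behind per-species restoration
# tables. No multiple-testing correction is applied by default (per-species
# reporting); a Bonferroni flag exists.

#' Per-species two-group comparison (Student's t)
#'
#' Unpaired two-tailed Student's (equal-variance) t test per species,
#' computed in closed form. Species with fewer than 2 replicates in either
#' group are skipped with a message. Degenerate case: identical group means
#' with zero pooled variance give t = 0, p = 1; different means with zero
#' variance give p = 0.
#'
#' @param quant `quant_result` table (or any data.frame with `species`,
#'   `group` and a value column).
#' @param group_a,group_b Group labels; `group_a` is the first (its mean is
#'   `mean_a`, and the sign of t is mean_a - mean_b).
#' @param value Value column (default `"amount_per_phosphate"`).
#' @param var_equal Use the pooled-variance Student test (default TRUE);
#'   FALSE gives Welch.
#' @return data.frame of class `species_comparison`: `species`, `group_a`,
#'   `group_b`, `mean_a`, `mean_b`, `n_a`, `n_b`, `t_statistic`, `df`,
#'   `p_value`.
#' @export
#' @examples
#' q <- data.frame(species = "PA(16:0/18:2)",
#'                 group = rep(c("WT", "mut"), each = 3),
#'                 amount_per_phosphate = c(1, 2, 3, 4, 5, 6))
#' compare_species(q, "WT", "mut")  # t = -3.674, p = 0.0214
compare_species <- function(quant, group_a, group_b,
                            value = "amount_per_phosphate",
                            var_equal = TRUE) {
  stopifnot(all(c("species", "group", value) %in% names(quant)))
  rows <- lapply(split(quant, quant$species), function(d) {
    xa <- d[[value]][d$group == group_a]
    xb <- d[[value]][d$group == group_b]
    if (length(xa) < 2 || length(xb) < 2) {
      message("skipping species ", d$species[1],
              ": fewer than 2 replicates in a group")
      return(NULL)
    }
    na <- length(xa); nb <- length(xb)
    ma <- mean(xa); mb <- mean(xb)
    va <- stats::var(xa); vb <- stats::var(xb)
    if (var_equal) {
      sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
      se <- sqrt(sp2 * (1 / na + 1 / nb))
      df <- na + nb - 2
    } else {
      se <- sqrt(va / na + vb / nb)
      df <- (va / na + vb / nb)^2 /
        ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    }
    if (se == 0) {
      tstat <- if (ma == mb) 0 else sign(ma - mb) * Inf
      p <- if (ma == mb) 1 else 0
    } else {
      tstat <- (ma - mb) / se
      p <- 2 * stats::pt(-abs(tstat), df)
    }
    data.frame(species = d$species[1], group_a = group_a, group_b = group_b,
               mean_a = ma, mean_b = mb, n_a = na, n_b = nb,
               t_statistic = tstat, df = df, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(species = character(0), group_a = character(0),
                      group_b = character(0), mean_a = numeric(0),
                      mean_b = numeric(0), n_a = integer(0), n_b = integer(0),
                      t_statistic = numeric(0), df = numeric(0),
                      p_value = numeric(0))
  rownames(out) <- NULL
  class(out) <- c("species_comparison", "data.frame")
  out
}

#' Restoration / elevation calls per species
#'
#' Given the reconstituted-vs-wild-type and reconstituted-vs-mutant
#' comparisons (both with the reconstituted group as `group_a`):
#' `restored_to_wt` iff p(vs WT) >= alpha (no detectable difference from
#' wild type); `elevated_over_mutant` iff p(vs mutant) < alpha AND the
#' reconstituted mean exceeds the mutant mean. Species missing from either
#' comparison are omitted.
#'
#' @param vs_wt `species_comparison` of reconstituted vs wild type.
#' @param vs_mutant `species_comparison` of reconstituted vs mutant.
#' @param alpha Significance level (default 0.05).
#' @param bonferroni Apply a Bonferroni correction across species before
#'   calling (default FALSE, matching per-species reporting).
#' @return data.frame of class `restoration_call`: `species`,
#'   `restored_to_wt`, `elevated_over_mutant`, `p_vs_wt`, `p_vs_mutant`,
#'   `mean_reconstituted`, `mean_wt`, `mean_mutant`.
#' @export
call_restoration <- function(vs_wt, vs_mutant, alpha = 0.05,
                             bonferroni = FALSE) {
  common <- intersect(vs_wt$species, vs_mutant$species)
  missing <- union(setdiff(vs_wt$species, common),
                   setdiff(vs_mutant$species, common))
  if (length(missing))
    message("omitting species without both comparisons: ",
            paste(missing, collapse = ", "))
  w <- vs_wt[match(common, vs_wt$species), ]
  m <- vs_mutant[match(common, vs_mutant$species), ]
  thr <- if (bonferroni) alpha / length(common) else alpha
  out <- data.frame(
    species = common,
    restored_to_wt = w$p_value >= thr,
    elevated_over_mutant = m$p_value < thr & m$mean_a > m$mean_b,
    p_vs_wt = w$p_value, p_vs_mutant = m$p_value,
    mean_reconstituted = w$mean_a, mean_wt = w$mean_b, mean_mutant = m$mean_b,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("restoration_call", "data.frame")
  out
}
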