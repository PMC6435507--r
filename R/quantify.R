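# Internal-standard relative quantitation of PA species, normalized to
# total lipid phosphate (pmol analyte per nmol Pi).

#' Sample metadata table constructor/validator
#'
#' @param sample_id Character vector of unique sample identifiers.
#' @param group Group label per sample (e.g. genotype).
#' @param replicate Replicate index per sample.
#' @param total_phosphate_nmol Total lipid phosphate per sample (nmol,
#'   externally measured; the normalization denominator). Must be > 0.
#' @return data.frame of class `sample_meta`.
#' @export
sample_meta <- function(sample_id, group, replicate, total_phosphate_nmol) {
  if (anyDuplicated(sample_id)) stop("sample_id values must be unique")
  if (any(total_phosphate_nmol <= 0))
    stop("total_phosphate_nmol must be > 0")
  structure(data.frame(sample_id = as.character(sample_id),
                       group = as.character(group),
                       replicate = as.integer(replicate),
                       total_phosphate_nmol = as.numeric(total_phosphate_nmol),
                       stringsAsFactors = FALSE),
            class = c("sample_meta", "data.frame"))
}

#' Internal-standard quantitation of species peak areas
#'
#' Ratio-based single-point quantitation against a spiked internal standard
#' (default the odd-chain species PA(17:0/14:1), which cannot occur
#' endogenously): `amount_pmol = area_species / area_standard * spiked_pmol`
#' with an assumed response factor of 1.0, then normalized per nmol total
#' lipid phosphate. Being a ratio, the result is invariant to any global
#' intensity scaling of a run.
#'
#' @param areas data.frame with columns `sample_id`, `species`, `area` (one
#'   row per species per sample; a `not_detected` logical column is
#'   honoured if present).
#' @param meta A [sample_meta()] table.
#' @param is_amounts Named numeric vector: spiked amount (pmol) per internal
#'   standard species, e.g. `c("PA(17:0/14:1)" = 10)`.
#' @param standard Species label of the internal standard to use (default
#'   `"PA(17:0/14:1)"`; must be a name of `is_amounts` and present in every
#'   sample's areas).
#' @param response_factors Optional named numeric vector of per-species
#'   response factors (default all 1.0); amounts are divided by the factor.
#' @return data.frame of class `quant_result`: `sample_id`, `group`,
#'   `replicate`, `species`, `amount_pmol`, `amount_per_phosphate`
#'   (pmol/nmol), `flag` (`ok`/`not_detected`/`below_linear`/`above_linear`).
#' @export
quantify_species <- function(areas, meta, is_amounts,
                             standard = "PA(17:0/14:1)",
                             response_factors = NULL) {
  stopifnot(all(c("sample_id", "species", "area") %in% names(areas)))
  if (!standard %in% names(is_amounts))
    stop("no spiked amount given for standard ", standard)
  spike <- is_amounts[[standard]]
  rows <- lapply(split(areas, areas$sample_id), function(a) {
    sid <- a$sample_id[1]
    mrow <- meta[meta$sample_id == sid, , drop = FALSE]
    if (nrow(mrow) != 1) stop("sample missing from metadata: ", sid)
    std_area <- a$area[a$species == standard]
    if (length(std_area) != 1)
      stop("internal standard ", standard, " missing in sample ", sid)
    if (!is.finite(std_area) || std_area <= 0)
      stop("internal standard area is zero/invalid in sample ", sid)
    targets <- a[!a$species %in% names(is_amounts), , drop = FALSE]
    rf <- rep(1, nrow(targets))
    if (!is.null(response_factors)) {
      hit <- match(targets$species, names(response_factors))
      rf[!is.na(hit)] <- response_factors[hit[!is.na(hit)]]
    }
    amount <- targets$area / std_area * spike / rf
    nd <- if ("not_detected" %in% names(targets)) targets$not_detected
          else targets$area <= 0
    flag <- ifelse(nd, "not_detected", check_linear_range(amount))
    amount[nd] <- 0
    data.frame(sample_id = sid, group = mrow$group,
               replicate = mrow$replicate, species = targets$species,
               amount_pmol = amount,
               amount_per_phosphate = amount / mrow$total_phosphate_nmol,
               flag = flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("quant_result", "data.frame")
  out
}

#' Per-sample total class amount
#'
#' Sum of species amounts per sample, in the same units (both `amount_pmol`
#' and `amount_per_phosphate`).
#'
#' @param results A `quant_result` table (one lipid class).
#' @return data.frame: `sample_id`, `group`, `total_pmol`,
#'   `total_per_phosphate`.
#' @export
total_class_amount <- function(results) {
  if (nrow(results) == 0) {
    warning("empty quantitation table: total is 0")
    return(data.frame(sample_id = character(0), group = character(0),
                      total_pmol = numeric(0),
                      total_per_phosphate = numeric(0)))
  }
  agg <- stats::aggregate(
    results[c("amount_pmol", "amount_per_phosphate")],
    by = list(sample_id = results$sample_id, group = results$group),
    FUN = sum)
  names(agg)[3:4] <- c("total_pmol", "total_per_phosphate")
  agg[order(agg$sample_id), ]
}

#' Linear-range flag for a quantified amount
#'
#' The instrument response is linear between 1 fmol and 12 pmol for PA
#' standards; amounts outside that window are flagged.
#'
#' @param amount_pmol Amount(s) in pmol.
#' @param lo,hi Linear range bounds in pmol (defaults 0.001 and 12).
#' @return Character vector: `"ok"`, `"below_linear"` or `"above_linear"`.
#' @export
#' @examples
#' check_linear_range(c(5, 13, 0.0005))
check_linear_range <- function(amount_pmol, lo = 0.001, hi = 12) {
  ifelse(amount_pmol < lo, "below_linear",
         ifelse(amount_pmol > hi, "above_linear", "ok"))
}

#' Write a quantitation table to CSV
#' @param results `quant_result` table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_quant_csv <- function(results, path) {
  utils::write.csv(results, path, row.names = FALSE)
  invisible(path)
}
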