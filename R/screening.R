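#' Volumetric lipid yield of a culture
#'
#' `dry_biomass * lipid_content / 100`: grams of lipid per litre of
#' culture, the quantity that actually matters when comparing feedstock
#' candidates whose biomass and lipid fraction trade off against each
#' other. Reported at three decimals (half-up). `NA` inputs propagate.
#'
#' @param dry_biomass Dry biomass in g per L of culture (>= 0).
#' @param lipid_content Lipid content as percent of dry biomass (0--100).
#' @return Numeric vector of yields in g L⁻¹.
#' @examples
#' lipid_volumetric_yield(1.34, 62.63)  # 0.839
#' @export
lipid_volumetric_yield <- function(dry_biomass, lipid_content) {
  if (any(dry_biomass < 0, na.rm = TRUE)) {
    abort("`dry_biomass` must be >= 0", class = "famescreen_config_error")
  }
  if (any(lipid_content < 0 | lipid_content > 100, na.rm = TRUE)) {
    abort("`lipid_content` must be within 0..100 percent",
          class = "famescreen_config_error")
  }
  round_half_up(dry_biomass * lipid_content / 100, 3L)
}

#' Join culture metrics, profiles, properties and compliance into one
#' screening table
#'
#' Builds the per-isolate feedstock screening summary: culture metrics
#' (dry biomass, lipid content), the derived volumetric lipid yield, FAME
#' recovery (total FAME as percent of total lipid), the average degree of
#' unsaturation, and the overall standards verdict.
#'
#' @param metrics Tibble of culture metrics as returned by
#'   [isolate_metrics()] (columns `sample_id`, `dry_biomass_g_per_L`,
#'   `lipid_content_pct`; extra columns are ignored).
#' @param profiles Named list of [fame_profile()] objects; samples without
#'   a profile get `NA` for the profile-derived columns.
#' @inheritParams compute_fuel_properties
#' @param criteria Criterion table for the compliance verdict.
#' @return Tibble with columns `sample_id`, `dry_biomass`,
#'   `lipid_content`, `lipid_yield`, `fame_recovery`, `adu`,
#'   `overall_pass`.
#' @examples
#' suppressWarnings(screening_summary())
#' @export
screening_summary <- function(metrics = isolate_metrics(),
                              profiles = microalgae_profiles(),
                              correlations = default_correlations(),
                              criteria = default_criteria(),
                              policy = "paper") {
  rows <- lapply(seq_len(nrow(metrics)), function(i) {
    id <- metrics$sample_id[[i]]
    biomass <- metrics$dry_biomass_g_per_L[[i]]
    lipid <- metrics$lipid_content_pct[[i]]
    prof <- profiles[[id]]
    if (is.null(prof)) {
      recovery <- NA_real_; adu <- NA_real_; ok <- NA
    } else {
      recovery <- total_fame(prof)
      props <- compute_fuel_properties(prof, correlations, policy)
      adu <- props$adu
      ok <- evaluate_compliance(props, criteria)$overall_pass
    }
    tibble(sample_id = id, dry_biomass = biomass, lipid_content = lipid,
           lipid_yield = lipid_volumetric_yield(biomass, lipid),
           fame_recovery = recovery, adu = adu, overall_pass = ok)
  })
  dplyr::bind_rows(rows)
}

#' Rank feedstock candidates by a screening metric
#'
#' Orders a screening table descending by the chosen key, breaking ties by
#' `sample_id` ascending so the ranking is deterministic. Records with a
#' missing key value are placed last, with a notice, rather than silently
#' interleaved (a biomass reported only graphically should not outrank a
#' measured one).
#'
#' @param records Data frame with a `sample_id` column and the key column,
#'   typically from [screening_summary()].
#' @param key One of `"lipid_yield"`, `"fame_recovery"`, `"dry_biomass"`,
#'   `"lipid_content"`.
#' @return `records` reordered; same rows, same columns.
#' @examples
#' rank_isolates(suppressWarnings(screening_summary()), "fame_recovery")
#' @export
rank_isolates <- function(records,
                          key = c("lipid_yield", "fame_recovery",
                                  "dry_biomass", "lipid_content")) {
  key <- match.arg(key)
  stopifnot(is.data.frame(records), nrow(records) > 0L,
            "sample_id" %in% names(records), key %in% names(records))
  v <- records[[key]]
  if (anyNA(v)) {
    inform(sprintf("ranking by %s: %s placed last (missing value)", key,
                   paste(records$sample_id[is.na(v)], collapse = ", ")))
  }
  ord <- order(is.na(v), -replace(v, is.na(v), 0), records$sample_id)
  records[ord, ]
}
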