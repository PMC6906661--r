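#' Default biodiesel standard criteria
#'
#' The packaged criterion set mirroring the biodiesel standard limits used
#' to judge the packaged isolates: kinematic viscosity 1.9--6.0 mm² s⁻¹,
#' specific gravity 0.85--0.90 kg L⁻¹ and cetane number >= 47 from the US
#' standard ASTM D6751; iodine value <= 120 g I₂/100 g from the European
#' standard EN 14214; and the reported working ranges ADU 0.6--1.6 and
#' HHV 38--41 MJ kg⁻¹, which carry source `paper_stated` because neither
#' standard assigns them. All bounds are inclusive. The set lives in a
#' replaceable data file.
#'
#' @return Tibble with columns `property`, `lower`, `upper`, `source`
#'   (`NA` on an unbounded side).
#' @export
default_criteria <- function() {
  as_tibble(utils::read.delim(
    fs_extdata("biodiesel_criteria.tsv"), check.names = FALSE,
    fileEncoding = "UTF-8",
    colClasses = c(property = "character", lower = "numeric",
                   upper = "numeric", source = "character")))
}

#' Evaluate fuel properties against standard criteria
#'
#' Compares a sample's fuel properties to a criterion set with inclusive
#' bounds, at the precision the properties carry: when they were produced
#' under the `"paper"` rounding policy the comparison uses the rounded
#' (printed-precision) values, which keeps verdicts like "HHV 41.4 exceeds
#' 41" deterministic rather than hinging on float noise.
#'
#' The margin of a verdict is the signed distance to the nearest bound:
#' zero or positive for a pass, and for a fail the negative magnitude of
#' the violation.
#'
#' @param properties A `fuel_properties` row from
#'   [compute_fuel_properties()].
#' @param criteria Criterion table, by default [default_criteria()]. A
#'   criterion naming a property absent from the input is a configuration
#'   error, not a silent skip.
#' @return An object of class `compliance_report`: list with `sample_id`,
#'   `verdicts` (tibble: `property`, `value`, `lower`, `upper`, `source`,
#'   `pass`, `margin`, in criteria order) and `overall_pass`.
#' @examples
#' pr <- compute_fuel_properties(microalgae_profiles()[["P2-15"]],
#'                               policy = "paper")
#' evaluate_compliance(pr)$overall_pass  # TRUE
#' @export
evaluate_compliance <- function(properties, criteria = default_criteria()) {
  stopifnot(inherits(properties, "fuel_properties"))
  field <- tolower(criteria$property)
  unknown <- setdiff(field, names(properties))
  if (length(unknown) > 0L) {
    abort(sprintf("criteria reference unknown properties: %s",
                  paste(criteria$property[field %in% unknown],
                        collapse = ", ")),
          class = "famescreen_config_error")
  }
  if (!all(is.na(criteria$lower) | is.na(criteria$upper) |
           criteria$lower <= criteria$upper) ||
      any(is.na(criteria$lower) & is.na(criteria$upper))) {
    abort("each criterion needs lower <= upper with at least one bound",
          class = "famescreen_config_error")
  }

  value <- vapply(field, function(f) properties[[f]], numeric(1))
  margin <- pmin(ifelse(is.na(criteria$lower), Inf, value - criteria$lower),
                 ifelse(is.na(criteria$upper), Inf, criteria$upper - value))
  verdicts <- tibble(property = criteria$property, value = value,
                     lower = criteria$lower, upper = criteria$upper,
                     source = criteria$source,
                     pass = margin >= 0, margin = margin)
  structure(list(sample_id = properties$sample_id, verdicts = verdicts,
                 overall_pass = all(verdicts$pass)),
            class = "compliance_report")
}

#' @export
print.compliance_report <- function(x, ...) {
  cat(sprintf("<compliance_report> %s: %s (%d/%d criteria met)\n",
              x$sample_id, if (x$overall_pass) "PASS" else "FAIL",
              sum(x$verdicts$pass), nrow(x$verdicts)))
  print(x$verdicts, ...)
  invisible(x)
}

#' Summarise compliance reports across samples
#'
#' One row per sample with a logical pass flag per criterion property, the
#' number of violated criteria and the overall verdict, ordered by
#' `sample_id`.
#'
#' @param reports List of `compliance_report` objects from
#'   [evaluate_compliance()].
#' @return Tibble with columns `sample_id`, one logical column per
#'   property, `n_violations` and `overall_pass`; zero rows for empty
#'   input.
#' @export
summarize_compliance <- function(reports) {
  if (length(reports) == 0L) {
    return(tibble(sample_id = character(0), n_violations = integer(0),
                  overall_pass = logical(0)))
  }
  stopifnot(all(vapply(reports, inherits, logical(1), "compliance_report")))
  rows <- lapply(reports, function(r) {
    flags <- as.list(setNames(r$verdicts$pass, r$verdicts$property))
    dplyr::bind_cols(tibble(sample_id = r$sample_id), tibble(!!!flags),
                     tibble(n_violations = sum(!r$verdicts$pass),
                            overall_pass = r$overall_pass))
  })
  out <- dplyr::bind_rows(rows)
  out[order(out$sample_id), ]
}
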