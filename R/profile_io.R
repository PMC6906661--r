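#' Construct a FAME composition profile
#'
#' A profile is one sample's fatty acid methyl ester composition: a set of
#' fatty acids with their mass percent *of total lipid* (not of the FAME
#' fraction). Percentages are deliberately not renormalised to the FAME
#' total: the mass fraction entering the average degree of unsaturation is
#' the fraction of total extracted lipid, which is what reproduces the
#' reference property tables.
#'
#' Components with an explicit zero are dropped with a notice (a zero cell
#' means "reported as absent", distinct from "not measured"). Duplicate
#' acids, non-positive values and a component sum exceeding
#' `100 + sum_tolerance` are errors unless `validate = FALSE`, in which
#' case they are left for [validate_profile()] to report as findings.
#'
#' @param sample_id Sample identifier string.
#' @param components Data frame with columns `shorthand` (any dialect
#'   accepted by [parse_shorthand()]) and `mass_percent`.
#' @param metadata Named list of free-form annotations (organism, source,
#'   date, ...).
#' @param sum_tolerance Allowed excess of the component sum over 100, in
#'   percentage points. Printed tables carry rounding error; default 0.5.
#' @param validate If `TRUE` (default), findings are escalated to errors.
#'
#' @return An object of class `fame_profile`: a list with elements
#'   `sample_id`, `components` (tibble: `shorthand`, `carbons`,
#'   `double_bonds`, `omega`, `mass_percent`) and `metadata`.
#'
#' @examples
#' p <- fame_profile("demo", data.frame(
#'   shorthand = c("C16", "C18:3n-3"), mass_percent = c(50, 30)))
#' total_fame(p)
#' @export
fame_profile <- function(sample_id, components, metadata = list(),
                         sum_tolerance = 0.5, validate = TRUE) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L,
            is.data.frame(components))
  if (!all(c("shorthand", "mass_percent") %in% names(components))) {
    abort("`components` needs columns `shorthand` and `mass_percent`",
          class = "famescreen_profile_error")
  }
  mass <- as.numeric(components$mass_percent)
  parsed <- if (nrow(components) > 0L) {
    parse_shorthand(as.character(components$shorthand))
  } else {
    parse_shorthand(character(0))
  }
  comp <- dplyr::bind_cols(parsed, mass_percent = mass)

  zero <- !is.na(comp$mass_percent) & comp$mass_percent == 0
  if (any(zero)) {
    inform(sprintf("%s: dropping %d zero-valued component(s): %s",
                   sample_id, sum(zero),
                   paste(comp$shorthand[zero], collapse = ", ")))
    comp <- comp[!zero, ]
  }

  prof <- structure(
    list(sample_id = sample_id, components = comp, metadata = metadata),
    class = "fame_profile")
  if (validate) {
    findings <- validate_profile(prof, sum_tolerance)
    if (nrow(findings) > 0L) {
      abort(paste0(sprintf("invalid profile '%s':\n", sample_id),
                   paste("-", findings$rule, ":", findings$detail,
                         collapse = "\n")),
            class = "famescreen_profile_error")
    }
  }
  prof
}

#' @export
print.fame_profile <- function(x, ...) {
  cat(sprintf("<fame_profile> %s: %d components, total FAME %.2f%% of lipid\n",
              x$sample_id, nrow(x$components), sum(x$components$mass_percent)))
  print(x$components, ...)
  invisible(x)
}

#' Validate a FAME profile
#'
#' Pure rule check: returns an ordered tibble of findings and never mutates
#' or throws. Rules, in order: non-numeric values, non-positive values,
#' single components above 100, duplicate acids, and the component sum
#' exceeding `100 + sum_tolerance`.
#'
#' @inheritParams fame_profile
#' @param profile A `fame_profile` (possibly built with `validate = FALSE`).
#' @return Tibble with columns `rule` and `detail`; zero rows when clean.
#' @export
validate_profile <- function(profile, sum_tolerance = 0.5) {
  stopifnot(inherits(profile, "fame_profile"))
  comp <- profile$components
  findings <- list()
  note <- function(rule, detail) {
    findings[[length(findings) + 1L]] <<- tibble(rule = rule, detail = detail)
  }

  if (anyNA(comp$mass_percent)) {
    note("non_numeric_value",
         paste(comp$shorthand[is.na(comp$mass_percent)], collapse = ", "))
  }
  bad <- !is.na(comp$mass_percent) & comp$mass_percent <= 0
  if (any(bad)) {
    note("non_positive_value", paste(comp$shorthand[bad], collapse = ", "))
  }
  over <- !is.na(comp$mass_percent) & comp$mass_percent > 100
  if (any(over)) {
    note("value_above_100", paste(comp$shorthand[over], collapse = ", "))
  }
  dup <- duplicated(comp$shorthand)
  if (any(dup)) {
    note("duplicate_acid", paste(unique(comp$shorthand[dup]), collapse = ", "))
  }
  total <- sum(comp$mass_percent, na.rm = TRUE)
  if (total > 100 + sum_tolerance) {
    note("sum_bound",
         sprintf("component sum %.2f exceeds 100 + %.2f", total, sum_tolerance))
  }
  if (length(findings) == 0L) {
    tibble(rule = character(0), detail = character(0))
  } else {
    dplyr::bind_rows(findings)
  }
}

#' Total FAME recovery of a profile
#'
#' Arithmetic sum of the component mass percentages: the total FAME yield
#' as percent of total lipid ("total rendemen"), reported at two decimals
#' (half-up).
#'
#' @param profile A `fame_profile`.
#' @return Numeric scalar; `0` for an empty profile.
#' @examples
#' total_fame(microalgae_profiles()[["P5-4"]])  # 86.04
#' @export
total_fame <- function(profile) {
  stopifnot(inherits(profile, "fame_profile"))
  round_half_up(sum(profile$components$mass_percent), 2L)
}

#' Read FAME composition profiles from a delimited table
#'
#' Expects a long-format table: first column fatty-acid shorthand, an
#' optional `fame_name` column (ignored on read), and one column per
#' sample holding mass percent of total lipid. Empty cells and `"-"` mean
#' "not detected" and yield no component; explicit zeros are dropped with
#' a notice. Loading is deterministic and order-preserving.
#'
#' @param path Path to the file.
#' @param format `"csv"`, `"tsv"`, or `"auto"` (default: by file
#'   extension, falling back to csv).
#' @param sum_tolerance Allowed excess of a column sum over 100.
#' @return Named list of [fame_profile()] objects, one per sample column.
#' @export
read_fame_profiles <- function(path, format = c("auto", "csv", "tsv"),
                               sum_tolerance = 0.5) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.tsv$|\\.tab$|\\.txt$", path, ignore.case = TRUE))
      "tsv" else "csv"
  }
  raw <- utils::read.table(path, header = TRUE,
                           sep = if (format == "tsv") "\t" else ",",
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", fileEncoding = "UTF-8")
  raw <- as_tibble(raw)
  if (ncol(raw) < 2L) {
    abort("profile table needs a shorthand column plus at least one sample column",
          class = "famescreen_io_error")
  }
  acid_col <- names(raw)[[1]]
  name_cols <- grep("^fame[_ ]?name$", names(raw), ignore.case = TRUE,
                    value = TRUE)
  sample_cols <- setdiff(names(raw), c(acid_col, name_cols))
  if (length(sample_cols) == 0L) {
    abort("no sample columns found", class = "famescreen_io_error")
  }

  shorthand <- parse_shorthand(raw[[acid_col]])$shorthand
  if (anyDuplicated(shorthand)) {
    abort(sprintf("duplicate acid rows: %s",
                  paste(unique(shorthand[duplicated(shorthand)]),
                        collapse = ", ")),
          class = "famescreen_io_error")
  }

  profiles <- lapply(sample_cols, function(sc) {
    cells <- raw[[sc]]
    present <- !is.na(cells) & nzchar(trimws(cells)) & trimws(cells) != "-"
    values <- suppressWarnings(as.numeric(cells[present]))
    if (anyNA(values)) {
      bad <- which(present)[is.na(values)]
      abort(sprintf("non-numeric cell in column '%s', row %d ('%s')",
                    sc, bad[[1]], cells[bad[[1]]]),
            class = "famescreen_io_error")
    }
    fame_profile(
      sample_id = sc,
      components = tibble(shorthand = shorthand[present],
                          mass_percent = values),
      metadata = list(source = path),
      sum_tolerance = sum_tolerance)
  })
  setNames(profiles, sample_cols)
}

#' Write FAME profiles to a delimited table
#'
#' Writes the same long layout [read_fame_profiles()] accepts: `shorthand`,
#' `fame_name` (blank where the acid has no catalog entry), one column per
#' profile. Values are serialised at two decimals; absent acids are empty
#' cells. Reading the file back reproduces the profiles up to component
#' order and two-decimal rounding.
#'
#' @param profiles List of [fame_profile()] objects.
#' @param path Output path; extension picks the delimiter as in
#'   [read_fame_profiles()].
#' @param format `"csv"`, `"tsv"`, or `"auto"`.
#' @return `path`, invisibly.
#' @export
write_fame_profiles <- function(profiles, path,
                                format = c("auto", "csv", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.tsv$|\\.tab$|\\.txt$", path, ignore.case = TRUE))
      "tsv" else "csv"
  }
  stopifnot(all(vapply(profiles, inherits, logical(1), "fame_profile")))

  acids <- unique(unlist(lapply(profiles, function(p) p$components$shorthand)))
  catalog <- fame_catalog()
  names_col <- catalog$fame_name[match(acids, catalog$shorthand)]
  names_col[is.na(names_col)] <- ""

  out <- tibble(shorthand = acids, fame_name = names_col)
  for (p in profiles) {
    idx <- match(acids, p$components$shorthand)
    vals <- ifelse(is.na(idx), "",
                   sprintf("%.2f", p$components$mass_percent[idx]))
    out[[p$sample_id]] <- vals
  }
  if (length(profiles) == 0L) {
    out <- tibble(shorthand = character(0), fame_name = character(0))
  }
  utils::write.table(out, path, sep = if (format == "tsv") "\t" else ",",
                     row.names = FALSE, quote = TRUE, na = "",
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Packaged microalgae FAME profiles
#'
#' The four freshwater microalgae isolate profiles shipped with the
#' package (isolates G4-3, G4-9, P2-15, P5-4: two *Micractinium
#' conductrix*, one *Choricystis parasitica*, one *Monoraphidium* sp.),
#' measured by GC-MS after direct transesterification and expressed as
#' mass percent of total lipid.
#'
#' @return Named list of four [fame_profile()] objects.
#' @examples
#' vapply(microalgae_profiles(), total_fame, numeric(1))
#' @export
microalgae_profiles <- function() {
  profiles <- read_fame_profiles(fs_extdata("microalgae_fame_profiles.csv"))
  metrics <- isolate_metrics()
  for (id in names(profiles)) {
    org <- metrics$organism[match(id, metrics$sample_id)]
    profiles[[id]]$metadata$organism <- org
  }
  profiles
}

#' Packaged isolate culture screening metrics
#'
#' Dry biomass (g per L of culture) and lipid content (percent of dry
#' biomass) for the four packaged isolates, as reported means with their
#' standard deviations. G4-9's dry biomass was reported only graphically
#' and is stored as missing. Standard deviations are carried as metadata
#' and never enter computations.
#'
#' @return Tibble with columns `sample_id`, `organism`,
#'   `dry_biomass_g_per_L`, `biomass_sd`, `lipid_content_pct`, `lipid_sd`.
#' @export
isolate_metrics <- function() {
  as_tibble(utils::read.csv(
    fs_extdata("isolate_culture_metrics.csv"), check.names = FALSE,
    fileEncoding = "UTF-8",
    colClasses = c(sample_id = "character", organism = "character",
                   dry_biomass_g_per_L = "numeric", biomass_sd = "numeric",
                   lipid_content_pct = "numeric", lipid_sd = "numeric")))
}
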