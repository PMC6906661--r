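#' Parse lipid shorthand nomenclature
#'
#' Parses fatty-acid shorthand such as `"C18:3n-3"` into its structural
#' fields: chain length, number of carbon--carbon double bonds, and omega
#' class (the position of the last double bond counted from the methyl end).
#' The double-bond count extracted here is the `M` that enters the average
#' degree of unsaturation, so it is always derived from the name and never
#' hand-entered.
#'
#' Accepted input dialects, all normalised to one canonical form:
#' * the leading `"C"` is optional and case-insensitive (`"18:3n-3"`);
#' * saturated acids may be written with an explicit `":0"` (`"C16:0"`);
#' * the omega class may be written `"n-3"`, `"(n-3)"`, `"ω3"` or
#'   `"w3"` (case-insensitive, optional hyphen);
#' * internal whitespace is ignored.
#'
#' The canonical rendering is `"C{carbons}"` for saturated acids (no
#' `":0"`), and `"C{carbons}:{double_bonds}n-{omega}"` otherwise. Positional
#' double-bond locants (as in "methyl 5,11,14,17-eicosatetraenoate") are
#' carried only in systematic ester names, never parsed into structure.
#'
#' Structural sanity checks reject impossible identities rather than guess:
#' `carbons >= 2`, `double_bonds <= floor((carbons - 2) / 2)`, and when an
#' omega class is present `1 <= omega <= carbons - 2`. An omega class on a
#' saturated acid, or a missing omega class on an unsaturated one, is a
#' parse error (an incorrect double-bond count would silently corrupt every
#' downstream unsaturation figure). Branched, hydroxy and trans-designated
#' acids are not supported.
#'
#' @param text Character vector of shorthand strings (any accepted dialect).
#'
#' @return A tibble with one row per input and columns `shorthand`
#'   (canonical form), `carbons`, `double_bonds` (both integer) and `omega`
#'   (integer, `NA` for saturated acids).
#'
#' @examples
#' parse_shorthand(c("C18:3n-3", "C16", "c20:4N-3", "18:2(n-6)"))
#'
#' @seealso [format_shorthand()] for the inverse, [lookup_fame_name()] for
#'   systematic methyl-ester names.
#' @export
parse_shorthand <- function(text) {
  if (!is.character(text)) {
    abort("`text` must be a character vector of shorthand strings",
          class = "famescreen_parse_error")
  }
  if (length(text) == 0L) {
    return(tibble(shorthand = character(0), carbons = integer(0),
                  double_bonds = integer(0), omega = integer(0)))
  }
  stripped <- gsub("[[:space:]]+", "", text)
  rows <- lapply(seq_along(stripped), function(i) {
    parse_one_shorthand(stripped[[i]], text[[i]])
  })
  dplyr::bind_rows(rows)
}

# One trimmed token -> validated structure row. `shown` is the original
# input, used verbatim in error messages.
parse_one_shorthand <- function(token, shown) {
  if (!nzchar(token)) {
    abort("empty shorthand string", class = "famescreen_parse_error")
  }
  m <- regmatches(token, regexec("^[Cc]?([0-9]+)(?::([0-9]+))?(.*)$", token))[[1]]
  if (length(m) == 0L) {
    abort(sprintf("malformed shorthand '%s'", shown),
          class = "famescreen_parse_error")
  }
  carbons <- as.integer(m[[2]])
  double_bonds <- if (nzchar(m[[3]])) as.integer(m[[3]]) else 0L
  rest <- m[[4]]

  omega <- NA_integer_
  if (nzchar(rest)) {
    om <- regmatches(rest, regexec(
      "^(?:[nN]-([0-9]+)|\\([nN]-([0-9]+)\\)|[ωWw]-?([0-9]+))$", rest))[[1]]
    if (length(om) == 0L) {
      abort(sprintf("malformed shorthand '%s': unrecognised suffix '%s'",
                    shown, rest),
            class = "famescreen_parse_error")
    }
    hit <- om[-1][nzchar(om[-1])]
    omega <- as.integer(hit[[1]])
  }

  new_fatty_acid(carbons, double_bonds, omega, shown = shown)
}

# Validating constructor shared by the parser and the formatter; enforces
# the structural invariants and renders the canonical shorthand.
new_fatty_acid <- function(carbons, double_bonds, omega, shown = NULL) {
  label <- shown %||% sprintf("(%s, %s, %s)", carbons, double_bonds, omega)
  if (is.na(carbons) || carbons < 2L) {
    abort(sprintf("'%s': chain length must be an integer >= 2", label),
          class = "famescreen_parse_error")
  }
  max_db <- (carbons - 2L) %/% 2L
  if (is.na(double_bonds) || double_bonds < 0L || double_bonds > max_db) {
    abort(sprintf(
      "'%s': double-bond count %s exceeds the structural bound %d for a C%d chain",
      label, double_bonds, max_db, carbons),
      class = "famescreen_parse_error")
  }
  if (double_bonds == 0L && !is.na(omega)) {
    abort(sprintf("'%s': omega class given for a saturated acid", label),
          class = "famescreen_parse_error")
  }
  if (double_bonds > 0L) {
    if (is.na(omega)) {
      abort(sprintf(
        "'%s': unsaturated shorthand lacks an omega class (n-z)", label),
        class = "famescreen_parse_error")
    }
    if (omega < 1L || omega > carbons - 2L) {
      abort(sprintf(
        "'%s': omega class %d outside the valid range 1..%d",
        label, omega, carbons - 2L),
        class = "famescreen_parse_error")
    }
  }
  shorthand <- if (double_bonds == 0L) {
    sprintf("C%d", carbons)
  } else {
    sprintf("C%d:%dn-%d", carbons, double_bonds, omega)
  }
  tibble(shorthand = shorthand, carbons = carbons,
         double_bonds = double_bonds, omega = omega)
}

#' Render the canonical shorthand of a fatty acid
#'
#' The inverse of [parse_shorthand()]: given structural fields, returns the
#' canonical shorthand string. Round trip holds by construction:
#' `parse_shorthand(format_shorthand(c, d, o))` reproduces `(c, d, o)` for
#' every valid identity.
#'
#' @param carbons Integer vector of chain lengths, or a data frame carrying
#'   `carbons`, `double_bonds` and `omega` columns (as returned by
#'   [parse_shorthand()]), in which case the other arguments are ignored.
#' @param double_bonds Integer vector of double-bond counts.
#' @param omega Integer vector of omega classes; `NA` for saturated acids.
#'
#' @return Character vector of canonical shorthand strings.
#'
#' @examples
#' format_shorthand(18, 3, 3)   # "C18:3n-3"
#' format_shorthand(14, 0)      # "C14"
#' @export
format_shorthand <- function(carbons, double_bonds = 0L, omega = NA_integer_) {
  if (is.data.frame(carbons)) {
    df <- carbons
    carbons <- df$carbons
    double_bonds <- df$double_bonds
    omega <- df$omega
  }
  n <- max(length(carbons), length(double_bonds), length(omega))
  carbons <- as.integer(rep_len(carbons, n))
  double_bonds <- as.integer(rep_len(double_bonds, n))
  omega <- as.integer(rep_len(omega, n))
  vapply(seq_len(n), function(i) {
    new_fatty_acid(carbons[[i]], double_bonds[[i]], omega[[i]])$shorthand
  }, character(1))
}

#' Catalog of fatty acids and their systematic methyl-ester names
#'
#' Returns the packaged catalog linking canonical shorthand identities to
#' systematic FAME (fatty acid methyl ester) names, e.g. `C18:3n-3` to
#' "Methyl α-linolenate". The catalog covers the 21 acids observed in
#' the packaged microalgae profiles (C14--C24, zero to five double bonds).
#'
#' @return A tibble with columns `shorthand`, `fame_name`, `carbons`,
#'   `double_bonds`, `omega`.
#' @examples
#' fame_catalog()
#' @export
fame_catalog <- function() {
  raw <- utils::read.delim(fs_extdata("fame_catalog.tsv"),
                           colClasses = "character", check.names = FALSE,
                           fileEncoding = "UTF-8")
  parsed <- parse_shorthand(raw$shorthand)
  stopifnot(identical(parsed$shorthand, raw$shorthand),
            !anyDuplicated(raw$fame_name))
  dplyr::bind_cols(parsed[, "shorthand"], fame_name = raw$fame_name,
                   parsed[, c("carbons", "double_bonds", "omega")])
}

#' Look up the systematic methyl-ester name of a fatty acid
#'
#' @param acid Character vector of shorthand strings (any dialect accepted
#'   by [parse_shorthand()]), or a data frame with a `shorthand` column of
#'   canonical strings.
#' @param catalog Catalog tibble, by default [fame_catalog()].
#'
#' @return Character vector of systematic names. An acid absent from the
#'   catalog is an error; the message lists the nearest catalog entries by
#'   chain length to help spot typos.
#'
#' @examples
#' lookup_fame_name("C20:4n-3")  # "Methyl 5,11,14,17-eicosatetraenoate"
#' @export
lookup_fame_name <- function(acid, catalog = fame_catalog()) {
  parsed <- if (is.data.frame(acid)) {
    parse_shorthand(acid$shorthand)
  } else {
    parse_shorthand(acid)
  }
  idx <- match(parsed$shorthand, catalog$shorthand)
  if (anyNA(idx)) {
    missing <- parsed[is.na(idx), ]
    nearest <- catalog[order(abs(catalog$carbons - missing$carbons[[1]]),
                             catalog$shorthand), ]
    abort(sprintf(
      "no catalog entry for '%s'; nearest entries by chain length: %s",
      missing$shorthand[[1]],
      paste(head(nearest$shorthand, 5L), collapse = ", ")),
      class = "famescreen_lookup_error")
  }
  catalog$fame_name[idx]
}
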