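#' Default fatty-acid panel for profile simulation
#'
#' The 21 distinct acids of the packaged microalgae profiles: C12--C24
#' chains with zero to five double bonds.
#'
#' @return Character vector of canonical shorthand strings.
#' @export
default_panel <- function() {
  fame_catalog()$shorthand
}

#' Specification for synthetic FAME profile generation
#'
#' Describes a batch of synthetic sparse composition profiles with the
#' statistical structure of real GC-MS FAME tables: a handful of acids
#' drawn from a panel, positive percentages produced by a normalised-gamma
#' (Dirichlet) composition, and a total FAME recovery below 100% of total
#' lipid.
#'
#' @param n_profiles Number of profiles to generate.
#' @param n_components Acids per profile, drawn without replacement from
#'   the panel. Default 13, the typical panel size of the packaged
#'   profiles (which carry 8--18 detected acids).
#' @param concentration Positive gamma shape controlling evenness of the
#'   composition: small values give a few dominant acids (as in real
#'   profiles), large values approach equal shares. Default 1.
#' @param recovery_range Length-2 numeric `(low, high)`: the profile total
#'   (percent of total lipid) is drawn uniformly from this range. Default
#'   `c(60, 90)`, the span of observed FAME recoveries in the packaged
#'   data.
#' @param panel Candidate acids (any shorthand dialect); default
#'   [default_panel()].
#' @param seed Integer seed; mandatory so every batch is reproducible.
#' @return An object of class `synthetic_spec`.
#' @seealso [generate_profiles()]
#' @export
synthetic_spec <- function(n_profiles = 1L, n_components = 13L,
                           concentration = 1, recovery_range = c(60, 90),
                           panel = default_panel(), seed) {
  if (missing(seed)) {
    abort("`seed` is mandatory: synthetic batches must be reproducible",
          class = "famescreen_config_error")
  }
  panel <- parse_shorthand(panel)
  if (anyDuplicated(panel$shorthand)) {
    abort("`panel` contains duplicate acids",
          class = "famescreen_config_error")
  }
  stopifnot(n_profiles >= 1L, concentration > 0,
            length(recovery_range) == 2L)
  if (n_components < 1L || n_components > nrow(panel)) {
    abort(sprintf("`n_components` must be within 1..%d (panel size)",
                  nrow(panel)),
          class = "famescreen_config_error")
  }
  if (!(recovery_range[[1]] > 0 &&
        recovery_range[[1]] <= recovery_range[[2]] &&
        recovery_range[[2]] <= 100)) {
    abort("`recovery_range` must satisfy 0 < low <= high <= 100",
          class = "famescreen_config_error")
  }
  structure(list(n_profiles = as.integer(n_profiles),
                 n_components = as.integer(n_components),
                 concentration = concentration,
                 recovery_range = as.numeric(recovery_range),
                 panel = panel, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate synthetic FAME profiles with known ground truth
#'
#' For each profile: `n_components` acids are sampled uniformly without
#' replacement from the panel; positive weights are drawn by normalising
#' independent gamma variates with shape `concentration` (the standard
#' construction of a symmetric Dirichlet composition); the weights are
#' scaled to a total drawn uniformly from `recovery_range`; and the
#' ground-truth average degree of unsaturation is recorded from the
#' unrounded weights at generation time. The same spec (including seed)
#' always yields identical output; the caller's RNG state is left
#' untouched.
#'
#' @param spec A [synthetic_spec()].
#' @return List of `synthetic_profile` objects: each a list with elements
#'   `profile` (a [fame_profile()]) and `truth_adu`.
#' @examples
#' batch <- generate_profiles(synthetic_spec(n_profiles = 2, seed = 42))
#' batch[[1]]$truth_adu - compute_adu(batch[[1]]$profile)  # 0
#' @export
generate_profiles <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  panel <- spec$panel
  withr::with_seed(spec$seed, {
    lapply(seq_len(spec$n_profiles), function(i) {
      idx <- sample.int(nrow(panel), spec$n_components)
      w <- rgamma(spec$n_components, shape = spec$concentration)
      w <- w / sum(w)
      total <- runif(1, spec$recovery_range[[1]], spec$recovery_range[[2]])
      mass <- w * total
      truth_adu <- sum(panel$double_bonds[idx] * mass) / 100
      profile <- fame_profile(
        sample_id = sprintf("SYN-%03d", i),
        components = tibble(shorthand = panel$shorthand[idx],
                            mass_percent = mass),
        metadata = list(generator = "synthetic", seed = spec$seed,
                        concentration = spec$concentration))
      structure(list(profile = profile, truth_adu = truth_adu),
                class = "synthetic_profile")
    })
  })
}

#' Build a two-component profile with an exact target ADU
#'
#' Closed-form construction used to exercise the property correlations at
#' a chosen unsaturation: the unsaturated acid carries
#' `x = 100 * target / M` percent (M its double-bond count) and a
#' saturated C16 filler tops the profile up to `recovery`, so
#' [compute_adu()] returns exactly `target` at full precision.
#'
#' @param target Desired ADU, within `0 <= target <= M * recovery / 100`.
#' @param unsat_acid Shorthand of an unsaturated acid (M >= 1); default
#'   `"C18:3n-3"`.
#' @param recovery Profile total as percent of total lipid.
#' @param sample_id Identifier for the resulting profile.
#' @return A [fame_profile()].
#' @examples
#' p <- make_profile_with_target_adu(1.5)  # C18:3n-3 at 50%, C16 at 50%
#' compute_adu(p)
#' @export
make_profile_with_target_adu <- function(target, unsat_acid = "C18:3n-3",
                                         recovery = 100,
                                         sample_id = "synthetic-target") {
  acid <- parse_shorthand(unsat_acid)
  if (acid$double_bonds < 1L) {
    abort(sprintf("'%s' is saturated; need an acid with at least one double bond",
                  acid$shorthand),
          class = "famescreen_config_error")
  }
  stopifnot(recovery > 0, recovery <= 100)
  upper <- acid$double_bonds * recovery / 100
  if (target < 0 || target > upper) {
    abort(sprintf("target ADU %.4g outside the feasible range [0, %.4g] for %s at %.4g%% recovery",
                  target, upper, acid$shorthand, recovery),
          class = "famescreen_config_error")
  }
  x <- 100 * target / acid$double_bonds
  comp <- tibble(shorthand = c(acid$shorthand, "C16"),
                 mass_percent = c(x, recovery - x))
  comp <- comp[comp$mass_percent > 0, ]
  fame_profile(sample_id, comp,
               metadata = list(generator = "target-adu", target = target))
}
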