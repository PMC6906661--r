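test_that("round_half_up rounds ties away from zero at fixed decimals", {
  expect_equal(round_half_up(2.5), 3)
  expect_equal(round_half_up(-2.5), -3)
  expect_equal(round_half_up(0.125, 2), 0.13)   # round() would give 0.12
  expect_equal(round_half_up(1.6671, 2), 1.67)
  expect_equal(round_half_up(c(0.881565, 41.45), c(3, 1)), c(0.882, 41.5))
})

test_that("compute_adu matches the published values on the packaged profiles", {
  profs <- microalgae_profiles()
  expect_equal(vapply(profs, compute_adu, numeric(1), policy = "paper"),
               c("G4-3" = 1.63, "G4-9" = 1.67, "P2-15" = 1.21, "P5-4" = 2.08))
  # full precision against hand-summed double-bond weighted totals
  expect_equal(vapply(profs, compute_adu, numeric(1)),
               c("G4-3" = 1.6277, "G4-9" = 1.6671,
                 "P2-15" = 1.2144, "P5-4" = 2.0787),
               tolerance = 1e-12)
})

test_that("compute_adu handles degenerate and hand-computable profiles", {
  expect_equal(compute_adu(empty_profile()), 0)
  sat <- mk_profile("sat", c("C14" = 10, "C16" = 40, "C18" = 20))
  expect_equal(compute_adu(sat, policy = "paper"), 0)
  half <- mk_profile("half", c("C16" = 50, "C18:3n-3" = 50))
  expect_equal(compute_adu(half), 1.5)
})

test_that("apply_correlation evaluates single correlations at printed precision", {
  co <- default_correlations()
  row <- function(p) co[co$property == p, ]
  expect_equal(apply_correlation(row("IV"), 0, policy = "paper"), 12.71)
  expect_equal(apply_correlation(row("IV"), 1.63, policy = "paper"), 133.94)
  expect_equal(apply_correlation(row("CN"), 1.21, policy = "paper"), 54.8)
  expect_equal(apply_correlation(row("HHV"), 2.08, policy = "paper"), 42.2)
  expect_error(apply_correlation(co, 1), class = "famescreen_config_error")
  expect_error(apply_correlation(row("IV"), -0.1),
               class = "famescreen_config_error")
})

test_that("paper policy reproduces the full published property table", {
  profs <- microalgae_profiles()
  got <- suppressWarnings(fuel_properties_table(profs, policy = "paper"))
  for (col in c("adu", "vis", "sg", "cn", "iv", "hhv")) {
    expect_equal(got[[col]], reference_properties[[col]], info = col)
  }
})

test_that("an empty profile returns the rounded correlation intercepts", {
  props <- NULL
  expect_warning(
    props <- compute_fuel_properties(empty_profile(), policy = "paper"),
    class = "famescreen_extrapolation")
  expect_equal(unlist(props[, c("adu", "vis", "sg", "cn", "iv", "hhv")]),
               c(adu = 0, vis = 5.21, sg = 0.873, cn = 62.9,
                 iv = 12.71, hhv = 38.5))
})

test_that("only two-stage rounding reproduces the published table", {
  g49 <- microalgae_profiles()[["G4-9"]]
  paper <- suppressWarnings(compute_fuel_properties(g49, policy = "paper"))
  none <- suppressWarnings(compute_fuel_properties(g49, policy = "none"))
  expect_equal(paper$iv, 136.91)
  expect_equal(none$iv, 74.373 * 1.6671 + 12.71, tolerance = 1e-12)
  expect_equal(none$iv, 136.70, tolerance = 1e-4)
  expect_false(isTRUE(all.equal(none$iv, paper$iv, tolerance = 1e-3)))
})

test_that("ADU is linear under mixing of profiles", {
  for (seed in 1:5) {
    batch <- generate_profiles(
      synthetic_spec(n_profiles = 2, n_components = 6, seed = seed,
                     recovery_range = c(30, 45)))
    p <- batch[[1]]$profile
    q <- batch[[2]]$profile
    w <- runif(1)
    scale_comp <- function(prof, f) {
      cc <- prof$components
      tibble::tibble(shorthand = cc$shorthand,
                     mass_percent = cc$mass_percent * f)
    }
    mixed <- dplyr::bind_rows(scale_comp(p, w), scale_comp(q, 1 - w)) |>
      dplyr::group_by(shorthand) |>
      dplyr::summarise(mass_percent = sum(mass_percent), .groups = "drop")
    mix <- fame_profile("mix", mixed)
    expect_equal(compute_adu(mix),
                 w * compute_adu(p) + (1 - w) * compute_adu(q),
                 tolerance = 1e-12)
  }
})

test_that("ADU is bounded by the most unsaturated acid times total recovery", {
  batch <- generate_profiles(synthetic_spec(n_profiles = 20, seed = 99))
  for (s in batch) {
    comp <- s$profile$components
    adu <- compute_adu(s$profile)
    expect_gte(adu, 0)
    expect_lte(adu,
               max(comp$double_bonds) * sum(comp$mass_percent) / 100 + 1e-12)
  }
})

test_that("properties are strictly monotone in ADU at full precision", {
  co <- default_correlations()
  grid <- seq(0, 3, by = 0.25)
  vals <- lapply(setNames(co$property, co$property), function(p) {
    apply_correlation(co[co$property == p, ], grid, policy = "none")
  })
  expect_true(all(diff(vals$Vis) < 0))
  expect_true(all(diff(vals$CN) < 0))
  expect_true(all(diff(vals$SG) > 0))
  expect_true(all(diff(vals$IV) > 0))
  expect_true(all(diff(vals$HHV) > 0))
})

test_that("iodine value is proportional to ADU above its intercept", {
  iv <- default_correlations()[default_correlations()$property == "IV", ]
  for (adu in c(0.4, 1.1, 2.7)) {
    expect_equal((apply_correlation(iv, adu) - 12.71) / adu, 74.373,
                 tolerance = 1e-10)
  }
})

test_that("out-of-calibration ADU triggers an extrapolation warning", {
  hot <- make_profile_with_target_adu(2.5)
  expect_warning(compute_fuel_properties(hot),
                 class = "famescreen_extrapolation")
  ok <- make_profile_with_target_adu(1.0)
  expect_no_warning(compute_fuel_properties(ok))
})
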