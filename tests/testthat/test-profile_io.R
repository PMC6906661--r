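test_that("packaged isolate profiles load with the expected shape", {
  profs <- microalgae_profiles()
  expect_named(profs, c("G4-3", "G4-9", "P2-15", "P5-4"))
  counts <- vapply(profs, function(p) nrow(p$components), integer(1))
  expect_equal(unname(counts), c(13L, 8L, 13L, 18L))
  expect_equal(profs[["P2-15"]]$metadata$organism, "Choricystis parasitica")
  # dominant components as reported: C16 for P2-15, C18:3n-3 for P5-4
  top <- function(p) p$components$shorthand[which.max(p$components$mass_percent)]
  expect_equal(top(profs[["P2-15"]]), "C16")
  expect_equal(top(profs[["P5-4"]]), "C18:3n-3")
})

test_that("total_fame reproduces the published recovery totals exactly", {
  profs <- microalgae_profiles()
  expect_equal(vapply(profs, total_fame, numeric(1)), reference_totals)
  expect_equal(total_fame(empty_profile()), 0)
})

test_that("reading handles minimal tables, zeros, and malformed input", {
  path <- withr::local_tempfile(fileext = ".csv")

  writeLines(c("shorthand,S1", "C16,50.0"), path)
  profs <- read_fame_profiles(path)
  expect_length(profs, 1L)
  expect_equal(profs[["S1"]]$components$mass_percent, 50)

  writeLines(c("shorthand,S1", "C16,50", "C16,10"), path)
  expect_error(read_fame_profiles(path), class = "famescreen_io_error")

  writeLines(c("shorthand,S1", "C16,50", "C18,0"), path)
  expect_message(profs <- read_fame_profiles(path), "zero-valued")
  expect_equal(profs[["S1"]]$components$shorthand, "C16")

  writeLines(c("shorthand,S1", "C16,fifty"), path)
  expect_error(read_fame_profiles(path), class = "famescreen_io_error")

  writeLines(c("shorthand,S1", "C16,80", "C18,25"), path)
  expect_error(read_fame_profiles(path), class = "famescreen_profile_error")

  writeLines(c("shorthand,S1", "notanacid,50"), path)
  expect_error(read_fame_profiles(path), class = "famescreen_parse_error")
})

test_that("empty cells and dashes mean not-detected", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("shorthand,A,B", "C16,50,-", "C18,,30"), path)
  profs <- read_fame_profiles(path)
  expect_equal(profs[["A"]]$components$shorthand, "C16")
  expect_equal(profs[["B"]]$components$shorthand, "C18")
})

test_that("write/read round trip preserves acid and two-decimal value multisets", {
  profs <- microalgae_profiles()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fame_profiles(profs, path)
  back <- read_fame_profiles(path)
  expect_named(back, names(profs))
  for (id in names(profs)) {
    a <- profs[[id]]$components
    b <- back[[id]]$components
    expect_equal(
      b[order(b$shorthand), c("shorthand", "mass_percent")],
      {
        x <- a[order(a$shorthand), c("shorthand", "mass_percent")]
        x$mass_percent <- round_half_up(x$mass_percent, 2)
        x
      },
      info = id)
  }
})

test_that("writing tolerates empty input and acids without catalog names", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_fame_profiles(list(), path)
  header_only <- utils::read.csv(path, check.names = FALSE)
  expect_equal(names(header_only), c("shorthand", "fame_name"))
  expect_equal(nrow(header_only), 0L)

  odd <- mk_profile("odd", c("C13" = 40))  # valid acid, not in catalog
  write_fame_profiles(list(odd), path)
  back <- read_fame_profiles(path)
  expect_equal(back[["odd"]]$components$shorthand, "C13")
})

test_that("validate_profile reports findings as data, purely and in order", {
  clean <- microalgae_profiles()[["G4-3"]]
  expect_equal(nrow(validate_profile(clean)), 0L)

  over <- mk_profile("over", c("C16" = 60, "C18" = 41), validate = FALSE)
  f <- validate_profile(over, sum_tolerance = 0.5)
  expect_equal(f$rule, "sum_bound")
  expect_equal(validate_profile(over, sum_tolerance = 0.5), f)  # pure
  expect_equal(nrow(validate_profile(over, sum_tolerance = 1)), 0L)

  neg <- mk_profile("neg", c("C16" = -1), validate = FALSE)
  expect_equal(validate_profile(neg)$rule, "non_positive_value")

  dup <- fame_profile("dup",
                      tibble::tibble(shorthand = c("C16", "c16"),
                                     mass_percent = c(50, 10)),
                      validate = FALSE)
  expect_equal(validate_profile(dup)$rule, "duplicate_acid")
  expect_error(fame_profile("dup",
                            tibble::tibble(shorthand = c("C16", "C16"),
                                           mass_percent = c(50, 10))),
               class = "famescreen_profile_error")
})

test_that("isolate metrics carry the reported means and store G4-9 biomass as missing", {
  m <- isolate_metrics()
  expect_equal(m$sample_id, c("G4-3", "G4-9", "P2-15", "P5-4"))
  expect_equal(m$dry_biomass_g_per_L, c(1.34, NA, 0.18, 1.30))
  expect_equal(m$lipid_content_pct, c(62.63, 89.10, 57.48, 66.72))
})
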