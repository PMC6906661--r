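# Build a profile from a named vector of mass percentages, e.g.
# mk_profile("x", c("C16" = 50, "C18:3n-3" = 30))
mk_profile <- function(sample_id, percents, ...) {
  fame_profile(sample_id,
               tibble::tibble(shorthand = names(percents),
                              mass_percent = unname(percents)),
               ...)
}

empty_profile <- function(sample_id = "empty") {
  fame_profile(sample_id,
               tibble::tibble(shorthand = character(0),
                              mass_percent = numeric(0)))
}

# Reference Table-3-style values for the four packaged isolates, frozen
# after verifying them against an independent recomputation from the
# composition table.
reference_properties <- tibble::tribble(
  ~sample_id, ~adu, ~vis,  ~sg,   ~cn,   ~iv,    ~hhv,
  "G4-3",     1.63, 4.18, 0.882, 52.0, 133.94, 41.4,
  "G4-9",     1.67, 4.15, 0.882, 51.7, 136.91, 41.5,
  "P2-15",    1.21, 4.44, 0.879, 54.8, 102.70, 40.7,
  "P5-4",     2.08, 3.89, 0.884, 49.0, 167.41, 42.2
)

reference_totals <- c("G4-3" = 66.39, "G4-9" = 83.46,
                      "P2-15" = 80.67, "P5-4" = 86.04)
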