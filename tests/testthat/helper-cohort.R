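# Shared synthetic cohort fixtures, generated once per test run.

.fixture_env <- new.env(parent = emptyenv())

default_test_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    .fixture_env$cohort <- generate_patient_cohort(cohort_params(seed = 42L))
  }
  .fixture_env$cohort
}

default_test_report <- function() {
  if (is.null(.fixture_env$report)) {
    .fixture_env$report <- run_pipeline(default_test_cohort())
  }
  .fixture_env$report
}

# minimal hand-built cell table row
make_cell <- function(x = 0, y = 0, compartment = "stroma", cd3 = FALSE,
                      cd8 = FALSE, cd4 = FALSE, foxp3 = FALSE, ki67 = FALSE,
                      pdl1 = FALSE, ck = FALSE, pmn_marker = FALSE,
                      macro_marker = FALSE, intensity_bin = 0,
                      diameter_um = 8, roundness = 0.9) {
  data.frame(cell_id = "c", x_um = x, y_um = y, compartment = compartment,
             phenotype = NA_character_, cd3 = cd3, cd8 = cd8, cd4 = cd4,
             foxp3 = foxp3, ki67 = ki67, pdl1 = pdl1, ck = ck,
             pmn_marker = pmn_marker, macro_marker = macro_marker,
             intensity_bin = intensity_bin, diameter_um = diameter_um,
             roundness = roundness, stringsAsFactors = FALSE)
}
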