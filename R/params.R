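#' Parameters for one synthetic MIF slide
#'
#' Describes the point-pattern structure of a simulated multiplex
#' immunofluorescence (MIF) field: field size, tumor-nest geometry, per-
#' phenotype cell densities in the stromal and tumor compartments, marker
#' fractions, and the Treg exclusion radius that plants the spatial structure
#' recovered by the proximity module (proliferating Ki67+ T cells held at
#' least `treg_exclusion_radius_um` away from any Treg).
#'
#' Densities are in cells per mm^2; lengths in micrometers.  Setting
#' `treg_exclusion_radius_um = 0` yields complete spatial randomness between
#' Tregs and Ki67+ T cells.
#'
#' @param field_width_um,field_height_um Field dimensions in um.
#' @param tumor_nest_count Number of circular tumor nests.
#' @param nest_radius_range_um Range the nest radii are drawn from (um).
#' @param tumor_cell_density Tumor cells per mm^2 of nest area.
#' @param stromal_density Named vector of stromal densities (cells/mm^2) for
#'   phenotypes `cd8_t`, `cd4_t`, `treg`, `pmn`, `macrophage`.
#' @param intratumoral_density Same phenotypes, densities inside nests.
#' @param ki67_fraction_tcell Fraction of conventional T cells that are Ki67+.
#' @param ki67_fraction_tumor Fraction of tumor cells that are Ki67+.
#' @param treg_exclusion_radius_um Minimum allowed distance between a Treg and
#'   any Ki67+ conventional T cell (um, >= 0).
#' @param pdl1_fraction_myeloid Fraction of myeloid cells that are PD-L1+.
#' @param intensity_bin_probs Probabilities for intensity bins 0..3 (sum 1).
#' @param cell_diameter_mean_um,cell_diameter_sd_um Cell diameter distribution.
#' @return A `slide_pattern_params` list.
#' @export
slide_pattern_params <- function(field_width_um = 1000,
                                 field_height_um = 1000,
                                 tumor_nest_count = 4,
                                 nest_radius_range_um = c(120, 220),
                                 tumor_cell_density = 1200,
                                 stromal_density = c(cd8_t = 120, cd4_t = 120,
                                                     treg = 50, pmn = 80,
                                                     macrophage = 80),
                                 intratumoral_density = c(cd8_t = 40, cd4_t = 40,
                                                          treg = 15, pmn = 25,
                                                          macrophage = 30),
                                 ki67_fraction_tcell = 0.25,
                                 ki67_fraction_tumor = 0.3,
                                 treg_exclusion_radius_um = 40,
                                 pdl1_fraction_myeloid = 0.4,
                                 intensity_bin_probs = c(0.4, 0.3, 0.2, 0.1),
                                 cell_diameter_mean_um = 8,
                                 cell_diameter_sd_um = 1.5) {
  phenos <- c("cd8_t", "cd4_t", "treg", "pmn", "macrophage")
  stromal_density <- stromal_density[phenos]
  intratumoral_density <- intratumoral_density[phenos]

  .check_number(field_width_um, "field_width_um", lower = 1)
  .check_number(field_height_um, "field_height_um", lower = 1)
  .check_number(tumor_nest_count, "tumor_nest_count", lower = 0)
  .check_number(tumor_cell_density, "tumor_cell_density", lower = 0)
  for (d in list(stromal_density, intratumoral_density)) {
    if (anyNA(d) || any(!is.finite(d)) || any(d < 0)) {
      .param_error("phenotype densities must be named, finite and >= 0 for: ",
                   paste(phenos, collapse = ", "))
    }
  }
  .check_proportion(ki67_fraction_tcell, "ki67_fraction_tcell")
  .check_proportion(ki67_fraction_tumor, "ki67_fraction_tumor")
  .check_number(treg_exclusion_radius_um, "treg_exclusion_radius_um", lower = 0)
  .check_proportion(pdl1_fraction_myeloid, "pdl1_fraction_myeloid")
  if (length(intensity_bin_probs) != 4L || any(intensity_bin_probs < 0) ||
      abs(sum(intensity_bin_probs) - 1) > 1e-9) {
    .param_error("intensity_bin_probs must be a 4-vector summing to 1")
  }
  .check_number(cell_diameter_mean_um, "cell_diameter_mean_um", lower = 0.1)
  .check_number(cell_diameter_sd_um, "cell_diameter_sd_um", lower = 0)

  structure(list(
    field_width_um = field_width_um,
    field_height_um = field_height_um,
    tumor_nest_count = as.integer(tumor_nest_count),
    nest_radius_range_um = nest_radius_range_um,
    tumor_cell_density = tumor_cell_density,
    stromal_density = stromal_density,
    intratumoral_density = intratumoral_density,
    ki67_fraction_tcell = ki67_fraction_tcell,
    ki67_fraction_tumor = ki67_fraction_tumor,
    treg_exclusion_radius_um = treg_exclusion_radius_um,
    pdl1_fraction_myeloid = pdl1_fraction_myeloid,
    intensity_bin_probs = intensity_bin_probs,
    cell_diameter_mean_um = cell_diameter_mean_um,
    cell_diameter_sd_um = cell_diameter_sd_um
  ), class = "slide_pattern_params")
}

# Apply named overrides to a slide_pattern_params object, revalidating.
.modify_slide_params <- function(params, overrides) {
  for (nm in names(overrides)) params[[nm]] <- overrides[[nm]]
  do.call(slide_pattern_params, unclass(params))
}

#' Parameters for a synthetic patient cohort
#'
#' Bundles everything the cohort generator needs: cohort size and responder
#' fraction, per-class pre/post slide patterns (the planted MIF and spatial
#' effects), pathology viable-fraction ranges, lesion and variant parameters,
#' per-caller noise, and ELISpot count parameters.  The defaults are the study
#' conditions used throughout the package's validation suite: 14 patients with
#' 5 responders; responders gain post-treatment tumor CD8 infiltration, lose
#' stromal Tregs, start with lower stromal myeloid density, and collapse the
#' Treg exclusion radius after treatment.
#'
#' @param n_patients Number of patients (>= 1).
#' @param responder_fraction Fraction of patients drawn as pathologic
#'   responders (pTR >= 50).
#' @param slide_params List with elements `responder` and `nonresponder`, each
#'   a list with `pre` and `post` [slide_pattern_params()].  `NULL` builds the
#'   default planted-effect structure.
#' @param slides_per_patient H&E blocks scored per primary site.
#' @param bed_area_range_mm2 Per-slide tumor-bed area range (mm^2).
#' @param viable_fraction_responder,viable_fraction_nonresponder Ranges the
#'   per-slide viable fractions are drawn from, by response class.
#' @param mutation_count_mean Mean somatic mutation count per patient
#'   (Poisson).
#' @param indel_fraction Fraction of variants that are indels.
#' @param vaf_shape Beta shape parameters for variant allele fractions.
#' @param tpm_meanlog,tpm_sdlog Log-normal parameters for transcript TPM.
#' @param strong_binder_fraction Fraction of peptides assigned IC50 <= 200 nM
#'   by the synthetic binding predictor.
#' @param caller_sensitivity Named per-caller detection probabilities.
#' @param caller_false_rate Named per-caller private false-call rates
#'   (expected false calls as a fraction of the truth count).
#' @param elispot_baseline_mean Mean background/pre-treatment spot count.
#' @param elispot_responder_npos Function(void)->integer or fixed params; here
#'   a length-2 vector `c(floor, binom_n)` with success prob
#'   `elispot_responder_p`: n_positive = floor + Binomial(binom_n, p).
#' @param elispot_responder_p,elispot_nonresponder_p Per-condition positivity
#'   probabilities entering the draws above (non-responders use
#'   Binomial(n_conditions, p)).
#' @param elispot_spot_mu,elispot_spot_size Negative-binomial mean/size for the
#'   post-treatment spot-count inflation of positive conditions (shifted by
#'   +6 so positive wells clear the 5-spot threshold).
#' @param n_elispot_conditions Neoepitope wells per patient plate.
#' @param seed Integer seed; same seed implies byte-identical cohorts.
#' @return A `cohort_params` list.
#' @export
cohort_params <- function(n_patients = 14,
                          responder_fraction = 5 / 14,
                          slide_params = NULL,
                          slides_per_patient = 3,
                          bed_area_range_mm2 = c(40, 120),
                          viable_fraction_responder = c(0.31, 0.49),
                          viable_fraction_nonresponder = c(0.56, 0.96),
                          mutation_count_mean = 80,
                          indel_fraction = 0.1,
                          vaf_shape = c(2, 8),
                          tpm_meanlog = log(5),
                          tpm_sdlog = 1.5,
                          strong_binder_fraction = 0.15,
                          caller_sensitivity = c(LoFreq = 0.92, MuSE = 0.88,
                                                 Mutect2 = 0.95, Strelka2 = 0.93),
                          caller_false_rate = c(LoFreq = 0.03, MuSE = 0.05,
                                                Mutect2 = 0.02, Strelka2 = 0.03),
                          elispot_baseline_mean = 0.5,
                          elispot_responder_npos = c(3, 5),
                          elispot_responder_p = 0.4,
                          elispot_nonresponder_p = 0.05,
                          elispot_spot_mu = 10,
                          elispot_spot_size = 3,
                          n_elispot_conditions = 9,
                          seed = 1L) {
  .check_number(n_patients, "n_patients", lower = 1)
  .check_proportion(responder_fraction, "responder_fraction")
  if (any(caller_sensitivity < 0) || any(caller_sensitivity > 1)) {
    .param_error("caller_sensitivity values must be in [0, 1]")
  }
  if (any(caller_false_rate < 0)) {
    .param_error("caller_false_rate values must be >= 0")
  }
  .check_proportion(elispot_responder_p, "elispot_responder_p")
  .check_proportion(elispot_nonresponder_p, "elispot_nonresponder_p")
  .check_proportion(strong_binder_fraction, "strong_binder_fraction")

  if (is.null(slide_params)) slide_params <- default_cohort_slide_params()

  structure(list(
    n_patients = as.integer(n_patients),
    responder_fraction = responder_fraction,
    slide_params = slide_params,
    slides_per_patient = as.integer(slides_per_patient),
    bed_area_range_mm2 = bed_area_range_mm2,
    viable_fraction_responder = viable_fraction_responder,
    viable_fraction_nonresponder = viable_fraction_nonresponder,
    mutation_count_mean = mutation_count_mean,
    indel_fraction = indel_fraction,
    vaf_shape = vaf_shape,
    tpm_meanlog = tpm_meanlog,
    tpm_sdlog = tpm_sdlog,
    strong_binder_fraction = strong_binder_fraction,
    caller_sensitivity = caller_sensitivity,
    caller_false_rate = caller_false_rate,
    elispot_baseline_mean = elispot_baseline_mean,
    elispot_responder_npos = elispot_responder_npos,
    elispot_responder_p = elispot_responder_p,
    elispot_nonresponder_p = elispot_nonresponder_p,
    elispot_spot_mu = elispot_spot_mu,
    elispot_spot_size = elispot_spot_size,
    n_elispot_conditions = as.integer(n_elispot_conditions),
    seed = as.integer(seed)
  ), class = "cohort_params")
}

#' Default per-class pre/post slide patterns (the planted effects)
#'
#' Responders: lower pre-treatment stromal myeloid density, post-treatment
#' tumor CD8 influx (x3.5), stromal Treg reduction, and collapse of the Treg
#' exclusion radius (40 um -> 0).  Non-responders: unchanged pattern pre/post.
#'
#' @return Nested list `list(responder = list(pre, post), nonresponder = ...)`.
#' @export
default_cohort_slide_params <- function() {
  base <- slide_pattern_params()
  resp_pre <- .modify_slide_params(base, list(
    stromal_density = c(cd8_t = 120, cd4_t = 120, treg = 50, pmn = 40,
                        macrophage = 40)
  ))
  resp_post <- .modify_slide_params(resp_pre, list(
    stromal_density = c(cd8_t = 150, cd4_t = 130, treg = 25, pmn = 45,
                        macrophage = 50),
    intratumoral_density = c(cd8_t = 140, cd4_t = 60, treg = 15, pmn = 30,
                             macrophage = 45),
    treg_exclusion_radius_um = 0
  ))
  nonresp <- .modify_slide_params(base, list(
    stromal_density = c(cd8_t = 120, cd4_t = 120, treg = 50, pmn = 120,
                        macrophage = 120)
  ))
  list(responder = list(pre = resp_pre, post = resp_post),
       nonresponder = list(pre = nonresp, post = nonresp))
}

#' Cohort parameters with all planted effects removed
#'
#' Every patient, regardless of drawn response class, shares one slide pattern
#' at both timepoints and non-responder ELISpot behavior.  Pathology still
#' assigns pTR by class, so response labels are present but independent of all
#' correlates -- the null configuration used for type-I-error calibration.
#'
#' @param ... Passed through to [cohort_params()].
#' @return A `cohort_params` object.
#' @export
null_cohort_params <- function(...) {
  base <- slide_pattern_params()
  flat <- list(pre = base, post = base)
  cohort_params(slide_params = list(responder = flat, nonresponder = flat),
                elispot_responder_npos = c(0, 9),
                elispot_responder_p = 0.05,
                ...)
}
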