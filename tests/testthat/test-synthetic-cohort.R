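test_that("slide generator enforces the Treg exclusion radius", {
  params <- slide_pattern_params(treg_exclusion_radius_um = 40)
  cells <- generate_cell_slide(params, seed = 2)
  k <- cells[cells$phenotype %in% c("CD8 T cell", "CD4 T cell") & cells$ki67, ]
  tr <- cells[cells$phenotype == "Treg", ]
  dmin <- min(outer(seq_len(nrow(k)), seq_len(nrow(tr)), function(i, j) {
    sqrt((k$x_um[i] - tr$x_um[j])^2 + (k$y_um[i] - tr$y_um[j])^2)
  }))
  expect_gte(dmin, 40)
})

test_that("with exclusion off, Ki67 status is exchangeable wrt Treg distance", {
  params <- slide_pattern_params(treg_exclusion_radius_um = 0,
                                 stromal_density = c(cd8_t = 150, cd4_t = 150,
                                                     treg = 60, pmn = 50,
                                                     macrophage = 50),
                                 intratumoral_density = c(cd8_t = 150,
                                                          cd4_t = 150,
                                                          treg = 60, pmn = 50,
                                                          macrophage = 50))
  cells <- generate_cell_slide(params, seed = 1)
  tr <- cells[cells$phenotype == "Treg", ]
  tc <- cells[cells$phenotype %in% c("CD8 T cell", "CD4 T cell"), ]
  nn <- vapply(seq_len(nrow(tc)), function(i) {
    min(sqrt((tc$x_um[i] - tr$x_um)^2 + (tc$y_um[i] - tr$y_um)^2))
  }, numeric(1))
  p <- wilcox.test(nn[tc$ki67], nn[!tc$ki67])$p.value
  expect_gt(p, 0.001)  # no planted difference
})

test_that("counts follow the Poisson intensity (no nests, known density)", {
  params <- slide_pattern_params(field_width_um = 1000, field_height_um = 1000,
                                 tumor_nest_count = 0,
                                 stromal_density = c(cd8_t = 0, cd4_t = 0,
                                                     treg = 50, pmn = 0,
                                                     macrophage = 0),
                                 treg_exclusion_radius_um = 0)
  counts <- vapply(1:20, function(s) {
    sum(generate_cell_slide(params, seed = s)$phenotype == "Treg")
  }, numeric(1))
  lims <- qpois(c(0.005, 0.995), 50)
  expect_true(all(counts >= lims[1] & counts <= lims[2]))
  expect_gt(var(counts), 0)
})

test_that("generators are deterministic under a fixed seed", {
  p <- slide_pattern_params()
  expect_identical(generate_cell_slide(p, seed = 7),
                   generate_cell_slide(p, seed = 7))
  cp <- cohort_params(n_patients = 3, seed = 13)
  expect_identical(generate_patient_cohort(cp), generate_patient_cohort(cp))
})

test_that("invalid slide parameters are rejected", {
  expect_error(slide_pattern_params(tumor_cell_density = -5))
  expect_error(slide_pattern_params(intensity_bin_probs = c(0.5, 0.5, 0.1, 0.1)),
               "summing")
  expect_error(slide_pattern_params(ki67_fraction_tcell = 1.5))
  expect_error(slide_pattern_params(treg_exclusion_radius_um = -1))
  expect_error(cohort_params(n_patients = 0))
  expect_error(cohort_params(caller_sensitivity = c(LoFreq = 1.2, MuSE = 1,
                                                    Mutect2 = 1, Strelka2 = 1)))
})

test_that("cohort plants exactly the requested number of responders", {
  co <- default_test_cohort()
  ptrs <- vapply(co$patients, function(p) {
    compute_ptr(p$slide_areas[p$slide_areas$site == "primary", ])
  }, numeric(1))
  expect_equal(sum(ptrs >= 50), 5L)
  expect_setequal(which(ptrs >= 50), co$responder_ids)

  none <- generate_patient_cohort(
    cohort_params(n_patients = 4, responder_fraction = 0, seed = 3),
    include = "pathology")
  ptrs0 <- vapply(none$patients, function(p) compute_ptr(p$slide_areas),
                  numeric(1))
  expect_true(all(ptrs0 < 50))
})

test_that("caller call sets obey the sensitivity/false-call model", {
  truth <- data.frame(chrom = "chr1", pos = 1:50, ref = "A", alt = "G",
                      type = "SNV", vaf = 0.2, stringsAsFactors = FALSE)
  perfect <- generate_caller_callsets(
    truth, list(sensitivity = c(LoFreq = 1, MuSE = 1, Mutect2 = 1,
                                Strelka2 = 1),
                false_rate = c(LoFreq = 0, MuSE = 0, Mutect2 = 0,
                               Strelka2 = 0)), seed = 1)
  cons <- consensus_snvs(perfect$snv)
  expect_equal(nrow(cons), 50L)
  expect_true(all(cons$n_support == 4L))

  blind <- generate_caller_callsets(
    truth, list(sensitivity = c(LoFreq = 0, MuSE = 0, Mutect2 = 0,
                                Strelka2 = 0),
                false_rate = c(LoFreq = 0, MuSE = 0, Mutect2 = 0,
                               Strelka2 = 0)), seed = 1)
  expect_true(all(vapply(blind$snv, function(cs) nrow(cs$variants),
                         integer(1)) == 0L))

  expect_error(generate_caller_callsets(
    truth, list(sensitivity = c(LoFreq = 2, MuSE = 1, Mutect2 = 1,
                                Strelka2 = 1),
                false_rate = c(LoFreq = 0, MuSE = 0, Mutect2 = 0,
                               Strelka2 = 0)), seed = 1), "sensitivity")

  dup <- rbind(truth, truth[1, ])
  expect_error(generate_caller_callsets(
    dup, list(sensitivity = c(LoFreq = 1, MuSE = 1, Mutect2 = 1,
                              Strelka2 = 1),
              false_rate = c(LoFreq = 0, MuSE = 0, Mutect2 = 0,
                             Strelka2 = 0)), seed = 1), "distinct")
})

test_that("MuSE emits no indel call set and indel callers are the named three", {
  co <- default_test_cohort()
  p1 <- co$patients[[1]]
  expect_setequal(vapply(p1$callsets$snv, `[[`, character(1), "caller"),
                  c("LoFreq", "MuSE", "Mutect2", "Strelka2"))
  expect_setequal(vapply(p1$callsets$indel, `[[`, character(1), "caller"),
                  c("LoFreq", "Mutect2", "Strelka2"))
  for (cs in p1$callsets$indel) {
    expect_true(all(cs$variants$type == "INDEL"))
  }
})

test_that("core TGF-beta pathway mutations are planted in all but one patient", {
  co <- default_test_cohort()
  has_core <- vapply(co$patients, function(p) any(p$truth_variants$core_tgfb),
                     logical(1))
  expect_equal(sum(has_core), 13L)
})
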