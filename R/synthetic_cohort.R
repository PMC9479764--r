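# Synthetic patient cohort generator.
#
# Produces, per patient: pre/post MIF cell tables (with planted response-class
# effects), pathology slide areas whose viable fractions put responders at
# pTR >= 50 exactly, lesion measurements, a somatic truth variant set with
# per-caller call sets, protein contexts for neoepitope enumeration, a TPM
# table, HLA alleles, and an ELISpot plate with responder-dependent
# post-treatment spot inflation.

CORE_TGFB_GENES <- c("TGFBR1", "TGFBR2", "SMAD2", "SMAD3", "SMAD4",
                     "ACVR1B", "ACVR2A", "TGFB1")

HLA_POOL <- c("HLA-A*01:01", "HLA-A*02:01", "HLA-A*03:01", "HLA-B*07:02",
              "HLA-B*08:01", "HLA-B*44:02", "HLA-C*07:01", "HLA-C*07:02")

.random_protein <- function(len) {
  paste(sample(AA_ALPHABET, len, replace = TRUE), collapse = "")
}

# random novel variants avoiding a set of existing keys
.random_variants <- function(n, type, existing_keys) {
  if (n == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      type = character(0), vaf = numeric(0),
                      stringsAsFactors = FALSE))
  }
  rows <- list()
  while (length(rows) < n) {
    chrom <- paste0("chr", sample(1:22, 1))
    pos <- sample.int(5e7, 1) + 1e6L
    if (type == "SNV") {
      ref <- sample(c("A", "C", "G", "T"), 1)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    } else if (stats::runif(1) < 0.5) {  # insertion
      ref <- sample(c("A", "C", "G", "T"), 1)
      alt <- paste0(ref, paste(sample(c("A", "C", "G", "T"),
                                      sample(1:3, 1), replace = TRUE),
                               collapse = ""))
    } else {  # deletion
      alt <- sample(c("A", "C", "G", "T"), 1)
      ref <- paste0(alt, paste(sample(c("A", "C", "G", "T"),
                                      sample(1:3, 1), replace = TRUE),
                               collapse = ""))
    }
    key <- .variant_key(chrom, pos, ref, alt)
    if (key %in% existing_keys) next
    existing_keys <- c(existing_keys, key)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt, type = type,
      vaf = round(stats::runif(1, 0.02, 0.3), 4), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Simulate per-caller call sets from a truth variant set
#'
#' Each caller's set is the truth set thinned by an independent per-variant
#' Bernoulli keep at that caller's sensitivity, plus caller-private false
#' calls (Poisson with mean `false_rate x n_truth` of that type).  SNV sets
#' are produced for LoFreq, MuSE, Mutect2 and Strelka2; indel sets for
#' LoFreq, Mutect2 and Strelka2 (MuSE emits no indels).
#'
#' @param truth data.frame with `chrom`, `pos`, `ref`, `alt`, `type`
#'   (`"SNV"`/`"INDEL"`) and optionally `vaf`; keys must be distinct.
#' @param noise List with named vectors `sensitivity` and `false_rate`
#'   (per-caller; sensitivities in \[0, 1\]).
#' @param seed Integer seed.
#' @return List with elements `snv` and `indel`, each a list of
#'   [caller_callset()] objects.
#' @export
generate_caller_callsets <- function(truth, noise, seed = 1L) {
  sens <- noise$sensitivity
  fr <- noise$false_rate
  if (any(sens < 0) || any(sens > 1)) {
    .param_error("sensitivity must be in [0, 1]")
  }
  truth_keys <- .variant_key(truth$chrom, truth$pos, truth$ref, truth$alt)
  if (anyDuplicated(truth_keys)) {
    .param_error("truth variants must have distinct (chrom,pos,ref,alt)")
  }
  set.seed(as.integer(seed))
  make_sets <- function(callers, type) {
    sub <- truth[truth$type == type, , drop = FALSE]
    lapply(callers, function(cl) {
      keep <- if (nrow(sub) > 0L) {
        stats::runif(nrow(sub)) < sens[[cl]]
      } else logical(0)
      detected <- sub[keep, , drop = FALSE]
      n_false <- stats::rpois(1, fr[[cl]] * nrow(sub))
      false_calls <- .random_variants(n_false, type, truth_keys)
      cols <- c("chrom", "pos", "ref", "alt", "type", "vaf")
      if (!"vaf" %in% names(detected)) detected$vaf <- NA_real_
      caller_callset(cl, rbind(detected[, cols, drop = FALSE],
                               false_calls[, cols, drop = FALSE]))
    })
  }
  list(snv = make_sets(SNV_CALLERS, "SNV"),
       indel = make_sets(INDEL_CALLERS, "INDEL"))
}

# one patient's somatic truth set + protein contexts
.generate_patient_variants <- function(params, plant_core_tgfb) {
  n_mut <- max(1L, stats::rpois(1, params$mutation_count_mean))
  is_indel <- stats::runif(n_mut) < params$indel_fraction
  genes <- sprintf("GENE%04d", sample.int(5000, n_mut))
  if (plant_core_tgfb) genes[1] <- sample(CORE_TGFB_GENES, 1)

  existing <- character(0)
  var_rows <- list()
  consequences <- list()
  proteins <- character(0)
  for (i in seq_len(n_mut)) {
    type <- if (is_indel[i]) "INDEL" else "SNV"
    v <- .random_variants(1L, type, existing)
    existing <- c(existing, .variant_key(v$chrom, v$pos, v$ref, v$alt))
    L <- sample(100:300, 1)
    prot <- .random_protein(L)
    if (type == "SNV") {
      kind <- sample(c("missense", "synonymous", "stop_gained"), 1,
                     prob = c(0.8, 0.1, 0.1))
      p <- sample.int(L, 1)
      ref_aa <- substr(prot, p, p)
      cons <- switch(kind,
        missense = variant_consequence("missense", p, ref_aa = ref_aa,
                                       alt_aa = sample(setdiff(AA_ALPHABET,
                                                               ref_aa), 1)),
        synonymous = variant_consequence("synonymous", p, ref_aa = ref_aa,
                                         alt_aa = ref_aa),
        stop_gained = variant_consequence("stop_gained", p))
    } else {
      kind <- sample(c("frameshift", "inframe_insertion", "inframe_deletion"),
                     1, prob = c(0.7, 0.15, 0.15))
      cons <- switch(kind,
        frameshift = {
          p <- sample.int(L - 5L, 1)
          variant_consequence("frameshift", p,
                              tail = .random_protein(sample(5:30, 1)))
        },
        inframe_insertion = variant_consequence(
          "inframe_insertion", sample.int(L - 1L, 1),
          ins_seq = .random_protein(sample(1:3, 1))),
        inframe_deletion = {
          dl <- sample(1:3, 1)
          variant_consequence("inframe_deletion", sample.int(L - dl, 1),
                              del_len = dl)
        })
    }
    vaf <- min(1, max(0.02, stats::rbeta(1, params$vaf_shape[1],
                                         params$vaf_shape[2])))
    v$vaf <- round(vaf, 4)
    v$gene <- genes[i]
    v$tpm <- round(stats::rlnorm(1, params$tpm_meanlog, params$tpm_sdlog), 3)
    v$present_pretreatment <- stats::runif(1) < 0.9
    v$core_tgfb <- genes[i] %in% CORE_TGFB_GENES
    var_rows[[i]] <- v
    key <- existing[length(existing)]
    consequences[[key]] <- cons
    proteins[[genes[i]]] <- prot
  }
  truth <- do.call(rbind, var_rows)
  list(truth = truth, consequences = consequences, proteins = proteins)
}

# one patient's ELISpot plate
.generate_patient_elispot <- function(params, is_responder) {
  nc <- params$n_elispot_conditions
  n_pos <- if (is_responder) {
    params$elispot_responder_npos[1] +
      stats::rbinom(1, params$elispot_responder_npos[2],
                    params$elispot_responder_p)
  } else {
    stats::rbinom(1, nc, params$elispot_nonresponder_p)
  }
  n_pos <- min(n_pos, nc)
  pos_idx <- if (n_pos > 0L) sample.int(nc, n_pos) else integer(0)

  rows <- list()
  add <- function(condition, type, tp, lambda) {
    rows[[length(rows) + 1L]] <<- data.frame(
      condition = condition, condition_type = type, timepoint = tp,
      rep1 = stats::rpois(1, lambda), rep2 = stats::rpois(1, lambda),
      stringsAsFactors = FALSE)
  }
  for (j in seq_len(nc)) {
    cond <- sprintf("pep%02d", j)
    if (j %in% pos_idx) {
      mu_post <- 6 + stats::rnbinom(1, size = params$elispot_spot_size,
                                    mu = params$elispot_spot_mu)
      lam_pre <- if (stats::runif(1) < 0.5) 1.5 else 0
      add(cond, "neoepitope", "pre", lam_pre)
      add(cond, "neoepitope", "post", mu_post)
    } else {
      add(cond, "neoepitope", "pre", params$elispot_baseline_mean)
      add(cond, "neoepitope", "post", params$elispot_baseline_mean)
    }
  }
  cef_lambda <- if (stats::runif(1) < 0.5) 20 else 0.3
  add("CEF", "cef", "pre", cef_lambda)
  add("CEF", "cef", "post", cef_lambda)
  add("E7", "e7_control", "pre", 50)
  add("E7", "e7_control", "post", 50)
  add("none", "background", "pre", 0.3)
  add("none", "background", "post", 0.3)
  do.call(rbind, rows)
}

# scale all immune densities of a slide pattern by one patient-level factor
.scale_slide_densities <- function(sp, factor) {
  .modify_slide_params(sp, list(
    stromal_density = sp$stromal_density * factor,
    intratumoral_density = sp$intratumoral_density * factor))
}

#' Generate a complete synthetic patient cohort
#'
#' @param params A [cohort_params()] object.
#' @param include Character vector of components to generate; any subset of
#'   `c("pathology", "radiology", "mif", "variants", "elispot")`.  Smaller
#'   subsets are useful for focused simulation studies (e.g. type-I-error
#'   calibration needs only pathology + MIF).
#' @return A `synthetic_cohort` list with `params`, `responder_ids`, and
#'   `patients` (per-patient component lists).  Fixed seed implies an
#'   identical cohort.
#' @export
generate_patient_cohort <- function(params = cohort_params(),
                                    include = c("pathology", "radiology",
                                                "mif", "variants",
                                                "elispot")) {
  if (!inherits(params, "cohort_params")) {
    .param_error("params must be a cohort_params object")
  }
  n <- params$n_patients
  if (n < 1L) .param_error("n_patients must be >= 1")
  set.seed(params$seed)

  n_resp <- as.integer(round_half_up(n * params$responder_fraction))
  responder_ids <- sort(sample.int(n, n_resp))
  nonresp_ids <- setdiff(seq_len(n), responder_ids)
  # 1-year recurrences planted among non-responders (rate ~ 1/7 of cohort)
  n_recur <- min(length(nonresp_ids), as.integer(round_half_up(n / 7)))
  recur_ids <- if (n_recur > 0L) sample(nonresp_ids, n_recur) else integer(0)
  # nodal status: ~2/14 pathologically positive, ~5/14 suspicious-but-N0
  n_ln_pos <- as.integer(round_half_up(n * 2 / 14))
  n_ln_susp <- as.integer(round_half_up(n * 5 / 14))
  ln_assign <- sample(seq_len(n))
  ln_pos_ids <- ln_assign[seq_len(n_ln_pos)]
  ln_susp_ids <- ln_assign[n_ln_pos + seq_len(n_ln_susp)]
  # one patient (if any) left without a core TGF-beta pathway mutation
  no_tgfb_patient <- if (n > 1L) sample.int(n, 1) else 0L

  patients <- vector("list", n)
  for (i in seq_len(n)) {
    seed_i <- .derive_seed(params$seed, i)
    set.seed(seed_i)
    is_resp <- i %in% responder_ids
    class_name <- if (is_resp) "responder" else "nonresponder"
    pat <- list(
      patient_id = sprintf("P%02d", i),
      response_class = class_name,
      rfs_1yr = !(i %in% recur_ids),
      ln_status = if (i %in% ln_pos_ids) "positive" else
        if (i %in% ln_susp_ids) "suspicious_n0" else "none",
      hla = sample(HLA_POOL, 3)
    )

    if ("pathology" %in% include) {
      vf_range <- if (is_resp) params$viable_fraction_responder else
        params$viable_fraction_nonresponder
      ns <- params$slides_per_patient
      bed <- stats::runif(ns, params$bed_area_range_mm2[1],
                          params$bed_area_range_mm2[2])
      vf <- stats::runif(ns, vf_range[1], vf_range[2])
      slide_areas <- data.frame(
        patient_id = pat$patient_id, site = "primary",
        block_id = sprintf("B%02d", seq_len(ns)),
        viable_area_mm2 = round(bed * vf, 3), bed_area_mm2 = round(bed, 3),
        stringsAsFactors = FALSE)
      if (pat$ln_status == "positive") {
        bed_ln <- stats::runif(2, 20, 60)
        vf_ln <- stats::runif(2, 0.2, 0.8)
        slide_areas <- rbind(slide_areas, data.frame(
          patient_id = pat$patient_id, site = "LN",
          block_id = c("LN01", "LN02"),
          viable_area_mm2 = round(bed_ln * vf_ln, 3),
          bed_area_mm2 = round(bed_ln, 3), stringsAsFactors = FALSE))
      }
      pat$slide_areas <- slide_areas
    }

    if ("radiology" %in% include) {
      lesion <- function(site, l_range) {
        l <- stats::runif(1, l_range[1], l_range[2])
        w <- l * stats::runif(1, 0.5, 1)
        growth <- exp(stats::rnorm(1, log(1.15), 0.3))
        data.frame(
          patient_id = pat$patient_id, site = site,
          timepoint = c("pre", "post"),
          length_mm = round(c(l, l * sqrt(growth)), 1),
          width_mm = round(c(w, w * sqrt(growth)), 1),
          suspicious_flag = site == "LN", stringsAsFactors = FALSE)
      }
      lesions <- lesion("primary", c(15, 40))
      if (pat$ln_status != "none") lesions <- rbind(lesions, lesion("LN", c(12, 25)))
      pat$lesions <- lesions
    }

    if ("mif" %in% include) {
      het <- exp(stats::rnorm(1, 0, 0.25))
      sp <- params$slide_params[[class_name]]
      cells_list <- list()
      areas <- list()
      for (tp in c("pre", "post")) {
        sp_tp <- .scale_slide_densities(sp[[tp]], het)
        slide_seed <- .derive_seed(seed_i, if (tp == "pre") 1001L else 2001L)
        cells <- generate_cell_slide(sp_tp, seed = slide_seed)
        areas[[tp]] <- data.frame(
          patient_id = pat$patient_id, timepoint = tp,
          tumor_area_mm2 = attr(cells, "tumor_area_mm2"),
          stroma_area_mm2 = attr(cells, "stroma_area_mm2"),
          stringsAsFactors = FALSE)
        cells$patient_id <- pat$patient_id
        cells$timepoint <- tp
        cells_list[[tp]] <- cells
      }
      set.seed(.derive_seed(seed_i, 3001L))  # reset after slide sub-seeds
      pat$cells <- do.call(rbind, cells_list)
      rownames(pat$cells) <- NULL
      pat$areas <- do.call(rbind, areas)
      rownames(pat$areas) <- NULL
    }

    if ("variants" %in% include) {
      set.seed(.derive_seed(seed_i, 4001L))
      vg <- .generate_patient_variants(params, plant_core_tgfb = i != no_tgfb_patient)
      pat$truth_variants <- vg$truth
      pat$consequences <- vg$consequences
      pat$proteins <- vg$proteins
      pat$tpm <- data.frame(gene = vg$truth$gene, tpm = vg$truth$tpm,
                            stringsAsFactors = FALSE)
      pat$callsets <- generate_caller_callsets(
        vg$truth,
        list(sensitivity = params$caller_sensitivity,
             false_rate = params$caller_false_rate),
        seed = .derive_seed(seed_i, 5001L))
    }

    if ("elispot" %in% include) {
      set.seed(.derive_seed(seed_i, 6001L))
      plate <- .generate_patient_elispot(params, is_resp)
      plate$patient_id <- pat$patient_id
      pat$elispot <- plate[, c("patient_id", "condition", "condition_type",
                               "timepoint", "rep1", "rep2")]
    }

    patients[[i]] <- pat
  }
  names(patients) <- vapply(patients, `[[`, character(1), "patient_id")
  structure(list(params = params, responder_ids = responder_ids,
                 include = include, patients = patients),
            class = "synthetic_cohort")
}
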