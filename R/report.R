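# Cohort report: runs every analysis stage over a cohort, assembles the
# per-patient summary (waterfall-ordered by primary pTR), computes the printed
# rates, and tests each planted correlate against the pathologic-response
# split with a two-sided Mann-Whitney U test.  No multiple-testing correction
# is applied (the report annotates the number of tests performed).

# MIF metrics for one patient from phenotyped cells + compartment areas
.patient_mif_metrics <- function(cells, areas) {
  get <- function(tp, pheno, comp) {
    a <- areas[areas$timepoint == tp, , drop = FALSE]
    area <- switch(comp,
                   tumor = a$tumor_area_mm2,
                   stroma = a$stroma_area_mm2,
                   whole = a$tumor_area_mm2 + a$stroma_area_mm2)
    cc <- cells[cells$timepoint == tp, , drop = FALSE]
    cell_density(cc, pheno, comp, area)$density
  }
  dens <- list()
  for (tp in c("pre", "post")) {
    for (pheno in c("CD8 T cell", "Treg", "PMN", "Macrophage")) {
      for (comp in c("tumor", "stroma", "whole")) {
        dens[[paste(tp, pheno, comp)]] <- get(tp, pheno, comp)
      }
    }
  }
  ratio <- function(tp, comp) {
    cd8_treg_ratio(dens[[paste(tp, "CD8 T cell", comp)]],
                   dens[[paste(tp, "Treg", comp)]])
  }
  list(
    tumor_cd8_pre = dens[["pre CD8 T cell tumor"]],
    tumor_cd8_post = dens[["post CD8 T cell tumor"]],
    log2fc_tumor_cd8 = log2_fc(dens[["pre CD8 T cell tumor"]],
                               dens[["post CD8 T cell tumor"]]),
    log2fc_stromal_treg = log2_fc(dens[["pre Treg stroma"]],
                                  dens[["post Treg stroma"]]),
    log2fc_cd8_treg_ratio_tumor = log2_fc(ratio("pre", "tumor"),
                                          ratio("post", "tumor")),
    log2fc_cd8_treg_ratio_stroma = log2_fc(ratio("pre", "stroma"),
                                           ratio("post", "stroma")),
    log2fc_cd8_treg_ratio_whole = log2_fc(ratio("pre", "whole"),
                                          ratio("post", "whole")),
    pre_stromal_myeloid = dens[["pre PMN stroma"]] +
      dens[["pre Macrophage stroma"]],
    stromal_immune_fraction_pre =
      stromal_immune_fraction(cells[cells$timepoint == "pre", , drop = FALSE])
  )
}

# proximity shifts for one patient (pairwise mode, Ki67+ classes and pooled)
.patient_proximity <- function(cells, config) {
  res <- list()
  for (tp in c("pre", "post")) {
    cc <- cells[cells$timepoint == tp, , drop = FALSE]
    by_class <- proximity_by_class(cc, config)
    pooled_d <- c(by_class[["Ki67+CD8"]]$distances,
                  by_class[["Ki67+CD4"]]$distances)
    by_class$pooled <- list(
      n_pairs = length(pooled_d),
      mean_distance_um = if (length(pooled_d)) mean(pooled_d) else NA_real_,
      distances = pooled_d)
    res[[tp]] <- by_class
  }
  list(
    mean_distances = list(pre = mean_distance_by_class(res$pre[PROXIMITY_CLASSES]),
                          post = mean_distance_by_class(res$post[PROXIMITY_CLASSES])),
    shift_ki67_cd8 = proximity_shift(res$pre[["Ki67+CD8"]],
                                     res$post[["Ki67+CD8"]]),
    shift_ki67_cd4 = proximity_shift(res$pre[["Ki67+CD4"]],
                                     res$post[["Ki67+CD4"]]),
    shift_ki67_pooled = proximity_shift(res$pre$pooled, res$post$pooled)
  )
}

# consensus + neoepitope stage for one patient
.patient_neoepitopes <- function(pat, predictor, max_per_patient) {
  cons_snv <- consensus_snvs(pat$callsets$snv)
  cons_indel <- consensus_indels(pat$callsets$indel)
  consensus <- rbind(cons_snv, cons_indel)
  truth_keys <- .variant_key(pat$truth_variants$chrom, pat$truth_variants$pos,
                             pat$truth_variants$ref, pat$truth_variants$alt)
  cand_rows <- list()
  for (j in seq_len(nrow(consensus))) {
    key <- .variant_key(consensus$chrom[j], consensus$pos[j],
                        consensus$ref[j], consensus$alt[j])
    t_idx <- match(key, truth_keys)
    if (is.na(t_idx)) next  # false consensus call: no annotation available
    cons <- pat$consequences[[key]]
    if (is.null(cons)) next
    gene <- pat$truth_variants$gene[t_idx]
    ctx <- build_mutant_context(gene, pat$proteins[[gene]], cons)
    peptides <- enumerate_9mers(ctx)
    if (length(peptides) == 0L) next
    cand_rows[[length(cand_rows) + 1L]] <- data.frame(
      peptide = peptides, variant_key = key, gene = gene,
      tpm = pat$truth_variants$tpm[t_idx],
      vaf = consensus$vaf[j],
      present_pretreatment = pat$truth_variants$present_pretreatment[t_idx],
      stringsAsFactors = FALSE)
  }
  if (length(cand_rows) == 0L) {
    return(list(consensus = consensus, candidates = NULL,
                n_mutations = nrow(consensus), n_ic50_500 = 0L,
                n_selected = 0L))
  }
  cands <- do.call(rbind, cand_rows)
  pred <- predict_best_ic50(cands$peptide, pat$hla, predictor)
  cands <- merge(cands, pred, by = "peptide", sort = FALSE)
  ranked <- rank_candidates(cands)
  selected <- select_candidates(ranked, max_per_patient = max_per_patient)
  list(consensus = consensus, candidates = selected,
       n_mutations = nrow(consensus),
       n_ic50_500 = sum(selected$ic50_nm < 500),
       n_selected = sum(selected$selected))
}

#' Run the full correlative pipeline over a cohort
#'
#' Executes pathology scoring, radiographic volume change, MIF
#' quantification, spatial proximity, variant consensus, neoepitope
#' enumeration/selection and ELISpot calling for every patient, then builds
#' the cohort report.
#'
#' @param cohort A `synthetic_cohort` (or a list of the same shape holding
#'   real data).
#' @param proximity Config for the spatial stage ([proximity_config()];
#'   pairwise mode is the default used for mean-distance statistics).
#' @param predictor Binding predictor; defaults to the synthetic stand-in
#'   parameterized by the cohort's `strong_binder_fraction`.
#' @param max_per_patient Neoepitope synthesis cap per patient.
#' @param speculative_ln Count possible LN CRs as true CRs in the any-site
#'   response tally (the speculative 71% figure vs the confirmed 43%).
#' @return List with `patients` (summary data.frame, waterfall-ordered by
#'   descending primary pTR), `rates`, `associations`, `n_tests`, and
#'   `details` (per-patient stage outputs).
#' @export
run_pipeline <- function(cohort, proximity = proximity_config(),
                         predictor = NULL, max_per_patient = 12,
                         speculative_ln = FALSE) {
  if (is.null(predictor)) {
    sbf <- tryCatch(cohort$params$strong_binder_fraction,
                    error = function(e) NULL)
    predictor <- synthetic_binding_predictor(
      strong_fraction = if (is.null(sbf)) 0.15 else sbf)
  }
  rows <- list()
  details <- list()
  for (pat in cohort$patients) {
    row <- list(patient_id = pat$patient_id,
                response_class_true = pat$response_class %||% NA_character_,
                rfs_1yr = pat$rfs_1yr %||% NA,
                ln_status = pat$ln_status %||% NA_character_)
    det <- list()

    if (!is.null(pat$slide_areas)) {
      prim <- pat$slide_areas[pat$slide_areas$site == "primary", , drop = FALSE]
      ptr <- compute_ptr(prim)
      call <- classify_response(ptr)
      row$ptr_primary <- ptr
      row$class_primary <- call$class
      row$pr_flag <- call$pr_flag
      ln_rows <- pat$slide_areas[pat$slide_areas$site == "LN", , drop = FALSE]
      row$possible_ln_cr <- identical(pat$ln_status, "suspicious_n0")
      if (nrow(ln_rows) > 0L) {
        row$ptr_ln <- compute_ptr(ln_rows)
        row$discordant <- classify_discordance(ptr, row$ptr_ln)
      } else if (row$possible_ln_cr) {
        row$ptr_ln <- NA_integer_
        row$discordant <- classify_discordance(ptr, 100, ln_possible_cr = TRUE)
      } else {
        row$ptr_ln <- NA_integer_
        row$discordant <- NA
      }
    }

    if (!is.null(pat$lesions)) {
      vol <- function(site) {
        le <- pat$lesions[pat$lesions$site == site, , drop = FALSE]
        if (nrow(le) == 0L) return(NA_real_)
        volume_change(le[le$timepoint == "pre", , drop = FALSE],
                      le[le$timepoint == "post", , drop = FALSE])
      }
      row$vol_change_primary <- vol("primary")
      row$vol_change_ln <- vol("LN")
    }

    if (!is.null(pat$cells)) {
      cells <- assign_phenotypes(pat$cells)
      mif <- .patient_mif_metrics(cells, pat$areas)
      prox <- .patient_proximity(cells, proximity)
      row <- c(row, mif[c("log2fc_tumor_cd8", "log2fc_stromal_treg",
                          "log2fc_cd8_treg_ratio_tumor",
                          "log2fc_cd8_treg_ratio_stroma",
                          "log2fc_cd8_treg_ratio_whole",
                          "pre_stromal_myeloid",
                          "stromal_immune_fraction_pre")])
      row$shift_ki67_cd8 <- prox$shift_ki67_cd8
      row$shift_ki67_cd4 <- prox$shift_ki67_cd4
      row$shift_ki67_pooled <- prox$shift_ki67_pooled
      det$mif <- mif
      det$proximity <- prox
    }

    if (!is.null(pat$callsets)) {
      neo <- .patient_neoepitopes(pat, predictor, max_per_patient)
      row$n_mutations <- neo$n_mutations
      row$n_core_tgfb <- sum(pat$truth_variants$core_tgfb)
      row$n_neoepitopes_ic50_500 <- neo$n_ic50_500
      row$n_selected_neoepitopes <- neo$n_selected
      det$neoepitopes <- neo
    }

    if (!is.null(pat$elispot)) {
      flags <- classify_plate(pat$elispot)
      agg <- patient_aggregates(flags)
      row$n_positive_neoepitopes <- agg$n_positive_neoepitopes
      row$cumulative_spot_count <- agg$cumulative_spot_count
      row$cef_positive <- agg$cef_positive
      det$elispot_flags <- flags
    }

    rows[[pat$patient_id]] <- row
    details[[pat$patient_id]] <- det
  }

  all_names <- unique(unlist(lapply(rows, names)))
  patients <- do.call(rbind, lapply(rows, function(r) {
    missing <- setdiff(all_names, names(r))
    for (m in missing) r[[m]] <- NA
    as.data.frame(r[all_names], stringsAsFactors = FALSE)
  }))
  rownames(patients) <- NULL
  if ("ptr_primary" %in% names(patients)) {
    patients <- patients[order(-patients$ptr_primary, patients$patient_id), ,
                         drop = FALSE]
    rownames(patients) <- NULL
  }

  report <- build_report(patients, speculative_ln = speculative_ln)
  report$details <- details
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the cohort report from a patient-summary table
#'
#' @param patients Per-patient summary data.frame (as produced by
#'   [run_pipeline()]; rows are reordered by descending primary pTR).
#' @param speculative_ln Count possible LN CRs as CRs in the any-site tally.
#' @return List with `patients`, `rates` (integer percents via
#'   [rate_percent()]), `associations` (Mann-Whitney p per correlate vs the
#'   PR split) and `n_tests`.
#' @export
build_report <- function(patients, speculative_ln = FALSE) {
  n <- nrow(patients)
  if ("ptr_primary" %in% names(patients)) {
    patients <- patients[order(-patients$ptr_primary, patients$patient_id), ,
                         drop = FALSE]
    rownames(patients) <- NULL
  }

  rates <- list()
  if (all(c("pr_flag") %in% names(patients)) && !all(is.na(patients$pr_flag))) {
    rates$pr_rate_primary <- rate_percent(sum(patients$pr_flag, na.rm = TRUE), n)
    ln_pr <- !is.na(patients$ptr_ln) & patients$ptr_ln >= 50
    confirmed <- patients$pr_flag | ln_pr
    rates$any_site_ppr_confirmed <- rate_percent(sum(confirmed, na.rm = TRUE), n)
    spec <- confirmed | (!is.na(patients$possible_ln_cr) & patients$possible_ln_cr)
    rates$any_site_ppr_speculative <- rate_percent(sum(spec, na.rm = TRUE), n)
    if (speculative_ln) rates$any_site_ppr <- rates$any_site_ppr_speculative
  }
  if ("rfs_1yr" %in% names(patients) && !all(is.na(patients$rfs_1yr))) {
    rates$rfs_1yr <- rate_percent(sum(patients$rfs_1yr, na.rm = TRUE), n)
  }
  if ("n_core_tgfb" %in% names(patients) && !all(is.na(patients$n_core_tgfb))) {
    rates$core_tgfb_mutated <- rate_percent(sum(patients$n_core_tgfb > 0,
                                                na.rm = TRUE), n)
  }
  if ("cef_positive" %in% names(patients) && !all(is.na(patients$cef_positive))) {
    rates$cef_positive <- rate_percent(sum(patients$cef_positive, na.rm = TRUE), n)
  }

  correlates <- intersect(
    c("log2fc_tumor_cd8", "log2fc_cd8_treg_ratio_tumor",
      "log2fc_cd8_treg_ratio_stroma", "log2fc_cd8_treg_ratio_whole",
      "pre_stromal_myeloid", "shift_ki67_pooled", "n_mutations",
      "n_neoepitopes_ic50_500", "n_positive_neoepitopes",
      "cumulative_spot_count"),
    names(patients))
  associations <- NULL
  if ("pr_flag" %in% names(patients) && length(correlates) > 0L) {
    assoc_rows <- lapply(correlates, function(v) {
      res <- compare_by_response(patients[[v]], patients$pr_flag)
      data.frame(correlate = v, U = res$U, p = res$p,
                 n_responder = res$n_responder,
                 n_nonresponder = res$n_nonresponder,
                 significant = !is.na(res$p) && res$p < 0.05,
                 stringsAsFactors = FALSE)
    })
    associations <- do.call(rbind, assoc_rows)
  }

  list(patients = patients, rates = rates, associations = associations,
       n_tests = if (is.null(associations)) 0L else nrow(associations))
}
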