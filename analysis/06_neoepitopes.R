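#!/usr/bin/env Rscript
# Neoepitope candidate pipeline: novel 9-mer enumeration from consensus
# variants, best-IC50 prediction over each patient's HLA class I alleles,
# ranking by log2(TPM+1) x VAF, and the three selection criteria
# (pretreatment presence, IC50 <= 200 nM, TPM >= 4).  Writes
# results/neoepitope_candidates.tsv.

suppressPackageStartupMessages(library(neocorr))

cohort <- read_cohort(file.path("results", "cohort"))
predictor <- synthetic_binding_predictor(
  strong_fraction = cohort$params$strong_binder_fraction)

all_cands <- list()
for (p in cohort$patients) {
  cons <- rbind(consensus_snvs(p$callsets$snv),
                consensus_indels(p$callsets$indel))
  truth_keys <- with(p$truth_variants, paste(chrom, pos, ref, alt, sep = ":"))
  rows <- list()
  for (j in seq_len(nrow(cons))) {
    key <- paste(cons$chrom[j], cons$pos[j], cons$ref[j], cons$alt[j],
                 sep = ":")
    t_idx <- match(key, truth_keys)
    if (is.na(t_idx) || is.null(p$consequences[[key]])) next
    gene <- p$truth_variants$gene[t_idx]
    ctx <- build_mutant_context(gene, p$proteins[[gene]],
                                p$consequences[[key]])
    peps <- enumerate_9mers(ctx)
    if (length(peps) == 0) next
    rows[[length(rows) + 1L]] <- data.frame(
      peptide = peps, variant_key = key, gene = gene,
      tpm = p$truth_variants$tpm[t_idx], vaf = cons$vaf[j],
      present_pretreatment = p$truth_variants$present_pretreatment[t_idx],
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) next
  cands <- do.call(rbind, rows)
  cands <- merge(cands, predict_best_ic50(cands$peptide, p$hla, predictor),
                 by = "peptide", sort = FALSE)
  out <- select_candidates(rank_candidates(cands))
  all_cands[[p$patient_id]] <- cbind(patient_id = p$patient_id, out)
}

tab <- do.call(rbind, all_cands)
rownames(tab) <- NULL
dir.create("results", showWarnings = FALSE)
write.table(tab, file.path("results", "neoepitope_candidates.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

cat(sprintf("Enumerated %d candidate 9-mers; %d pass all three selection criteria (%d patients).\n",
            nrow(tab), sum(tab$selected), length(all_cands)))
cat(sprintf("Predicted binders with IC50 < 500 nM: %d.\n",
            sum(tab$ic50_nm < 500)))
cat("Candidate table written to results/neoepitope_candidates.tsv\n")
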