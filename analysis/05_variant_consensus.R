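#!/usr/bin/env Rscript
# Ensemble somatic-variant consensus: reads each patient's per-caller VCFs,
# retains SNVs supported by >= 3 of 4 callers and indels by >= 2 of 3, and
# writes per-patient consensus VCFs plus a cohort summary table.

suppressPackageStartupMessages(library(neocorr))

cdir <- file.path("results", "cohort")
cohort <- read_cohort(cdir)
dir.create(file.path("results", "consensus"), recursive = TRUE,
           showWarnings = FALSE)

rows <- list()
for (p in cohort$patients) {
  cons <- rbind(consensus_snvs(p$callsets$snv),
                consensus_indels(p$callsets$indel))
  write_vcf(cons, file.path("results", "consensus",
                            paste0(p$patient_id, "_consensus.vcf")))
  truth_keys <- with(p$truth_variants, paste(chrom, pos, ref, alt, sep = ":"))
  cons_keys <- with(cons, paste(chrom, pos, ref, alt, sep = ":"))
  rows[[length(rows) + 1L]] <- data.frame(
    patient_id = p$patient_id,
    n_truth = length(truth_keys),
    n_consensus = nrow(cons),
    n_snv = sum(cons$type == "SNV"),
    n_indel = sum(cons$type == "INDEL"),
    recall = round(mean(truth_keys %in% cons_keys), 3),
    false_calls = sum(!cons_keys %in% truth_keys),
    core_tgfb_mutated = any(p$truth_variants$core_tgfb),
    stringsAsFactors = FALSE)
}
tab <- do.call(rbind, rows)
write.table(tab, file.path("results", "consensus_summary.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

cat(sprintf("Consensus voting: mean recall %.3f, %d false consensus calls across %d patients.\n",
            mean(tab$recall), sum(tab$false_calls), nrow(tab)))
cat(sprintf("Tumors with core TGF-beta pathway mutations: %d%% (%d/%d).\n",
            rate_percent(sum(tab$core_tgfb_mutated), nrow(tab)),
            sum(tab$core_tgfb_mutated), nrow(tab)))
cat("Consensus VCFs written under results/consensus/\n")
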