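#!/usr/bin/env Rscript
# ELISpot response calling: per-condition detected/positive/increased flags
# from duplicate spot means and per-patient aggregates (number of positive
# neoepitopes, cumulative post-treatment spot count, CEF control).  Writes
# results/elispot_flags.tsv and results/elispot_aggregates.tsv.

suppressPackageStartupMessages(library(neocorr))

cohort <- read_cohort(file.path("results", "cohort"))

flags_all <- list(); aggs <- list()
for (p in cohort$patients) {
  flags <- classify_plate(p$elispot)
  agg <- patient_aggregates(flags)
  flags_all[[p$patient_id]] <- flags
  aggs[[length(aggs) + 1L]] <- data.frame(
    patient_id = p$patient_id,
    n_positive_neoepitopes = agg$n_positive_neoepitopes,
    cumulative_spot_count = agg$cumulative_spot_count,
    cef_positive = agg$cef_positive,
    response_class = p$response_class, stringsAsFactors = FALSE)
}
flags_tab <- do.call(rbind, flags_all)
agg_tab <- do.call(rbind, aggs)

dir.create("results", showWarnings = FALSE)
write.table(flags_tab, file.path("results", "elispot_flags.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(agg_tab, file.path("results", "elispot_aggregates.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)

neo <- flags_tab[flags_tab$condition_type == "neoepitope", ]
cat(sprintf("Neoepitope wells positive post-treatment: %d%% (%d/%d).\n",
            rate_percent(sum(neo$positive), nrow(neo)), sum(neo$positive),
            nrow(neo)))
cat(sprintf("Patients with >= 1 positive neoepitope response: %d of %d; CEF positive: %d%%.\n",
            sum(agg_tab$n_positive_neoepitopes > 0), nrow(agg_tab),
            rate_percent(sum(agg_tab$cef_positive), nrow(agg_tab))))
cat("ELISpot tables written under results/\n")
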