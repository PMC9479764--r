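# Readers and writers for the pipeline's on-disk interchange formats:
# cell tables and plates as CSV, expression as TSV, call sets as minimal
# VCF 4.2, proteins as FASTA, cohort manifest as JSON.

#' Write / read a segmented-cell table (CSV)
#'
#' @param cells Cell table data.frame.
#' @param path File path.
#' @return `read_cell_table` returns the data.frame.
#' @export
write_cell_table <- function(cells, path) {
  utils::write.csv(cells, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a minimal VCF 4.2 call set
#'
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt` and
#'   optionally `vaf`; consensus tables may carry `supporting_callers` /
#'   `n_support`, written as INFO SUPPORT / NSUPPORT.
#' @param path Output path.
#' @param caller Caller name written as INFO CALLER (per-caller sets).
#' @return The path, invisibly.
#' @export
write_vcf <- function(variants, path, caller = NULL) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=CALLER,Number=1,Type=String,Description=\"Source caller\">",
    "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Variant allele fraction\">",
    "##INFO=<ID=SUPPORT,Number=.,Type=String,Description=\"Supporting callers\">",
    "##INFO=<ID=NSUPPORT,Number=1,Type=Integer,Description=\"Number of supporting callers\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  info <- vapply(seq_len(nrow(variants)), function(i) {
    parts <- character(0)
    if (!is.null(caller)) parts <- c(parts, paste0("CALLER=", caller))
    if (!is.null(variants$vaf) && !is.na(variants$vaf[i])) {
      parts <- c(parts, paste0("VAF=", variants$vaf[i]))
    }
    if (!is.null(variants$supporting_callers)) {
      parts <- c(parts, paste0("SUPPORT=", variants$supporting_callers[i]),
                 paste0("NSUPPORT=", variants$n_support[i]))
    }
    if (length(parts) == 0L) "." else paste(parts, collapse = ";")
  }, character(1))
  body <- if (nrow(variants) > 0L) {
    paste(variants$chrom, variants$pos, ".", variants$ref, variants$alt,
          ".", "PASS", info, sep = "\t")
  } else character(0)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a per-caller VCF
#'
#' @param path VCF path (plain text or gzipped).
#' @param caller Caller name for the resulting call set; defaults to the
#'   INFO CALLER field when present.
#' @param pass_only Keep only FILTER == PASS / "." records (default TRUE;
#'   set FALSE to ingest everything).
#' @return A [caller_callset()].
#' @export
read_caller_vcf <- function(path, caller = NULL, pass_only = TRUE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  info <- vcfR::getINFO(v)
  if (nrow(fix) == 0L) {
    return(caller_callset(caller %||% "unknown",
                          data.frame(chrom = character(0), pos = integer(0),
                                     ref = character(0), alt = character(0),
                                     type = character(0), vaf = numeric(0))))
  }
  if (pass_only) {
    keep <- is.na(fix$FILTER) | fix$FILTER %in% c("PASS", ".")
    fix <- fix[keep, , drop = FALSE]
    info <- info[keep]
  }
  grab <- function(field) {
    m <- regexpr(paste0(field, "=[^;]+"), info)
    out <- rep(NA_character_, length(info))
    ok <- !is.na(m) & m > 0
    out[ok] <- sub(paste0(field, "="), "", regmatches(info, m))
    out
  }
  if (is.null(caller)) {
    cl <- grab("CALLER")
    caller <- if (all(is.na(cl))) "unknown" else stats::na.omit(cl)[1]
  }
  vaf <- suppressWarnings(as.numeric(grab("VAF")))
  variants <- data.frame(
    chrom = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF,
    alt = fix$ALT,
    type = ifelse(nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L, "SNV", "INDEL"),
    vaf = vaf, stringsAsFactors = FALSE)
  caller_callset(caller, variants)
}

#' Write / read a TPM expression table (TSV)
#'
#' @param tpm data.frame with `gene` and `tpm`.
#' @param path File path.
#' @export
write_tpm_table <- function(tpm, path) {
  utils::write.table(tpm, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tpm_table
#' @export
read_tpm_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read protein sequences (FASTA)
#'
#' @param proteins Named character vector of amino-acid sequences.
#' @param path File path.
#' @export
write_proteins_fasta <- function(proteins, path) {
  aa <- Biostrings::AAStringSet(proteins)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' @rdname write_proteins_fasta
#' @export
read_proteins_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(aa), names(aa))
}

#' Write a synthetic cohort to a directory
#'
#' Writes cell tables, compartment areas, slide areas, lesions, clinical
#' labels and HLA as CSV/TSV; per-caller call sets as minimal VCF 4.2;
#' expression as TSV; proteins as FASTA (record names `patient|gene`);
#' variant consequences and the cohort manifest as JSON.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "vcf"), showWarnings = FALSE)
  pats <- cohort$patients

  gather <- function(field) {
    do.call(rbind, Filter(Negate(is.null), lapply(pats, `[[`, field)))
  }
  clin <- do.call(rbind, lapply(pats, function(p) data.frame(
    patient_id = p$patient_id, response_class = p$response_class,
    rfs_1yr = p$rfs_1yr, ln_status = p$ln_status,
    hla = paste(p$hla, collapse = ";"), stringsAsFactors = FALSE)))
  utils::write.csv(clin, file.path(dir, "clinical.csv"), row.names = FALSE)

  for (nm in c("slide_areas", "lesions", "areas", "elispot")) {
    tab <- gather(nm)
    if (!is.null(tab)) {
      utils::write.csv(tab, file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
  }
  cells <- gather("cells")
  if (!is.null(cells)) write_cell_table(cells, file.path(dir, "cells.csv"))

  have_variants <- !is.null(pats[[1]]$truth_variants)
  if (have_variants) {
    tpm <- do.call(rbind, lapply(pats, function(p) {
      cbind(patient_id = p$patient_id, p$tpm)
    }))
    write_tpm_table(tpm, file.path(dir, "tpm.tsv"))
    prots <- do.call(c, unname(lapply(pats, function(p) {
      stats::setNames(p$proteins, paste0(p$patient_id, "|", names(p$proteins)))
    })))
    write_proteins_fasta(prots, file.path(dir, "proteins.faa"))
    truth <- do.call(rbind, lapply(pats, function(p) {
      cbind(patient_id = p$patient_id, p$truth_variants)
    }))
    utils::write.csv(truth, file.path(dir, "truth_variants.csv"),
                     row.names = FALSE)
    for (p in pats) {
      for (set in c("snv", "indel")) {
        for (cs in p$callsets[[set]]) {
          write_vcf(cs$variants,
                    file.path(dir, "vcf", paste0(p$patient_id, "_",
                                                 cs$caller, "_", set, ".vcf")),
                    caller = cs$caller)
        }
      }
    }
    cons_json <- lapply(pats, function(p) {
      lapply(p$consequences, function(cc) {
        Filter(Negate(is.null), unclass(cc))
      })
    })
    jsonlite::write_json(cons_json, file.path(dir, "consequences.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  manifest <- list(
    n_patients = length(pats),
    patient_ids = names(pats),
    responder_ids = cohort$responder_ids,
    include = cohort$include,
    seed = cohort$params$seed,
    strong_binder_fraction = cohort$params$strong_binder_fraction)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return A `synthetic_cohort`-shaped list suitable for [run_pipeline()].
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  clin <- utils::read.csv(file.path(dir, "clinical.csv"),
                          stringsAsFactors = FALSE)
  opt <- function(f, reader = function(p) utils::read.csv(p, stringsAsFactors = FALSE)) {
    p <- file.path(dir, f)
    if (file.exists(p)) reader(p) else NULL
  }
  slide_areas <- opt("slide_areas.csv")
  lesions <- opt("lesions.csv")
  areas <- opt("areas.csv")
  elispot <- opt("elispot.csv")
  cells <- opt("cells.csv", read_cell_table)
  tpm <- opt("tpm.tsv", read_tpm_table)
  truth <- opt("truth_variants.csv")
  prots <- opt("proteins.faa", read_proteins_fasta)
  cons_all <- opt("consequences.json",
                  function(p) jsonlite::read_json(p, simplifyVector = FALSE))

  subset_or_null <- function(tab, pid) {
    if (is.null(tab)) return(NULL)
    out <- tab[tab$patient_id == pid, , drop = FALSE]
    rownames(out) <- NULL
    if (nrow(out)) out else NULL
  }
  patients <- lapply(seq_len(nrow(clin)), function(i) {
    pid <- clin$patient_id[i]
    pat <- list(patient_id = pid,
                response_class = clin$response_class[i],
                rfs_1yr = clin$rfs_1yr[i],
                ln_status = clin$ln_status[i],
                hla = strsplit(clin$hla[i], ";")[[1]],
                slide_areas = subset_or_null(slide_areas, pid),
                lesions = subset_or_null(lesions, pid),
                areas = subset_or_null(areas, pid),
                cells = subset_or_null(cells, pid),
                elispot = subset_or_null(elispot, pid))
    tv <- subset_or_null(truth, pid)
    if (!is.null(tv)) {
      pat$truth_variants <- tv[, setdiff(names(tv), "patient_id"), drop = FALSE]
      pt <- subset_or_null(tpm, pid)
      pat$tpm <- pt[, setdiff(names(pt), "patient_id"), drop = FALSE]
      pref <- paste0(pid, "|")
      mine <- startsWith(names(prots), pref)
      pat$proteins <- stats::setNames(prots[mine],
                                      sub(pref, "", names(prots)[mine],
                                          fixed = TRUE))
      pat$consequences <- lapply(cons_all[[pid]], function(cc) {
        do.call(variant_consequence, cc)
      })
      read_set <- function(set, callers) {
        lapply(callers, function(cl) {
          read_caller_vcf(file.path(dir, "vcf",
                                    paste0(pid, "_", cl, "_", set, ".vcf")),
                          caller = cl)
        })
      }
      pat$callsets <- list(snv = read_set("snv", SNV_CALLERS),
                           indel = read_set("indel", INDEL_CALLERS))
    }
    pat
  })
  names(patients) <- clin$patient_id
  structure(list(params = list(seed = manifest$seed,
                               strong_binder_fraction =
                                 manifest$strong_binder_fraction),
                 responder_ids = manifest$responder_ids,
                 include = manifest$include,
                 patients = patients),
            class = "synthetic_cohort")
}

#' Write the cohort report tables
#'
#' Writes the waterfall-ordered patient table and association table as TSV
#' and a machine-readable JSON summary of every statistic.
#'
#' @param report Output of [run_pipeline()] / [build_report()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(report$patients, file.path(dir, "patient_summary.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(report$associations)) {
    utils::write.table(report$associations, file.path(dir, "associations.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(
    list(rates = report$rates,
         associations = report$associations,
         n_tests = report$n_tests),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  invisible(dir)
}
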