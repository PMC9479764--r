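# Ensemble somatic-variant consensus.
#
# SNVs are retained when detected by at least 3 of the 4 callers (LoFreq,
# MuSE, Mutect2, Strelka2); indels when detected by at least 2 of the 3 indel
# callers (LoFreq, Mutect2, Strelka2; MuSE calls no indels).  Variant identity
# is the exact (chrom, pos, ref, alt) key after parsimony normalization of
# indel representations; caller-specific annotations are ignored entirely.

SNV_CALLERS <- c("LoFreq", "MuSE", "Mutect2", "Strelka2")
INDEL_CALLERS <- c("LoFreq", "Mutect2", "Strelka2")

#' Normalize a variant representation
#'
#' Parsimony normalization: trims a shared suffix, then a shared prefix
#' (advancing `pos`), so equivalent indel spellings from different callers
#' map to one key.
#'
#' @param pos 1-based position.
#' @param ref,alt Reference and alternate alleles.
#' @return List with normalized `pos`, `ref`, `alt`.
#' @export
normalize_variant <- function(pos, ref, alt) {
  r <- strsplit(ref, "")[[1]]
  a <- strsplit(alt, "")[[1]]
  while (length(r) > 1L && length(a) > 1L && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]
    a <- a[-length(a)]
  }
  while (length(r) > 1L && length(a) > 1L && r[1] == a[1]) {
    r <- r[-1]
    a <- a[-1]
    pos <- pos + 1L
  }
  list(pos = as.integer(pos), ref = paste(r, collapse = ""),
       alt = paste(a, collapse = ""))
}

.variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Construct a caller call set
#'
#' @param caller Caller name.
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt`, `type`
#'   (`"SNV"`/`"INDEL"`) and optionally `vaf`.
#' @param normalize Apply [normalize_variant()] on ingest (default TRUE).
#' @return A `caller_callset` list with a deduplication-checked key column.
#' @export
caller_callset <- function(caller, variants, normalize = TRUE) {
  stopifnot(is.data.frame(variants))
  if (nrow(variants) > 0L && normalize) {
    norm <- Map(normalize_variant, variants$pos, variants$ref, variants$alt)
    variants$pos <- vapply(norm, `[[`, integer(1), "pos")
    variants$ref <- vapply(norm, `[[`, character(1), "ref")
    variants$alt <- vapply(norm, `[[`, character(1), "alt")
  }
  key <- .variant_key(variants$chrom, variants$pos, variants$ref, variants$alt)
  if (anyDuplicated(key)) {
    .param_error("duplicate variant keys within call set for ", caller)
  }
  if (caller == "MuSE" && any(variants$type == "INDEL")) {
    .param_error("MuSE call sets cannot contain indels")
  }
  variants$key <- key
  structure(list(caller = caller, variants = variants),
            class = "caller_callset")
}

# shared voting core
.consensus_vote <- function(callsets, expected_callers, type, min_support) {
  callers <- vapply(callsets, `[[`, character(1), "caller")
  if (anyDuplicated(callers)) {
    .param_error("configuration error: duplicate caller in call sets")
  }
  if (!setequal(callers, expected_callers) ||
      length(callers) != length(expected_callers)) {
    .param_error("configuration error: expected exactly callers ",
                 paste(expected_callers, collapse = ", "))
  }
  tabs <- lapply(callsets, function(cs) {
    v <- cs$variants
    v <- v[v$type == type, , drop = FALSE]
    v$caller <- rep(cs$caller, nrow(v))
    v
  })
  all_calls <- do.call(rbind, tabs)
  if (is.null(all_calls) || nrow(all_calls) == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      type = character(0), supporting_callers = character(0),
                      n_support = integer(0), vaf = numeric(0),
                      stringsAsFactors = FALSE))
  }
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      type = character(0), supporting_callers = character(0),
                      n_support = integer(0), vaf = numeric(0),
                      stringsAsFactors = FALSE)
  support <- split(all_calls, all_calls$key)
  keep <- support[vapply(support, nrow, integer(1)) >= min_support]
  if (length(keep) == 0L) return(empty)
  rows <- lapply(keep, function(g) {
    # VAF: primary caller (Mutect2) when it supports the variant, else the
    # mean over supporters; NA when no caller reports one
    vaf <- NA_real_
    if (!is.null(g$vaf)) {
      m2 <- g$vaf[g$caller == "Mutect2"]
      vaf <- if (length(m2) == 1L && !is.na(m2)) m2 else
        mean(g$vaf, na.rm = TRUE)
      if (is.nan(vaf)) vaf <- NA_real_
    }
    data.frame(chrom = g$chrom[1], pos = g$pos[1], ref = g$ref[1],
               alt = g$alt[1], type = g$type[1],
               supporting_callers = paste(sort(g$caller), collapse = ","),
               n_support = nrow(g), vaf = vaf, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$pos, out$ref, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Consensus SNVs (>= 3 of 4 callers)
#'
#' @param callsets List of exactly the four SNV [caller_callset()]s
#'   (LoFreq, MuSE, Mutect2, Strelka2), in any order.
#' @return data.frame of retained SNVs with `supporting_callers`,
#'   `n_support` and `vaf` (Mutect2's when available, else supporter mean).
#' @export
consensus_snvs <- function(callsets) {
  .consensus_vote(callsets, SNV_CALLERS, "SNV", 3L)
}

#' Consensus indels (>= 2 of 3 callers)
#'
#' @param callsets List of exactly the three indel [caller_callset()]s
#'   (LoFreq, Mutect2, Strelka2), in any order.
#' @return data.frame of retained indels, as [consensus_snvs()].
#' @export
consensus_indels <- function(callsets) {
  .consensus_vote(callsets, INDEL_CALLERS, "INDEL", 2L)
}

#' log2(TPM + 1) expression transform
#'
#' @param tpm Nonnegative transcripts-per-million values.
#' @return `log2(tpm + 1)`.
#' @export
log2_tpm <- function(tpm) {
  if (any(!is.finite(tpm)) || any(tpm < 0)) {
    .param_error("tpm must be finite and >= 0")
  }
  log2(tpm + 1)
}
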