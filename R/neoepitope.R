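# Neoepitope candidate enumeration, ranking and selection.
#
# Candidate 9-mers are all sliding windows of the mutant protein that overlap
# at least one altered residue and do not occur anywhere in the wild-type
# protein.  Candidates are ranked by expression and variant allele frequency
# (rank_score = log2(TPM + 1) x VAF) and selected when (a) the source variant
# is present in the pretreatment sample, (b) best predicted IC50 <= 200 nM,
# and (c) TPM >= 4.

#' Describe a protein-level variant consequence
#'
#' @param kind One of `"missense"`, `"inframe_insertion"`,
#'   `"inframe_deletion"`, `"frameshift"`, `"synonymous"`, `"stop_gained"`.
#' @param pos 1-based amino-acid position of the change.
#' @param ref_aa,alt_aa Reference/alternate residues (missense/synonymous).
#' @param ins_seq Inserted residues (in-frame insertion).
#' @param del_len Number of deleted residues (in-frame deletion).
#' @param tail Novel C-terminal sequence up to (excluding) the new stop
#'   (frameshift); empty means an immediate stop.
#' @return A `variant_consequence` list.
#' @export
variant_consequence <- function(kind, pos, ref_aa = NULL, alt_aa = NULL,
                                ins_seq = NULL, del_len = NULL, tail = NULL) {
  kind <- match.arg(kind, c("missense", "inframe_insertion",
                            "inframe_deletion", "frameshift", "synonymous",
                            "stop_gained"))
  structure(list(kind = kind, pos = as.integer(pos), ref_aa = ref_aa,
                 alt_aa = alt_aa, ins_seq = ins_seq, del_len = del_len,
                 tail = tail),
            class = "variant_consequence")
}

.empty_context <- function(gene, wildtype, reason) {
  structure(list(gene = gene, wildtype_sequence = wildtype,
                 mutant_sequence = "", altered_positions = integer(0),
                 reason = reason),
            class = "protein_context")
}

#' Build the mutant protein context for a variant
#'
#' Applies a protein-level consequence to the wild-type sequence and records
#' which mutant positions are altered: the substituted residue for a
#' missense; inserted residues plus both junction residues for an in-frame
#' insertion; the junction for an in-frame deletion; and everything from the
#' shift onward (to the residue before the new stop) for a frameshift.
#' Synonymous variants and changes producing no novel residue (immediate
#' stop, truncation) yield an empty-context sentinel.
#'
#' @param gene Gene symbol.
#' @param wildtype Wild-type amino-acid sequence (20-letter alphabet).
#' @param consequence A [variant_consequence()].
#' @return A `protein_context` list with `gene`, `wildtype_sequence`,
#'   `mutant_sequence`, `altered_positions` (empty when no novel peptide can
#'   arise; `reason` then says why).
#' @export
build_mutant_context <- function(gene, wildtype, consequence) {
  stopifnot(inherits(consequence, "variant_consequence"))
  L <- nchar(wildtype)
  p <- consequence$pos
  if (p < 1L || p > L) .param_error("consequence position outside protein")
  k <- consequence$kind

  if (k == "synonymous") {
    return(.empty_context(gene, wildtype, "not nonsilent"))
  }
  if (k == "stop_gained") {
    return(.empty_context(gene, wildtype, "truncation introduces no novel residue"))
  }
  if (k == "missense") {
    if (!is.null(consequence$ref_aa) &&
        substr(wildtype, p, p) != consequence$ref_aa) {
      .param_error("reference residue mismatch at position ", p)
    }
    if (identical(consequence$alt_aa, "*")) {
      return(.empty_context(gene, wildtype, "immediate stop"))
    }
    mutant <- wildtype
    substr(mutant, p, p) <- consequence$alt_aa
    altered <- p
  } else if (k == "inframe_insertion") {
    ins <- consequence$ins_seq
    mutant <- paste0(substr(wildtype, 1, p), ins, substr(wildtype, p + 1, L))
    altered <- intersect(p:(p + nchar(ins) + 1L), seq_len(nchar(mutant)))
  } else if (k == "inframe_deletion") {
    dl <- consequence$del_len
    if (p + dl - 1L > L) .param_error("deletion runs past protein end")
    mutant <- paste0(substr(wildtype, 1, p - 1L), substr(wildtype, p + dl, L))
    altered <- intersect(c(p - 1L, p), seq_len(nchar(mutant)))
  } else {  # frameshift
    tail_seq <- consequence$tail
    if (is.null(tail_seq) || nchar(tail_seq) == 0L) {
      return(.empty_context(gene, wildtype, "immediate stop"))
    }
    mutant <- paste0(substr(wildtype, 1, p - 1L), tail_seq)
    altered <- p:nchar(mutant)
  }
  if (length(altered) == 0L) {
    return(.empty_context(gene, wildtype, "no altered residue"))
  }
  structure(list(gene = gene, wildtype_sequence = wildtype,
                 mutant_sequence = mutant,
                 altered_positions = as.integer(altered), reason = NULL),
            class = "protein_context")
}

.kmers <- function(seq, k = 9L) {
  L <- nchar(seq)
  if (L < k) return(character(0))
  substring(seq, 1:(L - k + 1L), k:L)
}

#' Enumerate novel mutant 9-mers
#'
#' All 9-residue windows of the mutant sequence that overlap at least one
#' altered position, minus any peptide that also occurs as a wild-type 9-mer
#' of the same protein; duplicates removed keeping leftmost-first order.
#'
#' @param context A `protein_context` from [build_mutant_context()].
#' @param k Peptide length (default 9).
#' @return Character vector of novel peptides (possibly empty).
#' @export
enumerate_9mers <- function(context, k = 9L) {
  mut <- context$mutant_sequence
  altered <- context$altered_positions
  L <- nchar(mut)
  if (L < k || length(altered) == 0L) return(character(0))
  starts <- 1:(L - k + 1L)
  hit <- vapply(starts, function(s) any(altered >= s & altered <= s + k - 1L),
                logical(1))
  peptides <- substring(mut, starts[hit], starts[hit] + k - 1L)
  wt_set <- .kmers(context$wildtype_sequence, k)
  unique(peptides[!peptides %in% wt_set])
}

#' Rank neoepitope candidates
#'
#' `rank_score = log2(TPM + 1) x VAF`, sorted descending; ties broken by
#' ascending IC50, then lexicographic peptide.  The combiner of the two
#' ranking keys (expression and allele frequency) is a package choice and is
#' configurable via `score_fn`.
#'
#' @param candidates data.frame with columns `peptide`, `tpm`, `vaf`,
#'   `ic50_nm` (and anything else, carried through).
#' @param score_fn Function(tpm, vaf) -> score.
#' @return `candidates` ordered by rank with a `rank_score` column.
#' @export
rank_candidates <- function(candidates,
                            score_fn = function(tpm, vaf) log2_tpm(tpm) * vaf) {
  if (nrow(candidates) == 0L) {
    candidates$rank_score <- numeric(0)
    return(candidates)
  }
  if (any(candidates$vaf <= 0) || any(candidates$vaf > 1)) {
    .param_error("vaf must be in (0, 1]")
  }
  candidates$rank_score <- score_fn(candidates$tpm, candidates$vaf)
  ord <- order(-candidates$rank_score, candidates$ic50_nm, candidates$peptide)
  out <- candidates[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Best predicted binding per peptide over the patient's HLA alleles
#'
#' Scores every peptide against every class I allele and keeps the lowest
#' (strongest) IC50.  Peptides for which the predictor fails (error or NA on
#' all alleles) are dropped with a warning.
#'
#' @param peptides Character vector of peptides.
#' @param alleles Patient HLA class I alleles.
#' @param predictor Function(peptide, allele) -> IC50 in nM (see
#'   [synthetic_binding_predictor()] / [lookup_binding_predictor()]).
#' @return data.frame with `peptide`, `hla_allele` (best), `ic50_nm`.
#' @export
predict_best_ic50 <- function(peptides, alleles, predictor) {
  rows <- lapply(peptides, function(pep) {
    vals <- vapply(alleles, function(al) {
      v <- tryCatch(predictor(pep, al), error = function(e) NA_real_)
      if (is.null(v) || length(v) != 1L) NA_real_ else as.numeric(v)
    }, numeric(1))
    if (all(is.na(vals))) {
      warning("binding prediction failed for peptide ", pep,
              "; candidate dropped", call. = FALSE)
      return(NULL)
    }
    best <- which.min(vals)
    data.frame(peptide = pep, hla_allele = alleles[best],
               ic50_nm = vals[best], stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(peptide = character(0), hla_allele = character(0),
                      ic50_nm = numeric(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Apply the three selection criteria
#'
#' Keeps ranked candidates whose source variant is present in the
#' pretreatment sample, whose best IC50 is at most `ic50_max_nm` (200 nM) and
#' whose expression is at least `tpm_min` (raw TPM >= 4 by default;
#' `tpm_on_log` switches the threshold to the log2(TPM+1) scale), truncated
#' to `max_per_patient` by rank.  Selection is a pure filter: the selected
#' set is a subset of the ranked set with order preserved.
#'
#' @param ranked Output of [rank_candidates()]; needs a logical
#'   `present_pretreatment` column.
#' @param max_per_patient Cap on candidates per patient (default 12).
#' @param ic50_max_nm IC50 cutoff in nM.
#' @param tpm_min Expression cutoff.
#' @param tpm_on_log Apply `tpm_min` to log2(TPM+1) instead of raw TPM.
#' @return `ranked` with a logical `selected` column (TRUE for at most
#'   `max_per_patient` rows).
#' @export
select_candidates <- function(ranked, max_per_patient = 12,
                              ic50_max_nm = 200, tpm_min = 4,
                              tpm_on_log = FALSE) {
  expr <- if (tpm_on_log) log2_tpm(ranked$tpm) else ranked$tpm
  pass <- ranked$present_pretreatment & ranked$ic50_nm <= ic50_max_nm &
    expr >= tpm_min
  pass[is.na(pass)] <- FALSE
  idx <- which(pass)
  if (length(idx) > max_per_patient) idx <- idx[seq_len(max_per_patient)]
  ranked$selected <- FALSE
  ranked$selected[idx] <- TRUE
  ranked
}
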