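# Pluggable peptide-MHC binding predictor interface.
#
# A predictor is any function(peptide, hla_allele) -> IC50 in nM that is
# deterministic for fixed inputs.  Binding prediction itself is outside this
# package's scope; two implementations of the interface are provided: a
# file/table-backed lookup, and a deterministic synthetic stand-in for
# simulated cohorts.

#' Table-backed binding predictor
#'
#' @param table data.frame with columns `peptide`, `allele`, `ic50_nm` (e.g.
#'   read from a precomputed predictions TSV).
#' @return Predictor function(peptide, allele) -> IC50 (NA when absent from
#'   the table).
#' @export
lookup_binding_predictor <- function(table) {
  stopifnot(all(c("peptide", "allele", "ic50_nm") %in% names(table)))
  key <- paste(table$peptide, table$allele)
  ic50 <- stats::setNames(table$ic50_nm, key)
  function(peptide, allele) {
    v <- ic50[paste(peptide, allele)]
    unname(v)
  }
}

#' Synthetic binding predictor (deterministic stand-in)
#'
#' Hash-seeded deterministic IC50 values: each (peptide, allele) pair maps to
#' a uniform deviate; a `strong_fraction` of pairs fall in the strong-binder
#' range (IC50 <= 200 nM by default), the rest in the weak range.  Purely a
#' synthetic stand-in for simulation -- no biophysics.
#'
#' @param strong_fraction Fraction of pairs assigned a strong-binder IC50.
#' @param strong_range,weak_range IC50 ranges (nM) for the two classes.
#' @param salt String mixed into the hash so different cohorts can have
#'   independent assignments.
#' @return Predictor function(peptide, allele) -> IC50 in nM.
#' @export
synthetic_binding_predictor <- function(strong_fraction = 0.15,
                                        strong_range = c(20, 200),
                                        weak_range = c(250, 5000),
                                        salt = "") {
  .check_proportion(strong_fraction, "strong_fraction")
  function(peptide, allele) {
    u <- .hash_unit(paste0(salt, peptide, "|", allele))
    if (strong_fraction > 0 && u < strong_fraction) {
      w <- u / strong_fraction
      strong_range[1] + w * diff(strong_range)
    } else {
      w <- if (strong_fraction < 1) (u - strong_fraction) / (1 - strong_fraction) else 0
      weak_range[1] + w * diff(weak_range)
    }
  }
}
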